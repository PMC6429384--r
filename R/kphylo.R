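# Alignment-free k-mer distance phylogeny of monomer/consensus sequences,
# rooted on the ancestral monomer.

#' Parameters for the k-mer phylogeny
#'
#' @param k k-mer length (4..15; default 9, chosen for ~40-400 bp monomers).
#' @param distance_form `"one_minus_F"` (default) or `"neg_log_F"` where `F`
#'   is the fractional common k-mer count
#'   `|P1 n P2| / min(|P1|, |P2|)` over distinct k-mer sets.
#' @param circular treat sequences as circular when profiling (default TRUE
#'   for monomers: rotation then cannot change the profile).
#' @return list of class `kphylo_params`.
#' @export
kphylo_params <- function(k = 9, distance_form = c("one_minus_F", "neg_log_F"),
                          circular = TRUE) {
  stopifnot(k >= 4, k <= 15)
  distance_form <- match.arg(distance_form)
  structure(list(k = as.integer(k), distance_form = distance_form,
                 circular = circular), class = "kphylo_params")
}

#' Distinct k-mer profile of a sequence
#'
#' The sequence is canonicalized (lexicographically smallest rotation over
#' both strands) before profiling so that monomer phase and strand cannot
#' affect distances; if `circular`, the first `k - 1` bases are appended so
#' the profile wraps.
#'
#' @param seq DNA string of length >= `k`.
#' @param params a [kphylo_params()].
#' @return character vector of distinct k-mers.
#' @export
kmer_profile <- function(seq, params = kphylo_params()) {
  k <- params$k
  if (nchar(seq) < k) stop("sequence shorter than k")
  s <- canonical_rotation(seq)
  if (params$circular) s <- paste0(s, substr(s, 1, k - 1))
  n <- nchar(s)
  unique(substring(s, 1:(n - k + 1), k:n))
}

#' Fractional common k-mer distance between two profiles
#'
#' `F = |p1 n p2| / min(|p1|, |p2|)`; `one_minus_F` gives `d = 1 - F` in
#' `[0, 1]`, `neg_log_F` gives `d = -ln(max(F, eps))` with
#' `eps = 1 / (|p1| + |p2| + 1)`.
#'
#' @param p1,p2 non-empty k-mer profiles (character vectors).
#' @param params a [kphylo_params()].
#' @return the distance (numeric scalar).
#' @export
fractional_common_distance <- function(p1, p2, params = kphylo_params()) {
  if (!length(p1) || !length(p2)) stop("empty profile")
  F <- length(intersect(p1, p2)) / min(length(p1), length(p2))
  if (params$distance_form == "one_minus_F") {
    1 - F
  } else {
    -log(max(F, 1 / (length(p1) + length(p2) + 1)))
  }
}

#' k-mer distance matrix over a set of sequences
#'
#' @param seqs named character vector of DNA sequences.
#' @param params a [kphylo_params()].
#' @return symmetric distance matrix with zero diagonal.
#' @export
kmer_distance_matrix <- function(seqs, params = kphylo_params()) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  profs <- lapply(seqs, kmer_profile, params = params)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- fractional_common_distance(profs[[i]], profs[[j]], params)
    }
  }
  D
}

#' Minimum-evolution tree from a distance matrix, rooted on the ancestral leaf
#'
#' Neighbor-joining starting topology, OLS branch lengths and
#' nearest-neighbour-interchange hill climbing under the minimum-evolution
#' criterion; negative branch lengths are clamped to zero after the search
#' and the tree is rooted on the leaf labelled `root_label`.
#'
#' @param D symmetric non-negative distance matrix (>= 3 labels).
#' @param root_label leaf to root on (default `"ancestral"`); `NULL` leaves
#'   the tree unrooted.
#' @return an [ape::phylo] tree.
#' @export
me_tree <- function(D, root_label = "ancestral") {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need >= 3 labels")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("negative distances")
  tr <- ape::fastme.ols(stats::as.dist(D), nni = TRUE)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(root_label)) {
    if (!root_label %in% tr$tip.label) {
      stop("root label '", root_label, "' not among leaves")
    }
    tr <- ape::root(tr, outgroup = root_label, resolve.root = TRUE)
  }
  tr
}

#' Full monomer tree pipeline: sequences to Newick
#'
#' Canonicalize, profile, compute fractional-common-k-mer distances, build
#' the minimum-evolution tree rooted on the `ancestral` reference, and
#' serialize to Newick.  Fully deterministic.
#'
#' @param seqs named character vector of monomer/consensus sequences,
#'   including one named `ancestral` (see [family_reference()]).
#' @param params a [kphylo_params()].
#' @return a Newick string.
#' @export
monomer_tree_pipeline <- function(seqs, params = kphylo_params()) {
  stopifnot(length(seqs) >= 3)
  D <- kmer_distance_matrix(seqs, params)
  if ("ancestral" %in% names(seqs)) {
    write_newick(me_tree(D, root_label = "ancestral"))
  } else {
    ape::write.tree(me_tree(D, root_label = NULL))
  }
}
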