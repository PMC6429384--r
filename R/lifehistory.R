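# Family membership, homogenization metrics and classification of each
# lineage's satDNA evolutionary mode.

#' Does a consensus belong to the satDNA family?
#'
#' True iff a local alignment between the consensus (both strands,
#' circularly doubled) and the family reference reaches `min_identity`
#' percent over at least `min_len` aligned bases.  A self-contained
#' stand-in for a BLAST confirmation against the family reference.
#'
#' @param consensus DNA string to test.
#' @param reference family reference: a [family_reference()] record or DNA
#'   string (default: the shipped 37-bp ancestral fragment).
#' @param min_identity minimum percent identity.
#' @param min_len minimum aligned length (bases).
#' @return list with `member` (logical), `identity`, `aligned_len`,
#'   `strand`.
#' @export
family_membership <- function(consensus, reference = family_reference(),
                              min_identity = 70, min_len = 15) {
  refseq <- if (is.data.frame(reference)) reference$sequence[1] else as.character(reference)
  if (!nchar(refseq)) stop("empty reference")
  dc <- double_circ(consensus)
  best <- list(member = FALSE, identity = 0, aligned_len = 0L, strand = "+")
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dc else revcomp(dc)
    al <- sw_align_cpp(s, refseq)
    cols <- al$columns
    if (!cols) next
    idy <- 100 * al$matches / cols
    if (idy * cols > best$identity * best$aligned_len || best$aligned_len == 0) {
      best <- list(member = idy >= min_identity && cols >= min_len,
                   identity = idy, aligned_len = cols, strand = strand)
    }
  }
  best
}

#' Homogenization index of a species' monomer set
#'
#' Mean pairwise identity among sampled monomers (canonical rotation and
#' strand, gap-tolerant global alignment), mapped to `[0, 1]`.  High values
#' indicate concerted evolution (ongoing homogenization); low values
#' indicate accumulated multidirectional divergence.
#'
#' @param monomers character vector of >= 10 monomer sequences.
#' @param max_sample sampling cap (pairwise cost grows quadratically).
#' @param seed integer seed for the sampling.
#' @return numeric in `[0, 1]`.
#' @export
homogenization_index <- function(monomers, max_sample = 200, seed = 1) {
  if (length(monomers) < 10) stop("need >= 10 monomers")
  if (length(monomers) > max_sample) {
    monomers <- with_seed(seed, sample(monomers, max_sample))
  }
  canon <- vapply(monomers, canonical_rotation, character(1), USE.NAMES = FALSE)
  n <- length(canon)
  tot <- 0; cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    # identical canonical forms need no alignment; otherwise identity at the
    # best rotation/strand (monomer phase is arbitrary)
    idy <- if (canon[i] == canon[j]) 100 else rotational_identity(monomers[i], monomers[j])
    tot <- tot + idy; cnt <- cnt + 1
  }
  (tot / cnt) / 100
}

#' Classify a lineage's satDNA evolutionary mode
#'
#' Three modes: `non_concerted` (multiple family clusters or a low
#' homogenization index: low homogenization with multidirectional trends),
#' `concerted_hor` (concerted evolution with a trend toward increased
#' monomer complexity/length, i.e. proposed HOR units present), and
#' `concerted_mutational` (concerted evolution with mutation and
#' recombination only).
#'
#' @param species species name.
#' @param n_family_clusters number of family clusters in the genome.
#' @param n_hor_units number of proposed HOR units.
#' @param homogenization_index value in `[0, 1]` from
#'   [homogenization_index()].
#' @param multi_cluster_min clusters at or above which the family is
#'   considered fragmented (non-concerted signal).
#' @param h_min homogenization index below which evolution is considered
#'   non-concerted.
#' @return list of class `evolution_classification` with the metrics, the
#'   `mode`, the thresholds and a free-text `evidence` audit trail.
#' @export
classify_lineage <- function(species, n_family_clusters, n_hor_units,
                             homogenization_index,
                             multi_cluster_min = 3, h_min = 0.75) {
  stopifnot(homogenization_index >= 0, homogenization_index <= 1)
  if (n_family_clusters >= multi_cluster_min || homogenization_index < h_min) {
    mode <- "non_concerted"
    why <- sprintf("clusters=%d (>=%d) or index=%.3f (<%.2f)",
                   n_family_clusters, multi_cluster_min,
                   homogenization_index, h_min)
  } else if (n_hor_units >= 1) {
    mode <- "concerted_hor"
    why <- sprintf("%d proposed HOR unit(s), index=%.3f",
                   n_hor_units, homogenization_index)
  } else {
    mode <- "concerted_mutational"
    why <- sprintf("single/few clusters (%d), no HOR units, index=%.3f",
                   n_family_clusters, homogenization_index)
  }
  structure(list(species = species,
                 n_family_clusters = n_family_clusters,
                 n_hor_units = n_hor_units,
                 homogenization_index = homogenization_index,
                 mode = mode,
                 thresholds = c(multi_cluster_min = multi_cluster_min,
                                h_min = h_min),
                 evidence = why),
            class = "evolution_classification")
}

#' Assemble the per-species report
#'
#' One record per species with its metrics, mode and tree placement;
#' serializable to JSON.  Missing stages are flagged rather than fatal.
#'
#' @param classifications list of [classify_lineage()] results.
#' @param tree_newick Newick string of the monomer tree (or `NA`).
#' @param inventories per-species HOR counts (named integer vector, or
#'   `NULL`).
#' @return list with `species` (list of per-species records), `tree`,
#'   `complete` (logical flag).
#' @export
lifehistory_report <- function(classifications, tree_newick = NA_character_,
                               inventories = NULL) {
  recs <- lapply(classifications, function(cl) {
    list(species = cl$species,
         n_family_clusters = cl$n_family_clusters,
         n_hor_units = cl$n_hor_units,
         homogenization_index = cl$homogenization_index,
         mode = cl$mode,
         evidence = cl$evidence)
  })
  names(recs) <- vapply(classifications, `[[`, character(1), "species")
  complete <- !is.na(tree_newick) && length(recs) > 0
  list(species = recs, tree = tree_newick,
       hor_counts = as.list(inventories), complete = complete)
}

#' Validate a life-history report against its schema
#'
#' @param report a list as returned by [lifehistory_report()] (possibly
#'   round-tripped through JSON).
#' @return `TRUE` if valid, otherwise a character vector of problems.
#' @export
validate_report <- function(report) {
  probs <- character(0)
  if (!is.list(report$species)) probs <- c(probs, "missing species records")
  need <- c("species", "n_family_clusters", "n_hor_units",
            "homogenization_index", "mode")
  for (r in report$species) {
    miss <- setdiff(need, names(r))
    if (length(miss)) probs <- c(probs, paste("record missing:", paste(miss, collapse = ",")))
    if (!is.null(r$mode) && !r$mode %in%
        c("concerted_mutational", "concerted_hor", "non_concerted")) {
      probs <- c(probs, paste("bad mode:", r$mode))
    }
  }
  if (length(probs)) probs else TRUE
}
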