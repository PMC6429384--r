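# Reconstruction of the conserved ancestral monomer fragment from exact
# shared substrings across species monomer sets.  Monomers are circular
# (phase is arbitrary), so each is doubled (s + s minus the last base)
# before substring search, and both strands are considered.

# the family's reconstructed 37-bp conserved ancestral fragment, shipped as
# the default reference for membership tests and tree rooting
ANCESTRAL_37 <- "TCAAACAAAGCTAATTGAATCAAATGAAAGTCAAATG"

double_circ <- function(s) {
  n <- nchar(s)
  substr(paste0(s, s), 1, 2 * n - 1)
}

#' Maximal exact shared substrings between two monomer sets
#'
#' All maximal substrings of length >= `min_len` occurring exactly (100%
#' identity) in at least one monomer of each set, treating monomers as
#' circular strings and considering both strands of set `b`.  Maximality is
#' per supporting pair: the match is not extendable on either side.
#' Fragment length is capped at the monomer length (a circular self-overlap
#' cannot exceed one full turn).
#'
#' @param monomers_a,monomers_b character vectors of monomer sequences.
#' @param min_len minimum fragment length (>= 4).
#' @return data.frame with columns `sequence`, `length`, `a_id`, `a_start`,
#'   `b_id`, `b_start`, `strand` (of the match in `b`); starts are 1-based
#'   positions modulo the monomer length (circular coordinates).
#' @export
shared_exact_fragments <- function(monomers_a, monomers_b, min_len = 8) {
  if (min_len < 4) stop("min_len < 4 rejected (chance matches)")
  if (!length(monomers_a) || !length(monomers_b)) stop("empty monomer set")
  out <- list()
  for (ia in seq_along(monomers_a)) {
    a <- monomers_a[ia]
    da <- double_circ(a)
    la <- nchar(a)
    for (ib in seq_along(monomers_b)) {
      b <- monomers_b[ib]
      lb <- nchar(b)
      for (strand in c("+", "-")) {
        db <- double_circ(if (strand == "+") b else revcomp(b))
        runs <- max_shared_substrings_cpp(da, db, min_len)
        if (!nrow(runs)) next
        # cap at one full turn and keep only runs whose start lies in the
        # first copy of the doubled strings (avoid duplicated reports)
        runs$length <- pmin(runs$length, la, lb)
        keep <- runs$a_start <= la & runs$b_start <= lb & runs$length >= min_len
        runs <- runs[keep, , drop = FALSE]
        if (!nrow(runs)) next
        runs$sequence <- substring(da, runs$a_start,
                                   runs$a_start + runs$length - 1L)
        out[[length(out) + 1L]] <- data.frame(
          sequence = runs$sequence, length = runs$length,
          a_id = ia, a_start = runs$a_start,
          b_id = ib, b_start = runs$b_start, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(0), length = integer(0),
                      a_id = integer(0), a_start = integer(0),
                      b_id = integer(0), b_start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  # drop fragments strictly contained in another fragment of the same pair
  res <- res[order(-res$length), , drop = FALSE]
  res <- res[!duplicated(res[c("sequence", "a_id", "b_id", "a_start", "b_start")]), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# does `frag` occur exactly in any monomer of the set (circular, both strands)?
occurs_in_set <- function(frag, monomers) {
  for (m in monomers) {
    dm <- double_circ(m)
    if (grepl(frag, dm, fixed = TRUE) || grepl(frag, revcomp(dm), fixed = TRUE)) {
      return(TRUE)
    }
  }
  FALSE
}

find_support <- function(frag, monomers) {
  sup <- list()
  lf <- nchar(frag)
  for (i in seq_along(monomers)) {
    lm <- nchar(monomers[i])
    for (strand in c("+", "-")) {
      dm <- double_circ(if (strand == "+") monomers[i] else revcomp(monomers[i]))
      hit <- regexpr(frag, dm, fixed = TRUE)
      if (hit > 0 && hit <= lm) {
        sup[[length(sup) + 1L]] <- data.frame(
          monomer = i, start = as.integer(hit), end = as.integer(hit) + lf - 1L,
          strand = strand, rotation_offset = as.integer(hit) - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(sup)) do.call(rbind, c(sup, list(make.row.names = FALSE))) else NULL
}

#' Reconstruct the conserved ancestral monomer fragment
#'
#' Computes exact shared fragments between a reference species and every
#' other species, merges overlapping supported intervals on the reference
#' monomers, and returns the longest merged conserved region that occurs
#' exactly in at least one monomer of every species.  Deterministic
#' tie-break: longest, then lexicographically smallest canonical sequence.
#'
#' @param monomer_sets named list (>= 2 species) of monomer character
#'   vectors.
#' @param min_len minimum fragment length (bp).
#' @return an object of class `ancestral_fragment`: list with `sequence`,
#'   `length` and `support` (per species data.frame of monomer id, start,
#'   end, strand, rotation offset).
#' @export
reconstruct_ancestral <- function(monomer_sets, min_len = 8) {
  stopifnot(length(monomer_sets) >= 2)
  sets <- monomer_sets
  ref_sp <- names(sets)[1]
  ref <- sets[[1]]
  others <- sets[-1]

  # per reference monomer, positions (on the doubled string, first turn)
  # supported by a shared fragment with every other species
  candidates <- character(0)
  for (im in seq_along(ref)) {
    lm <- nchar(ref[im])
    cov <- matrix(FALSE, length(others), 2 * lm - 1)
    for (io in seq_along(others)) {
      fr <- shared_exact_fragments(ref[im], others[[io]], min_len)
      for (r in seq_len(nrow(fr))) {
        cov[io, fr$a_start[r]:(fr$a_start[r] + fr$length[r] - 1L)] <- TRUE
      }
    }
    shared <- apply(cov, 2, all)
    r <- rle(shared)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_len)) {
      len <- min(r$lengths[j], lm)
      candidates <- c(candidates,
                      substr(double_circ(ref[im]), starts[j], starts[j] + len - 1L))
    }
  }
  candidates <- unique(candidates)
  # a merged region must itself occur exactly in all species (incl. reference)
  ok <- candidates[vapply(candidates, function(fr) {
    all(vapply(sets, function(ms) occurs_in_set(fr, ms), logical(1)))
  }, logical(1))]
  # maximal candidates can still be trimmed if the full merged run is not
  # shared by all; fall back to longest common prefixes is not attempted —
  # instead also test all sub-runs obtained by shrinking from either side
  if (!length(ok) && length(candidates)) {
    for (cand in candidates[order(-nchar(candidates))]) {
      if (nchar(cand) - 1L < min_len) next
      for (len in seq(nchar(cand) - 1L, min_len, by = -1L)) {
        subs <- substring(cand, 1:(nchar(cand) - len + 1L),
                          len:nchar(cand))
        hit <- subs[vapply(subs, function(fr) {
          all(vapply(sets, function(ms) occurs_in_set(fr, ms), logical(1)))
        }, logical(1))]
        if (length(hit)) { ok <- hit; break }
      }
      if (length(ok)) break
    }
  }
  if (!length(ok)) stop("no conserved core")
  lens <- nchar(ok)
  best <- ok[lens == max(lens)]
  canon <- vapply(best, canonical_rotation, character(1))
  frag <- best[order(canon)][1]
  support <- lapply(sets, function(ms) find_support(frag, ms))
  structure(list(sequence = frag, length = nchar(frag), support = support),
            class = "ancestral_fragment")
}

#' Family reference monomer record
#'
#' Packages an ancestral fragment as the family reference used by the
#' membership test and for rooting the k-mer tree.  Without an argument the
#' shipped 37-bp conserved ancestral fragment is used.
#'
#' @param ancestral an `ancestral_fragment`, a DNA string, or `NULL` for the
#'   default reference.
#' @return data.frame record with `id` (`"ancestral"`) and `sequence`.
#' @export
family_reference <- function(ancestral = NULL) {
  seqn <- if (is.null(ancestral)) {
    ANCESTRAL_37
  } else if (inherits(ancestral, "ancestral_fragment")) {
    ancestral$sequence
  } else {
    as.character(ancestral)
  }
  data.frame(id = "ancestral", sequence = seqn, stringsAsFactors = FALSE)
}
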