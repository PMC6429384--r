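#' Higher-order repeat (HOR) model
#'
#' A proposed HOR unit: a repeating unit composed of several diverged
#' subrepeats that amplifies as a block (e.g. a 117 bp unit of three 39 bp
#' subrepeats).
#'
#' @param unit_length unit length in bp.
#' @param subrepeat_length subrepeat length in bp.
#' @param subrepeat_count number of subrepeats per unit (>= 2).
#' @param subrepeat_identity_matrix pairwise percent identities among
#'   subrepeats (optional).
#' @param inter_unit_identity_range `(min, max)` percent identity among
#'   physical unit copies (optional).
#' @param source `(species, cluster)` provenance (optional).
#' @param consensus unit consensus sequence (optional).
#' @return a list of class `hor_model`.
#' @export
hor_model <- function(unit_length, subrepeat_length, subrepeat_count,
                      subrepeat_identity_matrix = NULL,
                      inter_unit_identity_range = NULL,
                      source = NULL, consensus = NULL) {
  stopifnot(subrepeat_count >= 2)
  if (abs(unit_length - subrepeat_count * subrepeat_length) > subrepeat_count) {
    stop("unit length inconsistent with subrepeat length x count (indel slack exceeded)")
  }
  structure(list(unit_length = unit_length,
                 subrepeat_length = subrepeat_length,
                 subrepeat_count = subrepeat_count,
                 subrepeat_identity_matrix = subrepeat_identity_matrix,
                 inter_unit_identity_range = inter_unit_identity_range,
                 source = source, consensus = consensus),
            class = "hor_model")
}

# cut a sequence into ceil(len/p) frames of nominal length p (last ragged)
cut_frames <- function(s, p) {
  n <- nchar(s)
  starts <- seq(1, n, by = p)
  substring(s, starts, pmin(starts + p - 1L, n))
}

#' Decompose a tandem consensus into subrepeats
#'
#' Scans subperiods `p` from `min_subrepeat` to half the consensus length,
#' cuts the consensus into frames of length `p` and computes the mean
#' pairwise frame identity (gap-tolerant global alignment).  The subperiod
#' maximizing mean identity is returned if it reaches
#' `min_internal_identity`; otherwise the consensus is not a HOR.
#'
#' @param consensus DNA string (>= 2 x `min_subrepeat`).
#' @param min_subrepeat shortest subrepeat considered (bp).
#' @param min_internal_identity minimum mean pairwise frame identity (%).
#' @param source optional `(species, cluster)` provenance.
#' @return a [hor_model()] or `NULL` if no subperiod qualifies.
#' @export
decompose_consensus <- function(consensus, min_subrepeat = 15,
                                min_internal_identity = 60, source = NULL) {
  len <- nchar(consensus)
  if (len < 2 * min_subrepeat) stop("consensus shorter than 2 x min_subrepeat")
  best <- NULL
  for (p in min_subrepeat:(len %/% 2)) {
    # the unit must be a near-integer multiple of the subperiod
    # (ragged units allowed up to one base of slack per subrepeat)
    k <- round(len / p)
    if (k < 2 || abs(len - k * p) > k) next
    frames <- cut_frames(consensus, p)
    if (nchar(frames[length(frames)]) < p / 2) frames <- frames[-length(frames)]
    if (length(frames) < 2) next
    nf <- length(frames)
    idm <- matrix(100, nf, nf)
    for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
      idm[i, j] <- idm[j, i] <- global_identity(frames[i], frames[j])
    }
    mean_id <- mean(idm[upper.tri(idm)])
    if (is.null(best) || mean_id > best$mean_id) {
      best <- list(p = p, mean_id = mean_id, idm = idm, k = k)
    }
  }
  if (is.null(best) || best$mean_id < min_internal_identity) return(NULL)
  hor_model(unit_length = len, subrepeat_length = best$p,
            subrepeat_count = best$k,
            subrepeat_identity_matrix = best$idm,
            source = source, consensus = consensus)
}

# correlation of per-copy mismatch profiles at frame lag `m` minus lag 1,
# computed at the shorter period: systematic mismatches recurring every m-th
# frame indicate that the true duplication unit is m frames long.
profile_consistency <- function(alignment, m) {
  copies <- alignment$copies
  if (is.null(copies) || nrow(copies) < 2 * m + 1) return(0)
  cons <- apply(copies, 2, function(col) {
    col <- col[!is.na(col) & col %in% DNA_BASES]
    if (!length(col)) return(NA_character_)
    DNA_BASES[which.max(table(factor(col, levels = DNA_BASES)))]
  })
  keep <- !is.na(cons)
  if (sum(keep) < 4) return(0)
  copies <- copies[, keep, drop = FALSE]
  cons <- cons[keep]
  mm <- t(apply(copies, 1, function(row) as.numeric(row != cons)))
  lag_cor <- function(lag) {
    vals <- c()
    for (i in 1:(nrow(mm) - lag)) {
      a <- mm[i, ]; b <- mm[i + lag, ]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 4) next
      a <- a[ok]; b <- b[ok]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      vals <- c(vals, cor(a, b))
    }
    if (!length(vals)) 0 else mean(vals)
  }
  lag_cor(m) - lag_cor(1)
}

#' Choose the unit of duplication among candidate periods
#'
#' Starting from the smallest candidate, a larger candidate period is
#' promoted to the unit if either (a) its percent matches exceeds the current
#' choice's by at least `margin` percentage points, or (b) it is a near
#' integer multiple `m` of the current choice, it fits at least as well
#' (percent matches not lower than the current choice's), and the positional mismatch
#' profile at the shorter period is consistent with an `m`-frame unit
#' (mismatches recur every `m`-th frame: lag-`m` profile correlation exceeds
#' lag-1 by more than `profile_margin`) *and* the long-period consensus is
#' built from genuinely diverged subrepeats (its internal frame identity
#' lies at least `min_hor_gap` points below the inter-unit percent matches).
#' Route (b) operationalizes the criterion that the mismatches and indels
#' must be more consistent with the longer monomer for it to be accepted as
#' the duplication unit.
#'
#' @param seq the tandem array sequence.
#' @param candidate_periods integer vector of candidate periods (>= 1 of
#'   them); periods above half the sequence length are ignored.
#' @param params a [tandem_params()] (provides `margin` and
#'   `profile_margin`).
#' @param cache optional named list of [refine_consensus()] results keyed by
#'   period, to avoid recomputation.
#' @return the chosen period (integer).
#' @export
choose_unit <- function(seq, candidate_periods, params = tandem_params(),
                        cache = list()) {
  cand <- sort(unique(as.integer(candidate_periods)))
  cand <- cand[cand >= 1 & cand <= nchar(seq) / 2]
  if (!length(cand)) {
    cand <- sort(unique(as.integer(candidate_periods)))
    if (!length(cand)) stop("empty candidate list")
    return(min(cand))
  }
  get_ref <- function(p) {
    key <- as.character(p)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- tryCatch(
        suppressWarnings(refine_consensus(seq, p, params)),
        error = function(e) NULL)
    }
    cache[[key]]
  }
  current <- cand[1]
  for (p in cand[-1]) {
    ref_cur <- get_ref(current); ref_p <- get_ref(p)
    if (is.null(ref_p)) next
    if (is.null(ref_cur)) { current <- p; next }
    if (ref_p$alignment$percent_matches >=
        ref_cur$alignment$percent_matches + params$margin) {
      current <- p
      next
    }
    m <- round(p / current)
    if (m >= 2 && abs(p - m * current) <= max(2, 0.02 * p) &&
        ref_p$alignment$percent_matches >=
          ref_cur$alignment$percent_matches &&
        profile_consistency(ref_cur$alignment, m) > params$profile_margin) {
      # a genuine higher-order unit is composed of diverged subrepeats: the
      # internal frame identity of the long-period consensus must sit well
      # below the inter-unit identity, otherwise the long period is a mere
      # harmonic of the short one
      frames <- cut_frames(ref_p$consensus, current)
      if (nchar(frames[length(frames)]) < current / 2) {
        frames <- frames[-length(frames)]
      }
      internal <- if (length(frames) >= 2) {
        ids <- c()
        for (fi in 1:(length(frames) - 1)) for (fj in (fi + 1):length(frames)) {
          ids <- c(ids, global_identity(frames[fi], frames[fj]))
        }
        mean(ids)
      } else 100
      if (ref_p$alignment$percent_matches - internal >= params$min_hor_gap) {
        current <- p
      }
    }
  }
  current
}

#' Percent-identity range among physical HOR unit copies
#'
#' Cuts the array into unit-length frames and reports the minimum and
#' maximum pairwise global-alignment identity.
#'
#' @param array_seq the tandem array DNA string (>= 2 unit copies).
#' @param model a [hor_model()] (its `unit_length` is used).
#' @return numeric `c(min, max)` percent identity.
#' @export
unit_similarity_range <- function(array_seq, model) {
  u <- model$unit_length
  frames <- cut_frames(array_seq, u)
  frames <- frames[nchar(frames) == u]
  if (length(frames) < 2) stop("array contains fewer than 2 unit copies")
  ids <- c()
  for (i in 1:(length(frames) - 1)) for (j in (i + 1):length(frames)) {
    ids <- c(ids, global_identity(frames[i], frames[j]))
  }
  c(min(ids), max(ids))
}

#' Inventory of proposed HOR units across species
#'
#' Every family tandem hit whose consensus decomposes into subrepeats and
#' whose unit length exceeds 1.5x the reference monomer length becomes a
#' proposed HOR unit; units are deduplicated at 95% identity (canonical
#' rotation/strand) within species.
#'
#' @param hits data.frame of tandem hits with columns `species`, `cluster`,
#'   `consensus`, `family_member` (logical).
#' @param reference_monomer_len length of the family's basic monomer (bp).
#' @param min_subrepeat,min_internal_identity passed to
#'   [decompose_consensus()].
#' @param dedup_identity percent identity above which two proposed units are
#'   the same unit.
#' @return list with `models` (list of [hor_model()]) and `counts` (named
#'   integer vector per species).
#' @export
hor_inventory <- function(hits, reference_monomer_len,
                          min_subrepeat = 15, min_internal_identity = 60,
                          dedup_identity = 95) {
  models <- list()
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      if (!isTRUE(hits$family_member[i])) next
      cons <- hits$consensus[i]
      if (nchar(cons) <= 1.5 * reference_monomer_len) next
      if (nchar(cons) < 2 * min_subrepeat) next
      m <- decompose_consensus(cons, min_subrepeat, min_internal_identity,
                               source = list(species = hits$species[i],
                                             cluster = hits$cluster[i]))
      if (is.null(m)) next
      dup <- FALSE
      for (prev in models) {
        if (!identical(prev$source$species, m$source$species)) next
        if (abs(nchar(prev$consensus) - nchar(cons)) > 0.2 * nchar(cons)) next
        if (rotational_identity(prev$consensus, cons) >= dedup_identity) {
          dup <- TRUE; break
        }
      }
      if (!dup) models[[length(models) + 1L]] <- m
    }
  }
  species <- unique(hits$species)
  counts <- setNames(integer(length(species)), species)
  for (m in models) counts[m$source$species] <- counts[m$source$species] + 1L
  list(models = models, counts = counts)
}
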