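#' Parameters for tandem repeat detection
#'
#' Alignment weights and the stochastic pattern model follow the familiar
#' tandem-repeat-finder regime (match +2, mismatch/indel penalty 7, pattern
#' model with 80% match and 10% indel probability, minimum score 50).
#'
#' @param match_weight,mismatch_penalty,indel_penalty alignment weights
#'   (penalties are positive numbers, subtracted).
#' @param match_prob,indel_prob stochastic pattern model probabilities used
#'   for the candidate-period support threshold.
#' @param min_score minimum wraparound alignment score to report a hit.
#' @param max_period largest candidate period considered (bp).
#' @param probe_kmer probe k-mer length for candidate-period discovery.
#' @param max_candidates number of top candidate periods examined in detail.
#' @param margin,profile_margin,min_hor_gap unit-choice thresholds, see
#'   [choose_unit()].
#' @return a list of class `tandem_params`.
#' @export
tandem_params <- function(match_weight = 2, mismatch_penalty = 7,
                          indel_penalty = 7, match_prob = 0.80,
                          indel_prob = 0.10, min_score = 50,
                          max_period = 500, probe_kmer = 5,
                          max_candidates = 8, margin = 10,
                          profile_margin = 0.5, min_hor_gap = 3) {
  stopifnot(match_prob > 0, match_prob < 1, indel_prob > 0, indel_prob < 1,
            min_score > 0)
  structure(as.list(environment()), class = "tandem_params")
}

#' Candidate tandem periods from probe k-mer recurrence
#'
#' For every distance `d` between re-occurrences of exact probe k-mers,
#' support is accumulated; candidates are local maxima of the support curve
#' exceeding a binomial-model threshold derived from the background k-mer
#' match probability.  Sorted by support, strongest first.
#'
#' @param seq DNA string (>= 20 bp).
#' @param params a [tandem_params()].
#' @return data.frame with columns `period` and `support`.
#' @export
candidate_periods <- function(seq, params = tandem_params()) {
  n <- nchar(seq)
  if (n < 20) stop("sequence shorter than 20 bp")
  k <- params$probe_kmer
  max_d <- min(params$max_period, n - k)
  if (max_d < 2) return(data.frame(period = integer(0), support = integer(0)))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  support <- integer(max_d)
  pos_by_kmer <- split(seq_along(kmers), kmers)
  for (pos in pos_by_kmer) {
    if (length(pos) < 2) next
    d <- diff(pos)  # successive occurrences capture the fundamental periods
    # also one further neighbour to support harmonics
    d2 <- if (length(pos) > 2) pos[-(1:2)] - pos[1:(length(pos) - 2)] else integer(0)
    dd <- c(d, d2)
    dd <- dd[dd <= max_d]
    if (length(dd)) {
      tab <- tabulate(dd, nbins = max_d)
      support <- support + tab
    }
  }
  # binomial null from base composition
  bases <- table(factor(s2c(seq), levels = DNA_BASES))
  p_base <- sum((bases / sum(bases))^2)
  p0 <- p_base^k
  d_all <- seq_len(max_d)
  m_d <- pmax(1L, n - k + 1L - d_all)
  # recurrences of one k-mer are not independent (a triple contributes
  # several distances), which fattens the tail beyond the binomial bound;
  # doubling the bound absorbs this while true tandem support (a large
  # fraction of all positions) remains far above it
  thr <- pmax(4, 2 * qbinom(1 - 0.001 / max_d, m_d, p0))
  ok <- which(support >= thr & support > 0)
  if (!length(ok)) return(data.frame(period = integer(0), support = integer(0)))
  # local maxima within a +/-2 window
  is_max <- vapply(ok, function(d) {
    win <- max(1, d - 2):min(max_d, d + 2)
    support[d] == max(support[win])
  }, logical(1))
  cand <- data.frame(period = ok[is_max], support = support[ok[is_max]])
  # collapse near-duplicate periods (+/-1), keeping the stronger
  cand <- cand[order(-cand$support, cand$period), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    close_by <- abs(cand$period - cand$period[i]) <= 1 & seq_len(nrow(cand)) > i
    keep[close_by] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  head(cand, params$max_candidates * 3L)
}

#' Wraparound alignment of a sequence against a cyclic pattern
#'
#' Dynamic programming of the whole sequence against tandem repetitions of
#' the pattern with free start/end phase.  Statistics are computed over all
#' alignment columns: `percent_matches = 100 * matches / columns`,
#' `percent_indels = 100 * indel columns / columns`.
#'
#' @param seq DNA string.
#' @param pattern non-empty DNA pattern (the cyclic unit).
#' @param params a [tandem_params()].
#' @return list with `score`, `percent_matches`, `percent_indels`,
#'   `columns`, `n_copies`, `copies` (character matrix of per-copy bases by
#'   pattern column, `NA` where a column was deleted in that copy) and
#'   `col_of_seq` (pattern column aligned to each sequence position, 0 for
#'   insertions).
#' @export
wraparound_align <- function(seq, pattern, params = tandem_params()) {
  stopifnot(nchar(pattern) > 0)
  r <- wrap_dp_cpp(seq, pattern, params$match_weight,
                   params$mismatch_penalty, params$indel_penalty)
  p <- nchar(pattern)
  col <- r$col_of_seq
  ch <- s2c(seq)
  aligned <- which(col > 0)
  copies <- NULL
  n_copies <- 0
  if (length(aligned)) {
    jj <- col[aligned]
    copy_idx <- cumsum(c(1L, diff(jj) < 0))  # wrap = column decreases
    n_copies <- max(copy_idx)
    copies <- matrix(NA_character_, n_copies, p)
    copies[cbind(copy_idx, jj)] <- ch[aligned]
  }
  list(score = r$score,
       percent_matches = 100 * r$matches / max(1L, r$columns),
       percent_indels = 100 * r$indels / max(1L, r$columns),
       columns = r$columns,
       matches = r$matches,
       n_copies = n_copies,
       copies = copies,
       col_of_seq = col)
}

#' Refine a period-length consensus by iterated wraparound alignment
#'
#' Cuts the sequence into period frames via the wraparound alignment, takes
#' the per-column majority base, and iterates align -> consensus until a
#' fixed point (at most 10 iterations).  On non-convergence the best-scoring
#' consensus seen is returned with a warning.
#'
#' @param seq DNA string containing >= 2 copies at the candidate period.
#' @param period candidate period (bp).
#' @param params a [tandem_params()].
#' @return list with `consensus` (in sequence phase), `alignment` (the final
#'   [wraparound_align()] result) and `converged`.
#' @export
refine_consensus <- function(seq, period, params = tandem_params()) {
  n <- nchar(seq)
  stopifnot(period >= 1, n >= 2 * period)
  # initial pattern: majority over in-phase frames
  starts <- seq(1, n - period + 1, by = period)
  frames <- substring(seq, starts, starts + period - 1L)
  cons <- majority_consensus(do.call(rbind, strsplit(frames, "")))
  best <- NULL
  converged <- FALSE
  seen <- character(0)
  for (it in 1:10) {
    al <- wraparound_align(seq, cons, params)
    if (is.null(best) || al$score > best$alignment$score) {
      best <- list(consensus = cons, alignment = al)
    }
    if (is.null(al$copies)) break
    # drop columns present in fewer than half the copies (deletion consensus)
    keep <- colSums(!is.na(al$copies)) >= max(1, nrow(al$copies) / 2)
    new_cons <- majority_consensus(al$copies[, keep, drop = FALSE])
    if (nchar(new_cons) < 2) break
    if (new_cons == cons) { converged <- TRUE; break }
    if (new_cons %in% seen) break  # cycle
    seen <- c(seen, cons)
    cons <- new_cons
  }
  if (!converged && it == 10) {
    warning("consensus refinement did not converge; returning best-scoring consensus")
  }
  final <- wraparound_align(seq, best$consensus, params)
  list(consensus = best$consensus, alignment = final, converged = converged)
}

#' Detect tandem repeats in a sequence
#'
#' For each candidate period the consensus is refined and the sequence
#' wraparound-aligned against it; hits with score at least `min_score` and at
#' least ~2 copies are emitted.  Overlapping hits at harmonically related
#' periods are resolved with the unit-choice rule (see [choose_unit()]): the
#' shortest period wins unless a longer one has decisively stronger match
#' support or a mismatch profile consistent with the longer unit.
#'
#' @param seq DNA string.
#' @param params a [tandem_params()].
#' @param seq_id identifier used in the output table.
#' @return data.frame of tandem hits: `seq_id`, `start`, `end` (0-based
#'   half-open), `period`, `copy_number`, `percent_matches`,
#'   `percent_indels`, `score`, `consensus` (canonical rotation), `chosen`
#'   (whether the hit survived unit choice).  Empty for non-repetitive input.
#' @export
detect_tandem <- function(seq, params = tandem_params(), seq_id = "seq") {
  n <- nchar(seq)
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), period = integer(0),
                      copy_number = numeric(0), percent_matches = numeric(0),
                      percent_indels = numeric(0), score = numeric(0),
                      consensus = character(0), chosen = logical(0),
                      stringsAsFactors = FALSE)
  if (n < 20) return(empty)
  cand <- candidate_periods(seq, params)
  cand <- cand[cand$period >= 2 & cand$period <= n / 2, , drop = FALSE]
  cand <- head(cand, params$max_candidates)
  if (!nrow(cand)) return(empty)
  hits <- list()
  aligns <- list()
  for (i in seq_len(nrow(cand))) {
    p <- cand$period[i]
    ref <- tryCatch(suppressWarnings(refine_consensus(seq, p, params)),
                    error = function(e) NULL)
    if (is.null(ref)) next
    al <- ref$alignment
    period_eff <- nchar(ref$consensus)
    copy_number <- n / period_eff
    if (al$score < params$min_score || copy_number < 1.9) next
    key <- as.character(period_eff)
    if (!is.null(aligns[[key]])) next  # refined to an already-seen period
    aligns[[key]] <- ref
    hits[[key]] <- data.frame(
      seq_id = seq_id, start = 0L, end = n, period = period_eff,
      copy_number = copy_number,
      percent_matches = al$percent_matches,
      percent_indels = al$percent_indels,
      score = al$score,
      consensus = canonical_rotation(ref$consensus),
      chosen = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  # the top-scoring hit defines the dominant repeat; the unit-of-duplication
  # question (basic monomer vs HOR) is arbitrated among its near-divisors
  base <- out$period[which.max(out$score)]
  harmonic <- vapply(out$period, function(p) {
    if (p > base) return(FALSE)
    m <- round(base / p)
    m >= 1 && abs(base - m * p) <= max(2, 0.02 * base)
  }, logical(1))
  fam <- out$period[harmonic]
  chosen_p <- choose_unit(seq, fam, params, cache = aligns)
  out$chosen <- out$period == chosen_p
  out <- out[order(-out$chosen, -out$score, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dominant self-alignment periods from exact 8-mer matches
#'
#' A stand-in for the self-to-self dot plot: the histogram of diagonal
#' offsets of exact 8-mer self-matches; parallel diagonals at offsets `p`,
#' `2p`, ... indicate tandem structure with motif length `p`.
#'
#' @param seq DNA string (>= 40 bp).
#' @param min_support minimum number of 8-mer matches at an offset.
#' @return data.frame with `offset` and `support`, strongest first.
#' @export
self_period_scan <- function(seq, min_support = 5) {
  n <- nchar(seq)
  stopifnot(n >= 40)
  k <- 8L
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  pos_by_kmer <- split(seq_along(kmers), kmers)
  support <- integer(n - k)
  for (pos in pos_by_kmer) {
    if (length(pos) < 2) next
    cmb <- utils::combn(pos, 2)
    d <- cmb[2, ] - cmb[1, ]
    support <- support + tabulate(d, nbins = n - k)
  }
  ok <- which(support >= min_support)
  data.frame(offset = ok, support = support[ok])[order(-support[ok]), ]
}
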