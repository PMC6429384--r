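# All-vs-all read-similarity graph clustering: a desk-scale stand-in for
# graph-based repeat identification from shotgun reads.

#' Parameters for read-similarity clustering
#'
#' Defaults mirror the published regime: hits above 90% identity over at
#' least 55% of the (shorter) read length; clusters kept at >= 0.01% of the
#' input reads.
#'
#' @param min_identity minimum percent identity of a local alignment hit.
#' @param min_coverage_fraction minimum aligned span as a fraction of the
#'   shorter read's length.
#' @param min_cluster_fraction minimum cluster size as a fraction of input
#'   reads.
#' @param max_reads sampling cap for all-vs-all comparison.
#' @param prefilter_kmer shared k-mer required before alignment (speed).
#' @param seed integer seed for sampling.
#' @return list of class `clustering_params`.
#' @export
clustering_params <- function(min_identity = 90, min_coverage_fraction = 0.55,
                              min_cluster_fraction = 0.0001,
                              max_reads = 20000, prefilter_kmer = 13,
                              seed = 1) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_coverage_fraction > 0, min_coverage_fraction <= 1,
            min_cluster_fraction >= 0)
  structure(as.list(environment()), class = "clustering_params")
}

#' Sample reads proportionally to genome size
#'
#' Per-species counts are proportional to the weights (largest-remainder
#' rounding), total at most `max_reads`; seeded and reproducible.
#'
#' @param reads named list (per species) of read character vectors.
#' @param genome_size_weights named positive weights, one per species.
#' @param max_reads total sample cap.
#' @param seed integer seed.
#' @return named list of sampled read vectors.
#' @export
sample_reads <- function(reads, genome_size_weights, max_reads, seed = 1) {
  sp <- names(reads)
  if (is.null(sp) || !all(sp %in% names(genome_size_weights))) {
    stop("weights must name every species in `reads`")
  }
  w <- genome_size_weights[sp]
  if (any(w <= 0)) stop("weights must be > 0")
  total <- min(max_reads, sum(lengths(reads)))
  quota <- total * w / sum(w)
  n_i <- floor(quota)
  rem <- quota - n_i
  short <- total - sum(n_i)
  if (short > 0) {
    add <- order(-rem)[seq_len(short)]
    n_i[add] <- n_i[add] + 1
  }
  n_i <- pmin(n_i, lengths(reads))
  out <- list()
  for (i in seq_along(sp)) {
    out[[sp[i]]] <- with_seed(hash31(paste0("sample:", sp[i]), seed), {
      reads[[sp[i]]][sort(sample(length(reads[[sp[i]]]), n_i[i]))]
    })
  }
  out
}

# candidate pairs sharing at least one exact k-mer (either strand)
prefilter_pairs <- function(reads, k) {
  n <- length(reads)
  rc <- revcomp(reads)
  kmer_ids <- function(s) {
    m <- nchar(s)
    if (m < k) return(character(0))
    unique(substring(s, 1:(m - k + 1), k:m))
  }
  kl <- lapply(seq_len(n), function(i) unique(c(kmer_ids(reads[i]),
                                                kmer_ids(rc[i]))))
  groups <- split(rep(seq_len(n), lengths(kl)), unlist(kl))
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups)) return(matrix(integer(0), ncol = 2))
  keys <- unlist(lapply(groups, function(v) {
    v <- sort(unique(v))
    if (length(v) < 2) return(numeric(0))
    cb <- utils::combn(v, 2)
    cb[1, ] * (n + 1) + cb[2, ]
  }), use.names = FALSE)
  keys <- sort(unique(keys))
  cbind(as.integer(keys %/% (n + 1)), as.integer(keys %% (n + 1)))
}

#' All-vs-all read similarity hits
#'
#' A hit is recorded for a read pair iff the best local alignment (either
#' strand) has identity above `min_identity` percent over an aligned span of
#' at least `min_coverage_fraction` of the shorter read.  Pairs are
#' prefiltered by a shared exact k-mer; alignment uses match +1, mismatch
#' -2, gap -3 scoring.  Hits are symmetric and stored once with `i < j`.
#'
#' @param reads character vector of reads (>= 2).
#' @param params a [clustering_params()].
#' @return data.frame with columns `i`, `j`, `identity`, `coverage`,
#'   `strand`.
#' @export
pairwise_hits <- function(reads, params = clustering_params()) {
  if (length(reads) < 2) stop("need >= 2 reads")
  reads <- toupper(unname(reads))
  cand <- prefilter_pairs(reads, params$prefilter_kmer)
  if (!nrow(cand)) {
    return(data.frame(i = integer(0), j = integer(0), identity = numeric(0),
                      coverage = numeric(0), strand = character(0)))
  }
  rc <- revcomp(reads)
  np <- nrow(cand)
  idy <- numeric(np); cov <- numeric(np); strand <- character(np)
  for (q in seq_len(np)) {
    i <- cand[q, 1]; j <- cand[q, 2]
    shorter <- min(nchar(reads[i]), nchar(reads[j]))
    best <- list(idy = -Inf, cov = 0, strand = "+", ok = FALSE)
    for (st in c("+", "-")) {
      b <- if (st == "+") reads[j] else rc[j]
      al <- sw_align_cpp(reads[i], b)
      cols <- al$columns
      id_q <- if (cols) 100 * al$matches / cols else 0
      span <- min(al$a_end - al$a_start + 1L, al$b_end - al$b_start + 1L)
      cv <- span / shorter
      ok <- id_q > params$min_identity && cv >= params$min_coverage_fraction
      better <- if (ok == best$ok) {
        id_q > best$idy || (id_q == best$idy && cv > best$cov)
      } else ok  # a qualifying alignment beats any non-qualifying one
      if (better) best <- list(idy = id_q, cov = cv, strand = st, ok = ok)
      if (ok) break  # a qualifying forward hit settles the pair
    }
    idy[q] <- best$idy; cov[q] <- best$cov; strand[q] <- best$strand
  }
  keep <- idy > params$min_identity & cov >= params$min_coverage_fraction
  res <- data.frame(i = cand[keep, 1], j = cand[keep, 2],
                    identity = idy[keep], coverage = cov[keep],
                    strand = strand[keep], stringsAsFactors = FALSE)
  res[order(res$i, res$j), , drop = FALSE]
}

#' Clusters as connected components of the read-similarity graph
#'
#' Components with >= 2 reads become clusters, ordered by size (largest
#' first) then by smallest read id; remaining reads are counted as singlets.
#'
#' @param hits data.frame with columns `i`, `j` (read indices).
#' @param n_reads total number of reads.
#' @return list with `clusters` (list of `repeat_cluster` objects: `id`,
#'   `read_ids`, `genome_fraction` placeholder, `contigs`) and `n_singlets`.
#' @export
connected_clusters <- function(hits, n_reads) {
  if (nrow(hits) && (max(hits$i, hits$j) > n_reads || min(hits$i, hits$j) < 1)) {
    stop("hit indices outside 1..n_reads")
  }
  g <- igraph::make_empty_graph(n = n_reads, directed = FALSE)
  if (nrow(hits)) {
    g <- igraph::add_edges(g, rbind(hits$i, hits$j))
  }
  comp <- igraph::components(g)
  members <- split(seq_len(n_reads), comp$membership)
  members <- members[lengths(members) >= 2]
  ord <- order(-lengths(members),
               vapply(members, min, numeric(1)))
  members <- members[ord]
  clusters <- lapply(seq_along(members), function(ci) {
    structure(list(id = ci, read_ids = members[[ci]],
                   genome_fraction = NA_real_, contigs = NULL,
                   family_member = NA),
              class = "repeat_cluster")
  })
  list(clusters = clusters,
       n_singlets = n_reads - sum(lengths(members)))
}

#' Filter clusters by abundance and set genome fractions
#'
#' Keeps clusters holding at least `min_cluster_fraction` of the input reads
#' and sets `genome_fraction = 100 * |reads| / n_reads`.
#'
#' @param clusters list of clusters from [connected_clusters()].
#' @param params a [clustering_params()].
#' @param n_reads total number of input reads (> 0).
#' @return filtered list of clusters with `genome_fraction` set.
#' @export
filter_clusters <- function(clusters, params, n_reads) {
  stopifnot(n_reads > 0)
  out <- list()
  for (cl in clusters) {
    frac <- length(cl$read_ids) / n_reads
    if (frac >= params$min_cluster_fraction) {
      cl$genome_fraction <- 100 * frac
      out[[length(out) + 1L]] <- cl
    }
  }
  out
}

#' Greedy consensus contigs for a cluster
#'
#' Overlap-layout-consensus at desk scale: seed with the longest read,
#' place reads onto the growing layout by best local alignment (>= 30 bp
#' overlap, >= 90% identity, either strand; highest-identity placements
#' first), extend the layout with overhangs, and take the column-majority
#' consensus.  Repeats
#' on leftover reads, so at least one contig is always emitted.  Contigs of
#' tandem arrays can be partially chimeric by construction (variant
#' combinations that do not exist in the genome); downstream consumers
#' treat them as consensus material only.
#'
#' @param cluster a `repeat_cluster`.
#' @param reads character vector of all reads (indexed by the cluster's
#'   `read_ids`).
#' @param min_overlap,min_identity placement thresholds.
#' @return character vector of contig sequences (longest first).
#' @export
build_contigs <- function(cluster, reads, min_overlap = 30, min_identity = 90) {
  ids <- cluster$read_ids
  rs <- toupper(unname(reads[ids]))
  if (length(rs) == 1) return(rs)
  contigs <- character(0)
  remaining <- seq_along(rs)
  rcs <- revcomp(rs)
  while (length(remaining)) {
    seed <- remaining[which.max(nchar(rs[remaining]))]
    placements <- list(list(seq = rs[seed], offset = 0L))
    layout <- rs[seed]
    remaining <- setdiff(remaining, seed)
    repeat {
      if (!length(remaining)) break
      # one evaluation pass against the current layout, then place the
      # qualifying reads in order of placement identity: identity tracks
      # tandem phase, so this keeps the layout phase-coherent instead of
      # letting ~90%-identity cross-phase placements scramble it
      cands <- list()
      for (q in remaining) {
        for (strand in c("+", "-")) {
          rq <- if (strand == "+") rs[q] else rcs[q]
          al <- sw_align_cpp(rq, layout)
          cols <- al$columns
          if (!cols) next
          idy <- 100 * al$matches / cols
          span <- min(al$a_end - al$a_start + 1L, al$b_end - al$b_start + 1L)
          if (span >= min_overlap && idy >= min_identity) {
            offset <- al$b_start - al$a_start
            # extensions are preferred over internal placements at equal
            # identity: tandem-periodic reads place equally well
            # internally, which would collapse the contig onto one period
            ext <- max(0, -offset) +
              max(0, offset + nchar(rq) - nchar(layout))
            val <- round(idy) * 1000 + span + 2 * ext
            if (is.null(cands[[as.character(q)]]) ||
                val > cands[[as.character(q)]]$val) {
              cands[[as.character(q)]] <- list(q = q, seq = rq, span = span,
                                               offset = offset, val = val)
            }
          }
        }
      }
      if (!length(cands)) break
      ordered <- cands[order(-vapply(cands, `[[`, numeric(1), "val"))]
      for (ci in seq_along(ordered)) {
        cand <- ordered[[ci]]
        off <- cand$offset
        if (off < 0) {
          pad <- -off
          layout <- paste0(substr(cand$seq, 1, pad), layout)
          for (ii in seq_along(placements)) {
            placements[[ii]]$offset <- placements[[ii]]$offset + pad
          }
          # shift the coordinates of the not-yet-placed candidates as well
          if (ci < length(ordered)) {
            for (k in (ci + 1):length(ordered)) {
              ordered[[k]]$offset <- ordered[[k]]$offset + pad
            }
          }
          off <- 0L
        }
        endpos <- off + nchar(cand$seq)
        if (endpos > nchar(layout)) {
          layout <- paste0(layout,
                           substr(cand$seq, nchar(layout) - off + 1L,
                                  nchar(cand$seq)))
        }
        placements[[length(placements) + 1L]] <- list(seq = cand$seq,
                                                      offset = off)
        remaining <- setdiff(remaining, cand$q)
      }
    }
    # column-majority consensus over placements
    L <- nchar(layout)
    m <- matrix(NA_character_, length(placements), L)
    for (ii in seq_along(placements)) {
      pl <- placements[[ii]]
      x <- s2c(pl$seq)
      cols <- pl$offset + seq_along(x)
      ok <- cols >= 1 & cols <= L
      m[ii, cols[ok]] <- x[ok]
    }
    contigs <- c(contigs, majority_consensus(m))
  }
  contigs[order(-nchar(contigs))]
}
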