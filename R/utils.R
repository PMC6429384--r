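#' @useDynLib satfam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor qbinom runif rpois rbinom rgeom setNames
#' @importFrom utils head write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

s2c <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

c2s <- function(x) paste0(x, collapse = "")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' @param n length in bases.
#' @return a DNA string of length `n`.
#' @export
random_dna <- function(n) {
  c2s(sample(DNA_BASES, n, replace = TRUE))
}

all_rotations <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(character(0))
  d <- paste0(s, s)
  substring(d, seq_len(n), seq_len(n) + n - 1L)
}

#' Canonical rotation of a circular DNA sequence
#'
#' Satellite monomers have arbitrary phase and strand; comparisons use the
#' lexicographically smallest rotation over both strands as the canonical
#' form.
#'
#' @param s a DNA string.
#' @return the canonical rotation (a DNA string of the same length).
#' @export
canonical_rotation <- function(s) {
  min(c(all_rotations(s), all_rotations(revcomp(s))))
}

#' Percent identity of the global alignment of two sequences
#'
#' Gap-tolerant: identity is computed over all alignment columns, including
#' internal gap columns (PID1 in Biostrings terms, extended to end gaps).
#'
#' @param a,b DNA strings.
#' @return percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b) {
  al <- nw_align_cpp(a, b)
  100 * al$matches / max(1L, al$columns)
}

sub_matrix <- function(match = 1, mismatch = -2) {
  m <- matrix(mismatch, 5, 5,
              dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
  diag(m) <- match
  m["N", ] <- m[, "N"] <- mismatch
  m
}

# identity over circular rotation + strand: pick the best-matching rotation
# of b (positional scan over both strands), then one gap-tolerant global
# alignment against it
rotational_identity <- function(a, b) {
  if (a == b) return(100)
  rots <- c(all_rotations(b), all_rotations(revcomp(b)))
  xa <- s2c(a)
  la <- length(xa)
  rot_chars <- strsplit(rots, "", fixed = TRUE)
  scores <- vapply(rot_chars, function(xr) {
    m <- min(la, length(xr))
    sum(xa[seq_len(m)] == xr[seq_len(m)])
  }, numeric(1), USE.NAMES = FALSE)
  global_identity(a, rots[which.max(scores)])
}

#' Mutate a DNA sequence by iid substitutions (and optional indels)
#'
#' @param s DNA string.
#' @param sub_rate per-site substitution probability.
#' @param indel_rate per-site probability of starting an indel (geometric
#'   length, mean 1.5).
#' @return mutated DNA string.
#' @export
mutate_seq <- function(s, sub_rate, indel_rate = 0) {
  x <- s2c(s)
  n <- length(x)
  hit <- which(runif(n) < sub_rate)
  for (i in hit) x[i] <- sample(setdiff(DNA_BASES, x[i]), 1)
  if (indel_rate > 0 && n > 2) {
    k <- rbinom(1, n, indel_rate)
    for (ev in seq_len(k)) {
      len <- 1 + rgeom(1, 2 / 3)  # mean 1.5
      pos <- sample(length(x), 1)
      if (runif(1) < 0.5) {
        x <- append(x, sample(DNA_BASES, len, replace = TRUE), after = pos)
      } else if (length(x) - len >= 2) {
        x <- x[-(pos:min(length(x), pos + len - 1))]
      }
    }
  }
  c2s(x)
}

# deterministic 31-bit hash of a string (for per-branch RNG streams)
hash31 <- function(s, seed = 0L) {
  h <- (as.double(seed) %% 2147483647) + 1
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

# evaluate expr under a local RNG stream, restoring global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# majority base per column of a character matrix (rows = copies), ties broken
# by fixed base order; NA entries ignored; columns with no bases dropped.
majority_consensus <- function(m) {
  cols <- apply(m, 2, function(col) {
    col <- col[!is.na(col) & col %in% DNA_BASES]
    if (!length(col)) return(NA_character_)
    tab <- table(factor(col, levels = DNA_BASES))
    DNA_BASES[which.max(tab)]
  })
  c2s(cols[!is.na(cols)])
}
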