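# Independent oracles used across the suite.  These deliberately do not
# share code with the package's implementation paths they check.

# plain-R wraparound DP (score only): iterate each row to a fixed point
wrap_dp_ref <- function(seq, pat, match = 2, mismatch = 7, indel = 7) {
  s <- strsplit(seq, "")[[1]]
  q <- strsplit(pat, "")[[1]]
  n <- length(s); p <- length(q)
  W <- matrix(-Inf, n + 1, p)
  W[1, ] <- 0
  for (i in 2:(n + 1)) {
    repeat {
      old <- W[i, ]
      for (j in 1:p) {
        jm <- if (j == 1) p else j - 1
        diag <- W[i - 1, jm] + if (s[i - 1] == q[j]) match else -mismatch
        up <- W[i - 1, j] - indel
        left <- W[i, jm] - indel
        W[i, j] <- max(diag, up, left)
      }
      if (identical(W[i, ], old)) break
    }
  }
  max(W[n + 1, ])
}

# union-find connected components
uf_components <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

# all circular substrings (both strands) of a monomer, length >= min_len
circ_substrings <- function(s, min_len) {
  out <- character(0)
  for (x in c(s, as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))) {
    L <- nchar(x)
    d <- substr(paste0(x, x), 1, 2 * L - 1)
    for (len in min_len:L) {
      for (st in 1:L) {
        if (st + len - 1 <= nchar(d)) out <- c(out, substr(d, st, st + len - 1))
      }
    }
  }
  unique(out)
}

# brute-force maximal shared substrings between two monomer sets
shared_bruteforce <- function(set_a, set_b, min_len) {
  subs_a <- unique(unlist(lapply(set_a, circ_substrings, min_len = min_len)))
  subs_b <- unique(unlist(lapply(set_b, circ_substrings, min_len = min_len)))
  common <- intersect(subs_a, subs_b)
  # maximal = not contained in a longer common substring
  keep <- vapply(common, function(x) {
    !any(nchar(common) > nchar(x) & vapply(common, function(y) {
      nchar(y) > nchar(x) && grepl(x, y, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  sort(common[keep])
}

# canonical form of a fragment for set comparisons (strand-insensitive)
frag_canon <- function(x) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  pmin(x, rc)
}

# positional mismatch fraction between equal-length strings
hamming_frac <- function(a, b) {
  xa <- strsplit(a, "")[[1]]; xb <- strsplit(b, "")[[1]]
  mean(xa != xb)
}
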