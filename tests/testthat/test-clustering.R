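test_that("pairwise hits: identity, strand handling, and negative control", {
  set.seed(9)
  r <- random_dna(100)
  hits <- pairwise_hits(c(r, r))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 100)
  expect_gte(hits$coverage, 1)

  # reverse complement must still hit
  hits_rc <- pairwise_hits(c(r, revcomp(r)))
  expect_equal(nrow(hits_rc), 1)
  expect_identical(hits_rc$strand, "-")

  # two unrelated random reads: no qualifying local alignment
  hits0 <- pairwise_hits(c(random_dna(100), random_dna(100)))
  expect_equal(nrow(hits0), 0)
  expect_error(pairwise_hits(character(0)), ">= 2")
})

test_that("connected components match a union-find oracle on random graphs", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 100
    m <- sample(30:120, 1)
    edges <- cbind(sample(n, m, TRUE), sample(n, m, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    hits <- data.frame(i = pmin(edges[, 1], edges[, 2]),
                       j = pmax(edges[, 1], edges[, 2]))
    cc <- connected_clusters(hits, n)
    oracle <- uf_components(as.matrix(hits), n)
    oracle_big <- Filter(function(v) length(v) >= 2, oracle)
    got <- lapply(cc$clusters, function(cl) sort(cl$read_ids))
    expect_setequal(
      vapply(got, paste, character(1), collapse = ","),
      vapply(oracle_big, function(v) paste(sort(v), collapse = ","), character(1)))
    expect_equal(cc$n_singlets, n - sum(lengths(oracle_big)))
  }
})

test_that("cluster ordering and trivial component cases", {
  hits <- data.frame(i = c(1, 2), j = c(2, 3))
  cc <- connected_clusters(hits, 4)
  expect_equal(length(cc$clusters), 1)
  expect_identical(cc$clusters[[1]]$read_ids, 1:3)
  expect_equal(cc$n_singlets, 1)

  cc0 <- connected_clusters(data.frame(i = integer(0), j = integer(0)), 5)
  expect_equal(length(cc0$clusters), 0)
  expect_equal(cc0$n_singlets, 5)
})

test_that("abundance filtering applies the input-read fraction threshold", {
  mk <- function(sz) structure(list(id = 1, read_ids = seq_len(sz)),
                               class = "repeat_cluster")
  p <- clustering_params()  # min fraction 1e-4
  expect_equal(length(filter_clusters(list(mk(1)), p, 100000)), 0)
  kept <- filter_clusters(list(mk(10)), p, 100000)
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]]$genome_fraction, 0.01)
  p0 <- clustering_params(min_cluster_fraction = 0)
  expect_equal(length(filter_clusters(list(mk(1), mk(2)), p0, 1e5)), 2)
})

test_that("genome fractions plus singlets account for every read", {
  set.seed(21)
  mono <- random_dna(40)
  arr <- paste(replicate(40, mutate_seq(mono, 0.03)), collapse = "")
  starts <- sample(nchar(arr) - 99, 60, replace = TRUE)
  reads <- c(substring(arr, starts, starts + 99),
             replicate(30, random_dna(100)))
  hits <- pairwise_hits(reads)
  cc <- connected_clusters(hits, length(reads))
  cl <- filter_clusters(cc$clusters, clustering_params(), length(reads))
  total <- sum(vapply(cl, function(x) x$genome_fraction, numeric(1))) +
    100 * cc$n_singlets / length(reads)
  expect_equal(total, 100, tolerance = 1e-6)
})

test_that("greedy contigs reassemble an error-free tiling", {
  set.seed(4)
  src <- random_dna(500)
  starts <- round(seq(1, 401, length.out = 10))
  reads <- substring(src, starts, starts + 99)
  cl <- structure(list(id = 1, read_ids = 1:10), class = "repeat_cluster")
  contigs <- build_contigs(cl, reads)
  expect_equal(length(contigs), 1)
  expect_gte(global_identity(contigs[1], src), 99)

  single <- structure(list(id = 2, read_ids = 5L), class = "repeat_cluster")
  expect_identical(build_contigs(single, reads), reads[5])
})

test_that("contigs from a satellite cluster contain tandem monomer copies", {
  fx <- fixture("cfic_like")
  reads <- fragment_to_reads(fx$truth, read_length = 250, coverage = 2,
                             seed = 1)$cfic
  hits <- pairwise_hits(reads)
  cc <- connected_clusters(hits, length(reads))
  cl <- filter_clusters(cc$clusters, clustering_params(), length(reads))
  contigs <- build_contigs(cl[[1]], reads)
  al <- wraparound_align(contigs[1], fx$truth$planted_monomer$cfic)
  expect_gte(nchar(contigs[1]), 3 * 40)
  expect_gte(al$percent_matches, 90)  # <= 10% mismatch to the planted monomer
})

test_that("proportional read sampling uses largest-remainder rounding", {
  reads <- list(a = as.character(1:500), b = as.character(1:500))
  s <- sample_reads(reads, c(a = 1, b = 1), 100, seed = 1)
  expect_identical(lengths(s), c(a = 50L, b = 50L))
  s2 <- sample_reads(reads, c(a = 960, b = 1920), 300, seed = 1)
  expect_identical(lengths(s2), c(a = 100L, b = 200L))
  s3 <- sample_reads(reads, c(a = 960, b = 1920), 300, seed = 1)
  expect_identical(s2, s3)
  expect_error(sample_reads(reads, c(a = 1), 10), "every species")
})

test_that("k-mer prefilter loses almost no true hits", {
  fx <- fixture("cfic_like")
  reads <- fragment_to_reads(fx$truth, read_length = 150, coverage = 1,
                             seed = 2)$cfic
  p <- clustering_params()
  with_pf <- pairwise_hits(reads, p)
  # exhaustive reference: disable the prefilter by sharing every pair
  p_all <- clustering_params(prefilter_kmer = 1)
  without_pf <- pairwise_hits(reads, p_all)
  expect_gte(nrow(with_pf), 0.99 * nrow(without_pf))
})
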