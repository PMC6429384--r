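test_that("k-mer profiles are rotation/strand invariant and correctly sized", {
  p4 <- kphylo_params(k = 4, circular = FALSE)
  prof <- kmer_profile("ACGTACGT", p4)
  expect_setequal(prof, c("ACGT", "CGTA", "GTAC", "TACG"))

  p <- kphylo_params(k = 5)
  s <- with_seed(3, random_dna(60))
  rot <- paste0(substr(s, 21, 60), substr(s, 1, 20))
  expect_setequal(kmer_profile(s, p), kmer_profile(rot, p))
  expect_setequal(kmer_profile(s, p), kmer_profile(revcomp(s), p))

  # circular profile size <= sequence length (brute-force enumeration)
  for (len in c(20, 33, 50)) {
    x <- random_dna(len)
    prof <- kmer_profile(x, p)
    expect_lte(length(prof), len)
    cx <- canonical_rotation(x)
    wrapped <- paste0(cx, substr(cx, 1, 4))
    brute <- unique(substring(wrapped, 1:len, 5:(len + 4)))
    expect_setequal(prof, brute)
  }
  expect_error(kmer_profile("ACG", p), "shorter than k")
})

test_that("fractional common k-mer distance behaves as a divergence measure", {
  p <- kphylo_params()
  s <- with_seed(11, random_dna(300))
  prof <- kmer_profile(s, p)
  expect_equal(fractional_common_distance(prof, prof, p), 0)

  d1 <- kmer_profile(strrep("AT", 50), kphylo_params(k = 6))
  d2 <- kmer_profile(strrep("GC", 50), kphylo_params(k = 6))
  expect_equal(fractional_common_distance(d1, d2, kphylo_params(k = 6)), 1)
  expect_error(fractional_common_distance(character(0), prof, p), "empty")

  # mean distance increases with substitution divergence (50 replicates)
  ladder <- c(0, 0.05, 0.1, 0.2, 0.3)
  means <- with_seed(11, {
    vapply(ladder, function(rate) {
      mean(vapply(1:50, function(i) {
        a <- random_dna(200)
        b <- mutate_seq(a, rate)
        fractional_common_distance(kmer_profile(a, p), kmer_profile(b, p), p)
      }, numeric(1)))
    }, numeric(1))
  })
  expect_true(all(diff(means) > 0))
})

test_that("neg_log_F distance form is finite and zero for identity", {
  p <- kphylo_params(distance_form = "neg_log_F")
  a <- kmer_profile(with_seed(4, random_dna(100)), p)
  expect_equal(fractional_common_distance(a, a, p), 0)
  b <- kmer_profile(strrep("ACGGT", 30), p)
  d <- fractional_common_distance(a, b, p)
  expect_true(is.finite(d) && d > 0)
})

test_that("three-taxon branch lengths solve the closed-form equations", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- me_tree(D, root_label = NULL)
  # x = (dab + dac - dbc)/2 etc.
  want <- c(a = 1, b = 2, c = 3)
  got <- setNames(tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(got[names(want)], want, tolerance = 1e-9)
})

test_that("additive five-taxon matrices are recovered exactly", {
  truth <- ape::read.tree(text = "((a:1,b:2):1,(c:1.5,(d:0.5,e:0.7):1):0.5);")
  D <- cophenetic(truth)
  tr <- me_tree(D, root_label = NULL)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(truth)), 0,
               ignore_attr = TRUE)
  expect_equal(cophenetic(tr)[rownames(D), colnames(D)], D, tolerance = 1e-9)
})

test_that("the ME tree rejects invalid matrices and roots on the ancestor", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(me_tree(D), ">= 3")
  D3 <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(me_tree(D3), "symmetric")

  seqs <- with_seed(9, {
    anc <- random_dna(100)
    c(ancestral = anc,
      s1 = mutate_seq(anc, 0.05), s2 = mutate_seq(anc, 0.08),
      s3 = mutate_seq(anc, 0.2))
  })
  tr <- me_tree(kmer_distance_matrix(seqs), root_label = "ancestral")
  expect_true(ape::is.rooted(tr))
  expect_true("ancestral" %in% tr$tip.label)
  expect_true(all(tr$edge.length >= 0))
  expect_error(me_tree(kmer_distance_matrix(seqs), root_label = "zz"), "root label")
})

test_that("the monomer tree pipeline is deterministic and drop-one stable", {
  seqs <- with_seed(13, {
    anc <- random_dna(120)
    c(ancestral = anc, a = mutate_seq(anc, 0.05), b = mutate_seq(anc, 0.05),
      c = mutate_seq(anc, 0.15), d = mutate_seq(anc, 0.15))
  })
  n1 <- monomer_tree_pipeline(seqs)
  n2 <- monomer_tree_pipeline(seqs)
  expect_identical(n1, n2)
  expect_match(n1, ";$")

  D_all <- kmer_distance_matrix(seqs)
  D_sub <- kmer_distance_matrix(seqs[-2])
  expect_equal(D_all[rownames(D_sub), colnames(D_sub)], D_sub)

  # duplicate sequences give a zero-distance cherry but a valid tree
  dup <- c(seqs, e = unname(seqs["a"]))
  expect_silent(monomer_tree_pipeline(dup))
})

test_that("same-clade species pair up in the k-mer tree of simulated lineages", {
  # concerted regimes throughout: HOR formation rewrites a lineage's array
  # and legitimately erases its similarity to the sister species
  ok <- 0L
  for (s in 1:5) {
    cfg <- seven_species_config(s)
    cfg$hor_prob <- 0
    cfg$regimes[] <- "concerted"
    truth <- evolve_library(cfg)
    seqs <- c(unlist(truth$planted_monomer),
              ancestral = cfg$ancestral_monomer)
    tr <- me_tree(kmer_distance_matrix(seqs), root_label = "ancestral")
    sib <- function(pair) {
      mrca <- ape::getMRCA(tr, pair)
      length(ape::extract.clade(tr, mrca)$tip.label) == 2
    }
    if (sib(c("fic", "sue")) && sib(c("pam", "ilj"))) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})
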