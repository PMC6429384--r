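two_leaf_config <- function(...) {
  sim_config(ancestral_monomer = strrep("ACGTTGACGA", 4),
             lineage_tree = "(a:1,b:1);", ...)
}

test_that("zero-rate evolution is the identity on the tandemized monomer", {
  cfg <- two_leaf_config(point_mut_rate = 0, indel_rate = 0,
                         exchange_rate = 0, conversion_rate = 0,
                         array_copies_target = 10, seed = 42)
  truth <- evolve_library(cfg)
  for (sp in c("a", "b")) {
    expect_identical(truth$species_monomers[[sp]],
                     rep(cfg$ancestral_monomer, 10))
    expect_identical(truth$species_arrays[[sp]],
                     strrep(cfg$ancestral_monomer, 10))
  }
  expect_equal(nrow(truth$event_log), 0)
})

test_that("identical configurations give byte-identical truths and reads", {
  cfg <- two_leaf_config(point_mut_rate = 0.02, indel_rate = 0.002,
                         exchange_rate = 5, conversion_rate = 20,
                         array_copies_target = 20, seed = 11)
  t1 <- evolve_library(cfg)
  t2 <- evolve_library(cfg)
  expect_identical(t1$species_arrays, t2$species_arrays)
  expect_identical(t1$event_log, t2$event_log)
  r1 <- fragment_to_reads(t1, read_length = 30, coverage = 2, seed = 3)
  r2 <- fragment_to_reads(t2, read_length = 30, coverage = 2, seed = 3)
  expect_identical(r1, r2)
})

test_that("simulator rejects invalid configurations", {
  expect_error(sim_config("ACGTACGTAAA", "(a:1);"), "leaves")
  expect_error(sim_config("ACGTA", "(a:1,b:1);"), "short")
  expect_error(two_leaf_config(point_mut_rate = -1), "non-negative")
  expect_error(two_leaf_config(suppression_factor = 2), "suppression")
})

test_that("point mutation rate calibrated for ~10% leaf divergence lands there", {
  # oracle: under Jukes-Cantor, observed divergence between the two leaves is
  # 3/4 (1 - exp(-4/3 * 2 r t)); 2rt = 0.105 gives 0.0997
  r <- 0.105 / 2
  divs <- vapply(1:20, function(s) {
    cfg <- two_leaf_config(point_mut_rate = r, indel_rate = 0,
                           exchange_rate = 0, conversion_rate = 0,
                           array_copies_target = 10, seed = s)
    truth <- evolve_library(cfg)
    a <- truth$species_monomers$a
    b <- truth$species_monomers$b
    mean(vapply(seq_along(a), function(i) hamming_frac(a[i], b[i]), numeric(1)))
  }, numeric(1))
  expect_gt(mean(divs), 0.07)
  expect_lt(mean(divs), 0.13)
})

test_that("unequal exchange duplicates or deletes a contiguous run", {
  out <- apply_unequal_exchange(c("A", "B", "C"), start = 2, run_len = 1,
                                action = "dup")
  expect_identical(as.character(out), c("A", "B", "B", "C"))
  out <- apply_unequal_exchange(c("AA", "BB"), start = 1, run_len = 1,
                                action = "del")
  expect_identical(as.character(out), "BB")
  # contraction never empties the array
  out <- apply_unequal_exchange(c("AA", "BB"), start = 1, run_len = 5,
                                action = "del")
  expect_gte(length(out), 1)
  expect_error(apply_unequal_exchange("AA"), ">= 2")
})

test_that("seeded exchange events replay identically through an independent replayer", {
  monos <- paste0("m", sprintf("%03d", 1:100))
  arr <- monos
  events <- list()
  set.seed(99)
  for (e in 1:200) {
    out <- apply_unequal_exchange(arr, run_mean = 5)
    events[[e]] <- list(start = attr(out, "event_start"),
                        len = attr(out, "event_len"),
                        action = attr(out, "event_action"))
    arr <- as.character(out)
    if (length(arr) < 2) break
  }
  # independent replay from the recorded event list
  replay <- monos
  for (ev in events) {
    idx <- ev$start:(ev$start + ev$len - 1)
    replay <- if (ev$action == "dup") {
      append(replay, replay[idx], after = ev$start + ev$len - 1)
    } else {
      replay[-idx]
    }
  }
  expect_identical(sort(arr), sort(replay))
  expect_identical(arr, replay)
})

test_that("gene conversion overwrites the acceptor tract only", {
  arr <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG")
  expect_identical(apply_gene_conversion(arr, 2, 2, 8), arr)
  out <- apply_gene_conversion(arr, 1, 3, 8)
  expect_identical(out, c("AAAAAAAA", "CCCCCCCC", "AAAAAAAA"))
  out <- apply_gene_conversion(arr, 1, 2, 3, tract_start = 2)
  expect_identical(out[2], "CAAACCCC")
  expect_identical(out[1], arr[1])
  expect_error(apply_gene_conversion(arr, 0, 2, 4), "out of range")
})

test_that("repeated conversion from one donor monotonically homogenizes", {
  set.seed(5)
  arr <- vapply(1:20, function(i) random_dna(40), character(1))
  mean_id <- function(a) {
    tot <- 0; cnt <- 0
    for (i in 1:(length(a) - 1)) for (j in (i + 1):length(a)) {
      tot <- tot + mean(strsplit(a[i], "")[[1]] == strsplit(a[j], "")[[1]])
      cnt <- cnt + 1
    }
    tot / cnt
  }
  ids <- mean_id(arr)
  for (acc in 2:20) {
    arr <- apply_gene_conversion(arr, 1, acc, 40)
    ids <- c(ids, mean_id(arr))
  }
  expect_true(all(diff(ids) > 0))
  expect_equal(ids[length(ids)], 1)
})

test_that("HOR formation amplifies the block as the new unit", {
  arr <- replicate(10, random_dna(39))
  res <- apply_hor_formation(arr, block_start = 4, block_size = 3)
  expect_s3_class(res$model, "hor_model")
  expect_equal(res$model$unit_length, 117)
  expect_equal(res$model$subrepeat_count, 3)
  expect_identical(res$array[1:3], arr[4:6])
  expect_gte(length(res$array) / 3, 3)

  res2 <- apply_hor_formation(replicate(4, random_dna(40)), 1, 2)
  expect_equal(res2$model$unit_length, 80)
  expect_error(apply_hor_formation(arr, 1, 1), "block_size")
})

test_that("planted HOR keeps inter-unit identity above inter-subrepeat identity", {
  set.seed(7)
  base <- random_dna(39)
  block <- vapply(1:3, function(i) mutate_seq(base, 0.08), character(1))
  res <- apply_hor_formation(rep(block, 2), 1, 3, n_copies = 10)
  arr <- vapply(res$array, mutate_seq, character(1), sub_rate = 0.025,
                USE.NAMES = FALSE)
  units <- vapply(seq(1, length(arr), by = 3), function(i) {
    paste0(arr[i:(i + 2)], collapse = "")
  }, character(1))
  inter_unit <- mean(vapply(2:length(units), function(i) {
    100 * (1 - hamming_frac(units[1], units[i]))
  }, numeric(1)))
  inter_sub <- mean(c(100 * (1 - hamming_frac(block[1], block[2])),
                      100 * (1 - hamming_frac(block[1], block[3])),
                      100 * (1 - hamming_frac(block[2], block[3]))))
  expect_gte(inter_unit, inter_sub)
})

test_that("read fragmentation hits the coverage expectation and stays in-array", {
  cfg <- two_leaf_config(point_mut_rate = 0, indel_rate = 0,
                         exchange_rate = 0, conversion_rate = 0,
                         array_copies_target = 25, seed = 2)  # 1000 bp arrays
  truth <- evolve_library(cfg)
  reads <- fragment_to_reads(truth, read_length = 100, coverage = 1, seed = 1)
  expect_true(abs(length(reads$a) - 10) <= 2)
  big <- fragment_to_reads(truth, read_length = 100, coverage = 8, seed = 1)
  bases <- sum(nchar(big$a))
  expect_lt(abs(bases - 8 * 1000) / (8 * 1000), 0.1)
  # every read is an exact substring of its species' array
  for (rd in big$a) expect_true(grepl(rd, truth$species_arrays$a, fixed = TRUE))
  expect_error(fragment_to_reads(truth, coverage = 0), "coverage")
})

test_that("concerted regimes homogenize; suppressed regimes diversify", {
  mean_pair_id <- function(m) {
    m <- m[seq_len(min(15, length(m)))]
    tot <- 0; cnt <- 0
    for (i in 1:(length(m) - 1)) for (j in (i + 1):length(m)) {
      tot <- tot + rotational_identity(m[i], m[j]); cnt <- cnt + 1
    }
    tot / cnt
  }
  subfam_count <- function(m, cutoff = 80) {
    m <- m[seq_len(min(15, length(m)))]
    n <- length(m)
    edges <- matrix(integer(0), ncol = 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (rotational_identity(m[i], m[j]) >= cutoff) {
        edges <- rbind(edges, c(i, j))
      }
    }
    length(uf_components(edges, n))
  }
  ok_regime <- logical(0); ok_subfam <- logical(0)
  for (s in 1:5) {
    fx <- cached_fixture(s)
    tr <- fx$truth
    intra_fic <- mean_pair_id(tr$species_monomers$fic)
    # concerted evolution: within-species identity exceeds the identity to
    # other species' monomers (averaged over the other lineages; a sister
    # species that split only recently sits at the noise margin by itself)
    others <- setdiff(names(tr$species_monomers), "fic")
    inter <- mean(vapply(others, function(sp) {
      mean(vapply(1:10, function(i) {
        rotational_identity(tr$species_monomers$fic[i],
                            tr$species_monomers[[sp]][i])
      }, numeric(1)))
    }, numeric(1)))
    ok_regime <- c(ok_regime, intra_fic > inter)
    ok_subfam <- c(ok_subfam,
                   subfam_count(tr$species_monomers$vul) >
                     subfam_count(tr$species_monomers$fic))
  }
  expect_true(all(ok_regime))
  expect_true(all(ok_subfam))
})
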