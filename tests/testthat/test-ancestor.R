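test_that("exact shared fragments: identity, disjoint and planted cases", {
  m <- "ACGGTTAACCGGTTAACCGGTCAAGGCTAAGGCTAACCAA"
  fr <- shared_exact_fragments(m, m)
  expect_gte(max(fr$length), nchar(m))  # capped at one full turn
  expect_true(m %in% fr$sequence || any(grepl(substr(m, 1, 20), fr$sequence)))

  # alphabets with no shared content on either strand
  fr0 <- shared_exact_fragments(strrep("A", 40), strrep("G", 40))
  expect_equal(nrow(fr0), 0)
  expect_error(shared_exact_fragments(m, m, min_len = 3), "min_len")
  expect_error(shared_exact_fragments(character(0), m), "empty")
})

test_that("a planted 12-mer is recovered exactly (brute-force oracle)", {
  planted <- with_seed(6, {
    core <- random_dna(12)
    a <- paste0(random_dna(14), core, random_dna(14))
    b <- paste0(random_dna(10), core, random_dna(18))
    list(core = core, a = a, b = b)
  })
  fr <- shared_exact_fragments(planted$a, planted$b, min_len = 8)
  oracle <- shared_bruteforce(planted$a, planted$b, min_len = 8)
  expect_setequal(unique(frag_canon(fr$sequence)), unique(frag_canon(oracle)))
  # the planted core is recovered (possibly chance-extended by flanking
  # agreement, in which case a maximal fragment contains it)
  expect_true(any(grepl(planted$core, fr$sequence, fixed = TRUE) |
                  grepl(planted$core, revcomp(fr$sequence), fixed = TRUE)))
})

test_that("fragment search is symmetric and matches brute force on small sets", {
  set.seed(41)
  for (rep in 1:4) {
    core <- random_dna(10)
    set_a <- replicate(3, paste0(random_dna(sample(8:20, 1)), core,
                                 random_dna(sample(8:20, 1))))
    set_b <- replicate(2, paste0(random_dna(sample(8:20, 1)), core,
                                 random_dna(sample(8:20, 1))))
    ab <- shared_exact_fragments(set_a, set_b, min_len = 8)
    ba <- shared_exact_fragments(set_b, set_a, min_len = 8)
    expect_setequal(unique(frag_canon(ab$sequence)), unique(frag_canon(ba$sequence)))
    oracle <- shared_bruteforce(set_a, set_b, min_len = 8)
    # every maximal brute-force fragment is found, and nothing longer
    expect_true(all(frag_canon(oracle) %in% frag_canon(ab$sequence)))
    expect_equal(max(ab$length), max(nchar(oracle)))
  }
})

test_that("the conserved ancestral fragment is reconstructed exactly", {
  fx <- fixture("two_species_ancestor")
  frag <- reconstruct_ancestral(fx$truth$species_monomers)
  expect_s3_class(frag, "ancestral_fragment")
  expect_equal(frag$length, 37)
  expect_identical(frag$sequence, fx$expected$core)
  # support intervals really carry the fragment in every species
  for (sp in names(frag$support)) {
    sup <- frag$support[[sp]]
    expect_gte(nrow(sup), 1)
    mono <- fx$truth$species_monomers[[sp]][sup$monomer[1]]
    doubled <- paste0(mono, mono)
    found <- substr(doubled, sup$start[1], sup$end[1])
    if (sup$strand[1] == "-") found <- revcomp(found)
    expect_true(found == frag$sequence || revcomp(found) == frag$sequence)
  }
})

test_that("identical species sets reconstruct the whole monomer", {
  m <- with_seed(17, random_dna(40))
  sets <- list(s1 = rep(m, 3), s2 = rep(m, 2), s3 = m)
  frag <- reconstruct_ancestral(sets)
  expect_equal(frag$length, 40)
  expect_identical(canonical_rotation(frag$sequence), canonical_rotation(m))
})

test_that("a planted core across four species is recovered with bounded extension", {
  sets <- with_seed(8, {
    core <- random_dna(20)
    sets <- lapply(1:4, function(i) {
      vapply(1:3, function(j) paste0(random_dna(10), core, random_dna(10)),
             character(1))
    })
    names(sets) <- paste0("sp", 1:4)
    attr(sets, "core") <- core
    sets
  })
  frag <- reconstruct_ancestral(sets)
  expect_gte(frag$length, 20)
  expect_lte(frag$length, 22)
  expect_true(grepl(attr(sets, "core"), frag$sequence, fixed = TRUE) ||
              grepl(attr(sets, "core"), revcomp(frag$sequence), fixed = TRUE))
})

test_that("raising min_len never lengthens the reconstruction", {
  fx <- fixture("two_species_ancestor")
  l8 <- reconstruct_ancestral(fx$truth$species_monomers, min_len = 8)$length
  l12 <- reconstruct_ancestral(fx$truth$species_monomers, min_len = 12)$length
  l20 <- reconstruct_ancestral(fx$truth$species_monomers, min_len = 20)$length
  expect_true(l12 <= l8 && l20 <= l12)
})

test_that("no conserved core is an error, not a fabricated fragment", {
  sets <- list(a = strrep("A", 40), b = strrep("G", 40))
  expect_error(reconstruct_ancestral(sets), "no conserved core")
})

test_that("the family reference defaults to the 37-bp fragment and round-trips", {
  ref <- family_reference()
  expect_equal(nchar(ref$sequence), 37)
  fa <- tempfile(fileext = ".fasta")
  write_sequences(ref, fa)
  back <- read_sequences(fa)
  expect_identical(back$sequence, ref$sequence)
  expect_true(family_membership(ref$sequence, ref)$member)

  fx <- fixture("two_species_ancestor")
  frag <- reconstruct_ancestral(fx$truth$species_monomers)
  expect_identical(family_reference(frag)$sequence, frag$sequence)
})
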