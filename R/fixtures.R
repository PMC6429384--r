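# Named simulation fixtures: small, seeded study conditions used throughout
# the test-suite and the analysis scripts.  Each returns the configuration
# (where a tree simulation is involved), the resulting `sim_truth`, and the
# summary the construction guarantees.

#' Seeded simulation fixtures
#'
#' * `cfic_like`: a uniform tandem array — a planted random 40-bp monomer in
#'   200 copies, each copy independently substituted at 5% per site (seed 1).
#'   Emulates a homogeneous satellite array with a single basic monomer.
#' * `hor_worked_example`: a higher-order repeat array — three subrepeats
#'   derived from one 39-bp ancestor (~15% pairwise inter-subrepeat
#'   divergence) forming a 117-bp unit amplified into 35 tandem copies with
#'   <= 5% inter-unit divergence (seed 7).
#' * `vulvaria_like`: a non-concerted genome — six divergent subfamilies
#'   (~20% each from one 40-bp ancestor) in separate arrays with little
#'   within-subfamily homogenization (seed 5).
#' * `two_species_ancestor`: two species' monomer sets descended from the
#'   conserved 37-bp ancestral fragment embedded in a 40-bp monomer; the
#'   core is exactly conserved, the 3-bp flanks are species-specific and
#'   differ at the core-adjacent positions (seed 3).
#' * `seven_species`: a 7-leaf lineage tree (two sister-species clades, two
#'   isolated lineages, one early-branching non-concerted lineage) evolved
#'   with the full event model; HOR formation planted on three terminal
#'   branches.
#'
#' @param name fixture name.
#' @param seed root seed; the default is each fixture's canonical seed.
#' @return list with `name`, `config` (a [sim_config()] or `NULL` for
#'   direct constructions), `truth` (a `sim_truth`) and `expected` (the
#'   summary guaranteed by construction).
#' @export
fixture <- function(name = c("cfic_like", "hor_worked_example",
                             "vulvaria_like", "two_species_ancestor",
                             "seven_species"),
                    seed = NULL) {
  name <- match.arg(name)
  switch(name,
    cfic_like = fixture_cfic(if (is.null(seed)) 1L else seed),
    hor_worked_example = fixture_hor(if (is.null(seed)) 7L else seed),
    vulvaria_like = fixture_vulvaria(if (is.null(seed)) 5L else seed),
    two_species_ancestor = fixture_two_species(if (is.null(seed)) 3L else seed),
    seven_species = fixture_seven(if (is.null(seed)) 1L else seed))
}

sim_truth_direct <- function(species_monomers, planted_monomer,
                             planted_hors = NULL, background = NULL) {
  sp <- names(species_monomers)
  if (is.null(planted_hors)) {
    planted_hors <- setNames(rep(list(list()), length(sp)), sp)
  }
  if (is.null(background)) background <- setNames(rep(list(""), length(sp)), sp)
  structure(list(
    species_arrays = lapply(species_monomers, c2s),
    species_monomers = species_monomers,
    true_tree = NULL,
    planted_monomer = planted_monomer,
    planted_hors = planted_hors,
    background = background,
    event_log = NULL,
    config = NULL), class = "sim_truth")
}

fixture_cfic <- function(seed) {
  truth <- with_seed(hash31("cfic_like", seed), {
    monomer <- random_dna(40)
    copies <- vapply(seq_len(200), function(i) mutate_seq(monomer, 0.05),
                     character(1))
    sim_truth_direct(list(cfic = copies), list(cfic = monomer))
  })
  list(name = "cfic_like", config = NULL, truth = truth,
       expected = list(monomer_length = 40L, period = 40L, copies = 200L,
                       divergence = 0.05))
}

fixture_hor <- function(seed) {
  truth <- with_seed(hash31("hor_worked_example", seed), {
    base <- random_dna(39)
    subs <- vapply(1:3, function(i) mutate_seq(base, 0.083), character(1))
    n_units <- 35L
    monomers <- character(0)
    for (u in seq_len(n_units)) {
      monomers <- c(monomers,
                    vapply(subs, mutate_seq, character(1), sub_rate = 0.015,
                           USE.NAMES = FALSE))
    }
    model <- hor_model(unit_length = 117L, subrepeat_length = 39L,
                       subrepeat_count = 3L, consensus = c2s(subs))
    sim_truth_direct(list(hor = monomers), list(hor = base),
                     planted_hors = list(hor = list(model)))
  })
  list(name = "hor_worked_example", config = NULL, truth = truth,
       expected = list(unit_length = 117L, subrepeat_length = 39L,
                       subrepeat_count = 3L, n_units = 35L))
}

fixture_vulvaria <- function(seed) {
  truth <- with_seed(hash31("vulvaria_like", seed), {
    anc <- random_dna(40)
    n_sub <- 6L
    subfams <- vapply(seq_len(n_sub), function(i) mutate_seq(anc, 0.20),
                      character(1))
    arrays <- lapply(subfams, function(s) {
      vapply(seq_len(40), function(i) mutate_seq(s, 0.02), character(1))
    })
    # two proposed HOR units: blocks of three diverged subfamily monomers
    # amplified as a unit (multidirectional trends include unit-length growth)
    hors <- list()
    for (h in 1:2) {
      block <- vapply(subfams[(3 * h - 2):(3 * h)], mutate_seq, character(1),
                      sub_rate = 0.02, USE.NAMES = FALSE)
      units <- character(0)
      for (u in 1:30) {
        units <- c(units, vapply(block, mutate_seq, character(1),
                                 sub_rate = 0.015, USE.NAMES = FALSE))
      }
      arrays <- c(arrays, list(units))
      hors[[h]] <- hor_model(unit_length = sum(nchar(block)),
                             subrepeat_length = round(mean(nchar(block))),
                             subrepeat_count = 3L, consensus = c2s(block))
    }
    monomers <- unlist(arrays)
    tr <- sim_truth_direct(list(vul = monomers), list(vul = anc),
                           planted_hors = list(vul = hors))
    tr$species_arrays <- list(vul = vapply(arrays, c2s, character(1)))
    tr
  })
  list(name = "vulvaria_like", config = NULL, truth = truth,
       expected = list(n_subfamilies = 6L, subfamily_divergence = 0.20,
                       n_hor_arrays = 2L))
}

fixture_two_species <- function(seed) {
  core <- ANCESTRAL_37
  truth <- with_seed(hash31("two_species_ancestor", seed), {
    spacer_a <- random_dna(3)
    repeat {
      spacer_b <- random_dna(3)
      # core-adjacent spacer bases must differ between the species so the
      # exact shared fragment is the conserved core itself (flanks are then
      # >= 2/3 diverged); the monomer is circular, so both spacer ends abut
      # the core
      if (substr(spacer_b, 1, 1) != substr(spacer_a, 1, 1) &&
          substr(spacer_b, 3, 3) != substr(spacer_a, 3, 3)) break
    }
    mono_a <- paste0(core, spacer_a)
    mono_b <- paste0(core, spacer_b)
    sim_truth_direct(
      list(species_a = rep(mono_a, 12), species_b = rep(mono_b, 12)),
      list(species_a = mono_a, species_b = mono_b))
  })
  list(name = "two_species_ancestor", config = NULL, truth = truth,
       expected = list(core = core, core_length = 37L, monomer_length = 40L))
}

#' @rdname fixture
#' @export
seven_species_config <- function(seed = 1L) {
  # sister species within a clade are much more similar to each other in
  # family structure than species across clades; the deep split carries the
  # non-concerted lineage
  tree <- paste0("((((fic:0.4,sue:0.4):1.1,(pam:0.4,ilj:0.4):1.1):0.5,",
                 "(acu:1.6,bry:1.6):0.4):0.5,vul:4.5);")
  sim_config(
    ancestral_monomer = with_seed(hash31("seven_species_monomer", 7L),
                                  random_dna(40)),
    lineage_tree = tree,
    point_mut_rate = 0.05, indel_rate = 0.001,
    exchange_rate = 20, conversion_rate = 4000,
    hor_prob = c(acu = 1, bry = 1, ilj = 1),
    hor_block_size = 3,
    regimes = c(fic = "concerted", sue = "concerted", pam = "concerted",
                ilj = "concerted", acu = "concerted", bry = "concerted",
                vul = "non_concerted"),
    suppression_factor = 0.02,
    array_copies_target = 300, exchange_run_mean = 10,
    conversion_run_mean = 30,
    background_bp = 100000, read_length = 250, coverage = 0.8,
    seed = seed)
}

fixture_seven <- function(seed) {
  cfg <- seven_species_config(seed)
  truth <- evolve_library(cfg)
  list(name = "seven_species", config = cfg, truth = truth,
       expected = list(
         regimes = cfg$regimes,
         hor_species = c("acu", "bry", "ilj"),
         modes = c(fic = "concerted_mutational", sue = "concerted_mutational",
                   pam = "concerted_mutational", acu = "concerted_hor",
                   bry = "concerted_hor", ilj = "concerted_hor",
                   vul = "non_concerted"),
         clade_pairs = list(c("fic", "sue"), c("pam", "ilj"))))
}
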