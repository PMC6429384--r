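#' Simulation configuration for satDNA family evolution
#'
#' Describes the evolution of a satellite family over a rooted lineage tree:
#' an ancestral monomer is amplified into a tandem array at the root and each
#' branch accumulates point mutations, small indels, unequal-exchange
#' amplifications/contractions, gene-conversion homogenization and (optionally)
#' a higher-order repeat (HOR) formation event.  Leaves marked
#' `non_concerted` have their homogenization machinery (gene conversion and
#' unequal exchange) suppressed on the terminal branch by
#' `suppression_factor`, producing the low-homogenization, multidirectional
#' regime; all other leaves evolve concertedly.
#'
#' Rates are per unit branch length: `point_mut_rate` in substitutions per
#' site, `indel_rate` in events per site (geometric lengths, mean 1.5),
#' `exchange_rate` and `conversion_rate` in events per array.
#'
#' @param ancestral_monomer DNA string, length >= 10.
#' @param lineage_tree rooted [ape::phylo] tree (or Newick string) with branch
#'   lengths; >= 2 leaves.
#' @param point_mut_rate,indel_rate,exchange_rate,conversion_rate non-negative
#'   per-branch rates (see above).
#' @param hor_prob probability of one HOR-formation event per branch; a
#'   named vector assigns per-branch probabilities by branch (child node)
#'   label, with 0 for unnamed branches.
#' @param hor_block_size monomers per HOR unit formed by such an event.
#' @param hor_diversify per-site substitution rate applied to the block
#'   monomers at HOR formation (the unit forms from modified, diverged
#'   monomers).
#' @param hor_copy_noise per-site substitution rate applied to each emitted
#'   unit copy, standing in for post-formation drift.
#' @param regimes named character vector mapping each leaf to `"concerted"` or
#'   `"non_concerted"`; unnamed scalar recycles to all leaves.
#' @param suppression_factor factor in `[0, 1]` applied to conversion and
#'   exchange rates on non-concerted terminal branches.
#' @param array_copies_target number of monomer copies in the root array;
#'   also the homeostatic size target biasing unequal exchange toward
#'   contraction when the array grows beyond it (and vice versa).
#' @param exchange_run_mean mean length (monomers) of an unequal-exchange run.
#' @param conversion_run_mean mean length (monomers) of a gene-conversion
#'   tract: conversion events copy a run of adjacent monomers from a donor
#'   region onto an acceptor region (tracts commonly span several monomers).
#' @param background_bp non-repetitive genomic background per species
#'   (bases); gives cluster genome fractions a denominator.
#' @param read_length,coverage read simulation defaults used by
#'   [fragment_to_reads()].
#' @param seed integer root seed; per-branch streams are derived by hashing
#'   the branch label with it, so per-branch results are order-independent.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(ancestral_monomer, lineage_tree,
                       point_mut_rate = 0.02, indel_rate = 0.001,
                       exchange_rate = 10, conversion_rate = 40,
                       hor_prob = 0, hor_block_size = 3,
                       hor_diversify = 0.06, hor_copy_noise = 0.015,
                       regimes = "concerted", suppression_factor = 0.05,
                       array_copies_target = 100, exchange_run_mean = 8,
                       conversion_run_mean = 10, background_bp = 0,
                       read_length = 100, coverage = 5, seed = 1) {
  if (is.character(lineage_tree)) lineage_tree <- ape::read.tree(text = lineage_tree)
  stopifnot(inherits(lineage_tree, "phylo"))
  if (!ape::is.rooted(lineage_tree)) stop("lineage tree must be rooted")
  if (length(lineage_tree$tip.label) < 2) stop("tree must have >= 2 leaves")
  if (nchar(ancestral_monomer) < 10) stop("ancestral monomer too short (>= 10 bp)")
  if (nchar(ancestral_monomer) == 0) stop("empty ancestral monomer")
  rates <- c(point_mut_rate, indel_rate, exchange_rate, conversion_rate, hor_prob)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (suppression_factor < 0 || suppression_factor > 1) {
    stop("suppression factor must be in [0, 1]")
  }
  tips <- lineage_tree$tip.label
  if (is.null(names(regimes))) {
    regimes <- setNames(rep(regimes, length.out = length(tips)), tips)
  }
  regimes <- unname(regimes[tips])
  if (any(is.na(regimes)) || !all(regimes %in% c("concerted", "non_concerted"))) {
    stop("regimes must map every leaf to 'concerted' or 'non_concerted'")
  }
  structure(list(
    ancestral_monomer = toupper(ancestral_monomer),
    lineage_tree = lineage_tree,
    point_mut_rate = point_mut_rate, indel_rate = indel_rate,
    exchange_rate = exchange_rate, conversion_rate = conversion_rate,
    hor_prob = hor_prob, hor_block_size = hor_block_size,
    hor_diversify = hor_diversify, hor_copy_noise = hor_copy_noise,
    regimes = setNames(regimes, tips),
    suppression_factor = suppression_factor,
    array_copies_target = array_copies_target,
    exchange_run_mean = exchange_run_mean,
    conversion_run_mean = conversion_run_mean,
    background_bp = background_bp,
    read_length = read_length, coverage = coverage, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Unequal exchange on a tandem array
#'
#' Duplicates (amplification) or deletes (contraction) a contiguous run of
#' monomers, chosen 50/50; monomer sequences are unaltered.  A contraction
#' never empties the array (at least one monomer is retained).
#'
#' @param array character vector of monomers (length >= 2).
#' @param seed optional seed for a self-contained draw.
#' @param run_mean mean run length (geometric).
#' @param start,run_len,action force the event (`action` is `"dup"` or
#'   `"del"`) instead of drawing it; used for auditing and tests.
#' @return the modified monomer vector, with attributes `event_start`,
#'   `event_len`, `event_action`.
#' @export
apply_unequal_exchange <- function(array, seed = NULL, run_mean = 8,
                                   start = NULL, run_len = NULL, action = NULL) {
  n <- length(array)
  if (n < 2) stop("array must have >= 2 monomers")
  draw <- function() {
    if (is.null(action)) action <<- if (runif(1) < 0.5) "dup" else "del"
    if (is.null(run_len)) run_len <<- 1 + rgeom(1, 1 / run_mean)
    run_len <<- min(run_len, if (action == "del") n - 1L else n)
    if (is.null(start)) start <<- sample(n - run_len + 1L, 1)
  }
  if (!is.null(seed)) with_seed(seed, draw()) else draw()
  run_len <- min(run_len, if (action == "del") n - 1L else n - start + 1L)
  idx <- start:(start + run_len - 1L)
  out <- if (action == "dup") {
    append(array, array[idx], after = start + run_len - 1L)
  } else {
    array[-idx]
  }
  attr(out, "event_start") <- start
  attr(out, "event_len") <- run_len
  attr(out, "event_action") <- action
  out
}

#' Gene conversion between two monomers of an array
#'
#' Overwrites a tract of the acceptor monomer (aligned by position) with the
#' donor's tract; the donor is unchanged and the array length is unchanged.
#'
#' @param array character vector of monomers.
#' @param donor_index,acceptor_index 1-based monomer indices.
#' @param tract_len tract length in bases (<= monomer length).
#' @param tract_start 1-based tract start within the monomer.
#' @return the modified monomer vector.
#' @export
apply_gene_conversion <- function(array, donor_index, acceptor_index,
                                  tract_len, tract_start = 1L) {
  n <- length(array)
  if (donor_index < 1 || donor_index > n || acceptor_index < 1 || acceptor_index > n) {
    stop("monomer index out of range")
  }
  donor <- array[donor_index]
  acceptor <- array[acceptor_index]
  tract_len <- min(tract_len, nchar(donor), nchar(acceptor) - tract_start + 1L)
  if (tract_len < 1) return(array)
  end <- tract_start + tract_len - 1L
  substr(acceptor, tract_start, end) <- substr(donor, tract_start, end)
  array[acceptor_index] <- acceptor
  array
}

#' HOR formation: a diverged block becomes the new unit of amplification
#'
#' The block of `block_size` monomers at `block_start` is amplified as a unit:
#' the returned array consists of `n_copies` (>= 3) tandem copies of the
#' block.  Subsequent per-copy divergence is applied by the caller (the
#' branch's remaining mutation events).
#'
#' @param array character vector of monomers.
#' @param block_start 1-based index of the block's first monomer.
#' @param block_size monomers per HOR unit (>= 2).
#' @param n_copies number of unit copies emitted (default keeps the array
#'   size roughly constant, minimum 3).
#' @return list with `array` (new monomer vector) and `model` (a
#'   [hor_model()] ground truth).
#' @export
apply_hor_formation <- function(array, block_start, block_size,
                                n_copies = NULL) {
  if (block_size < 2) stop("block_size must be >= 2")
  if (block_start < 1 || block_start + block_size - 1 > length(array)) {
    stop("block out of range")
  }
  block <- array[block_start:(block_start + block_size - 1L)]
  if (is.null(n_copies)) n_copies <- max(3L, floor(length(array) / block_size))
  n_copies <- max(3L, n_copies)
  new_array <- rep(block, n_copies)
  model <- hor_model(unit_length = sum(nchar(block)),
                     subrepeat_length = round(mean(nchar(block))),
                     subrepeat_count = block_size)
  list(array = new_array, model = model)
}

# ---- branch evolution ----

evolve_branch <- function(array, t, cfg, branch_id, suppress = FALSE) {
  sfac <- if (suppress) cfg$suppression_factor else 1
  with_seed(hash31(branch_id, cfg$seed), {
    sites <- sum(nchar(array))
    mono_len0 <- nchar(cfg$ancestral_monomer)
    n_ev <- c(
      sub  = rpois(1, cfg$point_mut_rate * t * sites),
      ind  = rpois(1, cfg$indel_rate * t * sites),
      exch = rpois(1, cfg$exchange_rate * t * sfac),
      conv = rpois(1, cfg$conversion_rate * t * sfac)
    )
    p_hor <- if (!is.null(names(cfg$hor_prob))) {
      ph <- cfg$hor_prob[branch_id]
      if (is.na(ph)) 0 else unname(ph)
    } else cfg$hor_prob
    hor_event <- p_hor > 0 && runif(1) < p_hor
    types <- sample(c(rep("sub", n_ev["sub"]), rep("ind", n_ev["ind"]),
                      rep("exch", n_ev["exch"]), rep("conv", n_ev["conv"])))
    times <- sort(runif(length(types), 0, t))
    n_after <- integer(length(types))
    hor_model <- NULL
    for (e in seq_along(types)) {
      ty <- types[e]
      n <- length(array)
      if (ty == "sub") {
        m <- sample.int(n, 1)
        x <- s2c(array[m])
        i <- sample.int(length(x), 1)
        x[i] <- sample(setdiff(DNA_BASES, x[i]), 1)
        array[m] <- c2s(x)
      } else if (ty == "ind") {
        m <- sample.int(n, 1)
        x <- s2c(array[m])
        len <- 1 + rgeom(1, 2 / 3)
        if (runif(1) < 0.5) {
          if (length(x) + len <= 1.2 * mono_len0) {
            pos <- sample.int(length(x), 1)
            x <- append(x, sample(DNA_BASES, len, replace = TRUE), after = pos)
          }
        } else {
          if (length(x) - len >= 0.8 * mono_len0) {
            pos <- sample.int(length(x) - len + 1L, 1)
            x <- x[-(pos:(pos + len - 1L))]
          }
        }
        array[m] <- c2s(x)
      } else if (ty == "exch") {
        if (n >= 2) {
          # homeostatic bias: contraction more likely when above the size
          # target, amplification when below
          tgt <- cfg$array_copies_target
          p_dup <- tgt^2 / (tgt^2 + n^2)
          act <- if (runif(1) < p_dup) "dup" else "del"
          array <- apply_unequal_exchange(array, run_mean = cfg$exchange_run_mean,
                                          action = act)
        }
      } else if (ty == "conv") {
        if (n >= 2) {
          # conversion tract spans a run of adjacent monomers; each acceptor
          # monomer is replaced by its position-aligned donor monomer
          r <- min(1 + rgeom(1, 1 / cfg$conversion_run_mean), n - 1L)
          don <- sample.int(n - r + 1L, 1)
          acc <- sample.int(n - r + 1L, 1)
          if (don != acc) {
            array[acc:(acc + r - 1L)] <- array[don:(don + r - 1L)]
          }
        }
      }
      n_after[e] <- length(array)
    }
    # HOR formation is modeled as a terminal event on its branch: a block of
    # monomers is diversified and then amplified as the new repeat unit, with
    # light per-copy divergence standing in for post-formation drift
    if (hor_event && length(array) >= cfg$hor_block_size &&
        cfg$hor_block_size >= 2) {
      bs <- cfg$hor_block_size
      st <- sample.int(length(array) - bs + 1L, 1)
      block <- vapply(array[st:(st + bs - 1L)], mutate_seq, character(1),
                      sub_rate = cfg$hor_diversify, USE.NAMES = FALSE)
      array[st:(st + bs - 1L)] <- block
      res <- apply_hor_formation(array, st, bs)
      array <- vapply(res$array, mutate_seq, character(1),
                      sub_rate = cfg$hor_copy_noise, USE.NAMES = FALSE)
      hor_model <- res$model
      types <- c(types, "hor")
      times <- c(times, t)
      n_after <- c(n_after, length(array))
    }
    log <- if (length(types)) {
      data.frame(branch = branch_id, time = times, event_type = types,
                 details = paste0("n_after=", n_after),
                 stringsAsFactors = FALSE)
    } else NULL
    list(array = array, log = log, hor_model = hor_model)
  })
}

#' Evolve a satDNA library over a lineage tree
#'
#' Runs the per-branch event process (point mutation, indels, unequal
#' exchange, gene conversion, optional HOR formation) from the root array
#' (exact tandem copies of the ancestral monomer) down to every leaf.  With
#' all rates zero, every leaf array consists of exact tandem copies of the
#' ancestral monomer.  The event log and all arrays are reproducible from the
#' configuration's seed.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_truth`: list with `species_arrays` (map
#'   species -> list of array DNA strings), `species_monomers` (map species ->
#'   monomer character vector), `true_tree`, `planted_monomer` (per-species
#'   majority-consensus monomer), `planted_hors`, `background` (per-species
#'   background DNA string), `event_log` and `config`.
#' @export
evolve_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$lineage_tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  edge_len <- function(node) tree$edge.length[tree$edge[, 2] == node]
  node_lab <- function(node) {
    if (node <= ntip) tree$tip.label[node] else paste0("node", node)
  }

  arrays <- list(); hors <- list(); logs <- list()
  recurse <- function(node, array, inherited_hors) {
    for (ch in kids(node)) {
      lab <- node_lab(ch)
      is_tip <- ch <= ntip
      suppress <- is_tip && config$regimes[[lab]] == "non_concerted"
      res <- evolve_branch(array, edge_len(ch), config, lab, suppress)
      logs[[length(logs) + 1L]] <<- res$log
      ch_hors <- c(inherited_hors, if (!is.null(res$hor_model)) list(res$hor_model))
      if (is_tip) {
        arrays[[lab]] <<- res$array
        hors[[lab]] <<- ch_hors
      } else {
        recurse(ch, res$array, ch_hors)
      }
    }
  }
  root_array <- rep(config$ancestral_monomer, config$array_copies_target)
  recurse(root, root_array, list())

  background <- lapply(setNames(tree$tip.label, tree$tip.label), function(sp) {
    if (config$background_bp > 0) {
      with_seed(hash31(paste0("bg:", sp), config$seed),
                random_dna(config$background_bp))
    } else ""
  })
  planted <- lapply(arrays, function(a) {
    lens <- nchar(a)
    mode_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    same <- a[lens == mode_len]
    majority_consensus(do.call(rbind, strsplit(same, "")))
  })
  flat_logs <- Filter(Negate(is.null), logs)
  event_log <- if (length(flat_logs)) {
    do.call(rbind, c(flat_logs, list(make.row.names = FALSE)))
  } else {
    data.frame(branch = character(0), time = numeric(0),
               event_type = character(0), details = character(0))
  }
  structure(list(
    species_arrays = lapply(arrays, c2s),
    species_monomers = arrays,
    true_tree = tree,
    planted_monomer = planted,
    planted_hors = hors,
    background = background,
    event_log = event_log,
    config = config
  ), class = "sim_truth")
}

#' Shotgun reads from simulated arrays
#'
#' Reads are exact substrings drawn uniformly from each species' arrays plus
#' its non-repetitive background; expected total bases equal
#' `coverage x total bases`.
#'
#' @param truth a `sim_truth` from [evolve_library()].
#' @param read_length read length in bp (must not exceed the shortest array).
#' @param coverage fold coverage (> 0).
#' @param seed integer seed.
#' @return named list (per species) of named character vectors of reads.
#' @export
fragment_to_reads <- function(truth, read_length = NULL, coverage = NULL,
                              seed = NULL) {
  cfg <- truth$config
  if (is.null(read_length)) read_length <- cfg$read_length
  if (is.null(coverage)) coverage <- cfg$coverage
  if (is.null(seed)) seed <- cfg$seed
  if (coverage <= 0) stop("coverage must be > 0")
  out <- list()
  for (sp in names(truth$species_arrays)) {
    sources <- c(truth$species_arrays[[sp]], truth$background[[sp]])
    sources <- sources[nchar(sources) >= read_length]
    if (!length(sources)) stop("read_length exceeds every source sequence for ", sp)
    total <- sum(nchar(sources))
    n_reads <- round(coverage * total / read_length)
    out[[sp]] <- with_seed(hash31(paste0("reads:", sp), seed), {
      src <- sample(length(sources), n_reads, replace = TRUE,
                    prob = nchar(sources))
      starts <- vapply(src, function(i) {
        sample(nchar(sources[i]) - read_length + 1L, 1)
      }, integer(1))
      setNames(substring(sources[src], starts, starts + read_length - 1L),
               sprintf("%s_r%05d", sp, seq_len(n_reads)))
    })
  }
  out
}
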