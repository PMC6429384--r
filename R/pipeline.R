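# End-to-end pipeline over a simulated (or user-provided) read set:
# clustering -> contigs -> tandem detection -> HOR inventory -> membership ->
# homogenization metrics -> k-mer tree -> per-lineage classification.

#' Run the satDNA life-history pipeline on a simulation truth
#'
#' Stages: (1) shotgun reads per species; (2) all-vs-all read clustering and
#' abundance filtering; (3) greedy consensus contigs for the largest
#' clusters; (4) family membership of cluster contigs against the family
#' reference; (5) tandem detection on family contigs and HOR inventory;
#' (6) homogenization index over the species' monomers; (7) k-mer
#' minimum-evolution tree of the species consensus monomers rooted on the
#' ancestral reference; (8) classification and report.
#'
#' In simulation mode the family reference defaults to the configuration's
#' ancestral monomer and the homogenization index is computed from the
#' simulated monomer lists; on real data both come from the reconstruction
#' and tandem stages.
#'
#' @param truth a `sim_truth` (from [evolve_library()] or [fixture()]).
#' @param outdir optional output directory for stage TSV/FASTA/Newick/JSON
#'   files.
#' @param cl_params a [clustering_params()].
#' @param t_params a [tandem_params()].
#' @param reference family reference sequence (default: the simulation's
#'   ancestral monomer, else the shipped 37-bp fragment).
#' @param max_clusters_per_species clusters examined in detail per species.
#' @param min_family_cluster_frac minimum fraction of the species' reads a
#'   family cluster must hold to count toward the multi-cluster
#'   fragmentation signal used by [classify_lineage()].
#' @param index_sample monomers sampled for the homogenization index.
#' @param seed seed for read generation and sampling (default: the
#'   configuration's seed).
#' @return list with `report`, `classifications`, `clusters` (per-species
#'   summary data.frame), `tandem_hits`, `inventory`, `tree` (Newick) and
#'   `reads_per_species`.
#' @export
run_pipeline <- function(truth, outdir = NULL,
                         cl_params = clustering_params(),
                         t_params = tandem_params(),
                         reference = NULL,
                         max_clusters_per_species = 8,
                         min_family_cluster_frac = 0.02,
                         index_sample = 40,
                         seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(reference)) {
    reference <- if (!is.null(truth$config)) {
      truth$config$ancestral_monomer
    } else ANCESTRAL_37
  }
  ref_len <- nchar(reference)
  if (is.null(seed)) seed <- if (!is.null(truth$config)) truth$config$seed else 1L

  reads <- fragment_to_reads(truth, seed = seed)
  species <- names(reads)
  cluster_rows <- list()
  hit_rows <- list()
  classifications <- list()

  for (sp in species) {
    rd <- reads[[sp]]
    hits <- pairwise_hits(rd, cl_params)
    cc <- connected_clusters(hits, length(rd))
    clusters <- filter_clusters(cc$clusters, cl_params, length(rd))
    n_family <- 0L
    examined <- head(clusters, max_clusters_per_species)
    for (cl in examined) {
      contigs <- build_contigs(cl, rd)
      contig <- contigs[1]
      memb <- family_membership(contig, reference)
      fam <- isTRUE(memb$member)
      # only genomically abundant family clusters count toward the
      # multi-cluster (fragmentation) signal; at desk scale the published
      # 0.01%-of-reads cutoff admits chance two-read clusters, so the
      # classification count uses a stricter fraction
      if (fam && length(cl$read_ids) / length(rd) >= min_family_cluster_frac) {
        n_family <- n_family + 1L
      }
      cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
        species = sp, cluster_id = cl$id, n_reads = length(cl$read_ids),
        genome_fraction = cl$genome_fraction, n_contigs = length(contigs),
        contig_len = nchar(contig), family_member = fam,
        stringsAsFactors = FALSE)
      if (fam && nchar(contig) >= 80) {
        th <- detect_tandem(contig, t_params, seq_id = paste0(sp, "_cl", cl$id))
        chosen <- th[th$chosen, , drop = FALSE]
        if (nrow(chosen) && chosen$period[1] > 1.5 * ref_len &&
            length(cl$read_ids) >= 8) {
          # a species-level HOR unit must be reproducible in an independent
          # window: a single short contig can cover one local multi-monomer
          # duplication that does not represent the array
          half <- cl$read_ids[seq_along(cl$read_ids) %% 2 == 0]
          cl2 <- structure(list(id = cl$id, read_ids = half),
                           class = "repeat_cluster")
          contig2 <- build_contigs(cl2, rd)[1]
          confirmed <- FALSE
          if (nchar(contig2) >= 1.9 * chosen$period[1]) {
            th2 <- detect_tandem(contig2, t_params)
            ch2 <- th2[th2$chosen, , drop = FALSE]
            confirmed <- nrow(ch2) > 0 &&
              abs(ch2$period[1] - chosen$period[1]) <= 0.1 * chosen$period[1]
          }
          if (!confirmed) {
            basic <- th[th$period <= 1.5 * ref_len, , drop = FALSE]
            chosen <- if (nrow(basic)) basic[which.max(basic$score), , drop = FALSE] else chosen[0, ]
          }
        }
        if (nrow(chosen)) {
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            species = sp, cluster = cl$id, period = chosen$period[1],
            copy_number = chosen$copy_number[1],
            percent_matches = chosen$percent_matches[1],
            percent_indels = chosen$percent_indels[1],
            score = chosen$score[1], consensus = chosen$consensus[1],
            family_member = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
    idx <- homogenization_index(truth$species_monomers[[sp]],
                                max_sample = index_sample,
                                seed = hash31(paste0("idx:", sp), seed))
    classifications[[sp]] <- list(sp = sp, n_family = n_family, idx = idx)
  }

  tandem_hits <- if (length(hit_rows)) {
    do.call(rbind, c(hit_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(species = character(0), cluster = integer(0),
               period = integer(0), copy_number = numeric(0),
               percent_matches = numeric(0), percent_indels = numeric(0),
               score = numeric(0), consensus = character(0),
               family_member = logical(0), stringsAsFactors = FALSE)
  }
  inventory <- hor_inventory(tandem_hits, reference_monomer_len = ref_len)

  final <- lapply(species, function(sp) {
    m <- classifications[[sp]]
    n_hor <- if (sp %in% names(inventory$counts)) inventory$counts[[sp]] else 0L
    classify_lineage(sp, m$n_family, n_hor, m$idx)
  })
  names(final) <- species

  tree_seqs <- c(unlist(truth$planted_monomer), ancestral = reference)
  tree_newick <- tryCatch(monomer_tree_pipeline(tree_seqs),
                          error = function(e) NA_character_)
  report <- lifehistory_report(final, tree_newick, inventory$counts)

  clusters_df <- if (length(cluster_rows)) {
    do.call(rbind, c(cluster_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(species = character(0), cluster_id = integer(0),
               n_reads = integer(0), genome_fraction = numeric(0),
               n_contigs = integer(0), contig_len = integer(0),
               family_member = logical(0), stringsAsFactors = FALSE)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(clusters_df, file.path(outdir, "clusters.tsv"))
    write_tsv(tandem_hits, file.path(outdir, "tandem_hits.tsv"))
    arr <- data.frame(
      id = sprintf("%s|array_1|truth_monomer_len=%d", species,
                   vapply(truth$planted_monomer[species], nchar, integer(1))),
      sequence = unlist(truth$species_arrays[species]),
      stringsAsFactors = FALSE)
    write_sequences(arr, file.path(outdir, "arrays.fasta"))
    if (!is.na(tree_newick)) {
      writeLines(tree_newick, file.path(outdir, "monomer_tree.nwk"))
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(report = report, classifications = final, clusters = clusters_df,
       tandem_hits = tandem_hits, inventory = inventory,
       tree = tree_newick, reads_per_species = lengths(reads))
}
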