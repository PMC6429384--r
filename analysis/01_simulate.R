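#!/usr/bin/env Rscript
# Simulate the study conditions: a uniform satellite array, a higher-order
# repeat array, a non-concerted multi-subfamily genome, a two-species
# descendant pair of the conserved ancestral monomer, and the seven-lineage
# tree simulation.  Writes arrays (FASTA), reads (FASTQ), the true tree
# (Newick) and the event log (TSV) under results/simulation/.

suppressMessages(library(satfam))
outdir <- "results/simulation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

for (name in c("cfic_like", "hor_worked_example", "vulvaria_like",
               "two_species_ancestor", "seven_species")) {
  fx <- fixture(name)
  arrays <- fx$truth$species_arrays
  recs <- do.call(rbind, lapply(names(arrays), function(sp) {
    data.frame(
      id = sprintf("%s|array_%d|truth_monomer_len=%d",
                   sp, seq_along(arrays[[sp]]),
                   nchar(fx$truth$planted_monomer[[sp]])),
      sequence = arrays[[sp]], stringsAsFactors = FALSE)
  }))
  write_sequences(recs, file.path(outdir, paste0(name, "_arrays.fasta")))
  cat(name, ": ", nrow(recs), "arrays,",
      sum(nchar(recs$sequence)), "bp total\n")
  if (name == "seven_species") {
    reads <- fragment_to_reads(fx$truth)
    rr <- data.frame(id = unlist(lapply(reads, names)),
                     sequence = unlist(reads), stringsAsFactors = FALSE)
    write_sequences(rr, file.path(outdir, "seven_species_reads.fastq"),
                    format = "fastq")
    writeLines(write_newick(fx$truth$true_tree),
               file.path(outdir, "seven_species_true_tree.nwk"))
    write_tsv(fx$truth$event_log, file.path(outdir, "seven_species_events.tsv"))
    cat("  reads per species:",
        paste(names(reads), lengths(reads), collapse = ", "), "\n")
    cat("  events simulated:", nrow(fx$truth$event_log), "\n")
  }
}
cat("done; simulation inputs for the later stages are regenerated on demand",
    "from the same seeds, so downstream scripts are self-contained.\n")
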