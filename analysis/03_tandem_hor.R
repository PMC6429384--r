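#!/usr/bin/env Rscript
# Tandem-repeat detection and higher-order repeat decomposition on the
# fixture arrays: the monomer table (period, copy number, percent matches,
# percent indels, consensus) and the proposed HOR inventory.  Writes
# results/tandem/monomer_table.tsv and hor_models.tsv.

suppressMessages(library(satfam))
outdir <- "results/tandem"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

rows <- list(); hor_rows <- list()
for (name in c("cfic_like", "hor_worked_example", "vulvaria_like")) {
  fx <- fixture(name)
  sp <- names(fx$truth$species_arrays)[1]
  for (ai in seq_along(fx$truth$species_arrays[[sp]])) {
    arr <- fx$truth$species_arrays[[sp]][ai]
    if (nchar(arr) < 100) next
    hits <- detect_tandem(arr, seq_id = sprintf("%s_array%d", name, ai))
    hits <- hits[hits$chosen, , drop = FALSE]
    if (!nrow(hits)) next
    rows[[length(rows) + 1L]] <- cbind(fixture = name, hits[1, ])
    m <- if (nchar(hits$consensus[1]) >= 30) {
      decompose_consensus(hits$consensus[1])
    } else NULL
    if (!is.null(m)) {
      rng <- tryCatch(unit_similarity_range(arr, m), error = function(e) c(NA, NA))
      hor_rows[[length(hor_rows) + 1L]] <- data.frame(
        fixture = name, array = ai, unit_length = m$unit_length,
        subrepeat_length = m$subrepeat_length,
        subrepeat_count = m$subrepeat_count,
        mean_internal_identity = round(mean(
          m$subrepeat_identity_matrix[upper.tri(m$subrepeat_identity_matrix)]), 1),
        inter_unit_min = round(rng[1], 1), inter_unit_max = round(rng[2], 1),
        stringsAsFactors = FALSE)
    }
  }
}
tab <- do.call(rbind, rows)
write_tsv(tab, file.path(outdir, "monomer_table.tsv"))
cat("monomer table:\n")
print(tab[, c("fixture", "period", "copy_number", "percent_matches",
              "percent_indels", "score")])
if (length(hor_rows)) {
  hor_tab <- do.call(rbind, hor_rows)
  write_tsv(hor_tab, file.path(outdir, "hor_models.tsv"))
  cat("\nproposed HOR units (decomposable consensi):\n")
  print(hor_tab)
}
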