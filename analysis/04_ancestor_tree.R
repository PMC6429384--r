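#!/usr/bin/env Rscript
# Ancestral-monomer reconstruction from exact shared fragments, and the
# alignment-free k-mer (k = 9) minimum-evolution tree of the species
# consensus monomers rooted on the ancestral reference.  Writes
# results/ancestor/{ancestral_fragment.fasta,support.tsv,monomer_tree.nwk,
# kmer_distances.tsv}.

suppressMessages(library(satfam))
outdir <- "results/ancestor"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

fx <- fixture("two_species_ancestor")
frag <- reconstruct_ancestral(fx$truth$species_monomers, min_len = 8)
cat("reconstructed conserved fragment:", frag$sequence,
    "(", frag$length, "bp )\n")
write_sequences(data.frame(id = "ancestral", sequence = frag$sequence),
                file.path(outdir, "ancestral_fragment.fasta"))
sup <- do.call(rbind, lapply(names(frag$support), function(sp) {
  cbind(species = sp, frag$support[[sp]])
}))
write_tsv(sup, file.path(outdir, "support.tsv"))

sv <- fixture("seven_species")
seqs <- c(unlist(sv$truth$planted_monomer),
          ancestral = sv$config$ancestral_monomer)
D <- kmer_distance_matrix(seqs)
write_tsv(cbind(label = rownames(D), as.data.frame(round(D, 4))),
          file.path(outdir, "kmer_distances.tsv"))
nwk <- monomer_tree_pipeline(seqs)
writeLines(nwk, file.path(outdir, "monomer_tree.nwk"))
cat("k-mer ME tree:", nwk, "\n")
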