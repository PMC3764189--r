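#!/usr/bin/env Rscript
# Build the default synthetic ortholog set: 20 genes (7 with conserved
# composite LAG-1 + FoxA sites, 5 with focal-only decayed LAG-1 sites,
# 8 negatives) across a focal species and three relatives, 5 kb upstream
# regions evolved at d = 0.05 with no indels. Inputs for the screen are
# written as FASTA/GFF3/TSV under results/fixture/.

library(cisfoot)

sim <- simulate_ortholog_set(simulation_params(seed = 1L))
paths <- write_ortholog_set(sim, "results/fixture")

cat("Simulated", nrow(sim$truth), "genes across",
    length(sim$genomes), "species\n")
print(table(sim$truth$class))
cat("Planted composite genes:",
    paste(sim$truth$gene_id[sim$truth$composite], collapse = ", "), "\n")
cat("Files written under results/fixture/\n")
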