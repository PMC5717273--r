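#!/usr/bin/env Rscript
# Step 1: simulate the paired WGBS study.
#
# Generates a 2 Mb AT-rich genome with tiled gene models, assigns a sparse
# CpG-dominant true methylome (bimodal CpG methylation, ~0.68% of CpGs in
# the high component), plants 50 differential regions of 1-3 kb with a
# methylation shift of 0.3 (60% hyper in group A), and emits per-cytosine
# bisulfite counts at 25x coverage with a non-conversion rate of 0.0015,
# plus one unmethylated lambda spike-in per library. All outputs are
# written as plain-text reports under results/sim/.

suppressMessages(library(methylscan))

outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1L)
sim <- simulate_methylome_pair(cfg)

write_fasta(sim$genome, file.path(outdir, "genome.fa"))
write_gene_models_gff3(sim$models, file.path(outdir, "genes.gff3"))
write_cytosine_report(sim$sample_a, file.path(outdir, "groupA.cx.tsv"))
write_cytosine_report(sim$sample_b, file.path(outdir, "groupB.cx.tsv"))
write_cytosine_report(sim$lambda_a, file.path(outdir, "lambdaA.cx.tsv"))
write_cytosine_report(sim$lambda_b, file.path(outdir, "lambdaB.cx.tsv"))
write_truth_bed(sim$truth, file.path(outdir, "truth.bed"))
writeLines(paste0(names(cfg), ": ", vapply(cfg, function(x)
  paste(x, collapse = ","), character(1L))),
  file.path(outdir, "config.txt"))

cat("Simulated", sum(nchar(sim$genome)), "bp on", length(sim$genome),
    "chromosomes;", nrow(sim$models$genes), "gene models;",
    nrow(sim$sample_a$records), "cytosine sites per sample;",
    nrow(sim$truth), "planted regions (",
    sum(sim$truth$direction == "hyper"), "hyper /",
    sum(sim$truth$direction == "hypo"), "hypo ).\n")
cat("Outputs in", outdir, "\n")
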