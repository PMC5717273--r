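#!/usr/bin/env Rscript
# Step 5: metagene methylation profiles and flanking k-mer preferences.
#
# Computes length-normalised (20-bin) methylation profiles over promoter,
# 5'UTR, exon, intron and 3'UTR instances per context, and characterises
# the 9-mer sequence context around methylated cytosines (position 4 = the
# methylated C), stratified into high/low methylation classes (CG: >75%,
# non-CG: >25%).

suppressMessages({
  library(methylscan)
  library(data.table)
})

simdir <- "results/sim"
tabdir <- "results/tables"
dir.create(tabdir, recursive = TRUE, showWarnings = FALSE)

genome <- read_fasta(file.path(simdir, "genome.fa"))
chrom_lengths <- vapply(genome, nchar, integer(1L))
models <- read_gene_models(file.path(simdir, "genes.gff3"))
idx <- build_component_index(models, chrom_lengths)

calls <- fread(file.path(tabdir, "site_calls_groupA.tsv"))

profiles <- rbindlist(lapply(c("CG", "CHG", "CHH"), function(ctx) {
  p <- metagene_profile(calls, idx, context = ctx, n_bins = 20L)
  p[, context := ctx]
  p
}))
fwrite(profiles, file.path(tabdir, "metagene_profiles.tsv"), sep = "\t")
cg_prom <- profiles[context == "CG" & component == "promoter" &
                      !is.na(mean_ml)]
cat(sprintf("CG promoter profile: %.4f (5' end) -> %.4f (TSS end)\n",
            cg_prom$mean_ml[1L], cg_prom$mean_ml[nrow(cg_prom)]))

mc <- calls[is_methylated == TRUE]
mc[, stratum := classify_high_low(ml_corrected, context)]
pfm_rows <- list()
for (ctx in c("CG", "CHG", "CHH")) {
  for (lev in c("high", "low")) {
    sub <- mc[context == ctx & stratum == lev]
    if (nrow(sub) == 0L) {
      cat(sprintf("stratum %s/%s: no methylated sites, skipped\n", ctx, lev))
      next
    }
    km <- extract_flanking_kmers(genome, sub[, .(chrom, pos, strand)],
                                 k = 9L, c_offset = 4L)
    if (length(km$kmers) == 0L) next
    prof <- position_frequency_matrix(km$kmers)
    cat(sprintf("stratum %s/%s: %d 9-mers, consensus %s\n",
                ctx, lev, prof$n_kmers, prof$consensus))
    pfm_rows[[paste(ctx, lev)]] <- data.table(
      context = ctx, stratum = lev, position = seq_len(prof$k),
      A = prof$pfm["A", ], C = prof$pfm["C", ],
      G = prof$pfm["G", ], T = prof$pfm["T", ],
      consensus = strsplit(prof$consensus, "")[[1L]],
      n_kmers = prof$n_kmers)
  }
}
fwrite(rbindlist(pfm_rows), file.path(tabdir, "kmer_pfms.tsv"), sep = "\t")
cat("Profiles written under", tabdir, "\n")
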