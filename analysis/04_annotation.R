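#!/usr/bin/env Rscript
# Step 4: gene-component annotation of DMRs and DMG/DEG intersection.
#
# Maps each DMR onto the gene components it overlaps (2 kb promoter, 5'UTR,
# exon, intron, 3'UTR), tabulates the component distribution split by
# hyper/hypo direction, derives the gene-level table of differentially
# methylated genes (DMGs), and intersects the DMG set with a synthetic
# differentially-expressed-gene list standing in for an external
# transcriptome study.

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
dmrs <- read_dmr_table(file.path(tabdir, "dmrs.tsv"))

idx <- build_component_index(models, chrom_lengths, promoter_length = 2000L)
ann <- annotate_dmrs(dmrs, idx)
fwrite(ann$hits, file.path(tabdir, "dmr_component_hits.tsv"), sep = "\t")

dist <- component_distribution(ann)
fwrite(dist, file.path(tabdir, "component_distribution.tsv"), sep = "\t")

dmg <- count_dmgs(ann)
fwrite(dmg, file.path(tabdir, "dmg_table.tsv"), sep = "\t")

# annotate the DMR table with its genes/components and rewrite it
hit_str <- ann$hits[, .(genes = paste(sort(unique(gene_id)), collapse = ","),
                        components = paste(sort(unique(component)),
                                           collapse = ",")),
                    by = dmr_id]
dmrs[, `:=`(genes = "", components = "")]
dmrs[hit_str$dmr_id, `:=`(genes = hit_str$genes,
                          components = hit_str$components)]
write_dmr_table(dmrs, file.path(tabdir, "dmrs_annotated.tsv"))

# synthetic DEG list: a reproducible draw from the gene universe enriched
# for DMGs, standing in for an external expression study
set.seed(2026L)
universe <- models$genes$gene_id
n_deg <- max(10L, round(0.25 * length(universe)))
pick <- unique(c(sample(dmg$gene_id, min(5L, nrow(dmg))),
                 sample(universe, n_deg)))[seq_len(n_deg)]
writeLines(sort(pick), file.path(simdir, "synthetic_deg_list.txt"))
deg <- read_deg_list(file.path(simdir, "synthetic_deg_list.txt"))
venn <- intersect_dmg_deg(dmg$gene_id, deg)
writeLines(jsonlite::toJSON(venn, auto_unbox = TRUE, pretty = TRUE),
           file.path(tabdir, "dmg_deg_venn.json"))

cat(sprintf("Annotated %d of %d DMRs to %d genes.\n",
            length(unique(ann$hits$dmr_id)), nrow(dmrs), nrow(dmg)))
print(dist)
cat(sprintf("DMG/DEG intersection: %d DMGs x %d DEGs -> %d shared genes\n",
            venn$n_dmg, venn$n_deg, venn$n_overlap))
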