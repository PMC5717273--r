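# Shared fixture builders (all fixtures are generated in code).

# Quick record table: CpG sites with consistent context/tricontext.
cg_records <- function(chrom, pos, n_meth, n_unmeth, strand = "+") {
  data.table::data.table(chrom = chrom, pos = pos, strand = strand,
                         n_meth = n_meth, n_unmeth = n_unmeth,
                         context = "CG", tricontext = "CGT")
}

# A sample pair sharing CpG positions with per-site counts chosen so group
# A has methylation level ml_a and group B ml_b at every site.
flat_pair <- function(pos, ml_a, ml_b, depth = 10L, chrom = "chr1") {
  ma <- as.integer(round(ml_a * depth))
  mb <- as.integer(round(ml_b * depth))
  a <- methylome(cg_records(chrom, pos, ma, depth - ma),
                 nonconversion_rate = 0, label = "A")
  b <- methylome(cg_records(chrom, pos, mb, depth - mb),
                 nonconversion_rate = 0, label = "B")
  list(a = a, b = b)
}

# Three-gene toy annotation used for annotation tests: plus-strand gene,
# minus-strand gene, and a plus-strand gene whose promoter is clipped at
# the contig start.
toy_models <- function() {
  genes <- data.table::data.table(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chrA", "chrA", "chrB"),
    strand = c("+", "-", "+"),
    tss = c(5000L, 20000L, 100L),
    start = c(5000L, 17201L, 100L),
    end = c(6799L, 20000L, 1899L))
  feats <- data.table::rbindlist(list(
    data.table::data.table(
      gene_id = "g1", chrom = "chrA", strand = "+",
      component = c("utr5", "exon", "intron", "exon", "utr3"),
      start = c(5000L, 5200L, 5600L, 6200L, 6600L),
      end = c(5199L, 5599L, 6199L, 6599L, 6799L)),
    data.table::data.table(
      gene_id = "g2", chrom = "chrA", strand = "-",
      component = c("utr3", "exon", "intron", "exon", "utr5"),
      start = c(17201L, 17401L, 17801L, 19401L, 19801L),
      end = c(17400L, 17800L, 19400L, 19800L, 20000L)),
    data.table::data.table(
      gene_id = "g3", chrom = "chrB", strand = "+",
      component = c("utr5", "exon", "utr3"),
      start = c(100L, 300L, 1700L),
      end = c(299L, 1699L, 1899L))))
  gene_models(genes, feats)
}

toy_chrom_lengths <- c(chrA = 30000L, chrB = 5000L)

# Deterministic random DNA string.
random_seq <- function(n, seed, gc = 0.4) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
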