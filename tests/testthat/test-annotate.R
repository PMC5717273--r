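test_that("promoters derive from the TSS per strand and clip at contig bounds", {
  idx <- build_component_index(toy_models(), toy_chrom_lengths)
  proms <- idx$components[idx$components$component == "promoter", ]
  g1 <- proms[proms$gene_id == "g1", ]   # + strand, tss 5000
  expect_equal(c(g1$start, g1$end), c(3000L, 4999L))
  g2 <- proms[proms$gene_id == "g2", ]   # - strand, tss 20000
  expect_equal(c(g2$start, g2$end), c(20001L, 22000L))
  g3 <- proms[proms$gene_id == "g3", ]   # + strand, tss 100: clipped
  expect_equal(c(g3$start, g3$end), c(1L, 99L))

  bad <- toy_models()
  bad$genes$tss[1L] <- 50000L
  expect_error(build_component_index(bad, toy_chrom_lengths), "outside contig")
})

test_that("DMR annotation matches the enumerated expectation on the toy genome", {
  idx <- build_component_index(toy_models(), toy_chrom_lengths)
  dmrs <- data.table::data.table(
    chrom = c("chrA", "chrA", "chrA", "chrB", "chrA"),
    start = c(4990L, 5550L, 21500L, 250L, 10000L),
    end = c(5010L, 6300L, 22500L, 350L, 10500L),
    direction = c("hyper", "hyper", "hypo", "hyper", "hypo"))
  ann <- annotate_dmrs(dmrs, idx)
  want <- data.table::data.table(
    dmr_id = c(1L, 1L, 2L, 2L, 3L, 4L, 4L),
    gene_id = c("g1", "g1", "g1", "g1", "g2", "g3", "g3"),
    component = c("promoter", "utr5",   # spans the promoter boundary
                  "exon", "intron",     # multi-component DMR (two exons, one row)
                  "promoter",           # minus-strand promoter only
                  "utr5", "exon"))      # chrB gene
  data.table::setorder(want, dmr_id, gene_id, component)
  expect_equal(ann$hits, want)
  # DMR 5 is intergenic and promoter-free: present but hit-less
  expect_equal(nrow(ann$dmrs), 5L)
  expect_false(5L %in% ann$hits$dmr_id)
})

test_that("every reported hit is a real interval intersection (all-pairs oracle)", {
  idx <- build_component_index(toy_models(), toy_chrom_lengths)
  set.seed(5)
  dmrs <- data.table::data.table(
    chrom = sample(c("chrA", "chrB"), 40L, replace = TRUE,
                   prob = c(0.8, 0.2)),
    start = sample.int(25000L, 40L))
  dmrs$start <- pmin(dmrs$start,
                     toy_chrom_lengths[dmrs$chrom] - 1200L)
  dmrs$end <- dmrs$start + sample(50:1200, 40L, replace = TRUE)
  dmrs$direction <- "hyper"
  ann <- annotate_dmrs(dmrs, idx)
  comp <- idx$components
  naive <- list()
  for (i in seq_len(nrow(dmrs))) {
    for (j in seq_len(nrow(comp))) {
      if (dmrs$chrom[i] == comp$chrom[j] &&
          dmrs$start[i] <= comp$end[j] && dmrs$end[i] >= comp$start[j]) {
        naive[[length(naive) + 1L]] <- data.table::data.table(
          dmr_id = i, gene_id = comp$gene_id[j], component = comp$component[j])
      }
    }
  }
  naive <- unique(data.table::rbindlist(naive))
  data.table::setorder(naive, dmr_id, gene_id, component)
  expect_equal(ann$hits[ann$hits$component != "gene_body", ], naive)
})

test_that("annotation is invariant to DMR input order", {
  idx <- build_component_index(toy_models(), toy_chrom_lengths)
  dmrs <- data.table::data.table(
    chrom = c("chrA", "chrB", "chrA"),
    start = c(4990L, 250L, 5550L), end = c(5010L, 350L, 6300L),
    direction = c("hyper", "hypo", "hyper"))
  a1 <- annotate_dmrs(dmrs, idx)
  perm <- c(3L, 1L, 2L)
  a2 <- annotate_dmrs(dmrs[perm, ], idx)
  # map a2 ids back through the permutation and compare hit sets
  remapped <- data.table::copy(a2$hits)[, dmr_id := perm[dmr_id]]
  data.table::setorder(remapped, dmr_id, gene_id, component)
  expect_equal(remapped, a1$hits)
})

test_that("mirroring the genome maps promoter hits onto promoter hits", {
  L <- toy_chrom_lengths[["chrA"]]
  m <- toy_models()
  genes <- m$genes[m$genes$chrom == "chrA", ]
  feats <- m$features[m$features$chrom == "chrA", ]
  flip <- function(s, e) list(start = L - e + 1L, end = L - s + 1L)
  mg <- data.table::copy(genes)
  mg$strand <- ifelse(genes$strand == "+", "-", "+")
  mg$tss <- L - genes$tss + 1L
  sw <- flip(genes$start, genes$end)
  mg$start <- sw$start; mg$end <- sw$end
  mf <- data.table::copy(feats)
  mf$strand <- ifelse(feats$strand == "+", "-", "+")
  swf <- flip(feats$start, feats$end)
  mf$start <- swf$start; mf$end <- swf$end
  mirror <- gene_models(mg, mf)
  idx <- build_component_index(gene_models(genes, feats), c(chrA = L))
  midx <- build_component_index(mirror, c(chrA = L))
  dmr <- data.table::data.table(chrom = "chrA", start = 4990L, end = 5010L,
                                direction = "hyper")
  swd <- flip(dmr$start, dmr$end)
  mdmr <- data.table::data.table(chrom = "chrA", start = swd$start,
                                 end = swd$end, direction = "hyper")
  h <- annotate_dmrs(dmr, idx)$hits
  mh <- annotate_dmrs(mdmr, midx)$hits
  expect_setequal(h$component, mh$component)
  expect_true("promoter" %in% mh$component)
})

test_that("component distribution counts, splits by direction and conserves", {
  idx <- build_component_index(toy_models(), toy_chrom_lengths)
  dmrs <- data.table::data.table(
    chrom = c("chrA", "chrA", "chrA"),
    start = c(5250L, 5300L, 5700L), end = c(5400L, 5500L, 5900L),
    direction = c("hyper", "hypo", "hyper"))
  ann <- annotate_dmrs(dmrs, idx)
  dist <- component_distribution(ann)
  ex <- dist[dist$component == "exon", ]
  intr <- dist[dist$component == "intron", ]
  expect_equal(ex$n_dmrs, 2L)
  expect_equal(intr$n_dmrs, 1L)
  expect_equal(ex$pct, 100 * 2 / 3)
  expect_equal(intr$pct, 100 * 1 / 3)
  expect_equal(dist$n_hyper + dist$n_hypo, dist$n_dmrs)
})

test_that("gene-level DMG table aggregates distinct DMRs with directions", {
  idx <- build_component_index(toy_models(), toy_chrom_lengths)
  dmrs <- data.table::data.table(
    chrom = c("chrA", "chrA", "chrB"),
    start = c(5250L, 6250L, 250L), end = c(5400L, 6400L, 350L),
    direction = c("hyper", "hyper", "hypo"))
  ann <- annotate_dmrs(dmrs, idx)
  dmg <- count_dmgs(ann)
  g1 <- dmg[dmg$gene_id == "g1", ]
  expect_equal(g1$n_dmrs, 2L)
  expect_true(g1$any_hyper)
  expect_false(g1$any_hypo)
  g3 <- dmg[dmg$gene_id == "g3", ]
  expect_equal(g3$n_dmrs, 1L)
  expect_true(g3$any_hypo)
  # no annotated DMRs -> empty table
  far <- data.table::data.table(chrom = "chrA", start = 12000L, end = 12100L,
                                direction = "hyper")
  expect_equal(nrow(count_dmgs(annotate_dmrs(far, idx))), 0L)
})

test_that("DMG/DEG intersection returns the Venn triple", {
  ov <- intersect_dmg_deg(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$overlap, c("b", "c"))
  expect_equal(c(ov$n_dmg, ov$n_deg, ov$n_overlap), c(3L, 3L, 2L))
  expect_equal(intersect_dmg_deg(c("a"), c("b"))$n_overlap, 0L)
  same <- intersect_dmg_deg(c("x", "y"), c("y", "x"))
  expect_equal(same$overlap, c("x", "y"))
})
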