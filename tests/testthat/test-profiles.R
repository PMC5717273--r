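test_that("high/low stratification uses the strict context thresholds", {
  expect_equal(classify_high_low(0.8, "CG"), "high")
  expect_equal(classify_high_low(0.75, "CG"), "low")    # strictly above
  expect_equal(classify_high_low(0.3, "CHH"), "high")
  expect_equal(classify_high_low(0.25, "CHG"), "low")
  expect_equal(classify_high_low(c(0.9, 0.1), c("CG", "CG")),
               c("high", "low"))
  expect_error(classify_high_low(NA_real_, "CG"), "undefined")
  expect_error(classify_high_low(0.5, "XX"), "context")
})

test_that("flanking k-mers are sliced 5'->3' on the site's strand", {
  g <- c(c1 = "TTTTTTTTTCTTTTTTTT")   # C at position 10
  got <- extract_flanking_kmers(g, data.frame(chrom = "c1", pos = 10L,
                                              strand = "+"))
  expect_equal(got$kmers, "TTTCTTTTT")
  expect_equal(got$n_skipped, 0L)

  # minus strand: reverse complement of the plus-strand slice
  g2 <- c(c1 = "AAAAAAAAAGAAAAAAAA")  # G at 10 = minus-strand C
  got2 <- extract_flanking_kmers(g2, data.frame(chrom = "c1", pos = 10L,
                                                strand = "-"))
  expect_equal(got2$kmers, "TTTCTTTTT")

  # arbitrary sequence: slice then reverse complement must agree
  g3 <- c(c1 = "ACGTTGCAGGCATTACGGA")
  got3 <- extract_flanking_kmers(g3, data.frame(chrom = "c1", pos = 10L,
                                                strand = "-"))
  expect_equal(got3$kmers, revcomp(substr(g3[[1L]], 5L, 13L)))

  # too close to the contig start: skipped and counted
  got4 <- extract_flanking_kmers(g, data.frame(chrom = "c1",
                                               pos = c(2L, 10L),
                                               strand = "+"))
  expect_equal(got4$kmers, "TTTCTTTTT")
  expect_equal(got4$n_skipped, 1L)

  # N in the window: skipped
  gn <- c(c1 = "TTTTTTTNTCTTTTTTTT")
  gotn <- extract_flanking_kmers(gn, data.frame(chrom = "c1", pos = 10L,
                                                strand = "+"))
  expect_equal(gotn$n_skipped, 1L)
})

test_that("position frequency matrix columns are probabilities with consensus", {
  p1 <- position_frequency_matrix("TTTCTTTTT")
  expect_equal(p1$consensus, "TTTCTTTTT")
  expect_equal(unname(p1$pfm["C", 4L]), 1)

  p2 <- position_frequency_matrix(c("AAACAAAAA", "TTTCTTTTT"))
  expect_equal(unname(p2$pfm["A", 1L]), 0.5)
  expect_equal(unname(p2$pfm["T", 1L]), 0.5)
  expect_equal(p2$consensus, "WWWCWWWWW")
  expect_true(all(abs(colSums(p2$pfm) - 1) < 1e-9))
  expect_equal(unname(p2$pfm["C", 4L]), 1)   # cytosine column is always pure C

  expect_error(position_frequency_matrix(character(0L)), "no k-mers")
})

test_that("metagene profile is flat for uniform methylation and conserves sites", {
  idx <- build_component_index(toy_models(), toy_chrom_lengths)
  pos <- seq(3001L, 6790L, by = 10L)
  calls <- data.table::data.table(chrom = "chrA", pos = pos, strand = "+",
                                  context = "CG", ml_corrected = 0.5)
  prof <- metagene_profile(calls, idx, context = "CG", n_bins = 10L)
  covered <- prof[!is.na(prof$mean_ml), ]
  expect_true(all(abs(covered$mean_ml - 0.5) < 1e-12))

  # conservation: binned site total equals sites inside component instances
  comp <- idx$components
  inside <- vapply(pos, function(p) {
    any(comp$chrom == "chrA" & comp$start <= p & comp$end >= p)
  }, logical(1L))
  expect_equal(sum(prof$n_sites), sum(inside))
  # empty bins are flagged, not invented
  expect_true(all(is.na(prof$mean_ml[prof$n_sites == 0L])))
})

test_that("minus-strand instances are read 5'->3' with respect to the gene", {
  # one plus gene and its mirrored minus twin with the same linear gradient
  genes <- data.table::data.table(
    gene_id = c("gp", "gm"), chrom = c("cp", "cm"), strand = c("+", "-"),
    tss = c(1001L, 3000L), start = c(1001L, 1001L), end = c(3000L, 3000L))
  feats <- data.table::data.table(
    gene_id = c("gp", "gm"), chrom = c("cp", "cm"), strand = c("+", "-"),
    component = "exon", start = 1001L, end = 3000L)
  idx <- build_component_index(gene_models(genes, feats),
                               c(cp = 4000L, cm = 4000L))
  pos <- seq(1001L, 3000L, by = 4L)
  grad <- (pos - 1001L) / 1999L
  calls <- rbind(
    data.table::data.table(chrom = "cp", pos = pos, context = "CG",
                           ml_corrected = grad),
    data.table::data.table(chrom = "cm", pos = pos, context = "CG",
                           ml_corrected = grad))
  prof <- metagene_profile(calls, idx, "CG", n_bins = 10L)
  ex <- prof[prof$component == "exon", ]
  # both instances contribute; plus ascends left-to-right, minus descends,
  # so check against the single-instance profiles
  pp <- metagene_profile(calls[calls$chrom == "cp", ],
                         build_component_index(
                           gene_models(genes[1L, ], feats[1L, ]),
                           c(cp = 4000L)), "CG", 10L)
  pm <- metagene_profile(calls[calls$chrom == "cm", ],
                         build_component_index(
                           gene_models(genes[2L, ], feats[2L, ]),
                           c(cm = 4000L)), "CG", 10L)
  pp_ex <- pp[pp$component == "exon", ]
  pm_ex <- pm[pm$component == "exon", ]
  expect_equal(pm_ex$mean_ml, rev(pp_ex$mean_ml), tolerance = 1e-9)
  expect_true(all(diff(pp_ex$mean_ml) > 0))
  expect_equal(ex$n_sites, pp_ex$n_sites + pm_ex$n_sites)
})

test_that("a planted promoter gradient is recovered as a monotone profile", {
  # promoter methylation decaying linearly toward the TSS, as metagene input
  genes <- data.table::data.table(gene_id = "g", chrom = "c", strand = "+",
                                  tss = 2001L, start = 2001L, end = 4000L)
  feats <- data.table::data.table(gene_id = "g", chrom = "c", strand = "+",
                                  component = "exon", start = 2001L,
                                  end = 4000L)
  idx <- build_component_index(gene_models(genes, feats), c(c = 5000L))
  pos <- seq(1L, 2000L, by = 3L)
  ml <- 0.8 * (2001L - pos) / 2000L    # high far upstream, ~0 at the TSS
  calls <- data.table::data.table(chrom = "c", pos = pos, context = "CG",
                                  ml_corrected = ml)
  prof <- metagene_profile(calls, idx, "CG", n_bins = 20L)
  pr <- prof[prof$component == "promoter", ]
  expect_true(all(diff(pr$mean_ml) < 0))
})
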