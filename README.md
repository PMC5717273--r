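# methylscan

Sliding-window comparison of sparse invertebrate methylomes from
whole-genome bisulfite sequencing (WGBS).

Insect methylomes — the honeybee brain is the canonical example — are
nothing like vertebrate ones: fewer than 1% of cytosines are methylated,
more than 99% of the methylated sites sit in CpG context, and individual
CpGs are either near-fully methylated or not at all. Comparing two such
methylomes (for example, a trained versus an untrained group in a learning
paradigm, each a single pooled library without replicates) calls for
count-based exact tests over sliding windows rather than replicate-aware
dispersion models. `methylscan` implements that workflow for analysts
working from Bismark-style per-cytosine reports:

- **Site calling.** The methylation level of a cytosine is
  `ML(C) = reads(mC) / (reads(mC) + reads(umC))`. The bisulfite
  non-conversion rate `r` is estimated from an unmethylated lambda
  spike-in as `r = Σ n_meth / Σ (n_meth + n_unmeth)` and levels are
  corrected as `ML' = max(0, (ML − r) / (1 − r))`. A site is called
  methylated when the one-sided binomial tail
  `P(X ≥ n_meth | n, r)` survives Benjamini–Hochberg correction at
  FDR 0.05 (depth ≥ 5).
- **Context statistics and landscape.** Strand-aware CG/CHG/CHH
  classification (H ∈ {A, C, T}, read 5′→3′ on the cytosine's strand),
  genome-wide mC percentages per context, and a 3000 bp / 600 bp
  sliding-window methylation landscape.
- **DMR calling.** 1000 bp windows stepped by 100 bp; windows with
  strictly more than 10 cytosines covered in both samples are tested;
  windows with fold change > 2 **and** methylation difference > 0.1
  **and** Fisher's exact P < 0.05 are potential DMRs; after FDR
  correction (q < 0.05), overlapping candidates are merged and re-tested
  iteratively until a fixed point, yielding a non-overlapping final set
  with hyper/hypo directions.
- **Annotation.** DMRs are assigned to every gene component they overlap
  by ≥ 1 bp — promoter (2 kb upstream of the TSS), 5′UTR, exon, intron,
  3′UTR — giving component distributions and a gene-level DMG table to
  intersect with external differentially-expressed-gene lists.
- **Profiles.** Length-normalised metagene methylation profiles per
  component and context, and 9-mer position-frequency matrices around
  methylated sites stratified into high/low methylation (CG: > 75%,
  non-CG: > 25%).
- **Simulation.** A synthetic methylome generator that emulates the
  sparse CpG-dominant regime (bimodal CpG methylation, Poisson coverage,
  binomial counts with conversion failure, lambda spike-in) and plants
  differential regions with ground truth, so the whole pipeline can be
  evaluated end to end.

## Worked example

The `analysis/` directory is a numbered workflow over the package; running
the scripts in order reproduces the full study on synthetic data:

```sh
Rscript analysis/01_simulate.R        # paired 2 Mb study with 50 planted regions
Rscript analysis/02_site_calls.R      # site calls + context statistics
Rscript analysis/03_dmr_detection.R   # DMR calling + truth evaluation
Rscript analysis/04_annotation.R      # gene-component annotation, DMG/DEG overlap
Rscript analysis/05_context_profiles.R  # metagene profiles + 9-mer PFMs
```

Step 3 prints, for the default configuration (seed 1):

```
Called 50 DMRs (30 hyper, 20 hypo) against 50 planted regions:
  sensitivity 1.000, precision 1.000 at 30% overlap
  group A median DMR level 0.167 vs group B 0.003
```

i.e. every planted 1–3 kb region with a methylation shift of 0.3 is
recovered at the swDMR-style thresholds, with no false regions, and the
group-A/group-B contrast inside the called regions matches the planted
direction split. Step 2 reports each library's bisulfite conversion rate
(≈ 99.85%, the spike-in regime) and step 4 tabulates the component
distribution of the calls (exons and introns carrying the largest shares).

The same machinery is available programmatically:

```r
library(methylscan)
sim  <- simulate_methylome_pair(sim_config(seed = 1))
dmrs <- call_dmrs(sim$sample_a, sim$sample_b, sim$lambda_a, sim$lambda_b,
                  chrom_lengths = sim$chrom_lengths)
evaluate_calls(dmrs, sim$truth, min_overlap_fraction = 0.3)[c("sensitivity", "precision")]
#> $sensitivity [1] 1      $precision [1] 1
```

## Limitations

One pooled sample per group is assumed (no replicate-aware dispersion
modelling); read-level artefacts (alignment, duplicates, sequencing
error) are upstream of this package and out of scope, as are GO/KEGG
enrichment of the resulting gene lists.
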