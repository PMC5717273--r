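---
title: "Comparing sparse methylomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing sparse methylomes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methylscan` compares two whole-genome bisulfite sequencing (WGBS)
methylomes of the sparse, CpG-dominant kind found in insects. This
vignette is the package's own account of the statistical models it uses,
the parameters that matter, what the bundled simulator does and does not
emulate, and the choices made where the design was genuinely open.

## The observation model

Bisulfite treatment converts unmethylated cytosines to uracil (read as T)
while methylated cytosines stay C. For a cytosine covered by
`n = reads(mC) + reads(umC)` reads, the methylation level is the fraction

```
ML(C) = reads(mC) / (reads(mC) + reads(umC)).
```

Conversion is imperfect: a fraction `r` of truly unmethylated cytosines
escapes conversion and is read as methylated. `r` is estimated from an
unmethylated lambda-phage spike-in as the pooled ratio of methylated to
total read counts over all lambda cytosines; the commonly reported
"BS conversion rate" is `1 − r` (the spike-in regime here is
`r ≈ 0.0015`, i.e. conversion ≈ 99.85%). Observed levels are corrected by
inverting the mixture `ML_obs = ML + (1 − ML)·r`:

```
ML' = max(0, (ML_obs − r) / (1 − r)),
```

clamped at zero so sites below the non-conversion floor do not go
negative. Every downstream computation consumes the corrected level; the
correction is applied uniformly because applying it only in some places
would make effect sizes incomparable across modules.

### Site calling

The methylated count at a site is modelled as Binomial(n, p). Under the
null hypothesis that the site is unmethylated, p = r, so a site is
declared methylated when the one-sided upper tail
`P(X ≥ reads(mC) | n, r)` is small. One-sidedness is deliberate — only an
*excess* of methylated reads is evidence of methylation; a deficit is
noise. P-values are corrected across all tested sites by
Benjamini–Hochberg, and a site is called at `q < alpha` (default 0.05)
with at least one methylated read. Sites below `min_depth` (default 5
reads — the coverage level at which a binomial call starts to be
meaningful, and a conventional WGBS reporting threshold) are not tested.
The degenerate case `r = 0` with methylated reads present yields `p = 0`
without numerical failure.

### Context classification

Contexts are read 5′→3′ on the cytosine's own strand: CG when the next
base is G; CHG when the next base is H (A, C or T) and the one after is
G; CHH otherwise. Minus-strand sites are plus-strand Gs whose downstream
bases are the reverse complement of the upstream plus-strand bases.
Sites within 2 bp of the strandwise contig end, or whose two downstream
bases include an N, have undefined context and are excluded from every
statistic — a truncated context could misclassify CHG/CHH.

## The DMR caller

Regions, not single sites, are the unit of biological interest. The
caller scans each chromosome with windows of 1000 bp stepped by 100 bp
(both configurable through `dmr_params()`); these values, along with all
thresholds below, are the standard parameterisation of sliding-window DMR
detection for single-library insect WGBS comparisons:

1. A window is testable only when **strictly more than** `min_sites = 10`
   cytosines reach `min_depth` coverage in *both* samples. A window
   testable in one sample only is uninterpretable, so the depth filter is
   applied jointly.
2. Per testable window, each group's level is the **unweighted mean of
   per-site corrected MLs**, while the test statistic is Fisher's exact
   test on the **pooled raw counts**
   `[[Σ mC_A, Σ umC_A], [Σ mC_B, Σ umC_B]]`. The split is intentional:
   counts carry the evidence, site means define the effect size on the
   methylation scale.
3. Windows pass when fold change > 2 **and** |difference| > 0.1 **and**
   Fisher P < 0.05 — all strict inequalities, read literally from the
   thresholds' definitions (a fold change of exactly 2 fails). The fold
   change is `max(m_A, m_B) / max(min(m_A, m_B), ε)` with zero-guard
   `ε = 1e-6`, which avoids infinite folds at ML 0 while preserving
   ranking; the dual filter means ε never decides a call on its own,
   because a window passing on fold alone still needs difference > 0.1.
4. Benjamini–Hochberg is applied across the passing windows and
   candidates with q < 0.05 are kept.
5. Overlapping candidates (≥ 1 bp; adjacent windows do not merge) are
   unioned into spans, each span is re-tested from scratch (site count,
   group means, fold, difference, Fisher P), spans failing any filter are
   dropped entirely (no splitting back — the simplest rule that reaches a
   fixed point), and the cycle repeats until nothing changes (guarded at
   100 iterations; after the first union the span set is non-overlapping,
   so the guard is defensive). A final BH pass over the surviving spans
   keeps q < 0.05 and assigns the hyper/hypo direction from the group
   means (hyper = group A higher).

FDR placement during the iteration was an open choice: the contract here
is raw-P plus effect-size filters inside the loop, with FDR applied once
at window selection and once over the final spans. Applying BH inside
every iteration would make q-values depend on the transient number of
spans, which changes as regions merge.

Fisher's exact test is implemented in the package (two-sided by summing
hypergeometric point probabilities not exceeding the observed table's,
with the conventional 1e-7 relative tie slack) because its exact tie
behaviour is part of the caller's contract; the table is canonicalised by
row/column swaps — which leave the p-value invariant — so relabelling the
samples produces bit-identical p-values and exactly mirrored calls. The
test suite cross-checks it against both `stats::fisher.test` and an
independent log-binomial enumeration. BH correction delegates to
`stats::p.adjust`.

## Annotation and profiles

The promoter is the 2 kb immediately upstream of the TSS
(`[tss − 2000, tss − 1]` on +, `[tss + 1, tss + 2000]` on −, clipped to
the contig). Gene-body components are made disjoint by subtracting UTR
intervals from exons; introns are the gaps between a gene's sorted exons.
When a gene has several transcripts the representative is the one with
the longest genomic span — components are annotated per gene, not per
isoform. A DMR collects a (gene, component) hit for every component it
overlaps by ≥ 1 bp, so one DMR may legitimately hit several genes and
several components; a DMR inside an annotated gene's span that touches no
component (an annotation gap, e.g. missing UTRs) is kept as a `gene_body`
hit so the gene is not silently lost, but that fallback category is
excluded from component percentages.

Metagene profiles divide every component instance into `n_bins = 20`
equal-length bins oriented 5′→3′ with respect to the gene — 20 bins
resolves within-component trends at the component sizes the simulator
produces without emptying bins. A site's bin is its fractional position
`(pos − start + 0.5) / width`; instances shorter than the bin count
simply populate the bins their sites fall into. Empty bins report an
`NA` mean and a zero count rather than an invented value.

K-mer preference analysis takes the sites passing the methylation call,
stratifies them into high/low (CG: ML > 0.75, non-CG: ML > 0.25, strict,
following the conventional high/low definition for each context class),
and extracts the 9-mer with the cytosine at position 4 (three bases
upstream, five downstream) read 5′→3′ on the site's strand. The offset is
a parameter because the alignment convention is not canonical; 4 centres
the immediate upstream context that non-CG methylation discriminates.
Consensus ties become IUPAC ambiguity codes; windows leaving the contig
or containing N are skipped and counted.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions the package is
designed for:

| parameter | default | meaning |
|---|---|---|
| `genome_length_bp` | 2 Mb (4 chromosomes) | desk-scale stand-in for a 200+ Mb genome |
| `gc_fraction` | 0.33 | AT-rich insect genome |
| `cg_meth_high_fraction` | 0.0068 | expected mCG/CG fraction (≈ 0.68%) |
| `beta_high_mean`, `beta_high_conc` | 0.8, 10 | high-methylation Beta component |
| `noncg_meth_rate` | 0 | near-zero non-CG methylation |
| `mean_coverage` | 25 | Poisson read depth |
| `nonconversion_rate` | 0.0015 | conversion ≈ 99.85% |
| `n_dmrs`, `dmr_length_range`, `dmr_delta` | 50, 1–3 kb, 0.3 | planted differential regions |
| `dmr_hyper_fraction` | 0.6 | hyper share of planted regions |

CpG methylation is a two-component mixture: with probability
`cg_meth_high_fraction` a site's true level is drawn from
Beta(mean 0.8, concentration 10); otherwise it is exactly 0. "Exactly 0"
rather than "a small positive level" is a deliberate simplification — it
makes the expected genome-wide mCG/CG fraction equal the mixture weight,
so parameter-recovery checks have a closed-form target, and it matches
the observation that unmethylated insect CpGs show no intermediate
levels. Both strands of a CpG are drawn independently, since nothing in
the pipeline assumes strand symmetry. With these defaults roughly 0.1–0.2%
of all cytosines carry methylation, >99% of it at CpGs — the sparse
regime the caller is built for. Coverage is Poisson rather than negative
binomial: only a mean-coverage figure is being emulated, and
overdispersion would only loosen the calibration checks without changing
any contract.

Planted regions are non-overlapping (≥ 2 kb apart), restricted to
stretches with at least 10 CpGs per kb so the caller's site filter is
satisfiable, and shift **every cytosine** in the region by `dmr_delta` in
exactly one group: hyper regions shift group A up, hypo regions shift
group B up. The asymmetric-up construction exists because the sparse
baseline sits near ML 0 — shifting group A *down* from zero would clamp
to no shift at all, making hypomethylated truth regions unrecoverable by
construction. Shifting the opposite group up instead gives
`|ML_A − ML_B| = delta` inside every region for both directions, which is
what a recovery benchmark needs.

What the generator does **not** emulate: read-level artefacts (alignment
ambiguity, duplicates, sequencing error), fragment-level correlation
between neighbouring sites' coverage, chromosome-scale methylation
domains, CpG-island structure, and biological replication (one pooled
sample per group, matching the no-replicate design rather than improving
on it). Passing the end-to-end tests therefore demonstrates that the
caller recovers clean planted signal at realistic sparsity, coverage and
conversion noise — not that it is robust to alignment artefacts or
between-replicate variance.

## Numerical conventions and degenerate inputs

- Coordinates are 1-based inclusive in every on-disk format (cytosine
  reports, GFF3, DMR tables); BED is the single 0-based half-open format
  and is converted at the reader/writer boundary only.
- Zero-coverage methylation level is `NA`, never 0 — "no data" and
  "unmethylated" are different statements.
- Zero-read cytosines may appear in reports and are retained in the
  sample; depth filters exclude them downstream.
- DMR tables write numerics with 17 significant digits so
  write-then-read round-trips bit-exactly.
- Quartile summaries of DMR levels use the linear-interpolation
  convention (`quantile` type 7), matching standard boxplot statistics.
- An empty lambda sample, an all-zero Fisher table, an empty truth set,
  an empty k-mer set and an empty DMR list are errors, not silent zeros.

## Problem sizes

The test suite and the acceptance script run the full pipeline on 2 Mb
genomes at 25× coverage (about 1.3 M cytosine records per sample), with
smaller 60–400 kb configurations for targeted properties; these sizes
give the statistical checks (sensitivity/precision of region recovery,
FDR calibration on the spike-in, parameter recovery within ±10%) enough
sites to be meaningful while keeping a full run in minutes on one CPU.

## Known limitations

Single-site differential testing, strand-merged CpG calls,
replicate-aware dispersion models (beta-binomial) and smoothing-based
region callers are out of scope. GO/KEGG enrichment is deliberately not
implemented; the gene-level DMG table is exportable to any enrichment
tool. The merge rule drops a failing merged span entirely rather than
splitting it back into passing sub-windows; with clean planted signal the
two behaviours coincide, but on marginal real regions the rule is
conservative.
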