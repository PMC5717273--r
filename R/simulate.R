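# Gene template used when tiling synthetic gene models (bp):
# utr5 200 | exon 400 | intron 600 | exon 400 | intron 600 | exon 400 | utr3 200
GENE_TEMPLATE <- list(utr = 200L, exon = 400L, intron = 600L, n_exons = 3L)
GENE_SPAN <- with(GENE_TEMPLATE, 2L * utr + n_exons * exon + (n_exons - 1L) * intron)

#' Simulate a genome and tiled gene models
#'
#' Draws a random sequence at the configured GC fraction, split into
#' `n_chroms` equal chromosomes, and tiles gene models (alternating strands)
#' with a fixed utr5/exon/intron/utr3 template separated by intergenic gaps
#' wide enough to host 2 kb promoters. Deterministic under the config seed.
#'
#' @param config a [sim_config] object.
#' @return List with `genome` (named character vector) and `models`
#'   (a [gene_models] object).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  len <- as.integer(floor(config$genome_length_bp / config$n_chroms))
  gc <- config$gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome <- character(config$n_chroms)
  names(genome) <- paste0("chr", seq_len(config$n_chroms))
  for (i in seq_len(config$n_chroms)) {
    genome[i] <- paste(sample(names(probs), len, replace = TRUE, prob = probs),
                       collapse = "")
  }
  period <- GENE_SPAN + config$gene_spacing_bp
  first <- config$gene_spacing_bp + 1L
  last_start <- len - GENE_SPAN - 2000L
  if (last_start < first) {
    stop("genome too short to host gene models: need at least ",
         first + GENE_SPAN + 2000L, " bp per chromosome")
  }
  genes <- list(); feats <- list()
  for (i in seq_len(config$n_chroms)) {
    chr <- names(genome)[i]
    starts <- seq.int(first, last_start, by = period)
    for (j in seq_along(starts)) {
      s <- starts[j]
      strand <- if (j %% 2L == 1L) "+" else "-"
      gid <- sprintf("g_%s_%03d", chr, j)
      u <- GENE_TEMPLATE$utr; e <- GENE_TEMPLATE$exon; intr <- GENE_TEMPLATE$intron
      bounds <- s + cumsum(c(0L, u, e, intr, e, intr, e, u)) # 8 breakpoints
      comp_plus <- c("utr5", "exon", "intron", "exon", "intron", "exon", "utr3")
      comp <- if (strand == "+") comp_plus else rev(comp_plus)
      fs <- bounds[-length(bounds)]
      fe <- bounds[-1L] - 1L
      feats[[length(feats) + 1L]] <- data.table(
        gene_id = gid, chrom = chr, strand = strand,
        component = comp, start = fs, end = fe)
      genes[[length(genes) + 1L]] <- data.table(
        gene_id = gid, chrom = chr, strand = strand,
        tss = if (strand == "+") s else s + GENE_SPAN - 1L,
        start = s, end = s + GENE_SPAN - 1L)
    }
  }
  list(genome = genome,
       models = gene_models(rbindlist(genes), rbindlist(feats)))
}

#' Assign a true methylation level to every cytosine
#'
#' CpG cytosines are drawn from a two-component mixture: with probability
#' `cg_meth_high_fraction` the true methylation level comes from a Beta
#' distribution (mean `beta_high_mean`, concentration `beta_high_conc`);
#' otherwise it is exactly 0. Non-CpG cytosines get `noncg_meth_rate`. Both
#' strands of a CpG are drawn independently.
#'
#' @param genome named character vector of sequences.
#' @param config a [sim_config] object.
#' @param seed integer seed for this step (derived from the config seed by
#'   default).
#' @return data.table of cytosine sites (as [cytosine_sites()]) with an
#'   added `ml` column of true methylation levels.
#' @export
assign_true_methylome <- function(genome, config, seed = config$seed + 1000L) {
  stopifnot(inherits(config, "sim_config"))
  sites <- cytosine_sites(genome)
  set.seed(seed)
  sites[, ml := 0]
  is_cg <- sites$context == "CG"
  ncg <- sum(is_cg)
  if (ncg > 0L) {
    a <- config$beta_high_mean * config$beta_high_conc
    b <- (1 - config$beta_high_mean) * config$beta_high_conc
    high <- runif(ncg) < config$cg_meth_high_fraction
    draw <- rbeta(ncg, a, b)
    sites[is_cg, ml := ifelse(high, draw, 0)]
  }
  sites[context != "CG", ml := config$noncg_meth_rate]
  sites[]
}

#' Plant differential regions into a true methylome
#'
#' Chooses `n_dmrs` non-overlapping regions (lengths uniform in
#' `dmr_length_range`, at least 2 kb apart, restricted to stretches with at
#' least 10 CpG sites per kb) and creates the two group maps: inside a
#' hypermethylated region every cytosine of group A is shifted up by
#' `dmr_delta` (clamped to 1); inside a hypomethylated region group B is
#' shifted up instead, so group A is lower by `dmr_delta`. Outside planted
#' regions the two maps are identical.
#'
#' @param truth_map output of [assign_true_methylome()].
#' @param config a [sim_config] object.
#' @param chrom_lengths named integer vector of sequence lengths.
#' @param seed integer seed for this step.
#' @return List with `map_a`, `map_b` (per-group true ML maps) and
#'   `regions` (data.table chrom, start, end, direction, delta; sorted,
#'   pairwise disjoint).
#' @export
plant_dmrs <- function(truth_map, config, chrom_lengths,
                       seed = config$seed + 2000L) {
  stopifnot(inherits(config, "sim_config"))
  map_a <- copy(truth_map)
  map_b <- copy(truth_map)
  n <- config$n_dmrs
  if (n == 0L) {
    return(list(map_a = map_a, map_b = map_b,
                regions = data.table(chrom = character(), start = integer(),
                                     end = integer(), direction = character(),
                                     delta = numeric())))
  }
  set.seed(seed)
  cg <- truth_map[context == "CG", .(chrom, pos)]
  setkey(cg, chrom, pos)
  chroms <- names(chrom_lengths)
  placed <- data.table(chrom = character(), start = integer(), end = integer())
  min_gap <- 2000L
  attempts <- 0L
  while (nrow(placed) < n) {
    attempts <- attempts + 1L
    if (attempts > 20000L) {
      stop("cannot place ", n, " non-overlapping regions; genome too small")
    }
    len <- sample(config$dmr_length_range[1L]:config$dmr_length_range[2L], 1L)
    chr <- sample(chroms, 1L, prob = chrom_lengths / sum(chrom_lengths))
    maxs <- chrom_lengths[[chr]] - len + 1L
    if (maxs < 1L) next
    s <- sample.int(maxs, 1L)
    e <- s + len - 1L
    same <- placed[chrom == chr]
    if (nrow(same) && any(s <= same$end + min_gap & e >= same$start - min_gap)) next
    n_cg <- nrow(cg[.(chr), nomatch = 0L][pos >= s & pos <= e])
    if (n_cg < 10 * len / 1000) next
    placed <- rbind(placed, data.table(chrom = chr, start = s, end = e))
  }
  n_hyper <- round(n * config$dmr_hyper_fraction)
  dirs <- sample(c(rep("hyper", n_hyper), rep("hypo", n - n_hyper)))
  placed[, direction := dirs]
  placed[, delta := config$dmr_delta]
  d <- config$dmr_delta
  for (i in seq_len(nrow(placed))) {
    r <- placed[i]
    if (r$direction == "hyper") {
      map_a[chrom == r$chrom & pos >= r$start & pos <= r$end,
            ml := pmin(1, ml + d)]
    } else {
      map_b[chrom == r$chrom & pos >= r$start & pos <= r$end,
            ml := pmin(1, ml + d)]
    }
  }
  setorder(placed, chrom, start)
  list(map_a = map_a, map_b = map_b, regions = placed[])
}

#' Emit observed bisulfite counts from a true methylation map
#'
#' Per site, coverage is Poisson(`mean_coverage`); the probability that a
#' read reports a methylated C is `ml + (1 - ml) * r`, where `r` is the
#' bisulfite non-conversion rate (truly unmethylated cytosines escaping
#' conversion are read as methylated); the methylated count is Binomial.
#' Zero-coverage sites are retained (downstream depth filters drop them).
#'
#' @param true_map data.table with chrom, pos, strand, context, tricontext,
#'   ml.
#' @param config a [sim_config] object.
#' @param seed integer seed for this step.
#' @param label sample label.
#' @return A [methylome] object (non-conversion rate unset, as for a real
#'   sample before lambda estimation).
#' @export
emit_counts <- function(true_map, config, seed = config$seed + 3000L,
                        label = "sim") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  N <- nrow(true_map)
  depth <- rpois(N, config$mean_coverage)
  p_obs <- true_map$ml + (1 - true_map$ml) * config$nonconversion_rate
  n_meth <- rbinom(N, depth, p_obs)
  rec <- data.table(chrom = true_map$chrom, pos = true_map$pos,
                    strand = true_map$strand, n_meth = n_meth,
                    n_unmeth = depth - n_meth,
                    context = true_map$context,
                    tricontext = true_map$tricontext)
  methylome(rec, label = label)
}

#' Emit an unmethylated lambda spike-in sample
#'
#' Simulates the unmethylated lambda-phage control used to estimate the
#' bisulfite non-conversion rate: a separate contig with true methylation 0
#' at every cytosine, observed through the same coverage and conversion
#' model as [emit_counts()].
#'
#' @param config a [sim_config] object.
#' @param lambda_length contig length in bp (default: the configured
#'   lambda length, 48502 bp as for phage lambda).
#' @param seed integer seed for this step.
#' @param label sample label.
#' @return A [methylome] object on contig `"lambda"`.
#' @export
emit_lambda <- function(config, lambda_length = config$lambda_length_bp,
                        seed = config$seed + 5000L, label = "lambda") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  seq <- paste(sample(DNA_BASES, lambda_length, replace = TRUE), collapse = "")
  genome <- c(lambda = seq)
  sites <- cytosine_sites(genome)
  sites[, ml := 0]
  # reuse the current RNG stream for counts
  N <- nrow(sites)
  depth <- rpois(N, config$mean_coverage)
  n_meth <- rbinom(N, depth, config$nonconversion_rate)
  rec <- data.table(chrom = sites$chrom, pos = sites$pos,
                    strand = sites$strand, n_meth = n_meth,
                    n_unmeth = depth - n_meth, context = sites$context,
                    tricontext = sites$tricontext)
  methylome(rec, label = label)
}

#' Simulate a full paired-methylome study
#'
#' Orchestrates [simulate_genome()], [assign_true_methylome()],
#' [plant_dmrs()], [emit_counts()] for both groups and [emit_lambda()] for
#' both libraries, deriving one sub-seed per stage from the config seed.
#' One pooled sample per group, mirroring a no-replicate WGBS design.
#'
#' @param config a [sim_config] object.
#' @return List with genome, models, chrom_lengths, map_a, map_b, truth
#'   (planted regions), sample_a, sample_b, lambda_a, lambda_b, config.
#' @export
simulate_methylome_pair <- function(config = sim_config()) {
  g <- simulate_genome(config)
  chrom_lengths <- vapply(g$genome, nchar, integer(1L))
  truth_map <- assign_true_methylome(g$genome, config)
  pl <- plant_dmrs(truth_map, config, chrom_lengths)
  list(genome = g$genome,
       models = g$models,
       chrom_lengths = chrom_lengths,
       map_a = pl$map_a,
       map_b = pl$map_b,
       truth = pl$regions,
       sample_a = emit_counts(pl$map_a, config, seed = config$seed + 3000L,
                              label = "groupA"),
       sample_b = emit_counts(pl$map_b, config, seed = config$seed + 4000L,
                              label = "groupB"),
       lambda_a = emit_lambda(config, seed = config$seed + 5000L,
                              label = "lambdaA"),
       lambda_b = emit_lambda(config, seed = config$seed + 6000L,
                              label = "lambdaB"),
       config = config)
}

#' Evaluate called DMRs against planted truth regions
#'
#' A truth region counts as recovered when some single called DMR overlaps
#' at least `min_overlap_fraction` of it. Sensitivity is the recovered
#' fraction of truth regions; precision is the fraction of called DMRs that
#' overlap any truth region by at least 1 bp.
#'
#' @param calls data.frame of called DMRs (chrom, start, end).
#' @param truth data.frame of truth regions (chrom, start, end); must be
#'   non-empty.
#' @param min_overlap_fraction required covered fraction of a truth region.
#' @return List with sensitivity, precision (NA when nothing was called),
#'   n_called, n_truth, and `hits`, a per-truth-region table with the best
#'   single-call overlap fraction and a recovered flag.
#' @export
evaluate_calls <- function(calls, truth, min_overlap_fraction = 0.3) {
  truth <- as.data.table(truth)
  calls <- as.data.table(calls)
  if (nrow(truth) == 0L) stop("empty truth set: sensitivity undefined")
  best <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i]
    cand <- calls[chrom == tr$chrom]
    if (nrow(cand) == 0L) next
    ov <- pmax(0L, pmin(cand$end, tr$end) - pmax(cand$start, tr$start) + 1L)
    best[i] <- max(ov) / (tr$end - tr$start + 1L)
  }
  hits <- data.table(truth[, .(chrom, start, end)],
                     best_overlap = best,
                     recovered = best >= min_overlap_fraction)
  called_hit <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i]
    tr <- truth[chrom == cl$chrom]
    if (nrow(tr) == 0L) next
    called_hit[i] <- any(pmin(tr$end, cl$end) - pmax(tr$start, cl$start) >= 0L)
  }
  list(sensitivity = mean(hits$recovered),
       precision = if (nrow(calls)) mean(called_hit) else NA_real_,
       n_called = nrow(calls),
       n_truth = nrow(truth),
       hits = hits[])
}
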