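#' Estimate the bisulfite non-conversion rate from a lambda spike-in
#'
#' The lambda genome is unmethylated, so any cytosine sequenced as C at a
#' lambda reference position reflects failed conversion. The rate is the
#' pooled ratio r = sum(n_meth) / sum(n_meth + n_unmeth) over all lambda
#' cytosines; the BS conversion rate usually reported is `1 - r`.
#'
#' @param lambda_sample a [methylome] of the lambda spike-in.
#' @return r, a fraction in `[0, 1]`.
#' @export
estimate_nonconversion <- function(lambda_sample) {
  stopifnot(inherits(lambda_sample, "methylome"))
  rec <- lambda_sample$records
  total <- sum(as.numeric(rec$n_meth)) + sum(as.numeric(rec$n_unmeth))
  if (nrow(rec) == 0L || total == 0) {
    stop("lambda sample has no sequenced cytosines; cannot estimate r")
  }
  sum(as.numeric(rec$n_meth)) / total
}

#' Per-site methylation level
#'
#' ML(C) = reads(mC) / (reads(mC) + reads(umC)). Zero-coverage sites are
#' undefined and return `NA` (distinct from 0).
#'
#' @param n_meth,n_unmeth non-negative read counts (vectorised).
#' @return Numeric vector of methylation levels in `[0, 1]`, `NA` where
#'   coverage is zero.
#' @export
methylation_level <- function(n_meth, n_unmeth) {
  if (any(n_meth < 0, na.rm = TRUE) || any(n_unmeth < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  total <- n_meth + n_unmeth
  ifelse(total > 0, n_meth / total, NA_real_)
}

#' Correct a methylation level for bisulfite non-conversion
#'
#' Inverts the observation model `ml_obs = ml + (1 - ml) * r`:
#' `ml_corrected = max(0, (ml_obs - r) / (1 - r))`, clamped at zero so
#' levels below the non-conversion floor do not go negative.
#'
#' @param ml_raw observed methylation level(s) in `[0, 1]`.
#' @param r non-conversion rate in `[0, 1)`.
#' @return Corrected methylation level(s).
#' @export
correct_ml <- function(ml_raw, r) {
  if (length(r) != 1L || is.na(r) || r < 0 || r >= 1) {
    stop("r must be a single value in [0, 1)")
  }
  pmax(0, (ml_raw - r) / (1 - r))
}

#' Call methylated cytosine sites with a binomial test
#'
#' For every site with depth >= `min_depth`, tests the one-sided binomial
#' tail P(X >= n_meth | n, r) against the null that all methylated reads
#' are conversion failures at rate `r`. P-values are corrected across all
#' tested sites by Benjamini-Hochberg; a site is called methylated when
#' q < `alpha` and it has at least one methylated read.
#'
#' @param sample a [methylome] object.
#' @param r non-conversion rate; defaults to the sample's stored rate.
#' @param alpha FDR level for the methylation call.
#' @param min_depth minimum read depth for a site to be tested.
#' @return data.table of tested sites with ml_raw, ml_corrected, p_value,
#'   q_value and is_methylated columns.
#' @export
call_methylated_sites <- function(sample, r = NULL, alpha = 0.05,
                                  min_depth = 5L) {
  stopifnot(inherits(sample, "methylome"))
  if (is.null(r)) r <- sample$nonconversion_rate
  if (is.na(r)) stop("non-conversion rate unknown; pass r or estimate it")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  calls <- copy(sample$records)
  calls[, depth := n_meth + n_unmeth]
  calls <- calls[depth >= min_depth]
  calls[, ml_raw := methylation_level(n_meth, n_unmeth)]
  calls[, ml_corrected := correct_ml(ml_raw, r)]
  # one-sided upper tail; r = 0 with n_meth > 0 gives p = 0 cleanly
  calls[, p_value := pbinom(n_meth - 1L, depth, r, lower.tail = FALSE)]
  calls[, q_value := bh_fdr(p_value)]
  calls[, is_methylated := q_value < alpha & n_meth >= 1L]
  calls[]
}

#' Genome-wide methylation context statistics
#'
#' Tabulates methylated-site percentages per context relative to the
#' genome-wide context census (all cytosines with defined context) and the
#' distribution of methylated sites across CG/CHG/CHH.
#'
#' @param calls output of [call_methylated_sites()].
#' @param genome named character vector of sequences (for the census).
#' @return List with n_mC, pct_mC_of_C, pct_mCG_of_CG, pct_mCHG_of_CHG,
#'   pct_mCHH_of_CHH (percent scale) and `context_shares`, the fractions of
#'   methylated sites in each context (sums to 1; NA when n_mC is 0, with
#'   the percentage fields all 0).
#' @export
genome_wide_stats <- function(calls, genome) {
  census <- cytosine_sites(genome)
  tot <- census[, .N, by = context]
  totals <- c(CG = 0, CHG = 0, CHH = 0)
  totals[tot$context] <- tot$N
  mc <- calls[is_methylated == TRUE, .N, by = context]
  mcounts <- c(CG = 0, CHG = 0, CHH = 0)
  mcounts[mc$context] <- mc$N
  n_mC <- sum(mcounts)
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  shares <- if (n_mC > 0) mcounts / n_mC else
    c(CG = NA_real_, CHG = NA_real_, CHH = NA_real_)
  list(n_mC = n_mC,
       pct_mC_of_C = pct(n_mC, sum(totals)),
       pct_mCG_of_CG = pct(mcounts[["CG"]], totals[["CG"]]),
       pct_mCHG_of_CHG = pct(mcounts[["CHG"]], totals[["CHG"]]),
       pct_mCHH_of_CHH = pct(mcounts[["CHH"]], totals[["CHH"]]),
       context_shares = shares)
}

#' Sliding-window methylation landscape
#'
#' Tiles each chromosome with windows of `window` bp stepped by `step` bp
#' starting at position 1 (the last windows are truncated at the contig
#' end) and pools read counts per window. Empty windows are emitted with
#' zero counts; the pooled methylation level of an empty window is `NA`.
#'
#' @param sample a [methylome] object.
#' @param window window size in bp.
#' @param step step size in bp.
#' @param chrom_lengths named vector of contig lengths; defaults to the
#'   largest covered position per contig.
#' @return data.table with chrom, start, end, n_sites (covered cytosines),
#'   n_meth, n_unmeth, ml_pooled.
#' @export
sliding_window_landscape <- function(sample, window = 3000L, step = 600L,
                                     chrom_lengths = NULL) {
  stopifnot(inherits(sample, "methylome"))
  rec <- sample$records
  if (is.null(chrom_lengths)) {
    ml <- rec[, .(len = max(pos)), by = chrom]
    chrom_lengths <- stats::setNames(ml$len, ml$chrom)
  }
  out <- list()
  for (chr in names(chrom_lengths)) {
    len <- as.integer(chrom_lengths[[chr]])
    starts <- seq.int(1L, len, by = as.integer(step))
    ends <- pmin(starts + as.integer(window) - 1L, len)
    sub <- rec[chrom == chr]
    setorder(sub, pos)
    covered <- sub[n_meth + n_unmeth > 0L]
    cpos <- covered$pos
    cs_m <- c(0, cumsum(as.numeric(covered$n_meth)))
    cs_u <- c(0, cumsum(as.numeric(covered$n_unmeth)))
    lo <- findInterval(starts - 1L, cpos)
    hi <- findInterval(ends, cpos)
    nm <- cs_m[hi + 1L] - cs_m[lo + 1L]
    nu <- cs_u[hi + 1L] - cs_u[lo + 1L]
    out[[chr]] <- data.table(chrom = chr, start = starts, end = ends,
                             n_sites = hi - lo,
                             n_meth = nm, n_unmeth = nu,
                             ml_pooled = ifelse(nm + nu > 0, nm / (nm + nu),
                                                NA_real_))
  }
  rbindlist(out)
}
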