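# Site table restricted to positions reaching min_depth in BOTH samples,
# with per-sample corrected methylation levels. One row per shared site.
shared_site_table <- function(sample_a, sample_b, r_a, r_b, min_depth) {
  ra <- sample_a$records[n_meth + n_unmeth >= min_depth,
                         .(chrom, pos, strand, meth_a = n_meth,
                           unmeth_a = n_unmeth)]
  rb <- sample_b$records[n_meth + n_unmeth >= min_depth,
                         .(chrom, pos, strand, meth_b = n_meth,
                           unmeth_b = n_unmeth)]
  sh <- merge(ra, rb, by = c("chrom", "pos", "strand"))
  sh[, ml_a := correct_ml(meth_a / (meth_a + unmeth_a), r_a)]
  sh[, ml_b := correct_ml(meth_b / (meth_b + unmeth_b), r_b)]
  setorder(sh, chrom, pos, strand)
  sh[]
}

# Interval statistics over a shared-site table: unweighted mean of per-site
# corrected MLs per group, fold change with zero guard, absolute difference,
# and Fisher's exact p on the pooled raw counts.
region_stats <- function(regions, shared, params) {
  if (nrow(regions) == 0L) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      n_sites = integer(), ml_a = numeric(), ml_b = numeric(),
                      fold_change = numeric(), difference = numeric(),
                      p_value = numeric()))
  }
  out <- vector("list", length(unique(regions$chrom)))
  j <- 0L
  for (chr in unique(regions$chrom)) {
    reg <- regions[chrom == chr]
    sub <- shared[chrom == chr]
    cpos <- sub$pos
    cs_ma <- c(0, cumsum(as.numeric(sub$meth_a)))
    cs_ua <- c(0, cumsum(as.numeric(sub$unmeth_a)))
    cs_mb <- c(0, cumsum(as.numeric(sub$meth_b)))
    cs_ub <- c(0, cumsum(as.numeric(sub$unmeth_b)))
    cs_la <- c(0, cumsum(sub$ml_a))
    cs_lb <- c(0, cumsum(sub$ml_b))
    lo <- findInterval(reg$start - 1L, cpos)
    hi <- findInterval(reg$end, cpos)
    ns <- hi - lo
    ma <- cs_ma[hi + 1L] - cs_ma[lo + 1L]
    ua <- cs_ua[hi + 1L] - cs_ua[lo + 1L]
    mb <- cs_mb[hi + 1L] - cs_mb[lo + 1L]
    ub <- cs_ub[hi + 1L] - cs_ub[lo + 1L]
    la <- (cs_la[hi + 1L] - cs_la[lo + 1L]) / pmax(ns, 1L)
    lb <- (cs_lb[hi + 1L] - cs_lb[lo + 1L]) / pmax(ns, 1L)
    j <- j + 1L
    out[[j]] <- data.table(chrom = chr, start = reg$start, end = reg$end,
                           n_sites = ns, ml_a = la, ml_b = lb,
                           sum_ma = ma, sum_ua = ua, sum_mb = mb,
                           sum_ub = ub)
  }
  res <- rbindlist(out)
  res[, fold_change := pmax(ml_a, ml_b) / pmax(pmin(ml_a, ml_b),
                                               params$epsilon)]
  res[, difference := abs(ml_a - ml_b)]
  res[, p_value := fisher_p_vec(sum_ma, sum_ua, sum_mb, sum_ub)]
  res[, c("sum_ma", "sum_ua", "sum_mb", "sum_ub") := NULL]
  setorder(res, chrom, start)
  res[]
}

#' Scan the genome with sliding windows and test each window
#'
#' Slides windows of `params$window` bp stepped by `params$step` bp over
#' each chromosome from position 1. A window is retained only when strictly
#' more than `params$min_sites` cytosine sites reach `params$min_depth`
#' coverage in both samples. For each retained window the unweighted mean
#' of per-site non-conversion-corrected methylation levels is computed per
#' group, together with the fold change (zero-guarded), the absolute
#' difference, and a two-sided Fisher's exact p-value on the pooled read
#' counts `[[sum methA, sum unmethA], [sum methB, sum unmethB]]`.
#'
#' @param sample_a,sample_b [methylome] objects with non-conversion rates
#'   set (estimate via [estimate_nonconversion()]).
#' @param params a [dmr_params] object.
#' @param chrom_lengths named vector of contig lengths; defaults to the
#'   largest shared covered position per contig.
#' @return data.table of retained windows with chrom, start, end, n_sites,
#'   ml_a, ml_b, fold_change, difference, p_value.
#' @export
scan_windows <- function(sample_a, sample_b, params = dmr_params(),
                         chrom_lengths = NULL) {
  stopifnot(inherits(sample_a, "methylome"), inherits(sample_b, "methylome"))
  r_a <- sample_a$nonconversion_rate
  r_b <- sample_b$nonconversion_rate
  if (is.na(r_a) || is.na(r_b)) {
    stop("non-conversion rates unset; estimate them from lambda first")
  }
  shared <- shared_site_table(sample_a, sample_b, r_a, r_b, params$min_depth)
  scan_windows_shared(shared, params, chrom_lengths)
}

scan_windows_shared <- function(shared, params, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    ml <- shared[, .(len = max(pos)), by = chrom]
    chrom_lengths <- stats::setNames(ml$len, ml$chrom)
  }
  wins <- list()
  for (chr in names(chrom_lengths)) {
    len <- as.integer(chrom_lengths[[chr]])
    starts <- seq.int(1L, len, by = params$step)
    ends <- pmin(starts + params$window - 1L, len)
    sub <- shared[chrom == chr]
    if (nrow(sub) == 0L) next
    cpos <- sub$pos
    lo <- findInterval(starts - 1L, cpos)
    hi <- findInterval(ends, cpos)
    keep <- (hi - lo) > params$min_sites
    if (!any(keep)) next
    wins[[length(wins) + 1L]] <- data.table(chrom = chr,
                                            start = starts[keep],
                                            end = ends[keep])
  }
  if (length(wins) == 0L) {
    return(region_stats(data.table(chrom = character(), start = integer(),
                                   end = integer()),
                        shared, params))
  }
  region_stats(rbindlist(wins), shared, params)
}

#' Select potential DMRs from tested windows
#'
#' Keeps windows passing the dual effect-size filters (fold change strictly
#' above `min_fold` and methylation difference strictly above `min_diff`)
#' together with a raw Fisher p-value strictly below `p_raw`; then applies
#' Benjamini-Hochberg across the kept windows and retains those with
#' q strictly below `q_final`.
#'
#' @param windows output of [scan_windows()].
#' @param params a [dmr_params] object.
#' @return data.table of potential DMRs (windows plus q_value).
#' @export
select_potential_dmrs <- function(windows, params = dmr_params()) {
  keep <- windows[fold_change > params$min_fold &
                    difference > params$min_diff &
                    p_value < params$p_raw]
  if (nrow(keep) == 0L) {
    keep[, q_value := numeric(0L)]
    return(keep[])
  }
  keep[, q_value := bh_fdr(p_value)]
  keep <- keep[q_value < params$q_final]
  setorder(keep, chrom, start)
  keep[]
}

# union of intervals overlapping by >= 1 bp (adjacent intervals stay apart)
merge_overlapping <- function(regions) {
  out <- list()
  for (chr in unique(regions$chrom)) {
    reg <- regions[chrom == chr]
    setorder(reg, start, end)
    ms <- reg$start[1L]; me <- reg$end[1L]
    starts <- integer(0L); ends <- integer(0L)
    if (nrow(reg) > 1L) {
      for (i in 2L:nrow(reg)) {
        if (reg$start[i] <= me) {
          me <- max(me, reg$end[i])
        } else {
          starts <- c(starts, ms); ends <- c(ends, me)
          ms <- reg$start[i]; me <- reg$end[i]
        }
      }
    }
    out[[length(out) + 1L]] <- data.table(chrom = chr,
                                          start = c(starts, ms),
                                          end = c(ends, me))
  }
  res <- rbindlist(out)
  setorder(res, chrom, start)
  res[]
}

#' Merge overlapping potential DMRs and re-test until a fixed point
#'
#' Iteratively unions all potential DMRs that overlap by at least 1 bp into
#' merged spans, recomputes site counts, group methylation levels, fold
#' change, difference and Fisher p over each merged span, and drops spans
#' failing the site-count, effect-size or raw-p filters. Iteration stops at
#' a fixed point (guarded at 100 iterations). Benjamini-Hochberg is then
#' applied across the surviving regions, keeping q < `q_final`, and the
#' hyper/hypo direction is assigned from the group means (hyper when group
#' A exceeds group B). The result is idempotent: feeding it back in
#' reproduces it.
#'
#' @param potential output of [select_potential_dmrs()] (or any interval
#'   set with chrom/start/end columns).
#' @param sample_a,sample_b [methylome] objects with non-conversion rates
#'   set.
#' @param params a [dmr_params] object.
#' @return data.table of final DMRs: chrom, start, end, n_sites, ml_a,
#'   ml_b, fold_change, difference, p_value, q_value, direction; sorted and
#'   pairwise non-overlapping.
#' @export
merge_and_retest <- function(potential, sample_a, sample_b,
                             params = dmr_params()) {
  r_a <- sample_a$nonconversion_rate
  r_b <- sample_b$nonconversion_rate
  if (is.na(r_a) || is.na(r_b)) {
    stop("non-conversion rates unset; estimate them from lambda first")
  }
  shared <- shared_site_table(sample_a, sample_b, r_a, r_b, params$min_depth)
  merge_and_retest_shared(potential, shared, params)
}

merge_and_retest_shared <- function(potential, shared, params) {
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      ml_a = numeric(), ml_b = numeric(),
                      fold_change = numeric(), difference = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      direction = character())
  regions <- as.data.table(potential)[, .(chrom, start, end)]
  if (nrow(regions) == 0L) return(empty)
  stats <- NULL
  for (iter in seq_len(100L)) {
    merged <- merge_overlapping(regions)
    stats <- region_stats(merged, shared, params)
    stats <- stats[n_sites > params$min_sites &
                     fold_change > params$min_fold &
                     difference > params$min_diff &
                     p_value < params$p_raw]
    new_regions <- stats[, .(chrom, start, end)]
    same <- nrow(new_regions) == nrow(regions) &&
      all(new_regions$chrom == regions$chrom) &&
      all(new_regions$start == regions$start) &&
      all(new_regions$end == regions$end)
    if (same) break
    regions <- new_regions
    if (nrow(regions) == 0L) return(empty)
    if (iter == 100L) stop("merge-and-retest failed to reach a fixed point")
  }
  if (nrow(stats) == 0L) return(empty)
  stats[, q_value := bh_fdr(p_value)]
  stats <- stats[q_value < params$q_final]
  if (nrow(stats) == 0L) return(empty)
  stats[, direction := ifelse(ml_a > ml_b, "hyper", "hypo")]
  setorder(stats, chrom, start)
  stats[]
}

#' Call differentially methylated regions between two samples
#'
#' End-to-end composition: estimate each sample's bisulfite non-conversion
#' rate from its lambda spike-in, correct site methylation levels, scan
#' 1000/100 sliding windows, select potential DMRs with the dual
#' effect-size filters plus Fisher p and FDR thresholds, and merge-and-
#' retest overlapping candidates to a non-overlapping final set.
#'
#' @param sample_a,sample_b [methylome] objects for the two conditions.
#' @param lambda_a,lambda_b lambda spike-in [methylome]s; when `NULL` the
#'   sample's stored non-conversion rate is used instead.
#' @param params a [dmr_params] object.
#' @param chrom_lengths named vector of contig lengths (optional).
#' @return data.table of final DMRs as in [merge_and_retest()].
#' @export
call_dmrs <- function(sample_a, sample_b, lambda_a = NULL, lambda_b = NULL,
                      params = dmr_params(), chrom_lengths = NULL) {
  r_a <- if (!is.null(lambda_a)) estimate_nonconversion(lambda_a) else
    sample_a$nonconversion_rate
  r_b <- if (!is.null(lambda_b)) estimate_nonconversion(lambda_b) else
    sample_b$nonconversion_rate
  if (is.na(r_a) || is.na(r_b)) {
    stop("non-conversion rate unavailable: provide lambda samples or set it")
  }
  shared <- shared_site_table(sample_a, sample_b, r_a, r_b, params$min_depth)
  windows <- scan_windows_shared(shared, params, chrom_lengths)
  potential <- select_potential_dmrs(windows, params)
  merge_and_retest_shared(potential, shared, params)
}

#' Five-number summary of DMR methylation levels per group
#'
#' Quartiles use the linear-interpolation convention (`quantile` type 7),
#' matching the usual boxplot statistics.
#'
#' @param dmrs non-empty data.table of DMRs with ml_a and ml_b columns.
#' @return data.table with one row per group (a, b): min, q1, median, q3,
#'   max.
#' @export
dmr_level_summary <- function(dmrs) {
  dmrs <- as.data.table(dmrs)
  if (nrow(dmrs) == 0L) stop("no DMRs: summary undefined")
  five <- function(x) {
    q <- quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    data.table(min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L],
               max = q[5L])
  }
  rbind(cbind(data.table(group = "a"), five(dmrs$ml_a)),
        cbind(data.table(group = "b"), five(dmrs$ml_b)))
}
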