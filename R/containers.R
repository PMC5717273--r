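#' Construct a methylome sample
#'
#' A methylome sample holds one Bismark-style per-cytosine count table plus
#' the sample's bisulfite non-conversion rate (if known). Records are stored
#' sorted by (chrom, pos, strand) with duplicate positions rejected, so that
#' downstream window arithmetic can rely on ordering.
#'
#' @param records data.frame with columns `chrom` (character), `pos`
#'   (1-based integer position of the cytosine), `strand` (`"+"` or `"-"`),
#'   `n_meth` and `n_unmeth` (non-negative read counts), `context`
#'   (`"CG"`, `"CHG"` or `"CHH"`) and `tricontext` (3-mer read 5'->3' on the
#'   cytosine's strand, starting with `C`).
#' @param nonconversion_rate fraction of truly unmethylated cytosines that
#'   escape bisulfite conversion (symbol r), in `[0, 1]`; `NA` if not yet
#'   estimated.
#' @param label free-text sample label.
#' @return An object of class `methylome`.
#' @export
methylome <- function(records, nonconversion_rate = NA_real_, label = "") {
  req <- c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context", "tricontext")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  rec <- as.data.table(records)[, req, with = FALSE]
  rec[, chrom := as.character(chrom)]
  rec[, pos := as.integer(pos)]
  rec[, n_meth := as.integer(n_meth)]
  rec[, n_unmeth := as.integer(n_unmeth)]
  if (nrow(rec) > 0L) {
    if (anyNA(rec$pos) || any(rec$pos < 1L)) stop("pos must be a positive integer")
    if (!all(rec$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (anyNA(rec$n_meth) || anyNA(rec$n_unmeth) ||
        any(rec$n_meth < 0L) || any(rec$n_unmeth < 0L)) {
      stop("n_meth and n_unmeth must be non-negative integers")
    }
    bad <- which(rec$context != derive_context(rec$tricontext))
    if (length(bad)) {
      stop("context inconsistent with tricontext at record ", bad[1L],
           " (", rec$context[bad[1L]], " vs ", rec$tricontext[bad[1L]], ")")
    }
    setorder(rec, chrom, pos, strand)
    if (anyDuplicated(rec, by = c("chrom", "pos", "strand"))) {
      stop("duplicate (chrom, pos, strand) keys in records")
    }
  }
  if (!is.na(nonconversion_rate) &&
      (nonconversion_rate < 0 || nonconversion_rate > 1)) {
    stop("nonconversion_rate must be in [0, 1]")
  }
  structure(list(records = rec,
                 nonconversion_rate = as.numeric(nonconversion_rate),
                 label = as.character(label)),
            class = "methylome")
}

# Context implied by a trinucleotide read 5'->3' on the cytosine's strand.
# CG <=> 2nd base G; CHG <=> 2nd base H and 3rd base G; CHH otherwise.
# Trinucleotides not starting with C, or containing non-ACGT, give NA.
derive_context <- function(tricontext) {
  b1 <- substr(tricontext, 1L, 1L)
  b2 <- substr(tricontext, 2L, 2L)
  b3 <- substr(tricontext, 3L, 3L)
  ok <- b1 == "C" & b2 %in% c("A", "C", "G", "T") & b3 %in% c("A", "C", "G", "T")
  out <- ifelse(b2 == "G", "CG", ifelse(b3 == "G", "CHG", "CHH"))
  out[!ok] <- NA_character_
  out
}

#' @export
print.methylome <- function(x, ...) {
  cat("<methylome>", if (nzchar(x$label)) paste0("'", x$label, "'") else "", "\n")
  cat("  sites:", nrow(x$records), "on",
      length(unique(x$records$chrom)), "sequence(s)\n")
  cat("  non-conversion rate:",
      if (is.na(x$nonconversion_rate)) "not estimated"
      else format(x$nonconversion_rate, digits = 4), "\n")
  invisible(x)
}

#' Simulation configuration for paired synthetic methylomes
#'
#' Defaults emulate a sparse invertebrate (honeybee-like) brain methylome at
#' sequencing scale reduced to desk size: AT-rich genome, methylation almost
#' exclusively at CpG sites, bimodal CpG methylation (a minority of sites
#' highly methylated, the rest unmethylated), ~25x coverage, bisulfite
#' non-conversion ~0.0015, and planted differential regions.
#'
#' @param genome_length_bp total simulated genome length in bp.
#' @param n_chroms number of equally sized chromosomes.
#' @param gc_fraction genomic GC content in `[0, 1]`.
#' @param cg_meth_high_fraction probability that a CpG cytosine is drawn from
#'   the high-methylation component; with the unmethylated component at ML 0
#'   this is also the expected genome-wide mCG/CG fraction.
#' @param mean_coverage mean per-site read depth (Poisson).
#' @param nonconversion_rate bisulfite non-conversion rate r in `[0, 1]`.
#' @param n_dmrs number of planted differential regions.
#' @param dmr_length_range length-2 vector, planted region length range (bp).
#' @param dmr_delta absolute methylation-level shift inside planted regions,
#'   in `(0, 1]`.
#' @param dmr_hyper_fraction fraction of planted regions hypermethylated in
#'   group A relative to group B.
#' @param noncg_meth_rate true methylation level of CHG/CHH sites.
#' @param beta_high_mean,beta_high_conc mean and concentration of the Beta
#'   distribution for the high CpG methylation component.
#' @param gene_spacing_bp intergenic gap between tiled gene models (leaves
#'   room for 2 kb promoters).
#' @param lambda_length_bp length of the unmethylated lambda spike-in contig.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length_bp = 2e6,
                       n_chroms = 4L,
                       gc_fraction = 0.33,
                       cg_meth_high_fraction = 0.0068,
                       mean_coverage = 25,
                       nonconversion_rate = 0.0015,
                       n_dmrs = 50L,
                       dmr_length_range = c(1000L, 3000L),
                       dmr_delta = 0.3,
                       dmr_hyper_fraction = 0.6,
                       noncg_meth_rate = 0,
                       beta_high_mean = 0.8,
                       beta_high_conc = 10,
                       gene_spacing_bp = 4200L,
                       lambda_length_bp = 48502L,
                       seed = 1L) {
  cfg <- list(genome_length_bp = as.numeric(genome_length_bp),
              n_chroms = as.integer(n_chroms),
              gc_fraction = as.numeric(gc_fraction),
              cg_meth_high_fraction = as.numeric(cg_meth_high_fraction),
              mean_coverage = as.numeric(mean_coverage),
              nonconversion_rate = as.numeric(nonconversion_rate),
              n_dmrs = as.integer(n_dmrs),
              dmr_length_range = as.integer(dmr_length_range),
              dmr_delta = as.numeric(dmr_delta),
              dmr_hyper_fraction = as.numeric(dmr_hyper_fraction),
              noncg_meth_rate = as.numeric(noncg_meth_rate),
              beta_high_mean = as.numeric(beta_high_mean),
              beta_high_conc = as.numeric(beta_high_conc),
              gene_spacing_bp = as.integer(gene_spacing_bp),
              lambda_length_bp = as.integer(lambda_length_bp),
              seed = as.integer(seed))
  for (f in c("gc_fraction", "cg_meth_high_fraction", "nonconversion_rate",
              "dmr_hyper_fraction", "noncg_meth_rate")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(f, " must be in [0, 1]")
    }
  }
  if (cfg$mean_coverage <= 0) stop("mean_coverage must be > 0")
  if (cfg$dmr_delta <= 0 || cfg$dmr_delta > 1) stop("dmr_delta must be in (0, 1]")
  if (length(cfg$dmr_length_range) != 2L ||
      cfg$dmr_length_range[1L] > cfg$dmr_length_range[2L] ||
      cfg$dmr_length_range[1L] < 1L) {
    stop("dmr_length_range must be an ascending positive length-2 vector")
  }
  if (cfg$genome_length_bp < cfg$n_chroms) stop("genome too short")
  structure(cfg, class = "sim_config")
}

#' DMR caller parameters
#'
#' Defaults follow the swDMR parameterisation used for honeybee WGBS
#' comparisons: 1000 bp windows stepped by 100 bp, windows kept only with
#' strictly more than `min_sites` cytosines covered in both samples, effect
#' filters fold change > 2 and methylation difference > 0.1, Fisher's exact
#' P < 0.05, and FDR-corrected q < 0.05.
#'
#' @param window window size in bp.
#' @param step step length in bp.
#' @param min_sites windows must contain strictly more than this many
#'   cytosine sites covered in both samples.
#' @param min_fold minimum fold change between group mean methylation levels
#'   (strict).
#' @param min_diff minimum absolute difference of group mean methylation
#'   levels (strict).
#' @param p_raw raw Fisher's-exact-test p-value threshold (strict).
#' @param q_final FDR-corrected q-value threshold (strict).
#' @param epsilon zero-guard for the fold-change denominator.
#' @param min_depth per-site read-depth floor; a site counts toward a window
#'   only if it reaches this depth in both samples.
#' @return An object of class `dmr_params`.
#' @export
dmr_params <- function(window = 1000L, step = 100L, min_sites = 10L,
                       min_fold = 2, min_diff = 0.1, p_raw = 0.05,
                       q_final = 0.05, epsilon = 1e-6, min_depth = 5L) {
  p <- list(window = as.integer(window), step = as.integer(step),
            min_sites = as.integer(min_sites), min_fold = as.numeric(min_fold),
            min_diff = as.numeric(min_diff), p_raw = as.numeric(p_raw),
            q_final = as.numeric(q_final), epsilon = as.numeric(epsilon),
            min_depth = as.integer(min_depth))
  if (p$step > p$window) stop("step must be <= window")
  if (p$window < 1L || p$step < 1L) stop("window and step must be positive")
  if (p$min_fold <= 0 || p$min_diff <= 0 || p$p_raw <= 0 || p$q_final <= 0 ||
      p$epsilon <= 0) {
    stop("thresholds must be positive")
  }
  structure(p, class = "dmr_params")
}
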