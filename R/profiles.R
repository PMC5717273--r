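IUPAC_CODE <- c(A = "A", C = "C", G = "G", T = "T",
                AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Classify sites as high or low methylation
#'
#' CpG sites are high when their methylation level strictly exceeds 0.75;
#' non-CpG (CHG/CHH) sites when it strictly exceeds 0.25; otherwise low.
#'
#' @param ml methylation level(s); `NA` is an error (undefined level).
#' @param context matching context vector ("CG", "CHG" or "CHH").
#' @return Character vector of "high"/"low".
#' @export
classify_high_low <- function(ml, context) {
  n <- max(length(ml), length(context))
  ml <- rep_len(ml, n)
  context <- rep_len(context, n)
  if (anyNA(ml)) stop("undefined methylation level")
  if (!all(context %in% c("CG", "CHG", "CHH"))) stop("unknown context")
  thr <- ifelse(context == "CG", 0.75, 0.25)
  ifelse(ml > thr, "high", "low")
}

#' Extract flanking k-mers around methylated cytosines
#'
#' For each site the k-mer containing `c_offset - 1` bases upstream and
#' `k - c_offset` bases downstream of the cytosine is read 5'->3' on the
#' site's strand (minus-strand k-mers are the reverse complement of the
#' plus-strand slice). Sites whose window leaves the contig or contains an
#' `N` are skipped and counted.
#'
#' @param genome named character vector of sequences.
#' @param sites data.frame with chrom, pos, strand of methylated cytosines.
#' @param k k-mer length (default 9).
#' @param c_offset 1-based position of the cytosine within the k-mer
#'   (default 4: three bases upstream, five downstream).
#' @return List with `kmers` (character vector) and `n_skipped`.
#' @export
extract_flanking_kmers <- function(genome, sites, k = 9L, c_offset = 4L) {
  sites <- as.data.table(sites)
  k <- as.integer(k); c_offset <- as.integer(c_offset)
  if (c_offset < 1L || c_offset > k) stop("c_offset must lie within the k-mer")
  kmers <- character(0L)
  n_skipped <- 0L
  for (chr in unique(sites$chrom)) {
    if (!chr %in% names(genome)) stop("unknown sequence: ", chr)
    seq <- genome[[chr]]
    L <- nchar(seq)
    sub <- sites[chrom == chr]
    plus <- sub$strand == "+"
    ws <- ifelse(plus, sub$pos - (c_offset - 1L), sub$pos - (k - c_offset))
    we <- ifelse(plus, sub$pos + (k - c_offset), sub$pos + (c_offset - 1L))
    ok <- ws >= 1L & we <= L
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    km <- substring(seq, ws[ok], we[ok])
    flip <- !plus[ok]
    if (any(flip)) km[flip] <- revcomp(km[flip])
    has_n <- grepl("N", km, fixed = TRUE)
    n_skipped <- n_skipped + sum(has_n)
    kmers <- c(kmers, km[!has_n])
  }
  list(kmers = kmers, n_skipped = n_skipped)
}

#' Position frequency matrix of a k-mer set
#'
#' Column-wise base fractions over aligned k-mers plus a consensus string
#' (argmax base per column; ties become IUPAC ambiguity codes). When the
#' k-mers come from [extract_flanking_kmers()], the column at the cytosine
#' offset is 100% C.
#'
#' @param kmers non-empty character vector of equal-length k-mers.
#' @return An object of class `kmer_profile`: list with `pfm` (4 x k matrix
#'   of fractions, rows A/C/G/T), `consensus`, `n_kmers`, `k`.
#' @export
position_frequency_matrix <- function(kmers) {
  if (length(kmers) == 0L) stop("no k-mers: profile undefined")
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("k-mers must have equal length")
  mat <- matrix(0, nrow = 4L, ncol = k, dimnames = list(DNA_BASES, NULL))
  split_mat <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  for (j in seq_len(k)) {
    tab <- table(factor(split_mat[, j], levels = DNA_BASES))
    mat[, j] <- as.numeric(tab) / length(kmers)
  }
  consensus <- vapply(seq_len(k), function(j) {
    mx <- max(mat[, j])
    top <- DNA_BASES[mat[, j] >= mx - 1e-9]
    unname(IUPAC_CODE[paste(top, collapse = "")])
  }, character(1L))
  structure(list(pfm = mat, consensus = paste(consensus, collapse = ""),
                 n_kmers = length(kmers), k = k),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat("<kmer_profile>", x$n_kmers, "k-mers of length", x$k,
      "- consensus", x$consensus, "\n")
  invisible(x)
}

#' Metagene methylation profile over gene components
#'
#' Each component instance (every promoter, UTR, exon or intron interval)
#' is divided into `n_bins` equal-length bins oriented 5'->3' with respect
#' to its gene's strand. Every site of the requested context contributes
#' its corrected methylation level to the bin holding its fractional
#' position within the instance; the profile is the per-bin mean across all
#' instances of a component type. Bins with no sites have `NA` mean and a
#' zero count. Instances shorter than `n_bins` bp simply populate the bins
#' their sites fall into.
#'
#' @param calls output of [call_methylated_sites()] (needs chrom, pos,
#'   context, ml_corrected).
#' @param index a [build_component_index()] result.
#' @param context one of "CG", "CHG", "CHH".
#' @param n_bins number of bins per component instance (default 20).
#' @return data.table with component, bin (1..n_bins), mean_ml, n_sites.
#' @export
metagene_profile <- function(calls, index, context = "CG", n_bins = 20L) {
  stopifnot(inherits(index, "component_index"))
  n_bins <- as.integer(n_bins)
  ctx <- context
  sites <- as.data.table(calls)[context == ctx, .(chrom, pos, ml_corrected)]
  comp <- copy(index$components)
  comp[, inst_id := .I]
  components <- unique(comp$component)
  grid <- CJ(component = components, bin = seq_len(n_bins))
  if (nrow(sites) == 0L || nrow(comp) == 0L) {
    grid[, `:=`(mean_ml = NA_real_, n_sites = 0L)]
    return(grid[])
  }
  setkey(comp, chrom, start, end)
  sites[, `:=`(start = pos, end = pos)]
  ov <- foverlaps(sites, comp, type = "within", nomatch = NULL)
  if (nrow(ov) == 0L) {
    grid[, `:=`(mean_ml = NA_real_, n_sites = 0L)]
    return(grid[])
  }
  ov[, width := end - start + 1L]
  ov[, frac := (pos - start + 0.5) / width]
  ov[strand == "-", frac := 1 - frac]
  ov[, bin := pmin(n_bins, as.integer(floor(frac * n_bins)) + 1L)]
  prof <- ov[, .(mean_ml = mean(ml_corrected), n_sites = .N),
             by = .(component, bin)]
  out <- merge(grid, prof, by = c("component", "bin"), all.x = TRUE)
  out[is.na(n_sites), n_sites := 0L]
  setorder(out, component, bin)
  out[]
}
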