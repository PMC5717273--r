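#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value for the table
#' `[[a, b], [c, d]]` by summing all hypergeometric point probabilities not
#' exceeding the observed table's probability (with a relative tie slack of
#' 1e-7, the usual convention). The table is canonicalised (row/column
#' swaps, which leave the p-value invariant) so that swapping the two
#' samples yields a bit-identical p-value.
#'
#' @param a,b,c,d non-negative integer cell counts; row 1 is sample A
#'   (methylated, unmethylated), row 2 sample B.
#' @return p-value in `(0, 1]`.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all four cells are zero; test undefined")
  # canonicalise: smaller row first, then smaller column first
  if (a + b > c + d || (a + b == c + d && a > c)) {
    tmp <- c(a, b); a <- c; b <- d; c <- tmp[1L]; d <- tmp[2L]
  }
  if (a + c > b + d || (a + c == b + d && a > b)) {
    tmp <- c(a, c); a <- b; b <- tmp[1L]; c <- d; d <- tmp[2L]
  }
  m <- a + b
  n2 <- c + d
  s <- a + c
  k <- max(0L, s - n2):min(m, s)
  probs <- dhyper(k, m, n2, s)
  p_obs <- dhyper(a, m, n2, s)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# vectorised wrapper used by the window scan
fisher_p_vec <- function(a, b, c, d) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- fisher_exact_two_sided(a[i], b[i], c[i], d[i])
  }
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values: q_(i) = min over j >= i of
#' min(1, p_(j) * m / j), mapped back to the input order. Delegates to
#' `stats::p.adjust(method = "BH")` after range validation.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0L))
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
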