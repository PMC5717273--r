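# Independent reference implementations used to cross-check the package.

# Two-sided Fisher p by explicit hypergeometric enumeration via log
# binomial coefficients (route independent of dhyper).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; s <- a + c
  k <- max(0L, s - n2):min(m, s)
  lp <- lchoose(m, k) + lchoose(n2, s - k) - lchoose(m + n2, s)
  probs <- exp(lp)
  p_obs <- probs[match(a, k)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Naive Benjamini-Hochberg step-up: q_(i) = min(1, min_{j>=i} (m/j) p_(j)).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  run <- Inf
  for (j in m:1) {
    run <- min(run, (m / j) * ps[j])
    q[j] <- min(1, run)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Context classification via regex on the sequence and on its reverse
# complement, mapping minus-strand coordinates back.
context_oracle <- function(seq) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }
  scan_one <- function(s) {
    find <- function(pat) {
      m <- gregexpr(pat, s, perl = TRUE)[[1L]]
      if (m[1L] == -1L) integer(0L) else as.integer(m)
    }
    # lookahead so overlapping matches are all found; N never matches
    list(CG = find("C(?=G)"),
         CHG = find("C(?=[ACT]G)"),
         CHH = find("C(?=[ACT][ACT])"))
  }
  L <- nchar(seq)
  plus <- scan_one(seq)
  minus_rc <- scan_one(rc(seq))
  minus <- lapply(minus_rc, function(p) sort(L - p + 1L))
  pieces <- list()
  for (ctx in c("CG", "CHG", "CHH")) {
    if (length(plus[[ctx]])) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        pos = plus[[ctx]], strand = "+", context = ctx)
    }
    if (length(minus[[ctx]])) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        pos = minus[[ctx]], strand = "-", context = ctx)
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

# Upper binomial tail by explicit log-binomial summation.
binom_tail_oracle <- function(k, n, r) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(r) + (n - j) * log1p(-r)))
}
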