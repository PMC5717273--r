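DNA_BASES <- c("A", "C", "G", "T")
BASE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N and IUPAC codes).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0L))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Enumerate all cytosine sites of a genome with their context
#'
#' Walks both strands of every sequence and reports each cytosine (a `C` on
#' the plus strand; a plus-strand `G` read as `C` on the minus strand)
#' together with its CG/CHG/CHH context and trinucleotide, both read 5'->3'
#' on the cytosine's own strand. Sites within 2 bp of the contig 3' end (on
#' the site's strand) or whose two downstream bases include an `N` have
#' undefined context and are omitted.
#'
#' @param genome named character vector of upper-case sequences.
#' @return data.table with columns chrom, pos (1-based), strand, context,
#'   tricontext, sorted by (chrom, pos, strand).
#' @export
cytosine_sites <- function(genome) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  pieces <- list()
  for (chr in names(genome)) {
    chars <- strsplit(genome[[chr]], "", fixed = TRUE)[[1L]]
    L <- length(chars)
    idx <- which(chars == "C")
    idx <- idx[idx <= L - 2L]
    if (length(idx)) {
      b1 <- chars[idx + 1L]
      b2 <- chars[idx + 2L]
      ok <- b1 %in% DNA_BASES & b2 %in% DNA_BASES
      if (any(ok)) {
        i <- idx[ok]; b1 <- b1[ok]; b2 <- b2[ok]
        pieces[[length(pieces) + 1L]] <- data.table(
          chrom = chr, pos = i, strand = "+",
          context = ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH")),
          tricontext = paste0("C", b1, b2))
      }
    }
    idx <- which(chars == "G")
    idx <- idx[idx >= 3L]
    if (length(idx)) {
      c1 <- unname(BASE_COMP[chars[idx - 1L]])  # next base 5'->3' on minus
      c2 <- unname(BASE_COMP[chars[idx - 2L]])
      ok <- c1 %in% DNA_BASES & c2 %in% DNA_BASES & !is.na(c1) & !is.na(c2)
      if (any(ok)) {
        i <- idx[ok]; c1 <- c1[ok]; c2 <- c2[ok]
        pieces[[length(pieces) + 1L]] <- data.table(
          chrom = chr, pos = i, strand = "-",
          context = ifelse(c1 == "G", "CG", ifelse(c2 == "G", "CHG", "CHH")),
          tricontext = paste0("C", c1, c2))
      }
    }
  }
  if (length(pieces) == 0L) {
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      tricontext = character()))
  }
  out <- rbindlist(pieces)
  setorder(out, chrom, pos, strand)
  out[]
}

#' Classify the sequence context of given cytosine positions
#'
#' For each (chrom, pos, strand) the base at the position must be a cytosine
#' on that strand (a plus-strand `G` for minus-strand sites). The two
#' downstream bases 5'->3' on the site's strand decide the context: CG if
#' the next base is G, CHG if the next base is H (A/C/T) and the one after
#' is G, CHH otherwise. Sites within 2 bp of the contig 3' end or adjacent
#' to `N` get `NA` context (undefined).
#'
#' @param genome named character vector of sequences.
#' @param chrom,pos,strand vectors (recycled to common length).
#' @return data.table with columns chrom, pos, strand, context, tricontext
#'   in input order.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(as.character(strand), n)
  context <- rep(NA_character_, n)
  tricontext <- rep(NA_character_, n)
  for (chr in unique(chrom)) {
    if (!chr %in% names(genome)) stop("unknown sequence: ", chr)
    chars <- strsplit(genome[[chr]], "", fixed = TRUE)[[1L]]
    L <- length(chars)
    sel <- which(chrom == chr)
    p <- pos[sel]
    if (any(p < 1L | p > L)) stop("position outside sequence ", chr)
    plus <- strand[sel] == "+"
    base <- chars[p]
    if (any(plus & base != "C") || any(!plus & base != "G")) {
      stop("base at requested position is not a cytosine on that strand")
    }
    # plus strand
    ip <- sel[plus]
    pp <- p[plus]
    okp <- pp <= L - 2L
    if (any(okp)) {
      b1 <- chars[pp[okp] + 1L]; b2 <- chars[pp[okp] + 2L]
      def <- b1 %in% DNA_BASES & b2 %in% DNA_BASES
      ctx <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
      ctx[!def] <- NA_character_
      tri <- ifelse(def, paste0("C", b1, b2), NA_character_)
      context[ip[okp]] <- ctx
      tricontext[ip[okp]] <- tri
    }
    # minus strand
    im <- sel[!plus]
    pm <- p[!plus]
    okm <- pm >= 3L
    if (any(okm)) {
      c1 <- unname(BASE_COMP[chars[pm[okm] - 1L]])
      c2 <- unname(BASE_COMP[chars[pm[okm] - 2L]])
      def <- c1 %in% DNA_BASES & c2 %in% DNA_BASES & !is.na(c1) & !is.na(c2)
      ctx <- ifelse(c1 == "G", "CG", ifelse(c2 == "G", "CHG", "CHH"))
      ctx[!def] <- NA_character_
      tri <- ifelse(def, paste0("C", c1, c2), NA_character_)
      context[im[okm]] <- ctx
      tricontext[im[okm]] <- tri
    }
  }
  data.table(chrom = chrom, pos = pos, strand = strand,
             context = context, tricontext = tricontext)
}
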