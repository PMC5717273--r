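#' Read a Bismark-style per-cytosine report
#'
#' Expects seven tab-separated columns per line, no header:
#' chrom, 1-based position, strand, count methylated, count unmethylated,
#' context (CG/CHG/CHH), trinucleotide. Records are validated (context must
#' be consistent with the trinucleotide), deduplicated-checked, and returned
#' sorted by (chrom, pos, strand) regardless of input line order.
#'
#' @param path file path.
#' @param label sample label; defaults to the file name.
#' @return A [methylome] object.
#' @export
read_cytosine_report <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) {
    return(methylome(data.table(chrom = character(), pos = integer(),
                                strand = character(), n_meth = integer(),
                                n_unmeth = integer(), context = character(),
                                tricontext = character()),
                     label = label))
  }
  bad <- which(nf != 7L)
  if (length(bad)) {
    stop("malformed cytosine report line ", bad[1L], " in ", path,
         ": expected 7 tab-separated fields, found ", nf[bad[1L]])
  }
  dt <- fread(path, sep = "\t", header = FALSE, colClasses = "character",
              col.names = c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                            "context", "tricontext"))
  for (col in c("pos", "n_meth", "n_unmeth")) {
    ok <- grepl("^[0-9]+$", dt[[col]])
    if (!all(ok)) {
      stop("malformed cytosine report line ", which(!ok)[1L], " in ", path,
           ": field '", col, "' is not a non-negative integer")
    }
  }
  dt[, pos := as.integer(pos)]
  dt[, n_meth := as.integer(n_meth)]
  dt[, n_unmeth := as.integer(n_unmeth)]
  methylome(dt, label = label)
}

#' Write a methylome sample as a per-cytosine report
#'
#' @param sample a [methylome] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sample, path) {
  stopifnot(inherits(sample, "methylome"))
  fwrite(sample$records, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Sequences are upper-cased; only A/C/G/T/N are accepted. Names are the
#' first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return Named character vector, one element per sequence.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence '", names(seqs)[bad][1L],
         "' contains characters outside A/C/G/T/N")
  }
  seqs
}

#' Write a genome FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Construct a gene-model set
#'
#' @param genes data.frame with columns gene_id, chrom, strand, tss, start,
#'   end (1-based inclusive gene span).
#' @param features data.frame with columns gene_id, chrom, strand, component
#'   (one of utr5/exon/intron/utr3, where `exon` excludes UTR overlap so the
#'   four components are disjoint within a gene), start, end.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, features) {
  genes <- as.data.table(genes)
  features <- as.data.table(features)
  stopifnot(all(c("gene_id", "chrom", "strand", "tss", "start", "end") %in%
                  names(genes)),
            all(c("gene_id", "chrom", "strand", "component", "start", "end") %in%
                  names(features)))
  if (nrow(genes) && !all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  if (nrow(features) && !all(features$component %in%
                             c("utr5", "exon", "intron", "utr3"))) {
    stop("unknown feature component")
  }
  if (nrow(features) && any(features$start > features$end)) {
    stop("feature start > end")
  }
  setorder(genes, chrom, start)
  setorder(features, chrom, start, gene_id)
  structure(list(genes = genes[], features = features[]),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models>", nrow(x$genes), "genes,",
      nrow(x$features), "component intervals\n")
  invisible(x)
}

# Merge sorted 1-based inclusive intervals that overlap or touch.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  if (length(start) <= 1L) return(list(start = start, end = end))
  ms <- start[1L]; me <- end[1L]
  outs <- integer(0L); oute <- integer(0L)
  for (i in 2L:length(start)) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(outs, ms), end = c(oute, me))
}

# Subtract intervals b from intervals a (1-based inclusive), returning the
# uncovered parts of a.
subtract_intervals <- function(a_start, a_end, b_start, b_end) {
  if (length(a_start) == 0L) return(list(start = integer(), end = integer()))
  if (length(b_start) == 0L) return(list(start = a_start, end = a_end))
  ir_a <- IRanges::IRanges(a_start, a_end)
  ir_b <- IRanges::IRanges(b_start, b_end)
  d <- IRanges::setdiff(ir_a, ir_b)
  list(start = IRanges::start(d), end = IRanges::end(d))
}

#' Read gene models from a GFF3 annotation
#'
#' Parses gene / mRNA / exon / five_prime_UTR / three_prime_UTR features.
#' For genes with several transcripts the representative transcript is the
#' one with the longest genomic span. Introns are derived as the gaps
#' between the representative transcript's sorted exons; the exon component
#' is reported with UTR overlap removed so the four gene-body components are
#' disjoint. The TSS is the 5'-most coordinate on the plus strand and the
#' 3'-most on the minus strand. Genes with no exons are skipped with a
#' warning; an undetermined strand is an error.
#'
#' @param path GFF3 file path.
#' @return A [gene_models] object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1L))
  } else rep(NA_character_, length(gr))
  dt <- data.table(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   type = type, id = ids, parent = parent)
  genes_dt <- dt[type == "gene"]
  if (nrow(genes_dt) == 0L) stop("no gene features in ", path)
  tx_dt <- dt[type %in% c("mRNA", "transcript")]
  exon_dt <- dt[type == "exon"]
  utr5_dt <- dt[type == "five_prime_UTR"]
  utr3_dt <- dt[type == "three_prime_UTR"]

  out_genes <- list(); out_feats <- list()
  for (i in seq_len(nrow(genes_dt))) {
    g <- genes_dt[i]
    if (!g$strand %in% c("+", "-")) {
      stop("gene ", g$id, " has unknown strand '", g$strand, "'")
    }
    txs <- tx_dt[parent == g$id]
    if (nrow(txs) > 0L) {
      rep_tx <- txs[which.max(end - start + 1L)]
      ex <- exon_dt[parent == rep_tx$id]
      u5 <- utr5_dt[parent == rep_tx$id]
      u3 <- utr3_dt[parent == rep_tx$id]
    } else {
      ex <- exon_dt[parent == g$id]
      u5 <- utr5_dt[parent == g$id]
      u3 <- utr3_dt[parent == g$id]
    }
    if (nrow(ex) == 0L) {
      warning("gene ", g$id, " has no exons; skipped")
      next
    }
    setorder(ex, start)
    tss <- if (g$strand == "+") min(ex$start, g$start) else max(ex$end, g$end)
    feats <- list()
    # introns: gaps between raw exons
    if (nrow(ex) > 1L) {
      istart <- ex$end[-nrow(ex)] + 1L
      iend <- ex$start[-1L] - 1L
      keep <- istart <= iend
      if (any(keep)) {
        feats$intron <- data.table(start = istart[keep], end = iend[keep])
      }
    }
    utr_start <- c(u5$start, u3$start); utr_end <- c(u5$end, u3$end)
    coding <- subtract_intervals(ex$start, ex$end, utr_start, utr_end)
    if (length(coding$start)) {
      feats$exon <- data.table(start = coding$start, end = coding$end)
    }
    if (nrow(u5)) feats$utr5 <- data.table(start = u5$start, end = u5$end)
    if (nrow(u3)) feats$utr3 <- data.table(start = u3$start, end = u3$end)
    fdt <- rbindlist(feats, idcol = "component")
    fdt[, `:=`(gene_id = g$id, chrom = g$chrom, strand = g$strand)]
    out_feats[[length(out_feats) + 1L]] <- fdt
    out_genes[[length(out_genes) + 1L]] <- data.table(
      gene_id = g$id, chrom = g$chrom, strand = g$strand,
      tss = as.integer(tss),
      start = min(ex$start, g$start), end = max(ex$end, g$end))
  }
  if (length(out_genes) == 0L) stop("no usable genes in ", path)
  gene_models(rbindlist(out_genes), rbindlist(out_feats))
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and UTR features with ID/Parent links. Exon lines
#' are reconstructed as the union of the disjoint utr5/exon/utr3 components
#' (merging adjacent pieces), matching the usual GFF3 convention that exons
#' include their UTR parts.
#'
#' @param models a [gene_models] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  lines <- c("##gff-version 3")
  gffline <- function(chrom, src, type, start, end, strand, attrs) {
    paste(chrom, src, type, start, end, ".", strand, ".", attrs, sep = "\t")
  }
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i]
    f <- models$features[gene_id == g$gene_id]
    txid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
               gffline(g$chrom, "methylscan", "gene", g$start, g$end,
                       g$strand, paste0("ID=", g$gene_id)),
               gffline(g$chrom, "methylscan", "mRNA", g$start, g$end,
                       g$strand, paste0("ID=", txid, ";Parent=", g$gene_id)))
    exonic <- f[component %in% c("utr5", "exon", "utr3")]
    if (nrow(exonic)) {
      m <- merge_intervals(exonic$start, exonic$end)
      lines <- c(lines, gffline(g$chrom, "methylscan", "exon",
                                m$start, m$end, g$strand,
                                paste0("ID=", txid, ".exon", seq_along(m$start),
                                       ";Parent=", txid)))
    }
    for (comp in c("utr5", "utr3")) {
      u <- f[component == comp]
      if (nrow(u)) {
        gtype <- if (comp == "utr5") "five_prime_UTR" else "three_prime_UTR"
        lines <- c(lines, gffline(g$chrom, "methylscan", gtype,
                                  u$start, u$end, g$strand,
                                  paste0("ID=", txid, ".", comp,
                                         seq_len(nrow(u)), ";Parent=", txid)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

DMR_TABLE_COLS <- c("chrom", "start", "end", "n_sites", "ml_a", "ml_b",
                    "fold_change", "difference", "p_value", "q_value",
                    "direction", "genes", "components")

#' Write a DMR table
#'
#' Tab-separated with header `chrom start end n_sites ml_a ml_b fold_change
#' difference p_value q_value direction genes components`. Numeric columns
#' are written with 17 significant digits so that write-then-read
#' round-trips bit-exactly.
#'
#' @param dmrs data.frame of DMRs; missing `genes`/`components` columns are
#'   filled with empty strings.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dmr_table <- function(dmrs, path) {
  dt <- as.data.table(dmrs)
  if (!"genes" %in% names(dt)) dt[, genes := ""]
  if (!"components" %in% names(dt)) dt[, components := ""]
  missing <- setdiff(DMR_TABLE_COLS, names(dt))
  if (length(missing)) stop("DMR table lacks columns: ",
                            paste(missing, collapse = ", "))
  out <- dt[, DMR_TABLE_COLS, with = FALSE]
  for (col in c("ml_a", "ml_b", "fold_change", "difference",
                "p_value", "q_value")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a DMR table written by [write_dmr_table()]
#'
#' @param path file path.
#' @return data.table of DMRs.
#' @export
read_dmr_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("chrom", "direction",
                                              "genes", "components")))
  if (!identical(names(dt), DMR_TABLE_COLS)) {
    stop("unexpected DMR table header in ", path)
  }
  for (col in c("ml_a", "ml_b", "fold_change", "difference",
                "p_value", "q_value")) {
    dt[[col]] <- as.numeric(dt[[col]])
  }
  dt[, start := as.integer(start)]
  dt[, end := as.integer(end)]
  dt[, n_sites := as.integer(n_sites)]
  dt[]
}

#' Write planted truth regions as BED
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive.
#' Columns: chrom, start-1, end, direction, delta, ".".
#'
#' @param truth data.frame with chrom, start, end, direction, delta.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  dt <- as.data.table(truth)
  out <- data.table(chrom = dt$chrom, start = dt$start - 1L, end = dt$end,
                    name = dt$direction, score = dt$delta, strand = ".")
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a truth-region BED written by [write_truth_bed()]
#'
#' @param path file path.
#' @return data.table with chrom, start, end (1-based inclusive),
#'   direction, delta.
#' @export
read_truth_bed <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("chrom", "start", "end", "name", "score",
                            "strand"))
  data.table(chrom = as.character(dt$chrom), start = as.integer(dt$start + 1L),
             end = as.integer(dt$end), direction = as.character(dt$name),
             delta = as.numeric(dt$score))
}

#' Read a gene-identifier list (one id per line)
#'
#' @param path file path.
#' @return Character vector of unique, non-empty identifiers.
#' @export
read_deg_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
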