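#' Build an interval index of gene functional components
#'
#' Indexes promoter, 5'UTR, exon, intron and 3'UTR intervals per gene. The
#' promoter is the 2 kb immediately upstream of the transcription start
#' site: `[tss - promoter_length, tss - 1]` on the plus strand and
#' `[tss + 1, tss + promoter_length]` on the minus strand, clipped to the
#' contig bounds. Gene spans are kept alongside so DMRs falling in a
#' component gap of an annotated gene can still be attributed to it.
#'
#' @param models a [gene_models] object.
#' @param chrom_lengths named vector of contig lengths.
#' @param promoter_length promoter size in bp (default 2000).
#' @return An object of class `component_index`.
#' @export
build_component_index <- function(models, chrom_lengths,
                                  promoter_length = 2000L) {
  stopifnot(inherits(models, "gene_models"))
  promoter_length <- as.integer(promoter_length)
  genes <- models$genes
  proms <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    if (!g$chrom %in% names(chrom_lengths)) {
      stop("gene ", g$gene_id, " on unknown contig ", g$chrom)
    }
    clen <- as.integer(chrom_lengths[[g$chrom]])
    if (g$tss < 1L || g$tss > clen) {
      stop("gene ", g$gene_id, " has TSS outside contig bounds")
    }
    if (g$strand == "+") {
      ps <- max(1L, g$tss - promoter_length)
      pe <- g$tss - 1L
    } else {
      ps <- g$tss + 1L
      pe <- min(clen, g$tss + promoter_length)
    }
    if (ps <= pe) {
      proms[[length(proms) + 1L]] <- data.table(
        gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
        component = "promoter", start = ps, end = pe)
    }
  }
  feats <- copy(models$features)
  for (i in seq_len(nrow(feats))) {
    clen <- as.integer(chrom_lengths[[feats$chrom[i]]])
    if (feats$start[i] < 1L) feats[i, start := 1L]
    if (feats$end[i] > clen) feats[i, end := clen]
  }
  comp <- rbind(if (length(proms)) rbindlist(proms) else NULL, feats)
  setorder(comp, chrom, start, gene_id)
  structure(list(components = comp[],
                 gene_spans = copy(genes),
                 promoter_length = promoter_length,
                 chrom_lengths = chrom_lengths),
            class = "component_index")
}

#' @export
print.component_index <- function(x, ...) {
  cat("<component_index>", nrow(x$components), "component intervals for",
      nrow(x$gene_spans), "genes; promoter", x$promoter_length, "bp\n")
  invisible(x)
}

#' Annotate DMRs with the gene components they overlap
#'
#' A DMR receives a (gene, component) hit for every component interval it
#' overlaps by at least 1 bp; a DMR may hit several genes and several
#' components of the same gene. A DMR overlapping an annotated gene's span
#' without touching any of its components (an annotation gap) is assigned
#' the fallback category `gene_body` for that gene, so the gene hit is not
#' lost; `gene_body` is excluded from component percentages.
#'
#' @param dmrs data.table of DMRs (chrom, start, end, direction, ...).
#' @param index a [build_component_index()] result.
#' @return An object of class `annotated_dmrs`: list with `dmrs` (the input
#'   with a dmr_id column) and `hits` (data.table dmr_id, gene_id,
#'   component). Intergenic promoter-free DMRs appear in `dmrs` but have no
#'   rows in `hits`.
#' @export
annotate_dmrs <- function(dmrs, index) {
  stopifnot(inherits(index, "component_index"))
  dmrs <- as.data.table(dmrs)
  dmrs <- copy(dmrs)[, dmr_id := .I]
  comp <- index$components
  hits_list <- list()
  if (nrow(dmrs) && nrow(comp)) {
    dgr <- GenomicRanges::GRanges(dmrs$chrom,
                                  IRanges::IRanges(dmrs$start, dmrs$end))
    cgr <- GenomicRanges::GRanges(comp$chrom,
                                  IRanges::IRanges(comp$start, comp$end))
    ov <- GenomicRanges::findOverlaps(dgr, cgr, minoverlap = 1L)
    if (length(ov)) {
      hits_list$comp <- unique(data.table(
        dmr_id = S4Vectors::queryHits(ov),
        gene_id = comp$gene_id[S4Vectors::subjectHits(ov)],
        component = comp$component[S4Vectors::subjectHits(ov)]))
    }
    # gene-body fallback: overlaps the gene span but none of its body
    # components (promoter hits do not count toward the body)
    spans <- index$gene_spans
    sgr <- GenomicRanges::GRanges(spans$chrom,
                                  IRanges::IRanges(spans$start, spans$end))
    sov <- GenomicRanges::findOverlaps(dgr, sgr, minoverlap = 1L)
    if (length(sov)) {
      span_hits <- data.table(dmr_id = S4Vectors::queryHits(sov),
                              gene_id = spans$gene_id[S4Vectors::subjectHits(sov)])
      body <- if (is.null(hits_list$comp)) {
        data.table(dmr_id = integer(), gene_id = character())
      } else {
        unique(hits_list$comp[component != "promoter", .(dmr_id, gene_id)])
      }
      gaps <- span_hits[!body, on = c("dmr_id", "gene_id")]
      if (nrow(gaps)) {
        hits_list$body <- gaps[, .(dmr_id, gene_id, component = "gene_body")]
      }
    }
  }
  hits <- if (length(hits_list)) rbindlist(hits_list) else
    data.table(dmr_id = integer(), gene_id = character(),
               component = character())
  setorder(hits, dmr_id, gene_id, component)
  structure(list(dmrs = dmrs[], hits = hits[]), class = "annotated_dmrs")
}

#' @export
print.annotated_dmrs <- function(x, ...) {
  cat("<annotated_dmrs>", nrow(x$dmrs), "DMRs,", nrow(x$hits),
      "(gene, component) hits,", length(unique(x$hits$gene_id)), "genes\n")
  invisible(x)
}

#' Distribution of DMRs across gene components
#'
#' Counts DMRs per component (a DMR counts once for every component it
#' touches, so multi-component DMRs contribute to several rows) split into
#' hyper- and hypomethylated, with percentages normalised by the total
#' number of component assignments. The `gene_body` fallback category is
#' tabulated with an `NA` percentage and excluded from the normalisation.
#'
#' @param annotated an [annotate_dmrs()] result; its `dmrs` table must
#'   carry a `direction` column.
#' @return data.table with component, n_dmrs, n_hyper, n_hypo, pct.
#' @export
component_distribution <- function(annotated) {
  stopifnot(inherits(annotated, "annotated_dmrs"))
  dirs <- annotated$dmrs[, .(dmr_id, direction)]
  h <- unique(annotated$hits[, .(dmr_id, component)])
  h <- merge(h, dirs, by = "dmr_id")
  tab <- h[, .(n_dmrs = .N,
               n_hyper = sum(direction == "hyper"),
               n_hypo = sum(direction == "hypo")),
           by = component]
  lv <- c("promoter", "utr5", "exon", "intron", "utr3", "gene_body")
  tab <- tab[order(match(component, lv))]
  total <- sum(tab[component != "gene_body"]$n_dmrs)
  tab[, pct := ifelse(component == "gene_body", NA_real_,
                      if (total > 0) 100 * n_dmrs / total else NA_real_)]
  tab[]
}

#' Gene-level table of differentially methylated genes
#'
#' One row per gene hit by at least one DMR, with the number of distinct
#' DMRs touching it and flags for hyper/hypomethylated DMRs among them.
#'
#' @param annotated an [annotate_dmrs()] result.
#' @return data.table with gene_id, n_dmrs, n_hyper, n_hypo, any_hyper,
#'   any_hypo.
#' @export
count_dmgs <- function(annotated) {
  stopifnot(inherits(annotated, "annotated_dmrs"))
  dirs <- annotated$dmrs[, .(dmr_id, direction)]
  h <- unique(annotated$hits[, .(dmr_id, gene_id)])
  if (nrow(h) == 0L) {
    return(data.table(gene_id = character(), n_dmrs = integer(),
                      n_hyper = integer(), n_hypo = integer(),
                      any_hyper = logical(), any_hypo = logical()))
  }
  h <- merge(h, dirs, by = "dmr_id")
  out <- h[, .(n_dmrs = .N,
               n_hyper = sum(direction == "hyper"),
               n_hypo = sum(direction == "hypo")),
           by = gene_id]
  out[, any_hyper := n_hyper > 0L]
  out[, any_hypo := n_hypo > 0L]
  setorder(out, gene_id)
  out[]
}

#' Intersect differentially methylated and differentially expressed genes
#'
#' @param dmg_ids character vector of differentially methylated gene ids.
#' @param deg_ids character vector of differentially expressed gene ids
#'   (external list).
#' @return List with `overlap` (sorted intersection), n_dmg, n_deg,
#'   n_overlap — the Venn triple.
#' @export
intersect_dmg_deg <- function(dmg_ids, deg_ids) {
  dmg <- unique(as.character(dmg_ids))
  deg <- unique(as.character(deg_ids))
  ov <- sort(intersect(dmg, deg))
  list(overlap = ov, n_dmg = length(dmg), n_deg = length(deg),
       n_overlap = length(ov))
}
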