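#' Map lncRNAs to cis-target coding genes
#'
#' A coding gene is a cis target of a lncRNA when the gap between their
#' genomic spans is at most \code{window} bp (overlapping spans have
#' distance 0), on the same chromosome, on either strand. Distances follow
#' the \code{GenomicRanges::distance} convention: the number of bases
#' strictly between the two spans, so a gene starting 1001 bp after the
#' lncRNA end lies at distance 1000 and is still linked with the default
#' window. One lncRNA may link several genes and vice versa.
#'
#' @param lncrnas exon-level data.frame (or \code{\link{tx_summary}} output)
#'   of lncRNA transcripts.
#' @param coding exon-level data.frame of coding transcripts; gene spans are
#'   min exon start to max exon end per gene.
#' @param window maximum gap in bp (default 1000, i.e. +/- 1 kb).
#' @return link table data.frame: source_id, target_gene, link_type
#'   ("cis_target"), distance; sorted by source then target.
#' @export
cis_targets <- function(lncrnas, coding, window = 1000L) {
  if (window < 0) stop("window must be non-negative")
  lnc_tx <- if ("n_exons" %in% names(lncrnas)) lncrnas else tx_summary(lncrnas)
  gene_span <- gene_spans(coding)
  empty <- data.frame(source_id = character(), target_gene = character(),
                      link_type = character(), distance = integer())
  if (nrow(lnc_tx) == 0L || nrow(gene_span) == 0L) return(empty)

  lnc_gr <- GenomicRanges::GRanges(lnc_tx$chrom,
                                   IRanges::IRanges(lnc_tx$start, lnc_tx$end))
  gene_gr <- GenomicRanges::GRanges(gene_span$chrom,
                                    IRanges::IRanges(gene_span$start,
                                                     gene_span$end))
  hits <- GenomicRanges::findOverlaps(lnc_gr, gene_gr, maxgap = window,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(lnc_gr[qi], gene_gr[si], ignore.strand = TRUE)
  out <- data.frame(
    source_id = lnc_tx$transcript_id[qi],
    target_gene = gene_span$gene_id[si],
    link_type = "cis_target",
    distance = as.integer(d),
    stringsAsFactors = FALSE
  )
  out <- out[out$distance <= window, , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$source_id, out$target_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-gene genomic span from an exon table.
gene_spans <- function(coding) {
  dt <- data.table::as.data.table(coding)
  as.data.frame(dt[, list(chrom = chrom[1], start = min(start),
                          end = max(end), strand = strand[1]),
                   by = "gene_id"])
}

#' Map circRNAs to their origin coding genes
#'
#' A coding gene is an origin gene of a circRNA when the circle interval
#' \code{[acceptor, donor]} overlaps at least one of the gene's exons by at
#' least 1 bp. A circle spanning exons of two genes yields two links.
#' Overlap is strand-agnostic unless \code{stranded = TRUE}.
#'
#' @param junctions data.frame of back-splice junctions (chrom, acceptor,
#'   donor, strand, and an id column \code{circ_id} or a generated one).
#' @param coding exon-level data.frame of coding transcripts.
#' @param stranded require the junction strand to match the gene strand.
#' @return link table data.frame: source_id, target_gene, link_type
#'   ("origin"), distance (always 0).
#' @export
origin_genes <- function(junctions, coding, stranded = FALSE) {
  empty <- data.frame(source_id = character(), target_gene = character(),
                      link_type = character(), distance = integer())
  if (nrow(junctions) == 0L || nrow(coding) == 0L) return(empty)
  ids <- junctions$circ_id %||%
    sprintf("%s:%d-%d", junctions$chrom, junctions$acceptor, junctions$donor)
  circ_gr <- GenomicRanges::GRanges(
    junctions$chrom,
    IRanges::IRanges(junctions$acceptor, junctions$donor),
    strand = junctions$strand %||% "*"
  )
  ex_gr <- exons_granges(coding)
  hits <- GenomicRanges::findOverlaps(circ_gr, ex_gr,
                                      ignore.strand = !stranded)
  if (length(hits) == 0L) return(empty)
  out <- unique(data.frame(
    source_id = ids[S4Vectors::queryHits(hits)],
    target_gene = coding$gene_id[S4Vectors::subjectHits(hits)],
    link_type = "origin",
    distance = 0L,
    stringsAsFactors = FALSE
  ))
  out <- out[order(out$source_id, out$target_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
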