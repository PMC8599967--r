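#' Per-transcript summary of an exon table
#'
#' @param exons exon-level data.frame (transcript_id, gene_id, chrom,
#'   strand, start, end, biotype, cov).
#' @return data.frame with one row per transcript: transcript_id, gene_id,
#'   chrom, strand, start, end, n_exons, length (summed exon length),
#'   cov, biotype.
#' @export
tx_summary <- function(exons) {
  dt <- data.table::as.data.table(exons)
  out <- dt[, list(
    gene_id = gene_id[1], chrom = chrom[1], strand = strand[1],
    start = min(start), end = max(end), n_exons = .N,
    length = sum(end - start + 1L), cov = cov[1], biotype = biotype[1]
  ), by = "transcript_id"]
  as.data.frame(out)
}

# GRanges of exons, with transcript id metadata.
exons_granges <- function(exons) {
  GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand,
    transcript_id = exons$transcript_id
  )
}

# Intron intervals of every reference transcript (gaps between its exons).
reference_introns <- function(ref_exons) {
  parts <- split(seq_len(nrow(ref_exons)), ref_exons$transcript_id)
  rows <- lapply(parts, function(ix) {
    ex <- ref_exons[ix, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) return(NULL)
    data.frame(chrom = ex$chrom[1],
               start = ex$end[-nrow(ex)] + 1L,
               end = ex$start[-1] - 1L,
               transcript_id = ex$transcript_id[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), transcript_id = character())
  }
  out[out$end >= out$start, , drop = FALSE]
}

#' Assign lncRNA class codes against a reference annotation
#'
#' For every novel transcript, relative to the reference coding genes:
#' \describe{
#'   \item{x (antisense)}{at least one exon overlaps a reference exon on the
#'     opposite strand and none overlaps on the same strand;}
#'   \item{i (intronic)}{the transcript lies entirely within a single intron
#'     of one reference transcript (any strand), with no exonic overlap;}
#'   \item{u (intergenic)}{no overlap with any reference gene span;}
#'   \item{other}{anything else, in particular same-strand exonic overlap.}
#' }
#' Precedence is x before i before u. A transcript on a chromosome absent
#' from the reference is classed u with a warning.
#'
#' @param novel exon-level data.frame of transcripts to classify.
#' @param reference exon-level data.frame of reference coding transcripts.
#' @return data.frame with transcript_id, code.
#' @export
assign_class_code <- function(novel, reference) {
  nov_tx <- tx_summary(novel)
  if (nrow(nov_tx) == 0L) {
    return(data.frame(transcript_id = character(), code = character()))
  }
  missing_chr <- !nov_tx$chrom %in% unique(reference$chrom)
  if (any(missing_chr)) {
    warning("transcript(s) on chromosome(s) absent from the reference; classed u")
  }

  nov_gr <- exons_granges(novel)
  ref_gr <- exons_granges(reference)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(nov_gr, ref_gr, ignore.strand = TRUE))
  same <- as.character(GenomicRanges::strand(nov_gr))[S4Vectors::queryHits(hits)] ==
    as.character(GenomicRanges::strand(ref_gr))[S4Vectors::subjectHits(hits)]
  ss_tx <- unique(nov_gr$transcript_id[S4Vectors::queryHits(hits)[same]])
  as_tx <- unique(nov_gr$transcript_id[S4Vectors::queryHits(hits)[!same]])

  # gene spans (min start to max end over the gene's exons)
  ref_tx <- tx_summary(reference)
  gene_span <- data.table::as.data.table(ref_tx)[, list(
    chrom = chrom[1], start = min(start), end = max(end)
  ), by = "gene_id"]
  span_gr <- GenomicRanges::GRanges(gene_span$chrom,
                                    IRanges::IRanges(gene_span$start,
                                                     gene_span$end))
  nov_span_gr <- GenomicRanges::GRanges(nov_tx$chrom,
                                        IRanges::IRanges(nov_tx$start,
                                                         nov_tx$end))
  span_hit <- suppressWarnings(
    GenomicRanges::countOverlaps(nov_span_gr, span_gr,
                                 ignore.strand = TRUE)) > 0

  introns <- reference_introns(reference)
  if (nrow(introns)) {
    intron_gr <- GenomicRanges::GRanges(introns$chrom,
                                        IRanges::IRanges(introns$start,
                                                         introns$end))
    within_intron <- suppressWarnings(GenomicRanges::countOverlaps(
      nov_span_gr, intron_gr, type = "within", ignore.strand = TRUE)) > 0
  } else {
    within_intron <- rep(FALSE, nrow(nov_tx))
  }

  code <- character(nrow(nov_tx))
  for (i in seq_len(nrow(nov_tx))) {
    tid <- nov_tx$transcript_id[i]
    code[i] <- if (missing_chr[i]) "u"
    else if (tid %in% ss_tx) "other"
    else if (tid %in% as_tx) "x"
    else if (within_intron[i]) "i"
    else if (!span_hit[i]) "u"
    else "other"
  }
  data.frame(transcript_id = nov_tx$transcript_id, code = code,
             stringsAsFactors = FALSE)
}

#' Apply the lncRNA filter cascade
#'
#' A transcript is kept as an expressed lncRNA iff its spliced length
#' exceeds 200 nt (strict), it has at least 2 exons, its class code is one
#' of x/u/i, and its assembly coverage exceeds 3 (strict).
#'
#' @param transcripts exon-level data.frame of the candidate transcripts.
#' @param codes data.frame from \code{\link{assign_class_code}}.
#' @param min_length,min_exons,min_cov filter thresholds (length and
#'   coverage strict, exon count inclusive).
#' @return data.frame with transcript_id, code, length, n_exons, coverage,
#'   kept. The kept transcript ids are \code{out$transcript_id[out$kept]}.
#' @export
filter_lncrna <- function(transcripts, codes, min_length = 200,
                          min_exons = 2L, min_cov = 3) {
  tx <- tx_summary(transcripts)
  tab <- merge(tx, codes, by = "transcript_id", all.x = TRUE, sort = FALSE)
  tab$code[is.na(tab$code)] <- "other"
  data.frame(
    transcript_id = tab$transcript_id,
    code = tab$code,
    length = tab$length,
    n_exons = tab$n_exons,
    coverage = tab$cov,
    kept = tab$length > min_length & tab$n_exons >= min_exons &
      tab$code %in% c("x", "u", "i") & tab$cov > min_cov,
    stringsAsFactors = FALSE
  )
}
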