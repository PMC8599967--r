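#' Split a read into its terminal anchors
#'
#' The back-splice caller works on the two fixed-length terminal substrings
#' of a read (20 bp by default): the first \code{anchor_len} bases (5'
#' anchor) and the last \code{anchor_len} bases (3' anchor).
#'
#' @param read character scalar.
#' @param anchor_len anchor length in bp.
#' @return list with \code{five_prime} and \code{three_prime}, or a
#'   rejection list (\code{status = "too-short"}) when the read cannot hold
#'   two anchors.
#' @export
extract_anchors <- function(read, anchor_len = 20L) {
  L <- nchar(read)
  if (L < 2L * anchor_len) {
    return(list(status = "too-short", five_prime = NULL, three_prime = NULL))
  }
  list(status = "ok",
       five_prime = substr(read, 1L, anchor_len),
       three_prime = substr(read, L - anchor_len + 1L, L))
}

# Flanking dinucleotides that a junction on `strand` must show on the
# FORWARD genome, for a given signal convention. `conv` is c(left, right)
# in plus-strand terms; minus-strand circles show the reverse-complemented,
# swapped pair.
signal_flanks <- function(convention, strand) {
  conv <- switch(convention,
                 "AG-GT" = c("AG", "GT"),
                 "GT-AG" = c("GT", "AG"),
                 stop("unknown signal convention: ", convention))
  if (strand == "+") conv else c(revcomp(conv[2]), revcomp(conv[1]))
}

# Count how far a read can be extended base-by-base against the genome.
# `read_pos(j)` / `gen_pos(j)` give the read index and 1-based genome
# coordinate of the j-th extension step; `comp` complements the genome base
# (minus-strand geometry).
extend_match <- function(read, gseq, read_pos, gen_pos, n_max, comp = FALSE) {
  e <- 0L
  clen <- nchar(gseq)
  for (j in seq_len(n_max)) {
    gp <- gen_pos(j)
    if (gp < 1L || gp > clen) break
    gb <- substr(gseq, gp, gp)
    if (comp) gb <- chartr("ACGT", "TGCA", gb)
    if (substr(read, read_pos(j), read_pos(j)) != gb) break
    e <- j
  }
  e
}

#' Call a back-splice junction from a single unmapped read
#'
#' Implements anchor-based circRNA detection: (1) the two terminal
#' \code{anchor_len}-mers of the read are mapped exactly; (2) each anchor
#' must have exactly one genomic hit, both on the same chromosome and
#' strand; (3) the anchors must appear in reversed genomic order relative to
#' a linear read (the 5' anchor downstream of the 3' anchor on the plus
#' strand, mirrored on the minus strand) — the hallmark of a read spanning a
#' back-splice; (4) both anchors are extended toward the read interior
#' against the genome to localise the breakpoint; among breakpoints
#' consistent with the read, the one whose flanking genomic dinucleotides
#' match the splice signal is chosen (smallest 5'-anchor extension breaks
#' ties); (5) the junction is reported with \code{acceptor} = leftmost
#' circle base and \code{donor} = rightmost circle base (1-based), plus a
#' \code{signal_ok} flag.
#'
#' @param index a \code{\link{build_index}} result (carries the genome).
#' @param read character scalar; must not be linearly mappable.
#' @param anchor_len anchor length (default 20).
#' @param max_span maximum circle span in bp (default 100000).
#' @param signal \code{"AG-GT"} (acceptor-side AG immediately upstream of
#'   the circle start, donor-side GT immediately downstream of its end, as
#'   the canonical GT-AG intron written acceptor-first), \code{"GT-AG"}
#'   (swapped orientation) or \code{"off"} (no requirement; the flag is
#'   still computed under the AG-GT convention).
#' @return list with \code{status = "ok"} and fields \code{chrom},
#'   \code{acceptor}, \code{donor}, \code{strand}, \code{signal_ok}; or
#'   \code{status} set to a rejection reason: \code{too-short},
#'   \code{unmapped-anchor}, \code{ambiguous}, \code{discordant},
#'   \code{collinear}, \code{too-long}, \code{no-extension},
#'   \code{no-signal}.
#' @export
call_backsplice <- function(index, read, anchor_len = 20L,
                            max_span = 100000L, signal = "AG-GT") {
  signal <- match.arg(signal, c("AG-GT", "GT-AG", "off"))
  require_signal <- signal != "off"
  convention <- if (signal == "off") "AG-GT" else signal
  al <- as.integer(anchor_len)
  L <- nchar(read)
  reject <- function(why) list(status = why)

  anc <- extract_anchors(read, al)
  if (anc$status != "ok") return(reject(anc$status))
  h5 <- map_linear(index, anc$five_prime)
  h3 <- map_linear(index, anc$three_prime)
  if (nrow(h5) == 0L || nrow(h3) == 0L) return(reject("unmapped-anchor"))
  if (nrow(h5) > 1L || nrow(h3) > 1L) return(reject("ambiguous"))
  if (h5$chrom != h3$chrom || h5$strand != h3$strand) return(reject("discordant"))
  chrom <- h5$chrom
  strand <- h5$strand
  gseq <- index$genome$seq[[chrom]]
  p5 <- h5$pos + 1L   # 1-based start of the 5' anchor's forward window
  p3 <- h3$pos + 1L

  if (strand == "+") {
    if (p5 <= p3) return(reject("collinear"))
    span <- p5 - p3 + L - al
  } else {
    if (p3 <= p5) return(reject("collinear"))
    span <- p3 - p5 + L - al
  }
  if (span > max_span) return(reject("too-long"))

  n_free <- L - 2L * al
  if (strand == "+") {
    e5 <- extend_match(read, gseq, function(j) al + j,
                       function(j) p5 + al + j - 1L, n_free)
    e3 <- extend_match(read, gseq, function(j) L - al + 1L - j,
                       function(j) p3 - j, n_free)
  } else {
    e5 <- extend_match(read, gseq, function(j) al + j,
                       function(j) p5 - j, n_free, comp = TRUE)
    e3 <- extend_match(read, gseq, function(j) L - al + 1L - j,
                       function(j) p3 + al - 1L + j, n_free, comp = TRUE)
  }
  lo <- max(al, L - al - e3)
  hi <- min(al + e5, L - al)
  if (lo > hi) return(reject("no-extension"))

  flanks <- signal_flanks(convention, strand)
  clen <- nchar(gseq)
  boundaries <- function(s) {
    if (strand == "+") c(p3 + s + al - L, p5 + s - 1L)
    else c(p5 + al - s, p3 + L - s - 1L)
  }
  sig_at <- function(s) {
    b <- boundaries(s)
    if (b[1] - 2L < 1L || b[2] + 2L > clen) return(FALSE)
    substr(gseq, b[1] - 2L, b[1] - 1L) == flanks[1] &&
      substr(gseq, b[2] + 1L, b[2] + 2L) == flanks[2]
  }
  cand_s <- lo:hi
  ok_sig <- vapply(cand_s, sig_at, logical(1))
  if (any(ok_sig)) {
    s <- cand_s[which(ok_sig)[1]]
    signal_ok <- TRUE
  } else if (require_signal) {
    return(reject("no-signal"))
  } else {
    s <- lo
    signal_ok <- FALSE
  }
  b <- boundaries(s)
  if (b[1] < 1L || b[2] > clen || b[1] >= b[2]) return(reject("no-extension"))
  list(status = "ok", chrom = chrom, acceptor = b[1], donor = b[2],
       strand = strand, signal_ok = signal_ok)
}

#' Merge identical junction calls and apply a support threshold
#'
#' @param calls data.frame of accepted calls with columns chrom, acceptor,
#'   donor, strand, signal_ok (one row per supporting read).
#' @param min_support junctions with fewer supporting reads are dropped
#'   (default 1, i.e. no threshold).
#' @return data.frame with one row per distinct junction: chrom, acceptor,
#'   donor, strand, signal_ok (all supporting calls agreed), support;
#'   sorted by coordinate.
#' @export
collapse_and_count <- function(calls, min_support = 1L) {
  empty <- data.frame(chrom = character(), acceptor = integer(),
                      donor = integer(), strand = character(),
                      signal_ok = logical(), support = integer())
  if (is.null(calls) || nrow(calls) == 0L) return(empty)
  dt <- data.table::as.data.table(calls)
  out <- dt[, list(signal_ok = all(signal_ok), support = .N),
            by = c("chrom", "acceptor", "donor", "strand")]
  out <- out[out$support >= min_support]
  data.table::setorderv(out, c("chrom", "acceptor", "donor", "strand"))
  as.data.frame(out)
}

#' TPM quantification of junction support
#'
#' Transcripts-per-million over back-splice junctions:
#' \code{rate_i = support_i / (length_i / 1000)}; \code{tpm_i = rate_i /
#' sum(rate) * 1e6}. With all-zero support all TPMs are zero. The default
#' effective length is the genomic span of the circle
#' (\code{donor - acceptor + 1}); passing \code{effective_lengths = 1}
#' (recycled) makes TPM proportional to raw junction support.
#'
#' @param junctions data.frame from \code{\link{collapse_and_count}}.
#' @param effective_lengths positive lengths in nt, recycled; NULL uses the
#'   genomic span.
#' @return the input with columns \code{length} and \code{tpm} appended.
#' @export
tpm_quantify <- function(junctions, effective_lengths = NULL) {
  n <- nrow(junctions)
  if (is.null(effective_lengths)) {
    len <- junctions$donor - junctions$acceptor + 1L
  } else {
    len <- rep_len(effective_lengths, n)
  }
  if (any(len <= 0)) stop("effective lengths must be positive")
  if (any(junctions$support < 0)) stop("support must be non-negative")
  rate <- junctions$support / (len / 1000)
  total <- sum(rate)
  junctions$length <- len
  junctions$tpm <- if (total > 0) rate / total * 1e6 else rep(0, n)
  junctions
}

#' Detect circRNAs from a read set
#'
#' Full caller: each read is first triaged with \code{\link{map_linear}};
#' contiguously mappable reads are set aside, the remainder go through
#' \code{\link{call_backsplice}}, and accepted calls are collapsed, filtered
#' by support and TPM-quantified.
#'
#' @param index a \code{\link{build_index}} result.
#' @param reads data.frame with columns \code{id}, \code{seq} (e.g. from
#'   \code{\link{simulate_reads}} or \code{\link{read_fastq}}).
#' @param anchor_len,max_span,signal passed to \code{\link{call_backsplice}}.
#' @param min_support passed to \code{\link{collapse_and_count}}.
#' @return list with \code{junctions} (collapsed, TPM-quantified),
#'   \code{n_mapped} (linearly mapped reads) and \code{rejections} (table of
#'   rejection reasons over unmapped reads).
#' @export
detect_circrnas <- function(index, reads, anchor_len = 20L,
                            max_span = 100000L, signal = "AG-GT",
                            min_support = 1L) {
  calls <- list()
  reasons <- character(0)
  n_mapped <- 0L
  for (i in seq_len(nrow(reads))) {
    rd <- reads$seq[i]
    if (nrow(map_linear(index, rd)) > 0L) {
      n_mapped <- n_mapped + 1L
      next
    }
    res <- call_backsplice(index, rd, anchor_len = anchor_len,
                           max_span = max_span, signal = signal)
    if (res$status == "ok") {
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = res$chrom, acceptor = res$acceptor, donor = res$donor,
        strand = res$strand, signal_ok = res$signal_ok,
        stringsAsFactors = FALSE
      )
    } else {
      reasons <- c(reasons, res$status)
    }
  }
  junctions <- collapse_and_count(
    if (length(calls)) do.call(rbind, calls) else NULL,
    min_support = min_support
  )
  junctions <- tpm_quantify(junctions)
  list(junctions = junctions, n_mapped = n_mapped,
       rejections = table(reasons))
}
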