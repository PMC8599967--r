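#' Build an exact k-mer index of a genome
#'
#' Indexes every genomic k-mer on both strands. A plus-strand entry at
#' position p means the k-mer equals the genome slice starting at p; a
#' minus-strand entry means the k-mer equals the reverse complement of that
#' slice. Positions are 0-based. The default k of 20 is the anchor length
#' used for back-splice detection.
#'
#' @param genome a \code{\link{genome_ref}}.
#' @param k k-mer length (1 <= k <= shortest chromosome).
#' @return object of class \code{kmer_index}: list with \code{k},
#'   \code{genome}, a position table (chrom, pos, strand) and a hashed
#'   environment mapping each k-mer to its row indices in that table.
#' @export
build_index <- function(genome, k = 20L) {
  stopifnot(inherits(genome, "genome_ref"))
  k <- as.integer(k)
  if (k < 1L || k > min(nchar(genome$seq))) {
    stop("k must satisfy 1 <= k <= shortest chromosome length")
  }
  tabs <- lapply(names(genome$seq), function(chrom) {
    s <- genome$seq[[chrom]]
    L <- nchar(s)
    n <- L - k + 1L
    fwd <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    rs <- revcomp(s)
    # window i of revcomp(s) corresponds to forward start L - k + 2 - i
    rcs <- substring(rs, seq_len(n), seq_len(n) + k - 1L)[n:1]
    list(kmer = c(fwd, rcs),
         chrom = rep(chrom, 2L * n),
         pos = c(seq_len(n), seq_len(n)) - 1L,
         strand = rep(c("+", "-"), each = n))
  })
  kmer <- unlist(lapply(tabs, `[[`, "kmer"), use.names = FALSE)
  pos_tab <- list(
    chrom = unlist(lapply(tabs, `[[`, "chrom"), use.names = FALSE),
    pos = unlist(lapply(tabs, `[[`, "pos"), use.names = FALSE),
    strand = unlist(lapply(tabs, `[[`, "strand"), use.names = FALSE)
  )
  env <- list2env(split(seq_along(kmer), kmer),
                  envir = new.env(hash = TRUE, size = length(kmer)))
  structure(list(k = k, genome = genome, pos_tab = pos_tab,
                 n_entries = length(kmer), env = env),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k, ",", x$n_entries, "entries\n")
  invisible(x)
}

# Raw index lookup: positions of one k-mer as a list(chrom, pos, strand)
# of equal-length vectors (zero length if the k-mer is absent).
index_lookup <- function(index, query) {
  ix <- index$env[[query]]
  if (is.null(ix)) ix <- integer(0)
  list(chrom = index$pos_tab$chrom[ix],
       pos = index$pos_tab$pos[ix],
       strand = index$pos_tab$strand[ix])
}

#' Map a read to the genome by exact contiguous matching
#'
#' Seeds with the read's first k-mer and verifies the full read against the
#' genome (forward strand) or its reverse complement (minus strand).
#' Ambiguous bases never match. This is the linear-read triage step: reads
#' with at least one placement are "mapped"; reads with none are candidates
#' for back-splice calling.
#'
#' @param index a \code{\link{build_index}} result.
#' @param read character scalar, length >= k.
#' @param max_mismatches reserved; only 0 (exact) is supported.
#' @return data.frame of anchor hits: \code{chrom}, \code{pos} (0-based
#'   forward coordinate of the match start), \code{strand}, \code{unique}.
#'   Zero rows when the read has no contiguous placement.
#' @export
map_linear <- function(index, read, max_mismatches = 0L) {
  stopifnot(inherits(index, "kmer_index"))
  if (!is.character(read) || length(read) != 1L || !nzchar(read)) {
    stop("read must be a non-empty character scalar")
  }
  if (max_mismatches != 0L) stop("only exact matching (max_mismatches = 0) is supported")
  L <- nchar(read)
  k <- index$k
  if (L < k) stop("read shorter than the index k-mer length")
  no_hit <- data.frame(chrom = character(), pos = integer(),
                       strand = character(), unique = logical())
  if (grepl("[^ACGT]", read)) return(no_hit)

  seed <- substr(read, 1L, k)
  cand <- index_lookup(index, seed)
  n_cand <- length(cand$pos)
  if (n_cand == 0L) return(no_hit)

  rc_read <- NULL
  h_chrom <- character(0); h_pos <- integer(0); h_strand <- character(0)
  for (i in seq_len(n_cand)) {
    chrom <- cand$chrom[i]
    clen <- nchar(index$genome$seq[[chrom]])
    if (cand$strand[i] == "+") {
      p <- cand$pos[i]                       # 0-based forward start of read
      if (p + L > clen) next
      if (genome_slice(index$genome, chrom, p + 1L, p + L) == read) {
        h_chrom <- c(h_chrom, chrom); h_pos <- c(h_pos, p)
        h_strand <- c(h_strand, "+")
      }
    } else {
      # seed matches minus strand: its forward window starts at cand$pos and
      # holds the LAST k bases of the reverse-complemented read placement
      p <- cand$pos[i] - (L - k)             # forward start of full placement
      if (p < 0L || p + L > clen) next
      if (is.null(rc_read)) rc_read <- revcomp(read)
      if (genome_slice(index$genome, chrom, p + 1L, p + L) == rc_read) {
        h_chrom <- c(h_chrom, chrom); h_pos <- c(h_pos, p)
        h_strand <- c(h_strand, "-")
      }
    }
  }
  if (length(h_pos) == 0L) return(no_hit)
  hits <- unique(data.frame(chrom = h_chrom, pos = h_pos, strand = h_strand,
                            stringsAsFactors = FALSE))
  hits <- hits[order(hits$chrom, hits$pos, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits$unique <- nrow(hits) == 1L
  hits
}
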