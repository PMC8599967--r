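#' Write a genome as FASTA
#' @param genome a \code{\link{genome_ref}}.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return a \code{\link{genome_ref}}.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  genome_ref(stats::setNames(as.character(ss),
                             sub("\\s.*$", "", names(ss))))
}

#' Write reads as FASTQ (constant quality)
#' @param reads data.frame with columns id, seq.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file.
#' @return data.frame with columns id, seq.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(ss)),
             seq = unname(as.character(ss)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an exon table as GTF
#'
#' One exon feature per row; 1-based inclusive coordinates; attributes
#' gene_id, transcript_id, gene_biotype and cov.
#'
#' @param exons exon-level data.frame.
#' @param path output file.
#' @export
write_gtf <- function(exons, path) {
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_biotype "%s"; cov "%s";',
    exons$gene_id, exons$transcript_id, exons$biotype, exons$cov
  )
  lines <- paste(exons$chrom, "plaqomics", "exon", exons$start, exons$end,
                 ".", exons$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read an exon table from GTF
#'
#' Parses exon features into the exon-level data.frame used across the
#' package. Attributes gene_id and transcript_id are required; gene_biotype
#' and cov are optional (defaults "novel" and 0).
#'
#' @param path GTF file.
#' @return exon-level data.frame (transcript_id, gene_id, chrom, strand,
#'   start, end, biotype, cov).
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 9L)
  if (length(bad)) {
    stop(sprintf("malformed GTF line %d in %s", bad[1], path))
  }
  keep <- vapply(parts, function(p) p[3] == "exon", logical(1))
  parts <- parts[keep]
  grab <- function(attr_str, key, default = NA_character_) {
    m <- regmatches(attr_str, regexec(paste0(key, ' "([^"]*)"'), attr_str))[[1]]
    if (length(m) == 2L) m[2] else default
  }
  rows <- lapply(parts, function(p) {
    data.frame(
      transcript_id = grab(p[9], "transcript_id"),
      gene_id = grab(p[9], "gene_id"),
      chrom = p[1], strand = p[7],
      start = as.integer(p[4]), end = as.integer(p[5]),
      biotype = grab(p[9], "gene_biotype", "novel"),
      cov = as.numeric(grab(p[9], "cov", "0")),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || any(is.na(out$transcript_id)) || any(is.na(out$gene_id))) {
    stop("GTF exons must carry transcript_id and gene_id attributes")
  }
  out
}

#' Write a feature-by-sample matrix as TSV
#' @param om an \code{\link{omics_matrix}} or matrix.
#' @param path output file.
#' @export
write_matrix_tsv <- function(om, path) {
  m <- if (inherits(om, "omics_matrix")) om$values else om
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample matrix from TSV
#' @param path TSV with a feature_id column and one column per sample.
#' @param groups,layer passed to \code{\link{omics_matrix}}; when groups is
#'   NULL a plain matrix is returned.
#' @export
read_matrix_tsv <- function(path, groups = NULL, layer = "mrna") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (is.null(groups)) return(m)
  omics_matrix(m, groups, layer)
}

#' Read a GMT gene-set collection
#' @param path GMT file (set name, description, tab-separated genes).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write junctions as BED6
#'
#' 0-based half-open convention: chromStart = acceptor - 1, chromEnd =
#' donor; score is the junction read support.
#'
#' @param junctions data.frame from \code{\link{collapse_and_count}}.
#' @param path output file.
#' @export
write_junctions_bed <- function(junctions, path) {
  if (nrow(junctions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- sprintf("circ|%s:%d-%d", junctions$chrom, junctions$acceptor,
                  junctions$donor)
  lines <- paste(junctions$chrom, junctions$acceptor - 1L, junctions$donor,
                 name, junctions$support, junctions$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
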