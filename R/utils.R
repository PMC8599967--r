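#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over character vectors in the DNA alphabet
#' (U is accepted and treated as T).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTUNacgtun", "TGCAANtgcaan", s), "",
                       fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Derive a stream-specific seed from a master seed
#'
#' Keeps every random stream in the package a deterministic function of one
#' user-visible seed while avoiding accidental stream reuse across stages.
#' Result stays below 2^31.
#'
#' @param seed master integer seed.
#' @param offset small integer identifying the stream.
#' @keywords internal
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Number of (possibly overlapping is NOT counted; gregexpr is non-overlapping,
# which is adequate for random 20-mers) fixed-string occurrences.
count_occurrences <- function(hay, pat) {
  m <- gregexpr(pat, hay, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
}
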