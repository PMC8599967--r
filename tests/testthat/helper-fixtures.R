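# Shared fixtures, all generated in code.

random_genome_string <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A hand-planted back-splice fixture on a small random genome: a circle
# [acceptor, donor] with canonical flanks and one 100 nt junction read.
# strand "+" emits the read forward, "-" in transcript (reverse) orientation.
make_circ_fixture <- function(seed = 101, strand = "+") {
  s <- random_genome_string(2000, seed)
  a <- 501L; d <- 1100L
  flank <- if (strand == "+") c("AG", "GT") else c("AC", "CT")
  substr(s, a - 2L, a - 1L) <- flank[1]
  substr(s, d + 1L, d + 2L) <- flank[2]
  g <- genome_ref(c(chr1 = s))
  read <- if (strand == "+") {
    paste0(genome_slice(g, "chr1", d - 49L, d),
           genome_slice(g, "chr1", a, a + 49L))
  } else {
    paste0(plaqomics:::revcomp(genome_slice(g, "chr1", a, a + 49L)),
           plaqomics:::revcomp(genome_slice(g, "chr1", d - 49L, d)))
  }
  list(genome = g, read = read, acceptor = a, donor = d, strand = strand)
}

# Brute-force exact placements of a read via Biostrings pattern matching on
# the genome and its reverse complement (independent of the k-mer mapper).
brute_force_placements <- function(genome, read) {
  gseq <- Biostrings::DNAString(genome$seq[[1]])
  fwd <- Biostrings::start(Biostrings::matchPattern(read, gseq))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  rev <- Biostrings::start(Biostrings::matchPattern(rc, gseq))
  list(fwd = sort(fwd), rev = sort(rev))
}

# Minimal DE-record table for integration tests.
de_record <- function(feature_id, lfc, p, lfc_threshold = 1, p_threshold = 0.05) {
  data.frame(
    feature_id = feature_id,
    baseMean = 100,
    log2FoldChange = lfc,
    pvalue = p,
    qvalue = p,
    is_de = abs(lfc) > lfc_threshold & p < p_threshold,
    stringsAsFactors = FALSE
  )
}
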