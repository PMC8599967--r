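#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the package targets: two groups of five plaque samples
#' (stable vs unstable), a small genome carrying multi-exon coding genes,
#' planted antisense/intergenic/intronic lncRNAs, planted circRNAs whose
#' back-splice junctions carry canonical AG/GT flanks, negative-binomial
#' two-group counts with planted log2 fold changes, and a label-free
#' proteomics intensity table with a small subset concordant with the mRNA
#' changes.
#'
#' @param seed master seed; every random stream derives from it.
#' @param genome_length genome size in bp (single chromosome), >= 10000.
#' @param n_coding_genes number of non-overlapping multi-exon coding genes.
#' @param n_lncrnas_per_class planted lncRNAs per class code (x, u, i).
#' @param n_decoys_per_kind planted disqualified transcripts per kind
#'   (short, mono-exonic, low-coverage, same-strand overlap).
#' @param n_circrnas planted circRNAs (at most one per coding gene).
#' @param read_length read length in nt; must be >= 40 (twice the anchor).
#' @param junction_reads_per_circ back-splice-spanning reads emitted per
#'   planted circRNA.
#' @param n_linear_reads linearly mappable reads sampled from transcripts.
#' @param error_rate per-base substitution rate applied to reads (default 0).
#' @param n_samples_per_group samples per group (default 5 vs 5).
#' @param n_features features in the simulated count matrix.
#' @param frac_de fraction of count features with a planted fold change.
#' @param planted_lfc magnitude of the planted log2 fold change (sign is
#'   drawn per feature).
#' @param nb_dispersion negative-binomial dispersion (var = mu + a*mu^2).
#' @param n_proteins proteins in the simulated LFQ table.
#' @param prot_frac_de fraction of proteins with a planted fold change.
#' @param n_concordant proteins planted as differential in both the count
#'   and the protein layer with the same sign.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_coding_genes = 20L,
                       n_lncrnas_per_class = 5L,
                       n_decoys_per_kind = 5L,
                       n_circrnas = 5L,
                       read_length = 100L,
                       junction_reads_per_circ = 3L,
                       n_linear_reads = 2000L,
                       error_rate = 0,
                       n_samples_per_group = 5L,
                       n_features = 2000L,
                       frac_de = 0.1,
                       planted_lfc = 2,
                       nb_dispersion = 0.1,
                       n_proteins = 300L,
                       prot_frac_de = 0.1,
                       n_concordant = 2L) {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    n_coding_genes = as.integer(n_coding_genes),
    n_lncrnas_per_class = as.integer(n_lncrnas_per_class),
    n_decoys_per_kind = as.integer(n_decoys_per_kind),
    n_circrnas = as.integer(n_circrnas),
    read_length = as.integer(read_length),
    junction_reads_per_circ = as.integer(junction_reads_per_circ),
    n_linear_reads = as.integer(n_linear_reads),
    error_rate = error_rate,
    n_samples_per_group = as.integer(n_samples_per_group),
    n_features = as.integer(n_features),
    frac_de = frac_de,
    planted_lfc = planted_lfc,
    nb_dispersion = nb_dispersion,
    n_proteins = as.integer(n_proteins),
    prot_frac_de = prot_frac_de,
    n_concordant = as.integer(n_concordant)
  )
  if (cfg$genome_length < 10000L) stop("genome_length must be >= 10,000 bp")
  if (cfg$read_length < 40L) stop("read_length must be >= 40 (twice the 20 bp anchor)")
  if (cfg$frac_de < 0 || cfg$frac_de > 1) stop("frac_de must lie in [0, 1]")
  if (cfg$prot_frac_de < 0 || cfg$prot_frac_de > 1) stop("prot_frac_de must lie in [0, 1]")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be non-negative")
  if (cfg$error_rate < 0 || cfg$error_rate > 1) stop("error_rate must lie in [0, 1]")
  counts <- c(cfg$n_coding_genes, cfg$n_lncrnas_per_class, cfg$n_decoys_per_kind,
              cfg$n_circrnas, cfg$junction_reads_per_circ, cfg$n_linear_reads,
              cfg$n_samples_per_group, cfg$n_features, cfg$n_proteins,
              cfg$n_concordant)
  if (any(counts < 0L)) stop("all count parameters must be >= 0")
  if (cfg$n_circrnas > cfg$n_coding_genes) {
    stop("n_circrnas must not exceed n_coding_genes (one circRNA per gene)")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a random genome
#'
#' Uniform base composition, uppercase A/C/G/T, one chromosome named
#' \code{chr1}. Deterministic for a fixed seed.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return an object of class \code{genome_ref}: a list with element
#'   \code{seq}, a named character vector of chromosome sequences.
#' @export
gen_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$genome_length <= 0L) stop("genome length must be positive")
  set.seed(derive_seed(cfg$seed, 1L))
  bases <- sample(c("A", "C", "G", "T"), cfg$genome_length, replace = TRUE)
  genome_ref(stats::setNames(paste(bases, collapse = ""), "chr1"))
}

#' Construct a genome reference object
#'
#' @param seqs named character vector of uppercase chromosome sequences.
#' @return object of class \code{genome_ref}.
#' @export
genome_ref <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  structure(list(seq = seqs), class = "genome_ref")
}

#' Slice a genome (1-based, inclusive)
#' @param genome a \code{genome_ref}.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @keywords internal
genome_slice <- function(genome, chrom, start, end) {
  substr(genome$seq[[chrom]], start, end)
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("genome_ref:", length(x$seq), "chromosome(s),",
      sum(nchar(x$seq)), "bp total\n")
  invisible(x)
}

# Replace bases of one chromosome in place (1-based start).
genome_edit <- function(genome, chrom, start, replacement) {
  s <- genome$seq[[chrom]]
  substr(s, start, start + nchar(replacement) - 1L) <- replacement
  genome$seq[[chrom]] <- s
  genome
}

# One exon-table row block for a transcript.
exon_rows <- function(transcript_id, gene_id, chrom, strand, starts, ends,
                      biotype, cov) {
  data.frame(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, start = as.integer(starts), end = as.integer(ends),
    biotype = biotype, cov = cov, stringsAsFactors = FALSE
  )
}

#' Plant gene models, lncRNAs and circRNAs on a genome
#'
#' Lays out non-overlapping multi-exon coding genes on alternating strands,
#' then plants one set of lncRNAs per class code — antisense (x): exonic
#' overlap with a coding exon on the opposite strand; intergenic (u): in a
#' gene desert more than 2 kb from any coding gene; intronic (i): strictly
#' inside a single intron — plus, optionally, disqualified decoy transcripts
#' (short, mono-exonic, low-coverage, same-strand exonic overlap). Finally it
#' plants circRNAs spanning two consecutive exons of distinct coding genes
#' and rewrites the four flanking genomic bases so that every back-splice
#' junction carries the canonical splice signal (AG upstream of the circle
#' start and GT downstream of its end on the plus strand; the reverse
#' complement arrangement for minus-strand genes). Junction anchor 20-mers
#' are checked for genome-wide uniqueness and the circle is moved to the next
#' exon pair on collision.
#'
#' @param genome a \code{genome_ref} from \code{\link{gen_genome}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return list with elements \code{genome} (the edited genome that all
#'   downstream steps must use), \code{transcripts} (exon-level data.frame:
#'   transcript_id, gene_id, chrom, strand, start, end, biotype, cov) and
#'   \code{truth} (list with \code{circ_junctions}, \code{lnc_labels},
#'   \code{decoys}).
#' @export
gen_annotation <- function(genome, cfg) {
  stopifnot(inherits(genome, "genome_ref"), inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 2L))
  chrom <- names(genome$seq)[1]
  glen <- nchar(genome$seq[[chrom]])

  exons <- list()
  genes <- list()   # per-gene exon starts/ends for later use
  cursor <- 1000L

  ## ---- coding genes ----
  for (g in seq_len(cfg$n_coding_genes)) {
    n_ex <- sample(3:5, 1L)
    ex_len <- sample(80:200, n_ex, replace = TRUE)
    in_len <- sample(300:600, max(n_ex - 1L, 0L), replace = TRUE)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- cursor
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + ex_len[e] - 1L
      pos <- ends[e] + if (e < n_ex) in_len[e] + 1L else 1L
    }
    gene_end <- ends[n_ex]
    if (gene_end > glen - 3000L) {
      stop("genome too small to place the requested coding genes")
    }
    strand <- if (g %% 2L == 1L) "+" else "-"
    gid <- sprintf("GENE%02d", g)
    exons[[length(exons) + 1L]] <- exon_rows(
      paste0(gid, ".t1"), gid, chrom, strand, starts, ends,
      "protein_coding", round(stats::runif(1, 10, 100), 2)
    )
    genes[[g]] <- list(id = gid, strand = strand, starts = starts, ends = ends)
    cursor <- gene_end + sample(400:800, 1L) + 1L
  }
  last_gene_end <- max(vapply(genes, function(x) max(x$ends), integer(1)))

  truth_lnc <- list()
  mstrg <- 0L
  new_mstrg <- function() {
    mstrg <<- mstrg + 1L
    sprintf("MSTRG.%d.1", mstrg)
  }

  ## ---- antisense (x): exon inside a coding exon, opposite strand ----
  for (k in seq_len(cfg$n_lncrnas_per_class)) {
    gn <- genes[[((k - 1L) %% cfg$n_coding_genes) + 1L]]
    exA_start <- gn$starts[2] + 10L
    exA_end <- min(gn$ends[2] - 10L, exA_start + 139L)
    lenA <- exA_end - exA_start + 1L
    exB_start <- gn$ends[2] + 21L            # inside the following intron
    lenB <- max(120L, 205L - lenA)
    exB_end <- exB_start + lenB - 1L
    tid <- new_mstrg()
    exons[[length(exons) + 1L]] <- exon_rows(
      tid, sub("\\.1$", "", tid), chrom, if (gn$strand == "+") "-" else "+",
      c(exA_start, exB_start), c(exA_end, exB_end),
      "novel", round(stats::runif(1, 4, 40), 2)
    )
    truth_lnc[[length(truth_lnc) + 1L]] <- c(tid, "x")
  }

  ## ---- intronic (i): strictly inside intron 1, same strand as host ----
  for (k in seq_len(cfg$n_lncrnas_per_class)) {
    gn <- genes[[((k - 1L) %% cfg$n_coding_genes) + 1L]]
    i_start <- gn$ends[1] + 1L
    tid <- new_mstrg()
    s1 <- i_start + 15L
    exons[[length(exons) + 1L]] <- exon_rows(
      tid, sub("\\.1$", "", tid), chrom, gn$strand,
      c(s1, s1 + 140L), c(s1 + 109L, s1 + 249L),
      "novel", round(stats::runif(1, 4, 40), 2)
    )
    truth_lnc[[length(truth_lnc) + 1L]] <- c(tid, "i")
  }

  ## ---- intergenic (u): gene desert, > 2 kb away from any coding gene ----
  desert <- last_gene_end + 2001L
  for (k in seq_len(cfg$n_lncrnas_per_class)) {
    tid <- new_mstrg()
    s1 <- desert
    exons[[length(exons) + 1L]] <- exon_rows(
      tid, sub("\\.1$", "", tid), chrom, sample(c("+", "-"), 1L),
      c(s1, s1 + 200L), c(s1 + 149L, s1 + 339L),
      "novel", round(stats::runif(1, 4, 40), 2)
    )
    truth_lnc[[length(truth_lnc) + 1L]] <- c(tid, "u")
    desert <- desert + 340L + 400L
  }

  ## ---- disqualified decoys ----
  decoys <- list()
  add_decoy <- function(tid, kind, code, rows) {
    exons[[length(exons) + 1L]] <<- rows
    decoys[[length(decoys) + 1L]] <<- c(tid, kind, code)
  }
  for (k in seq_len(cfg$n_decoys_per_kind)) {
    # short: two exons, spliced length exactly 200 (filter requires > 200)
    tid <- new_mstrg()
    add_decoy(tid, "short", "u", exon_rows(
      tid, sub("\\.1$", "", tid), chrom, "+",
      c(desert, desert + 140L), c(desert + 99L, desert + 239L),
      "novel", round(stats::runif(1, 4, 40), 2)))
    desert <- desert + 240L + 300L

    # mono-exonic: long enough but a single exon
    tid <- new_mstrg()
    add_decoy(tid, "monoexonic", "u", exon_rows(
      tid, sub("\\.1$", "", tid), chrom, "-",
      desert, desert + 399L, "novel", round(stats::runif(1, 4, 40), 2)))
    desert <- desert + 400L + 300L

    # low coverage: valid intergenic structure, coverage at/below 3
    tid <- new_mstrg()
    add_decoy(tid, "lowcov", "u", exon_rows(
      tid, sub("\\.1$", "", tid), chrom, "+",
      c(desert, desert + 180L), c(desert + 129L, desert + 309L),
      "novel", round(stats::runif(1, 0.2, 3), 2)))
    desert <- desert + 310L + 300L

    # same-strand exonic overlap with a coding gene -> class "other"
    gn <- genes[[((k - 1L) %% cfg$n_coding_genes) + 1L]]
    exA_start <- gn$starts[3] + 5L
    exA_end <- min(gn$ends[3] - 5L, exA_start + 129L)
    exB_start <- gn$ends[3] + 31L
    tid <- new_mstrg()
    add_decoy(tid, "samestrand", "other", exon_rows(
      tid, sub("\\.1$", "", tid), chrom, gn$strand,
      c(exA_start, exB_start), c(exA_end, exB_start + 149L),
      "novel", round(stats::runif(1, 4, 40), 2)))
  }
  if (desert > glen) stop("genome too small to place the requested transcripts")

  ## ---- circRNAs: span two consecutive exons of distinct coding genes ----
  h1 <- as.integer(ceiling(cfg$read_length / 2))
  h2 <- cfg$read_length - h1
  circ <- list()
  for (cidx in seq_len(cfg$n_circrnas)) {
    gn <- genes[[cidx]]
    placed <- FALSE
    for (first_ex in 2:(length(gn$starts) - 1L)) {
      a <- gn$starts[first_ex]
      d <- gn$ends[first_ex + 1L]
      # splice-signal flanks in forward-genome letters
      flank <- if (gn$strand == "+") c("AG", "GT") else c("AC", "CT")
      cand <- genome_edit(genome, chrom, a - 2L, flank[1])
      cand <- genome_edit(cand, chrom, d + 1L, flank[2])
      # junction-read anchor 20-mers must be unique genome-wide
      anchors <- if (gn$strand == "+") {
        c(genome_slice(cand, chrom, d - h1 + 1L, d - h1 + 20L),
          genome_slice(cand, chrom, a + h2 - 20L, a + h2 - 1L))
      } else {
        c(genome_slice(cand, chrom, a + h1 - 20L, a + h1 - 1L),
          genome_slice(cand, chrom, d - h2 + 1L, d - h2 + 20L))
      }
      n_occ <- vapply(anchors, function(s) {
        count_occurrences(cand$seq[[chrom]], s) +
          count_occurrences(cand$seq[[chrom]], revcomp(s))
      }, integer(1))
      if (all(n_occ == 1)) {
        genome <- cand
        circ[[length(circ) + 1L]] <- data.frame(
          circ_id = sprintf("circ%03d", cidx), chrom = chrom,
          acceptor = a, donor = d, strand = gn$strand, gene_id = gn$id,
          stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place a circRNA with unique junction anchors")
  }

  transcripts <- do.call(rbind, exons)
  rownames(transcripts) <- NULL
  truth <- list(
    circ_junctions = if (length(circ)) do.call(rbind, circ) else
      data.frame(circ_id = character(), chrom = character(),
                 acceptor = integer(), donor = integer(),
                 strand = character(), gene_id = character()),
    lnc_labels = if (length(truth_lnc)) {
      m <- do.call(rbind, truth_lnc)
      data.frame(transcript_id = m[, 1], label = m[, 2], stringsAsFactors = FALSE)
    } else data.frame(transcript_id = character(), label = character()),
    decoys = if (length(decoys)) {
      m <- do.call(rbind, decoys)
      data.frame(transcript_id = m[, 1], kind = m[, 2],
                 expected_code = m[, 3], stringsAsFactors = FALSE)
    } else data.frame(transcript_id = character(), kind = character(),
                      expected_code = character())
  )
  list(genome = genome, transcripts = transcripts, truth = truth)
}

#' Spliced transcript sequence
#'
#' Concatenates exon slices in genomic order and reverse-complements for
#' minus-strand transcripts.
#'
#' @param genome a \code{genome_ref}.
#' @param exons data.frame with chrom/start/end for one transcript.
#' @param strand "+" or "-".
#' @return character scalar.
#' @export
spliced_seq <- function(genome, exons, strand) {
  exons <- exons[order(exons$start), , drop = FALSE]
  s <- paste(mapply(genome_slice, start = exons$start, end = exons$end,
                    MoreArgs = list(genome = genome, chrom = exons$chrom[1])),
             collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Simulate sequencing reads
#'
#' Linear reads are sampled uniformly over positions of spliced transcript
#' sequences (coding transcripts and planted lncRNAs). For every planted
#' circRNA, exactly \code{junction_reads_per_circ} back-splice-spanning reads
#' are emitted: the first half of each read is the 3' end of the circle's
#' last exon and the second half is the 5' start of its first exon, in
#' transcript orientation. Read ids encode provenance
#' (\code{lin|transcript|start} or \code{circ|circ_id|k}).
#'
#' @param genome the (edited) \code{genome_ref} from
#'   \code{\link{gen_annotation}}.
#' @param ann exon-level transcript data.frame from
#'   \code{\link{gen_annotation}}.
#' @param truth truth list from \code{\link{gen_annotation}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return data.frame with columns \code{id}, \code{seq}.
#' @export
simulate_reads <- function(genome, ann, truth, cfg) {
  set.seed(derive_seed(cfg$seed, 3L))
  L <- cfg$read_length
  h1 <- as.integer(ceiling(L / 2))
  h2 <- L - h1

  keep_ids <- c(
    unique(ann$transcript_id[ann$biotype == "protein_coding"]),
    truth$lnc_labels$transcript_id
  )
  tx_seqs <- vapply(keep_ids, function(tid) {
    ex <- ann[ann$transcript_id == tid, , drop = FALSE]
    spliced_seq(genome, ex, ex$strand[1])
  }, character(1))
  tx_seqs <- tx_seqs[nchar(tx_seqs) >= L]
  if (length(tx_seqs) == 0L && cfg$n_linear_reads > 0L) {
    stop("no transcript long enough for the requested read length")
  }

  ids <- character(0); seqs <- character(0)
  if (cfg$n_linear_reads > 0L) {
    n_pos <- nchar(tx_seqs) - L + 1L
    pick <- sample(seq_along(tx_seqs), cfg$n_linear_reads,
                   replace = TRUE, prob = n_pos)
    start <- vapply(n_pos[pick], function(np) sample.int(np, 1L), integer(1))
    seqs <- substr(rep(tx_seqs[pick], 1L), start, start + L - 1L)
    ids <- sprintf("lin|%s|%d", names(tx_seqs)[pick], start)
  }

  cj <- truth$circ_junctions
  for (i in seq_len(nrow(cj))) {
    a <- cj$acceptor[i]; d <- cj$donor[i]; chrom <- cj$chrom[i]
    if (d - a + 1L < L) stop("planted circle shorter than the read length")
    jseq <- if (cj$strand[i] == "+") {
      paste0(genome_slice(genome, chrom, d - h1 + 1L, d),
             genome_slice(genome, chrom, a, a + h2 - 1L))
    } else {
      paste0(revcomp(genome_slice(genome, chrom, a, a + h1 - 1L)),
             revcomp(genome_slice(genome, chrom, d - h2 + 1L, d)))
    }
    k <- cfg$junction_reads_per_circ
    ids <- c(ids, sprintf("circ|%s|%d", cj$circ_id[i], seq_len(k)))
    seqs <- c(seqs, rep(jseq, k))
  }

  if (cfg$error_rate > 0 && length(seqs)) {
    seqs <- vapply(seqs, function(s) {
      b <- strsplit(s, "")[[1]]
      hit <- stats::runif(length(b)) < cfg$error_rate
      if (any(hit)) {
        b[hit] <- vapply(b[hit], function(x) {
          sample(setdiff(c("A", "C", "G", "T"), x), 1L)
        }, character(1))
      }
      paste(b, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}

#' Simulate a two-group negative-binomial count matrix
#'
#' Feature-wise NB counts for \code{n_samples_per_group} stable and unstable
#' samples. A fraction \code{frac_de} of features receives a planted log2
#' fold change of magnitude \code{planted_lfc} (random sign) applied to the
#' unstable group mean.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{counts} (an \code{\link{omics_matrix}}, layer
#'   "mrna") and \code{truth} (data.frame feature_id, lfc of planted
#'   features).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_features < 1L) stop("n_features must be >= 1")
  set.seed(derive_seed(cfg$seed, 4L))
  n <- cfg$n_features
  m <- cfg$n_samples_per_group
  feat <- sprintf("F%05d", seq_len(n))
  base_mu <- stats::rlnorm(n, meanlog = log(100), sdlog = 1)
  n_de <- round(cfg$frac_de * n)
  de_idx <- if (n_de > 0L) sort(sample.int(n, n_de)) else integer(0)
  lfc <- numeric(n)
  if (n_de > 0L) lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * cfg$planted_lfc

  mu <- cbind(matrix(base_mu, n, m),
              matrix(base_mu * 2^lfc, n, m))
  counts <- matrix(
    if (cfg$nb_dispersion > 0) {
      stats::rnbinom(n * 2L * m, mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      stats::rpois(n * 2L * m, lambda = mu)
    },
    nrow = n, ncol = 2L * m,
    dimnames = list(feat, c(sprintf("stable_%d", seq_len(m)),
                            sprintf("unstable_%d", seq_len(m))))
  )
  groups <- rep(c("stable", "unstable"), each = m)
  list(
    counts = omics_matrix(counts, groups, layer = "mrna"),
    truth = data.frame(feature_id = feat[de_idx], lfc = lfc[de_idx],
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a label-free proteomics intensity table
#'
#' Log-normal LFQ-like intensities for a protein subset of the count-layer
#' features. \code{n_concordant} proteins are planted as differential with
#' the same sign as their mRNA fold change; the remaining planted protein
#' changes fall on features that are not differential at the mRNA level.
#'
#' @param counts_sim result of \code{\link{simulate_counts}} (the mRNA layer
#'   and its planted truth).
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{lfq} (an \code{\link{omics_matrix}}, layer
#'   "protein"), \code{truth} (data.frame feature_id, lfc) and
#'   \code{concordant} (character vector of feature ids planted in both
#'   layers).
#' @export
simulate_proteins <- function(counts_sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 5L))
  mrna_de <- counts_sim$truth
  if (cfg$n_concordant > nrow(mrna_de)) {
    stop("n_concordant exceeds the number of planted mRNA DE features")
  }
  all_feat <- rownames(counts_sim$counts$values)
  non_de <- setdiff(all_feat, mrna_de$feature_id)

  conc <- if (cfg$n_concordant > 0L) {
    sort(sample(mrna_de$feature_id, cfg$n_concordant))
  } else character(0)
  n_prot_de <- max(round(cfg$prot_frac_de * cfg$n_proteins), length(conc))
  extra_de <- sort(sample(non_de, n_prot_de - length(conc)))
  rest <- sort(sample(setdiff(non_de, extra_de),
                      cfg$n_proteins - n_prot_de))
  prot_feat <- c(conc, extra_de, rest)

  lfc <- numeric(length(prot_feat))
  names(lfc) <- prot_feat
  lfc[conc] <- sign(mrna_de$lfc[match(conc, mrna_de$feature_id)]) * cfg$planted_lfc
  lfc[extra_de] <- sample(c(-1, 1), length(extra_de), replace = TRUE) * cfg$planted_lfc

  m <- cfg$n_samples_per_group
  base <- stats::rnorm(length(prot_feat), mean = 25, sd = 1.5)
  log2_int <- cbind(matrix(base, length(prot_feat), m),
                    matrix(base + lfc, length(prot_feat), m)) +
    matrix(stats::rnorm(length(prot_feat) * 2L * m, sd = 0.25),
           length(prot_feat), 2L * m)
  vals <- 2^log2_int
  dimnames(vals) <- list(prot_feat, c(sprintf("stable_%d", seq_len(m)),
                                      sprintf("unstable_%d", seq_len(m))))
  groups <- rep(c("stable", "unstable"), each = m)
  planted <- lfc[lfc != 0]
  list(
    lfq = omics_matrix(vals, groups, layer = "protein"),
    truth = data.frame(feature_id = names(planted), lfc = unname(planted),
                       stringsAsFactors = FALSE),
    concordant = conc
  )
}
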