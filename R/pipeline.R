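#' Run the full synthetic multi-omics pipeline
#'
#' Executes the eight stages in dependency order — simulate, index, circ,
#' lncrna, de, links, integrate, cerna — on data generated from one
#' configuration, writing every intermediate to \code{outdir} together with
#' a machine-readable run manifest (package version, seed, per-stage record
#' counts, md5 of the written files).
#'
#' Stage content:
#' \enumerate{
#'   \item simulate: genome FASTA, annotation GTF, reads FASTQ, count and
#'     LFQ TSV matrices, truth JSON;
#'   \item index: k-mer index of the genome (in memory; entry count logged);
#'   \item circ: back-splice detection on the reads, BED6 + TSV output;
#'   \item lncrna: class codes and filter verdicts for novel transcripts;
#'   \item de: NB Wald tests on counts, Welch tests on LFQ intensities;
#'   \item links: cis-target and origin-gene tables;
#'   \item integrate: transcriptome-proteome consistency report and
#'     hypergeometric enrichment over a generated gene-set collection;
#'   \item cerna: seed-match ceRNA network and MCODE clusters of a
#'     synthetic PPI graph over the differential proteins.
#' }
#'
#' @param cfg a \code{\link{sim_config}} (or a list of its arguments).
#' @param outdir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_pipeline <- function(cfg = sim_config(), outdir = tempfile("plaqomics_"),
                         quiet = FALSE) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, as.list(cfg))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  counts_of <- list()

  ## 1 simulate -------------------------------------------------------------
  genome0 <- gen_genome(cfg)
  ann <- gen_annotation(genome0, cfg)
  genome <- ann$genome
  reads <- simulate_reads(genome, ann$transcripts, ann$truth, cfg)
  sim_counts <- simulate_counts(cfg)
  sim_prot <- simulate_proteins(sim_counts, cfg)
  write_fasta(genome, file.path(outdir, "genome.fa"))
  write_gtf(ann$transcripts, file.path(outdir, "annotation.gtf"))
  write_fastq(reads, file.path(outdir, "reads.fq"))
  write_matrix_tsv(sim_counts$counts, file.path(outdir, "counts.tsv"))
  write_matrix_tsv(sim_prot$lfq, file.path(outdir, "lfq.tsv"))
  jsonlite::write_json(
    list(circ_junctions = ann$truth$circ_junctions,
         lnc_labels = ann$truth$lnc_labels,
         decoys = ann$truth$decoys,
         de_features = sim_counts$truth,
         protein_de = sim_prot$truth,
         protein_concordant = sim_prot$concordant),
    file.path(outdir, "truth.json"), dataframe = "rows"
  )
  counts_of$simulate <- nrow(reads)
  say("simulate", "%d reads, %d transcripts, %d planted circRNAs",
      nrow(reads), length(unique(ann$transcripts$transcript_id)),
      nrow(ann$truth$circ_junctions))

  ## 2 index ----------------------------------------------------------------
  index <- build_index(genome, k = 20L)
  counts_of$index <- index$n_entries
  say("index", "%d k-mer entries", index$n_entries)

  ## 3 circ -----------------------------------------------------------------
  circ <- detect_circrnas(index, reads)
  write_junctions_bed(circ$junctions, file.path(outdir, "circ.bed"))
  utils::write.table(circ$junctions, file.path(outdir, "circ.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts_of$circ <- nrow(circ$junctions)
  say("circ", "%d junctions from %d reads (%d linearly mapped)",
      nrow(circ$junctions), nrow(reads), circ$n_mapped)

  ## 4 lncrna ---------------------------------------------------------------
  reference <- ann$transcripts[ann$transcripts$biotype == "protein_coding", ]
  novel <- ann$transcripts[ann$transcripts$biotype != "protein_coding", ]
  codes <- assign_class_code(novel, reference)
  verdicts <- filter_lncrna(novel, codes)
  utils::write.table(verdicts, file.path(outdir, "lnc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts_of$lncrna <- sum(verdicts$kept)
  say("lncrna", "%d/%d transcripts kept as expressed lncRNAs",
      sum(verdicts$kept), nrow(verdicts))

  ## 5 de -------------------------------------------------------------------
  de_mrna <- nb_test(sim_counts$counts)
  de_prot <- protein_test(sim_prot$lfq)
  utils::write.table(de_mrna, file.path(outdir, "de_mrna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(de_prot, file.path(outdir, "de_protein.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts_of$de <- sum(de_mrna$is_de) + sum(de_prot$is_de)
  say("de", "%d DE features (mRNA), %d DEPs (protein)",
      sum(de_mrna$is_de), sum(de_prot$is_de))

  ## 6 links ----------------------------------------------------------------
  kept_lnc <- novel[novel$transcript_id %in%
                      verdicts$transcript_id[verdicts$kept], ]
  links <- rbind(cis_targets(kept_lnc, reference),
                 origin_genes(circ$junctions, reference))
  utils::write.table(links, file.path(outdir, "links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts_of$links <- nrow(links)
  say("links", "%d links (%d cis-target, %d origin)", nrow(links),
      sum(links$link_type == "cis_target"), sum(links$link_type == "origin"))

  ## 7 integrate ------------------------------------------------------------
  report <- overlap_sets(de_mrna, de_prot, links)
  # gene-set collection generated from the count universe: one set enriched
  # in differential features plus random background sets
  set.seed(derive_seed(cfg$seed, 7L))
  universe <- de_mrna$feature_id
  de_genes <- de_mrna$feature_id[de_mrna$is_de]
  collection <- list()
  if (length(de_genes) >= 5L) {
    collection$planted_de_set <- c(
      sample(de_genes, min(20L, length(de_genes))),
      sample(setdiff(universe, de_genes), 10L)
    )
  }
  for (i in 1:5) {
    collection[[sprintf("random_set_%d", i)]] <- sample(universe, 30L)
  }
  enrich <- hypergeom_enrich(de_genes, collection, universe)
  utils::write.table(enrich, file.path(outdir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(outdir, "consistency.json"),
                       dataframe = "rows")
  counts_of$integrate <- nrow(report$mrna_dep) + nrow(report$lnc_target_dep) +
    nrow(report$circ_origin_dep)
  say("integrate", "overlaps: %d mRNA/DEP, %d lnc-target/DEP, %d circ-origin/DEP",
      nrow(report$mrna_dep), nrow(report$lnc_target_dep),
      nrow(report$circ_origin_dep))

  ## 8 cerna ----------------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 8L))
  lnc_seqs <- vapply(unique(kept_lnc$transcript_id), function(tid) {
    ex <- kept_lnc[kept_lnc$transcript_id == tid, ]
    spliced_seq(genome, ex, ex$strand[1])
  }, character(1))
  coding_ids <- unique(reference$transcript_id)
  utr_seqs <- vapply(coding_ids, function(tid) {
    ex <- reference[reference$transcript_id == tid, ]
    s <- spliced_seq(genome, ex, ex$strand[1])
    substr(s, max(1L, nchar(s) - 199L), nchar(s))
  }, character(1))
  names(utr_seqs) <- sub("\\.t1$", "", coding_ids)
  # miRNAs synthesised as reverse complements of 22-mers drawn from target
  # sequences, so the network carries planted binding sites
  draw_mir <- function(seqs, n) {
    vapply(seq_len(n), function(i) {
      s <- seqs[[sample(length(seqs), 1L)]]
      st <- sample(nchar(s) - 21L, 1L)
      revcomp(substr(s, st, st + 21L))
    }, character(1))
  }
  n_mir <- 6L
  mirs <- c(draw_mir(utr_seqs, n_mir / 2L),
            if (length(lnc_seqs)) draw_mir(lnc_seqs, n_mir / 2L) else
              draw_mir(utr_seqs, n_mir / 2L))
  names(mirs) <- sprintf("mir-%02d", seq_along(mirs))
  cerna <- build_cerna(lnc_seqs, mirs, utr_seqs)
  utils::write.table(cerna$edges, file.path(outdir, "cerna_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # synthetic PPI over differential proteins: one planted dense module plus
  # sparse background
  dep_genes <- de_prot$feature_id[de_prot$is_de]
  ppi <- synth_ppi(dep_genes, seed = derive_seed(cfg$seed, 9L))
  clusters <- mcode_cluster(ppi)
  cl_df <- if (length(clusters)) {
    data.frame(
      cluster_id = seq_along(clusters),
      score = vapply(clusters, `[[`, numeric(1), "score"),
      n = vapply(clusters, function(cl) length(cl$members), integer(1)),
      members = vapply(clusters, function(cl)
        paste(cl$members, collapse = ","), character(1))
    )
  } else {
    data.frame(cluster_id = integer(), score = numeric(), n = integer(),
               members = character())
  }
  utils::write.table(cl_df, file.path(outdir, "ppi_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts_of$cerna <- nrow(cerna$edges)
  say("cerna", "%d ceRNA edges, %d PPI clusters", nrow(cerna$edges),
      length(clusters))

  ## manifest ---------------------------------------------------------------
  files <- list.files(outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "plaqomics",
    version = as.character(utils::packageVersion("plaqomics")),
    seed = cfg$seed,
    stages = names(counts_of),
    stage_counts = counts_of,
    file_md5 = as.list(stats::setNames(unname(tools::md5sum(files)),
                                       basename(files)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    cfg = cfg, outdir = outdir, genome = genome, annotation = ann,
    reads = reads, counts = sim_counts, proteins = sim_prot, circ = circ,
    lnc = verdicts, de_mrna = de_mrna, de_protein = de_prot, links = links,
    report = report, enrichment = enrich, cerna = cerna,
    ppi_clusters = clusters, manifest = manifest
  ))
}

#' Synthetic PPI edge list with one planted dense module
#'
#' Builds a deterministic protein-protein interaction edge list over the
#' given genes: the first (up to) eight genes form a clique and the rest
#' receive sparse random edges. Used by the pipeline's cerna stage as a
#' stand-in for an externally supplied PPI network.
#'
#' @param genes character vector of node names.
#' @param seed integer seed.
#' @param p_background probability of a background edge.
#' @return two-column data.frame of undirected edges.
#' @export
synth_ppi <- function(genes, seed = 1L, p_background = 0.03) {
  genes <- unique(genes)
  empty <- data.frame(a = character(), b = character())
  if (length(genes) < 2L) return(empty)
  set.seed(seed)
  core <- genes[seq_len(min(8L, length(genes)))]
  edges <- if (length(core) >= 2L) t(utils::combn(core, 2L)) else
    matrix(character(0), 0, 2)
  rest_pairs <- if (length(genes) > length(core)) {
    all_pairs <- t(utils::combn(genes, 2L))
    in_core <- all_pairs[, 1] %in% core & all_pairs[, 2] %in% core
    cand <- all_pairs[!in_core, , drop = FALSE]
    cand[stats::runif(nrow(cand)) < p_background, , drop = FALSE]
  } else matrix(character(0), 0, 2)
  out <- rbind(as.data.frame(edges, stringsAsFactors = FALSE),
               as.data.frame(rest_pairs, stringsAsFactors = FALSE))
  names(out) <- c("a", "b")
  out
}
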