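test_that("genome generation honours length, alphabet and determinism", {
  cfg <- sim_config(seed = 1, genome_length = 10000)
  g1 <- gen_genome(cfg)
  expect_equal(nchar(g1$seq[["chr1"]]), 10000L)
  expect_false(grepl("[^ACGT]", g1$seq[["chr1"]]))
  g2 <- gen_genome(cfg)
  expect_identical(g1$seq, g2$seq)
  g3 <- gen_genome(sim_config(seed = 2, genome_length = 10000))
  expect_false(identical(g1$seq, g3$seq))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(genome_length = 5000), "genome_length")
  expect_error(sim_config(read_length = 39), "read_length")
  expect_error(sim_config(frac_de = 1.2), "frac_de")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
  expect_error(sim_config(n_circrnas = 30, n_coding_genes = 10), "n_circrnas")
})

test_that("annotation plants coding genes and lncRNA classes by construction", {
  cfg <- sim_config(seed = 3, n_coding_genes = 10, n_lncrnas_per_class = 4,
                    n_decoys_per_kind = 2, n_circrnas = 3)
  ann <- gen_annotation(gen_genome(cfg), cfg)
  tx <- tx_summary(ann$transcripts)
  coding <- tx[tx$biotype == "protein_coding", ]
  expect_equal(nrow(coding), 10L)
  expect_true(all(coding$n_exons >= 2))
  # coding genes do not overlap each other
  coding <- coding[order(coding$start), ]
  expect_true(all(coding$start[-1] > coding$end[-nrow(coding)]))

  labels <- ann$truth$lnc_labels
  expect_equal(unname(table(labels$label)[c("x", "u", "i")]),
               rep(4L, 3), ignore_attr = TRUE)
  # planted u lncRNAs keep clear of every coding gene span
  for (tid in labels$transcript_id[labels$label == "u"]) {
    lt <- tx[tx$transcript_id == tid, ]
    expect_true(all(lt$end < coding$start - 2000 | lt$start > coding$end + 2000))
  }
  # planted i lncRNAs sit strictly inside one intron of one coding gene
  for (tid in labels$transcript_id[labels$label == "i"]) {
    lt <- tx[tx$transcript_id == tid, ]
    ex <- ann$transcripts[ann$transcripts$biotype == "protein_coding", ]
    host <- ex[ex$gene_id == coding$gene_id[coding$start < lt$start &
                                              coding$end > lt$end][1], ]
    host <- host[order(host$start), ]
    introns <- cbind(host$end[-nrow(host)] + 1, host$start[-1] - 1)
    expect_true(any(lt$start > introns[, 1] & lt$end < introns[, 2]))
  }
  # planted lncRNAs satisfy the expressed-lncRNA filter by construction
  planted <- tx[tx$transcript_id %in% labels$transcript_id, ]
  expect_true(all(planted$length > 200))
  expect_true(all(planted$n_exons >= 2))
  expect_true(all(planted$cov > 3))
})

test_that("planted circle flanks carry the splice signal and unique anchors", {
  cfg <- sim_config(seed = 5, n_circrnas = 6)
  ann <- gen_annotation(gen_genome(cfg), cfg)
  g <- ann$genome
  cj <- ann$truth$circ_junctions
  expect_equal(nrow(cj), 6L)
  for (i in seq_len(nrow(cj))) {
    left <- genome_slice(g, cj$chrom[i], cj$acceptor[i] - 2, cj$acceptor[i] - 1)
    right <- genome_slice(g, cj$chrom[i], cj$donor[i] + 1, cj$donor[i] + 2)
    if (cj$strand[i] == "+") {
      expect_equal(c(left, right), c("AG", "GT"))
    } else {
      expect_equal(c(left, right), c("AC", "CT"))
    }
  }
})

test_that("junction reads are emitted per circle and span the back-splice", {
  cfg <- sim_config(seed = 8, n_circrnas = 5, junction_reads_per_circ = 2,
                    n_linear_reads = 50)
  ann <- gen_annotation(gen_genome(cfg), cfg)
  reads <- simulate_reads(ann$genome, ann$transcripts, ann$truth, cfg)
  jr <- reads[startsWith(reads$id, "circ|"), ]
  expect_equal(nrow(jr), 10L)
  # no junction read has a contiguous match in the genome (either strand)
  for (sq in unique(jr$seq)) {
    pl <- brute_force_placements(ann$genome, sq)
    expect_equal(length(pl$fwd) + length(pl$rev), 0L)
  }
  # with no circles every read comes from a contiguous transcript sequence
  cfg0 <- sim_config(seed = 8, n_circrnas = 0, n_linear_reads = 30)
  ann0 <- gen_annotation(gen_genome(cfg0), cfg0)
  reads0 <- simulate_reads(ann0$genome, ann0$transcripts, ann0$truth, cfg0)
  expect_true(all(startsWith(reads0$id, "lin|")))
})

test_that("read simulation is deterministic per seed", {
  cfg <- sim_config(seed = 9, n_linear_reads = 100)
  ann <- gen_annotation(gen_genome(cfg), cfg)
  r1 <- simulate_reads(ann$genome, ann$transcripts, ann$truth, cfg)
  r2 <- simulate_reads(ann$genome, ann$transcripts, ann$truth, cfg)
  expect_identical(r1, r2)
})

test_that("count simulation plants fold changes with the stated NB structure", {
  # no planted effects -> empty truth, and group mean ratio ~ 1 at 5,000
  # features (law of large numbers, +/- 5%)
  cfg0 <- sim_config(seed = 11, n_features = 5000, frac_de = 0)
  sim0 <- simulate_counts(cfg0)
  expect_equal(nrow(sim0$truth), 0L)
  gs <- sim0$counts$groups
  ratio <- mean(sim0$counts$values[, gs == "unstable"]) /
    mean(sim0$counts$values[, gs == "stable"])
  expect_lt(abs(ratio - 1), 0.05)

  cfg <- sim_config(seed = 11, n_features = 1000, frac_de = 0.1)
  sim1 <- simulate_counts(cfg)
  sim2 <- simulate_counts(cfg)
  expect_identical(sim1$counts$values, sim2$counts$values)
  expect_equal(nrow(sim1$truth), 100L)
  expect_true(all(abs(sim1$truth$lfc) == 2))
})

test_that("protein simulation plants a concordant subset and stays positive", {
  cfg <- sim_config(seed = 13, n_features = 500, frac_de = 0.1,
                    n_proteins = 100, n_concordant = 2)
  cs <- simulate_counts(cfg)
  ps <- simulate_proteins(cs, cfg)
  expect_length(ps$concordant, 2L)
  expect_true(all(ps$concordant %in% cs$truth$feature_id))
  # remaining protein-DE features avoid the mRNA-DE set
  others <- setdiff(ps$truth$feature_id, ps$concordant)
  expect_length(intersect(others, cs$truth$feature_id), 0L)
  expect_true(all(ps$lfq$values > 0))
  # concordant features share the mRNA sign
  for (f in ps$concordant) {
    expect_equal(sign(ps$truth$lfc[ps$truth$feature_id == f]),
                 sign(cs$truth$lfc[cs$truth$feature_id == f]))
  }
  # zero concordance gives disjoint planted sets
  cfg0 <- sim_config(seed = 13, n_features = 500, frac_de = 0.1,
                     n_proteins = 100, n_concordant = 0)
  ps0 <- simulate_proteins(cs, cfg0)
  expect_length(intersect(ps0$truth$feature_id, cs$truth$feature_id), 0L)
  cfg_tiny <- sim_config(seed = 1, n_features = 500, frac_de = 0.002,
                         n_concordant = 5)
  cs_tiny <- simulate_counts(cfg_tiny)   # only one planted DE feature
  expect_error(simulate_proteins(cs_tiny, cfg_tiny), "n_concordant")
})
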