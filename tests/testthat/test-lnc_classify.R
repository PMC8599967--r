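# independent all-pairs interval oracle for the class-code rules
oracle_class_code <- function(novel, reference) {
  nov_ids <- unique(novel$transcript_id)
  ref_tx <- split(reference, reference$transcript_id)
  gene_span <- do.call(rbind, lapply(split(reference, reference$gene_id),
    function(ex) data.frame(chrom = ex$chrom[1], start = min(ex$start),
                            end = max(ex$end))))
  vapply(nov_ids, function(tid) {
    ex <- novel[novel$transcript_id == tid, ]
    span <- c(min(ex$start), max(ex$end))
    ss <- FALSE; as <- FALSE
    for (i in seq_len(nrow(ex))) {
      for (j in seq_len(nrow(reference))) {
        if (ex$chrom[i] != reference$chrom[j]) next
        if (ex$start[i] <= reference$end[j] && ex$end[i] >= reference$start[j]) {
          if (ex$strand[i] == reference$strand[j]) ss <- TRUE else as <- TRUE
        }
      }
    }
    if (ss) return("other")
    if (as) return("x")
    for (rt in ref_tx) {
      rt <- rt[order(rt$start), ]
      if (nrow(rt) < 2 || rt$chrom[1] != ex$chrom[1]) next
      for (e in seq_len(nrow(rt) - 1)) {
        if (span[1] >= rt$end[e] + 1 && span[2] <= rt$start[e + 1] - 1) {
          return("i")
        }
      }
    }
    hit_span <- any(gene_span$chrom == ex$chrom[1] &
                      span[1] <= gene_span$end & span[2] >= gene_span$start)
    if (!hit_span) "u" else "other"
  }, character(1))
}

test_that("class codes recover every planted label and decoy verdict", {
  cfg <- sim_config(seed = 17, n_lncrnas_per_class = 6, n_decoys_per_kind = 3)
  ann <- gen_annotation(gen_genome(cfg), cfg)
  reference <- ann$transcripts[ann$transcripts$biotype == "protein_coding", ]
  novel <- ann$transcripts[ann$transcripts$biotype == "novel", ]
  codes <- assign_class_code(novel, reference)

  truth <- ann$truth$lnc_labels
  got <- codes$code[match(truth$transcript_id, codes$transcript_id)]
  expect_equal(got, truth$label)

  decoys <- ann$truth$decoys
  got_d <- codes$code[match(decoys$transcript_id, codes$transcript_id)]
  expect_equal(got_d, decoys$expected_code)

  verdicts <- filter_lncrna(novel, codes)
  expect_true(all(verdicts$kept[verdicts$transcript_id %in%
                                  truth$transcript_id]))
  expect_false(any(verdicts$kept[verdicts$transcript_id %in%
                                   decoys$transcript_id]))
})

test_that("overlap logic matches the brute-force all-pairs oracle", {
  cfg <- sim_config(seed = 19, n_coding_genes = 12, n_lncrnas_per_class = 5,
                    n_decoys_per_kind = 4)
  ann <- gen_annotation(gen_genome(cfg), cfg)
  reference <- ann$transcripts[ann$transcripts$biotype == "protein_coding", ]
  novel <- ann$transcripts[ann$transcripts$biotype == "novel", ]
  codes <- assign_class_code(novel, reference)
  oracle <- oracle_class_code(novel, reference)
  expect_equal(codes$code, unname(oracle[codes$transcript_id]))
})

test_that("filter thresholds are strict for length/coverage, inclusive for exons", {
  mk <- function(tid, len1, len2, cov, n_exons = 2) {
    starts <- if (n_exons == 2) c(1000, 2000) else 1000
    ends <- if (n_exons == 2) c(1000 + len1 - 1, 2000 + len2 - 1) else
      1000 + len1 - 1
    data.frame(transcript_id = tid, gene_id = tid, chrom = "chr1",
               strand = "+", start = starts, end = ends, biotype = "novel",
               cov = cov)
  }
  tx <- rbind(
    mk("t_len200", 100, 100, cov = 10),        # length exactly 200 -> out
    mk("t_len201", 100, 101, cov = 10),        # 201 -> in
    mk("t_cov3", 150, 150, cov = 3),           # coverage exactly 3 -> out
    mk("t_mono", 400, NA, cov = 10, n_exons = 1),
    mk("t_ok", 150, 151, cov = 3.01)
  )
  codes <- data.frame(transcript_id = unique(tx$transcript_id), code = "u")
  v <- filter_lncrna(tx, codes)
  kept <- v$transcript_id[v$kept]
  expect_setequal(kept, c("t_len201", "t_ok"))

  # monotonicity: relaxing thresholds never drops a kept transcript
  v2 <- filter_lncrna(tx, codes, min_length = 150, min_cov = 2)
  expect_true(all(kept %in% v2$transcript_id[v2$kept]))
})

test_that("transcripts on chromosomes absent from the reference become u", {
  ref <- data.frame(transcript_id = "r1", gene_id = "g1", chrom = "chr1",
                    strand = "+", start = c(100, 500), end = c(200, 600),
                    biotype = "protein_coding", cov = 10)
  nov <- data.frame(transcript_id = "n1", gene_id = "n1", chrom = "chr9",
                    strand = "+", start = c(100, 400), end = c(250, 550),
                    biotype = "novel", cov = 10)
  expect_warning(codes <- assign_class_code(nov, ref), "absent")
  expect_equal(codes$code, "u")
})
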