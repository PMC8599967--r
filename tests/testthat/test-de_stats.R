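test_that("size factors recover exact column scalings", {
  set.seed(51)
  base <- rpois(100, 50) + 1
  m <- cbind(s1 = base, s2 = 2L * base)
  sf <- size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  m_id <- cbind(a = base, b = base, c = base)
  expect_equal(unname(size_factors(m_id)), rep(1, 3))
  expect_equal(unname(size_factors(matrix(base, ncol = 1))), 1)

  m0 <- rbind(c(5, 0), c(0, 7))
  expect_warning(sf0 <- size_factors(m0), "library-size")
  expect_equal(exp(mean(log(sf0))), 1)
})

test_that("FPKM follows the formula", {
  counts <- matrix(c(10, 999990), ncol = 1,
                   dimnames = list(c("f1", "f2"), "s1"))
  out <- fpkm(counts, lengths = c(1000, 2000))
  expect_equal(out["f1", 1], 10)                   # 10*1e9/(1000*1e6)
  expect_equal(fpkm(counts, c(2000, 2000))["f1", 1], 5)  # doubling length halves
  z <- matrix(0, 2, 1)
  expect_equal(unname(fpkm(z, c(100, 100))), matrix(0, 2, 1))
})

test_that("FPKM and TPM agree up to a per-sample constant on equal lengths", {
  set.seed(53)
  counts <- matrix(rpois(50, 100), 10, 5)
  f <- fpkm(counts, lengths = 200)
  tpm_like <- sweep(counts, 2, colSums(counts), "/") * 1e6
  ratio <- f / tpm_like
  for (j in 1:5) expect_equal(diff(range(ratio[, j])), 0, tolerance = 1e-12)
})

test_that("nb_test flags planted effects and respects the strict criterion", {
  cfg <- sim_config(seed = 55, n_features = 800, frac_de = 0.1,
                    planted_lfc = 2, nb_dispersion = 0.1)
  sim <- simulate_counts(cfg)
  res <- nb_test(sim$counts)
  expect_true(all(res$pvalue >= 0 & res$pvalue <= 1))
  planted <- res$feature_id %in% sim$truth$feature_id
  expect_gt(mean(res$is_de[planted]), 0.8)
  expect_lt(mean(res$is_de[!planted]), 0.02)
  # the flag uses raw p with strict inequalities
  expect_equal(res$is_de,
               abs(res$log2FoldChange) > 1 & res$pvalue < 0.05)
  # BH q is monotone and >= p
  expect_true(all(res$qvalue >= res$pvalue - 1e-12))
  ord <- order(res$pvalue)
  expect_true(all(diff(cummax(res$qvalue[ord])) >= 0))
})

test_that("swapping group labels negates fold changes, keeps p", {
  cfg <- sim_config(seed = 57, n_features = 300, frac_de = 0.2)
  sim <- simulate_counts(cfg)
  res1 <- nb_test(sim$counts)
  flipped <- omics_matrix(sim$counts$values,
                          ifelse(sim$counts$groups == "stable",
                                 "unstable", "stable"),
                          layer = "mrna")
  res2 <- nb_test(flipped)
  expect_equal(res2$log2FoldChange, -res1$log2FoldChange)
  expect_equal(res2$pvalue, res1$pvalue)
})

test_that("all-zero features are never differential", {
  m <- rbind(zero = rep(0, 6), ok = c(10, 12, 9, 50, 60, 55))
  om <- omics_matrix(m, rep(c("stable", "unstable"), each = 3))
  res <- nb_test(om)
  expect_equal(res$pvalue[res$feature_id == "zero"], 1)
  expect_equal(res$log2FoldChange[res$feature_id == "zero"], 0)
  expect_false(res$is_de[res$feature_id == "zero"])
})

test_that("protein test computes log2 fold changes and low-n flags", {
  m <- rbind(
    same = rep(1000, 10),
    x4 = c(rep(1000, 5) * c(1, 1.01, 0.99, 1.02, 0.98),
           rep(4000, 5) * c(1, 1.01, 0.99, 1.02, 0.98)),
    sparse = c(1000, rep(0, 4), 2000, 3000, rep(0, 3)),
    gone = rep(0, 10)
  )
  colnames(m) <- paste0("s", 1:10)
  om <- omics_matrix(m, rep(c("stable", "unstable"), each = 5),
                     layer = "protein")
  res <- protein_test(om)
  expect_equal(res$log2FoldChange[res$feature_id == "same"], 0)
  expect_false(res$is_de[res$feature_id == "same"])
  expect_equal(res$log2FoldChange[res$feature_id == "x4"], 2,
               tolerance = 1e-9)
  expect_true(res$is_de[res$feature_id == "x4"])
  expect_true(res$low_n[res$feature_id == "sparse"])
  expect_equal(res$pvalue[res$feature_id == "sparse"], 1)
  expect_true(is.na(res$qvalue[res$feature_id == "gone"]))
  expect_false(res$is_de[res$feature_id == "gone"])
})

test_that("ddct reproduces worked fold changes and is shift-invariant", {
  mk_ct <- function(t_un, t_st, shift = 0) {
    rbind(
      data.frame(sample = paste0("u", 1:3), group = "unstable",
                 gene = "TGT", ct = t_un),
      data.frame(sample = paste0("u", 1:3), group = "unstable",
                 gene = "REF", ct = 15),
      data.frame(sample = paste0("s", 1:3), group = "stable",
                 gene = "TGT", ct = t_st + shift),
      data.frame(sample = paste0("s", 1:3), group = "stable",
                 gene = "REF", ct = 15 + shift)
    )
  }
  r <- ddct(mk_ct(20, 22), reference = "REF")
  expect_equal(r$ddct, -2)
  expect_equal(r$fold, 4)
  r0 <- ddct(mk_ct(20, 20), reference = "REF")
  expect_equal(r0$fold, 1)
  # adding a constant to every Ct of a sample leaves the fold unchanged
  r_shift <- ddct(mk_ct(20, 22, shift = 3), reference = "REF")
  expect_equal(r_shift$fold, 4)
  # a sample without reference Ct is dropped with a warning
  tab <- mk_ct(20, 22)
  tab <- tab[!(tab$sample == "u3" & tab$gene == "REF"), ]
  expect_warning(rd <- ddct(tab, reference = "REF"), "u3")
  expect_equal(rd$fold, 4)
})
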