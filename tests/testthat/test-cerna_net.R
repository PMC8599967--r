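# independent site scan: compare every target window against the reverse
# complement computed with Biostrings
oracle_seed_sites <- function(mirna, target) {
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::RNAStringSet(chartr("Tt", "Uu", s))))
  mir <- toupper(mirna); tgt <- toupper(chartr("Tt", "Uu", target))
  m8 <- rc(substr(mir, 2, 8))
  a1 <- paste0(rc(substr(mir, 2, 7)), "A")
  n <- nchar(tgt)
  out <- list()
  for (p in seq_len(max(n - 6, 0))) {
    w <- substr(tgt, p, p + 6)
    if (w == m8) {
      nxt <- if (p + 7 <= n) substr(tgt, p + 7, p + 7) else ""
      out[[length(out) + 1L]] <- data.frame(
        position = p, type = if (nxt == "A") "8mer" else "7mer-m8")
    } else if (w == a1) {
      prev <- if (p >= 2) substr(tgt, p - 1, p + 5) else ""
      if (prev != m8) {
        out[[length(out) + 1L]] <- data.frame(position = p, type = "7mer-A1")
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(position = integer(), type = character())
}

test_that("let-7-style seed gives an 8mer on its constructed complement", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  target <- paste0("GGGGG", "CUACCUCA", "GGGGG")
  sites <- seed_match(mir, target)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$type, "8mer")
  expect_equal(sites$position, 6L)
  # full reverse complement of a U-leading miRNA contains an 8mer
  rc_full <- plaqomics:::revcomp(mir)
  sites_rc <- seed_match(mir, rc_full)
  expect_true(any(sites_rc$type == "8mer"))
  # empty/short target: no sites
  expect_equal(nrow(seed_match(mir, "")), 0L)
  expect_error(seed_match("ACGUACG", "ACGU"), "at least 8")
})

test_that("seed matching equals the brute-force window oracle", {
  set.seed(71)
  for (i in 1:300) {
    mir <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
    tgt <- paste(sample(c("A", "C", "G", "T"), sample(30:120, 1), TRUE),
                 collapse = "")
    got <- seed_match(mir, tgt)
    want <- oracle_seed_sites(mir, tgt)
    expect_equal(got$position, want$position)
    expect_equal(got$type, want$type)
  }
})

test_that("ceRNA assembly counts planted edges exactly", {
  set.seed(73)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  mirs <- c(m1 = "UAAGGCACGCGGUGAAUGCCA",
            m2 = "UCCCUGAGACCCUAACUUGUGA",
            m3 = "UGGAAGACUAGUGAUUUUGUUGU")
  site <- function(m) plaqomics:::revcomp(chartr("U", "T", substr(m, 2, 8)))
  # one lncRNA carrying a site for each of the three miRNAs
  lnc <- c(L1 = paste0(rand(30), site(mirs[1]), rand(20), site(mirs[2]),
                       rand(20), site(mirs[3]), rand(30)))
  # each miRNA hits two mRNAs
  utrs <- c(
    T1 = paste0(rand(20), site(mirs[1]), rand(20), site(mirs[2]), rand(10)),
    T2 = paste0(rand(20), site(mirs[1]), rand(20), site(mirs[3]), rand(10)),
    T3 = paste0(rand(20), site(mirs[2]), rand(20), site(mirs[3]), rand(10))
  )
  net <- build_cerna(lnc, mirs, utrs)
  expect_equal(sum(net$edges$tier == "lnc_mir"), 3L)
  expect_equal(sum(net$edges$tier == "mir_mrna"), 6L)
  # duplicate sites collapse into one edge with a site count
  lnc_dup <- c(LD = paste0(rand(10), site(mirs[1]), rand(10), site(mirs[1]),
                           rand(10)))
  net_dup <- build_cerna(lnc_dup, mirs[1], character(0))
  expect_equal(nrow(net_dup$edges), 1L)
  expect_equal(net_dup$edges$n_sites, 2L)
  # no sites anywhere -> empty network
  net0 <- build_cerna(c(L = strrep("A", 50)), mirs[2], c(T = strrep("A", 50)))
  expect_equal(nrow(net0$edges), 0L)
})

test_that("MCODE recovers the K5 from K5-plus-pendant and splits components", {
  k5 <- t(utils::combn(paste0("v", 1:5), 2))
  edges <- rbind(k5, c("v5", "pend"))
  cl <- mcode_cluster(as.data.frame(edges))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members, paste0("v", 1:5))
  expect_equal(cl[[1]]$density, 1)

  two_k4 <- rbind(t(utils::combn(paste0("a", 1:4), 2)),
                  t(utils::combn(paste0("b", 1:4), 2)))
  cl2 <- mcode_cluster(as.data.frame(two_k4))
  expect_length(cl2, 2L)
  expect_setequal(
    vapply(cl2, function(x) paste(x$members, collapse = ","), character(1)),
    c("a1,a2,a3,a4", "b1,b2,b3,b4")
  )
  expect_length(mcode_cluster(data.frame(a = character(), b = character())),
                0L)
})

test_that("MCODE output is invariant to edge permutation and clusters connect", {
  set.seed(75)
  n <- 12
  m <- matrix(runif(n * n) < 0.35, n, n)
  m[lower.tri(m, diag = TRUE)] <- FALSE
  el <- which(m, arr.ind = TRUE)
  edges <- data.frame(a = paste0("n", el[, 1]), b = paste0("n", el[, 2]))
  cl1 <- mcode_cluster(edges)
  cl2 <- mcode_cluster(edges[sample(nrow(edges)), ])
  expect_identical(cl1, cl2)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  overall <- 2 * igraph::ecount(g) /
    (igraph::vcount(g) * (igraph::vcount(g) - 1))
  for (cl in cl1) {
    sub <- igraph::induced_subgraph(g, cl$members)
    expect_true(igraph::is_connected(sub))
    expect_gte(cl$density, overall)
  }
})
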