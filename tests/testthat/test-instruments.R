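test_that("select_genomewide filters at the threshold and preserves order", {
  tab <- make_sumstats(n = 2, seed = 1)
  tab$pval <- c(1e-9, 1e-7)
  expect_equal(select_genomewide(tab)$snp_id, "rs001")
  tab$pval <- c(1e-9, 1e-10)
  expect_equal(select_genomewide(tab)$snp_id, c("rs001", "rs002"))
  expect_equal(nrow(select_genomewide(tab, 1.0)), 2L)
  tab$pval <- c(0.5, 0.6)
  expect_warning(out <- select_genomewide(tab), "no variant")
  expect_equal(nrow(out), 0L)
})

test_that("greedy_clump keeps the lowest-p SNP of a linked pair", {
  tab <- make_sumstats(n = 2, seed = 2)
  tab$chrom <- c("1", "1"); tab$pos <- c(100000L, 105000L)
  tab$pval <- c(1e-10, 1e-9)
  ld <- ld_matrix(tab$snp_id, matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(greedy_clump(tab, ld)$snp_id, "rs001")
  ld2 <- ld_matrix(tab$snp_id, matrix(c(1, 5e-4, 5e-4, 1), 2))
  expect_equal(greedy_clump(tab, ld2)$snp_id, c("rs001", "rs002"))
})

test_that("greedy_clump matches the brute-force oracle on random LD", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 10
    tab <- make_sumstats(n = n, seed = seed)
    tab$chrom <- "1"
    tab$pos <- sort(sample.int(2e7, n))
    tab$pval <- runif(n, 1e-12, 1e-4)
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2; diag(m) <- 1
    # sparsify so clumping decisions vary
    m[m < 0.6] <- 0; m <- pmax(m, t(m)); diag(m) <- 1
    ld <- ld_matrix(tab$snp_id, m)
    kept <- greedy_clump(tab, ld, r2_threshold = 0.5, window_kb = 10000)
    expect_equal(kept$snp_id, oracle_clump(tab, ld$r2, 0.5, 1e7))
    # post-condition: no retained pair within window at or above threshold
    for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
      if (i < j && abs(kept$pos[i] - kept$pos[j]) <= 1e7) {
        expect_lt(ld$r2[kept$snp_id[i], kept$snp_id[j]], 0.5)
      }
    }
    # subset property
    expect_true(all(kept$snp_id %in% tab$snp_id))
  }
})

test_that("SNPs absent from the LD matrix are retained with a warning", {
  tab <- make_sumstats(n = 3, seed = 3)
  tab$chrom <- "1"; tab$pos <- c(1e5, 1.1e5, 1.2e5); tab$pval <- c(1e-10, 1e-9, 1e-8)
  ld <- ld_matrix(tab$snp_id[1:2], matrix(c(1, 0.9, 0.9, 1), 2))
  expect_warning(kept <- greedy_clump(tab, ld), "absent")
  expect_equal(kept$snp_id, c("rs001", "rs003"))
})

test_that("snp_f_statistic is the squared z-score", {
  expect_equal(snp_f_statistic(0.1, 0.02), 25)
  expect_equal(snp_f_statistic(0, 0.02), 0)
  expect_equal(snp_f_statistic(-0.1, 0.02), 25)
  expect_error(snp_f_statistic(0.1, 0), "> 0")
})

test_that("instrument_r2 matches the term-wise oracle and rejects missing eaf", {
  tab <- make_sumstats(n = 3, seed = 4)
  tab$eaf <- c(0.5, 0.2, 0.35); tab$beta <- c(0.2, -0.1, 0.05)
  expected <- 0
  for (j in 1:3) expected <- expected + 2 * tab$eaf[j] * (1 - tab$eaf[j]) * tab$beta[j]^2
  expect_equal(instrument_r2(tab), expected, tolerance = 1e-12)
  # single-SNP closed form: 2 * 0.5 * 0.5 * 0.2^2
  one <- tab[1, ]; expect_equal(instrument_r2(one), 0.02)
  tab$beta <- 0; expect_equal(instrument_r2(tab), 0)
  tab$eaf[2] <- NA
  expect_error(instrument_r2(tab), "rs002")
  # order invariance
  tab2 <- make_sumstats(n = 6, seed = 5)
  expect_equal(instrument_r2(tab2), instrument_r2(tab2[sample(6), ]))
})

test_that("overall_f evaluates the F formula and guards its domain", {
  # BMI-scale inputs: R^2 = 0.04, n = 806834, k = 312
  expect_equal(overall_f(0.04, 806834, 312), 107.70846688, tolerance = 1e-3)
  expect_equal(overall_f(0, 806834, 312), 0)
  # halving k roughly doubles F at small R^2
  expect_gt(overall_f(0.04, 806834, 156) / overall_f(0.04, 806834, 312), 1.99)
  expect_error(overall_f(1, 100, 2), "0, 1")
  expect_error(overall_f(0.1, 3, 2), "n > k")
})

test_that("instrument_r2 recovers the generative R^2 within Monte-Carlo error", {
  cfg <- sim_config(n_snps = 100L)
  est <- vapply(1:200, function(s) {
    cfg$seed <- s
    instrument_r2(simulate_two_sample(cfg)$exposure)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.04) / 0.04, 0.10)
})

test_that("ld matrices round-trip through square and long TSV formats", {
  m <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = NULL)
  ld <- ld_matrix(c("rs1", "rs2"), m)
  sq <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\trs1\trs2", "rs1\t1\t0.3", "rs2\t0.3\t1"), sq)
  expect_equal(read_ld_matrix(sq)$r2, ld$r2)
  lg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_a\tsnp_b\tr2", "rs1\trs2\t0.3"), lg)
  expect_equal(read_ld_matrix(lg)$r2[c("rs1", "rs2"), c("rs1", "rs2")], ld$r2)
  expect_error(ld_matrix(c("a", "b"), matrix(c(1, 2, 2, 1), 2)), "\\[0, 1\\]")
  expect_error(ld_matrix(c("a", "b"), matrix(c(1, 0.1, 0.3, 1), 2)), "symmetric")
})
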