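pal_tab <- function(ea, oa, eaf, beta = 0.1, id = "rs1", trait = "continuous") {
  summary_stats(data.frame(snp_id = id, chrom = "1", pos = 100L,
                           effect_allele = ea, other_allele = oa,
                           eaf = eaf, beta = beta, se = 0.01,
                           stringsAsFactors = FALSE),
                trait_name = trait, trait_type = trait)
}

test_that("is_palindromic identifies complementary allele pairs", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_equal(is_palindromic(c("A", "C", "G"), c("T", "A", "C")),
               c(TRUE, FALSE, TRUE))
  expect_error(is_palindromic("A", "N"), "A, C, G, T")
})

test_that("non-palindromic alignment: direct, swapped, strand-complement", {
  exp_t <- pal_tab("A", "G", 0.2)
  # same alleles -> aligned
  h <- harmonize(exp_t, pal_tab("A", "G", 0.2, beta = 0.05))
  expect_equal(h$status, "aligned")
  expect_equal(h$beta_out, 0.05)
  # swapped alleles -> sign flip
  h <- harmonize(exp_t, pal_tab("G", "A", 0.8, beta = 0.05))
  expect_equal(h$status, "flipped")
  expect_equal(h$beta_out, -0.05)
  expect_equal(h$eaf_out, 0.2)
  # strand complement (A/G reported as T/C) -> aligned, no flip
  h <- harmonize(exp_t, pal_tab("T", "C", 0.2, beta = 0.05))
  expect_equal(h$status, "aligned")
  expect_equal(h$beta_out, 0.05)
  # complement of swap -> flip
  h <- harmonize(exp_t, pal_tab("C", "T", 0.8, beta = 0.05))
  expect_equal(h$status, "flipped")
  expect_equal(h$beta_out, -0.05)
  # different locus entirely -> dropped
  h <- harmonize(exp_t, pal_tab("A", "C", 0.2, beta = 0.05))
  expect_equal(nrow(h), 0L)
  expect_equal(attr(h, "audit")$dropped_incompatible, 1L)
})

test_that("palindromic SNPs follow the MAF < 0.3 frequency rule", {
  # all four eaf-side combinations at low MAF
  cases <- list(
    list(eaf_exp = 0.12, eaf_out = 0.11, flip = FALSE),  # both minor
    list(eaf_exp = 0.12, eaf_out = 0.88, flip = TRUE),   # opposite sides
    list(eaf_exp = 0.88, eaf_out = 0.11, flip = TRUE),
    list(eaf_exp = 0.88, eaf_out = 0.89, flip = FALSE)
  )
  for (cs in cases) {
    h <- harmonize(pal_tab("A", "T", cs$eaf_exp),
                   pal_tab("A", "T", cs$eaf_out, beta = 0.05))
    expect_equal(h$status, "palindromic_kept")
    expect_equal(h$beta_out, if (cs$flip) -0.05 else 0.05,
                 info = sprintf("eaf_exp=%g eaf_out=%g", cs$eaf_exp, cs$eaf_out))
  }
  # MAF at or above 0.3 on either side -> dropped
  for (bad in list(c(0.45, 0.1), c(0.1, 0.45), c(0.31, 0.31))) {
    h <- harmonize(pal_tab("A", "T", bad[1]), pal_tab("A", "T", bad[2], beta = 0.05))
    expect_equal(nrow(h), 0L)
    expect_equal(attr(h, "audit")$dropped_palindromic, 1L)
  }
  # missing frequency on either side -> dropped
  h <- harmonize(pal_tab("A", "T", NA), pal_tab("A", "T", 0.1, beta = 0.05))
  expect_equal(attr(h, "audit")$dropped_palindromic, 1L)
})

test_that("duplicate SNP ids are a hard error", {
  dup <- summary_stats(data.frame(snp_id = c("rs1", "rs1"),
                                  effect_allele = "A", other_allele = "G",
                                  beta = 0.1, se = 0.01), "t")
  # constructor already dedupes, so build the duplicate table directly
  dup2 <- rbind(as.data.frame(pal_tab("A", "G", 0.2)),
                as.data.frame(pal_tab("A", "G", 0.2)))
  dup2 <- structure(dup2, trait_name = "t", trait_type = "continuous",
                    class = c("sumstats", "data.frame"))
  expect_error(harmonize(dup2, pal_tab("A", "G", 0.2)), "duplicate")
  expect_equal(nrow(dup), 1L)
})

test_that("harmonization is invariant to the outcome's allele orientation", {
  set.seed(11)
  sim <- simulate_two_sample(sim_config(n_snps = 30L, palindromic_fraction = 0.2,
                                        seed = 11))
  out_flipped <- as.data.frame(sim$outcome)
  ea <- out_flipped$effect_allele
  out_flipped$effect_allele <- out_flipped$other_allele
  out_flipped$other_allele <- ea
  out_flipped$beta <- -out_flipped$beta
  out_flipped$eaf <- 1 - out_flipped$eaf
  out_flipped <- summary_stats(out_flipped, attr(sim$outcome, "trait_name"),
                               attr(sim$outcome, "trait_type"))
  h1 <- harmonize(sim$exposure, sim$outcome)
  h2 <- harmonize(sim$exposure, out_flipped)
  expect_equal(h1$snp_id, h2$snp_id)
  expect_equal(h1$beta_out, h2$beta_out, tolerance = 1e-12)
  expect_equal(h1$eaf_out, h2$eaf_out, tolerance = 1e-12)
})

test_that("re-harmonizing the harmonized outcome against the exposure is a no-op", {
  sim <- simulate_two_sample(sim_config(n_snps = 25L, palindromic_fraction = 0.2,
                                        seed = 13))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # rebuild an outcome table from the harmonized records (exposure orientation)
  out2 <- summary_stats(data.frame(
    snp_id = h1$snp_id, chrom = h1$chrom, pos = h1$pos,
    effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_out, beta = h1$beta_out, se = h1$se_out,
    stringsAsFactors = FALSE), "outcome2", "binary")
  h2 <- harmonize(sim$exposure, out2)
  expect_equal(h2$snp_id, h1$snp_id)
  expect_equal(h2$beta_out, h1$beta_out, tolerance = 1e-12)
  expect_true(all(h2$status %in% c("aligned", "palindromic_kept")))
})

test_that("retained count is bounded and audit counts sum to the merge size", {
  sim <- simulate_two_sample(sim_config(n_snps = 40L, palindromic_fraction = 0.5,
                                        maf_range = c(0.05, 0.5), seed = 17))
  h <- harmonize(sim$exposure, sim$outcome)
  expect_lte(nrow(h), min(nrow(sim$exposure), nrow(sim$outcome)))
  expect_equal(sum(unlist(attr(h, "audit"))),
               length(intersect(sim$exposure$snp_id, sim$outcome$snp_id)))
})
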