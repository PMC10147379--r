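# Seeded generator of two-sample GWAS summary statistics with known causal
# truth, emulating the structure of published exposure/outcome GWAS: per-SNP
# exposure effects with sampling error, outcome effects under a causal slope
# plus configurable pleiotropy, planted outliers, palindromic alleles, and
# block-diagonal LD.

#' Simulation configuration
#'
#' Defaults mirror the scale of the real analyses the package targets: a
#' large continuous-trait exposure GWAS (n = 806,834, the GIANT + UK Biobank
#' BMI meta-analysis) against a case-control outcome GWAS of 6034 cases and
#' 6585 controls (the oral/oropharyngeal cancer OncoArray study), an
#' instrument of 50 independent SNPs explaining R^2 = 0.04 of the exposure.
#'
#' @param n_snps number of instrument SNPs.
#' @param n_exposure_sample exposure GWAS sample size.
#' @param n_outcome_cases,n_outcome_controls outcome GWAS case/control counts
#'   (for `outcome_type = "continuous"` their sum is the outcome sample size).
#' @param causal_beta true causal slope (log-OR per exposure SD for binary
#'   outcomes).
#' @param pleiotropy_mode `"none"`, `"balanced"`, `"directional"` or
#'   `"inside_violating"` (direct effects correlated 0.5 with the SNP-exposure
#'   effects, violating InSIDE).
#' @param pleio_mean,pleio_sd mean and SD of the direct (pleiotropic) effects
#'   on invalid SNPs.
#' @param prop_invalid proportion of SNPs carrying a direct effect; must be 0
#'   when `pleiotropy_mode = "none"`.
#' @param n_outliers number of planted outlier SNPs.
#' @param outlier_scale outlier offset, as a multiple of the SNP's outcome
#'   standard error.
#' @param maf_range interval within (0, 0.5] for minor-allele frequencies.
#' @param palindromic_fraction fraction of SNPs given A/T or C/G alleles.
#' @param ld_block_size SNPs per LD block (1 = independent instruments, the
#'   post-clumping situation).
#' @param ld_r2_within r^2 between distinct SNPs of the same block.
#' @param r2_target instrument R^2 on the exposure.
#' @param outcome_type `"binary"` (log-OR scale) or `"continuous"`.
#' @param seed RNG seed used by [simulate_two_sample()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_snps = 50L,
                       n_exposure_sample = 806834L,
                       n_outcome_cases = 6034L,
                       n_outcome_controls = 6585L,
                       causal_beta = 0.2,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violating"),
                       pleio_mean = 0,
                       pleio_sd = 0,
                       prop_invalid = 0,
                       n_outliers = 0L,
                       outlier_scale = 10,
                       maf_range = c(0.05, 0.5),
                       palindromic_fraction = 0,
                       ld_block_size = 1L,
                       ld_r2_within = 0,
                       r2_target = 0.04,
                       outcome_type = c("binary", "continuous"),
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  cfg <- list(n_snps = as.integer(n_snps),
              n_exposure_sample = as.integer(n_exposure_sample),
              n_outcome_cases = as.integer(n_outcome_cases),
              n_outcome_controls = as.integer(n_outcome_controls),
              causal_beta = causal_beta,
              pleiotropy_mode = pleiotropy_mode,
              pleio_mean = pleio_mean, pleio_sd = pleio_sd,
              prop_invalid = prop_invalid,
              n_outliers = as.integer(n_outliers),
              outlier_scale = outlier_scale,
              maf_range = maf_range,
              palindromic_fraction = palindromic_fraction,
              ld_block_size = as.integer(ld_block_size),
              ld_r2_within = ld_r2_within,
              r2_target = r2_target,
              outcome_type = outcome_type,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_snps < 1L) abort("n_snps must be >= 1")
    if (n_exposure_sample < 2L) abort("n_exposure_sample must be >= 2")
    if (prop_invalid < 0 || prop_invalid > 1) abort("prop_invalid must lie in [0, 1]")
    if (pleiotropy_mode == "none" && prop_invalid != 0) {
      abort("prop_invalid must be 0 when pleiotropy_mode = 'none'")
    }
    if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2]) {
      abort("maf_range must be an interval within (0, 0.5]")
    }
    if (palindromic_fraction < 0 || palindromic_fraction > 1) {
      abort("palindromic_fraction must lie in [0, 1]")
    }
    if (n_outliers < 0L || n_outliers > n_snps) abort("n_outliers out of range")
    if (ld_r2_within < 0 || ld_r2_within > 1) abort("ld_r2_within must lie in [0, 1]")
    if (r2_target <= 0 || r2_target >= 1) abort("infeasible R^2 target")
  })
  invisible(cfg)
}

NON_PALINDROMIC_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)
PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generative model, all on the summary-statistic scale: minor-allele
#' frequencies are uniform on `maf_range`; true SNP-exposure effects
#' `gamma_j` are a scaled half-normal (trait-increasing allele orientation)
#' normalized so `sum_j 2 p_j (1 - p_j) gamma_j^2 = r2_target`; estimated
#' effects add noise with `se_exp_j = 1 / sqrt(2 p_j (1 - p_j) n_exposure)`.
#' Direct (pleiotropic) effects `alpha_j` are drawn per `pleiotropy_mode` on
#' a `prop_invalid` random subset; true outcome effects are
#' `causal_beta * gamma_j + alpha_j` (log-OR scale for binary outcomes),
#' with `se_out_j = 1 / sqrt(2 p_j (1 - p_j) n_eff)` where `n_eff` is the
#' effective case-control size `n_cases n_controls / n_total` (or the total
#' sample size for continuous outcomes). Planted outliers add
#' `outlier_scale * se_out_j` to the true outcome effect. P-values are
#' two-sided normal. LD is block-diagonal with `ld_r2_within` inside blocks;
#' consecutive blocks sit 20 Mb apart so default-window clumping treats them
#' as independent.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `exposure` and `outcome` (`sumstats`),
#'   `ld` (`ld_matrix`) and `truth` (`sim_truth`: `causal_beta`, `gamma`,
#'   `alpha`, `outlier_indices`, `instrument_r2_true`).
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  k <- cfg$n_snps
  with_seed(cfg$seed, {
    maf <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])
    het <- 2 * maf * (1 - maf)
    # instruments emulate genome-wide-significant hits, whose effects are
    # bounded away from zero by the selection itself; a 3-fold spread in the
    # trait-increasing orientation, rescaled to the target R^2
    gamma <- stats::runif(k, 0.5, 1.5)
    gamma <- gamma * sqrt(cfg$r2_target / sum(het * gamma^2))
    se_exp <- 1 / sqrt(het * cfg$n_exposure_sample)

    n_total <- as.numeric(cfg$n_outcome_cases) + as.numeric(cfg$n_outcome_controls)
    n_eff <- if (cfg$outcome_type == "binary") {
      as.numeric(cfg$n_outcome_cases) * as.numeric(cfg$n_outcome_controls) / n_total
    } else {
      n_total
    }
    se_out <- 1 / sqrt(het * n_eff)

    alpha <- numeric(k)
    n_invalid <- round(cfg$prop_invalid * k)
    invalid <- if (n_invalid > 0) sample.int(k, n_invalid) else integer(0)
    if (length(invalid)) {
      alpha[invalid] <- switch(
        cfg$pleiotropy_mode,
        none = 0,
        balanced = stats::rnorm(n_invalid, 0, cfg$pleio_sd),
        directional = stats::rnorm(n_invalid, cfg$pleio_mean, cfg$pleio_sd),
        inside_violating = {
          # direct effects correlated 0.5 with gamma among invalid SNPs
          z <- scale(gamma[invalid])[, 1L]
          if (any(!is.finite(z))) z <- rep(0, n_invalid)
          cfg$pleio_mean + cfg$pleio_sd *
            (0.5 * z + sqrt(1 - 0.25) * stats::rnorm(n_invalid))
        })
    }

    outlier_idx <- if (cfg$n_outliers > 0) sample.int(k, cfg$n_outliers) else integer(0)
    gamma_true_out <- cfg$causal_beta * gamma + alpha
    gamma_true_out[outlier_idx] <- gamma_true_out[outlier_idx] +
      cfg$outlier_scale * se_out[outlier_idx]

    beta_exp <- gamma + stats::rnorm(k, 0, se_exp)
    beta_out <- gamma_true_out + stats::rnorm(k, 0, se_out)

    n_pal <- round(cfg$palindromic_fraction * k)
    pal_idx <- if (n_pal > 0) sample.int(k, n_pal) else integer(0)
    alleles <- NON_PALINDROMIC_PAIRS[sample.int(nrow(NON_PALINDROMIC_PAIRS), k,
                                                replace = TRUE), , drop = FALSE]
    if (length(pal_idx)) {
      alleles[pal_idx, ] <- PALINDROMIC_PAIRS[
        sample.int(nrow(PALINDROMIC_PAIRS), length(pal_idx), replace = TRUE), ,
        drop = FALSE]
    }
    # effect allele is the minor allele on a random half of SNPs
    eaf <- ifelse(stats::runif(k) < 0.5, maf, 1 - maf)

    block <- (seq_len(k) - 1L) %/% cfg$ld_block_size
    pos <- block * 2e7 + (seq_len(k) - 1L) %% cfg$ld_block_size * 1000L + 1L
    snp_id <- sprintf("rs%06d", seq_len(k))

    r2 <- outer(block, block, function(a, b) ifelse(a == b, cfg$ld_r2_within, 0))
    diag(r2) <- 1
    ld <- ld_matrix(snp_id, r2)

    exposure <- summary_stats(
      data.frame(snp_id = snp_id, chrom = "1", pos = pos,
                 effect_allele = alleles[, 1L], other_allele = alleles[, 2L],
                 eaf = eaf, beta = beta_exp, se = se_exp,
                 pval = pval_normal(beta_exp, se_exp),
                 n = cfg$n_exposure_sample, stringsAsFactors = FALSE),
      trait_name = "sim_exposure", trait_type = "continuous",
      unit_note = "per 1 SD of the simulated exposure")
    outcome <- summary_stats(
      data.frame(snp_id = snp_id, chrom = "1", pos = pos,
                 effect_allele = alleles[, 1L], other_allele = alleles[, 2L],
                 eaf = eaf, beta = beta_out, se = se_out,
                 pval = pval_normal(beta_out, se_out),
                 n = n_total,
                 n_cases = if (cfg$outcome_type == "binary") cfg$n_outcome_cases else NA,
                 stringsAsFactors = FALSE),
      trait_name = "sim_outcome",
      trait_type = if (cfg$outcome_type == "binary") "binary" else "continuous",
      unit_note = if (cfg$outcome_type == "binary") "log odds ratio" else "per 1 SD")

    truth <- structure(list(causal_beta = cfg$causal_beta,
                            gamma = gamma, alpha = alpha,
                            outlier_indices = sort(outlier_idx),
                            instrument_r2_true = sum(het * gamma^2)),
                       class = "sim_truth")
    list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
  })
}

#' Harmonized set straight from a simulation
#'
#' Convenience for estimator studies: simulates and harmonizes in one step
#' (the simulated tables share allele orientation, so harmonization aligns
#' every non-palindromic record).
#'
#' @param cfg a [sim_config()].
#' @return list with `hset` (a `harmonized_set`) and `truth`.
#' @export
simulate_harmonized <- function(cfg) {
  sim <- simulate_two_sample(cfg)
  list(hset = harmonize(sim$exposure, sim$outcome), truth = sim$truth)
}

#' Named simulation scenarios
#'
#' Documented presets covering the validation regimes of the estimator
#' battery:
#' \describe{
#'   \item{valid}{50 independent strong instruments, causal slope 0.2, no
#'     pleiotropy — nominal-coverage regime.}
#'   \item{balanced}{direct effects on every SNP, mean 0 (InSIDE holds):
#'     IVW remains unbiased, the Egger intercept is centred on 0.}
#'   \item{directional}{30% invalid SNPs with mean direct effect 0.05: the
#'     Egger intercept is centred on 0.015 and robust estimators should beat
#'     IVW.}
#'   \item{inside_violation}{as directional but with direct effects
#'     correlated 0.5 with the SNP-exposure effects.}
#'   \item{outliers}{3 planted outliers offset by 10 outcome standard
#'     errors — the MR-PRESSO regime.}
#'   \item{weak_instruments}{mean per-SNP F around 8, below the conventional
#'     F = 10 rule.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed stored in the returned config.
#' @return a `sim_config`.
#' @export
scenario_preset <- function(name = c("valid", "balanced", "directional",
                                     "inside_violation", "outliers",
                                     "weak_instruments"),
                            seed = 1L) {
  name <- match.arg(name)
  switch(name,
    valid = sim_config(seed = seed),
    balanced = sim_config(pleiotropy_mode = "balanced", prop_invalid = 1,
                          pleio_mean = 0, pleio_sd = 0.02, seed = seed),
    directional = sim_config(pleiotropy_mode = "directional",
                             prop_invalid = 0.3, pleio_mean = 0.05,
                             pleio_sd = 0.01, seed = seed),
    inside_violation = sim_config(pleiotropy_mode = "inside_violating",
                                  prop_invalid = 0.3, pleio_mean = 0.05,
                                  pleio_sd = 0.01, seed = seed),
    outliers = sim_config(n_outliers = 3L, outlier_scale = 10, seed = seed),
    # mean per-SNP F = 1 + r2 * n / k = 1 + 0.01 * 35000 / 50 = 8
    weak_instruments = sim_config(n_exposure_sample = 35000L,
                                  r2_target = 0.01, seed = seed))
}

#' Write a simulated dataset to delimited text
#'
#' Exposure and outcome tables are written in the canonical summary-stats
#' TSV schema, the LD matrix as a square TSV, and the generative truth as
#' JSON, so the pipeline consumes them unchanged.
#'
#' @param sim result of [simulate_two_sample()].
#' @param prefix output path prefix; files `<prefix>_exposure.tsv`,
#'   `<prefix>_outcome.tsv`, `<prefix>_ld.tsv`, `<prefix>_truth.json`.
#' @return invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- c(exposure = paste0(prefix, "_exposure.tsv"),
             outcome = paste0(prefix, "_outcome.tsv"),
             ld = paste0(prefix, "_ld.tsv"),
             truth = paste0(prefix, "_truth.json"))
  write_report(as.data.frame(sim$exposure), paths["exposure"], "tsv")
  write_report(as.data.frame(sim$outcome), paths["outcome"], "tsv")
  ld_df <- data.frame(snp_id = sim$ld$snp_ids, sim$ld$r2,
                      check.names = FALSE, stringsAsFactors = FALSE)
  write_report(ld_df, paths["ld"], "tsv")
  jsonlite::write_json(unclass(sim$truth), paths["truth"], digits = NA,
                       auto_unbox = TRUE)
  invisible(paths)
}
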