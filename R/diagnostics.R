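# Heterogeneity diagnostics: Cochran Q and MR-PRESSO.

#' Cochran Q heterogeneity statistic
#'
#' `Q = sum_j (beta_out_j - predicted_j)^2 / se_out_j^2`, where the
#' prediction is `slope * beta_exp_j` for an IVW (or Wald) fit and
#' `intercept + slope * beta_exp_j` for an Egger fit (computed in the Egger
#' orientation, exposure betas non-negative). Degrees of freedom are
#' `k - 1` (IVW) or `k - 2` (Egger); the p-value is the upper chi-square
#' tail. Q much larger than its degrees of freedom indicates invalid
#' instruments, e.g. horizontal pleiotropy.
#'
#' @param hset the `harmonized_set` the fit was produced from.
#' @param fitted an `mr_estimate` (IVW/Wald) or `egger_result`.
#' @return a `q_stats` list: `q`, `df`, `pval`.
#' @export
cochran_q <- function(hset, fitted) {
  stopifnot(inherits(hset, "harmonized_set"))
  k <- nrow(hset)
  if (inherits(fitted, "egger_result")) {
    o <- orient_positive(hset)
    pred <- fitted$intercept$est + fitted$slope$beta * o$beta_exp
    resid <- o$beta_out - pred
    df <- k - 2L
  } else if (inherits(fitted, "mr_estimate")) {
    resid <- hset$beta_out - fitted$beta * hset$beta_exp
    df <- k - 1L
  } else {
    abort("`fitted` must be an mr_estimate or egger_result")
  }
  if (df <= 0L) abort("Cochran Q needs positive degrees of freedom (k = %d)", k)
  q <- sum(resid^2 / hset$se_out^2)
  structure(list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "q_stats")
}

#' @export
print.q_stats <- function(x, ...) {
  cat(sprintf("<q_stats> Q = %.2f on %d df, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

# leave-one-out IVW slopes for columns of (x, y) matrices, weights w
loo_slopes <- function(x, y, w) {
  num <- sum(w * x * y)
  den <- sum(w * x^2)
  (num - w * x * y) / (den - w * x^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Three-part resampling diagnostic. Global test: the observed residual sum
#' of squares is `sum_j w_j (beta_out_j - b_{-j} beta_exp_j)^2` with
#' `w_j = 1 / se_out_j^2` and `b_{-j}` the IVW slope excluding SNP j; its
#' null distribution is built from `n_distributions` parametric datasets
#' simulated under the no-pleiotropy model (betas resampled about the
#' leave-one-out fit), and the global p-value is the empirical upper-tail
#' proportion. Outlier test: each SNP's observed weighted squared residual
#' is compared with its simulated distribution; p-values are
#' Bonferroni-adjusted (configurable) and SNPs below `sig_threshold` are
#' flagged. Distortion test: the shift between the outlier-corrected and
#' full IVW slopes is compared against slopes from removing random subsets
#' of the same size. The corrected estimate is the IVW fit on non-outliers.
#'
#' @param hset a `harmonized_set` with at least 4 SNPs.
#' @param n_distributions simulated datasets (default 1000).
#' @param sig_threshold significance level for the outlier test (default 0.05).
#' @param seed RNG seed.
#' @param adjust `"bonferroni"` (default) or `"none"` for per-SNP p-values.
#' @return a `presso_result`: `global_rss_observed`, `global_pval`,
#'   `outlier_indices`, `per_snp_pvals` (adjusted), `corrected_estimate`
#'   (an `mr_estimate`), `distortion_pval` (`NA` when no outliers).
#' @export
mr_presso <- function(hset, n_distributions = 1000L, sig_threshold = 0.05,
                      seed = NULL, adjust = c("bonferroni", "none")) {
  stopifnot(inherits(hset, "harmonized_set"))
  adjust <- match.arg(adjust)
  k <- nrow(hset)
  if (k < 4L) abort("MR-PRESSO needs at least 4 SNPs, got %d", k)
  x <- hset$beta_exp
  y <- hset$beta_out
  w <- 1 / hset$se_out^2
  b_loo <- loo_slopes(x, y, w)
  res_obs <- y - b_loo * x
  rss_j_obs <- w * res_obs^2
  rss_obs <- sum(rss_j_obs)

  S <- as.integer(n_distributions)
  sim <- with_seed(seed, {
    ex <- matrix(stats::rnorm(k * S, 0, hset$se_exp), k, S)
    ey <- matrix(stats::rnorm(k * S, 0, hset$se_out), k, S)
    xs <- x + ex
    ys <- b_loo * x + ey
    # leave-one-out slopes on each simulated dataset, vectorized by column
    num <- colSums(w * xs * ys)
    den <- colSums(w * xs^2)
    b_loo_s <- sweep(-w * xs * ys, 2, num, `+`) /
      sweep(-w * xs^2, 2, den, `+`)
    rss_j <- w * (ys - b_loo_s * xs)^2
    list(rss = colSums(rss_j), rss_j = rss_j)
  })
  global_pval <- mean(sim$rss >= rss_obs)

  per_snp <- rowMeans(sim$rss_j >= rss_j_obs)
  if (adjust == "bonferroni") per_snp <- pmin(1, per_snp * k)
  outliers <- which(per_snp < sig_threshold)

  if (length(outliers) && length(outliers) < k - 1L) {
    corrected <- mr_ivw(hset[-outliers, , drop = FALSE])
    full <- mr_ivw(hset)
    d_obs <- corrected$beta - full$beta
    d_null <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
      vapply(seq_len(S), function(s) {
        drop_idx <- sample.int(k, length(outliers))
        sub <- -drop_idx
        (sum(w[sub] * x[sub] * y[sub]) / sum(w[sub] * x[sub]^2)) - full$beta
      }, numeric(1L))
    })
    distortion_pval <- mean(abs(d_null) >= abs(d_obs))
  } else {
    if (length(outliers) >= k - 1L) {
      warning("nearly all SNPs flagged as outliers; corrected estimate kept as the full IVW",
              call. = FALSE)
      outliers <- integer(0)
    }
    corrected <- mr_ivw(hset)
    distortion_pval <- NA_real_
  }
  structure(list(global_rss_observed = rss_obs,
                 global_pval = global_pval,
                 outlier_indices = outliers,
                 per_snp_pvals = stats::setNames(per_snp, hset$snp_id),
                 corrected_estimate = corrected,
                 distortion_pval = distortion_pval),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> global RSS = %.2f, p = %.3g; %d outlier(s)\n",
              x$global_rss_observed, x$global_pval, length(x$outlier_indices)))
  if (length(x$outlier_indices)) {
    cat("  outliers:", paste(names(x$per_snp_pvals)[x$outlier_indices],
                             collapse = ", "), "\n")
    cat(sprintf("  distortion p = %.3g\n", x$distortion_pval))
  }
  cat("  corrected: ")
  print(x$corrected_estimate)
  invisible(x)
}
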