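# Causal-effect estimators: Wald ratio, IVW, MR-Egger (plain and
# SIMEX-corrected), weighted median, weighted mode, and the I^2_GX statistic.

#' Construct an MR estimate
#'
#' @param method one of `"wald"`, `"ivw"`, `"egger_slope"`,
#'   `"weighted_median"`, `"weighted_mode"`, `"egger_simex"`.
#' @param beta causal effect per exposure unit.
#' @param se standard error (> 0).
#' @param pval two-sided p-value.
#' @param n_snps number of SNPs used.
#' @param scale `"log_or"` for binary outcomes, `"sd"` for continuous.
#' @param ci_level confidence level (default 0.95, normal-theory).
#' @param df degrees of freedom for a t-based interval, or `NULL` for normal.
#' @return an `mr_estimate` list with `ci_low`/`ci_high` filled in.
#' @export
mr_estimate <- function(method, beta, se, pval, n_snps,
                        scale = c("log_or", "sd"), ci_level = 0.95, df = NULL) {
  scale <- match.arg(scale)
  if (!is_scalar_number(se) || se <= 0) abort("`se` must be > 0")
  q <- if (is.null(df)) stats::qnorm(1 - (1 - ci_level) / 2) else
    stats::qt(1 - (1 - ci_level) / 2, df = df)
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - q * se, ci_high = beta + q * se,
                 pval = pval, n_snps = n_snps, scale = scale),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  if (x$scale == "log_or") {
    cat(sprintf("<mr_estimate> %s: OR %.3f (95%% CI %.3f-%.3f), p = %.3g, %d SNP(s)\n",
                x$method, exp(x$beta), exp(x$ci_low), exp(x$ci_high), x$pval,
                x$n_snps))
  } else {
    cat(sprintf("<mr_estimate> %s: beta %.3f (SE %.3f), p = %.3g, %d SNP(s)\n",
                x$method, x$beta, x$se, x$pval, x$n_snps))
  }
  invisible(x)
}

hset_scale <- function(hset) {
  if (identical(attr(hset, "outcome_type"), "continuous")) "sd" else "log_or"
}

#' Per-SNP Wald ratios
#'
#' The Wald ratio is the SNP-outcome beta divided by the SNP-exposure beta.
#' First-order standard error: `se_out / |beta_exp|`. Second-order adds the
#' exposure-side term: `sqrt(se_out^2 / beta_exp^2 +
#' beta_out^2 se_exp^2 / beta_exp^4)`.
#'
#' @param hset a `harmonized_set`.
#' @param se_method `"first_order"` (default) or `"second_order"`.
#' @return data.frame with one row per SNP: `snp_id`, `beta`, `se`, `pval`.
#' @export
wald_ratio <- function(hset, se_method = c("first_order", "second_order")) {
  stopifnot(inherits(hset, "harmonized_set"))
  se_method <- match.arg(se_method)
  if (any(hset$beta_exp == 0)) {
    abort("Wald ratio undefined for beta_exp = 0 (snp %s)",
          hset$snp_id[which(hset$beta_exp == 0)[1L]])
  }
  beta <- hset$beta_out / hset$beta_exp
  se <- if (se_method == "first_order") {
    hset$se_out / abs(hset$beta_exp)
  } else {
    sqrt(hset$se_out^2 / hset$beta_exp^2 +
           hset$beta_out^2 * hset$se_exp^2 / hset$beta_exp^4)
  }
  data.frame(snp_id = hset$snp_id, beta = beta, se = se,
             pval = pval_normal(beta, se), stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted least-squares regression of the outcome betas on the exposure
#' betas through the origin with weights `1 / se_out^2` — algebraically the
#' inverse-variance-weighted meta-analysis of the per-SNP Wald ratios. Under
#' the default multiplicative random-effects model the fixed-effects standard
#' error is inflated by the square root of the residual scale
#' `Q / (k - 1)` when that scale exceeds 1 (never deflated).
#'
#' @param hset a `harmonized_set` with at least 2 SNPs; with a single SNP the
#'   Wald ratio is returned with a message.
#' @param model `"multiplicative_random_effects"` (default) or
#'   `"fixed_effects"`.
#' @return an `mr_estimate`.
#' @export
mr_ivw <- function(hset, model = c("multiplicative_random_effects",
                                   "fixed_effects")) {
  stopifnot(inherits(hset, "harmonized_set"))
  model <- match.arg(model)
  k <- nrow(hset)
  if (k == 0L) abort("empty harmonized set")
  if (all(hset$beta_exp == 0)) abort("all exposure betas are zero")
  if (k == 1L) {
    message("single SNP: returning the Wald ratio")
    w <- wald_ratio(hset)
    return(mr_estimate("wald", w$beta, w$se, w$pval, 1L, scale = hset_scale(hset)))
  }
  w <- 1 / hset$se_out^2
  x <- hset$beta_exp
  y <- hset$beta_out
  sxx <- sum(w * x^2)
  beta <- sum(w * x * y) / sxx
  se_fixed <- sqrt(1 / sxx)
  if (model == "multiplicative_random_effects") {
    phi <- sum(w * (y - beta * x)^2) / (k - 1)
    se <- se_fixed * sqrt(max(1, phi))
  } else {
    se <- se_fixed
  }
  mr_estimate("ivw", beta, se, pval_normal(beta, se), k, scale = hset_scale(hset))
}

# orient records so beta_exp >= 0 (Egger convention); flips both betas
orient_positive <- function(hset) {
  flip <- hset$beta_exp < 0
  hset$beta_exp[flip] <- -hset$beta_exp[flip]
  hset$beta_out[flip] <- -hset$beta_out[flip]
  hset
}

# closed-form weighted regression with intercept; returns coefficients and
# their variances under the multiplicative-residual model (scale floored at 1)
wls_with_intercept <- function(x, y, w, floor_scale = TRUE) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  denom <- sw * swxx - swx^2
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * sw * swxx ||
      denom <= 0) {
    abort("Egger regression is singular: no variation in exposure betas")
  }
  slope <- (sw * swxy - swx * swy) / denom
  intercept <- (swy - slope * swx) / sw
  k <- length(x)
  resid <- y - intercept - slope * x
  sigma2 <- sum(w * resid^2) / (k - 2)
  scale <- if (floor_scale) max(1, sigma2) else sigma2
  list(slope = slope, intercept = intercept,
       var_slope = scale * sw / denom,
       var_intercept = scale * swxx / denom,
       sigma2 = sigma2)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept, weights `1 / se_out^2`, after orienting every record so the
#' exposure beta is non-negative (Egger regression is not orientation
#' invariant; this is the established convention). The intercept estimates
#' the average directional pleiotropic effect; the slope is a consistent
#' causal estimate under the InSIDE assumption. Standard errors use the
#' multiplicative residual scale floored at 1; p-values use a t-distribution
#' with k - 2 degrees of freedom.
#'
#' @param hset a `harmonized_set` with at least 3 SNPs.
#' @return an `egger_result`: list with `slope` (an `mr_estimate`) and
#'   `intercept` (list with `est`, `se`, `pval`, `n_snps`).
#' @export
mr_egger <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  k <- nrow(hset)
  if (k < 3L) abort("MR-Egger needs at least 3 SNPs, got %d", k)
  o <- orient_positive(hset)
  fit <- wls_with_intercept(o$beta_exp, o$beta_out, 1 / o$se_out^2)
  slope_se <- sqrt(fit$var_slope)
  int_se <- sqrt(fit$var_intercept)
  slope <- mr_estimate("egger_slope", fit$slope, slope_se,
                       pval_t(fit$slope, slope_se, k - 2), k,
                       scale = hset_scale(hset), df = k - 2)
  structure(list(slope = slope,
                 intercept = list(est = fit$intercept, se = int_se,
                                  pval = pval_t(fit$intercept, int_se, k - 2),
                                  n_snps = k)),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4f (SE %.4f), p = %.3g\n",
              x$intercept$est, x$intercept$se, x$intercept$pval))
  invisible(x)
}

# weighted median of values v with weights w (normalized internally):
# smallest v whose cumulative weight reaches 1/2; at an exact boundary the
# midpoint of the two adjacent values is taken (matches the plain median for
# equal weights at any parity, and returns the ratio of any SNP carrying a
# strict weight majority exactly)
weighted_median_value <- function(v, w) {
  ord <- order(v)
  v <- v[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w)
  j <- which(cum >= 0.5 - 1e-12)[1L]
  if (abs(cum[j] - 0.5) <= 1e-12 && j < length(v)) (v[j] + v[j + 1L]) / 2 else v[j]
}

boot_se <- function(hset, statistic, n_boot, seed) {
  if (n_boot < 100L) {
    warning(sprintf("n_boot = %d is small; bootstrap SE will be noisy", n_boot),
            call. = FALSE)
  }
  ests <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(hset), hset$beta_exp, hset$se_exp)
      by <- stats::rnorm(nrow(hset), hset$beta_out, hset$se_out)
      statistic(bx, by)
    }, numeric(1L))
  })
  stats::sd(ests)
}

ratio_weights <- function(beta_exp, se_out) beta_exp^2 / se_out^2

# drop non-finite ratios/weights with a message; returns index vector
finite_ratio_idx <- function(hset) {
  r <- hset$beta_out / hset$beta_exp
  ok <- is.finite(r) & is.finite(ratio_weights(hset$beta_exp, hset$se_out)) &
    hset$beta_exp != 0
  if (!all(ok)) {
    message(sprintf("%d SNP(s) with non-finite Wald ratio excluded", sum(!ok)))
  }
  which(ok)
}

#' Weighted-median estimate
#'
#' The weighted median of the per-SNP Wald ratios, with weights equal to the
#' inverse variance of the first-order ratio (`beta_exp^2 / se_out^2`).
#' Consistent when at least 50% of the weight comes from valid instruments.
#' The standard error is a parametric bootstrap: exposure and outcome betas
#' are resampled from their normal sampling distributions and the weighted
#' median recomputed (weights included).
#'
#' @param hset a `harmonized_set` with at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an `mr_estimate`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(hset, "harmonized_set"))
  idx <- finite_ratio_idx(hset)
  hs <- hset[idx, , drop = FALSE]
  k <- nrow(hs)
  if (k < 3L) abort("weighted median needs at least 3 usable SNPs, got %d", k)
  est <- weighted_median_value(hs$beta_out / hs$beta_exp,
                               ratio_weights(hs$beta_exp, hs$se_out))
  se <- boot_se(hs, function(bx, by) {
    ok <- bx != 0
    weighted_median_value(by[ok] / bx[ok], ratio_weights(bx[ok], hs$se_out[ok]))
  }, n_boot, seed)
  mr_estimate("weighted_median", est, se, pval_normal(est, se), k,
              scale = hset_scale(hset))
}

# modified Silverman bandwidth on the ratio scale
mode_bandwidth <- function(r, phi) {
  s <- stats::sd(r)
  m <- stats::mad(r)
  spread <- if (m > 0) min(s, m) else s
  if (!is.finite(spread) || spread <= 0) spread <- 1e-8
  phi * 0.9 * spread * length(r)^(-1 / 5)
}

# weighted gaussian kernel density argmax, refined with optimize()
weighted_mode_value <- function(r, w, h) {
  w <- w / sum(w)
  dens <- function(x) {
    vapply(x, function(xi) sum(w * stats::dnorm((xi - r) / h)), numeric(1L))
  }
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512L)
  f <- dens(grid)
  i <- which.max(f)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) return(grid[i])
  stats::optimize(dens, c(lo, hi), maximum = TRUE, tol = 1e-9)$maximum
}

#' Weighted-mode estimate
#'
#' Kernel-smoothed weighted density of the per-SNP Wald ratios (normal
#' kernel; bandwidth `phi` times a modified Silverman rule,
#' `0.9 min(sd, mad) k^(-1/5)`); the estimate is the density argmax.
#' Consistent when the largest weighted cluster of SNPs consists of valid
#' instruments. Standard error by parametric bootstrap as in
#' [mr_weighted_median()].
#'
#' @param hset a `harmonized_set` with at least 3 SNPs.
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an `mr_estimate`.
#' @export
mr_weighted_mode <- function(hset, phi = 1, n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(hset, "harmonized_set"))
  idx <- finite_ratio_idx(hset)
  hs <- hset[idx, , drop = FALSE]
  k <- nrow(hs)
  if (k < 3L) abort("weighted mode needs at least 3 usable SNPs, got %d", k)
  r <- hs$beta_out / hs$beta_exp
  w <- ratio_weights(hs$beta_exp, hs$se_out)
  h <- mode_bandwidth(r, phi)
  est <- weighted_mode_value(r, w, h)
  se <- boot_se(hs, function(bx, by) {
    ok <- bx != 0
    rb <- by[ok] / bx[ok]
    weighted_mode_value(rb, ratio_weights(bx[ok], hs$se_out[ok]),
                        mode_bandwidth(rb, phi))
  }, n_boot, seed)
  mr_estimate("weighted_mode", est, se, pval_normal(est, se), k,
              scale = hset_scale(hset))
}

#' I^2_GX: regression dilution of the SNP-exposure estimates
#'
#' Quantifies violation of the NOME (negligible measurement error)
#' assumption in MR-Egger: `Q_GX` is the Cochran statistic of the exposure
#' betas with weights `1 / se_exp^2` around their weighted mean, and
#' `I^2_GX = max(0, (Q_GX - (k - 1)) / Q_GX)`. Values below about 0.9 flag
#' meaningful dilution of the Egger slope, conventionally addressed with
#' SIMEX (see [simex_egger()]). For strong instruments with mean per-SNP
#' statistic F, `I^2_GX` approaches `(F - 1) / F`.
#'
#' @param hset a `harmonized_set` with at least 2 SNPs.
#' @return the I^2_GX statistic in `[0, 1]`.
#' @export
i2_gx <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  k <- nrow(hset)
  if (k < 2L) abort("I^2_GX needs at least 2 SNPs")
  # computed on the exposure betas in their harmonized orientation; with
  # arbitrary effect-allele orientation the weighted mean is near 0 and
  # I^2_GX approaches (mean F - 1) / mean F
  g <- hset$beta_exp
  w <- 1 / hset$se_exp^2
  gbar <- sum(w * g) / sum(w)
  q_gx <- sum(w * (g - gbar)^2)
  if (q_gx <= 0) return(0)
  max(0, (q_gx - (k - 1)) / q_gx)
}

#' SIMEX-corrected MR-Egger
#'
#' Simulation-extrapolation correction of the Egger slope and intercept for
#' measurement error in the exposure betas (NOME violation). For each
#' lambda > 0, noise of variance `lambda * se_exp^2` is added to the exposure
#' betas and the Egger fit recomputed, averaging coefficients over `n_sim`
#' replicates; a quadratic (default) or linear trend in lambda is then
#' extrapolated back to lambda = -1, the no-measurement-error point.
#' Variances are extrapolated the same way.
#'
#' @param hset a `harmonized_set` with at least 3 SNPs.
#' @param lambdas non-negative grid of noise multipliers, default
#'   `c(0, 0.5, 1, 1.5, 2)`.
#' @param n_sim replicates per lambda (default 1000).
#' @param seed RNG seed.
#' @param extrapolation `"quadratic"` (default) or `"linear"`.
#' @return an `egger_result` with method label `"egger_simex"`.
#' @export
simex_egger <- function(hset, lambdas = c(0, 0.5, 1, 1.5, 2), n_sim = 1000L,
                        seed = NULL, extrapolation = c("quadratic", "linear")) {
  stopifnot(inherits(hset, "harmonized_set"))
  extrapolation <- match.arg(extrapolation)
  k <- nrow(hset)
  if (k < 3L) abort("SIMEX-Egger needs at least 3 SNPs")
  if (any(lambdas < 0)) abort("lambdas must be non-negative")
  lambdas <- sort(unique(lambdas))
  plain <- mr_egger(hset)
  if (all(hset$se_exp == 0) || identical(lambdas, 0)) {
    out <- relabel_egger(plain, "egger_simex")
    return(out)
  }
  o <- orient_positive(hset)
  w <- 1 / o$se_out^2
  coefs <- t(vapply(lambdas, function(lam) {
    if (lam == 0) {
      fit <- wls_with_intercept(o$beta_exp, o$beta_out, w)
      return(c(fit$slope, fit$intercept, fit$var_slope, fit$var_intercept))
    }
    sims <- with_seed(if (is.null(seed)) NULL else seed + round(lam * 1000), {
      vapply(seq_len(n_sim), function(s) {
        bx <- o$beta_exp + stats::rnorm(k, 0, sqrt(lam) * o$se_exp)
        # re-orient the perturbed record set (noise can change signs)
        flip <- bx < 0
        by <- ifelse(flip, -o$beta_out, o$beta_out)
        fit <- wls_with_intercept(abs(bx), by, w)
        c(fit$slope, fit$intercept, fit$var_slope, fit$var_intercept)
      }, numeric(4L))
    })
    rowMeans(sims)
  }, numeric(4L)))
  if (length(lambdas) < (if (extrapolation == "quadratic") 3L else 2L)) {
    abort("too few lambdas for %s extrapolation", extrapolation)
  }
  extrapolate <- function(y) {
    fit <- if (extrapolation == "quadratic") {
      stats::lm(y ~ lambdas + I(lambdas^2))
    } else {
      stats::lm(y ~ lambdas)
    }
    if (anyNA(stats::coef(fit))) abort("SIMEX extrapolation fit is singular")
    unname(stats::predict(fit, newdata = data.frame(lambdas = -1)))
  }
  slope_est <- extrapolate(coefs[, 1L])
  int_est <- extrapolate(coefs[, 2L])
  slope_se <- sqrt(max(extrapolate(coefs[, 3L]), 1e-12))
  int_se <- sqrt(max(extrapolate(coefs[, 4L]), 1e-12))
  slope <- mr_estimate("egger_simex", slope_est, slope_se,
                       pval_t(slope_est, slope_se, k - 2), k,
                       scale = hset_scale(hset), df = k - 2)
  structure(list(slope = slope,
                 intercept = list(est = int_est, se = int_se,
                                  pval = pval_t(int_est, int_se, k - 2),
                                  n_snps = k)),
            class = "egger_result")
}

relabel_egger <- function(egger, label) {
  egger$slope$method <- label
  egger
}
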