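# Shared fixtures and independently coded oracles.
# Oracles deliberately use a different computational route than the package
# (explicit normal equations via solve(), term-by-term sums, grid scans).

make_hset <- function(beta_exp, se_exp, beta_out, se_out,
                      snp_id = sprintf("rs%03d", seq_along(beta_exp)),
                      outcome_type = "binary", ...) {
  harmonized_set(data.frame(snp_id = snp_id, beta_exp = beta_exp,
                            se_exp = se_exp, beta_out = beta_out,
                            se_out = se_out, stringsAsFactors = FALSE, ...),
                 outcome_type = outcome_type)
}

make_sumstats <- function(n = 5, seed = 1, trait_type = "continuous", ...) {
  set.seed(seed)
  alleles <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  idx <- sample.int(4, n, replace = TRUE)
  summary_stats(data.frame(
    snp_id = sprintf("rs%03d", 1:n), chrom = "1", pos = seq(1e5, by = 5e4, length.out = n),
    effect_allele = alleles[idx, 1], other_allele = alleles[idx, 2],
    eaf = runif(n, 0.1, 0.9), beta = rnorm(n, 0, 0.05),
    se = runif(n, 0.005, 0.02), stringsAsFactors = FALSE
  ), trait_name = "fixture", trait_type = trait_type, ...)
}

# weighted least squares through the normal equations, X'WX b = X'Wy
oracle_wls <- function(x, y, w, intercept = FALSE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  XtW <- t(X * w)
  unname(solve(XtW %*% X, XtW %*% y)[, 1])
}

# Cochran Q accumulated term by term in a loop
oracle_q <- function(beta_exp, beta_out, se_out, slope, intercept = 0) {
  q <- 0
  for (j in seq_along(beta_exp)) {
    pred <- intercept + slope * beta_exp[j]
    q <- q + (beta_out[j] - pred)^2 / se_out[j]^2
  }
  q
}

# weighted median by scanning the weighted CDF on a fine grid of candidate
# values: smallest value at which the CDF reaches 1/2, with the exact-boundary
# midpoint convention
oracle_wmedian <- function(r, w) {
  w <- w / sum(w)
  cdf <- function(x) sum(w[r <= x])
  grid <- sort(unique(r))
  for (i in seq_along(grid)) {
    f <- cdf(grid[i])
    if (f >= 0.5 - 1e-12) {
      if (abs(f - 0.5) <= 1e-12 && i < length(grid)) {
        return((grid[i] + grid[i + 1]) / 2)
      }
      return(grid[i])
    }
  }
  grid[length(grid)]
}

# weighted kernel density argmax on a dense grid, refined locally
oracle_wmode <- function(r, w, h) {
  w <- w / sum(w)
  dens <- function(x) vapply(x, function(xi) sum(w * dnorm((xi - r) / h)), 0)
  coarse <- seq(min(r) - 3 * h, max(r) + 3 * h, by = h / 50)
  x0 <- coarse[which.max(dens(coarse))]
  fine <- seq(x0 - h / 25, x0 + h / 25, by = 1e-7 * max(1, abs(x0)))
  fine[which.max(dens(fine))]
}

# brute-force clumping oracle: replays greedy selection by p-value with
# explicit pairwise checks, independent of the package's bookkeeping
oracle_clump <- function(tab, r2, thr, window_bp) {
  ord <- order(tab$pval, tab$chrom, tab$pos, tab$snp_id)
  removed <- rep(FALSE, nrow(tab))
  kept <- logical(nrow(tab))
  for (i in ord) {
    if (removed[i]) next
    kept[i] <- TRUE
    for (j in seq_len(nrow(tab))) {
      if (j == i || kept[j] || removed[j]) next
      if (tab$chrom[j] == tab$chrom[i] &&
          abs(tab$pos[j] - tab$pos[i]) <= window_bp &&
          r2[tab$snp_id[i], tab$snp_id[j]] >= thr) {
        removed[j] <- TRUE
      }
    }
  }
  tab$snp_id[kept]
}

expect_estimate_equal <- function(a, b, tol = 1e-10) {
  expect_equal(a$beta, b$beta, tolerance = tol)
  expect_equal(a$se, b$se, tolerance = tol)
  expect_equal(a$pval, b$pval, tolerance = tol)
}
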