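# Instrument construction: significance filtering, greedy LD clumping,
# and instrument-strength statistics (F, R^2).

#' Construct an LD matrix
#'
#' @param snp_ids character vector of SNP identifiers.
#' @param r2 square symmetric matrix of squared correlations in `[0, 1]`
#'   with unit diagonal, ordered as `snp_ids`.
#' @return an `ld_matrix` object.
#' @export
ld_matrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  k <- length(snp_ids)
  if (!is.numeric(r2) || nrow(r2) != k || ncol(r2) != k) {
    abort("`r2` must be a %d x %d numeric matrix", k, k)
  }
  if (anyDuplicated(snp_ids)) abort("duplicate SNP ids in LD matrix")
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    abort("LD r^2 values must lie in [0, 1]")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) abort("LD matrix is not symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) abort("LD matrix diagonal must be 1")
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from TSV
#'
#' Accepts either a square matrix with SNP ids as header row and first
#' column, or a 3-column long format (`snp_a`, `snp_b`, `r2`); pairs absent
#' from the long format are taken as r^2 = 0.
#'
#' @param path file path.
#' @return an `ld_matrix` object.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  sep <- detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  header <- names(raw)
  if (ncol(raw) == 3L && all(tolower(header) %in% c("snp_a", "snp_b", "r2"))) {
    names(raw) <- tolower(header)
    ids <- unique(c(raw$snp_a, raw$snp_b))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 1
    for (i in seq_len(nrow(raw))) {
      m[raw$snp_a[i], raw$snp_b[i]] <- raw$r2[i]
      m[raw$snp_b[i], raw$snp_a[i]] <- raw$r2[i]
    }
    return(ld_matrix(ids, m))
  }
  ids <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  ld_matrix(ids, m)
}

#' Filter to genome-wide significant variants
#'
#' @param table a `sumstats` object.
#' @param p_threshold p-value threshold; records with `pval < p_threshold`
#'   are retained in input order. Default 5e-8, the conventional genome-wide
#'   significance level.
#' @return filtered `sumstats`; a warning is raised when nothing survives.
#' @export
select_genomewide <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "sumstats"))
  if (!is_scalar_number(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    abort("`p_threshold` must lie in (0, 1]")
  }
  keep <- table$pval < p_threshold
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning(sprintf("no variant reaches p < %g for %s", p_threshold,
                    attr(table, "trait_name")), call. = FALSE)
  }
  out
}

#' Greedy LD clumping
#'
#' Iteratively retains the unprocessed SNP with the smallest p-value (ties
#' broken by chromosome, position, then SNP id) and removes every SNP on the
#' same chromosome within `window_kb` whose r^2 with it is at least
#' `r2_threshold`. SNPs absent from `ld` are treated as unlinked and kept,
#' with a warning. SNPs lacking chromosome or position are treated as within
#' the window whenever an r^2 entry exists.
#'
#' @param table a `sumstats` object.
#' @param ld an `ld_matrix`, or `NULL` to treat all SNPs as unlinked.
#' @param r2_threshold clumping r^2 threshold (default 0.001).
#' @param window_kb window half-width in kilobases (default 10000, i.e. 10 Mb).
#' @return the retained subset of `table`, in input order.
#' @export
greedy_clump <- function(table, ld = NULL, r2_threshold = 0.001,
                         window_kb = 10000) {
  stopifnot(inherits(table, "sumstats"))
  if (!is.null(ld) && !inherits(ld, "ld_matrix")) abort("`ld` must be an ld_matrix")
  if (nrow(table) == 0L) return(table)
  ids <- table$snp_id
  if (!is.null(ld)) {
    absent <- setdiff(ids, ld$snp_ids)
    if (length(absent)) {
      warning(sprintf("%d SNP(s) absent from the LD matrix treated as unlinked: %s",
                      length(absent),
                      paste(utils::head(absent, 5L), collapse = ", ")),
              call. = FALSE)
    }
  }
  ord <- order(table$pval, table$chrom, table$pos, table$snp_id)
  status <- rep("pending", nrow(table))  # pending / kept / removed
  window_bp <- window_kb * 1000
  for (i in ord) {
    if (status[i] != "pending") next
    status[i] <- "kept"
    if (is.null(ld) || !(ids[i] %in% ld$snp_ids)) next
    for (j in seq_along(ids)) {
      if (status[j] != "pending" || !(ids[j] %in% ld$snp_ids)) next
      r2 <- ld$r2[ids[i], ids[j]]
      if (r2 < r2_threshold) next
      same_window <- if (!is.na(table$chrom[i]) && !is.na(table$chrom[j]) &&
                         !is.na(table$pos[i]) && !is.na(table$pos[j])) {
        table$chrom[i] == table$chrom[j] &&
          abs(table$pos[i] - table$pos[j]) <= window_bp
      } else TRUE
      if (same_window) status[j] <- "removed"
    }
  }
  table[status == "kept", , drop = FALSE]
}

#' Per-SNP F-statistic
#'
#' `F = (beta / se)^2`, the squared z-score of the SNP-exposure association.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @return numeric vector of F values.
#' @export
snp_f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) abort("`se` must be > 0")
  (beta / se)^2
}

#' Variance explained by an instrument
#'
#' Default estimator: `R^2 = sum_j 2 p_j (1 - p_j) beta_j^2`, valid when the
#' exposure is continuous and standardized to unit variance. The alternative
#' `"f_based"` estimator sums per-SNP `F / (F + n - 2)` and needs per-SNP
#' sample sizes (or `n`).
#'
#' @param table a `sumstats` object with `eaf` and `beta` for all records.
#' @param method `"af"` (allele-frequency based, default) or `"f_based"`.
#' @param n sample size override for `method = "f_based"` when the table has
#'   no `n` column.
#' @return total R^2, clipped to `[0, 1]`.
#' @export
instrument_r2 <- function(table, method = c("af", "f_based"), n = NULL) {
  stopifnot(inherits(table, "sumstats"))
  method <- match.arg(method)
  if (nrow(table) == 0L) return(0)
  if (method == "af") {
    bad <- which(is.na(table$eaf))
    if (length(bad)) {
      abort("missing eaf for record(s): %s",
            paste(utils::head(table$snp_id[bad], 5L), collapse = ", "))
    }
    r2 <- sum(2 * table$eaf * (1 - table$eaf) * table$beta^2)
  } else {
    n_j <- if (!is.null(n)) rep(n, nrow(table)) else table$n
    if (any(is.na(n_j))) abort("f_based R^2 needs per-SNP sample sizes")
    f <- snp_f_statistic(table$beta, table$se)
    r2 <- sum(f / (f + n_j - 2))
  }
  min(max(r2, 0), 1)
}

#' Overall instrument F-statistic
#'
#' `F = R^2 (n - k - 1) / ((1 - R^2) k)`; values below 10 conventionally
#' flag weak-instrument bias.
#'
#' @param r2_total variance explained, in `[0, 1)`.
#' @param n exposure GWAS sample size.
#' @param k number of SNPs in the instrument.
#' @return the overall F value.
#' @export
overall_f <- function(r2_total, n, k) {
  if (!is_scalar_number(r2_total) || r2_total < 0 || r2_total >= 1) {
    abort("`r2_total` must lie in [0, 1)")
  }
  if (!is_scalar_number(n) || !is_scalar_number(k) || k < 1 || n <= k + 1) {
    abort("need n > k + 1 >= 2")
  }
  r2_total * (n - k - 1) / ((1 - r2_total) * k)
}

#' Instrument-strength summary
#'
#' @param table a `sumstats` object (typically post-clumping).
#' @param n exposure sample size; defaults to the median of the table's `n`.
#' @param r2_method passed to [instrument_r2()].
#' @return an `instrument_stats` list: `n_snps`, `r2_total`, `f_overall`,
#'   `f_per_snp`.
#' @export
instrument_stats <- function(table, n = NULL, r2_method = "af") {
  stopifnot(inherits(table, "sumstats"))
  n <- n %||% stats::median(table$n, na.rm = TRUE)
  r2 <- instrument_r2(table, method = r2_method, n = n)
  f_per <- snp_f_statistic(table$beta, table$se)
  f_all <- if (is.finite(n)) overall_f(r2, n, nrow(table)) else NA_real_
  structure(list(n_snps = nrow(table), r2_total = r2, f_overall = f_all,
                 f_per_snp = stats::setNames(f_per, table$snp_id)),
            class = "instrument_stats")
}

#' @export
print.instrument_stats <- function(x, ...) {
  cat(sprintf("<instrument_stats> %d SNP(s); R^2 = %.4g; overall F = %.4g; mean per-SNP F = %.4g\n",
              x$n_snps, x$r2_total, x$f_overall, mean(x$f_per_snp)))
  invisible(x)
}
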