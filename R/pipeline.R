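# Orchestration: run the full per-analysis battery and emit report tables.

#' Assemble an analysis configuration
#'
#' @param exposure either a `sumstats` object or a list
#'   `list(path =, column_map =, trait_name =, trait_type =, unit_note =)`
#'   passed to [read_sumstats()].
#' @param outcomes a single outcome spec or an unnamed list of them (same
#'   forms as `exposure`); several outcomes sharing one exposure instrument
#'   model subsite-stratified analyses.
#' @param ld an `ld_matrix`, a path readable by [read_ld_matrix()], or `NULL`
#'   to skip clumping-by-LD (SNPs treated as unlinked).
#' @param p_select genome-wide significance threshold (default 5e-8).
#' @param clump_r2 clumping r^2 threshold (default 0.001).
#' @param window_kb clumping window in kb (default 10000).
#' @param palindrome_maf palindromic minor-allele-frequency bound (default 0.3).
#' @param presso_gate run MR-PRESSO only when the IVW Cochran Q p-value is
#'   below `presso_alpha` (default TRUE, mirroring a Q-gated outlier check).
#' @param presso_alpha gate level (default 0.05).
#' @param simex_i2_threshold run SIMEX-Egger when I^2_GX falls below this
#'   (default 0.90).
#' @param se_method Wald-ratio SE order (`"first_order"` default).
#' @param n_boot bootstrap replicates for median/mode (default 1000).
#' @param phi weighted-mode bandwidth factor (default 1).
#' @param simex_lambdas,simex_n_sim SIMEX grid and replicates.
#' @param presso_n_distributions MR-PRESSO simulated datasets (default 1000).
#' @param seed master seed; per-component seeds are derived from it.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(exposure, outcomes, ld = NULL,
                            p_select = 5e-8, clump_r2 = 0.001,
                            window_kb = 10000, palindrome_maf = 0.3,
                            presso_gate = TRUE, presso_alpha = 0.05,
                            simex_i2_threshold = 0.90,
                            se_method = "first_order",
                            n_boot = 1000L, phi = 1,
                            simex_lambdas = c(0, 0.5, 1, 1.5, 2),
                            simex_n_sim = 1000L,
                            presso_n_distributions = 1000L,
                            seed = 1L) {
  if (inherits(outcomes, "sumstats") ||
      (is.list(outcomes) && !is.null(outcomes$path))) {
    outcomes <- list(outcomes)
  }
  structure(list(exposure = exposure, outcomes = outcomes, ld = ld,
                 p_select = p_select, clump_r2 = clump_r2,
                 window_kb = window_kb, palindrome_maf = palindrome_maf,
                 presso_gate = presso_gate, presso_alpha = presso_alpha,
                 simex_i2_threshold = simex_i2_threshold,
                 se_method = se_method, n_boot = as.integer(n_boot), phi = phi,
                 simex_lambdas = simex_lambdas,
                 simex_n_sim = as.integer(simex_n_sim),
                 presso_n_distributions = as.integer(presso_n_distributions),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

resolve_table <- function(spec, default_type = "continuous") {
  if (inherits(spec, "sumstats")) return(spec)
  if (is.list(spec) && !is.null(spec$path)) {
    return(read_sumstats(spec$path, column_map = spec$column_map,
                         trait_name = spec$trait_name %||% basename(spec$path),
                         trait_type = spec$trait_type %||% default_type,
                         unit_note = spec$unit_note %||% ""))
  }
  abort("exposure/outcome spec must be a sumstats object or a list with $path")
}

estimate_row <- function(est, exposure, outcome, extra_method = NULL) {
  scale <- est$scale
  data.frame(exposure = exposure, outcome = outcome,
             method = extra_method %||% est$method,
             n_snps = est$n_snps, beta = est$beta, se = est$se,
             ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
             scale = scale,
             or = if (scale == "log_or") exp(est$beta) else NA_real_,
             or_low = if (scale == "log_or") exp(est$ci_low) else NA_real_,
             or_high = if (scale == "log_or") exp(est$ci_high) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Run the full MR analysis battery
#'
#' For each exposure x outcome pair: genome-wide significance filtering,
#' greedy LD clumping, harmonization, the four estimators (IVW, MR-Egger,
#' weighted median, weighted mode; single-SNP instruments fall back to the
#' Wald ratio), Cochran Q for the IVW and Egger fits, the Egger intercept
#' and I^2_GX; SIMEX-corrected Egger when I^2_GX falls below the configured
#' threshold; MR-PRESSO (and its outlier-corrected IVW) when the IVW Q
#' p-value falls below the gate. Binary-outcome estimates carry odds-ratio
#' columns (`exp` of beta and CI). An analysis in which no SNP survives
#' harmonization yields a `"no instrument"` status row rather than an error.
#'
#' @param cfg an [analysis_config()].
#' @return a `report_bundle`: `estimates` and `diagnostics` data.frames,
#'   `audit` (per-analysis harmonization and gating log) and `scatter`
#'   (per-analysis data.frames of per-SNP effects for plotting).
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  exposure <- resolve_table(cfg$exposure)
  ld <- cfg$ld
  if (is.character(ld)) ld <- read_ld_matrix(ld)
  exp_name <- attr(exposure, "trait_name")

  selected <- suppressWarnings(select_genomewide(exposure, cfg$p_select))
  clumped <- suppressWarnings(greedy_clump(selected, ld, cfg$clump_r2,
                                           cfg$window_kb))
  estimates <- list()
  diagnostics <- list()
  audit <- list(exposure = exp_name,
                n_input = nrow(exposure), n_selected = nrow(selected),
                n_clumped = nrow(clumped), analyses = list())
  scatter <- list()

  for (oi in seq_along(cfg$outcomes)) {
    outcome <- resolve_table(cfg$outcomes[[oi]], default_type = "binary")
    out_name <- attr(outcome, "trait_name")
    hset <- harmonize(clumped, outcome, cfg$palindrome_maf)
    k <- nrow(hset)
    analysis_audit <- list(outcome = out_name, harmonization = attr(hset, "audit"),
                           n_snps = k, gates = list())
    if (k == 0L) {
      estimates[[length(estimates) + 1L]] <- data.frame(
        exposure = exp_name, outcome = out_name, method = "none",
        n_snps = 0L, beta = NA_real_, se = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, pval = NA_real_, scale = NA_character_,
        or = NA_real_, or_low = NA_real_, or_high = NA_real_,
        stringsAsFactors = FALSE)
      estimates[[length(estimates)]]$status <- "no instrument"
      analysis_audit$status <- "no instrument"
      audit$analyses[[length(audit$analyses) + 1L]] <- analysis_audit
      next
    }
    rows <- list()
    diag_row <- list(exposure = exp_name, outcome = out_name, n_snps = k)
    seed_base <- cfg$seed + 1000L * oi

    ivw <- suppressMessages(mr_ivw(hset))
    rows[[length(rows) + 1L]] <- estimate_row(ivw, exp_name, out_name)
    if (k >= 3L) {
      egger <- mr_egger(hset)
      wmed <- mr_weighted_median(hset, n_boot = cfg$n_boot, seed = seed_base + 1L)
      wmode <- mr_weighted_mode(hset, phi = cfg$phi, n_boot = cfg$n_boot,
                                seed = seed_base + 2L)
      rows[[length(rows) + 1L]] <- estimate_row(egger$slope, exp_name, out_name)
      rows[[length(rows) + 1L]] <- estimate_row(wmed, exp_name, out_name)
      rows[[length(rows) + 1L]] <- estimate_row(wmode, exp_name, out_name)
      diag_row$egger_intercept <- egger$intercept$est
      diag_row$egger_intercept_se <- egger$intercept$se
      diag_row$egger_intercept_pval <- egger$intercept$pval
      q_egger <- if (k >= 3L) cochran_q(hset, egger) else NULL
      diag_row$q_egger <- q_egger$q
      diag_row$q_egger_df <- q_egger$df
      diag_row$q_egger_pval <- q_egger$pval
    } else {
      egger <- NULL
    }
    if (k >= 2L) {
      q_ivw <- cochran_q(hset, ivw)
      diag_row$q_ivw <- q_ivw$q
      diag_row$q_ivw_df <- q_ivw$df
      diag_row$q_ivw_pval <- q_ivw$pval
      diag_row$i2_gx <- i2_gx(hset)
    } else {
      q_ivw <- NULL
      diag_row$i2_gx <- NA_real_
    }

    simex_triggered <- !is.null(egger) && is.finite(diag_row$i2_gx) &&
      diag_row$i2_gx < cfg$simex_i2_threshold
    diag_row$simex_triggered <- simex_triggered
    if (simex_triggered) {
      sx <- simex_egger(hset, lambdas = cfg$simex_lambdas,
                        n_sim = cfg$simex_n_sim, seed = seed_base + 3L)
      rows[[length(rows) + 1L]] <- estimate_row(sx$slope, exp_name, out_name)
      diag_row$simex_intercept <- sx$intercept$est
    }
    analysis_audit$gates$simex <- simex_triggered

    presso_run <- k >= 4L &&
      (!cfg$presso_gate || (!is.null(q_ivw) && q_ivw$pval < cfg$presso_alpha))
    diag_row$presso_run <- presso_run
    if (presso_run) {
      pr <- suppressMessages(mr_presso(hset,
                                       n_distributions = cfg$presso_n_distributions,
                                       seed = seed_base + 4L))
      diag_row$presso_global_pval <- pr$global_pval
      diag_row$presso_n_outliers <- length(pr$outlier_indices)
      diag_row$presso_distortion_pval <- pr$distortion_pval
      rows[[length(rows) + 1L]] <- estimate_row(pr$corrected_estimate, exp_name,
                                                out_name,
                                                extra_method = "ivw_outlier_corrected")
    }
    analysis_audit$gates$presso <- presso_run

    est_df <- do.call(rbind, rows)
    est_df$status <- "ok"
    estimates[[length(estimates) + 1L]] <- est_df
    diagnostics[[length(diagnostics) + 1L]] <-
      as.data.frame(diag_row, stringsAsFactors = FALSE)
    wald <- wald_ratio(hset, se_method = cfg$se_method)
    scatter[[out_name]] <- data.frame(
      snp_id = hset$snp_id, beta_exp = hset$beta_exp, se_exp = hset$se_exp,
      beta_out = hset$beta_out, se_out = hset$se_out,
      wald_beta = wald$beta, wald_se = wald$se, stringsAsFactors = FALSE)
    audit$analyses[[length(audit$analyses) + 1L]] <- analysis_audit
  }

  structure(list(estimates = do.call(rbind, estimates),
                 diagnostics = if (length(diagnostics)) {
                   merge_diag_rows(diagnostics)
                 } else NULL,
                 audit = audit, scatter = scatter),
            class = "report_bundle")
}

# rbind diagnostics rows whose optional columns differ
merge_diag_rows <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (col in setdiff(cols, names(r))) r[[col]] <- NA
    r[, cols, drop = FALSE]
  }))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d estimate row(s), %d analysis/-es\n",
              nrow(x$estimates), length(x$audit$analyses)))
  print.data.frame(x$estimates)
  invisible(x)
}

fmt_or_ci <- function(beta, lo, hi) {
  sprintf("%.2f (%.2f-%.2f)", exp(beta), exp(lo), exp(hi))
}

#' Format a report bundle as publication-style rows
#'
#' `style = "table1"` yields one row per exposure x outcome with
#' "OR (95% CI)" and p-value per estimator plus the SNP count (binary
#' outcomes), or "beta (SE)" formatting for continuous outcomes.
#' `style = "supp2"` returns the diagnostics block (Q statistics, Egger
#' intercept, I^2_GX, SIMEX/PRESSO gating and outlier counts).
#'
#' @param bundle a `report_bundle`.
#' @param style `"table1"` or `"supp2"`.
#' @return data.frame of formatted rows.
#' @export
format_table <- function(bundle, style = c("table1", "supp2")) {
  style <- match.arg(style)
  stopifnot(inherits(bundle, "report_bundle"))
  if (is.null(bundle$estimates) || nrow(bundle$estimates) == 0L) {
    abort("empty report bundle")
  }
  if (style == "supp2") return(bundle$diagnostics)
  est <- bundle$estimates
  keys <- unique(est[, c("exposure", "outcome")])
  methods <- c(ivw = "ivw", weighted_median = "weighted_median",
               weighted_mode = "weighted_mode", egger = "egger_slope",
               wald = "wald")
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- est[est$exposure == keys$exposure[i] & est$outcome == keys$outcome[i], ]
    row <- list(exposure = keys$exposure[i], outcome = keys$outcome[i],
                n_snps = max(sub$n_snps, na.rm = TRUE))
    for (m in methods) {
      r <- sub[sub$method == m, ]
      label <- names(methods)[methods == m]
      if (nrow(r) == 0L || is.na(r$beta[1L])) next
      r <- r[1L, ]
      if (identical(r$scale, "log_or")) {
        row[[paste0(label, "_or_ci")]] <- fmt_or_ci(r$beta, r$ci_low, r$ci_high)
      } else {
        row[[paste0(label, "_beta_se")]] <- sprintf("%.2f (%.2f)", r$beta, r$se)
      }
      row[[paste0(label, "_pval")]] <- sprintf("%.3g", r$pval)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  merge_diag_rows(out)
}

#' Write all components of a report bundle
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if absent).
#' @param format `"tsv"`, `"csv"` or `"json"` for the tabular components;
#'   the audit log is always JSON.
#' @return invisibly, the written paths.
#' @export
write_report_bundle <- function(bundle, dir, format = "tsv") {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, paste0("estimates.", format))
  write_report(bundle$estimates, p, format)
  paths <- c(paths, p)
  if (!is.null(bundle$diagnostics)) {
    p <- file.path(dir, paste0("diagnostics.", format))
    write_report(bundle$diagnostics, p, format)
    paths <- c(paths, p)
  }
  for (nm in names(bundle$scatter)) {
    p <- file.path(dir, sprintf("scatter_%s.%s", gsub("[^A-Za-z0-9_.-]", "_", nm),
                                format))
    write_report(bundle$scatter[[nm]], p, format)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "audit.json")
  jsonlite::write_json(bundle$audit, p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, p))
}
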