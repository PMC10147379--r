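# Reading, validating and writing GWAS summary-statistics tables and reports.

SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n", "n_cases")
SUMSTATS_MANDATORY <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary-statistics table
#'
#' Validates and normalizes per-SNP GWAS association records into a
#' `sumstats` object (a `data.frame` with trait metadata attached).
#' Alleles are uppercased; records violating the type invariants
#' (non-positive or non-finite standard error, non-finite beta, identical or
#' non-ACGT alleles, p-value outside `(0, 1]`, duplicate SNP id) are dropped
#' and counted in the audit attached as `attr(x, "audit")`. Effect-allele
#' frequencies outside `[0, 1]` are set to `NA` rather than dropping the row.
#'
#' @param df data.frame with (a subset of) columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#'   `n_cases`. `snp_id`, the alleles, `beta` and `se` are mandatory.
#' @param trait_name trait label, e.g. `"BMI"`.
#' @param trait_type `"continuous"` (beta in SD units) or `"binary"`
#'   (beta on the log odds-ratio scale).
#' @param unit_note free-text unit annotation, e.g.
#'   `"per 1 SD BMI (4.81 kg/m^2)"`.
#' @return a `sumstats` data.frame; `attr(, "audit")` holds
#'   `n_input`, `n_kept` and a named vector of drop reasons.
#' @export
summary_stats <- function(df, trait_name, trait_type = c("continuous", "binary"),
                          unit_note = "") {
  trait_type <- match.arg(trait_type)
  if (!is.data.frame(df)) abort("`df` must be a data.frame")
  missing_cols <- setdiff(SUMSTATS_MANDATORY, names(df))
  if (length(missing_cols)) {
    abort("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "))
  }
  n_input <- nrow(df)
  out <- data.frame(
    snp_id = as.character(df$snp_id),
    chrom = if ("chrom" %in% names(df)) as.character(df$chrom) else NA_character_,
    pos = if ("pos" %in% names(df)) suppressWarnings(as.integer(df$pos)) else NA_integer_,
    effect_allele = toupper(as.character(df$effect_allele)),
    other_allele = toupper(as.character(df$other_allele)),
    eaf = if ("eaf" %in% names(df)) suppressWarnings(as.numeric(df$eaf)) else NA_real_,
    beta = suppressWarnings(as.numeric(df$beta)),
    se = suppressWarnings(as.numeric(df$se)),
    pval = if ("pval" %in% names(df)) suppressWarnings(as.numeric(df$pval)) else NA_real_,
    n = if ("n" %in% names(df)) suppressWarnings(as.numeric(df$n)) else NA_real_,
    n_cases = if ("n_cases" %in% names(df)) suppressWarnings(as.numeric(df$n_cases)) else NA_real_,
    stringsAsFactors = FALSE
  )
  # p-values are recomputed from the z-score when absent: several source GWAS
  # ship beta/se only.
  no_p <- is.na(out$pval) & is.finite(out$beta) & is.finite(out$se) & out$se > 0
  out$pval[no_p] <- pval_normal(out$beta[no_p], out$se[no_p])
  # p-values of extreme hits underflow double precision (|z| > ~38.6) and are
  # printed as 0 by many GWAS tools; clamp to the smallest positive double
  # rather than dropping the strongest instruments
  underflow <- !is.na(out$pval) & out$pval == 0 & is.finite(out$beta) &
    is.finite(out$se) & out$se > 0
  out$pval[underflow] <- .Machine$double.xmin

  drops <- c(bad_numeric = 0L, bad_se = 0L, bad_alleles = 0L, bad_pval = 0L,
             duplicate_snp = 0L)
  bad_numeric <- !is.finite(out$beta) | !is.finite(out$se) | is.na(out$snp_id) |
    out$snp_id == ""
  drops["bad_numeric"] <- sum(bad_numeric)
  keep <- !bad_numeric
  bad_se <- keep & out$se <= 0
  drops["bad_se"] <- sum(bad_se)
  keep <- keep & !bad_se
  bad_alleles <- keep & (!(out$effect_allele %in% VALID_ALLELES) |
                           !(out$other_allele %in% VALID_ALLELES) |
                           out$effect_allele == out$other_allele)
  drops["bad_alleles"] <- sum(bad_alleles)
  keep <- keep & !bad_alleles
  bad_pval <- keep & (!is.finite(out$pval) | out$pval <= 0 | out$pval > 1)
  drops["bad_pval"] <- sum(bad_pval)
  keep <- keep & !bad_pval
  dup <- keep & duplicated(out$snp_id)
  drops["duplicate_snp"] <- sum(dup)
  keep <- keep & !dup

  out$eaf[!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1)] <- NA_real_
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_name = trait_name,
            trait_type = trait_type,
            unit_note = unit_note,
            audit = list(n_input = n_input, n_kept = nrow(out), dropped = drops),
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s (%s), %d SNP(s)\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  audit <- attr(x, "audit")
  if (!is.null(audit) && audit$n_input > audit$n_kept) {
    cat(sprintf("  %d of %d input record(s) dropped at validation\n",
                audit$n_input - audit$n_kept, audit$n_input))
  }
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more row(s)\n", nrow(x) - 10L))
  invisible(x)
}

# keep sumstats attributes through `[` subsetting of rows
#' @export
`[.sumstats` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(SUMSTATS_MANDATORY %in% names(out))) {
    for (a in c("trait_name", "trait_type", "unit_note", "audit")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- c("sumstats", "data.frame")
  }
  out
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) abort("file is empty: %s", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_tab >= n_com) "\t" else ","
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a TSV or CSV (delimiter auto-detected from the header line) and maps
#' file columns onto the canonical schema via `column_map`. Records failing
#' validation are dropped and counted (see [summary_stats()]).
#'
#' @param path file path.
#' @param column_map named character vector or list mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`, `n_cases`) to column names in the file.
#'   Canonical names absent from the map are looked up verbatim in the header.
#'   May also be a path to a JSON or flat YAML file holding that mapping.
#' @inheritParams summary_stats
#' @return a `sumstats` object.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = basename(path),
                          trait_type = c("continuous", "binary"), unit_note = "") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) abort("file not found: %s", path)
  if (is.character(column_map) && length(column_map) == 1L &&
      file.exists(column_map) && is.null(names(column_map))) {
    column_map <- read_column_map(column_map)
  }
  column_map <- as.list(column_map %||% list())
  sep <- detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  mapped <- list()
  for (col in SUMSTATS_COLS) {
    src <- column_map[[col]] %||% col
    if (src %in% names(raw)) mapped[[col]] <- raw[[src]]
  }
  missing_cols <- setdiff(SUMSTATS_MANDATORY, names(mapped))
  if (length(missing_cols)) {
    abort("mapped column(s) not found in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(mapped, stringsAsFactors = FALSE)
  # a mostly unparseable beta/se column signals a wrong column map, not noise
  for (col in c("beta", "se")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    if (nrow(df) > 0 && mean(is.na(vals)) > 0.5) {
      abort("column '%s' in %s is numeric in fewer than half the rows", col, path)
    }
  }
  summary_stats(df, trait_name = trait_name, trait_type = trait_type,
                unit_note = unit_note)
}

#' Read a column map from JSON or flat YAML
#'
#' JSON is parsed with jsonlite; YAML support covers the flat
#' `canonical: file_column` form that column maps use.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return named list mapping canonical names to file column names.
#' @export
read_column_map <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.+)$", lines))
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) abort("unparseable column-map line: %s", lines[bad][1L])
  vals <- vapply(parts, `[`, "", 3L)
  vals <- gsub('^["\']|["\']$', "", vals)
  stats::setNames(as.list(vals), vapply(parts, `[`, "", 2L))
}

#' Write a report table
#'
#' Writes report rows (estimates, diagnostics, audits) as TSV, CSV or JSON.
#' Numeric values are written with 15 significant digits so that a read-back
#' round-trips to at least 12 significant digits.
#'
#' @param rows non-empty data.frame of report rows.
#' @param path output path.
#' @param format one of `"tsv"`, `"csv"`, `"json"`.
#' @export
write_report <- function(rows, path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    abort("`rows` must be a non-empty data.frame")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) abort("directory does not exist: %s", dir)
  if (format == "json") {
    jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = FALSE)
    return(invisible(path))
  }
  out <- as.data.frame(rows, stringsAsFactors = FALSE)
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA, sprintf("%.15g", out[[col]]))
    }
  }
  utils::write.table(out, path, sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"` or `"json"`; inferred from the extension
#'   when omitted.
#' @return data.frame of report rows.
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("tsv", "csv", "json")) abort("cannot infer format of %s", path)
  }
  if (format == "json") {
    return(jsonlite::fromJSON(path))
  }
  utils::read.table(path, header = TRUE, sep = if (format == "tsv") "\t" else ",",
                    stringsAsFactors = FALSE, check.names = FALSE, na.strings = "NA")
}
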