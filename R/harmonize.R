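# Harmonization of exposure and outcome summary statistics onto a common
# effect-allele orientation.

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is a SNP palindromic?
#'
#' A palindromic (ambiguous-strand) SNP has complementary alleles, i.e. the
#' allele pair is A/T or C/G, so strand cannot be resolved from the alleles
#' alone.
#'
#' @param effect_allele,other_allele single-letter alleles in `{A, C, G, T}`.
#' @return logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  if (any(!(effect_allele %in% VALID_ALLELES)) ||
      any(!(other_allele %in% VALID_ALLELES))) {
    abort("alleles must be one of A, C, G, T")
  }
  unname(ALLELE_COMPLEMENT[effect_allele] == other_allele)
}

complement_alleles <- function(x) unname(ALLELE_COMPLEMENT[toupper(x)])

harmonized_statuses <- c("aligned", "flipped", "palindromic_kept",
                         "dropped_palindromic", "dropped_incompatible")

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins the two tables on SNP id and re-orients each outcome record to
#' the exposure's effect allele. Non-palindromic SNPs: a direct allele match
#' is kept as `aligned`; a match after swapping effect/other alleles flips the
#' sign of the outcome beta (and `eaf_out := 1 - eaf_out`) and is marked
#' `flipped`; the same logic is applied after strand-complementing the outcome
#' alleles; anything else (including non-ACGT records) is
#' `dropped_incompatible`. Palindromic SNPs cannot be resolved by allele
#' labels: they are kept (`palindromic_kept`) only when both effect-allele
#' frequencies are available and both minor-allele frequencies fall below
#' `palindrome_maf_threshold`; orientation is then inferred from whether the
#' two frequencies sit on the same side of 0.5 (disagreement flips the outcome
#' beta); otherwise they are `dropped_palindromic`.
#'
#' @param exposure,outcome `sumstats` objects with unique SNP ids.
#' @param palindrome_maf_threshold minor-allele-frequency bound below which a
#'   palindromic SNP is considered inferable (default 0.3).
#' @return a `harmonized_set`: a data.frame of the retained records
#'   (`snp_id`, exposure-orientation alleles, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `eaf_exp`, `eaf_out`, `status`) with attributes
#'   `audit` (per-status counts over all merged SNPs), `exposure_name`,
#'   `outcome_name`, `outcome_type`.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_threshold = 0.3) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  if (anyDuplicated(exposure$snp_id)) abort("duplicate snp_id in exposure table")
  if (anyDuplicated(outcome$snp_id)) abort("duplicate snp_id in outcome table")
  if (!is_scalar_number(palindrome_maf_threshold) ||
      palindrome_maf_threshold <= 0 || palindrome_maf_threshold > 0.5) {
    abort("`palindrome_maf_threshold` must lie in (0, 0.5]")
  }

  common <- intersect(exposure$snp_id, outcome$snp_id)
  ei <- match(common, exposure$snp_id)
  oi <- match(common, outcome$snp_id)
  k <- length(common)
  status <- character(k)
  beta_out <- outcome$beta[oi]
  eaf_out <- outcome$eaf[oi]

  for (idx in seq_len(k)) {
    ea_e <- exposure$effect_allele[ei[idx]]
    oa_e <- exposure$other_allele[ei[idx]]
    ea_o <- outcome$effect_allele[oi[idx]]
    oa_o <- outcome$other_allele[oi[idx]]
    ok <- all(c(ea_e, oa_e, ea_o, oa_o) %in% VALID_ALLELES)
    if (!ok) {
      status[idx] <- "dropped_incompatible"
      next
    }
    if (is_palindromic(ea_e, oa_e)) {
      # allele labels are uninformative for palindromes; outcome alleles must
      # still name the same pair (possibly swapped/complemented)
      pair_ok <- setequal(c(ea_o, oa_o), c(ea_e, oa_e)) ||
        setequal(complement_alleles(c(ea_o, oa_o)), c(ea_e, oa_e))
      maf_e <- min(exposure$eaf[ei[idx]], 1 - exposure$eaf[ei[idx]])
      maf_o <- min(eaf_out[idx], 1 - eaf_out[idx])
      if (!pair_ok) {
        status[idx] <- "dropped_incompatible"
      } else if (is.na(maf_e) || is.na(maf_o) ||
                 maf_e >= palindrome_maf_threshold ||
                 maf_o >= palindrome_maf_threshold) {
        status[idx] <- "dropped_palindromic"
      } else {
        same_side <- (exposure$eaf[ei[idx]] < 0.5) == (eaf_out[idx] < 0.5)
        if (!same_side) {
          beta_out[idx] <- -beta_out[idx]
          eaf_out[idx] <- 1 - eaf_out[idx]
        }
        status[idx] <- "palindromic_kept"
      }
      next
    }
    orient <- align_non_palindromic(ea_e, oa_e, ea_o, oa_o)
    status[idx] <- orient
    if (orient == "flipped") {
      beta_out[idx] <- -beta_out[idx]
      eaf_out[idx] <- 1 - eaf_out[idx]
    }
  }

  audit <- table(factor(status, levels = harmonized_statuses))
  keep <- status %in% c("aligned", "flipped", "palindromic_kept")
  records <- data.frame(
    snp_id = common,
    chrom = exposure$chrom[ei],
    pos = exposure$pos[ei],
    effect_allele = exposure$effect_allele[ei],
    other_allele = exposure$other_allele[ei],
    beta_exp = exposure$beta[ei],
    se_exp = exposure$se[ei],
    beta_out = beta_out,
    se_out = outcome$se[oi],
    eaf_exp = exposure$eaf[ei],
    eaf_out = eaf_out,
    pval_exp = exposure$pval[ei],
    pval_out = outcome$pval[oi],
    status = status,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(records) <- NULL
  harmonized_set(records,
                 exposure_name = attr(exposure, "trait_name"),
                 outcome_name = attr(outcome, "trait_name"),
                 outcome_type = attr(outcome, "trait_type"),
                 audit = as.list(audit))
}

# aligned / flipped / dropped_incompatible for a non-palindromic SNP
align_non_palindromic <- function(ea_e, oa_e, ea_o, oa_o) {
  if (ea_o == ea_e && oa_o == oa_e) return("aligned")
  if (ea_o == oa_e && oa_o == ea_e) return("flipped")
  ea_c <- complement_alleles(ea_o)
  oa_c <- complement_alleles(oa_o)
  if (ea_c == ea_e && oa_c == oa_e) return("aligned")
  if (ea_c == oa_e && oa_c == ea_e) return("flipped")
  "dropped_incompatible"
}

#' Construct a harmonized set
#'
#' Low-level constructor used by [harmonize()] and the synthetic-data module;
#' validates the per-record invariants (positive standard errors).
#'
#' @param records data.frame with at least `snp_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`; optionally `eaf_exp`, `eaf_out`, `status`.
#' @param exposure_name,outcome_name trait labels.
#' @param outcome_type `"binary"` (log odds-ratio scale) or `"continuous"`.
#' @param audit named list of per-status counts.
#' @return a `harmonized_set` object.
#' @export
harmonized_set <- function(records, exposure_name = "exposure",
                           outcome_name = "outcome",
                           outcome_type = c("binary", "continuous"),
                           audit = NULL) {
  outcome_type <- match.arg(outcome_type)
  needed <- c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort("harmonized records lack column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  # se_out must be strictly positive (it weights every estimator); se_exp = 0
  # is permitted as the no-measurement-error limiting case
  if (nrow(records) > 0 &&
      (any(records$se_exp < 0) || any(records$se_out <= 0))) {
    abort("retained harmonized records must have positive standard errors")
  }
  if (!"status" %in% names(records)) records$status <- "aligned"
  if (!"eaf_exp" %in% names(records)) records$eaf_exp <- NA_real_
  if (!"eaf_out" %in% names(records)) records$eaf_out <- NA_real_
  structure(records,
            exposure_name = exposure_name,
            outcome_name = outcome_name,
            outcome_type = outcome_type,
            audit = audit,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s (%s outcome), %d retained SNP(s)\n",
              attr(x, "exposure_name"), attr(x, "outcome_name"),
              attr(x, "outcome_type"), nrow(x)))
  audit <- attr(x, "audit")
  if (!is.null(audit)) {
    drops <- unlist(audit)
    cat("  statuses:", paste(sprintf("%s=%d", names(drops), drops), collapse = ", "),
        "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more row(s)\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
`[.harmonized_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("beta_exp", "beta_out") %in% names(out))) {
    for (a in c("exposure_name", "outcome_name", "outcome_type", "audit")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- c("harmonized_set", "data.frame")
  }
  out
}
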