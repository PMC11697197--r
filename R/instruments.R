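#' Select genetic instruments for an exposure
#'
#' Retains genome-wide-significant SNPs (`pval < instrument_p_threshold`)
#' and prunes them to approximate independence with [greedy_clump()]. When
#' no LD matrix is supplied all significant SNPs are retained (treated as
#' unlinked) and a warning is logged, the appropriate behaviour for
#' synthetic panels generated without LD.
#'
#' @param exposure a [gwas_table()] for the exposure trait.
#' @param config an [analysis_config()].
#' @param ld an [ld_matrix()] covering the significant SNPs, or `NULL`.
#' @return A `gwas_table` of instruments (possibly empty), sorted by
#'   chromosome and position.
#' @export
select_instruments <- function(exposure, config = analysis_config(), ld = NULL) {
  stopifnot(inherits(exposure, "gwas_table"))
  if (nrow(exposure) == 0) stop("select_instruments: empty exposure table", call. = FALSE)
  sig <- exposure[exposure$pval < config$instrument_p_threshold, , drop = FALSE]
  if (nrow(sig) > 0 && !is.null(ld)) {
    sig <- greedy_clump(sig, ld, r2_threshold = config$clump_r2,
                        window_kb = config$clump_window_kb)
  } else if (nrow(sig) > 0) {
    message("select_instruments: no LD matrix supplied; treating the ",
            nrow(sig), " significant SNPs as independent")
  }
  out <- sig[order(sig$chr, sig$pos, sig$snp), , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("trait_id", "trait_label", "trait_kind")] <-
    attributes(exposure)[c("trait_id", "trait_label", "trait_kind")]
  class(out) <- class(exposure)
  out
}

#' Greedy LD clumping
#'
#' Iteratively keeps the remaining SNP with the smallest p-value and
#' discards every other SNP on the same chromosome within `window_kb`
#' kilobases whose squared correlation with it is at least `r2_threshold`.
#' P-value ties are broken by (chromosome, position, id) so the result is
#' deterministic.
#'
#' @param records a `gwas_table` or data frame of SNP records.
#' @param ld an [ld_matrix()]; every record's `snp` must appear in it.
#' @param r2_threshold squared-correlation threshold at or above which a
#'   neighbouring SNP is pruned.
#' @param window_kb window in kilobases.
#' @return The retained records, sorted by (chr, pos).
#' @export
greedy_clump <- function(records, ld, r2_threshold, window_kb) {
  stopifnot(inherits(ld, "ld_matrix"))
  df <- as.data.frame(records)
  if (nrow(df) == 0) return(records[0, , drop = FALSE])
  missing_ld <- setdiff(df$snp, ld$snp_ids)
  if (length(missing_ld) > 0) {
    stop("greedy_clump: SNP(s) absent from the LD matrix: ",
         paste(utils::head(missing_ld, 5), collapse = ", "), call. = FALSE)
  }
  ord <- order(df$pval, df$chr, df$pos, df$snp)
  df <- df[ord, , drop = FALSE]
  keep <- character(0)
  window_bp <- window_kb * 1000
  while (nrow(df) > 0) {
    lead <- df[1, ]
    keep <- c(keep, lead$snp)
    near <- df$chr == lead$chr & abs(df$pos - lead$pos) <= window_bp
    r2 <- ld$r2[lead$snp, df$snp]
    prune <- near & r2 >= r2_threshold
    prune[1] <- TRUE  # the lead itself leaves the pool
    df <- df[!prune, , drop = FALSE]
  }
  out <- as.data.frame(records)
  out <- out[out$snp %in% keep, , drop = FALSE]
  out <- out[order(out$chr, out$pos, out$snp), , drop = FALSE]
  rownames(out) <- NULL
  if (inherits(records, "gwas_table")) {
    attributes(out)[c("trait_id", "trait_label", "trait_kind")] <-
      attributes(records)[c("trait_id", "trait_label", "trait_kind")]
    class(out) <- class(records)
  }
  out
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the two tables to a common effect allele on the SNPs they share.
#' Outcome records whose alleles are swapped relative to the exposure have
#' their effect sign flipped and allele frequency complemented; strand
#' flips (A/T, C/G complements) are matched after complementing the outcome
#' alleles. Palindromic SNPs (A/T or C/G pairs), whose strand cannot be
#' resolved from the alleles, are retained only when both allele
#' frequencies are available, both lie outside the ambiguity band
#' `0.5 +/- palindrome_eaf_band`, and they agree in orientation; otherwise
#' they are dropped. Counts of SNPs handled by each rule are kept in the
#' `provenance` attribute.
#'
#' @param exposure,outcome [gwas_table()] objects.
#' @param palindrome_eaf_band half-width of the frequency ambiguity band.
#' @return A `harmonized_set`: a data frame of per-SNP effect pairs with
#'   columns `snp`, `beta_exp`, `se_exp`, `pval_exp`, `eaf_exp`,
#'   `beta_out`, `se_out`, `pval_out`, `eaf_out`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_band = 0.08) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  common <- intersect(exposure$snp, outcome$snp)
  if (length(common) == 0) {
    stop("harmonize: no SNPs shared between '", trait_id(exposure),
         "' and '", trait_id(outcome), "'", call. = FALSE)
  }
  ex <- exposure[match(common, exposure$snp), ]
  ou <- outcome[match(common, outcome$snp), ]

  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_y <- ou$effect_allele; oa_y <- ou$other_allele
  pal <- is_palindromic(ea_x, oa_x)

  same <- ea_y == ea_x & oa_y == oa_x
  swap <- ea_y == oa_x & oa_y == ea_x
  flip <- COMPLEMENT[ea_y] == ea_x & COMPLEMENT[oa_y] == oa_x
  flipswap <- COMPLEMENT[ea_y] == oa_x & COMPLEMENT[oa_y] == ea_x

  beta_out <- ou$beta
  eaf_out <- ou$eaf
  keep <- rep(FALSE, length(common))
  n_same <- n_swap <- n_flip <- n_pal_keep <- n_pal_drop <- n_incompat <- 0L

  for (i in seq_along(common)) {
    if (pal[i]) {
      # orientation must come from allele frequency
      aligned <- same[i]          # letters already match exposure coding
      swapped <- !aligned && swap[i]
      if (!aligned && !swapped) { n_incompat <- n_incompat + 1L; next }
      e_x <- ex$eaf[i]
      e_y <- if (swapped) 1 - ou$eaf[i] else ou$eaf[i]
      band_ok <- !is.na(e_x) && !is.na(e_y) &&
        abs(e_x - 0.5) > palindrome_eaf_band &&
        abs(e_y - 0.5) > palindrome_eaf_band
      if (band_ok && sign(e_x - 0.5) == sign(e_y - 0.5)) {
        keep[i] <- TRUE
        if (swapped) { beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i] }
        n_pal_keep <- n_pal_keep + 1L
      } else {
        n_pal_drop <- n_pal_drop + 1L
      }
    } else if (same[i] || flip[i]) {
      keep[i] <- TRUE
      n_same <- n_same + same[i]
      n_flip <- n_flip + flip[i]
    } else if (swap[i] || flipswap[i]) {
      keep[i] <- TRUE
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      n_swap <- n_swap + 1L
      n_flip <- n_flip + flipswap[i]
    } else {
      n_incompat <- n_incompat + 1L
    }
  }

  pairs <- data.frame(snp = common,
                      beta_exp = ex$beta, se_exp = ex$se,
                      pval_exp = ex$pval, eaf_exp = ex$eaf,
                      beta_out = beta_out, se_out = ou$se,
                      pval_out = ou$pval, eaf_out = eaf_out,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  harmonized_set(pairs,
                 exposure_id = trait_id(exposure),
                 outcome_id = trait_id(outcome),
                 outcome_kind = trait_kind(outcome),
                 provenance = list(n_exposure = nrow(exposure),
                                   n_outcome = nrow(outcome),
                                   n_common = length(common),
                                   n_same = as.integer(n_same),
                                   n_swapped = as.integer(n_swap),
                                   n_strand_flipped = as.integer(n_flip),
                                   n_palindromic_kept = n_pal_keep,
                                   n_palindromic_dropped = n_pal_drop,
                                   n_incompatible = n_incompat))
}

#' Construct a harmonized exposure/outcome effect set
#'
#' Low-level constructor used by [harmonize()] and by the simulation
#' helpers; validates the pair invariants (positive SEs, unique SNP ids).
#'
#' @param pairs data frame with columns `snp`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out` (optionally `pval_exp`, `pval_out`, `eaf_exp`,
#'   `eaf_out`).
#' @param exposure_id,outcome_id trait identifiers.
#' @param outcome_kind `"continuous"` or `"binary"`.
#' @param provenance optional list of per-rule counts.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(pairs, exposure_id = "exposure",
                           outcome_id = "outcome",
                           outcome_kind = "continuous",
                           provenance = list()) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  need <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out")
  stopifnot(all(need %in% names(pairs)))
  for (col in c("pval_exp", "pval_out", "eaf_exp", "eaf_out")) {
    if (!col %in% names(pairs)) pairs[[col]] <- NA_real_
  }
  if (anyDuplicated(pairs$snp)) stop("harmonized_set: duplicate snp ids", call. = FALSE)
  if (nrow(pairs) > 0 && (any(pairs$se_exp <= 0) || any(pairs$se_out <= 0))) {
    stop("harmonized_set: standard errors must be positive", call. = FALSE)
  }
  rownames(pairs) <- NULL
  structure(pairs, exposure_id = exposure_id, outcome_id = outcome_id,
            outcome_kind = outcome_kind, provenance = provenance,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s, %d SNPs\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x)))
  NextMethod()
}

# Subset a harmonized_set by row index, keeping metadata.
subset_harmonized <- function(h, idx) {
  pairs <- as.data.frame(h)[idx, , drop = FALSE]
  harmonized_set(pairs,
                 exposure_id = attr(h, "exposure_id"),
                 outcome_id = attr(h, "outcome_id"),
                 outcome_kind = attr(h, "outcome_kind"),
                 provenance = attr(h, "provenance"))
}

#' Exclude instruments associated with the outcome
#'
#' Removes harmonized pairs whose outcome-side p-value falls below
#' `p_threshold`, the guard against reverse causation and direct outcome
#' association. Idempotent; never increases the pair count.
#'
#' @param h a `harmonized_set`.
#' @param p_threshold outcome p-value threshold.
#' @return The filtered `harmonized_set`, with the number of exclusions
#'   appended to its provenance.
#' @export
exclude_outcome_associated <- function(h, p_threshold = 5e-8) {
  stopifnot(inherits(h, "harmonized_set"))
  drop <- !is.na(h$pval_out) & h$pval_out < p_threshold
  out <- subset_harmonized(h, !drop)
  prov <- attr(h, "provenance")
  prov$n_outcome_associated_excluded <- sum(drop) +
    (prov$n_outcome_associated_excluded %||% 0L)
  attr(out, "provenance") <- prov
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
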