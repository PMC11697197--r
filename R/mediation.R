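#' Product-of-coefficients mediation effect
#'
#' The indirect effect of the exposure on the outcome through one mediator:
#' the product of the exposure-to-mediator effect `beta1` and the
#' mediator-to-outcome effect `beta2`.
#'
#' @param beta1 exposure-to-mediator causal effect.
#' @param beta2 mediator-to-outcome causal effect.
#' @return `beta1 * beta2`.
#' @export
mediation_effect <- function(beta1, beta2) beta1 * beta2

#' Delta-method (Sobel) standard error of a mediation effect
#'
#' `sqrt(beta2^2 se1^2 + beta1^2 se2^2)`; an uncertainty companion to
#' [mediation_effect()].
#'
#' @param beta1,se1 first-step effect and standard error.
#' @param beta2,se2 second-step effect and standard error.
#' @return The approximate standard error of `beta1 * beta2`.
#' @export
sobel_se <- function(beta1, se1, beta2, se2) {
  sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
}

#' Proportion of the total effect that is mediated
#'
#' Expressed in percent and signed: a mediator working against the total
#' effect yields a negative proportion, and proportions above 100% are
#' passed through unchanged.
#'
#' @param mediation_effect indirect effect `beta1 * beta2`.
#' @param total_effect total exposure-to-outcome causal effect (non-zero).
#' @return `100 * mediation_effect / total_effect`.
#' @export
mediation_proportion <- function(mediation_effect, total_effect) {
  if (any(total_effect == 0)) {
    stop("mediation_proportion: total effect is zero; proportion undefined",
         call. = FALSE)
  }
  100 * mediation_effect / total_effect
}

#' One full MR analysis between two traits
#'
#' Runs the standard chain: instrument selection on the exposure,
#' harmonization against the outcome, optional exclusion of
#' outcome-associated SNPs, then IVW plus (when at least three instruments
#' survive) the MR-Egger intercept test.
#'
#' @param exposure,outcome [gwas_table()] objects.
#' @param config an [analysis_config()].
#' @param ld optional [ld_matrix()] for clumping.
#' @param exclude_outcome_snps drop instruments whose outcome p-value is
#'   below `config$outcome_exclusion_p` (used when the outcome is the
#'   disease endpoint).
#' @return A list with `h` (the final `harmonized_set`), `ivw` (the
#'   [ivw()] result), `egger` (the [egger()] result or `NULL`), and
#'   `n_snp`. Returns `NULL` with a warning when fewer than two
#'   instruments survive.
#' @export
mr_analysis <- function(exposure, outcome, config = analysis_config(),
                        ld = NULL, exclude_outcome_snps = FALSE) {
  instruments <- suppressMessages(select_instruments(exposure, config, ld))
  if (nrow(instruments) == 0) {
    warning("mr_analysis: no instruments for '", trait_id(exposure), "'",
            call. = FALSE)
    return(NULL)
  }
  h <- harmonize(instruments, outcome, config$palindrome_eaf_band)
  if (exclude_outcome_snps) {
    h <- exclude_outcome_associated(h, config$outcome_exclusion_p)
  }
  if (nrow(h) < 2) {
    warning("mr_analysis: fewer than 2 instruments survive for '",
            trait_id(exposure), "' -> '", trait_id(outcome), "'", call. = FALSE)
    return(NULL)
  }
  fit <- ivw(h, config)
  eg <- if (nrow(h) >= 3) egger(h, config$pleiotropy_alpha) else NULL
  list(h = h, ivw = fit, egger = eg, n_snp = nrow(h))
}

#' Two-step mediation Mendelian randomization
#'
#' Implements the two-step screen: (0) the total exposure-to-outcome
#' effect; (1) MR of the exposure on every candidate mediator, with BH-FDR
#' across the family; (2) MR of every mediator on the outcome (instruments
#' selected from the mediator's own GWAS, outcome-associated SNPs
#' excluded), again with BH-FDR. A mediator is reported when both steps
#' are significant at `config$fdr_alpha` and neither step's Egger
#' intercept is flagged at `config$pleiotropy_alpha`. Each reported row
#' carries `beta1`, `beta2`, their product, a Sobel standard error, the
#' total effect and the signed proportion mediated (percent).
#'
#' @param exposure a [gwas_table()] for the exposure.
#' @param mediators named list of [gwas_table()] objects, one per
#'   candidate mediator.
#' @param outcome a [gwas_table()] for the outcome.
#' @param config an [analysis_config()].
#' @param ld optional [ld_matrix()].
#' @return A data frame of `mediation_result` rows (one per eligible
#'   mediator; zero rows when none qualify), with attributes
#'   `total_effect` (the step-0 [mr_estimate()]), `screen1` and `screen2`
#'   (the two [family_filter()] q-value sets over all analysable
#'   mediators), and `all_mediators` (the unfiltered per-mediator table).
#' @export
two_step_mediation <- function(exposure, mediators, outcome,
                               config = analysis_config(), ld = NULL) {
  stopifnot(is.list(mediators), length(mediators) > 0)
  if (is.null(names(mediators)) || any(names(mediators) == "")) {
    names(mediators) <- vapply(mediators, trait_id, character(1))
  }

  total_fit <- mr_analysis(exposure, outcome, config, ld,
                           exclude_outcome_snps = TRUE)
  if (is.null(total_fit)) {
    stop("two_step_mediation: cannot estimate the total effect", call. = FALSE)
  }
  total_effect <- total_fit$ivw$estimate$beta

  rows <- lapply(names(mediators), function(id) {
    med <- mediators[[id]]
    s1 <- mr_analysis(exposure, med, config, ld, exclude_outcome_snps = FALSE)
    s2 <- mr_analysis(med, outcome, config, ld, exclude_outcome_snps = TRUE)
    if (is.null(s1) || is.null(s2)) {
      warning("two_step_mediation: skipping mediator '", id,
              "' (insufficient instruments)", call. = FALSE)
      return(NULL)
    }
    data.frame(
      mediator_id = id,
      n_snp1 = s1$n_snp, beta1 = s1$ivw$estimate$beta,
      se1 = s1$ivw$estimate$se, pval1 = s1$ivw$estimate$pval,
      egger_int1 = if (is.null(s1$egger)) NA_real_ else s1$egger$intercept$intercept,
      egger_p1 = if (is.null(s1$egger)) NA_real_ else s1$egger$intercept$pval,
      n_snp2 = s2$n_snp, beta2 = s2$ivw$estimate$beta,
      se2 = s2$ivw$estimate$se, pval2 = s2$ivw$estimate$pval,
      egger_int2 = if (is.null(s2$egger)) NA_real_ else s2$egger$intercept$intercept,
      egger_p2 = if (is.null(s2$egger)) NA_real_ else s2$egger$intercept$pval,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(tab) || nrow(tab) == 0) {
    stop("two_step_mediation: no analysable mediators", call. = FALSE)
  }

  screen1 <- family_filter(data.frame(id = tab$mediator_id, pval = tab$pval1),
                           config$fdr_alpha)
  screen2 <- family_filter(data.frame(id = tab$mediator_id, pval = tab$pval2),
                           config$fdr_alpha)
  tab$qval1 <- screen1$qval[match(tab$mediator_id, screen1$id)]
  tab$qval2 <- screen2$qval[match(tab$mediator_id, screen2$id)]
  tab$pleiotropy_ok <- (is.na(tab$egger_p1) | tab$egger_p1 >= config$pleiotropy_alpha) &
    (is.na(tab$egger_p2) | tab$egger_p2 >= config$pleiotropy_alpha)
  tab$mediation_effect <- mediation_effect(tab$beta1, tab$beta2)
  tab$sobel_se <- sobel_se(tab$beta1, tab$se1, tab$beta2, tab$se2)
  tab$total_effect <- total_effect
  tab$proportion_pct <- mediation_proportion(tab$mediation_effect, total_effect)

  eligible <- tab$qval1 < config$fdr_alpha & tab$qval2 < config$fdr_alpha &
    tab$pleiotropy_ok
  out <- tab[eligible, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            total_effect = total_fit$ivw$estimate,
            screen1 = screen1, screen2 = screen2,
            all_mediators = tab,
            class = c("mediation_result", "data.frame"))
}

#' Cross-source consistency of causal estimates
#'
#' Restricts to traits significant in every source and marks a trait
#' consistent when its estimated effects share one sign across all sources
#' (every pairwise product of betas positive).
#'
#' @param per_source named list (one element per data source, at least
#'   two) of data frames with columns `id`, `beta` and `qval`.
#' @param alpha per-source q-value threshold defining "significant".
#' @return A `source_comparison` data frame with one row per trait
#'   significant in all sources: `id`, one `beta_<source>` column per
#'   source, and `consistent`.
#' @export
cross_source_consistency <- function(per_source, alpha = 0.05) {
  if (!is.list(per_source) || length(per_source) < 2) {
    stop("cross_source_consistency: need at least 2 sources", call. = FALSE)
  }
  if (is.null(names(per_source)) || any(names(per_source) == "")) {
    stop("cross_source_consistency: sources must be named", call. = FALSE)
  }
  sig_ids <- lapply(per_source, function(s) s$id[s$qval < alpha])
  common <- Reduce(intersect, sig_ids)
  betas <- vapply(per_source, function(s) s$beta[match(common, s$id)],
                  numeric(length(common)))
  betas <- matrix(betas, nrow = length(common),
                  dimnames = list(NULL, names(per_source)))
  consistent <- apply(betas, 1, function(b) all(b > 0) || all(b < 0))
  out <- data.frame(id = common, stringsAsFactors = FALSE)
  for (src in names(per_source)) out[[paste0("beta_", src)]] <- betas[, src]
  out$consistent <- as.logical(consistent)
  structure(out, alpha = alpha, class = c("source_comparison", "data.frame"))
}
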