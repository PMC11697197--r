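#' Packaged reference screen tables
#'
#' Machine-readable copies of the numeric results of a published
#' BMI -> blood-metabolite -> cholelithiasis two-step MR screen (GIANT BMI
#' exposure `ieu-a-835`, 249 UK Biobank NMR metabolites
#' `ebi-a-GCST90092803`..`GCST90093051`, FinnGen cholelithiasis outcome):
#' the 176 metabolic traits associated with BMI after FDR and pleiotropy
#' filtering, the 85 traits associated with cholelithiasis, and the 49
#' mediators in their intersection with mediation effects and proportions.
#' Used by [verify_fixtures()] for arithmetic self-checks.
#'
#' @return A list of three data frames: `bmi_metabolites` (176 rows),
#'   `metabolites_cholelithiasis` (85 rows), `mediation` (49 rows).
#' @export
reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "mrmediate",
                                  mustWork = TRUE)
  list(
    bmi_metabolites = read.delim(path("bmi_metabolite_screen.tsv")),
    metabolites_cholelithiasis =
      read.delim(path("metabolite_cholelithiasis_screen.tsv")),
    mediation = read.delim(path("bmi_mediation_results.tsv")))
}

# one unit in the k-th printed significant figure of x
last_digit_unit <- function(x, sig = 3) 10^(floor(log10(abs(x))) - (sig - 1))

# is `printed` consistent with recomputation from inputs rounded to 3 sig
# figs?  `lo`/`hi` bound the recomputed value over the input rounding
# interval; one extra unit in the printed last digit absorbs the printed
# value's own rounding.
consistent_with_rounding <- function(printed, lo, hi) {
  u <- last_digit_unit(printed)
  printed >= lo - u & printed <= hi + u
}

egger_p_bounds <- function(intercept, se, n_snp) {
  ui <- last_digit_unit(intercept) / 2
  us <- last_digit_unit(se) / 2
  t_hi <- (abs(intercept) + ui) / pmax(se - us, .Machine$double.eps)
  t_lo <- pmax(abs(intercept) - ui, 0) / (se + us)
  list(lo = 2 * pt(-t_hi, n_snp - 2), hi = 2 * pt(-t_lo, n_snp - 2))
}

#' Verify the packaged reference tables arithmetically
#'
#' Recomputes every derivable cell of the packaged tables from its printed
#' inputs -- odds ratios and 95% confidence bounds from (beta, se), Egger
#' intercept p-values from (intercept, se, n_snp) via the t distribution
#' with `n_snp - 2` degrees of freedom, mediation effects as `beta1*beta2`
#' -- and checks each against the printed value, allowing for the printed
#' inputs' 3-significant-figure rounding. Also checks the structural
#' claims: the mediator table is exactly the intersection of the two
#' screens (49 traits), and the total effect implied by
#' `mediation_effect / proportion` is constant across mediators within 1%.
#'
#' @param fixtures the list returned by [reference_tables()].
#' @return A data frame with one row per check (`check`, `n`,
#'   `n_discrepant`), with the implied total effect in attribute
#'   `implied_total_effect`.
#' @export
verify_fixtures <- function(fixtures = reference_tables()) {
  t2 <- fixtures$bmi_metabolites
  t3 <- fixtures$metabolites_cholelithiasis
  t4 <- fixtures$mediation

  checks <- list()
  add <- function(name, ok) {
    checks[[length(checks) + 1]] <<- data.frame(
      check = name, n = length(ok), n_discrepant = sum(!ok),
      stringsAsFactors = FALSE)
  }

  # odds ratios and CI bounds from the printed (beta, se)
  ub <- last_digit_unit(t3$beta) / 2
  us <- last_digit_unit(t3$se) / 2
  add("or_from_beta", consistent_with_rounding(
    t3$or_, exp(t3$beta - ub), exp(t3$beta + ub)))
  add("lci95", consistent_with_rounding(
    t3$lci95, exp(t3$beta - ub - 1.96 * (t3$se + us)),
    exp(t3$beta + ub - 1.96 * (t3$se - us))))
  add("uci95", consistent_with_rounding(
    t3$uci95, exp(t3$beta - ub + 1.96 * (t3$se - us)),
    exp(t3$beta + ub + 1.96 * (t3$se + us))))

  # Egger intercept p-values from (intercept, se, n_snp)
  for (tab in list(list("egger_p_bmi_screen", t2$egger_intercept, t2$egger_se,
                        t2$n_snp, t2$egger_pval),
                   list("egger_p_outcome_screen", t3$egger_intercept,
                        t3$egger_se, t3$n_snp, t3$egger_pval),
                   list("egger_p_mediation_step1", t4$egger_intercept1,
                        t4$egger_se1, t4$n_snp1, t4$egger_pval1),
                   list("egger_p_mediation_step2", t4$egger_intercept2,
                        t4$egger_se2, t4$n_snp2, t4$egger_pval2))) {
    b <- egger_p_bounds(tab[[2]], tab[[3]], tab[[4]])
    add(tab[[1]], consistent_with_rounding(tab[[5]], b$lo, b$hi))
  }

  # mediation effects as products of the printed betas
  u1 <- last_digit_unit(t4$beta1) / 2
  u2 <- last_digit_unit(t4$beta2) / 2
  corners <- cbind((t4$beta1 - u1) * (t4$beta2 - u2),
                   (t4$beta1 - u1) * (t4$beta2 + u2),
                   (t4$beta1 + u1) * (t4$beta2 - u2),
                   (t4$beta1 + u1) * (t4$beta2 + u2))
  add("mediation_product", consistent_with_rounding(
    t4$mediation_effect, apply(corners, 1, min), apply(corners, 1, max)))

  # structural: mediators are the intersection of the two screens
  inter <- intersect(t2$id, t3$id)
  add("mediator_intersection",
      c(length(inter) == nrow(t4), setequal(inter, t4$id)))

  # implied total effect constant across mediators
  implied <- t4$mediation_effect / (t4$proportion_pct / 100)
  spread <- (max(implied) - min(implied)) / mean(implied)
  add("implied_total_effect_constant", spread < 0.01)

  out <- do.call(rbind, checks)
  attr(out, "implied_total_effect") <- mean(implied)
  out
}

#' Run the full four-step mediation workflow
#'
#' Orchestrates the analysis end to end: (1) total exposure-to-outcome
#' effect; (2) exposure-to-mediator screen with FDR and the
#' Egger-intercept pleiotropy screen; (3) mediator-to-outcome screen with
#' FDR, the pleiotropy screen and exclusion of outcome-associated SNPs;
#' (4) mediation synthesis (effects, Sobel SEs, proportions). Every stage
#' is recorded in a run manifest for traceability.
#'
#' @param exposure a [gwas_table()].
#' @param mediators named list of [gwas_table()]s.
#' @param outcome a [gwas_table()].
#' @param config an [analysis_config()].
#' @param ld optional [ld_matrix()].
#' @return A list with `mediation` (the [two_step_mediation()] result),
#'   `total_effect` (the step-1 [mr_estimate()]) and `manifest` (config,
#'   input row counts, per-stage provenance, seeds).
#' @export
run_full_analysis <- function(exposure, mediators, outcome,
                              config = analysis_config(), ld = NULL) {
  if (identical(trait_id(exposure), trait_id(outcome))) {
    warning("run_full_analysis: exposure and outcome share a source label; ",
            "two-sample assumptions may be violated", call. = FALSE)
  }
  res <- two_step_mediation(exposure, mediators, outcome, config, ld)
  total <- attr(res, "total_effect")
  screen1 <- attr(res, "screen1")
  screen2 <- attr(res, "screen2")
  manifest <- list(
    package_version = as.character(utils::packageVersion("mrmediate")),
    config = unclass(config),
    inputs = list(
      exposure = list(id = trait_id(exposure), n_snp = nrow(exposure)),
      mediators = lapply(mediators, function(mt)
        list(id = trait_id(mt), n_snp = nrow(mt))),
      outcome = list(id = trait_id(outcome), n_snp = nrow(outcome))),
    stages = list(
      total_effect = list(method = total$method, n_snp = total$n_snp,
                          beta = total$beta, se = total$se, pval = total$pval),
      exposure_to_mediators = list(n_tested = nrow(screen1),
                                   n_significant = sum(screen1$significant)),
      mediators_to_outcome = list(n_tested = nrow(screen2),
                                  n_significant = sum(screen2$significant)),
      mediation_synthesis = list(n_reported = nrow(res))),
    seed = config$rng_seed)
  list(mediation = res, total_effect = total, manifest = manifest)
}

#' Serialize a mediation result to tab-separated text
#'
#' Writes the mediation table in the reporting layout (`mediator_id`,
#' per-step effect columns, `mediation_effect`, `sobel_se`,
#' `total_effect`, `proportion_pct`), with numbers at full precision.
#'
#' @param result the data frame returned by [two_step_mediation()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_mediation_table <- function(result, path) {
  out <- as.data.frame(result)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.12g", x))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
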