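#' Analysis configuration
#'
#' Bundles the thresholds that drive instrument selection and inference.
#' The defaults are the conventional genome-wide criteria: instruments at
#' p < 5e-8, clumped at r-squared < 0.001 within a 10,000 kb window, SNPs
#' associated with the outcome at p < 5e-8 excluded, heterogeneity and
#' pleiotropy screens at 0.05, and FDR control at 0.05.
#'
#' @param instrument_p_threshold genome-wide significance threshold for
#'   selecting instruments.
#' @param clump_r2 r-squared threshold above which nearby SNPs are pruned.
#' @param clump_window_kb clumping window in kilobases; two SNPs are "near"
#'   when `|pos_i - pos_j| <= clump_window_kb * 1000` on the same chromosome.
#' @param outcome_exclusion_p SNPs with an outcome p-value below this are
#'   excluded from the instrument set.
#' @param q_test_alpha significance level of Cochran's Q deciding between
#'   fixed- and multiplicative-random-effects IVW.
#' @param fdr_alpha family-wise false-discovery-rate threshold.
#' @param pleiotropy_alpha significance level of the Egger-intercept screen.
#' @param palindrome_eaf_band half-width of the allele-frequency ambiguity
#'   band around 0.5 within which palindromic SNPs are dropped.
#' @param median_bootstrap_n parametric-bootstrap resamples for the
#'   weighted-median standard error.
#' @param presso_sim_n simulated datasets for the MR-PRESSO empirical null.
#' @param rng_seed seed for all stochastic components.
#' @return A list with class `analysis_config`.
#' @export
analysis_config <- function(instrument_p_threshold = 5e-8,
                            clump_r2 = 0.001,
                            clump_window_kb = 10000,
                            outcome_exclusion_p = 5e-8,
                            q_test_alpha = 0.05,
                            fdr_alpha = 0.05,
                            pleiotropy_alpha = 0.05,
                            palindrome_eaf_band = 0.08,
                            median_bootstrap_n = 1000,
                            presso_sim_n = 1000,
                            rng_seed = 1L) {
  cfg <- list(instrument_p_threshold = instrument_p_threshold,
              clump_r2 = clump_r2,
              clump_window_kb = as.integer(clump_window_kb),
              outcome_exclusion_p = outcome_exclusion_p,
              q_test_alpha = q_test_alpha,
              fdr_alpha = fdr_alpha,
              pleiotropy_alpha = pleiotropy_alpha,
              palindrome_eaf_band = palindrome_eaf_band,
              median_bootstrap_n = as.integer(median_bootstrap_n),
              presso_sim_n = as.integer(presso_sim_n),
              rng_seed = as.integer(rng_seed))
  probs <- c("instrument_p_threshold", "clump_r2", "outcome_exclusion_p",
             "q_test_alpha", "fdr_alpha", "pleiotropy_alpha")
  for (p in probs) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0 || cfg[[p]] >= 1) {
      stop("analysis_config: ", p, " must lie in (0, 1)", call. = FALSE)
    }
  }
  if (cfg$clump_window_kb <= 0 || cfg$median_bootstrap_n <= 0 ||
      cfg$presso_sim_n <= 0) {
    stop("analysis_config: window and counts must be positive", call. = FALSE)
  }
  class(cfg) <- "analysis_config"
  cfg
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
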