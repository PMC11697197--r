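#' Configuration of the three-trait GWAS generator
#'
#' Describes a linked exposure -> mediator(s) -> outcome system observed
#' through GWAS summary statistics. Each trait gets its own instrument
#' block of `n_snp` SNPs: the exposure block carries per-SNP effects
#' `gamma ~ N(0, gamma_sd^2)` on the exposure, and each mediator block
#' carries effects of the same scale directly on its mediator (these are
#' what make the mediator-to-outcome step estimable). Effects propagate
#' along the causal paths: a mediator inherits `theta1 * gamma` from the
#' exposure block, and the outcome receives
#' `(tau_direct + sum(theta1 * theta2)) * gamma` from the exposure block
#' and `theta2 * delta` from each mediator block. Observed effect sizes
#' add estimation noise at the per-study standard-error scales, and
#' horizontal pleiotropy can be layered on the outcome and mediators,
#' balanced (`N(0, pleiotropy_sd^2)`) or directional
#' (`N(pleiotropy_mean, pleiotropy_sd^2)`), aligned with the
#' exposure-increasing allele.
#'
#' The defaults describe a desk-scale study: 30 strong instruments per
#' trait (instrument effect SD at least ten times the exposure-side
#' standard error), one mediator with `theta1 = 0.2`, `theta2 = 0.3` and
#' direct effect `tau_direct = 0.3`, so the true total effect is 0.36 and
#' the true proportion mediated 100*0.06/0.36 = 16.7%.
#'
#' @param n_snp SNPs per instrument block (>= 4).
#' @param n_mediators number of mediator traits.
#' @param gamma_sd SD of per-SNP instrument effects.
#' @param theta1 exposure-to-mediator effect(s), recycled to `n_mediators`.
#' @param theta2 mediator-to-outcome effect(s), recycled likewise.
#' @param tau_direct direct exposure-to-outcome effect.
#' @param se_exp,se_med,se_out per-study standard-error scales
#'   (homoscedastic across SNPs).
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_mean mean pleiotropic effect (directional mode).
#' @param pleiotropy_sd SD of pleiotropic effects (balanced/directional).
#' @param maf_range allele-frequency interval, a subset of (0, 0.5].
#' @param seed RNG seed; generation is bit-reproducible.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_snp = 30, n_mediators = 1,
                              gamma_sd = 0.05,
                              theta1 = 0.2, theta2 = 0.3, tau_direct = 0.3,
                              se_exp = 0.004, se_med = 0.004, se_out = 0.01,
                              pleiotropy_mode = c("none", "balanced", "directional"),
                              pleiotropy_mean = 0.05, pleiotropy_sd = 0.01,
                              maf_range = c(0.05, 0.5), seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (n_snp < 4) stop("simulation_config: n_snp must be >= 4", call. = FALSE)
  if (any(c(gamma_sd, se_exp, se_med, se_out) <= 0)) {
    stop("simulation_config: scales must be positive", call. = FALSE)
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("simulation_config: maf_range must be an interval within (0, 0.5]",
         call. = FALSE)
  }
  structure(list(n_snp = as.integer(n_snp),
                 n_mediators = as.integer(n_mediators),
                 gamma_sd = gamma_sd,
                 theta1 = rep_len(theta1, n_mediators),
                 theta2 = rep_len(theta2, n_mediators),
                 tau_direct = tau_direct,
                 se_exp = se_exp, se_med = se_med, se_out = se_out,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "simulation_config")
}

# non-palindromic ordered allele pairs
ALLELE_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                         "G", "A", "G", "T", "T", "C", "T", "G"),
                       ncol = 2, byrow = TRUE)

# draw pleiotropic effects for one trait under the configured mode
draw_pleiotropy <- function(n, config) {
  switch(config$pleiotropy_mode,
         none = rep(0, n),
         balanced = rnorm(n, 0, config$pleiotropy_sd),
         directional = rnorm(n, config$pleiotropy_mean, config$pleiotropy_sd))
}

make_trait_table <- function(meta, beta, se, trait_id, trait_kind, n_sample) {
  pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  gwas_table(data.frame(snp = meta$snp, chr = meta$chr, pos = meta$pos,
                        effect_allele = meta$effect_allele,
                        other_allele = meta$other_allele,
                        eaf = meta$eaf, beta = beta, se = se, pval = pval,
                        n = n_sample, stringsAsFactors = FALSE),
             trait_id = trait_id, trait_kind = trait_kind)
}

#' Simulate a linked three-trait GWAS summary-statistics system
#'
#' Generates exposure, mediator and outcome summary-statistics tables over
#' a shared SNP panel with known causal structure (see
#' [simulation_config()]), plus the generating truth for
#' parameter-recovery tests. SNPs are unlinked and placed far apart so the
#' clumping window never merges them; alleles are drawn from
#' non-palindromic pairs so harmonization is exact.
#'
#' @param config a [simulation_config()].
#' @return A list with `exposure`, `mediators` (named list of
#'   [gwas_table()]s), `outcome`, and `truth` (a `simulation_truth` list
#'   holding the realized per-SNP effects, block assignment, the true
#'   total effect and true mediation proportions).
#' @export
simulate_three_trait_gwas <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$n_mediators
  n_block <- config$n_snp
  n_tot <- n_block * (1 + m)
  block <- rep(c("exposure", paste0("mediator_", seq_len(m))), each = n_block)

  with_preserved_seed(config$seed, {
    pair_idx <- sample.int(nrow(ALLELE_PAIRS), n_tot, replace = TRUE)
    chr <- as.character(rep_len(1:22, n_tot))
    meta <- data.frame(
      snp = sprintf("rs%06d", seq_len(n_tot)),
      chr = chr,
      pos = 1e6 + (ceiling(seq_len(n_tot) / 22) - 1) * 2e7,
      effect_allele = ALLELE_PAIRS[pair_idx, 1],
      other_allele = ALLELE_PAIRS[pair_idx, 2],
      eaf = runif(n_tot, config$maf_range[1], config$maf_range[2]),
      stringsAsFactors = FALSE)

    gamma <- ifelse(block == "exposure", rnorm(n_tot, 0, config$gamma_sd), 0)
    delta <- matrix(0, n_tot, m)
    for (k in seq_len(m)) {
      in_block <- block == paste0("mediator_", k)
      delta[in_block, k] <- rnorm(sum(in_block), 0, config$gamma_sd)
    }

    total_effect <- config$tau_direct + sum(config$theta1 * config$theta2)
    # pleiotropic effects aligned with the exposure-increasing allele
    orient <- ifelse(gamma == 0, 1, sign(gamma))
    alpha_out <- draw_pleiotropy(n_tot, config)
    alpha_med <- matrix(0, n_tot, m)

    beta_exp <- gamma + rnorm(n_tot, 0, config$se_exp)
    exposure <- make_trait_table(meta, beta_exp, rep(config$se_exp, n_tot),
                                 "sim_exposure", "continuous", 300000)

    mediators <- list()
    for (k in seq_len(m)) {
      alpha_med[, k] <- draw_pleiotropy(n_tot, config)
      mu <- config$theta1[k] * gamma + delta[, k] + orient * alpha_med[, k]
      beta_med <- mu + rnorm(n_tot, 0, config$se_med)
      mediators[[paste0("mediator_", k)]] <-
        make_trait_table(meta, beta_med, rep(config$se_med, n_tot),
                         paste0("sim_mediator_", k), "continuous", 110000)
    }

    mu_out <- total_effect * gamma +
      drop(delta %*% config$theta2) +
      orient * alpha_out
    beta_out <- mu_out + rnorm(n_tot, 0, config$se_out)
    outcome <- make_trait_table(meta, beta_out, rep(config$se_out, n_tot),
                                "sim_outcome", "binary", 400000)

    truth <- structure(list(
      config = config, block = block, gamma = gamma, delta = delta,
      alpha_out = alpha_out, alpha_med = alpha_med,
      theta1 = config$theta1, theta2 = config$theta2,
      tau_direct = config$tau_direct,
      total_effect = total_effect,
      mediation_effects = config$theta1 * config$theta2,
      proportion_pct = 100 * config$theta1 * config$theta2 / total_effect),
      class = "simulation_truth")

    list(exposure = exposure, mediators = mediators, outcome = outcome,
         truth = truth)
  })
}

#' Simulate a family of null MR p-values
#'
#' Draws `m` independent exposure-to-trait MR p-values under no causal
#' effect: one exposure panel is generated from `config`, and for each of
#' the `m` pseudo-traits the outcome-side effects at the selected
#' instruments are pure noise. Supports calibration checks of the FDR
#' machinery.
#'
#' @param m number of null tests.
#' @param config a [simulation_config()].
#' @return Numeric vector of `m` IVW p-values.
#' @export
simulate_null_family <- function(m, config = simulation_config()) {
  stopifnot(m >= 1)
  sim <- simulate_three_trait_gwas(config)
  instruments <- suppressMessages(select_instruments(sim$exposure, analysis_config()))
  if (nrow(instruments) < 2) stop("simulate_null_family: too few instruments", call. = FALSE)
  n <- nrow(instruments)
  cfg <- analysis_config()
  with_preserved_seed(config$seed + 1L, {
    vapply(seq_len(m), function(i) {
      h <- harmonized_set(data.frame(
        snp = instruments$snp,
        beta_exp = instruments$beta, se_exp = instruments$se,
        beta_out = rnorm(n, 0, config$se_out),
        se_out = rep(config$se_out, n), stringsAsFactors = FALSE))
      ivw(h, cfg)$estimate$pval
    }, numeric(1))
  })
}
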