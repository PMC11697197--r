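#' Construct an MR causal-effect estimate
#'
#' @param method one of `"wald"`, `"ivw_fixed"`, `"ivw_random"`, `"egger"`,
#'   `"weighted_median"`.
#' @param beta causal-effect estimate on the outcome scale.
#' @param se its standard error (> 0).
#' @param pval two-sided p-value.
#' @param n_snp number of instruments used.
#' @return An `mr_estimate` (list) carrying `beta`, `se`, `pval`, `n_snp`
#'   and the odds-ratio transform `or_`, `lci95`, `uci95` (meaningful when
#'   the outcome is binary).
#' @export
mr_estimate <- function(method, beta, se, pval, n_snp) {
  stopifnot(se > 0, pval > 0, pval <= 1, n_snp >= 1)
  ci <- beta_to_or(beta, se)
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 n_snp = as.integer(n_snp),
                 or_ = ci[["or_"]], lci95 = ci[["lci95"]], uci95 = ci[["uci95"]]),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta = %.4g (se %.3g), p = %.3g, n_snp = %d\n",
              x$method, x$beta, x$se, x$pval, x$n_snp))
  cat(sprintf("  OR %.3g (95%% CI %.3g-%.3g)\n", x$or_, x$lci95, x$uci95))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             pval = x$pval, or = x$or_, lci95 = x$lci95, uci95 = x$uci95,
             stringsAsFactors = FALSE)
}

two_sided_normal_p <- function(z) pmax(2 * pnorm(-abs(z)), 1e-300)

#' Wald ratio estimate from a single instrument
#'
#' The per-SNP causal estimate `beta_out / beta_exp` with the first-order
#' standard error `se_out / |beta_exp|` (uncertainty in the exposure
#' association is ignored, matching the weighting used by the IVW
#' estimator).
#'
#' @param h a `harmonized_set` with exactly one pair, or a list/row with
#'   `beta_exp`, `beta_out`, `se_out`.
#' @return An [mr_estimate()] with method `"wald"`.
#' @export
wald_ratio <- function(h) {
  if (inherits(h, "harmonized_set") || is.data.frame(h)) {
    stopifnot(nrow(h) == 1)
    h <- as.list(h[1, ])
  }
  if (h$beta_exp == 0) {
    stop("wald_ratio: degenerate instrument (beta_exp = 0)", call. = FALSE)
  }
  beta <- h$beta_out / h$beta_exp
  se <- h$se_out / abs(h$beta_exp)
  mr_estimate("wald", beta, se, two_sided_normal_p(beta / se), 1L)
}

#' Cochran's Q heterogeneity test
#'
#' Measures dispersion of the per-SNP Wald ratios about the IVW estimate,
#' `Q = sum w_j (ratio_j - beta_ivw)^2` with `w_j = (|beta_exp_j| / se_out_j)^2`,
#' referred to the upper tail of a chi-squared distribution with
#' `n_snp - 1` degrees of freedom.
#'
#' @param h a `harmonized_set` with at least two pairs.
#' @param beta_ivw the IVW point estimate.
#' @return A list `heterogeneity_test` with `q_stat`, `df`, `pval`.
#' @export
cochran_q <- function(h, beta_ivw) {
  if (nrow(h) < 2) stop("cochran_q: needs at least 2 SNPs", call. = FALSE)
  ratio <- h$beta_out / h$beta_exp
  w <- (h$beta_exp / h$se_out)^2
  q <- sum(w * (ratio - beta_ivw)^2)
  df <- nrow(h) - 1L
  structure(list(q_stat = q, df = df, pval = pchisq(q, df, lower.tail = FALSE)),
            class = "heterogeneity_test")
}

#' Inverse-variance weighted estimator
#'
#' The primary estimator: the inverse-variance-weighted mean of the per-SNP
#' Wald ratios, equivalently weighted least squares of outcome on exposure
#' effects through the origin with weights `1/se_out^2`. Cochran's Q decides
#' the error model: when its p-value falls below `q_test_alpha` the
#' fixed-effects standard error is inflated by `max(1, sqrt(Q/df))`
#' (multiplicative random effects) and the method is tagged `ivw_random`,
#' otherwise `ivw_fixed`. A single instrument falls back to [wald_ratio()].
#'
#' @param h a `harmonized_set`.
#' @param config an [analysis_config()] (only `q_test_alpha` is used).
#' @return A list with elements `estimate` (an [mr_estimate()]) and
#'   `heterogeneity` (a [cochran_q()] result, `NULL` for one SNP).
#' @export
ivw <- function(h, config = analysis_config()) {
  stopifnot(inherits(h, "harmonized_set") || is.data.frame(h))
  n <- nrow(h)
  if (n == 0) stop("ivw: empty instrument set", call. = FALSE)
  if (n == 1) return(list(estimate = wald_ratio(h), heterogeneity = NULL))
  w <- 1 / h$se_out^2
  beta <- sum(w * h$beta_exp * h$beta_out) / sum(w * h$beta_exp^2)
  se_fixed <- 1 / sqrt(sum(w * h$beta_exp^2))
  het <- cochran_q(h, beta)
  if (het$pval < config$q_test_alpha) {
    se <- se_fixed * max(1, sqrt(het$q_stat / het$df))
    method <- "ivw_random"
  } else {
    se <- se_fixed
    method <- "ivw_fixed"
  }
  list(estimate = mr_estimate(method, beta, se, two_sided_normal_p(beta / se), n),
       heterogeneity = het)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept, weights `1/se_out^2`, after orienting every pair so the
#' exposure effect is non-negative (both signs flipped when it is not). The
#' intercept estimates the average directional pleiotropic effect; a
#' non-zero intercept signals violation of the exclusion restriction. The
#' residual standard deviation is floored at 1 so standard errors never
#' deflate below the fixed-effects level; p-values come from the t
#' distribution with `n_snp - 2` degrees of freedom.
#'
#' @param h a `harmonized_set` with at least three pairs.
#' @param pleiotropy_alpha significance level at which the intercept test
#'   is flagged.
#' @return A list with `slope` (an [mr_estimate()], method `"egger"`) and
#'   `intercept` (a [pleiotropy_test()]).
#' @export
egger <- function(h, pleiotropy_alpha = 0.05) {
  n <- nrow(h)
  if (n < 3) stop("egger: needs at least 3 SNPs", call. = FALSE)
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  w <- 1 / h$se_out^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # floor the residual SD at 1: never report less dispersion than the
  # fixed-effects model implies
  est <- coef(sm)[, "Estimate"]
  se <- sqrt(diag(sm$cov.unscaled)) * max(1, sm$sigma)
  names(se) <- names(est)
  tval <- est / se
  pval <- pmax(2 * pt(-abs(tval), df = n - 2), 1e-300)
  list(slope = mr_estimate("egger", est[["bx"]], se[["bx"]], pval[["bx"]], n),
       intercept = pleiotropy_test(est[["(Intercept)"]], se[["(Intercept)"]],
                                   pval[["(Intercept)"]],
                                   alpha = pleiotropy_alpha))
}

# cumulative-weight-interpolated weighted median of `x` with weights `w`
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] < 0.5) return(x[length(x)])
  below <- max(which(cw < 0.5))
  x[below] + (x[below + 1] - x[below]) * (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

#' Weighted-median estimator
#'
#' Orders the per-SNP Wald ratios and takes the value at which the
#' cumulative inverse-variance weight crosses one half, interpolating
#' linearly; consistent when at least half the weight comes from valid
#' instruments. The standard error comes from a seeded parametric
#' bootstrap: exposure and outcome effects are resampled from normal
#' distributions centred on their estimates with their standard errors.
#'
#' @param h a `harmonized_set` with at least three pairs.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap (results are reproducible
#'   bit-for-bit under the same seed).
#' @return An [mr_estimate()] with method `"weighted_median"`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  n <- nrow(h)
  if (n < 3) stop("weighted_median: needs at least 3 SNPs", call. = FALSE)
  ratio <- h$beta_out / h$beta_exp
  w <- (h$beta_exp / h$se_out)^2
  beta <- weighted_median_point(ratio, w)
  boots <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(n, h$beta_exp, h$se_exp)
      by <- rnorm(n, h$beta_out, h$se_out)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], (bx[ok] / h$se_out[ok])^2)
    }, numeric(1))
  })
  se <- sd(boots)
  mr_estimate("weighted_median", beta, se, two_sided_normal_p(beta / se), n)
}

#' Convert a log-odds effect to an odds ratio with 95% CI
#'
#' @param beta effect on the log-odds scale.
#' @param se its standard error.
#' @return Named numeric vector `or_`, `lci95`, `uci95` where
#'   `or_ = exp(beta)` and the bounds are `exp(beta -/+ 1.96 se)`.
#' @export
beta_to_or <- function(beta, se) {
  stopifnot(se > 0)
  c(or_ = exp(beta), lci95 = exp(beta - 1.96 * se), uci95 = exp(beta + 1.96 * se))
}

#' Run every estimator on one harmonized set
#'
#' Convenience wrapper returning IVW (with heterogeneity), MR-Egger (slope
#' and intercept) and the weighted median as one table; estimators whose
#' minimum instrument count is not met are omitted.
#'
#' @param h a `harmonized_set`.
#' @param config an [analysis_config()].
#' @return A data frame with one row per estimator in the serialization
#'   layout `method`, `n_snp`, `beta`, `se`, `pval`, `or`, `lci95`,
#'   `uci95`, `q_stat`, `q_df`, `q_pval`.
#' @export
mr_all_methods <- function(h, config = analysis_config()) {
  res <- ivw(h, config)
  rows <- as.data.frame(res$estimate)
  rows$q_stat <- if (is.null(res$heterogeneity)) NA_real_ else res$heterogeneity$q_stat
  rows$q_df <- if (is.null(res$heterogeneity)) NA_integer_ else res$heterogeneity$df
  rows$q_pval <- if (is.null(res$heterogeneity)) NA_real_ else res$heterogeneity$pval
  if (nrow(h) >= 3) {
    eg <- egger(h, config$pleiotropy_alpha)
    wm <- weighted_median(h, config$median_bootstrap_n, config$rng_seed)
    extra <- rbind(as.data.frame(eg$slope), as.data.frame(wm))
    extra$q_stat <- NA_real_; extra$q_df <- NA_integer_; extra$q_pval <- NA_real_
    rows <- rbind(rows, extra)
  }
  rows$exposure_id <- attr(h, "exposure_id") %||% NA_character_
  rows$outcome_id <- attr(h, "outcome_id") %||% NA_character_
  rows[c("exposure_id", "outcome_id", setdiff(names(rows), c("exposure_id", "outcome_id")))]
}
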