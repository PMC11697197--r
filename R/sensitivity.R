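#' Construct an Egger-intercept pleiotropy test
#'
#' @param intercept Egger regression intercept (average directional
#'   pleiotropic effect per SNP).
#' @param se its standard error.
#' @param pval two-sided t p-value.
#' @param alpha significance level; the test is `flagged` when
#'   `pval < alpha`.
#' @return A `pleiotropy_test` list.
#' @export
pleiotropy_test <- function(intercept, se, pval, alpha = 0.05) {
  stopifnot(se > 0, pval > 0, pval <= 1)
  structure(list(intercept = intercept, se = se, pval = pval,
                 alpha = alpha, flagged = pval < alpha),
            class = "pleiotropy_test")
}

#' @export
print.pleiotropy_test <- function(x, ...) {
  cat(sprintf("<pleiotropy_test> intercept = %.3g (se %.3g), p = %.3g [%s]\n",
              x$intercept, x$se, x$pval,
              if (x$flagged) "pleiotropy flagged" else "no evidence"))
  invisible(x)
}

#' Egger-intercept screen
#'
#' Gatekeeper used by the screens: an exposure-outcome pair is excluded
#' from downstream results when the Egger intercept is significant at
#' `alpha` (strict inequality, so `pval == alpha` is retained).
#'
#' @param intercept_test a [pleiotropy_test()].
#' @param alpha significance level.
#' @return `TRUE` when the pair should be excluded for horizontal
#'   pleiotropy.
#' @export
egger_intercept_screen <- function(intercept_test, alpha = 0.05) {
  stopifnot(inherits(intercept_test, "pleiotropy_test"))
  intercept_test$pval < alpha
}

# fixed-effects IVW beta on vectors (helper used by presso)
ivw_beta <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)

# leave-one-out fixed-effects IVW betas, vectorised via sum updates
loo_ivw_beta <- function(bx, by, w) {
  num <- sum(w * bx * by)
  den <- sum(w * bx^2)
  (num - w * bx * by) / (den - w * bx^2)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Simulation-based residual-sum-of-squares framework for detecting
#' pleiotropic outlier instruments. For each SNP the leave-one-out IVW
#' estimate is formed and its weighted squared residual computed; the
#' observed global RSS is compared with RSS values from `n_sim` datasets
#' simulated under the no-pleiotropy model (exposure effects resampled
#' about their estimates, outcome effects about the leave-one-out
#' predictions). Per-SNP empirical p-values are Bonferroni-corrected by the
#' SNP count, and flagged outliers trigger a distortion test comparing the
#' outlier-removed IVW estimate with the distribution of the same contrast
#' under random pseudo-outlier sets of equal size. Empirical p-values use
#' the plus-one rule, so they are never smaller than `1/(n_sim + 1)`.
#'
#' @param h a `harmonized_set` with at least four pairs.
#' @param n_sim number of simulated datasets.
#' @param outlier_alpha significance level applied to the
#'   Bonferroni-corrected per-SNP p-values.
#' @param seed RNG seed; results are bit-reproducible under the same seed.
#' @param config an [analysis_config()] used when re-estimating IVW after
#'   outlier removal.
#' @return A `presso_result` list with `global_rss`, `global_pval`,
#'   `outlier_pvals` (named, Bonferroni-corrected), `outlier_ids`,
#'   `distortion_pval` (`NA` when no outliers are flagged) and
#'   `beta_corrected` (the [ivw()] estimate without the flagged SNPs,
#'   `NULL` when nothing is flagged or too few SNPs remain).
#' @export
presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1L,
                   config = analysis_config()) {
  n <- nrow(h)
  if (n < 4) stop("presso: needs at least 4 SNPs", call. = FALSE)
  bx <- h$beta_exp; by <- h$beta_out
  sx <- h$se_exp; sy <- h$se_out
  w <- 1 / sy^2

  beta_loo <- loo_ivw_beta(bx, by, w)
  rss_obs <- w * (by - beta_loo * bx)^2
  global_rss <- sum(rss_obs)

  sims <- with_preserved_seed(seed, {
    bx_star <- matrix(rnorm(n * n_sim, mean = bx, sd = sx), nrow = n)
    by_star <- matrix(rnorm(n * n_sim, mean = beta_loo * bx, sd = sy), nrow = n)
    # leave-one-out IVW within each simulated dataset
    num <- colSums(w * bx_star * by_star)
    den <- colSums(w * bx_star^2)
    loo_star <- (rep(num, each = n) - w * bx_star * by_star) /
      (rep(den, each = n) - w * bx_star^2)
    rss_star <- w * (by_star - loo_star * bx_star)^2
    list(per_snp = rss_star, total = colSums(rss_star),
         draws = runif(1))  # reserve stream position for the distortion draw
  })

  global_pval <- (1 + sum(sims$total >= global_rss)) / (n_sim + 1)
  raw_p <- (1 + rowSums(sims$per_snp >= rss_obs)) / (n_sim + 1)
  outlier_pvals <- pmin(1, raw_p * n)
  names(outlier_pvals) <- h$snp
  outlier_ids <- h$snp[outlier_pvals < outlier_alpha]

  distortion_pval <- NA_real_
  beta_corrected <- NULL
  if (length(outlier_ids) > 0 && n - length(outlier_ids) >= 2) {
    keep <- !(h$snp %in% outlier_ids)
    beta_all <- ivw_beta(bx, by, w)
    beta_no <- ivw_beta(bx[keep], by[keep], w[keep])
    d_obs <- beta_no - beta_all
    k <- length(outlier_ids)
    d_null <- with_preserved_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(s) {
        idx <- sample.int(n, k)
        ivw_beta(bx[-idx], by[-idx], w[-idx]) - beta_all
      }, numeric(1))
    })
    distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
    beta_corrected <- ivw(subset_harmonized(h, keep), config)$estimate
  }

  structure(list(global_rss = global_rss, global_pval = global_pval,
                 outlier_pvals = outlier_pvals, outlier_ids = outlier_ids,
                 distortion_pval = distortion_pval,
                 beta_corrected = beta_corrected,
                 n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> global RSS = %.4g, p = %.4g (%d sims)\n",
              x$global_rss, x$global_pval, x$n_sim))
  if (length(x$outlier_ids) > 0) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_pval))
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}
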