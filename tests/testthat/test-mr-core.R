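test_that("Wald ratio follows the first-order delta method", {
  h <- make_h(1, 0.3, se_out = 0.1)
  est <- wald_ratio(h)
  expect_equal(est$beta, 0.3)
  expect_equal(est$se, 0.1)

  est <- wald_ratio(make_h(-0.5, 0.2, se_out = 0.1))
  expect_equal(est$beta, -0.4)
  expect_equal(est$se, 0.2)

  # closed-form check on random pairs: beta_out/beta_exp, se_out/|beta_exp|,
  # two-sided normal p
  set.seed(2)
  for (i in 1:10) {
    bx <- rnorm(1); by <- rnorm(1); sy <- runif(1, 0.01, 0.5)
    est <- wald_ratio(make_h(bx, by, se_out = sy))
    expect_equal(est$beta, by / bx)
    expect_equal(est$se, sy / abs(bx))
    expect_equal(est$pval, 2 * pnorm(-abs((by / bx) / (sy / abs(bx)))))
  }
  expect_error(wald_ratio(make_h(0, 0.1)), "degenerate")
})

test_that("IVW equals the inverse-variance-weighted mean of Wald ratios", {
  # single instrument reduces exactly to the Wald ratio
  h1 <- make_h(0.2, 0.08, se_out = 0.03)
  expect_equal(ivw(h1)$estimate$beta, wald_ratio(h1)$beta)
  expect_equal(ivw(h1)$estimate$method, "wald")

  # identical ratios: beta = c, Q = 0, fixed effects
  h <- make_h(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20))
  res <- ivw(h)
  expect_equal(res$estimate$beta, 0.5)
  expect_equal(res$heterogeneity$q_stat, 0)
  expect_equal(res$heterogeneity$pval, 1)
  expect_equal(res$estimate$method, "ivw_fixed")

  # 20-SNP random sets against an independent oracle: the IVW estimate is
  # the mean of the Wald ratios weighted by their inverse variances
  for (seed in 1:5) {
    h <- random_h(20, theta = 0.25, seed = seed)
    ratios <- h$beta_out / h$beta_exp
    w <- (h$beta_exp / h$se_out)^2
    expect_equal(ivw(h)$estimate$beta, sum(w * ratios) / sum(w),
                 tolerance = 1e-10)
  }
})

test_that("fixed-effects IVW agrees with a meta-analysis cross-check", {
  skip_if_not_installed("metafor")
  h <- random_h(15, theta = 0.4, seed = 11)
  ratios <- h$beta_out / h$beta_exp
  se_r <- h$se_out / abs(h$beta_exp)
  fit <- metafor::rma(yi = ratios, sei = se_r, method = "FE")
  res <- ivw(h)
  expect_equal(res$estimate$beta, as.numeric(fit$beta), tolerance = 1e-8)
  q <- cochran_q(h, res$estimate$beta)
  expect_equal(q$q_stat, as.numeric(fit$QE), tolerance = 1e-8)
  expect_equal(q$pval, as.numeric(fit$QEp), tolerance = 1e-8)
})

test_that("IVW is invariant to jointly flipping subsets of effect signs", {
  h <- random_h(12, theta = -0.2, seed = 4)
  res0 <- ivw(h)
  set.seed(9)
  flip <- sample(c(-1, 1), 12, replace = TRUE)
  hf <- make_h(h$beta_exp * flip, h$beta_out * flip,
               se_exp = h$se_exp, se_out = h$se_out)
  resf <- ivw(hf)
  expect_equal(resf$estimate$beta, res0$estimate$beta)
  expect_equal(resf$estimate$se, res0$estimate$se)
})

test_that("random-effects inflation never reduces the standard error", {
  # heterogeneous data trip the Q gate; the multiplicative model only
  # ever inflates
  set.seed(21)
  h <- make_h(runif(15, 0.1, 0.3),
              runif(15, 0.1, 0.3) * runif(15, -1, 2), se_out = 0.01)
  res <- ivw(h)
  se_fixed <- 1 / sqrt(sum(h$beta_exp^2 / h$se_out^2))
  expect_gte(res$estimate$se, se_fixed)
  if (res$heterogeneity$pval < 0.05) {
    expect_equal(res$estimate$method, "ivw_random")
    expect_equal(res$estimate$se,
                 se_fixed * sqrt(res$heterogeneity$q_stat / res$heterogeneity$df))
  }
})

test_that("Cochran's Q matches hand arithmetic on two instruments", {
  # ratios 0.5 and 1.0 with ratio variances 0.01 and 0.04
  h <- make_h(c(1, 1), c(0.5, 1.0), se_out = c(0.1, 0.2))
  beta <- ivw(h)$estimate$beta
  # weights 100 and 25: beta = (100*0.5 + 25*1)/125 = 0.6
  expect_equal(beta, 0.6)
  q <- cochran_q(h, beta)
  expect_equal(q$q_stat, 100 * (0.5 - 0.6)^2 + 25 * (1.0 - 0.6)^2)
  expect_equal(q$df, 1)
  expect_equal(q$pval, pchisq(5, 1, lower.tail = FALSE))
  expect_error(cochran_q(make_h(1, 1), 1), "at least 2")
})

test_that("Egger recovers an exact linear law and matches the normal equations", {
  # exact line: intercept and slope recovered to numerical precision
  bx <- c(0.1, 0.15, 0.2, 0.3, 0.42)
  by <- 0.02 + 0.7 * bx
  h <- make_h(bx, by, se_out = c(0.05, 0.04, 0.06, 0.05, 0.07))
  res <- egger(h)
  expect_equal(res$slope$beta, 0.7, tolerance = 1e-10)
  expect_equal(res$intercept$intercept, 0.02, tolerance = 1e-10)

  # random sets against an independent weighted normal-equations solve
  for (seed in c(31, 32)) {
    h <- random_h(30, theta = 0.3, seed = seed)
    flip <- sign(h$beta_exp)
    x <- abs(h$beta_exp); y <- h$beta_out * flip
    w <- 1 / h$se_out^2
    X <- cbind(1, x)
    coefs <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
    res <- egger(h)
    expect_equal(res$intercept$intercept, coefs[1], tolerance = 1e-8)
    expect_equal(res$slope$beta, coefs[2], tolerance = 1e-8)
    # SEs from the weighted residual variance, floored at 1
    resid <- y - X %*% coefs
    sigma2 <- sum(w * resid^2) / (length(y) - 2)
    vc <- solve(t(X) %*% (w * X)) * max(1, sigma2)
    expect_equal(res$intercept$se, sqrt(vc[1, 1]), tolerance = 1e-8)
    expect_equal(res$slope$se, sqrt(vc[2, 2]), tolerance = 1e-8)
    # t p-values with n - 2 degrees of freedom
    expect_equal(res$intercept$pval,
                 2 * pt(-abs(coefs[1] / sqrt(vc[1, 1])), nrow(h) - 2),
                 tolerance = 1e-8)
  }
  expect_error(egger(make_h(c(1, 2), c(1, 2))), "at least 3")
})

test_that("Egger is invariant under the orientation rule", {
  h <- random_h(20, theta = 0.3, seed = 41)
  res0 <- egger(h)
  set.seed(42)
  flip <- sample(c(-1, 1), 20, replace = TRUE)
  hf <- make_h(h$beta_exp * flip, h$beta_out * flip,
               se_exp = h$se_exp, se_out = h$se_out)
  resf <- egger(hf)
  expect_equal(resf$slope$beta, res0$slope$beta)
  expect_equal(resf$intercept$intercept, res0$intercept$intercept)
})

test_that("weighted median interpolates the 50% cumulative-weight crossing", {
  # equal weights, ratios {1,2,3}: the unweighted median
  h <- make_h(c(1, 1, 1), c(1, 2, 3), se_out = 1)
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, 2)

  # one dominant weight pulls the estimate to that ratio
  h <- make_h(c(1, 1, 1, 1), c(1, 2, 3, 1.5), se_out = c(1, 1, 1, 1e-4))
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, 1.5,
               tolerance = 1e-3)

  # independent cumulative-weight-interpolation oracle on 5 SNPs
  h <- random_h(5, theta = 0.5, seed = 51)
  ratios <- h$beta_out / h$beta_exp
  w <- (h$beta_exp / h$se_out)^2
  ord <- order(ratios)
  r <- ratios[ord]; ww <- w[ord] / sum(w)
  cw <- cumsum(ww) - ww / 2
  k <- max(which(cw < 0.5))
  oracle <- r[k] + (r[k + 1] - r[k]) * (0.5 - cw[k]) / (cw[k + 1] - cw[k])
  est <- weighted_median(h, n_boot = 200, seed = 7)
  expect_equal(est$beta, oracle, tolerance = 1e-12)

  # bootstrap SE reproducible bit-for-bit under the same seed
  est2 <- weighted_median(h, n_boot = 200, seed = 7)
  expect_identical(est$se, est2$se)
  expect_error(weighted_median(make_h(c(1, 2), c(1, 2))), "at least 3")
})

test_that("log-odds to odds-ratio conversion is monotone and maps 0 to 1", {
  expect_equal(beta_to_or(0, 0.1),
               c(or_ = 1, lci95 = exp(-0.196), uci95 = exp(0.196)))
  b <- seq(-1, 1, by = 0.25)
  ors <- vapply(b, function(x) beta_to_or(x, 0.1)[["or_"]], numeric(1))
  expect_true(all(diff(ors) > 0))
  ci <- beta_to_or(0.3, 0.05)
  expect_lt(ci[["lci95"]], ci[["or_"]])
  expect_gt(ci[["uci95"]], ci[["or_"]])
})
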