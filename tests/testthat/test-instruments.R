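test_that("clumping keeps independent SNPs and prunes dominated neighbours", {
  df <- toy_gwas_df(2, pos = c(1000, 6000), pval = c(1e-10, 1e-9))
  tab <- gwas_table(df, trait_id = "x")
  ld0 <- ld_matrix(df$snp, diag(2))
  expect_equal(nrow(greedy_clump(tab, ld0, 0.001, 10000)), 2)

  r2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  ld5 <- ld_matrix(df$snp, r2)
  kept <- greedy_clump(tab, ld5, 0.001, 10000)
  expect_equal(kept$snp, "rs001")

  # outside the window the correlated pair survives
  df2 <- toy_gwas_df(2, pos = c(1000, 2e7), pval = c(1e-10, 1e-9))
  expect_equal(nrow(greedy_clump(gwas_table(df2, trait_id = "x"), ld5, 0.001, 10000)), 2)

  expect_error(greedy_clump(tab, ld_matrix("rs999", matrix(1)), 0.001, 10000),
               "absent")
})

test_that("clumping matches exhaustive enumeration on random 10-SNP instances", {
  for (seed in 1:8) {
    set.seed(seed)
    df <- toy_gwas_df(10,
                      chr = sample(c("1", "2"), 10, replace = TRUE),
                      pos = sample.int(3e7, 10),
                      pval = runif(10, 1e-12, 1e-6))
    tab <- gwas_table(df, trait_id = "x")
    ld <- random_ld(df$snp, seed + 100)
    kept <- greedy_clump(tab, ld, r2_threshold = 0.3, window_kb = 10000)
    expect_equal(sort(kept$snp), clump_oracle(df, ld$r2, 0.3, 10000))

    # invariants: subset, minimum p preserved, no close correlated pair kept
    expect_true(all(kept$snp %in% df$snp))
    expect_equal(min(kept$pval), min(df$pval))
    if (nrow(kept) > 1) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        close_pair <- kept$chr[i] == kept$chr[j] &&
          abs(kept$pos[i] - kept$pos[j]) <= 1e7
        expect_false(close_pair && ld$r2[kept$snp[i], kept$snp[j]] >= 0.3)
      }
    }
  }
})

test_that("instrument selection applies the significance threshold then clumps", {
  df <- toy_gwas_df(6, pval = rep(0.5, 6))
  tab <- gwas_table(df, trait_id = "x")
  expect_equal(nrow(select_instruments(tab)), 0)

  cfg <- analysis_config()
  expect_equal(cfg$instrument_p_threshold, 5e-8)
  expect_equal(cfg$clump_r2, 0.001)
  expect_equal(cfg$clump_window_kb, 10000L)
  expect_equal(cfg$outcome_exclusion_p, 5e-8)

  set.seed(5)
  df <- toy_gwas_df(12, chr = rep(c("1", "2"), 6),
                    pos = sample.int(2e7, 12),
                    pval = 10^runif(12, -12, -4))
  tab <- gwas_table(df, trait_id = "x")
  ld <- random_ld(df$snp, 9)
  got <- select_instruments(tab, analysis_config(clump_r2 = 0.3), ld)
  sig <- df[df$pval < 5e-8, ]
  expect_equal(sort(got$snp), clump_oracle(sig, ld$r2, 0.3, 10000))

  # without LD every significant SNP is retained, with a message
  expect_message(got2 <- select_instruments(tab, analysis_config()),
                 "independent")
  expect_equal(sort(got2$snp), sort(sig$snp))
})

test_that("harmonization aligns allele codings and drops ambiguous palindromes", {
  ex <- gwas_table(toy_gwas_df(1, effect_allele = "A", other_allele = "G",
                               beta = 0.1, eaf = 0.3), trait_id = "exp")
  # identical coding: pass-through
  ou <- gwas_table(toy_gwas_df(1, effect_allele = "A", other_allele = "G",
                               beta = 0.2, eaf = 0.3), trait_id = "out")
  h <- harmonize(ex, ou)
  expect_equal(h$beta_out, 0.2)

  # swapped alleles: sign flip and complemented frequency
  ou <- gwas_table(toy_gwas_df(1, effect_allele = "G", other_allele = "A",
                               beta = 0.2, eaf = 0.7), trait_id = "out")
  h <- harmonize(ex, ou)
  expect_equal(h$beta_out, -0.2)
  expect_equal(h$eaf_out, 0.3)
  expect_equal(attr(h, "provenance")$n_swapped, 1)

  # strand flip (T/C is A/G read from the other strand): no sign change
  ou <- gwas_table(toy_gwas_df(1, effect_allele = "T", other_allele = "C",
                               beta = 0.2), trait_id = "out")
  expect_equal(harmonize(ex, ou)$beta_out, 0.2)

  # strand flip plus swap
  ou <- gwas_table(toy_gwas_df(1, effect_allele = "C", other_allele = "T",
                               beta = 0.2), trait_id = "out")
  expect_equal(harmonize(ex, ou)$beta_out, -0.2)

  # incompatible alleles are dropped
  ex2 <- gwas_table(rbind(toy_gwas_df(1, effect_allele = "A", other_allele = "G"),
                          toy_gwas_df(2, effect_allele = "A", other_allele = "C")[2, ]),
                    trait_id = "exp")
  ou2 <- gwas_table(rbind(toy_gwas_df(1, effect_allele = "A", other_allele = "C"),
                          toy_gwas_df(2, effect_allele = "A", other_allele = "C")[2, ]),
                    trait_id = "out")
  h <- harmonize(ex2, ou2)
  expect_equal(nrow(h), 1)
  expect_equal(attr(h, "provenance")$n_incompatible, 1)

  # palindromic SNP inside the frequency ambiguity band: dropped
  exp_pal <- gwas_table(toy_gwas_df(1, effect_allele = "A", other_allele = "T",
                                    eaf = 0.45), trait_id = "exp")
  out_pal <- gwas_table(toy_gwas_df(1, effect_allele = "A", other_allele = "T",
                                    beta = 0.2, eaf = 0.45), trait_id = "out")
  h <- harmonize(exp_pal, out_pal)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "provenance")$n_palindromic_dropped, 1)

  # outside the band with agreeing orientation: retained
  exp_pal <- gwas_table(toy_gwas_df(1, effect_allele = "A", other_allele = "T",
                                    eaf = 0.2), trait_id = "exp")
  out_pal <- gwas_table(toy_gwas_df(1, effect_allele = "A", other_allele = "T",
                                    beta = 0.2, eaf = 0.25), trait_id = "out")
  expect_equal(harmonize(exp_pal, out_pal)$beta_out, 0.2)

  # outside the band but disagreeing orientation: dropped, not flipped
  out_pal <- gwas_table(toy_gwas_df(1, effect_allele = "A", other_allele = "T",
                                    beta = 0.2, eaf = 0.8), trait_id = "out")
  expect_equal(nrow(harmonize(exp_pal, out_pal)), 0)

  # missing frequency on either side: dropped
  out_pal <- gwas_table(toy_gwas_df(1, effect_allele = "A", other_allele = "T",
                                    beta = 0.2, eaf = NA), trait_id = "out")
  expect_equal(nrow(harmonize(exp_pal, out_pal)), 0)

  # empty overlap errors
  ex_b <- gwas_table(toy_gwas_df(2), trait_id = "b")
  ou_b <- gwas_table({d <- toy_gwas_df(2); d$snp <- c("zz1", "zz2"); d},
                     trait_id = "c")
  expect_error(harmonize(ex_b, ou_b), "no SNPs shared")
})

test_that("harmonization matches an orientation oracle on randomized codings", {
  set.seed(77)
  n <- 50
  pairs <- matrix(c("A","C","A","G","C","A","C","T","G","A","G","T","T","C","T","G"),
                  ncol = 2, byrow = TRUE)
  idx <- sample(nrow(pairs), n, replace = TRUE)
  base <- toy_gwas_df(n, pos = seq_len(n) * 1e6,
                      beta = rnorm(n), eaf = runif(n, 0.05, 0.95))
  base$effect_allele <- pairs[idx, 1]
  base$other_allele <- pairs[idx, 2]
  ex <- gwas_table(base, trait_id = "exp")

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  out_df <- base
  out_df$beta <- rnorm(n)
  coding <- sample(c("same", "swap", "flip", "flipswap"), n, replace = TRUE)
  for (i in seq_len(n)) {
    a1 <- base$effect_allele[i]; a2 <- base$other_allele[i]
    if (coding[i] == "swap") {
      out_df$effect_allele[i] <- a2; out_df$other_allele[i] <- a1
      out_df$eaf[i] <- 1 - out_df$eaf[i]
    } else if (coding[i] == "flip") {
      out_df$effect_allele[i] <- comp[a1]; out_df$other_allele[i] <- comp[a2]
    } else if (coding[i] == "flipswap") {
      out_df$effect_allele[i] <- comp[a2]; out_df$other_allele[i] <- comp[a1]
      out_df$eaf[i] <- 1 - out_df$eaf[i]
    }
  }
  ou <- gwas_table(out_df, trait_id = "out")
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), n)  # no palindromic pairs, nothing dropped
  # oracle: the aligned outcome effect flips sign exactly when the
  # outcome's effect allele is (possibly after strand complement) the
  # exposure's other allele
  flip_expected <- coding %in% c("swap", "flipswap")
  expect_equal(h$beta_out[match(base$snp, h$snp)],
               ifelse(flip_expected, -out_df$beta, out_df$beta))
})

test_that("harmonizing against an allele-swapped copy of itself negates the effects", {
  sim <- simulate_three_trait_gwas(simulation_config(n_snp = 30, seed = 3))
  tab <- sim$exposure
  swapped <- as.data.frame(tab)
  tmp <- swapped$effect_allele
  swapped$effect_allele <- swapped$other_allele
  swapped$other_allele <- tmp
  swapped$beta <- swapped$beta  # effect left as-is: the coding flip alone must negate
  swapped$eaf <- 1 - swapped$eaf
  swapped <- gwas_table(swapped, trait_id = "copy")
  h <- harmonize(tab, swapped)
  expect_equal(nrow(h), nrow(tab))
  expect_equal(h$beta_out, -h$beta_exp)
})

test_that("outcome-associated exclusion filters, never grows, and is idempotent", {
  h <- make_h(c(0.1, 0.2, 0.3), c(0.02, 0.04, 0.06),
              pval_out = c(0.5, 1e-9, 0.2))
  h1 <- exclude_outcome_associated(h, 5e-8)
  expect_equal(h1$snp, c("rs001", "rs003"))
  expect_equal(attr(h1, "provenance")$n_outcome_associated_excluded, 1)
  h2 <- exclude_outcome_associated(h1, 5e-8)
  expect_equal(as.data.frame(h2), as.data.frame(h1))
  expect_lte(nrow(h1), nrow(h))

  # nothing below the threshold: unchanged
  h3 <- exclude_outcome_associated(make_h(c(0.1, 0.2), c(0, 0),
                                          pval_out = c(0.5, 0.4)), 5e-8)
  expect_equal(nrow(h3), 2)

  # brute-force filter oracle on a synthetic set
  set.seed(8)
  h <- make_h(rnorm(40, 0, 0.1), rnorm(40, 0, 0.1),
              pval_out = 10^runif(40, -10, 0))
  got <- exclude_outcome_associated(h, 1e-4)
  expect_equal(got$snp, h$snp[!(h$pval_out < 1e-4)])
})
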