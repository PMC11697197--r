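# Small in-code builders used across the suite.

# a minimal valid GWAS data frame; fields can be overridden per row
toy_gwas_df <- function(n = 5, chr = "1", pos = NULL, beta = NULL, se = NULL,
                        pval = NULL, eaf = NULL,
                        effect_allele = "A", other_allele = "G") {
  data.frame(
    snp = sprintf("rs%03d", seq_len(n)),
    chr = rep_len(chr, n),
    pos = if (is.null(pos)) seq_len(n) * 1000 else pos,
    effect_allele = rep_len(effect_allele, n),
    other_allele = rep_len(other_allele, n),
    eaf = if (is.null(eaf)) rep(0.3, n) else eaf,
    beta = if (is.null(beta)) seq_len(n) / 10 else beta,
    se = if (is.null(se)) rep(0.05, n) else se,
    pval = if (is.null(pval)) rep(0.01, n) else pval,
    n = rep(1e5, n),
    stringsAsFactors = FALSE)
}

# harmonized set straight from effect vectors
make_h <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.05,
                   pval_out = NULL) {
  n <- length(beta_exp)
  df <- data.frame(
    snp = sprintf("rs%03d", seq_len(n)),
    beta_exp = beta_exp, se_exp = rep_len(se_exp, n),
    beta_out = beta_out, se_out = rep_len(se_out, n),
    stringsAsFactors = FALSE)
  if (!is.null(pval_out)) df$pval_out <- pval_out
  harmonized_set(df)
}

# random harmonized set under true effect `theta`
random_h <- function(n, theta = 0.3, seed = 1, se_out = 0.05, se_exp = 0.01) {
  set.seed(seed)
  bx <- rnorm(n, 0, 0.1)
  bx[abs(bx) < 0.02] <- 0.02  # keep instruments away from zero
  by <- theta * bx + rnorm(n, 0, se_out)
  make_h(bx, by, se_exp = se_exp, se_out = se_out)
}
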