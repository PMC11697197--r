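# Independent oracle implementations, written straight from the
# definitions and sharing no code with the package internals.

# exhaustive greedy clumping: repeatedly take the smallest-p record and
# remove everything correlated within the window
clump_oracle <- function(df, r2, r2_threshold, window_kb) {
  pool <- df[order(df$pval, df$chr, df$pos, df$snp), ]
  kept <- character(0)
  while (nrow(pool) > 0) {
    lead <- pool[1, ]
    kept <- c(kept, lead$snp)
    drop <- vapply(seq_len(nrow(pool)), function(i) {
      if (i == 1) return(TRUE)
      other <- pool[i, ]
      other$chr == lead$chr &&
        abs(other$pos - lead$pos) <= window_kb * 1000 &&
        r2[lead$snp, other$snp] >= r2_threshold
    }, logical(1))
    pool <- pool[!drop, ]
  }
  sort(kept)
}

random_ld <- function(snp_ids, seed) {
  set.seed(seed)
  k <- length(snp_ids)
  m <- matrix(runif(k * k), k, k)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  ld_matrix(snp_ids, m)
}

# brute-force step-up FDR: q_i = min over j with rank >= rank_i of m p_(j)/j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(vapply(i:m, function(j) m * ranked[j] / j, numeric(1)), 1)
  }
  q[order(ord)]
}
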