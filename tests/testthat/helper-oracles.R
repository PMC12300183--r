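# Independent brute-force oracles used to validate the package's
# statistics.  These deliberately re-derive each quantity from first
# principles (enumeration / textbook formulas) and never call the package
# functions they check.

# Benjamini-Hochberg step-up, written directly from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

# Two-sided Fisher exact p by hypergeometric point-probability summation:
# sum of P(X = k) over all k with P(k) <= P(observed), with the standard
# relative tolerance guard on the equality comparison.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # members
  n <- c + d          # non-members
  k <- a + c          # flagged
  x <- 0:min(m, k)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney U and position score for a member subset, from ranks.
oracle_u_score <- function(values, members) {
  rk <- rank(values)
  n1 <- sum(members)
  n2 <- sum(!members)
  U <- sum(rk[members]) - n1 * (n1 + 1) / 2
  list(U = U, s = 2 * U / (n1 * n2) - 1)
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive-permutation significance flags for a small two-group matrix,
# re-implementing the moderated-statistic FDR estimator with plain loops:
# d = diff / (se + s0), FDR(c) = mean_perm #{|d_perm| >= c} / #{|d_obs| >= c},
# monotone-smoothed, flag at the smallest c with FDR <= target.
oracle_perm_flags <- function(X, n1, s0, target_fdr) {
  dstat <- function(idx1) {
    idx2 <- setdiff(seq_len(ncol(X)), idx1)
    apply(X, 1, function(r) {
      x <- r[idx1]; y <- r[idx2]
      v <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
        (length(x) + length(y) - 2)
      se <- sqrt(v * (1 / length(x) + 1 / length(y)))
      if (se + s0 == 0) return(NA_real_)
      (mean(x) - mean(y)) / (se + s0)
    })
  }
  combos <- combn(ncol(X), n1, simplify = FALSE)
  d_obs <- dstat(seq_len(n1))
  perm_d <- unlist(lapply(combos, dstat))
  cand <- sort(unique(abs(d_obs)))
  fdr <- sapply(cand, function(cc) {
    min(1, (sum(abs(perm_d) >= cc, na.rm = TRUE) / length(combos)) /
          sum(abs(d_obs) >= cc))
  })
  for (i in rev(seq_along(fdr))[-1]) fdr[i] <- max(fdr[i], fdr[i + 1])
  hit <- which(fdr <= target_fdr)
  cstar <- if (length(hit)) cand[hit[1]] else Inf
  abs(d_obs) >= cstar
}

# Small simulated dataset shared by several tests.
make_small_sim <- function(n = 150, seed = 11, ...) {
  cfg <- sim_config(n_proteins = n, seed = seed, ...)
  truth <- simulate_ground_truth(cfg)
  list(cfg = cfg, truth = truth)
}
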