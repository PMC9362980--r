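# Independent brute-force oracles used to pin down the analytic routes.
# Deliberately naive implementations: explicit loops / textbook formulas,
# no code shared with the package internals.

# textbook Pearson correlation from sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# explicit tail-select-then-Pearson: sort, keep top-k/bottom-k (with boundary
# ties), zero the rest, correlate
oracle_extreme_pearson <- function(d1, p1, d2, p2, k) {
  ss <- function(d, p) sign(d) * (-log10(p))
  tails <- function(s) {
    thr_hi <- sort(s, decreasing = TRUE)[k]
    thr_lo <- sort(s, decreasing = FALSE)[k]
    out <- numeric(length(s))
    for (i in seq_along(s)) {
      if (s[i] >= thr_hi || s[i] <= thr_lo) out[i] <- s[i]
    }
    out
  }
  oracle_pearson(tails(ss(d1, p1)), tails(ss(d2, p2)))
}

# explicit weighted covariance / correlation
oracle_weighted_cor <- function(x, y, w) {
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

# hand-rolled two-sample equal-variance t-test p-value
oracle_ttest_p <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tt), df = na + nb - 2)
}

# hand-rolled Spearman rank correlation via Pearson on ranks
oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

# exhaustive Random Set moments: mean and variance of the member mean over
# every size-m subset of the scores
oracle_random_set_moments <- function(g, m) {
  sets <- utils::combn(length(g), m)
  means <- apply(sets, 2, function(idx) mean(g[idx]))
  list(mu = mean(means), sigma_m2 = mean((means - mean(means))^2))
}

# random signature fixture over a shared or partially shared gene space
random_signature <- function(n, gene_ids = sprintf("G%04d", seq_len(n))) {
  z <- rnorm(n)
  as_signature(tibble::tibble(
    gene_id = gene_ids,
    log2fc = z,
    p_value = pmax(2 * pnorm(-abs(z + rnorm(n, 0, 0.5))), 1e-300)
  ))
}

# tiny three-signature library with metadata used across IO and query tests
toy_library <- function(n = 40, seed = 99) {
  withr::with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n))
    sigs <- list(
      sigA = random_signature(n, genes),
      sigB = random_signature(n, genes),
      sigC = random_signature(n, genes)
    )
    signature_library(sigs, meta = tibble::tibble(
      signature_id = c("sigA", "sigB", "sigC"),
      perturbagen = c("drug1", "drug1", "drug2"),
      target_gene = c("MTOR", "MTOR", "EGFR"),
      cell_line = c("MCF7", "A549", "MCF7"),
      signature_type = c("CP", "CP", "CGS")
    ))
  })
}
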