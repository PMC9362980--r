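test_that("one or two replicates get equal weights", {
  Z1 <- matrix(rnorm(20), ncol = 1)
  expect_equal(unname(modz_weights(replicate_set(Z1))), 1)
  Z2 <- matrix(rnorm(40), ncol = 2)
  expect_equal(unname(modz_weights(replicate_set(Z2))), c(0.5, 0.5))
})

test_that("identical replicates share the weight evenly and reproduce themselves", {
  withr::with_seed(61, z <- rnorm(50))
  Z <- matrix(rep(z, 3), ncol = 3)
  w <- modz_weights(replicate_set(Z))
  expect_equal(unname(w), rep(1 / 3, 3))
  cons <- modz(replicate_set(Z), p_values = FALSE)
  expect_equal(cons$signature$log2fc, z)
})

test_that("an anti-correlated outlier replicate is clipped to raw weight 0.01", {
  withr::with_seed(62, {
    z <- rnorm(200)
    Z <- cbind(z + rnorm(200, 0, 0.1), z + rnorm(200, 0, 0.1),
               z + rnorm(200, 0, 0.1), -z + rnorm(200, 0, 0.1))
  })
  reps <- replicate_set(Z)
  w <- modz_weights(reps)
  # independent oracle: hand-rolled Spearman matrix, mean off-diagonal, clip, normalize
  C <- diag(4)
  for (i in 1:3) for (j in (i + 1):4) C[i, j] <- C[j, i] <- oracle_spearman(Z[, i], Z[, j])
  raw <- sapply(1:4, function(i) mean(C[i, -i]))
  clipped <- pmax(raw, 0.01)
  expect_equal(unname(w), clipped / sum(clipped), tolerance = 1e-12)
  expect_equal(unname(w[4]), 0.01 / sum(clipped), tolerance = 1e-12)
})

test_that("weights are normalized and bounded below for three or more replicates", {
  withr::with_seed(63, {
    for (i in 1:20) {
      R <- sample(3:6, 1)
      Z <- matrix(rnorm(100 * R), ncol = R)
      w <- modz_weights(replicate_set(Z))
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_true(all(w > 0))
    }
  })
})

test_that("MODZ is linear: shifting every replicate by c shifts the consensus by c", {
  withr::with_seed(64, Z <- matrix(rnorm(300), ncol = 3))
  a <- modz(replicate_set(Z), p_values = FALSE)
  b <- modz(replicate_set(Z + 2.5), p_values = FALSE)
  expect_equal(b$signature$log2fc, a$signature$log2fc + 2.5, tolerance = 1e-12)
})

test_that("a single replicate passes through with no inference and no QC", {
  z <- rnorm(30)
  cons <- modz(replicate_set(matrix(z, ncol = 1)))
  expect_equal(cons$signature$log2fc, z)
  expect_false("p_value" %in% names(cons$signature))
  expect_true(is.na(cons$qc_q75))
  expect_true(is.na(cons$passed_qc))
})

test_that("distil_cc_q75 is the type-7 75th percentile of pairwise Spearman correlations", {
  withr::with_seed(65, Z <- matrix(rnorm(400), ncol = 4))
  reps <- replicate_set(Z)
  cors <- c()
  for (i in 1:3) for (j in (i + 1):4) cors <- c(cors, oracle_spearman(Z[, i], Z[, j]))
  expect_equal(distil_cc_q75(reps), unname(quantile(cors, 0.75, type = 7)),
               tolerance = 1e-12)
  # two replicates: the single correlation is its own quantile
  expect_equal(distil_cc_q75(replicate_set(Z[, 1:2])), oracle_spearman(Z[, 1], Z[, 2]),
               tolerance = 1e-12)
})

test_that("distil_cc_q75 is invariant under strictly monotone per-replicate transforms", {
  withr::with_seed(66, z <- rnorm(80))
  Z <- unname(cbind(z, exp(z), z^3 + 2 * z))
  expect_equal(distil_cc_q75(replicate_set(Z)), 1.0)
})

test_that("QC passes only strictly above 0.2", {
  # ranks engineered so the single pairwise Spearman correlation is exactly 0.2
  Z <- cbind(1:5, c(2, 3, 5, 1, 4))
  reps <- replicate_set(Z)
  expect_equal(distil_cc_q75(reps), 0.2, tolerance = 1e-12)
  cons <- modz(reps)
  expect_false(cons$passed_qc)
  Z2 <- cbind(1:5, c(1, 3, 5, 2, 4)) # correlation 0.6
  expect_true(modz(replicate_set(Z2))$passed_qc)
})

test_that("genes whose MODZ is zero get p = 1", {
  Z <- rbind(c(-1, 1), c(2, 2), c(0.5, -0.5))
  reps <- replicate_set(Z)
  p <- eb_weighted_ttest(reps)
  expect_equal(p[1], 1)
  expect_equal(p[3], 1)
})

test_that("disabling shrinkage recovers the ordinary weighted one-sample t-test", {
  withr::with_seed(67, Z <- matrix(rnorm(200 * 4, mean = 0.3), ncol = 4))
  reps <- replicate_set(Z)
  # equal weights: compare to the textbook one-sample t-test per gene
  w <- rep(0.25, 4)
  p <- eb_weighted_ttest(reps, weights = w, prior_df = 0)
  for (g in c(1, 57, 123, 200)) {
    expect_equal(p[g], t.test(Z[g, ])$p.value, tolerance = 1e-10)
  }
})

test_that("EB shrinkage pulls every variance strictly between its own and the prior", {
  withr::with_seed(68, Z <- matrix(rnorm(500 * 4, sd = rep(sqrt(rchisq(500, 5) / 5), 4)),
                                   ncol = 4))
  reps <- replicate_set(Z)
  w <- modz_weights(reps)
  mu <- as.numeric(Z %*% w)
  s2 <- as.numeric(((Z - mu)^2) %*% w) / (1 - sum(w^2))
  fit <- limma::squeezeVar(s2, df = 3)
  if (is.finite(fit$df.prior)) {
    lo <- pmin(s2, fit$var.prior)
    hi <- pmax(s2, fit$var.prior)
    inner <- abs(s2 - fit$var.prior) > 1e-8
    expect_true(all(fit$var.post[inner] > lo[inner] & fit$var.post[inner] < hi[inner]))
  }
  expect_true(all(eb_weighted_ttest(reps) > 0 & eb_weighted_ttest(reps) <= 1))
})

test_that("the EB weighted t-test is calibrated under the null", {
  withr::with_seed(70, Z <- matrix(rnorm(2000 * 4), ncol = 4))
  p <- eb_weighted_ttest(replicate_set(Z))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("CGS aggregation reduces to the identity for one or two identical members", {
  withr::with_seed(71, sig <- random_signature(60))
  one <- cgs_aggregate(list(sig))
  expect_equal(one$signature$log2fc, sig$log2fc)
  two <- suppressWarnings(cgs_aggregate(list(sig, sig))) # zero residual variance
  expect_equal(two$signature$log2fc, sig$log2fc)
  expect_equal(sig_meta(two$signature)$signature_type, "CGS")
})

test_that("CGS aggregation rejects conflicting target genes", {
  withr::with_seed(72, {
    a <- as_signature(random_signature(20), meta = list(target_gene = "MTOR"))
    b <- as_signature(random_signature(20), meta = list(target_gene = "EGFR"))
  })
  expect_error(cgs_aggregate(list(a, b)), class = "sigconn_validation_error")
})

test_that("a CGS of noisy knockdown signatures tracks the latent profile better than the median member", {
  withr::with_seed(73, {
    latent <- rnorm(400)
    members <- lapply(1:3, function(i) {
      as_signature(tibble::tibble(
        gene_id = sprintf("G%04d", 1:400),
        log2fc = latent + rnorm(400, 0, 0.6)
      ), meta = list(target_gene = "MTOR"))
    })
  })
  cgs <- cgs_aggregate(members)
  member_cors <- sapply(members, function(m) cor(m$log2fc, latent))
  expect_gt(cor(cgs$signature$log2fc, latent), median(member_cors))
})
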