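make_toy_dataset <- function() {
  withr::with_seed(81, {
    X <- matrix(rnorm(20 * 9, mean = 8, sd = 2), nrow = 20)
    expression_dataset(
      X, gene_ids = sprintf("G%02d", 1:20), sample_ids = sprintf("S%d", 1:9),
      samples = tibble::tibble(
        sample_id = sprintf("S%d", 1:9),
        cell_line = c(rep("A549", 6), rep("MCF7", 3)),
        treatment = rep(c("drug", "vehicle", "drug"), 3)
      )
    )
  })
}

test_that("an all-pass filter is the identity and filters compose commutatively", {
  ds <- make_toy_dataset()
  all_kept <- filter_samples(ds, cell_line %in% c("A549", "MCF7"))
  expect_equal(all_kept$X, ds$X)
  f12 <- filter_samples(filter_samples(ds, cell_line == "A549"), treatment == "drug")
  f21 <- filter_samples(filter_samples(ds, treatment == "drug"), cell_line == "A549")
  expect_equal(f12$X, f21$X)
  expect_equal(f12$sample_ids, f21$sample_ids)
})

test_that("filtering selects by annotation and records provenance", {
  ds <- make_toy_dataset()
  a549 <- filter_samples(ds, cell_line == "A549")
  expect_equal(ncol(a549$X), 6)
  expect_match(a549$meta$sample_filters, "A549")
  expect_error(filter_samples(ds, cell_line == "HELA"),
               class = "sigconn_empty_selection_error")
})

test_that("identical group means give a zero signature with p = 1", {
  withr::with_seed(82, half <- matrix(rnorm(30 * 3, 8), nrow = 30))
  X <- cbind(half, half) # group B duplicates group A exactly
  ds <- expression_dataset(X, gene_ids = sprintf("G%02d", 1:30),
                           sample_ids = sprintf("S%d", 1:6))
  sig <- create_signature(ds, sprintf("S%d", 1:3), sprintf("S%d", 4:6))
  expect_equal(sig$log2fc, rep(0, 30))
  expect_equal(sig$p_value, rep(1, 30))
})

test_that("swapping the groups negates the effect and preserves the p-values", {
  sims <- simulate_diffexp(n_genes = 200, n_per_group = 4, n_affected = 20,
                           effect_size = 1.5, seed = 83)
  ab <- create_signature(sims$dataset, group == "A", group == "B")
  ba <- create_signature(sims$dataset, group == "B", group == "A")
  expect_equal(ba$log2fc, -ab$log2fc)
  expect_equal(ba$p_value, ab$p_value)
})

test_that("group selectors accept both sample ids and annotation predicates", {
  sims <- simulate_diffexp(n_genes = 50, n_per_group = 3, seed = 84)
  ds <- sims$dataset
  by_pred <- create_signature(ds, group == "A", group == "B")
  by_ids <- create_signature(ds, ds$sample_ids[1:3], ds$sample_ids[4:6])
  expect_equal(by_pred$log2fc, by_ids$log2fc)
  expect_error(create_signature(ds, ds$sample_ids[1:3], ds$sample_ids[3:6]),
               class = "sigconn_validation_error") # overlap
  expect_error(create_signature(ds, ds$sample_ids[1], ds$sample_ids[4:6]),
               class = "sigconn_validation_error") # <2 samples
  expect_error(create_signature(ds, c("NOPE"), ds$sample_ids[4:6]),
               class = "sigconn_validation_error")
})

test_that("disabling shrinkage recovers the ordinary pooled two-sample t-test", {
  sims <- simulate_diffexp(n_genes = 100, n_per_group = 5, n_affected = 10,
                           effect_size = 1, seed = 85)
  sig <- create_signature(sims$dataset, group == "A", group == "B", prior_df = 0)
  X <- sims$dataset$X
  for (g in c(1, 42, 100)) {
    want <- t.test(X[g, 1:5], X[g, 6:10], var.equal = TRUE)$p.value
    expect_equal(sig$p_value[g], want, tolerance = 1e-10)
  }
})

test_that("the moderated test agrees with the limma empirical-Bayes route", {
  sims <- simulate_diffexp(n_genes = 300, n_per_group = 4, n_affected = 30,
                           effect_size = 2, seed = 86)
  sig <- create_signature(sims$dataset, group == "A", group == "B")
  design <- cbind(intercept = 1, groupA = rep(c(1, 0), each = 4))
  fit <- limma::eBayes(limma::lmFit(sims$dataset$X, design))
  expect_equal(sig$log2fc, unname(fit$coefficients[, "groupA"]), tolerance = 1e-10)
  expect_equal(sig$p_value, unname(fit$p.value[, "groupA"]), tolerance = 1e-8)
})

test_that("planted effects are recovered near the top of the p-value ranking", {
  sims <- simulate_diffexp(n_genes = 1000, n_per_group = 5, n_affected = 50,
                           effect_size = 2, sigma = 1, seed = 87)
  sig <- create_signature(sims$dataset, group == "A", group == "B")
  ranks <- rank(sig$p_value)[match(sims$truth$gene_id, sig$gene_id)]
  expect_lt(median(ranks), 100) # median planted rank within the top 10%
})

test_that("null p-values are uniform (KS at the 1% level)", {
  sims <- simulate_diffexp(n_genes = 500, n_per_group = 5, seed = 88)
  sig <- create_signature(sims$dataset, group == "A", group == "B")
  ks <- suppressWarnings(stats::ks.test(sig$p_value, "punif"))
  expect_lt(ks$statistic, 1.628 / sqrt(500))
})

test_that("count-like matrices trigger the log-transform warning", {
  counts <- matrix(rpois(40, 200), nrow = 10)
  expect_warning(expression_dataset(counts), "log2")
})
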