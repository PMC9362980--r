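test_that("extreme Pearson of a signature with itself is 1, with its negation -1", {
  withr::with_seed(1, sig <- random_signature(30))
  self <- extreme_pearson(sig, sig, k = 5)
  expect_equal(self$score, 1.0)
  neg <- sig
  neg$log2fc <- -neg$log2fc
  expect_equal(extreme_pearson(sig, neg, k = 5)$score, -1.0)
})

test_that("extreme Pearson matches the brute-force tail-select oracle", {
  withr::with_seed(7, {
    for (i in 1:50) {
      a <- random_signature(20)
      b <- random_signature(20)
      got <- extreme_pearson(a, b, k = 5)
      want <- oracle_extreme_pearson(a$log2fc, a$p_value, b$log2fc, b$p_value, k = 5)
      expect_equal(got$score, want, tolerance = 1e-13)
      expect_equal(got$n_genes_used, 20L)
    }
  })
})

test_that("extreme Pearson is symmetric in its arguments", {
  withr::with_seed(11, {
    a <- random_signature(40)
    b <- random_signature(40)
  })
  expect_equal(extreme_pearson(a, b, k = 8)$score, extreme_pearson(b, a, k = 8)$score)
  expect_equal(extreme_pearson(a, b, k = 8)$p_value, extreme_pearson(b, a, k = 8)$p_value)
})

test_that("extreme Pearson scores over the gene-space intersection", {
  withr::with_seed(3, {
    a <- random_signature(30, gene_ids = sprintf("G%04d", 1:30))
    b <- random_signature(30, gene_ids = sprintf("G%04d", 11:40))
  })
  res <- extreme_pearson(a, b, k = 4)
  expect_equal(res$n_genes_used, 20L)
  tiny_a <- a[1:2, ]
  tiny_b <- b[20:21, ]
  expect_error(extreme_pearson(tiny_a, a[5:8, ], k = 1),
               class = "sigconn_overlap_error")
})

test_that("union_nonzero support restricts the correlation to extreme genes", {
  withr::with_seed(5, {
    a <- random_signature(50)
    b <- random_signature(50)
  })
  res <- extreme_pearson(a, b, k = 5, extreme_support = "union_nonzero")
  expect_lte(res$n_genes_used, 20L) # at most 2k per signature, overlapping
  expect_gte(res$n_genes_used, 10L)
})

test_that("uniform weights reduce the weighted correlation to textbook Pearson", {
  withr::with_seed(21, {
    n <- 60
    q <- as_signature(tibble::tibble(gene_id = sprintf("G%02d", 1:n),
                                     log2fc = rnorm(n), p_value = rep(0.05, n)))
    l <- as_signature(tibble::tibble(gene_id = sprintf("G%02d", 1:n),
                                     log2fc = rnorm(n), p_value = rep(0.01, n)))
  })
  expect_equal(weighted_correlation(q, l)$score, cor(q$log2fc, l$log2fc),
               tolerance = 1e-14)
})

test_that("a query without p-values uses library weights only, matching the explicit formula", {
  withr::with_seed(22, {
    n <- 40
    genes <- sprintf("G%02d", 1:n)
    q <- as_signature(tibble::tibble(gene_id = genes, log2fc = rnorm(n)))
    l <- random_signature(n, genes)
  })
  got <- weighted_correlation(q, l)
  w <- -log10(l$p_value)
  expect_equal(got$score, oracle_weighted_cor(q$log2fc, l$log2fc, w),
               tolerance = 1e-13)
  expect_equal(got$metric, "weighted_correlation")
})

test_that("full-signature weighted correlation matches the explicit product-weight formula", {
  withr::with_seed(23, {
    n <- 40
    genes <- sprintf("G%02d", 1:n)
    q <- random_signature(n, genes)
    l <- random_signature(n, genes)
  })
  got <- weighted_correlation(q, l)
  w <- (-log10(q$p_value)) * (-log10(l$p_value))
  keep <- w > 0
  expect_equal(got$score,
               oracle_weighted_cor(q$log2fc[keep], l$log2fc[keep], w[keep]),
               tolerance = 1e-13)
})

test_that("weighted correlation is invariant to positive scaling of the query", {
  withr::with_seed(24, l <- random_signature(50))
  q <- l
  q$log2fc <- 2 * q$log2fc
  expect_equal(weighted_correlation(q, l)$score, 1.0)
})

test_that("degenerate weights are rejected", {
  n <- 10
  genes <- sprintf("G%02d", 1:n)
  q <- as_signature(tibble::tibble(gene_id = genes, log2fc = rnorm(n)))
  l <- as_signature(tibble::tibble(gene_id = genes, log2fc = rnorm(n),
                                   p_value = rep(1, n)))
  expect_error(weighted_correlation(q, l), class = "sigconn_degenerate_error")
})

test_that("perfect up/down concordance scores 1 and label swap negates the score", {
  lib <- as_signature(tibble::tibble(
    gene_id = sprintf("G%02d", 1:10),
    log2fc = c(rep(1, 5), rep(-1, 5)),
    p_value = runif(10, 0.001, 0.5)
  ))
  q <- updown_query(up = sprintf("G%02d", 1:5), down = sprintf("G%02d", 6:10))
  expect_equal(updown_correlation(q, lib)$score, 1.0)
  swapped <- updown_query(up = sprintf("G%02d", 6:10), down = sprintf("G%02d", 1:5))
  withr::with_seed(31, lib2 <- random_signature(10, sprintf("G%02d", 1:10)))
  r1 <- updown_correlation(q, lib2)
  r2 <- updown_correlation(swapped, lib2)
  expect_equal(r2$score, -r1$score)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("up/down significance equals the two-sample equal-variance t-test", {
  withr::with_seed(32, {
    for (i in 1:200) {
      n_up <- sample(3:15, 1)
      n_dn <- sample(3:15, 1)
      genes <- sprintf("G%03d", 1:30)
      lib <- random_signature(30, genes)
      ids <- sample(genes, n_up + n_dn)
      q <- updown_query(up = ids[1:n_up], down = ids[(n_up + 1):(n_up + n_dn)])
      got <- updown_correlation(q, lib)
      a <- lib$log2fc[match(intersect(q$up, lib$gene_id), lib$gene_id)]
      b <- lib$log2fc[match(intersect(q$down, lib$gene_id), lib$gene_id)]
      want <- oracle_ttest_p(a, b)
      expect_equal(got$p_value, want, tolerance = 1e-10)
      # and the stats t.test route agrees too
      expect_equal(got$p_value, t.test(a, b, var.equal = TRUE)$p.value,
                   tolerance = 1e-10)
    }
  })
})

test_that("an up/down query that cannot populate both sides degrades to the gene-list metric", {
  withr::with_seed(33, lib <- random_signature(20, sprintf("G%02d", 1:20)))
  q <- updown_query(up = c("G01", "G02"), down = "ZZZ9")
  expect_warning(res <- updown_correlation(q, lib), "Random Set")
  expect_equal(res$metric, "random_set")
})

test_that("gene-list scoring follows the closed-form Random Set moments", {
  withr::with_seed(41, lib <- random_signature(50, sprintf("G%02d", 1:50)))
  q <- genelist_query(sprintf("G%02d", c(3, 9, 17, 30, 42, 44, 45, 50)))
  got <- random_set_score(q, lib)
  g <- -log10(lib$p_value)
  m <- 8
  N <- 50
  mu <- mean(g)
  sigma2 <- mean((g - mu)^2)
  sigma_m2 <- (N - m) / (N - 1) * sigma2 / m
  xbar <- mean(g[match(q$genes, lib$gene_id)])
  expect_equal(got$score, (xbar - mu) / sqrt(sigma_m2), tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pnorm(-abs(got$score)), tolerance = 1e-12)
  expect_equal(got$n_genes_used, 8L)
})

test_that("a single-gene member set has the full population variance", {
  withr::with_seed(42, lib <- random_signature(30, sprintf("G%02d", 1:30)))
  g <- -log10(lib$p_value)
  rs <- random_set_z(g, c(TRUE, rep(FALSE, 29)))
  expect_equal(rs$sigma_m2, mean((g - mean(g))^2), tolerance = 1e-12)
})

test_that("constant library significances give z = 0, p = 1", {
  lib <- as_signature(tibble::tibble(gene_id = sprintf("G%02d", 1:10),
                                     log2fc = rnorm(10), p_value = rep(0.05, 10)))
  res <- random_set_score(genelist_query(c("G01", "G02")), lib)
  expect_equal(res$score, 0)
  expect_equal(res$p_value, 1)
})

test_that("the gene-list statistic depends only on membership and the score multiset", {
  withr::with_seed(43, lib <- random_signature(40, sprintf("G%02d", 1:40)))
  q <- genelist_query(sprintf("G%02d", 1:6))
  base <- random_set_score(q, lib)
  shuffled <- lib
  nonmember <- which(!lib$gene_id %in% q$genes)
  perm <- withr::with_seed(44, sample(nonmember))
  shuffled$log2fc[nonmember] <- lib$log2fc[perm]
  shuffled$p_value[nonmember] <- lib$p_value[perm]
  moved <- random_set_score(q, shuffled)
  expect_equal(moved$score, base$score, tolerance = 1e-12)
  expect_equal(moved$p_value, base$p_value, tolerance = 1e-12)
})

test_that("gene-list queries with no or full overlap are rejected", {
  withr::with_seed(45, lib <- random_signature(10, sprintf("G%02d", 1:10)))
  expect_error(random_set_score(genelist_query("ZZZZ"), lib),
               class = "sigconn_overlap_error")
  expect_error(random_set_score(genelist_query(lib$gene_id), lib),
               class = "sigconn_degenerate_error")
})
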