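#' Replicate z-score sets
#'
#' Container for the Level-4-style replicate signatures of one perturbation:
#' a genes x replicates matrix of z-scores destined for moderated Z-score
#' (MODZ) consensus aggregation.
#'
#' @param Z Numeric matrix (genes in rows, replicates in columns) or a data
#'   frame with a `gene_id` column followed by one numeric column per
#'   replicate.
#' @param gene_ids,replicate_ids Optional ids; default to the dimnames.
#' @param meta Named list (perturbagen, cell line, dose, time, ...).
#' @return An object of class `replicate_set`.
#' @export
replicate_set <- function(Z, gene_ids = NULL, replicate_ids = NULL, meta = list()) {
  if (is.data.frame(Z)) {
    stopifnot("gene_id" %in% names(Z))
    gene_ids <- gene_ids %||% as.character(Z$gene_id)
    Z <- as.matrix(Z[setdiff(names(Z), "gene_id")])
  }
  Z <- as.matrix(Z)
  gene_ids <- toupper(gene_ids %||% rownames(Z) %||% sprintf("G%05d", seq_len(nrow(Z))))
  replicate_ids <- replicate_ids %||% colnames(Z) %||% sprintf("rep_%02d", seq_len(ncol(Z)))
  if (anyDuplicated(gene_ids)) {
    abort("duplicated gene ids in replicate set", class = "sigconn_validation_error")
  }
  if (anyDuplicated(replicate_ids)) {
    abort("duplicated replicate ids", class = "sigconn_validation_error")
  }
  if (ncol(Z) < 1) abort("at least one replicate required", class = "sigconn_validation_error")
  if (any(!is.finite(Z))) {
    abort("replicate z-scores must be finite (impute or drop at load time)",
          class = "sigconn_validation_error")
  }
  dimnames(Z) <- list(gene_ids, replicate_ids)
  structure(list(gene_ids = gene_ids, Z = Z, replicate_ids = replicate_ids,
                 meta = as.list(meta)),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("# A replicate set: ", nrow(x$Z), " genes x ", ncol(x$Z), " replicates\n", sep = "")
  invisible(x)
}

## pairwise Spearman correlation matrix over the full gene vectors;
## pairs involving a constant replicate get correlation 0 (with a warning).
spearman_matrix <- function(Z) {
  const <- apply(Z, 2, function(col) length(unique(col)) == 1)
  C <- suppressWarnings(cor(Z, method = "spearman"))
  if (any(const)) {
    warn("constant replicate column: undefined Spearman correlations set to 0")
    C[const, ] <- 0
    C[, const] <- 0
    diag(C) <- 1
  }
  C
}

#' MODZ replicate weights
#'
#' Weights for the moderated Z-score weighted average: with one or two
#' replicates the weights are equal; with three or more, each replicate's raw
#' weight is the mean of its pairwise Spearman correlations (over all genes)
#' with the other replicates, clipped below at 0.01, then normalized to sum
#' to one. The clip keeps anti-correlated outlier replicates from receiving
#' negative or zero weight while still down-weighting them heavily.
#'
#' @param reps A [replicate_set()] (or bare matrix).
#' @return Named numeric weight vector summing to 1.
#' @export
modz_weights <- function(reps) {
  if (!inherits(reps, "replicate_set")) reps <- replicate_set(reps)
  R <- ncol(reps$Z)
  if (R <= 2) {
    return(setNames(rep(1 / R, R), reps$replicate_ids))
  }
  C <- spearman_matrix(reps$Z)
  raw <- (rowSums(C) - 1) / (R - 1) # mean correlation with the other replicates
  clipped <- pmax(raw, 0.01)
  setNames(clipped / sum(clipped), reps$replicate_ids)
}

#' Moderated Z-score consensus signature
#'
#' Collapses Level-4-style replicate z-scores into a Level-5-style consensus:
#' per gene, the weighted average \eqn{\mathrm{MODZ}_g = \sum_i w_i Z_{gi}}
#' with the correlation-based weights of [modz_weights()]. When `p_values =
#' TRUE` (default, needs at least two replicates) each gene's consensus is
#' tested against zero with the empirical-Bayes weighted t-test
#' ([eb_weighted_ttest()]) using the same weights.
#'
#' @param reps A [replicate_set()].
#' @param p_values Attach EB weighted t-test p-values (requires >= 2
#'   replicates).
#' @param prior_df Passed to [eb_weighted_ttest()].
#' @return An object of class `consensus_signature`: a list with the
#'   consensus `signature` (a `cmap_sig` tibble), the replicate `weights`,
#'   the reproducibility statistic `qc_q75` ([distil_cc_q75()]; `NA` when
#'   fewer than two replicates) and the `passed_qc` flag (`NA` =
#'   not assessed).
#' @examples
#' sims <- simulate_replicates(n_genes = 100, n_replicates = 4, seed = 3)
#' cons <- modz(sims$replicates)
#' glance(cons)
#' @export
modz <- function(reps, p_values = TRUE, prior_df = NULL) {
  if (!inherits(reps, "replicate_set")) reps <- replicate_set(reps)
  w <- modz_weights(reps)
  d <- as.numeric(reps$Z %*% w)
  sig <- tibble(gene_id = reps$gene_ids, log2fc = d)
  R <- ncol(reps$Z)
  if (p_values && R >= 2) {
    p <- tryCatch(eb_weighted_ttest(reps, w, prior_df = prior_df),
                  sigconn_degenerate_error = function(e) {
                    warn("replicates carry no residual variance; p-values omitted")
                    NULL
                  })
    if (!is.null(p)) sig$p_value <- p
  }
  qc <- if (R >= 2) distil_cc_q75(reps) else NA_real_
  structure(
    list(
      signature = as_signature(sig, meta = reps$meta),
      weights = w,
      qc_q75 = qc,
      passed_qc = if (is.na(qc)) NA else qc > 0.2,
      n_replicates = R
    ),
    class = "consensus_signature"
  )
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat("# A MODZ consensus of ", x$n_replicates, " replicates; distil_cc_q75 = ",
      formatC(x$qc_q75, digits = 3, format = "fg"),
      " (passed: ", format(x$passed_qc), ")\n", sep = "")
  print(x$signature, ...)
  invisible(x)
}

#' Replicate reproducibility QC (distil_cc_q75)
#'
#' The 75th percentile (type-7 linear interpolation) of the pairwise
#' Spearman correlations among a perturbation's replicate signatures. A
#' signature passes QC when the statistic exceeds 0.2 (strictly).
#'
#' @param reps A [replicate_set()] with at least two replicates.
#' @return The QC statistic (scalar in \[-1, 1\]).
#' @export
distil_cc_q75 <- function(reps) {
  if (!inherits(reps, "replicate_set")) reps <- replicate_set(reps)
  if (ncol(reps$Z) < 2) {
    abort("QC needs at least two replicates", class = "sigconn_validation_error")
  }
  C <- spearman_matrix(reps$Z)
  unname(quantile(C[upper.tri(C)], 0.75, type = 7))
}

#' Empirical-Bayes weighted one-sample t-test against zero
#'
#' Tests, per gene, whether the MODZ consensus differs from zero, reusing the
#' MODZ replicate weights: the weighted mean is the MODZ value, the weighted
#' variance is \eqn{s_g^2 = \sum_i w_i (Z_{gi} - \mathrm{MODZ}_g)^2 /
#' (1 - \sum_i w_i^2)} (unbiased for weights that sum to one), gene-wise
#' variances are shrunk toward a common prior by the standard
#' scaled-inverse-chi-square moment-matching fit on log variances
#' (`limma::squeezeVar`), and the moderated statistic
#' \eqn{t_g = \mathrm{MODZ}_g / \sqrt{\tilde s_g^2 \sum_i w_i^2}} is referred
#' to a t distribution with \eqn{d_0 + (R - 1)} degrees of freedom.
#'
#' Genes with exactly zero weighted variance are excluded from the prior fit
#' and assigned the prior variance.
#'
#' @param reps A [replicate_set()] with `R >= 2` replicates.
#' @param weights Replicate weights summing to 1; defaults to
#'   [modz_weights()].
#' @param prior_df Override for the prior degrees of freedom \eqn{d_0}. The
#'   default `NULL` estimates it from the data; `0` disables shrinkage and
#'   reduces the test to the ordinary weighted one-sample t-test.
#' @return Numeric vector of two-sided p-values, one per gene.
#' @export
eb_weighted_ttest <- function(reps, weights = NULL, prior_df = NULL) {
  if (!inherits(reps, "replicate_set")) reps <- replicate_set(reps)
  R <- ncol(reps$Z)
  if (R < 2) {
    abort("replicate-level inference needs at least two replicates",
          class = "sigconn_validation_error")
  }
  w <- weights %||% modz_weights(reps)
  stopifnot(length(w) == R, all(w >= 0))
  w <- w / sum(w)
  mu <- as.numeric(reps$Z %*% w)
  sq_dev <- (reps$Z - mu)^2 # recycles mu down gene rows
  s2 <- as.numeric(sq_dev %*% w) / (1 - sum(w^2))
  df_resid <- R - 1
  sh <- squeeze_variances(s2, df_resid, prior_df)
  tstat <- mu / sqrt(sh$var_post * sum(w^2))
  2 * pt(-abs(tstat), df = sh$df_prior + df_resid)
}

## EB variance shrinkage shared by eb_weighted_ttest() and
## create_signature(); zero variances are excluded from the prior fit and
## assigned the prior variance. prior_df = 0 disables shrinkage; NULL
## estimates it (limma moment matching on log variances).
squeeze_variances <- function(s2, df_resid, prior_df = NULL) {
  pos <- s2 > 0
  if (!is.null(prior_df) && prior_df == 0) {
    return(list(var_post = s2, df_prior = 0, var_prior = NA_real_))
  }
  if (!any(pos)) {
    abort("all gene variances are zero; cannot fit a variance prior",
          class = "sigconn_degenerate_error")
  }
  fit <- limma::squeezeVar(s2[pos], df = df_resid)
  d0 <- fit$df.prior
  s02 <- fit$var.prior
  if (!is.null(prior_df)) {
    d0 <- prior_df
    var_post <- (d0 * s02 + df_resid * s2) / (d0 + df_resid)
  } else {
    var_post <- s2
    var_post[pos] <- fit$var.post
  }
  var_post[!pos] <- s02
  list(var_post = var_post, df_prior = d0, var_prior = s02)
}

#' Consensus gene signatures (CGS) across perturbations of one target
#'
#' shRNA and CRISPR knockdown signatures targeting the same gene are
#' aggregated into a single consensus gene signature by the same machinery
#' used for replicate aggregation: the member signatures' differential
#' expression vectors become the columns of a [replicate_set()] and are
#' combined by [modz()] with EB weighted t-test p-values.
#'
#' @param sigs A list of signatures (or `consensus_signature` objects)
#'   sharing a gene space and, if annotated, the same `target_gene`
#'   metadata.
#' @param target_gene Optional target gene recorded in the result metadata;
#'   inferred from member metadata when consistent.
#' @param prior_df Passed to [eb_weighted_ttest()].
#' @return A `consensus_signature` with `signature_type = "CGS"`.
#' @export
cgs_aggregate <- function(sigs, target_gene = NULL, prior_df = NULL) {
  if (inherits(sigs, "cmap_sig") || inherits(sigs, "consensus_signature")) {
    sigs <- list(sigs)
  }
  sigs <- lapply(sigs, function(s) {
    if (inherits(s, "consensus_signature")) s$signature else as_signature(s)
  })
  if (length(sigs) == 0) {
    abort("no signatures to aggregate", class = "sigconn_validation_error")
  }
  targets <- unlist(lapply(sigs, function(s) sig_meta(s)$target_gene))
  targets <- unique(targets[!is.na(targets)])
  if (length(targets) > 1) {
    abort(paste0("conflicting target genes: ", paste(targets, collapse = ", ")),
          class = "sigconn_validation_error")
  }
  target_gene <- target_gene %||% if (length(targets) == 1) targets else NULL
  gene_ids <- sigs[[1]]$gene_id
  same_space <- all(vapply(sigs, function(s) setequal(s$gene_id, gene_ids), logical(1)))
  if (!same_space) {
    abort("member signatures must share one gene space",
          class = "sigconn_validation_error")
  }
  Z <- vapply(sigs, function(s) s$log2fc[match(gene_ids, s$gene_id)],
              numeric(length(gene_ids)))
  Z <- matrix(Z, nrow = length(gene_ids))
  ids <- names(sigs) %||% vapply(seq_along(sigs), function(i) {
    sig_meta(sigs[[i]])$signature_id %||% sprintf("member_%02d", i)
  }, character(1))
  reps <- replicate_set(Z, gene_ids = gene_ids, replicate_ids = make.unique(ids),
                        meta = list(signature_type = "CGS", target_gene = target_gene))
  modz(reps, p_values = length(sigs) >= 2, prior_df = prior_df)
}
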