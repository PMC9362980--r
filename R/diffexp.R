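#' Expression datasets
#'
#' A genes x samples matrix of log-scale expression values plus per-sample
#' annotations (group labels, confounder levels). This is the input to
#' two-group signature construction; raw RNA-seq counts are out of scope and
#' should be transformed (e.g. `log2(CPM + 1)`) beforehand — the constructor
#' warns when a matrix looks like raw counts (integer-valued with a maximum
#' above 50).
#'
#' @param X Numeric matrix, genes in rows and samples in columns.
#' @param gene_ids,sample_ids Optional ids; default to the dimnames.
#' @param samples Optional data frame of sample annotations with a
#'   `sample_id` column.
#' @param meta Named list of dataset-level metadata.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(X, gene_ids = NULL, sample_ids = NULL,
                               samples = NULL, meta = list()) {
  X <- as.matrix(X)
  gene_ids <- toupper(gene_ids %||% rownames(X) %||% sprintf("G%05d", seq_len(nrow(X))))
  sample_ids <- sample_ids %||% colnames(X) %||% sprintf("S%03d", seq_len(ncol(X)))
  if (ncol(X) < 2) abort("need at least two samples", class = "sigconn_validation_error")
  if (anyDuplicated(gene_ids)) {
    abort("duplicated gene ids", class = "sigconn_validation_error")
  }
  if (anyDuplicated(sample_ids)) {
    abort("duplicated sample ids", class = "sigconn_validation_error")
  }
  if (any(!is.finite(X))) {
    abort("expression values must be finite after load-time filtering",
          class = "sigconn_validation_error")
  }
  if (max(X) > 50 && all(X == round(X))) {
    warn("matrix looks like raw counts (integer-valued, max > 50); transform to log scale, e.g. log2(CPM + 1), before building signatures")
  }
  dimnames(X) <- list(gene_ids, sample_ids)
  if (is.null(samples)) {
    samples <- tibble(sample_id = sample_ids)
  } else {
    samples <- as_tibble(samples)
    stopifnot("sample_id" %in% names(samples))
    if (!setequal(samples$sample_id, sample_ids)) {
      abort("sample annotations do not match the matrix columns",
            class = "sigconn_validation_error")
    }
    samples <- samples[match(sample_ids, samples$sample_id), ]
  }
  structure(list(gene_ids = gene_ids, X = X, sample_ids = sample_ids,
                 samples = samples, meta = as.list(meta)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("# An expression dataset: ", nrow(x$X), " genes x ", ncol(x$X), " samples\n", sep = "")
  ann <- setdiff(names(x$samples), "sample_id")
  if (length(ann)) cat("# sample annotations: ", paste(ann, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Filter samples by annotation
#'
#' Subsets an expression dataset to the samples whose annotations satisfy a
#' predicate — the mechanism for removing confounded samples before
#' constructing a signature (e.g. restricting to one cell line). Filters
#' compose and commute; the predicate text is recorded in the dataset
#' metadata for provenance.
#'
#' @param ds An [expression_dataset()].
#' @param ... Logical predicates over annotation columns, as in
#'   [dplyr::filter()].
#' @return The column-subset [expression_dataset()].
#' @examples
#' \dontrun{
#' filter_samples(ds, cell_line == "A549", dose > 1)
#' }
#' @export
filter_samples <- function(ds, ...) {
  stopifnot(inherits(ds, "expression_dataset"))
  quos <- rlang::enquos(...)
  kept <- dplyr::filter(ds$samples, !!!quos)
  if (nrow(kept) == 0) {
    abort("sample filter selected no samples", class = "sigconn_empty_selection_error")
  }
  keep_idx <- match(kept$sample_id, ds$sample_ids)
  filters <- c(ds$meta$sample_filters,
               vapply(quos, rlang::as_label, character(1)))
  meta <- ds$meta
  meta$sample_filters <- filters
  expression_dataset(ds$X[, keep_idx, drop = FALSE], gene_ids = ds$gene_ids,
                     sample_ids = ds$sample_ids[keep_idx], samples = kept,
                     meta = meta)
}

resolve_group <- function(ds, quo, label) {
  val <- rlang::eval_tidy(quo, data = ds$samples)
  if (is.character(val)) {
    missing_ids <- setdiff(val, ds$sample_ids)
    if (length(missing_ids)) {
      abort(paste0(label, ": unknown sample id(s) ", paste(missing_ids, collapse = ", ")),
            class = "sigconn_validation_error")
    }
    return(match(val, ds$sample_ids))
  }
  if (is.logical(val) && length(val) == ncol(ds$X)) {
    return(which(val))
  }
  abort(paste0(label, " must be sample ids or a logical predicate over annotations"),
        class = "sigconn_validation_error")
}

#' Create a two-group differential-expression signature
#'
#' Builds a perturbation signature by contrasting a treatment group against a
#' baseline group with an empirical-Bayes moderated two-sample t-test:
#' per gene, \eqn{d_g = \bar x_{A,g} - \bar x_{B,g}}, the pooled variance on
#' \eqn{n_A + n_B - 2} degrees of freedom is shrunk toward a common prior
#' (the same scaled-inverse-chi-square fit used in [eb_weighted_ttest()]),
#' and the moderated t is referred to \eqn{d_0 + n_A + n_B - 2} degrees of
#' freedom. Genes with zero pooled variance are assigned the prior variance.
#'
#' @param ds An [expression_dataset()] with log-scale values.
#' @param group_a,group_b Character vectors of sample ids, or unquoted
#'   logical predicates over the sample annotations (evaluated tidily), for
#'   the treatment (A) and baseline (B) group. Groups must be disjoint, with
#'   at least two samples each.
#' @param prior_df Override for the prior degrees of freedom; `0` disables
#'   shrinkage (ordinary pooled two-sample t-test), `NULL` (default)
#'   estimates it.
#' @return A signature tibble (`cmap_sig`) with `gene_id`, `log2fc`
#'   (A minus B) and moderated `p_value`.
#' @examples
#' sims <- simulate_diffexp(n_genes = 100, n_per_group = 4, n_affected = 10,
#'                          effect_size = 2, seed = 11)
#' sig <- create_signature(sims$dataset, group == "A", group == "B")
#' @export
create_signature <- function(ds, group_a, group_b, prior_df = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  ia <- resolve_group(ds, rlang::enquo(group_a), "group_a")
  ib <- resolve_group(ds, rlang::enquo(group_b), "group_b")
  if (length(intersect(ia, ib)) > 0) {
    abort("groups overlap", class = "sigconn_validation_error")
  }
  na <- length(ia)
  nb <- length(ib)
  if (na < 2 || nb < 2) {
    abort("each group needs at least two samples for a variance estimate",
          class = "sigconn_validation_error")
  }
  A <- ds$X[, ia, drop = FALSE]
  B <- ds$X[, ib, drop = FALSE]
  d <- rowMeans(A) - rowMeans(B)
  df_resid <- na + nb - 2
  ss <- rowSums((A - rowMeans(A))^2) + rowSums((B - rowMeans(B))^2)
  s2 <- ss / df_resid
  sh <- squeeze_variances(s2, df_resid, prior_df)
  tstat <- d / sqrt(sh$var_post * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tstat), df = sh$df_prior + df_resid)
  as_signature(
    tibble(gene_id = ds$gene_ids, log2fc = unname(d), p_value = pmax(unname(p), P_FLOOR)),
    meta = c(ds$meta, list(
      signature_type = "user",
      n_group_a = na, n_group_b = nb,
      prior_df = sh$df_prior
    ))
  )
}
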