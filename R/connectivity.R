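#' @noRd
## two-sided p-value for a (possibly weighted) Pearson correlation via the
## t-transform t = r * sqrt(df / (1 - r^2)); df is n - 2 for plain
## correlations and n_eff - 2 for weighted ones. Clamped into (0, 1].
corr_pvalue <- function(r, df) {
  p <- rep(1, length(r))
  ok <- !is.na(r) & df > 0
  tstat <- abs(r[ok]) * sqrt(df[ok] / pmax(1 - r[ok]^2, .Machine$double.eps^2))
  tstat[abs(r[ok]) >= 1] <- Inf
  p[ok] <- 2 * pt(-tstat, df = df[ok])
  p[is.na(r)] <- NA_real_
  pmin(pmax(p, P_FLOOR), 1)
}

connectivity_row <- function(signature_id, metric, score, p_value, n_genes_used,
                             flag = NA_character_) {
  tibble(
    signature_id = unname(signature_id), metric = metric, score = unname(score),
    p_value = unname(p_value), fdr = NA_real_,
    n_genes_used = as.integer(unname(n_genes_used)), flag = unname(flag)
  )
}

## intersect two signatures' gene spaces, preserving the first one's order
intersect_sigs <- function(a, b) {
  genes <- intersect(a$gene_id, b$gene_id)
  list(
    genes = genes,
    a = a[match(genes, a$gene_id), , drop = FALSE],
    b = b[match(genes, b$gene_id), , drop = FALSE]
  )
}

#' Extreme Pearson correlation between two signatures
#'
#' Connectivity metric for pairs of precomputed signatures: both signatures
#' are reduced to signed significances ([signed_significance()]), the tails
#' are kept by [extreme_signature()] with tail size `k`, and the score is the
#' standard Pearson correlation between the two extreme vectors over the
#' intersected gene space (zeros included by default).
#'
#' @param a,b Signatures with p-values.
#' @param k Tail size (default 100).
#' @param extreme_support `"all"` correlates over every intersected gene,
#'   including the zeroed entries (the default); `"union_nonzero"` restricts
#'   to genes that are extreme in at least one of the two signatures.
#' @return A one-row connectivity tibble with columns `signature_id`,
#'   `metric`, `score`, `p_value`, `fdr` (`NA` for a single pair),
#'   `n_genes_used` and `flag`.
#' @export
extreme_pearson <- function(a, b, k = 100, extreme_support = c("all", "union_nonzero")) {
  extreme_support <- match.arg(extreme_support)
  a <- as_signature(a)
  b <- as_signature(b)
  if (!has_p(a) || !has_p(b)) {
    abort("extreme Pearson connectivity needs p-values in both signatures",
          class = "sigconn_query_type_error")
  }
  m <- intersect_sigs(a, b)
  if (length(m$genes) < 3) {
    abort("fewer than 3 genes shared between the signatures",
          class = "sigconn_overlap_error")
  }
  sa <- signed_significance(m$a)$s
  sb <- signed_significance(m$b)$s
  ea <- extreme_transform(sa, as_tail_size(k, length(sa)))
  eb <- extreme_transform(sb, as_tail_size(k, length(sb)))
  if (extreme_support == "union_nonzero") {
    keep <- ea != 0 | eb != 0
    ea <- ea[keep]
    eb <- eb[keep]
  }
  n <- length(ea)
  if (n < 3 || sd(ea) == 0 || sd(eb) == 0) {
    abort(
      paste0("extreme vectors have zero variance over the scored support (n = ", n,
             "); correlation undefined"),
      class = "sigconn_degenerate_error"
    )
  }
  r <- cor(ea, eb)
  connectivity_row(
    signature_id = sig_meta(b)$signature_id %||% NA_character_,
    metric = "extreme_pearson", score = r,
    p_value = corr_pvalue(r, n - 2), n_genes_used = n
  )
}

## validates k and warns (once) when the gene space is smaller than 2k
as_tail_size <- function(k, n_genes) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    abort("`k` must be a single integer >= 1", class = "sigconn_parameter_error")
  }
  if (n_genes < 2 * k) {
    warn(paste0("gene space has ", n_genes, " genes < 2k = ", 2 * k,
                "; all genes retained as extreme"))
  }
  as.integer(k)
}

## weighted Pearson correlation; w >= 0, zero-weight points drop out.
## Returns r plus two effective sample sizes for the p-value t-transform:
## Kish's n_kish = (sum w)^2 / sum w^2 (exact when the weights carry no
## information about x and y) and the data-adjusted
## n_adj = (sum w xc^2)(sum w yc^2) / sum (w xc yc)^2, the self-normalized
## form that stays calibrated when the weights are functions of the
## observations themselves (as -log10 p weights are: p derives from d).
weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  xc <- x - mx
  yc <- y - my
  vx <- sum(w * xc^2)
  vy <- sum(w * yc^2)
  n_kish <- sw^2 / sum(w^2)
  if (vx <= 0 || vy <= 0) {
    return(list(r = NA_real_, n_kish = n_kish, n_adj = n_kish))
  }
  cross2 <- sum((w * xc * yc)^2)
  list(
    r = sum(w * xc * yc) / sqrt(vx * vy),
    n_kish = n_kish,
    n_adj = if (cross2 > 0) vx * vy / cross2 else n_kish
  )
}

#' Weighted correlation connectivity
#'
#' Connectivity metric for user-supplied full signatures: the weighted
#' Pearson correlation between the two vectors of log-differential
#' expressions, with per-gene weight
#' \eqn{w_i = (-\log_{10} p^{query}_i)(-\log_{10} p^{lib}_i)} when the query
#' carries p-values, and \eqn{w_i = -\log_{10} p^{lib}_i} when it does not
#' (differential-expression-only queries). Genes with zero weight drop out.
#'
#' The two-sided p-value uses the correlation t-transform with an effective
#' sample size in place of the gene count. Because the weights are functions
#' of the observations being correlated (a signature's p-values derive from
#' its differential expressions), Kish's classical
#' \eqn{n_{eff} = (\sum w)^2 / \sum w^2} understates the null variance of
#' the weighted correlation and gives anti-conservative p-values. The
#' default `effective_n = "adjusted"` therefore uses the self-normalized
#' form
#' \eqn{n^{*}_{eff} = (\sum_i w_i \tilde x_i^2)(\sum_i w_i \tilde y_i^2) /
#' \sum_i (w_i \tilde x_i \tilde y_i)^2}
#' (with \eqn{\tilde x, \tilde y} centered at the weighted means), which
#' estimates the null variance directly from the weighted products, stays
#' calibrated under data-dependent weights, and coincides with Kish's form
#' asymptotically when the weights carry no information about the data.
#' `effective_n = "kish"` selects the classical form.
#'
#' @param query A signature; `p_value` optional.
#' @param lib A library signature with p-values.
#' @param effective_n `"adjusted"` (default) or `"kish"`; see Details.
#' @return A one-row connectivity tibble (see [extreme_pearson()]).
#' @export
weighted_correlation <- function(query, lib, effective_n = c("adjusted", "kish")) {
  effective_n <- match.arg(effective_n)
  query <- as_signature(query)
  lib <- as_signature(lib)
  if (!has_p(lib)) {
    abort("library signature must carry p-values for the correlation weights",
          class = "sigconn_query_type_error")
  }
  m <- intersect_sigs(query, lib)
  if (length(m$genes) < 3) {
    abort("fewer than 3 genes shared between query and library signature",
          class = "sigconn_overlap_error")
  }
  w_lib <- neg_log10(m$b$p_value)
  w <- if (has_p(query)) neg_log10(m$a$p_value) * w_lib else w_lib
  used <- w > 0
  if (!any(used)) {
    abort("all correlation weights are zero (every p-value equals 1)",
          class = "sigconn_degenerate_error")
  }
  wp <- weighted_pearson(m$a$log2fc[used], m$b$log2fc[used], w[used])
  wp$n_eff <- if (effective_n == "adjusted") wp$n_adj else wp$n_kish
  flag <- NA_character_
  p <- corr_pvalue(wp$r, wp$n_eff - 2)
  if (!is.na(wp$r) && wp$n_eff <= 2) {
    p <- 1
    flag <- "n_eff_le_2"
  }
  connectivity_row(
    signature_id = sig_meta(lib)$signature_id %||% NA_character_,
    metric = "weighted_correlation", score = wp$r, p_value = p,
    n_genes_used = sum(used), flag = flag
  )
}

#' Up/down gene-list connectivity
#'
#' Encodes an up/down query as +1 for upregulated and -1 for downregulated
#' genes and reports the Pearson correlation between that vector and the
#' library signature's log-differential expressions over the matched genes.
#' The correlation's significance is computed through the t-transform, which
#' for a binary regressor is identical to the two-sided two-sample
#' equal-variance t-test comparing the library's differential expression
#' between up- and down-genes (point-biserial equivalence).
#'
#' If, after matching to the library gene space, fewer than 2 genes remain or
#' one of the two sides is empty, the query degrades to the gene-list Random
#' Set metric with a warning.
#'
#' @param query An [updown_query()].
#' @param lib A library signature.
#' @return A one-row connectivity tibble (see [extreme_pearson()]).
#' @export
updown_correlation <- function(query, lib) {
  stopifnot(inherits(query, "updown_query"))
  lib <- as_signature(lib)
  up <- intersect(query$up, lib$gene_id)
  down <- intersect(query$down, lib$gene_id)
  n_dropped <- (length(query$up) - length(up)) + (length(query$down) - length(down))
  if (length(up) + length(down) < 2 || length(up) == 0 || length(down) == 0) {
    warn(paste0(
      "up/down query matches ", length(up), " up and ", length(down),
      " down genes in the library gene space; falling back to the gene-list Random Set metric"
    ))
    return(random_set_score(genelist_query(c(query$up, query$down)), lib))
  }
  x <- c(rep(1, length(up)), rep(-1, length(down)))
  y <- lib$log2fc[match(c(up, down), lib$gene_id)]
  n <- length(x)
  if (sd(y) == 0) {
    return(connectivity_row(
      signature_id = sig_meta(lib)$signature_id %||% NA_character_,
      metric = "updown_correlation", score = NA_real_, p_value = 1,
      n_genes_used = n, flag = "zero_variance"
    ))
  }
  r <- cor(x, y)
  out <- connectivity_row(
    signature_id = sig_meta(lib)$signature_id %||% NA_character_,
    metric = "updown_correlation", score = r,
    p_value = corr_pvalue(r, n - 2), n_genes_used = n
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Gene-list Random Set connectivity
#'
#' Scores the enrichment of highly significant differential expression in the
#' library signature within a submitted gene list, via Random Set analysis:
#' each library gene gets the score \eqn{g_i = -\log_{10} p_i}; the mean
#' score of the matched query genes is standardized by the closed-form mean
#' and variance of a uniformly random gene set of the same size (see
#' [random_set_z()]); p-values are two-sided normal tails.
#'
#' @param query A [genelist_query()] (or character vector of gene ids).
#' @param lib A library signature with p-values.
#' @return A one-row connectivity tibble; `score` holds the enrichment z.
#' @export
random_set_score <- function(query, lib) {
  if (is.character(query)) query <- genelist_query(query)
  stopifnot(inherits(query, "genelist_query"))
  lib <- as_signature(lib)
  if (!has_p(lib)) {
    abort("gene-list connectivity needs library p-values",
          class = "sigconn_query_type_error")
  }
  member <- lib$gene_id %in% query$genes
  m <- sum(member)
  if (m == 0) {
    abort("no query gene found in the library signature's gene space",
          class = "sigconn_overlap_error")
  }
  if (m == nrow(lib)) {
    abort("query covers the entire gene space; enrichment is undefined",
          class = "sigconn_degenerate_error")
  }
  rs <- random_set_z(neg_log10(lib$p_value), member, tail = "two_sided")
  connectivity_row(
    signature_id = sig_meta(lib)$signature_id %||% NA_character_,
    metric = "random_set", score = rs$z, p_value = rs$p, n_genes_used = m
  )
}
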