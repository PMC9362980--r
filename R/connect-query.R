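#' Connect a query to every signature in a library
#'
#' Runs a connectivity-map analysis: one connectivity score, p-value and
#' BH-adjusted FDR per library signature, with the metric dispatched on the
#' query type:
#'
#' * a single signature id present in the library (a precomputed,
#'   library-member query) — extreme Pearson correlation of signed
#'   significances ([extreme_pearson()]);
#' * a full signature tibble with p-values — weighted correlation with
#'   per-gene weights \eqn{(-\log_{10} p^{query})(-\log_{10} p^{lib})}
#'   ([weighted_correlation()]);
#' * a signature tibble without p-values — weighted correlation using
#'   library p-values only;
#' * an [updown_query()] — +1/-1 point-biserial correlation
#'   ([updown_correlation()]);
#' * a [genelist_query()] or character vector of gene ids — Random Set
#'   enrichment ([random_set_score()]).
#'
#' @param query The query (see above).
#' @param library A [signature_library()].
#' @param k Tail size for the extreme Pearson metric (default 100 genes on
#'   each side).
#' @param metric Override the dispatched metric (`"extreme_pearson"` to
#'   score a full signature query the way library members are scored).
#' @param extreme_support See [extreme_pearson()].
#' @param effective_n Effective-sample-size convention for weighted
#'   correlation p-values; see [weighted_correlation()].
#' @return A tibble of class `connectivity_tbl` with one row per library
#'   signature: `signature_id`, `metric`, `score`, `p_value`, `fdr`
#'   (Benjamini-Hochberg across the library), `n_genes_used`, `flag`;
#'   sorted by `p_value` ascending with |score| descending, then id, as
#'   tie-breaks.
#' @examples
#' sims <- simulate_library(n_genes = 200, n_null = 20, rho_pairs = 0.9, seed = 7)
#' res <- connect_query(sims$plants$id_a[1], sims$library, k = 10)
#' head(res)
#' @export
connect_query <- function(query, library, k = 100, metric = NULL,
                          extreme_support = c("all", "union_nonzero"),
                          effective_n = c("adjusted", "kish")) {
  stopifnot(inherits(library, "signature_library"))
  extreme_support <- match.arg(extreme_support)
  effective_n <- match.arg(effective_n)
  qt <- query_type(query, library)
  metric <- metric %||% switch(
    qt,
    member = "extreme_pearson",
    signature = "weighted_correlation",
    diffexp = "weighted_correlation",
    updown = "updown_correlation",
    genelist = "random_set"
  )
  out <- switch(
    metric,
    extreme_pearson = connect_extreme(query, library, qt, k, extreme_support),
    weighted_correlation = connect_weighted(query, library, qt, effective_n),
    updown_correlation = connect_updown(query, library),
    random_set = connect_random_set(query, library),
    abort(paste0("unknown metric '", metric, "'"), class = "sigconn_validation_error")
  )
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out <- out[c("signature_id", "metric", "score", "p_value", "fdr",
               "n_genes_used", "flag")]
  out <- dplyr::arrange(out, .data$p_value, dplyr::desc(abs(.data$score)),
                        .data$signature_id)
  class(out) <- c("connectivity_tbl", class(out))
  attr(out, "query_type") <- qt
  out
}

query_type <- function(query, library) {
  if (inherits(query, "updown_query")) return("updown")
  if (inherits(query, "genelist_query")) return("genelist")
  if (is.character(query)) {
    if (length(query) == 1 && query %in% colnames(library$d)) return("member")
    return("genelist")
  }
  if (is.data.frame(query)) {
    return(if ("p_value" %in% names(query)) "signature" else "diffexp")
  }
  abort("unrecognized query type", class = "sigconn_validation_error")
}

require_lib_p <- function(library, what) {
  if (is.null(library$p)) {
    abort(paste0(what, " requires p-values for every library signature"),
          class = "sigconn_query_type_error")
  }
}

## signed significances for every library column
lib_signed_sig <- function(library) {
  require_lib_p(library, "signed-significance connectivity")
  sign(library$d) * neg_log10(library$p)
}

connect_extreme <- function(query, library, qt, k, extreme_support) {
  S <- lib_signed_sig(library)
  if (qt == "member") {
    sq <- S[, query]
  } else {
    query <- as_signature(query)
    if (!has_p(query)) {
      abort("extreme Pearson connectivity needs query p-values",
            class = "sigconn_query_type_error")
    }
    genes <- intersect(library$gene_ids, query$gene_id)
    if (length(genes) < 3) {
      abort("query shares fewer than 3 genes with the library",
            class = "sigconn_overlap_error")
    }
    S <- S[match(genes, library$gene_ids), , drop = FALSE]
    q <- query[match(genes, query$gene_id), ]
    sq <- signed_significance(q)$s
  }
  k <- as_tail_size(k, nrow(S))
  eq <- extreme_transform(sq, k)
  E <- apply(S, 2, extreme_transform, k = k)
  ids <- colnames(library$d)
  if (extreme_support == "all") {
    n <- nrow(E)
    sds <- apply(E, 2, sd)
    r <- rep(NA_real_, length(ids))
    ok <- sds > 0 & sd(eq) > 0
    if (any(ok)) r[ok] <- as.numeric(cor(eq, E[, ok, drop = FALSE]))
    p <- corr_pvalue(r, rep(n - 2, length(r)))
    n_used <- rep(n, length(ids))
  } else {
    res <- lapply(seq_along(ids), function(j) {
      keep <- eq != 0 | E[, j] != 0
      x <- eq[keep]
      y <- E[keep, j]
      if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
        return(c(NA_real_, NA_real_, length(x)))
      }
      r <- cor(x, y)
      c(r, corr_pvalue(r, length(x) - 2), length(x))
    })
    res <- do.call(rbind, res)
    r <- res[, 1]
    p <- res[, 2]
    n_used <- res[, 3]
  }
  connectivity_row(ids, "extreme_pearson", r, p, n_used,
                   flag = ifelse(is.na(r), "zero_variance", NA_character_))
}

connect_weighted <- function(query, library, qt, effective_n = "adjusted") {
  require_lib_p(library, "weighted correlation connectivity")
  query <- as_signature(query)
  genes <- intersect(library$gene_ids, query$gene_id)
  if (length(genes) < 3) {
    abort("query shares fewer than 3 genes with the library",
          class = "sigconn_overlap_error")
  }
  rows <- match(genes, library$gene_ids)
  D <- library$d[rows, , drop = FALSE]
  W <- neg_log10(library$p[rows, , drop = FALSE])
  q <- query[match(genes, query$gene_id), ]
  if (qt == "signature") {
    W <- W * neg_log10(q$p_value) # recycles down the gene rows
  }
  x <- q$log2fc
  sw <- colSums(W)
  zero_w <- sw == 0
  sw[zero_w] <- NA_real_
  mx <- colSums(W * x) / sw
  my <- colSums(W * D) / sw
  xc <- outer(x, mx, "-")          # genes x signatures, column-centered query
  yc <- D - rep(my, each = nrow(D))
  vx <- colSums(W * xc^2)
  vy <- colSums(W * yc^2)
  cross <- W * xc * yc
  r <- colSums(cross) / sqrt(vx * vy)
  r[!is.finite(r)] <- NA_real_
  n_eff <- if (effective_n == "adjusted") {
    cross2 <- colSums(cross^2)
    ifelse(cross2 > 0, vx * vy / cross2, sw^2 / colSums(W^2))
  } else {
    sw^2 / colSums(W^2)
  }
  p <- corr_pvalue(r, n_eff - 2)
  flag <- rep(NA_character_, ncol(D))
  low <- !is.na(r) & n_eff <= 2
  p[low] <- 1
  flag[low] <- "n_eff_le_2"
  flag[is.na(r)] <- "degenerate"
  connectivity_row(colnames(library$d), "weighted_correlation", r, p,
                   colSums(W > 0), flag = flag)
}

connect_updown <- function(query, library) {
  stopifnot(inherits(query, "updown_query"))
  up <- intersect(query$up, library$gene_ids)
  down <- intersect(query$down, library$gene_ids)
  if (length(up) + length(down) < 2 || length(up) == 0 || length(down) == 0) {
    warn("up/down query does not match both sides in the library gene space; falling back to the gene-list Random Set metric")
    return(connect_random_set(genelist_query(c(query$up, query$down)), library))
  }
  rows <- match(c(up, down), library$gene_ids)
  x <- c(rep(1, length(up)), rep(-1, length(down)))
  Y <- library$d[rows, , drop = FALSE]
  n <- length(x)
  sds <- apply(Y, 2, sd)
  r <- rep(NA_real_, ncol(Y))
  ok <- sds > 0
  if (any(ok)) r[ok] <- as.numeric(cor(x, Y[, ok, drop = FALSE]))
  p <- corr_pvalue(r, rep(n - 2, length(r)))
  p[!ok] <- 1
  connectivity_row(colnames(library$d), "updown_correlation", r, p, rep(n, ncol(Y)),
                   flag = ifelse(ok, NA_character_, "zero_variance"))
}

connect_random_set <- function(query, library) {
  if (is.character(query)) query <- genelist_query(query)
  stopifnot(inherits(query, "genelist_query"))
  require_lib_p(library, "gene-list connectivity")
  member <- library$gene_ids %in% query$genes
  m <- sum(member)
  N <- length(library$gene_ids)
  if (m == 0) {
    abort("no query gene found in the library gene space",
          class = "sigconn_overlap_error")
  }
  if (m == N) {
    abort("query covers the entire library gene space",
          class = "sigconn_degenerate_error")
  }
  G <- neg_log10(library$p)
  mu <- colMeans(G)
  sigma2 <- colMeans((G - rep(mu, each = N))^2)
  x_bar <- colMeans(G[member, , drop = FALSE])
  sigma_m2 <- (N - m) / (N - 1) * sigma2 / m
  z <- ifelse(sigma2 > 0, (x_bar - mu) / sqrt(sigma_m2), 0)
  p <- ifelse(sigma2 > 0, pmin(pmax(2 * pnorm(-abs(z)), P_FLOOR), 1), 1)
  connectivity_row(colnames(library$d), "random_set", z, p, rep(m, ncol(G)))
}

#' @export
print.connectivity_tbl <- function(x, ...) {
  cat("# Connectivity results: ", nrow(x), " library signatures, metric ",
      paste(unique(x$metric), collapse = "/"), "\n", sep = "")
  NextMethod()
}
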