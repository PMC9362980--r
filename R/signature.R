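#' Omics perturbation signatures
#'
#' A signature contrasts perturbed samples against baseline samples and is
#' stored as a tibble with one row per gene: `gene_id` (unique identifier,
#' treated as an opaque string), `log2fc` (log-scale differential expression:
#' a log2 ratio or a z-score, depending on provenance) and, optionally,
#' `p_value` (two-sided p-value in (0, 1]). Free-form metadata (perturbagen,
#' target gene, cell line, `signature_type` such as `"CP"`, `"CGS"`, `"OE"`,
#' `"disease"` or `"user"`) travels in the `"meta"` attribute.
#'
#' `as_signature()` validates any data frame with those columns and returns it
#' as a classed tibble. Gene identifiers are case-normalized to upper case so
#' that gene spaces intersect by exact match.
#'
#' @param x A data frame with columns `gene_id`, `log2fc` and optionally
#'   `p_value`.
#' @param meta Optional named list of metadata; merged over any metadata
#'   already attached to `x`.
#' @return A tibble of class `cmap_sig` with columns `gene_id`, `log2fc`
#'   and (if supplied) `p_value`.
#' @examples
#' sig <- as_signature(data.frame(
#'   gene_id = c("TP53", "MYC", "EGFR"),
#'   log2fc  = c(1.2, -0.8, 0.1),
#'   p_value = c(0.001, 0.04, 0.9)
#' ))
#' signed_significance(sig)
#' @export
as_signature <- function(x, meta = NULL) {
  if (!is.data.frame(x)) {
    abort("a signature must be a data frame", class = "sigconn_validation_error")
  }
  missing_cols <- setdiff(c("gene_id", "log2fc"), names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("signature is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "sigconn_validation_error"
    )
  }
  out <- as_tibble(x)[intersect(c("gene_id", "log2fc", "p_value"), names(x))]
  out$gene_id <- toupper(as.character(out$gene_id))
  if (anyDuplicated(out$gene_id)) {
    abort("duplicated gene identifiers in signature", class = "sigconn_validation_error")
  }
  if (!is.numeric(out$log2fc) || any(!is.finite(out$log2fc))) {
    abort("log2fc must be finite numeric", class = "sigconn_validation_error")
  }
  if (has_p(out)) {
    p <- out$p_value
    if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
      abort("p_value must lie in (0, 1]", class = "sigconn_validation_error")
    }
  }
  old_meta <- attr(x, "meta")
  attr(out, "meta") <- modifyList(as.list(old_meta %||% list()), as.list(meta %||% list()))
  class(out) <- c("cmap_sig", class(tibble()))
  out
}

has_p <- function(sig) "p_value" %in% names(sig)

#' @export
print.cmap_sig <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("# A perturbation signature: ", nrow(x), " genes",
      if (!has_p(x)) " (no p-values)", "\n", sep = "")
  if (length(meta)) {
    cat("# meta: ", paste(names(meta), unlist(lapply(meta, format)), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  print(as_tibble(unclass_sig(x)), ...)
  invisible(x)
}

unclass_sig <- function(x) {
  class(x) <- setdiff(class(x), "cmap_sig")
  x
}

#' Signature metadata
#'
#' @param sig A signature, see [as_signature()].
#' @return Named list of metadata key/value pairs.
#' @export
sig_meta <- function(sig) as.list(attr(sig, "meta") %||% list())

neg_log10 <- function(p) -log10(pmax(p, P_FLOOR))

#' Signed significance of a signature
#'
#' The per-gene signed significance is
#' \deqn{s_i = \mathrm{sign}(d_i) \cdot (-\log_{10} p_i)}
#' where \eqn{d_i} is the log-scale differential expression and \eqn{p_i} the
#' two-sided p-value. Genes with \eqn{p_i = 1} get \eqn{s_i = 0}; p-values are
#' clipped below at 1e-300 before the logarithm so the result is always
#' finite.
#'
#' @param sig A signature with a `p_value` column.
#' @return A tibble with columns `gene_id` and `s` in the gene order of `sig`.
#' @export
signed_significance <- function(sig) {
  sig <- as_signature(sig)
  if (!has_p(sig)) {
    abort(
      paste0(
        "signature carries no p-values, so signed significances are undefined; ",
        "use the weighted-correlation path (library p-values only) instead"
      ),
      class = "sigconn_query_type_error"
    )
  }
  tibble(gene_id = sig$gene_id, s = sign(sig$log2fc) * neg_log10(sig$p_value))
}

## tail-threshold transform shared by extreme_signature() and the vectorized
## library path: keeps s_i if s_i >= (k-th most positive) or s_i <= (k-th most
## negative); ties at either boundary are retained, so more than 2k nonzero
## entries are possible.
extreme_transform <- function(s, k) {
  n <- length(s)
  if (n < 2 * k) {
    return(s)
  }
  part <- sort(s, partial = c(k, n - k + 1))
  lower <- part[k]         # k-th most negative
  upper <- part[n - k + 1] # k-th most positive
  out <- s
  out[s > lower & s < upper] <- 0
  out
}

#' Extreme signed-significance signature
#'
#' Zeroes every signed significance other than the `k` most positive and `k`
#' most negative values. The boundary is inclusive, so ties with the k-th
#' value on either side are retained and the number of nonzero entries can
#' exceed `2k`. When the signature has fewer than `2k` genes every gene is
#' already "extreme" and the vector is returned unchanged (with a warning).
#'
#' @param s A tibble with columns `gene_id` and `s`, as returned by
#'   [signed_significance()], or a signature (converted first).
#' @param k Tail size; the default 100 keeps the top 100 and bottom 100 genes.
#' @return A tibble with columns `gene_id` and `e`.
#' @export
extreme_signature <- function(s, k = 100) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    abort("`k` must be a single integer >= 1", class = "sigconn_parameter_error")
  }
  k <- as.integer(k)
  if (is.data.frame(s) && !"s" %in% names(s)) {
    s <- signed_significance(s)
  }
  if (nrow(s) < 2 * k) {
    warn(paste0("signature has ", nrow(s), " genes < 2k = ", 2 * k,
                "; all genes retained as extreme"))
  }
  tibble(gene_id = s$gene_id, e = extreme_transform(s$s, k))
}

#' Up/down and gene-list query objects
#'
#' `updown_query()` holds disjoint sets of up- and downregulated gene
#' identifiers; connectivity encodes them as +1/-1 and correlates against
#' library log-differential expressions. `genelist_query()` holds a bare gene
#' list scored by Random Set enrichment of the library signature's
#' significances.
#'
#' @param up,down,genes Character vectors of gene identifiers
#'   (case-insensitive).
#' @return An object of class `updown_query` or `genelist_query`.
#' @export
updown_query <- function(up, down) {
  up <- unique(toupper(as.character(up)))
  down <- unique(toupper(as.character(down)))
  if (length(intersect(up, down)) > 0) {
    abort("up and down gene sets must be disjoint", class = "sigconn_validation_error")
  }
  if (length(up) + length(down) == 0) {
    abort("up/down query is empty", class = "sigconn_validation_error")
  }
  structure(list(up = up, down = down), class = "updown_query")
}

#' @rdname updown_query
#' @export
genelist_query <- function(genes) {
  genes <- unique(toupper(as.character(genes)))
  if (length(genes) == 0) {
    abort("gene list query is empty", class = "sigconn_validation_error")
  }
  structure(list(genes = genes), class = "genelist_query")
}

#' @export
print.updown_query <- function(x, ...) {
  cat("# Up/down query: ", length(x$up), " up, ", length(x$down), " down\n", sep = "")
  invisible(x)
}

#' @export
print.genelist_query <- function(x, ...) {
  cat("# Gene-list query: ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}
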