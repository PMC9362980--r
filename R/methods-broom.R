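#' Tidiers for sigconn objects
#'
#' Broom-style accessors: `tidy()` returns the per-gene or per-signature
#' table of an object, `glance()` a one-row summary.
#'
#' @param x The object.
#' @param ... Unused.
#' @name sigconn-tidiers
NULL

#' @rdname sigconn-tidiers
#' @export
tidy.consensus_signature <- function(x, ...) {
  as_tibble(unclass_sig(x$signature))
}

#' @rdname sigconn-tidiers
#' @export
glance.consensus_signature <- function(x, ...) {
  tibble(
    n_genes = nrow(x$signature),
    n_replicates = x$n_replicates,
    qc_q75 = x$qc_q75,
    passed_qc = x$passed_qc,
    min_weight = min(x$weights),
    max_weight = max(x$weights)
  )
}

#' @rdname sigconn-tidiers
#' @export
tidy.signature_library <- function(x, ...) {
  x$meta
}

#' @rdname sigconn-tidiers
#' @export
glance.signature_library <- function(x, ...) {
  tibble(
    n_signatures = ncol(x$d),
    n_genes = nrow(x$d),
    has_p_values = !is.null(x$p),
    gene_space_fingerprint = gene_space_fingerprint(x$gene_ids)
  )
}

#' @rdname sigconn-tidiers
#' @export
tidy.expression_dataset <- function(x, ...) {
  long <- as_tibble(x$X, rownames = "gene_id")
  long <- tidyr::pivot_longer(long, -"gene_id",
                              names_to = "sample_id", values_to = "expression")
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' @rdname sigconn-tidiers
#' @export
glance.expression_dataset <- function(x, ...) {
  tibble(
    n_genes = nrow(x$X),
    n_samples = ncol(x$X),
    annotations = paste(setdiff(names(x$samples), "sample_id"), collapse = ",")
  )
}

#' @rdname sigconn-tidiers
#' @export
tidy.replicate_set <- function(x, ...) {
  long <- as_tibble(x$Z, rownames = "gene_id")
  tidyr::pivot_longer(long, -"gene_id",
                      names_to = "replicate_id", values_to = "z")
}
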