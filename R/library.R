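#' Signature libraries
#'
#' A signature library is an indexed collection of signatures over a single
#' harmonized gene space, with one metadata row per signature (perturbagen,
#' target gene, cell line, signature type). Gene spaces of the member
#' signatures are harmonized to their intersection so that correlation
#' metrics never see missing values; the number of genes dropped from each
#' signature is recorded.
#'
#' @param sigs A named list of signatures ([as_signature()]); names are the
#'   signature identifiers. Unnamed lists get ids `sig_001`, ...
#' @param meta Optional data frame with a `signature_id` column plus any of
#'   `perturbagen`, `target_gene`, `cell_line`, `signature_type`. Rows are
#'   matched to `sigs` by id; missing fields become `NA`.
#' @return An object of class `signature_library` with components
#'   `gene_ids` (harmonized gene space), `d` and `p` (genes x signatures
#'   matrices; `p` is `NULL` if any member lacks p-values), `meta` (tibble,
#'   one row per signature, including `n_dropped` genes lost to
#'   harmonization).
#' @examples
#' sims <- simulate_library(n_genes = 50, n_null = 4, seed = 1)
#' lib <- sims$library
#' glance(lib)
#' @export
signature_library <- function(sigs, meta = NULL) {
  if (length(sigs) == 0) {
    abort("signature library must contain at least one signature",
          class = "sigconn_validation_error")
  }
  sigs <- lapply(sigs, as_signature)
  ids <- names(sigs)
  if (is.null(ids) || any(ids == "")) {
    ids <- sprintf("sig_%03d", seq_along(sigs))
    names(sigs) <- ids
  }
  if (anyDuplicated(ids)) {
    abort("signature ids must be unique", class = "sigconn_validation_error")
  }
  gene_ids <- Reduce(intersect, lapply(sigs, function(s) s$gene_id))
  if (length(gene_ids) == 0) {
    abort("signatures share no genes; cannot harmonize gene space",
          class = "sigconn_validation_error")
  }
  gene_ids <- sort(gene_ids)
  n_dropped <- vapply(sigs, function(s) nrow(s) - length(gene_ids), integer(1))
  d <- vapply(sigs, function(s) {
    s$log2fc[match(gene_ids, s$gene_id)]
  }, numeric(length(gene_ids)))
  d <- matrix(d, nrow = length(gene_ids), dimnames = list(gene_ids, ids))
  all_p <- all(vapply(sigs, has_p, logical(1)))
  p <- NULL
  if (all_p) {
    p <- vapply(sigs, function(s) s$p_value[match(gene_ids, s$gene_id)],
                numeric(length(gene_ids)))
    p <- matrix(p, nrow = length(gene_ids), dimnames = list(gene_ids, ids))
  }
  meta_tbl <- tibble(signature_id = ids, n_genes = nrow(d), n_dropped = unname(n_dropped))
  for (field in c("perturbagen", "target_gene", "cell_line", "signature_type")) {
    from_sig <- vapply(sigs, function(s) {
      v <- sig_meta(s)[[field]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
    meta_tbl[[field]] <- unname(from_sig)
  }
  if (!is.null(meta)) {
    meta <- as_tibble(meta)
    if (!"signature_id" %in% names(meta)) {
      abort("library metadata must have a signature_id column",
            class = "sigconn_validation_error")
    }
    idx <- match(ids, meta$signature_id)
    for (field in setdiff(names(meta), "signature_id")) {
      vals <- meta[[field]][idx]
      if (field %in% names(meta_tbl)) {
        keep <- !is.na(vals)
        meta_tbl[[field]][keep] <- as.character(vals[keep])
      } else {
        meta_tbl[[field]] <- vals
      }
    }
  }
  structure(
    list(gene_ids = gene_ids, d = d, p = p, meta = meta_tbl),
    class = "signature_library"
  )
}

#' @export
print.signature_library <- function(x, ...) {
  cat("# A signature library: ", ncol(x$d), " signatures x ", nrow(x$d),
      " genes", if (is.null(x$p)) " (no p-values)", "\n", sep = "")
  print(x$meta, ...)
  invisible(x)
}

#' Number of signatures / membership
#'
#' @param library A [signature_library()].
#' @param id A signature identifier.
#' @return `lib_sig()` returns the member signature as a `cmap_sig` tibble.
#' @export
lib_sig <- function(library, id) {
  stopifnot(inherits(library, "signature_library"))
  if (!id %in% colnames(library$d)) {
    abort(paste0("signature '", id, "' is not in the library"),
          class = "sigconn_validation_error")
  }
  out <- tibble(gene_id = library$gene_ids, log2fc = library$d[, id])
  if (!is.null(library$p)) out$p_value <- library$p[, id]
  row <- library$meta[library$meta$signature_id == id, ]
  meta <- as.list(row[setdiff(names(row), c("signature_id", "n_genes", "n_dropped"))])
  meta <- meta[!vapply(meta, function(v) all(is.na(v)), logical(1))]
  as_signature(out, meta = c(list(signature_id = id), meta))
}

## gene-space fingerprint used by library manifests: md5 of the sorted ids
gene_space_fingerprint <- function(gene_ids) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(sort(gene_ids), tf)
  unname(tools::md5sum(tf))
}
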