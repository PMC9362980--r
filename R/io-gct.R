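#' Read and write GCT expression matrices
#'
#' Text GCT, versions 1.2 and 1.3. A 1.2 file carries only the matrix; a 1.3
#' file adds row- and column-metadata blocks, which are captured into the
#' dataset's sample annotations (column metadata) and `meta$row_annotations`
#' (row metadata). Dimensions declared on line 2 are validated against the
#' parsed body and parse errors name the offending line.
#'
#' @param path File path.
#' @return `read_gct()` returns an [expression_dataset()].
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) {
    abort("GCT file has fewer than 3 lines", class = "sigconn_parse_error")
  }
  version <- trimws(lines[1])
  if (!version %in% c("#1.2", "#1.3")) {
    abort("line 1: expected '#1.2' or '#1.3'", class = "sigconn_parse_error")
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "[\t ]+")[[1]]))
  if (any(is.na(dims))) {
    abort("line 2: non-integer dimensions", class = "sigconn_parse_error")
  }
  cells <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  if (version == "#1.2") {
    if (length(dims) != 2) {
      abort("line 2: a #1.2 file declares exactly 2 dimensions", class = "sigconn_parse_error")
    }
    n_genes <- dims[1]
    n_samples <- dims[2]
    n_rmeta <- 1 # the Description column
    n_cmeta <- 0
  } else {
    if (length(dims) != 4) {
      abort("line 2: a #1.3 file declares exactly 4 dimensions", class = "sigconn_parse_error")
    }
    n_genes <- dims[1]
    n_samples <- dims[2]
    n_rmeta <- dims[3]
    n_cmeta <- dims[4]
  }
  header <- cells[[1]]
  if (length(header) != 1 + n_rmeta + n_samples) {
    abort(paste0("line 3: header has ", length(header), " fields, expected ",
                 1 + n_rmeta + n_samples), class = "sigconn_parse_error")
  }
  sample_ids <- header[(1 + n_rmeta + 1):length(header)]
  rmeta_names <- if (n_rmeta > 0) header[2:(1 + n_rmeta)] else character()
  body <- cells[-1]
  if (length(body) != n_cmeta + n_genes) {
    abort(paste0("body has ", length(body), " rows, expected ", n_cmeta + n_genes),
          class = "sigconn_parse_error")
  }
  samples <- tibble(sample_id = sample_ids)
  for (i in seq_len(n_cmeta)) {
    row <- body[[i]]
    if (length(row) != 1 + n_rmeta + n_samples) {
      abort(paste0("line ", 3 + i, ": column-metadata row has ", length(row),
                   " fields, expected ", 1 + n_rmeta + n_samples),
            class = "sigconn_parse_error")
    }
    samples[[row[1]]] <- utils::type.convert(
      row[(1 + n_rmeta + 1):length(row)], as.is = TRUE
    )
  }
  data_rows <- body[n_cmeta + seq_len(n_genes)]
  gene_ids <- character(n_genes)
  row_meta <- matrix(NA_character_, n_genes, length(rmeta_names))
  X <- matrix(NA_real_, n_genes, n_samples)
  for (g in seq_len(n_genes)) {
    row <- data_rows[[g]]
    line_no <- 3 + n_cmeta + g
    if (length(row) != 1 + n_rmeta + n_samples) {
      abort(paste0("line ", line_no, ": data row has ", length(row),
                   " fields, expected ", 1 + n_rmeta + n_samples),
            class = "sigconn_parse_error")
    }
    gene_ids[g] <- row[1]
    if (n_rmeta > 0) row_meta[g, ] <- row[2:(1 + n_rmeta)]
    vals <- suppressWarnings(as.numeric(row[(1 + n_rmeta + 1):length(row)]))
    if (any(is.na(vals))) {
      abort(paste0("line ", line_no, ": non-numeric expression value"),
            class = "sigconn_parse_error")
    }
    X[g, ] <- vals
  }
  if (anyDuplicated(gene_ids)) {
    abort("duplicated gene ids in GCT body", class = "sigconn_parse_error")
  }
  row_annotations <- NULL
  if (length(rmeta_names) > 0) {
    row_annotations <- as_tibble(setNames(as.data.frame(row_meta), rmeta_names))
    row_annotations <- dplyr::mutate(row_annotations,
                                     dplyr::across(dplyr::everything(),
                                                   ~ utils::type.convert(.x, as.is = TRUE)))
    row_annotations <- dplyr::bind_cols(tibble(gene_id = toupper(gene_ids)),
                                        row_annotations)
  }
  expression_dataset(
    X, gene_ids = gene_ids, sample_ids = sample_ids, samples = samples,
    meta = list(gct_version = sub("^#", "", version),
                row_annotations = row_annotations, source = path)
  )
}

## shortest round-trip decimal representation, so read(write(x)) is exact
fmt_num <- function(x) {
  vapply(x, function(v) {
    s <- format(v, digits = 15)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
}

#' @rdname read_gct
#' @param ds An [expression_dataset()].
#' @param version `"1.2"` (matrix only) or `"1.3"` (includes sample
#'   annotations as column metadata).
#' @return `write_gct()` invisibly returns `path`.
#' @export
write_gct <- function(ds, path, version = c("1.2", "1.3")) {
  stopifnot(inherits(ds, "expression_dataset"))
  version <- match.arg(version)
  con <- file(path, open = "wt")
  on.exit(close(con))
  n <- nrow(ds$X)
  m <- ncol(ds$X)
  vals <- apply(ds$X, 1, fmt_num)
  vals <- if (is.matrix(vals)) t(vals) else matrix(vals, nrow = n)
  if (version == "1.2") {
    writeLines(c("#1.2", paste(n, m, sep = "\t")), con)
    writeLines(paste(c("NAME", "Description", ds$sample_ids), collapse = "\t"), con)
    writeLines(paste(ds$gene_ids, "na",
                     apply(vals, 1, paste, collapse = "\t"), sep = "\t"), con)
  } else {
    ann <- ds$samples[setdiff(names(ds$samples), "sample_id")]
    n_cmeta <- ncol(ann)
    writeLines(c("#1.3", paste(n, m, 0, n_cmeta, sep = "\t")), con)
    writeLines(paste(c("id", ds$sample_ids), collapse = "\t"), con)
    for (a in names(ann)) {
      writeLines(paste(c(a, as.character(ann[[a]])), collapse = "\t"), con)
    }
    writeLines(paste(ds$gene_ids,
                     apply(vals, 1, paste, collapse = "\t"), sep = "\t"), con)
  }
  invisible(path)
}
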