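#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then gene identifiers,
#' tab-separated. Reading delegates to `fgsea::gmtPathways()` and returns a
#' named list of character vectors (descriptions are not retained).
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return `read_gmt()` a named list of gene-id vectors; `write_gmt()`
#'   invisibly returns `path`.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0)) {
    abort("GMT file contains an empty gene set", class = "sigconn_parse_error")
  }
  lapply(sets, toupper)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% names(sets)
  lines <- mapply(function(name, desc, genes) {
    paste(c(name, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read an up/down query
#'
#' Two dialects: a GMT file whose set names share a prefix and end in `_UP`
#' and `_DN` (or `_DOWN`), or a two-column TSV `gene_id\tdirection` with
#' direction +1 / -1 (a header line is allowed).
#'
#' @param path File path (`.gmt` for the GMT dialect, anything else is read
#'   as TSV).
#' @return An [updown_query()].
#' @export
read_updown <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- read_gmt(path)
    up_i <- grep("_UP$", names(sets), ignore.case = TRUE)
    dn_i <- grep("_(DN|DOWN)$", names(sets), ignore.case = TRUE)
    if (length(up_i) != 1 || length(dn_i) != 1) {
      abort("expected exactly one _UP and one _DN/_DOWN set in the GMT file",
            class = "sigconn_parse_error")
    }
    return(updown_query(up = sets[[up_i]], down = sets[[dn_i]]))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2) {
    abort("up/down TSV needs two columns: gene_id and direction",
          class = "sigconn_parse_error")
  }
  if (!identical(tolower(names(df)[1:2]), c("gene_id", "direction"))) {
    # headerless file: first row was data
    df <- dplyr::bind_rows(stats::setNames(as.list(names(df)), c("gene_id", "direction")),
                           stats::setNames(df[1:2], c("gene_id", "direction")))
  }
  dir <- suppressWarnings(as.numeric(df$direction))
  if (any(is.na(dir)) || !all(dir %in% c(-1, 1))) {
    abort("direction column must be +1 or -1", class = "sigconn_parse_error")
  }
  updown_query(up = df$gene_id[dir > 0], down = df$gene_id[dir < 0])
}

#' Read and write signature TSVs
#'
#' Dialect: UTF-8 TSV with header `gene_id`, `log2fc` and optionally
#' `p_value`; dot decimal separator. A signature without the `p_value`
#' column is valid and is routed to the weighted-correlation path using
#' library p-values only.
#'
#' @param path File path.
#' @param meta Metadata list attached to the signature.
#' @param sig A signature ([as_signature()]).
#' @return `read_signature_tsv()` a `cmap_sig` tibble; the writer invisibly
#'   returns `path`.
#' @export
read_signature_tsv <- function(path, meta = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("gene_id", "log2fc") %in% names(df))) {
    abort(paste0(path, ": signature TSV needs columns gene_id and log2fc"),
          class = "sigconn_parse_error")
  }
  df$log2fc <- as.numeric(df$log2fc)
  if ("p_value" %in% names(df)) df$p_value <- as.numeric(df$p_value)
  as_signature(df, meta = meta)
}

#' @rdname read_signature_tsv
#' @export
write_signature_tsv <- function(sig, path) {
  sig <- as_signature(sig)
  readr::write_tsv(unclass_sig(sig), path, progress = FALSE)
  invisible(path)
}

#' Read a grouping / metadata table
#'
#' Plain TSVs used as sidecars: replicate grouping
#' (`replicate_id`, `group_id`, `target_gene`) for aggregation, and
#' signature-to-perturbagen maps (`signature_id`, `perturbagen`,
#' `target_gene`) for perturbagen connectivity.
#'
#' @param path File path.
#' @return A tibble with the file's columns, all character.
#' @export
read_grouping <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Write connectivity results
#'
#' Results TSV dialect: `signature_id`, `metric`, `score`, `p_value`,
#' `fdr`, `n_genes_used`.
#'
#' @param res A `connectivity_tbl` from [connect_query()].
#' @param path File path.
#' @export
write_results_tsv <- function(res, path) {
  cols <- intersect(c("signature_id", "metric", "score", "p_value", "fdr",
                      "n_genes_used"), names(res))
  readr::write_tsv(as_tibble(res)[cols], path, progress = FALSE)
  invisible(path)
}

manifest_fields <- c("perturbagen", "target_gene", "cell_line", "signature_type",
                     "qc_q75", "passed_qc")

#' Load and write signature libraries on disk
#'
#' A library on disk is a directory of signature TSVs plus a manifest. The
#' manifest is either `manifest.tsv` (columns `signature_id`, `file`, and
#' optionally `perturbagen`, `target_gene`, `cell_line`, `signature_type`,
#' `qc_q75`, `passed_qc`) or `manifest.yaml` with the same rows under
#' `signatures:` plus a `gene_space_fingerprint`. `load_library()` accepts
#' the directory or a manifest path, reads every member, harmonizes gene
#' spaces to the intersection (recording dropped-gene counts) and verifies
#' the fingerprint when present.
#'
#' @param path Library directory or manifest file.
#' @return A [signature_library()].
#' @export
load_library <- function(path) {
  manifest_path <- path
  if (dir.exists(path)) {
    candidates <- file.path(path, c("manifest.tsv", "manifest.yaml", "manifest.yml"))
    manifest_path <- candidates[file.exists(candidates)][1]
    if (is.na(manifest_path)) {
      abort(paste0("no manifest.tsv/manifest.yaml found in ", path),
            class = "sigconn_parse_error")
    }
  }
  base_dir <- dirname(manifest_path)
  fingerprint <- NULL
  if (grepl("\\.ya?ml$", manifest_path)) {
    y <- yaml::read_yaml(manifest_path)
    rows <- dplyr::bind_rows(lapply(y$signatures, as_tibble))
    fingerprint <- y$gene_space_fingerprint
  } else {
    rows <- readr::read_tsv(manifest_path,
                            col_types = readr::cols(.default = readr::col_character()),
                            progress = FALSE)
  }
  if (!all(c("signature_id", "file") %in% names(rows))) {
    abort("manifest needs signature_id and file columns", class = "sigconn_parse_error")
  }
  if (anyDuplicated(rows$signature_id)) {
    abort("duplicate signature_id in manifest", class = "sigconn_parse_error")
  }
  paths <- ifelse(grepl("^/", rows$file), rows$file, file.path(base_dir, rows$file))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    abort(paste0("manifest entries not found on disk: ",
                 paste(missing_files, collapse = ", ")),
          class = "sigconn_parse_error")
  }
  sigs <- lapply(paths, read_signature_tsv)
  names(sigs) <- rows$signature_id
  lib <- signature_library(sigs, meta = rows[intersect(names(rows),
                                                       c("signature_id", manifest_fields))])
  if (!is.null(fingerprint) &&
      !identical(fingerprint, gene_space_fingerprint(lib$gene_ids))) {
    warn("gene-space fingerprint mismatch: harmonized gene space differs from the manifest's")
  }
  lib
}

#' @rdname load_library
#' @param library A [signature_library()].
#' @param dir Output directory (created if missing).
#' @param manifest_format `"tsv"` or `"yaml"`.
#' @export
write_library <- function(library, dir, manifest_format = c("tsv", "yaml")) {
  stopifnot(inherits(library, "signature_library"))
  manifest_format <- match.arg(manifest_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- colnames(library$d)
  files <- paste0(gsub("[^A-Za-z0-9_.-]", "_", ids), ".tsv")
  for (i in seq_along(ids)) {
    write_signature_tsv(lib_sig(library, ids[i]), file.path(dir, files[i]))
  }
  rows <- tibble(signature_id = ids, file = files)
  for (f in intersect(manifest_fields, names(library$meta))) {
    rows[[f]] <- as.character(library$meta[[f]])
  }
  if (manifest_format == "tsv") {
    readr::write_tsv(rows, file.path(dir, "manifest.tsv"), progress = FALSE)
  } else {
    yaml::write_yaml(
      list(gene_space_fingerprint = gene_space_fingerprint(library$gene_ids),
           signatures = lapply(seq_len(nrow(rows)), function(i) as.list(rows[i, ]))),
      file.path(dir, "manifest.yaml")
    )
  }
  invisible(dir)
}
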