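#' Plots for sigconn objects
#'
#' `autoplot()` methods (and `plot_*()` aliases) for the package's result
#' types, all returning ggplot objects:
#'
#' * a signature — volcano plot of `log2fc` vs \eqn{-\log_{10} p}, extreme
#'   tails highlighted;
#' * connectivity results — score vs \eqn{-\log_{10} p}, colored by FDR
#'   significance;
#' * a consensus signature — replicate MODZ weights with the QC verdict in
#'   the title;
#' * perturbagen connectivity — enrichment z per perturbagen.
#'
#' @param object The object to plot.
#' @param k Tail size highlighted in the signature volcano.
#' @param fdr_threshold Significance threshold used for coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @name sigconn-plots
NULL

#' @rdname sigconn-plots
#' @export
autoplot.cmap_sig <- function(object, k = 100, ...) {
  sig <- as_signature(object)
  if (!has_p(sig)) {
    abort("volcano plot needs p-values", class = "sigconn_validation_error")
  }
  s <- signed_significance(sig)
  e <- extreme_signature(s, k = min(k, max(1, floor(nrow(s) / 2))))
  df <- dplyr::mutate(as_tibble(unclass_sig(sig)),
                      neg_log10_p = neg_log10(.data$p_value),
                      extreme = e$e != 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                                   color = .data$extreme)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                name = "extreme tail") +
    ggplot2::labs(x = "log2 differential expression",
                  y = expression(-log[10] ~ "p-value")) +
    ggplot2::theme_minimal()
}

#' @rdname sigconn-plots
#' @export
plot_signature_volcano <- function(object, k = 100) autoplot.cmap_sig(object, k = k)

#' @rdname sigconn-plots
#' @export
autoplot.connectivity_tbl <- function(object, fdr_threshold = 0.05, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      neg_log10_p = -log10(pmax(.data$p_value, P_FLOOR)),
                      significant = .data$fdr < fdr_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$neg_log10_p,
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue"),
                                name = paste0("FDR < ", fdr_threshold)) +
    ggplot2::labs(x = paste0("connectivity score (",
                             paste(unique(df$metric), collapse = "/"), ")"),
                  y = expression(-log[10] ~ "p-value")) +
    ggplot2::theme_minimal()
}

#' @rdname sigconn-plots
#' @export
plot_connectivity <- function(object, fdr_threshold = 0.05) {
  autoplot.connectivity_tbl(object, fdr_threshold = fdr_threshold)
}

#' @rdname sigconn-plots
#' @export
autoplot.consensus_signature <- function(object, ...) {
  df <- tibble(replicate_id = names(object$weights),
               weight = as.numeric(object$weights))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$replicate_id, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      title = sprintf("MODZ weights; distil_cc_q75 = %.3f (QC %s)",
                      object$qc_q75,
                      ifelse(isTRUE(object$passed_qc), "pass", "fail/NA")),
      x = NULL, y = "weight"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname sigconn-plots
#' @export
autoplot.perturbagen_tbl <- function(object, fdr_threshold = 0.05, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      significant = .data$fdr < fdr_threshold)
  df$perturbagen <- factor(df$perturbagen, levels = rev(df$perturbagen))
  df <- utils::head(df, 30)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$perturbagen,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue"),
                               name = paste0("FDR < ", fdr_threshold)) +
    ggplot2::labs(x = "Random Set enrichment z", y = NULL) +
    ggplot2::theme_minimal()
}
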