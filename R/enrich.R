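#' Random Set standardized set statistic
#'
#' Given scores \eqn{g_1,\dots,g_G} over a universe of items and a member set
#' of size \eqn{m}, Random Set analysis standardizes the member mean
#' \eqn{\bar X} against the exact moments of the mean of a uniformly random
#' size-\eqn{m} set drawn without replacement:
#' \deqn{\mu = \frac{1}{G}\sum_i g_i, \qquad
#'   \sigma_m^2 = \frac{G-m}{G-1}\cdot\frac{\sigma^2}{m}}
#' with \eqn{\sigma^2} the population variance of the scores, giving
#' \eqn{z = (\bar X - \mu)/\sigma_m}. The z-statistic is invariant under
#' shifting or positively scaling all scores and depends only on set
#' membership and the score multiset.
#'
#' @param scores Numeric vector of finite per-item scores, or a data frame
#'   with columns `item_id` and `score`.
#' @param members Logical vector along `scores`, or a character vector of
#'   item ids (requires the data-frame form or named scores).
#' @param tail `"two_sided"` (gene-list connectivity) or `"upper"`
#'   (perturbagen connectivity).
#' @return A list with `z`, `p`, `m` (member count), `x_bar`, `mu` and
#'   `sigma_m2` (the closed-form variance of the random-set mean). When all
#'   scores are equal the variance is zero and `z = 0`, `p = 1` by
#'   convention.
#' @examples
#' random_set_z(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
random_set_z <- function(scores, members, tail = c("two_sided", "upper")) {
  tail <- match.arg(tail)
  if (is.data.frame(scores)) {
    stopifnot(all(c("item_id", "score") %in% names(scores)))
    ids <- as.character(scores$item_id)
    scores <- setNames(as.numeric(scores$score), ids)
  }
  if (is.character(members)) {
    if (is.null(names(scores))) {
      abort("character `members` requires named scores or the data-frame form",
            class = "sigconn_validation_error")
    }
    members <- names(scores) %in% members
  }
  g <- as.numeric(scores)
  if (any(!is.finite(g))) {
    abort("scores must be finite", class = "sigconn_validation_error")
  }
  G <- length(g)
  m <- sum(members)
  if (m == 0) abort("member set is empty", class = "sigconn_degenerate_error")
  if (m == G) abort("member set covers the whole universe", class = "sigconn_degenerate_error")
  mu <- mean(g)
  sigma2 <- mean((g - mu)^2)
  x_bar <- mean(g[members])
  sigma_m2 <- (G - m) / (G - 1) * sigma2 / m
  if (sigma2 == 0) {
    z <- 0
    p <- 1
  } else {
    z <- (x_bar - mu) / sqrt(sigma_m2)
    p <- if (tail == "upper") pnorm(z, lower.tail = FALSE) else 2 * pnorm(-abs(z))
  }
  list(z = z, p = pmin(pmax(p, P_FLOOR), 1), m = m, x_bar = x_bar,
       mu = mu, sigma_m2 = sigma_m2)
}

#' Perturbagen-level connectivity
#'
#' A perturbagen (drug, shRNA/CRISPR construct, overexpression vector) is
#' usually represented by many library signatures — one per cell line, dose
#' and time point. Perturbagen connectivity asks whether the individual
#' query-vs-signature connectivity scores of one perturbagen's signatures
#' are, as a set, unusually high: the per-signature scores form the universe
#' and each perturbagen's member set is tested with [random_set_z()]
#' (upper-tail on absolute scores by default, so strong concordant and
#' discordant connections both count; `signed = TRUE` ranks signed scores
#' instead).
#'
#' @param query Any query accepted by [connect_query()].
#' @param library A [signature_library()].
#' @param grouping Optional data frame `signature_id`, `perturbagen`
#'   (a third `target_gene` column is allowed and ignored here). Defaults to
#'   the library metadata's `perturbagen` column.
#' @param signed If `TRUE`, enrich the signed scores (positive tail =
#'   concordant connections) instead of absolute scores.
#' @param ... Passed on to [connect_query()].
#' @return A tibble of class `perturbagen_tbl`, one row per perturbagen:
#'   `perturbagen`, `z`, `p_value`, `fdr`, `n_signatures` and member-score
#'   summaries (`score_min`, `score_median`, `score_max`), sorted by
#'   `p_value`.
#' @export
perturbagen_connectivity <- function(query, library, grouping = NULL,
                                     signed = FALSE, ...) {
  stopifnot(inherits(library, "signature_library"))
  if (is.null(grouping)) {
    grouping <- library$meta[c("signature_id", "perturbagen")]
  }
  grouping <- as_tibble(grouping)
  stopifnot(all(c("signature_id", "perturbagen") %in% names(grouping)))
  if (anyDuplicated(grouping$signature_id)) {
    abort("each signature must map to exactly one perturbagen",
          class = "sigconn_validation_error")
  }
  res <- connect_query(query, library, ...)
  pert <- grouping$perturbagen[match(res$signature_id, grouping$signature_id)]
  if (any(is.na(pert))) {
    abort("grouping is missing perturbagen assignments for some library signatures",
          class = "sigconn_validation_error")
  }
  known <- setdiff(unique(grouping$perturbagen), unique(pert))
  if (length(known) > 0) {
    warn(paste0(length(known), " perturbagen(s) with no signature in the library omitted"))
  }
  universe <- if (signed) res$score else abs(res$score)
  out <- purrr::map_dfr(unique(pert), function(pp) {
    members <- pert == pp
    rs <- random_set_z(universe, members, tail = "upper")
    tibble(
      perturbagen = pp, z = rs$z, p_value = rs$p,
      n_signatures = sum(members),
      score_min = min(res$score[members]),
      score_median = stats::median(res$score[members]),
      score_max = max(res$score[members])
    )
  })
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out <- dplyr::arrange(out, .data$p_value, dplyr::desc(.data$z), .data$perturbagen)
  out <- out[c("perturbagen", "z", "p_value", "fdr", "n_signatures",
               "score_min", "score_median", "score_max")]
  class(out) <- c("perturbagen_tbl", class(out))
  attr(out, "signed") <- signed
  out
}
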