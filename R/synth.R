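#' Simulate a two-group expression experiment with planted effects
#'
#' Generates a log-scale expression dataset of the kind signature
#' construction consumes: gene baselines are drawn from Normal(8, 2^2)
#' (typical of log2 microarray intensities), i.i.d. Normal(0, sigma^2) noise
#' is added per sample, and a planted log-fold-change of `effect_size` is
#' added to `n_affected` randomly chosen genes in group A. The returned
#' truth table identifies the affected genes.
#'
#' All randomness is drawn inside [withr::with_seed()], so a fixed seed
#' yields byte-identical output and the caller's RNG state is untouched.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group: a single number or `c(nA, nB)`.
#' @param n_affected Number of genes receiving the planted effect.
#' @param effect_size Planted log-fold-change Delta (group A minus B).
#' @param sigma Noise standard deviation (log2 units).
#' @param baseline_mean,baseline_sd Gene baseline distribution parameters.
#' @param seed Integer seed.
#' @return A list: `dataset` (an [expression_dataset()] with a `group`
#'   annotation of "A"/"B") and `truth` (tibble `gene_id`, `effect`; empty
#'   when `n_affected = 0`).
#' @export
simulate_diffexp <- function(n_genes = 1000, n_per_group = 5, n_affected = 0,
                             effect_size = 0, sigma = 1,
                             baseline_mean = 8, baseline_sd = 2, seed = 1) {
  if (n_affected > n_genes) {
    abort("more affected genes than genes", class = "sigconn_spec_error")
  }
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  na <- n_per_group[1]
  nb <- n_per_group[2]
  withr::with_seed(seed, {
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    X <- baseline + matrix(stats::rnorm(n_genes * (na + nb), 0, sigma),
                           nrow = n_genes)
    affected <- sort(sample.int(n_genes, n_affected))
    if (n_affected > 0) {
      X[affected, seq_len(na)] <- X[affected, seq_len(na)] + effect_size
    }
    samples <- tibble(
      sample_id = sprintf("S%03d", seq_len(na + nb)),
      group = rep(c("A", "B"), c(na, nb))
    )
    list(
      dataset = expression_dataset(
        X, gene_ids = gene_ids, sample_ids = samples$sample_id,
        samples = samples,
        meta = list(simulated = TRUE, seed = seed, sigma = sigma,
                    effect_size = effect_size)
      ),
      truth = tibble(gene_id = gene_ids[affected],
                     effect = rep(effect_size, n_affected))
    )
  })
}

#' Simulate replicate z-score sets sharing a latent consensus
#'
#' Each replicate equals a latent per-gene consensus profile (standard
#' normal) plus i.i.d. Normal(0, sigma^2) replicate noise — the structure
#' MODZ aggregation assumes. The latent consensus is returned for recovery
#' checks.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Number of replicate columns.
#' @param sigma Per-replicate noise standard deviation (z-score units).
#' @param seed Integer seed.
#' @param meta Metadata attached to the replicate set.
#' @return A list: `replicates` (a [replicate_set()]) and `consensus`
#'   (tibble `gene_id`, `z`).
#' @export
simulate_replicates <- function(n_genes = 978, n_replicates = 5, sigma = 0.3,
                                seed = 1, meta = list()) {
  withr::with_seed(seed, {
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
    consensus <- stats::rnorm(n_genes)
    Z <- consensus + matrix(stats::rnorm(n_genes * n_replicates, 0, sigma),
                            nrow = n_genes)
    list(
      replicates = replicate_set(
        Z, gene_ids = gene_ids,
        replicate_ids = sprintf("rep_%02d", seq_len(n_replicates)),
        meta = c(meta, list(simulated = TRUE, seed = seed, sigma = sigma))
      ),
      consensus = tibble(gene_id = gene_ids, z = consensus)
    )
  })
}

## one simulated z-score signature: d ~ given z vector, p from the normal tail
z_signature <- function(z, gene_ids, meta = list()) {
  as_signature(
    tibble(gene_id = gene_ids, log2fc = z,
           p_value = pmax(2 * pnorm(-abs(z)), P_FLOOR)),
    meta = meta
  )
}

#' Simulate a signature library with planted connectivity structure
#'
#' Builds a library of independent null signatures (per-gene z-scores
#' standard normal, p-values from the two-sided normal tail — uniform under
#' the null) and optionally plants structure on the same signed-significance
#' scale so every connectivity metric can see it:
#'
#' * `rho_pairs` — for each correlation rho, a pair of signatures whose
#'   z-score vectors are bivariate normal with correlation rho;
#' * `planted_group` — `list(size =, rho =)`: one perturbagen whose `size`
#'   member signatures each correlate rho with a latent query profile; the
#'   query signature built from that profile is returned.
#'
#' Null signatures are assigned to perturbagens in consecutive blocks of
#' `perturbagen_size`; planted pair members are their own perturbagens and
#' the planted group is the perturbagen `"planted_group"`.
#'
#' @param n_genes Genes in the shared gene space.
#' @param n_null Number of independent null signatures.
#' @param rho_pairs Numeric vector of planted pair correlations in \[0, 1\].
#' @param planted_group `NULL` or `list(size =, rho =)`.
#' @param perturbagen_size Null signatures per perturbagen.
#' @param seed Integer seed.
#' @return A list: `library` (a [signature_library()]), `query` (the latent
#'   query signature when a group is planted, else `NULL`) and `plants`
#'   (tibble `kind`, `id_a`, `id_b`, `rho`, `perturbagen`).
#' @export
simulate_library <- function(n_genes = 978, n_null = 100, rho_pairs = NULL,
                             planted_group = NULL, perturbagen_size = 1,
                             seed = 1) {
  if (!is.null(rho_pairs) && any(rho_pairs < 0 | rho_pairs > 1)) {
    abort("planted correlations must lie in [0, 1]", class = "sigconn_spec_error")
  }
  if (!is.null(planted_group) &&
      (planted_group$rho < 0 || planted_group$rho > 1)) {
    abort("planted correlations must lie in [0, 1]", class = "sigconn_spec_error")
  }
  withr::with_seed(seed, {
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
    cols <- list()
    ids <- character()
    pert <- character()
    plants <- list()
    query <- NULL
    if (n_null > 0) {
      cols$null <- matrix(stats::rnorm(n_genes * n_null), nrow = n_genes)
      ids <- c(ids, sprintf("null_%04d", seq_len(n_null)))
      pert <- c(pert, sprintf("pert_%04d", (seq_len(n_null) - 1) %/% perturbagen_size + 1))
    }
    for (j in seq_along(rho_pairs)) {
      rho <- rho_pairs[j]
      x <- stats::rnorm(n_genes)
      y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n_genes)
      ida <- sprintf("pair%02d_a", j)
      idb <- sprintf("pair%02d_b", j)
      cols[[ida]] <- cbind(x, y)
      ids <- c(ids, ida, idb)
      pert <- c(pert, ida, idb)
      plants[[length(plants) + 1]] <-
        tibble(kind = "pair", id_a = ida, id_b = idb, rho = rho,
               perturbagen = NA_character_)
    }
    if (!is.null(planted_group)) {
      rho <- planted_group$rho
      latent <- stats::rnorm(n_genes)
      size <- planted_group$size
      if (size > 0) {
        noise <- matrix(stats::rnorm(n_genes * size), nrow = n_genes)
        cols$group <- rho * latent + sqrt(1 - rho^2) * noise
        gids <- sprintf("group_%02d", seq_len(size))
        ids <- c(ids, gids)
        pert <- c(pert, rep("planted_group", size))
        plants <- c(plants, lapply(gids, function(id) {
          tibble(kind = "group", id_a = "query", id_b = id, rho = rho,
                 perturbagen = "planted_group")
        }))
      }
      query <- z_signature(latent, gene_ids,
                           meta = list(signature_id = "query", signature_type = "user"))
    }
    if (length(ids) == 0) {
      abort("library simulation produced no signatures", class = "sigconn_spec_error")
    }
    D <- do.call(cbind, cols)
    dimnames(D) <- list(gene_ids, ids)
    P <- pmax(2 * pnorm(-abs(D)), P_FLOOR)
    meta <- tibble(
      signature_id = ids, n_genes = n_genes, n_dropped = 0L,
      perturbagen = pert, target_gene = NA_character_, cell_line = NA_character_,
      signature_type = "CP"
    )
    list(
      library = structure(
        list(gene_ids = gene_ids, d = D, p = P, meta = meta),
        class = "signature_library"
      ),
      query = query,
      plants = if (length(plants)) dplyr::bind_rows(plants) else
        tibble(kind = character(), id_a = character(), id_b = character(),
               rho = numeric(), perturbagen = character())
    )
  })
}
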