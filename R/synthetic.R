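#' Specification of a synthetic expression dataset
#'
#' Defines everything the generator needs to emulate atlas-style expression
#' tables: per-structure log-normal energies with controlled between-gene
#' Pearson correlations, multiplicative noise, and optional planted
#' fold-differences across a chosen segment boundary.
#'
#' Energies are log-normal (non-negative, multiplicative structure-to-
#' structure variation): a Gaussian copula on the log scale carries the
#' correlation structure. Target correlations are specified on the
#' *observed* (energy) scale; the latent log-scale correlation is obtained
#' by the exact moment back-transform
#' r_latent = log(1 + r (e^(sigma^2) - 1)) / sigma^2 (common sigma), so the
#' sampled energies have the requested linear correlation, not merely the
#' requested rank correlation.
#'
#' @param seed Integer seed; every draw flows from it.
#' @param n_structures Number of structures per age (default 19, one per
#'   level-3 transverse segment).
#' @param ages Subset of [AGE_STAGES] (default "P56").
#' @param genes Gene symbols to simulate.
#' @param target_correlations Data frame with columns `gene_a`, `gene_b`,
#'   `r` (|r| < 1); unlisted pairs are uncorrelated.
#' @param sigma Log-scale standard deviation of the multiplicative noise
#'   (default 0.3; 0 gives a constant table at baseline).
#' @param planted_folds Data frame with columns `gene`, `boundary`
#'   (integer: the fold applies to structures with position > boundary),
#'   `fold` (> 0).
#' @param baseline_energy Baseline energy (default 1.0, the calibration
#'   point at which one energy unit equals 25,000 surface molecules).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_structures = 19L,
                           ages = "P56",
                           genes = c("Cdh2", "Cdh13"),
                           target_correlations = NULL,
                           sigma = 0.3,
                           planted_folds = NULL,
                           baseline_energy = 1.0) {
  if (!all(ages %in% AGE_STAGES)) {
    cadh_abort(paste0("unknown age stage: ",
                      paste(setdiff(ages, AGE_STAGES), collapse = ", ")),
               "cadhesion_error_unknown_age")
  }
  if (sigma < 0 || baseline_energy < 0 || n_structures < 1) {
    cadh_abort("sigma and baseline_energy must be non-negative; n_structures >= 1",
               "cadhesion_error_spec")
  }
  if (!is.null(target_correlations)) {
    target_correlations <- tibble::as_tibble(target_correlations)
    stopifnot(all(c("gene_a", "gene_b", "r") %in% names(target_correlations)))
    if (any(abs(target_correlations$r) >= 1)) {
      cadh_abort("|target r| must be < 1", "cadhesion_error_spec")
    }
    if (!all(c(target_correlations$gene_a, target_correlations$gene_b)
             %in% genes)) {
      cadh_abort("correlation targets name genes outside the gene list",
                 "cadhesion_error_spec")
    }
  }
  if (!is.null(planted_folds)) {
    planted_folds <- tibble::as_tibble(planted_folds)
    stopifnot(all(c("gene", "boundary", "fold") %in% names(planted_folds)))
    if (any(planted_folds$fold <= 0)) {
      cadh_abort("planted folds must be positive", "cadhesion_error_spec")
    }
    if (any(planted_folds$boundary < 1 |
            planted_folds$boundary >= n_structures)) {
      cadh_abort("boundary must lie strictly inside 1..n_structures",
                 "cadhesion_error_spec")
    }
  }
  structure(
    list(seed = as.integer(seed), n_structures = as.integer(n_structures),
         ages = ages, genes = genes,
         target_correlations = target_correlations,
         sigma = sigma, planted_folds = planted_folds,
         baseline_energy = baseline_energy),
    class = "synthetic_spec"
  )
}

latent_correlation <- function(r_obs, sigma) {
  if (sigma == 0) return(r_obs)
  log(1 + r_obs * (exp(sigma^2) - 1)) / sigma^2
}

build_latent_sigma <- function(spec) {
  g <- spec$genes
  R <- diag(length(g))
  dimnames(R) <- list(g, g)
  tc <- spec$target_correlations
  if (!is.null(tc)) {
    for (k in seq_len(nrow(tc))) {
      rl <- latent_correlation(tc$r[k], spec$sigma)
      R[tc$gene_a[k], tc$gene_b[k]] <- rl
      R[tc$gene_b[k], tc$gene_a[k]] <- rl
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    repaired <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    dev <- max(abs(repaired - R))
    rlang::warn(sprintf(
      "correlation targets not jointly positive definite; nearest-PD repair applied (max shift %.4f)", dev))
    if (dev > 0.05) {
      cadh_abort("correlation targets jointly infeasible: nearest-PD repair shifts a target by > 0.05",
                 "cadhesion_error_spec")
    }
    R <- repaired
  }
  R * spec$sigma^2
}

#' Generate a synthetic expression table
#'
#' Draws, for each age in the spec, per-structure log-energies from a
#' multivariate normal whose covariance embeds the requested between-gene
#' correlations, exponentiates and scales them to the baseline energy, and
#' multiplies the planted fold onto one side of each named boundary.
#' Structures are labeled `s01..sNN` with anterior-to-posterior positions
#' 1..N. Fully reproducible under a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @return Expression tibble in the [read_expression_table()] dialect.
#' @export
#' @examples
#' tbl <- generate_expression_table(synthetic_spec(seed = 7, sigma = 0))
#' all(tbl$energy == 1)
generate_expression_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  Sigma <- build_latent_sigma(spec)
  n <- spec$n_structures
  ids <- sprintf("s%02d", seq_len(n))
  rows <- list()
  for (age in spec$ages) {
    z <- if (spec$sigma == 0) {
      matrix(0, n, length(spec$genes), dimnames = list(NULL, spec$genes))
    } else {
      m <- MASS::mvrnorm(n, mu = rep(0, length(spec$genes)), Sigma = Sigma)
      colnames(m) <- spec$genes
      m
    }
    energy <- spec$baseline_energy * exp(z)
    if (!is.null(spec$planted_folds)) {
      for (k in seq_len(nrow(spec$planted_folds))) {
        pf <- spec$planted_folds[k, ]
        after <- seq_len(n) > pf$boundary
        energy[after, pf$gene] <- energy[after, pf$gene] * pf$fold
      }
    }
    rows[[age]] <- tibble::tibble(
      gene = rep(spec$genes, each = n),
      structure_id = rep(ids, times = length(spec$genes)),
      age = age,
      energy = as.vector(energy),
      density = NA_real_, intensity = NA_real_,
      experiment_id = NA_character_
    )
  }
  validate_expression_table(dplyr::bind_rows(rows))
}

#' Generate pixel summaries with analytically known energies
#'
#' Emits random pixel summaries (total pixels, expressing subset, summed
#' intensity) together with the closed-form energy each one implies, so
#' the expression-energy formula and the unionize aggregation can be
#' checked against known values.
#'
#' @param n Number of summaries.
#' @param seed Integer seed.
#' @param max_pixels Upper bound on total pixels per summary.
#' @return Tibble with `sum_expressing_intensity`, `n_expressing_pixels`,
#'   `n_total_pixels`, `known_energy`.
#' @export
generate_pixel_grids <- function(n = 20, seed = 1L, max_pixels = 1000L) {
  set.seed(seed)
  n_total <- sample(seq_len(max_pixels), n, replace = TRUE)
  n_expr <- vapply(n_total, function(t) sample(0:t, 1L), integer(1))
  mean_int <- runif(n, 0, 50)
  sum_int <- ifelse(n_expr == 0, 0, n_expr * mean_int)
  tibble::tibble(
    sum_expressing_intensity = sum_int,
    n_expressing_pixels = n_expr,
    n_total_pixels = n_total,
    known_energy = sum_int / n_total
  )
}

#' Generate synthetic scRNA-seq cluster means
#'
#' Emulates a cluster-mean table from a large cortical survey: `n_clusters`
#' cell types of which `n_non_neuronal` carry a non-neuronal class label,
#' log-normal per-cluster means around gene baselines, and a strictly
#' positive housekeeping reference in every cluster. With `effect = 0` the
#' gene baselines equal `ish_baselines`, producing the null for the
#' ISH-vs-scRNA-seq comparison.
#'
#' @param genes Gene symbols (the reference gene is added if absent).
#' @param n_clusters Total clusters (study scale: 377).
#' @param n_non_neuronal Non-neuronal clusters to label (study scale: 24).
#' @param seed Integer seed.
#' @param baselines Named per-gene baseline means (default 1 for every
#'   gene, 100 for the reference).
#' @param effect Named per-gene multiplicative shift applied to baselines
#'   (default none).
#' @param sigma Log-scale spread of cluster means (default 0.4).
#' @param reference_gene Housekeeping symbol, default "Actb".
#' @return Tibble `cluster_id,class_label,gene,mean_expression`.
#' @export
generate_scrnaseq_clusters <- function(genes, n_clusters = 377L,
                                       n_non_neuronal = 24L, seed = 1L,
                                       baselines = NULL, effect = NULL,
                                       sigma = 0.4,
                                       reference_gene = "Actb") {
  if (n_non_neuronal >= n_clusters) {
    cadh_abort("n_non_neuronal must be smaller than n_clusters",
               "cadhesion_error_spec")
  }
  set.seed(seed)
  genes <- union(genes, reference_gene)
  base <- setNames(rep(1, length(genes)), genes)
  base[reference_gene] <- 100
  if (!is.null(baselines)) base[names(baselines)] <- baselines
  if (!is.null(effect)) base[names(effect)] <- base[names(effect)] * effect
  ids <- sprintf("cl%03d", seq_len(n_clusters))
  class_label <- c(rep("non-neuronal", n_non_neuronal),
                   rep("neuronal", n_clusters - n_non_neuronal))
  out <- tibble::tibble(
    cluster_id = rep(ids, each = length(genes)),
    class_label = rep(class_label, each = length(genes)),
    gene = rep(genes, times = n_clusters),
    mean_expression = as.vector(vapply(seq_len(n_clusters), function(i) {
      base[genes] * exp(rnorm(length(genes), 0, sigma))
    }, numeric(length(genes))))
  )
  if (any(out$mean_expression[out$gene == reference_gene] <= 0)) {
    rlang::warn("non-positive reference draw resampled")
    bad <- out$gene == reference_gene & out$mean_expression <= 0
    out$mean_expression[bad] <- base[reference_gene]
  }
  out
}
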