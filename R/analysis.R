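#' Pearson correlation with pairwise-complete observations
#'
#' Product-moment correlation over the pairwise-complete entries of two
#' vectors, with a two-sided p-value from the t transform
#' t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom. At least three
#' complete pairs and non-zero variance on both sides are required; a
#' constant vector is an error, not r = 0.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p`, `n`.
#' @export
#' @examples
#' pearson(c(1, 2, 3), c(1, 2, 4))$r # ~0.982
pearson <- function(x, y) {
  if (length(x) != length(y)) {
    cadh_abort("x and y must have equal length", "cadhesion_error_correlation")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    cadh_abort("need at least 3 pairwise-complete observations",
               "cadhesion_error_correlation")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    cadh_abort("constant vector: correlation undefined",
               "cadhesion_error_correlation")
  }
  r <- cor(x, y)
  r_cl <- min(1 - 1e-15, max(-1 + 1e-15, r))
  tstat <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Classify a correlation coefficient
#'
#' Bins r into low (< 0.70), intermediate (0.70 to < 0.90) and high
#' (>= 0.90) correlation; half-open intervals close the gaps between the
#' conventional 0.69/0.7 and 0.89/0.9 cutpoints.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @param cut_intermediate,cut_high Lower bounds of the intermediate and
#'   high bins.
#' @return Character vector over `{"low", "intermediate", "high"}`.
#' @export
classify_correlation <- function(r, cut_intermediate = 0.70, cut_high = 0.90) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    cadh_abort("r must lie in [-1, 1]", "cadhesion_error_correlation")
  }
  out <- ifelse(r >= cut_high, "high",
                ifelse(r >= cut_intermediate, "intermediate", "low"))
  out
}

#' Per-age correlation of two genes across structures
#'
#' For each requested age stage, correlates the expression energies of two
#' genes over the structures of one ontological level (observations are
#' structures; pairwise-complete). Ages where either gene is absent are
#' omitted with a warning.
#'
#' @param records Expression tibble (see [read_expression_table()]).
#' @param graph A [structure_graph()] used to restrict to one level.
#' @param gene_a,gene_b Gene symbols.
#' @param level Ontological level whose structures are the observations.
#' @param ages Age stages to analyze (default all seven).
#' @return Tibble with `age`, `r`, `p`, `n`.
#' @export
gene_pair_correlation_by_age <- function(records, graph, gene_a, gene_b,
                                         level = 3, ages = AGE_STAGES) {
  structs <- segments_at_level(graph, level)$id
  out <- list()
  for (age in ages) {
    m <- tryCatch(expression_matrix(records, age), error = function(e) NULL)
    keep <- intersect(colnames(m), structs)
    if (is.null(m) || !all(c(gene_a, gene_b) %in% rownames(m)) ||
        length(keep) < 3L) {
      rlang::warn(paste0("age ", age, " omitted: genes or structures missing"))
      next
    }
    pr <- tryCatch(pearson(m[gene_a, keep], m[gene_b, keep]),
                   error = function(e) NULL)
    if (is.null(pr)) {
      rlang::warn(paste0("age ", age, " omitted: correlation undefined"))
      next
    }
    out[[age]] <- tibble::tibble(age = age, r = pr$r, p = pr$p, n = pr$n)
  }
  dplyr::bind_rows(out)
}

#' Correlate cadherin profiles between cortical units and subpallial nuclei
#'
#' For every cortical (area, layer) unit and every subpallial nucleus,
#' correlates the two units' expression vectors over a cadherin panel
#' (default 12 genes). Units missing more than `max_missing` of the panel
#' are excluded with a warning. The result is a labeled correlation matrix
#' with companion p-value and n matrices.
#'
#' @param matrix Gene-by-structure energy matrix at one age (typically
#'   P56).
#' @param cortical_ids,nucleus_ids Column ids of the cortical units (rows
#'   of the result) and subpallial nuclei (columns).
#' @param panel Cadherin panel; default [DEFAULT_PANEL].
#' @param max_missing Maximum tolerated fraction of missing panel values
#'   per unit (default 0.25).
#' @param normalize If `TRUE`, each unit's panel vector is scaled to unit
#'   total before correlating (default `FALSE`: raw energies).
#' @return A `correlation_matrix` list with `r`, `p`, `n` matrices and the
#'   label vectors.
#' @export
cortex_subpallium_correlation <- function(matrix, cortical_ids, nucleus_ids,
                                          panel = DEFAULT_PANEL,
                                          max_missing = 0.25,
                                          normalize = FALSE) {
  panel <- sort(panel)
  missing_genes <- setdiff(panel, rownames(matrix))
  if (length(missing_genes) > 0L) {
    cadh_abort(paste0("panel genes absent from matrix: ",
                      paste(missing_genes, collapse = ", ")),
               "cadhesion_error_correlation")
  }
  usable <- function(ids) {
    keep <- vapply(ids, function(s) {
      mean(is.na(matrix[panel, s])) <= max_missing
    }, logical(1))
    if (any(!keep)) {
      rlang::warn(paste0("excluding units with > ", max_missing * 100,
                         "% missing panel values: ",
                         paste(ids[!keep], collapse = ", ")))
    }
    ids[keep]
  }
  cortical_ids <- usable(cortical_ids)
  nucleus_ids <- usable(nucleus_ids)
  vec <- function(s) {
    v <- matrix[panel, s]
    if (normalize && sum(v, na.rm = TRUE) > 0) v <- v / sum(v, na.rm = TRUE)
    v
  }
  r <- matrix(NA_real_, length(cortical_ids), length(nucleus_ids),
              dimnames = list(cortical_ids, nucleus_ids))
  p <- r; n <- r
  for (i in cortical_ids) {
    for (j in nucleus_ids) {
      pr <- tryCatch(pearson(vec(i), vec(j)), error = function(e) NULL)
      if (is.null(pr)) next
      r[i, j] <- pr$r; p[i, j] <- pr$p; n[i, j] <- pr$n
    }
  }
  structure(list(r = r, p = p, n = n,
                 row_labels = cortical_ids, col_labels = nucleus_ids),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> ", nrow(x$r), " x ", ncol(x$r), " units\n", sep = "")
  invisible(x)
}

#' Long-format export of a correlation matrix
#'
#' @param cm A `correlation_matrix`.
#' @param path Optional CSV path to write.
#' @return Tibble with `row`, `col`, `r`, `p`, `n`, `bin`.
#' @export
correlation_long <- function(cm, path = NULL) {
  stopifnot(inherits(cm, "correlation_matrix"))
  df <- tibble::tibble(
    row = rep(rownames(cm$r), times = ncol(cm$r)),
    col = rep(colnames(cm$r), each = nrow(cm$r)),
    r = as.vector(cm$r), p = as.vector(cm$p), n = as.vector(cm$n)
  )
  df$bin <- ifelse(is.na(df$r), NA_character_, classify_correlation(df$r))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE, na = "")
  df
}

#' Alar/basal expression ratio along the anterior--posterior axis
#'
#' For one gene and age, the log2 ratio of alar-plate to basal-plate
#' expression energy per transverse segment: values above zero indicate
#' higher alar expression, below zero higher basal expression (-2 is a
#' fourfold basal excess). A segment with both plates at zero is missing;
#' one zero side yields a signed infinite sentinel, flagged.
#'
#' @param records Expression tibble.
#' @param graph A [structure_graph()] whose plate-level structures carry
#'   `plate` labels and segment `ap_index`.
#' @param gene Gene symbol.
#' @param age Age stage.
#' @param level Level of the plate subdivisions (default 5).
#' @return Tibble ordered by `ap_index` with `segment`, `alar`, `basal`,
#'   `log2_ratio`, `infinite` flag.
#' @export
alar_basal_ratio <- function(records, graph, gene, age, level = 5) {
  records <- validate_expression_table(tibble::as_tibble(records))
  if (!gene %in% records$gene) {
    cadh_abort(paste0("gene not present in records: ", gene),
               "cadhesion_error_reference")
  }
  plates <- select_structures(graph, level = level)
  plates <- plates[plates$plate %in% c("alar", "basal"), ]
  sub <- records[records$gene == gene & records$age == age &
                   records$structure_id %in% plates$id, ]
  sub <- dplyr::left_join(sub,
                          plates[, c("id", "parent_id", "plate", "ap_index")],
                          by = c("structure_id" = "id"))
  wide <- tidyr::pivot_wider(
    sub[, c("parent_id", "ap_index", "plate", "energy")],
    names_from = "plate", values_from = "energy"
  )
  if (!all(c("alar", "basal") %in% names(wide)) || nrow(wide) == 0L) {
    cadh_abort("no segment has both alar and basal values",
               "cadhesion_error_profile")
  }
  wide <- wide[order(wide$ap_index), ]
  both_zero <- wide$alar == 0 & wide$basal == 0
  ratio <- log2(wide$alar / wide$basal)
  ratio[both_zero] <- NA_real_
  tibble::tibble(
    segment = wide$parent_id,
    ap_index = wide$ap_index,
    alar = wide$alar, basal = wide$basal,
    log2_ratio = ratio,
    infinite = is.infinite(ratio)
  )
}

#' Compare ISH expression energies with scRNA-seq cluster means
#'
#' Both modalities are normalized to a reference housekeeping gene
#' (default Actb). The ISH side averages, per gene, the normalized
#' energies over a cortical grid of (area, layer) cells; the scRNA-seq
#' side averages the normalized cluster means over neuronal clusters only
#' (clusters whose class label is in `non_neuronal_labels` are removed).
#' A paired two-sided test across genes compares the two mean profiles.
#'
#' @param ish Gene-by-unit energy matrix over the cortical grid (must
#'   include the reference gene row).
#' @param sc Cluster-mean tibble with columns
#'   `cluster_id,class_label,gene,mean_expression`.
#' @param genes Genes to compare (default: all shared non-reference
#'   genes).
#' @param reference_gene Housekeeping reference, default "Actb".
#' @param non_neuronal_labels Class labels identifying non-neuronal
#'   clusters to exclude.
#' @param test `"wilcoxon"` (paired signed-rank, default) or `"t"`
#'   (paired t-test).
#' @return List with `per_gene` tibble (`gene`, `ish_mean`, `sc_mean`),
#'   `statistic`, `p_value`, `n_clusters_used`, `test`.
#' @export
ish_scrnaseq_comparison <- function(ish, sc, genes = NULL,
                                    reference_gene = "Actb",
                                    non_neuronal_labels = "non-neuronal",
                                    test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  sc <- tibble::as_tibble(sc)
  needed <- c("cluster_id", "class_label", "gene", "mean_expression")
  if (!all(needed %in% names(sc))) {
    cadh_abort("cluster table must have columns cluster_id,class_label,gene,mean_expression",
               "cadhesion_error_parse")
  }
  ish_norm <- normalize_to_gene(ish, reference_gene)
  neuronal <- sc[!sc$class_label %in% non_neuronal_labels, ]
  n_clusters_used <- length(unique(neuronal$cluster_id))
  ref <- neuronal[neuronal$gene == reference_gene,
                  c("cluster_id", "mean_expression")]
  names(ref)[2] <- "ref_expression"
  if (any(ref$ref_expression <= 0)) {
    cadh_abort(paste0("reference gene non-positive in clusters: ",
                      paste(ref$cluster_id[ref$ref_expression <= 0],
                            collapse = ", ")),
               "cadhesion_error_reference")
  }
  neuronal <- dplyr::left_join(neuronal, ref, by = "cluster_id")
  neuronal$norm <- neuronal$mean_expression / neuronal$ref_expression
  if (is.null(genes)) {
    genes <- setdiff(intersect(rownames(ish), unique(sc$gene)),
                     reference_gene)
  }
  per_gene <- tibble::tibble(
    gene = genes,
    ish_mean = vapply(genes, function(g) mean(ish_norm[g, ], na.rm = TRUE),
                      numeric(1)),
    sc_mean = vapply(genes, function(g) {
      mean(neuronal$norm[neuronal$gene == g], na.rm = TRUE)
    }, numeric(1))
  )
  diffs <- per_gene$ish_mean - per_gene$sc_mean
  if (all(diffs == 0)) {
    ht <- list(statistic = 0, p.value = 1)
  } else if (test == "wilcoxon") {
    ht <- suppressWarnings(
      wilcox.test(per_gene$ish_mean, per_gene$sc_mean, paired = TRUE)
    )
  } else {
    ht <- t.test(per_gene$ish_mean, per_gene$sc_mean, paired = TRUE)
  }
  list(per_gene = per_gene,
       statistic = unname(ht$statistic),
       p_value = ht$p.value,
       n_clusters_used = n_clusters_used,
       test = test)
}

#' Export a heatmap of a matrix or correlation matrix
#'
#' Deterministic tile rendering of a numeric matrix (or the `r` component
#' of a `correlation_matrix`) to SVG or PNG via ggplot2.
#'
#' @param m Numeric matrix or `correlation_matrix`.
#' @param path Output path ending in `.svg` or `.png`.
#' @param palette Low/mid/high fill colors.
#' @param limits Optional fill limits, e.g. `c(-1, 1)` for correlations.
#' @return `path`, invisibly.
#' @export
heatmap_export <- function(m, path,
                           palette = c("#2166AC", "#F7F7F7", "#B2182B"),
                           limits = NULL) {
  if (inherits(m, "correlation_matrix")) {
    if (is.null(limits)) limits <- c(-1, 1)
    m <- m$r
  }
  if (length(m) == 0L || is.null(dim(m))) {
    cadh_abort("cannot render an empty or dimensionless matrix",
               "cadhesion_error_plot")
  }
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
  df <- tibble::tibble(
    row = factor(rep(rownames(m), times = ncol(m)), levels = rev(rownames(m))),
    col = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    value = as.vector(m)
  )
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                         fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = palette[1], mid = palette[2],
                                  high = palette[3],
                                  midpoint = if (is.null(limits)) mean(range(df$value, na.rm = TRUE)) else mean(limits),
                                  limits = limits) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("svg", "png")) {
    cadh_abort("heatmap path must end in .svg or .png", "cadhesion_error_plot")
  }
  if (ext == "svg") {
    grDevices::svg(path, width = 7, height = 5)
  } else {
    grDevices::png(path, width = 1400, height = 1000, res = 200)
  }
  on.exit(grDevices::dev.off())
  print(gp)
  invisible(path)
}
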