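test_that("pearson matches the frozen hand computation and the cor.test oracle", {
  pr <- pearson(c(1, 2, 3), c(1, 2, 4))
  expect_equal(pr$r, 0.98198, tolerance = 1e-4)
  expect_equal(pr$n, 3L)
  # perfect positive and negative dependence
  expect_equal(pearson(1:5, 2 * (1:5) + 3)$r, 1, tolerance = 1e-12)
  expect_equal(pearson(1:5, -(1:5))$r, -1, tolerance = 1e-12)
  # agreement with the independent stats::cor.test route on random vectors
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(30)
    y <- 0.4 * x + rnorm(30)
    ct <- cor.test(x, y)
    pr <- pearson(x, y)
    expect_equal(pr$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pr$p, ct$p.value, tolerance = 1e-12)
  }
  # pairwise-complete handling and guard rails
  expect_equal(pearson(c(1, 2, 3, NA), c(1, 2, 4, 9))$n, 3L)
  expect_error(pearson(c(1, 2), c(1, 2)), class = "cadhesion_error_correlation")
  expect_error(pearson(rep(1, 5), 1:5), class = "cadhesion_error_correlation")
})

test_that("correlation bins are total, monotone, and split at 0.70 and 0.90", {
  expect_equal(classify_correlation(0.86), "intermediate")
  expect_equal(classify_correlation(0.95), "high")
  expect_equal(classify_correlation(-0.2), "low")
  # bin boundaries are inclusive on the upper bin
  expect_equal(classify_correlation(c(0.6999, 0.70, 0.8999, 0.90)),
               c("low", "intermediate", "intermediate", "high"))
  # monotone over a grid
  grid <- seq(-1, 1, by = 0.01)
  bins <- factor(classify_correlation(grid),
                 levels = c("low", "intermediate", "high"), ordered = TRUE)
  expect_true(all(diff(as.integer(bins)) >= 0))
  expect_error(classify_correlation(1.5), class = "cadhesion_error_correlation")
})

test_that("per-age gene-pair correlations recover exact and planted dependence", {
  g <- tiny_graph(sprintf("s%02d", 1:20))
  # exact linear dependence gives r = 1 at every age
  ids <- sprintf("s%02d", 1:20)
  e <- runif(20, 1, 5)
  tbl <- dplyr::bind_rows(lapply(c("E13.5", "P56"), function(age) {
    dplyr::bind_rows(records_for("Cdh2", ids, e, age),
                     records_for("Cdh13", ids, 3 * e, age))
  }))
  out <- gene_pair_correlation_by_age(tbl, g, "Cdh2", "Cdh13",
                                      ages = c("E13.5", "P56"))
  expect_equal(nrow(out), 2L)
  expect_equal(out$r, c(1, 1), tolerance = 1e-12)
  # an age without both genes is omitted with a warning
  expect_warning(
    out2 <- gene_pair_correlation_by_age(tbl, g, "Cdh2", "Cdh13",
                                         ages = c("E13.5", "E18.5")),
    "omitted")
  expect_equal(out2$age, "E13.5")
  # a generated table hits the Fisher-z window around its target
  spec <- synthetic_spec(
    seed = 33, n_structures = 200, genes = c("Cdh2", "Cdh13"),
    target_correlations = data.frame(gene_a = "Cdh2", gene_b = "Cdh13",
                                     r = 0.86))
  m <- expression_matrix(generate_expression_table(spec), "P56")
  r_hat <- pearson(m["Cdh2", ], m["Cdh13", ])$r
  window <- fisher_z_interval(0.86, 200)
  expect_gt(r_hat, window[1])
  expect_lt(r_hat, window[2])
})

test_that("cortex-subpallium correlation finds planted matches and self-identity", {
  set.seed(7)
  panel <- DEFAULT_PANEL
  units <- c(paste0("ctx", 1:5), paste0("nuc", 1:6))
  m <- matrix(runif(length(panel) * length(units), 0.5, 8),
              length(panel), length(units),
              dimnames = list(panel, units))
  # plant one exact match between a cortical unit and a nucleus
  m[, "nuc3"] <- m[, "ctx2"]
  cm <- cortex_subpallium_correlation(m, paste0("ctx", 1:5),
                                      paste0("nuc", 1:6))
  expect_equal(dim(cm$r), c(5L, 6L))
  expect_equal(cm$r["ctx2", "nuc3"], 1, tolerance = 1e-12)
  expect_equal(unname(which.max(cm$r["ctx2", ])), 3L)
  # self-paired label sets put 1 on the diagonal
  cm_self <- cortex_subpallium_correlation(m, units[1:4], units[1:4])
  expect_equal(unname(diag(cm_self$r)), rep(1, 4), tolerance = 1e-12)
  # panel order does not matter
  cm_perm <- cortex_subpallium_correlation(m, paste0("ctx", 1:5),
                                           paste0("nuc", 1:6),
                                           panel = rev(panel))
  expect_equal(cm_perm$r, cm$r)
  # a unit with too many missing panel values is excluded with a warning
  m_miss <- m
  m_miss[1:5, "ctx1"] <- NA
  expect_warning(
    cm_miss <- cortex_subpallium_correlation(m_miss, paste0("ctx", 1:5),
                                             paste0("nuc", 1:6)),
    "excluding")
  expect_false("ctx1" %in% rownames(cm_miss$r))
  # long export carries bins
  long <- correlation_long(cm)
  expect_equal(nrow(long), 30L)
  expect_equal(long$bin[long$row == "ctx2" & long$col == "nuc3"], "high")
})

test_that("alar/basal log2 ratios are signed, antisymmetric, and flag zeros", {
  g <- atlas_ontology()
  segs <- segments_at_level(g, 3)$id
  plates <- select_structures(g, level = 5)
  alar_ids <- plates$id[plates$plate == "alar"][match(segs, plates$parent_id[plates$plate == "alar"])]
  basal_ids <- plates$id[plates$plate == "basal"][match(segs, plates$parent_id[plates$plate == "basal"])]
  alar_e <- c(4, rep(2, 17), 1)
  basal_e <- c(1, rep(2, 17), 0)
  tbl <- dplyr::bind_rows(records_for("Cdh8", alar_ids, alar_e),
                          records_for("Cdh8", basal_ids, basal_e))
  rp <- alar_basal_ratio(tbl, g, "Cdh8", "P56")
  expect_equal(nrow(rp), 19L)
  expect_equal(rp$log2_ratio[1], 2)             # fourfold alar excess
  expect_equal(rp$log2_ratio[2], 0)             # equal plates sit on the zero line
  expect_true(is.infinite(rp$log2_ratio[19]))   # zero basal -> +Inf sentinel
  expect_true(rp$infinite[19])
  # swapping plate labels negates every finite value
  tbl_swapped <- dplyr::bind_rows(records_for("Cdh8", alar_ids, basal_e),
                                  records_for("Cdh8", basal_ids, alar_e))
  rp_swapped <- alar_basal_ratio(tbl_swapped, g, "Cdh8", "P56")
  finite <- is.finite(rp$log2_ratio)
  expect_equal(rp_swapped$log2_ratio[finite], -rp$log2_ratio[finite])
  expect_error(alar_basal_ratio(tbl, g, "Cdh99", "P56"),
               class = "cadhesion_error_reference")
})

test_that("ISH vs scRNA-seq comparison normalizes both sides and counts clusters", {
  genes <- c("Cdh2", "Cdh13", "Cdh8", "Cdh11", "Cdh6")
  sc <- generate_scrnaseq_clusters(genes, n_clusters = 377,
                                   n_non_neuronal = 24, seed = 9)
  # ISH grid whose normalized means equal the sc-side means exactly
  sc_neuronal <- sc[sc$class_label == "neuronal", ]
  ref <- sc_neuronal$mean_expression[sc_neuronal$gene == "Actb"]
  sc_means <- vapply(genes, function(gg) {
    mean(sc_neuronal$mean_expression[sc_neuronal$gene == gg] / ref)
  }, numeric(1))
  ish <- matrix(rep(c(sc_means, 1), 24), length(genes) + 1, 24,
                dimnames = list(c(genes, "Actb"),
                                paste0("u", 1:24)))
  res <- ish_scrnaseq_comparison(ish, sc, genes = genes)
  expect_equal(res$n_clusters_used, 353L)
  expect_equal(res$per_gene$ish_mean, res$per_gene$sc_mean,
               tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_error(
    ish_scrnaseq_comparison(ish, dplyr::mutate(
      sc, mean_expression = ifelse(gene == "Actb", 0, mean_expression))),
    class = "cadhesion_error_reference")
})

test_that("equal-mean generation keeps the comparison test near its nominal size", {
  genes <- paste0("g", 1:12)
  reps <- 60
  pvals <- vapply(seq_len(reps), function(i) {
    sc <- generate_scrnaseq_clusters(genes, n_clusters = 40,
                                     n_non_neuronal = 4, seed = 1000 + i)
    # a noiseless shared reference keeps the per-gene differences
    # exchangeable: reference noise common to all genes would otherwise
    # shift every difference together and inflate the test size
    sc$mean_expression[sc$gene == "Actb"] <- 100
    set.seed(2000 + i)
    ish <- matrix(exp(rnorm((length(genes) + 1) * 10, 0, 0.4)),
                  length(genes) + 1, 10,
                  dimnames = list(c(genes, "Actb"), paste0("u", 1:10)))
    # both sides share gene baseline 1 against a reference baseline of 100
    ish["Actb", ] <- 100
    ish_scrnaseq_comparison(ish, sc, genes = genes)$p_value
  }, numeric(1))
  # under the null the rejection rate at alpha = 0.05 stays near nominal
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.3)
})

test_that("heatmaps render deterministically to SVG and PNG", {
  m <- matrix(c(0.1, 0.5, -0.3, 0.9), 2, 2)
  png1 <- tempfile(fileext = ".png"); png2 <- tempfile(fileext = ".png")
  heatmap_export(m, png1); heatmap_export(m, png2)
  expect_identical(readBin(png1, "raw", file.size(png1)),
                   readBin(png2, "raw", file.size(png2)))
  svg1 <- tempfile(fileext = ".svg"); svg2 <- tempfile(fileext = ".svg")
  heatmap_export(m, svg1); heatmap_export(m, svg2)
  # identical up to the device-instance counter in element ids
  normalize <- function(p) gsub("source-[0-9]+", "source-N", readLines(p))
  expect_identical(normalize(svg1), normalize(svg2))
  expect_error(heatmap_export(matrix(numeric(0), 0, 0), tempfile(fileext = ".svg")),
               class = "cadhesion_error_plot")
})
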