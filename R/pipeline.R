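#' Read and validate a pipeline run configuration
#'
#' YAML configuration naming the inputs (expression CSV, ontology JSON,
#' K_D CSV, optional scRNA-seq CSV), adhesion-parameter overrides, the
#' analysis panel and thresholds, an output directory and a seed.
#' Referenced input files must exist at validation time.
#'
#' @param path YAML config path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    cadh_abort(paste0("config not found: ", path), "cadhesion_error_config")
  }
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$panel <- cfg$panel %||% DEFAULT_PANEL
  for (key in c("expression_csv", "ontology_json", "kd_csv", "scrnaseq_csv")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      cadh_abort(paste0("configured input missing: ", key, " = ", cfg[[key]]),
                 "cadhesion_error_config")
    }
  }
  cfg$params <- do.call(adhesion_params, cfg$adhesion_params %||% list())
  cfg$config_hash <- unname(tools::md5sum(path))
  class(cfg) <- "run_config"
  cfg
}

output_header <- function(seed, config_hash = "none") {
  c(paste0("cadhesion ",
           as.character(utils::packageVersion("cadhesion"))),
    paste0("seed=", seed),
    paste0("config=", config_hash))
}

#' Generate synthetic inputs from a YAML spec
#'
#' Reads a YAML file mirroring the fields of [synthetic_spec()]
#' (`target_correlations` and `planted_folds` as lists of mappings),
#' writes the generated expression table and a manifest recording the
#' seed, and returns the written paths. Identical spec and seed produce
#' byte-identical output.
#'
#' @param spec_path YAML spec path.
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths (`expression`, `manifest`),
#'   invisibly.
#' @export
cmd_simulate <- function(spec_path, out_dir) {
  if (!file.exists(spec_path)) {
    cadh_abort(paste0("spec not found: ", spec_path), "cadhesion_error_config")
  }
  raw <- yaml::read_yaml(spec_path)
  to_df <- function(x) if (is.null(x)) NULL else dplyr::bind_rows(x)
  spec <- synthetic_spec(
    seed = raw$seed %||% 1L,
    n_structures = raw$n_structures %||% 19L,
    ages = raw$ages %||% "P56",
    genes = raw$genes %||% c("Cdh2", "Cdh13"),
    target_correlations = to_df(raw$target_correlations),
    sigma = raw$sigma %||% 0.3,
    planted_folds = to_df(raw$planted_folds),
    baseline_energy = raw$baseline_energy %||% 1.0
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tbl <- generate_expression_table(spec)
  expr_path <- file.path(out_dir, "expression.csv")
  write_expression_table(tbl, expr_path,
                         header_comment = output_header(spec$seed))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(seed = spec$seed, n_structures = spec$n_structures,
                        ages = spec$ages, genes = spec$genes,
                        sigma = spec$sigma,
                        baseline_energy = spec$baseline_energy,
                        rows = nrow(tbl)),
                   manifest_path)
  invisible(list(expression = expr_path, manifest = manifest_path))
}

#' Run the adhesion stage of the pipeline
#'
#' For every age present in the configured expression table, converts
#' energies to relative adhesion via the dimer-equilibrium model and
#' writes a full audit-trail CSV (molecules, concentrations, dimer
#' counts, per-dimer free energy, work, relative adhesion) plus one
#' per-age profile figure.
#'
#' @param config A `run_config` from [read_run_config()].
#' @return Named list of written paths, invisibly.
#' @export
cmd_adhesion <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$expression_csv)) {
    cadh_abort("config must name expression_csv", "cadhesion_error_config")
  }
  records <- read_expression_table(config$expression_csv)
  if (nrow(records) == 0L) {
    cadh_abort("expression table is empty", "cadhesion_error_config")
  }
  kd <- if (is.null(config$kd_csv)) read_kd_table() else read_kd_table(config$kd_csv)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  profiles <- list()
  for (age in intersect(AGE_STAGES, unique(records$age))) {
    m <- expression_matrix(records, age)
    prof <- adhesion_profile(m, kd, config$params)
    prof$age <- age
    profiles[[age]] <- prof
  }
  all_prof <- dplyr::bind_rows(profiles)
  csv_path <- file.path(config$out_dir, "adhesion_profile.csv")
  con <- file(csv_path, "wt")
  writeLines(paste0("# ", output_header(config$seed, config$config_hash)), con)
  write.csv(all_prof, con, row.names = FALSE, na = "")
  close(con)
  paths$profile <- csv_path
  fig_path <- file.path(config$out_dir, "adhesion_profile.svg")
  gp <- ggplot2::ggplot(all_prof,
                        ggplot2::aes(x = .data$structure_id,
                                     y = .data$relative_adhesion,
                                     group = .data$cadherin,
                                     color = .data$cadherin)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~age) +
    ggplot2::labs(x = "structure (anterior to posterior)",
                  y = "relative adhesion") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  grDevices::svg(fig_path, width = 8, height = 5)
  print(gp)
  grDevices::dev.off()
  paths$figure <- fig_path
  invisible(paths)
}

#' Run the correlation stage of the pipeline
#'
#' Correlates cadherin-panel expression vectors between two configured
#' structure sets (e.g. cortical (area, layer) units against subpallial
#' nuclei) at one age, writing the labeled r/p/n matrices, a long-format
#' table with correlation bins, and a heatmap.
#'
#' @param config A `run_config` naming `expression_csv`, `ontology_json`,
#'   and optionally `age` (default "P56") and `panel`.
#' @return Named list of written paths, invisibly.
#' @export
cmd_correlate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$expression_csv) || is.null(config$ontology_json)) {
    cadh_abort("config must name expression_csv and ontology_json",
               "cadhesion_error_config")
  }
  records <- read_expression_table(config$expression_csv)
  graph <- load_ontology(config$ontology_json)
  age <- config$age %||% "P56"
  m <- expression_matrix(records, age)
  cortical <- graph$structures$id[!is.na(graph$structures$area)]
  nuclei <- graph$structures$id[graph$structures$division != "none"]
  cortical <- intersect(cortical, colnames(m))
  nuclei <- intersect(nuclei, colnames(m))
  if (length(cortical) == 0L || length(nuclei) == 0L) {
    cadh_abort("no cortical units or no subpallial nuclei with expression data",
               "cadhesion_error_config")
  }
  cm <- cortex_subpallium_correlation(m, cortical, nuclei,
                                      panel = config$panel)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  long_path <- file.path(config$out_dir, "correlations.csv")
  con <- file(long_path, "wt")
  writeLines(paste0("# ", output_header(config$seed, config$config_hash)), con)
  writeLines(paste0("# panel=", paste(sort(config$panel), collapse = ",")), con)
  write.csv(correlation_long(cm), con, row.names = FALSE, na = "")
  close(con)
  heat_path <- file.path(config$out_dir, "correlations.svg")
  heatmap_export(cm, heat_path)
  invisible(list(correlations = long_path, heatmap = heat_path))
}

#' Assemble a run report
#'
#' Collates the outputs of the other stages in the configured output
#' directory into one markdown document, echoing every adhesion-model
#' constant (including the 25,000-molecule calibration) and the K_D
#' sources so the run is auditable. Re-running on unchanged inputs yields
#' an identical report body.
#'
#' @param config A `run_config`.
#' @return Path of the written report, invisibly.
#' @export
cmd_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  expected <- file.path(out, c("adhesion_profile.csv", "correlations.csv"))
  present <- expected[file.exists(expected)]
  if (length(present) == 0L) {
    cadh_abort(paste0("no upstream outputs found in ", out),
               "cadhesion_error_config")
  }
  kd <- if (is.null(config$kd_csv)) read_kd_table() else read_kd_table(config$kd_csv)
  p <- config$params
  lines <- c(
    "# cadhesion run report",
    "",
    paste0("seed: ", config$seed),
    paste0("config hash: ", config$config_hash),
    "",
    "## Adhesion model constants",
    "",
    paste0("- molecules per energy unit: ", p$molecules_per_energy_unit),
    paste0("- cell diameter (m): ", p$cell_diameter),
    paste0("- contact thickness (m): ", p$contact_thickness),
    paste0("- neighbors / contact fraction: ", p$n_neighbors, " / ",
           format(p$contact_fraction, digits = 6)),
    paste0("- participation fraction: ", p$participation_fraction),
    paste0("- count both cells: ", p$count_both_cells),
    paste0("- temperature (K): ", p$temperature),
    paste0("- reference: ", p$reference_molecules, " molecules of ",
           p$reference_cadherin, " at K_D = ", p$reference_kd, " M"),
    "",
    "## K_D sources",
    "",
    paste0("- ", kd$cadherin, ": ", format(kd$kd_molar, digits = 4),
           " M (", kd$source, ")"),
    "",
    "## Stage outputs",
    "",
    paste0("- ", basename(present))
  )
  report_path <- file.path(out, "report.md")
  writeLines(lines, report_path)
  invisible(report_path)
}
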