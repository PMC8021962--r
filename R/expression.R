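#' Pixel-level summary of one ISH structure volume
#'
#' The three sufficient statistics from which expression energy is computed:
#' the summed intensity of expressing pixels, the number of expressing
#' pixels, and the total number of pixels in the structure volume.
#'
#' @param sum_expressing_intensity Non-negative total intensity over
#'   expressing pixels.
#' @param n_expressing_pixels Non-negative count of expressing pixels.
#' @param n_total_pixels Positive total pixel count.
#' @return A `pixel_summary` list.
#' @export
pixel_summary <- function(sum_expressing_intensity, n_expressing_pixels,
                          n_total_pixels) {
  if (n_total_pixels <= 0) {
    cadh_abort("n_total_pixels must be positive", "cadhesion_error_pixels")
  }
  if (n_expressing_pixels > n_total_pixels) {
    cadh_abort("expressing pixels cannot exceed total pixels",
               "cadhesion_error_pixels")
  }
  if (n_expressing_pixels == 0 && sum_expressing_intensity != 0) {
    cadh_abort("intensity must be zero when no pixel expresses",
               "cadhesion_error_pixels")
  }
  if (sum_expressing_intensity < 0) {
    cadh_abort("summed intensity must be non-negative",
               "cadhesion_error_pixels")
  }
  structure(
    list(sum_expressing_intensity = as.numeric(sum_expressing_intensity),
         n_expressing_pixels = as.numeric(n_expressing_pixels),
         n_total_pixels = as.numeric(n_total_pixels)),
    class = "pixel_summary"
  )
}

#' Expression energy of a structure volume
#'
#' Expression energy is the atlas summary statistic for ISH signal:
#' mean intensity of expressing pixels times the fraction of expressing
#' pixels, i.e.
#' (sum of expressing pixel intensity / number of expressing pixels) x
#' (number of expressing pixels / total pixels), which reduces to summed
#' expressing intensity over total pixels. A volume with no expressing
#' pixel has energy 0.
#'
#' @param p A [pixel_summary()].
#' @return Non-negative expression energy.
#' @export
#' @examples
#' expression_energy(pixel_summary(30, 2, 4)) # 7.5
expression_energy <- function(p) {
  stopifnot(inherits(p, "pixel_summary"))
  if (p$n_expressing_pixels == 0) return(0)
  (p$sum_expressing_intensity / p$n_expressing_pixels) *
    (p$n_expressing_pixels / p$n_total_pixels)
}

#' Unionize pixel summaries across sections
#'
#' Aggregates per-section (or per-voxel-block) pixel summaries belonging to
#' one anatomical structure by component-wise summation, so the energy of
#' the union equals total expressing intensity over total pixels regardless
#' of how the volume was partitioned.
#'
#' @param parts Non-empty list of [pixel_summary()] objects.
#' @return A single [pixel_summary()].
#' @export
unionize <- function(parts) {
  if (length(parts) == 0L) {
    cadh_abort("cannot unionize an empty list of pixel summaries",
               "cadhesion_error_pixels")
  }
  stopifnot(all(vapply(parts, inherits, logical(1), "pixel_summary")))
  pixel_summary(
    sum(vapply(parts, `[[`, numeric(1), "sum_expressing_intensity")),
    sum(vapply(parts, `[[`, numeric(1), "n_expressing_pixels")),
    sum(vapply(parts, `[[`, numeric(1), "n_total_pixels"))
  )
}

EXPRESSION_COLS <- c("gene", "structure_id", "age", "energy", "density",
                     "intensity", "experiment_id")

#' Read a long-format expression table
#'
#' Reads the CSV dialect
#' `gene,structure_id,age,energy,density,intensity,experiment_id`
#' (UTF-8, '.' decimal, empty field = missing) into a validated tibble.
#' Invalid rows are reported with their line numbers: negative energies,
#' unknown age labels, and duplicated (gene, structure, age, experiment)
#' keys each raise a distinct error.
#'
#' @param path CSV path.
#' @return A tibble of expression records.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) {
    cadh_abort(paste0("expression table not found: ", path),
               "cadhesion_error_parse")
  }
  df <- read.csv(path, colClasses = c(
    gene = "character", structure_id = "character", age = "character",
    energy = "numeric", density = "numeric", intensity = "numeric",
    experiment_id = "character"
  ), na.strings = c("", "NA"), comment.char = "#")
  validate_expression_table(tibble::as_tibble(df))
}

validate_expression_table <- function(df) {
  missing_cols <- setdiff(EXPRESSION_COLS, names(df))
  if (length(missing_cols) > 0L) {
    cadh_abort(paste0("expression table missing columns: ",
                      paste(missing_cols, collapse = ", ")),
               "cadhesion_error_parse")
  }
  df <- df[, EXPRESSION_COLS]
  bad_energy <- which(!is.na(df$energy) & df$energy < 0)
  if (length(bad_energy) > 0L) {
    cadh_abort(paste0("negative energy in rows: ",
                      paste(bad_energy, collapse = ", ")),
               "cadhesion_error_negative_energy")
  }
  bad_age <- which(!df$age %in% AGE_STAGES)
  if (length(bad_age) > 0L) {
    cadh_abort(paste0("unknown age label '",
                      paste(unique(df$age[bad_age]), collapse = "', '"),
                      "' in rows: ", paste(bad_age, collapse = ", ")),
               "cadhesion_error_unknown_age")
  }
  key <- paste(df$gene, df$structure_id, df$age,
               ifelse(is.na(df$experiment_id), "", df$experiment_id))
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    cadh_abort(paste0("duplicate (gene, structure, age, experiment) key in rows: ",
                      paste(dup, collapse = ", ")),
               "cadhesion_error_duplicate_key")
  }
  df
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]; the round-trip is lossless.
#'
#' @param records Expression tibble.
#' @param path Output CSV path.
#' @param header_comment Optional character vector written as leading
#'   `#`-prefixed comment lines (e.g. seed provenance).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(records, path, header_comment = NULL) {
  records <- validate_expression_table(tibble::as_tibble(records))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  write.csv(records, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Pivot expression records to a gene-by-structure matrix
#'
#' Builds the wide matrix for one age stage: rows are genes, columns are
#' structures, entries are expression energies (missing where no record
#' exists).
#'
#' @param records Expression tibble.
#' @param age Single age stage to extract.
#' @return A numeric matrix with gene rownames and structure colnames.
#' @export
expression_matrix <- function(records, age) {
  records <- validate_expression_table(tibble::as_tibble(records))
  if (!age %in% AGE_STAGES) {
    cadh_abort(paste0("unknown age label: ", age),
               "cadhesion_error_unknown_age")
  }
  sub <- records[records$age == age, ]
  genes <- sort(unique(sub$gene))
  structs <- sort(unique(sub$structure_id))
  m <- matrix(NA_real_, length(genes), length(structs),
              dimnames = list(genes, structs))
  m[cbind(match(sub$gene, genes), match(sub$structure_id, structs))] <- sub$energy
  m
}

#' Normalize a gene-by-structure matrix to a reference gene
#'
#' Divides every column by the reference gene's value in that column
#' (typically beta-actin, Actb), so the reference row becomes identically 1.
#' Columns where the reference is zero or missing are an error, named in
#' the message.
#'
#' @param matrix Gene-by-structure numeric matrix.
#' @param reference_gene Row name of the reference gene.
#' @return Matrix of the same shape, reference-normalized.
#' @export
normalize_to_gene <- function(matrix, reference_gene = "Actb") {
  if (!reference_gene %in% rownames(matrix)) {
    cadh_abort(paste0("reference gene '", reference_gene,
                      "' absent from matrix"),
               "cadhesion_error_reference")
  }
  ref <- matrix[reference_gene, ]
  used <- colSums(!is.na(matrix)) > 0
  bad <- which(used & (is.na(ref) | ref <= 0))
  if (length(bad) > 0L) {
    cadh_abort(paste0("reference gene '", reference_gene,
                      "' non-positive or missing in columns: ",
                      paste(colnames(matrix)[bad], collapse = ", ")),
               "cadhesion_error_reference")
  }
  sweep(matrix, 2, ref, "/")
}

#' Flag structures with significant expression
#'
#' A structure is flagged as significantly expressing a gene when its
#' expression energy is at or above the threshold (default 1 energy unit,
#' inclusive). Missing energies stay missing.
#'
#' @param matrix Gene-by-structure energy matrix.
#' @param threshold Significance threshold in energy units.
#' @return Logical matrix of the same shape.
#' @export
significant_expression_flags <- function(matrix, threshold = 1.0) {
  matrix >= threshold
}

#' Build Allen-style RMA query and experiment-browse URLs
#'
#' Constructs the deterministic REST query string used to retrieve
#' structure-unionized expression values for a set of anatomical structure
#' ids within one ISH experiment (section data set), plus the human-facing
#' experiment browse URL. Purely string assembly; no network access.
#'
#' @param structure_ids Non-empty vector of structure ids.
#' @param section_data_set_id Experiment identifier.
#' @return List with elements `rma_url` and `browse_url`.
#' @export
#' @examples
#' build_rma_query(c(17, 23), "100081391")$browse_url
build_rma_query <- function(structure_ids, section_data_set_id) {
  if (length(structure_ids) == 0L) {
    cadh_abort("structure_ids must be non-empty", "cadhesion_error_query")
  }
  if (length(section_data_set_id) != 1L || is.na(section_data_set_id) ||
      !nzchar(section_data_set_id)) {
    cadh_abort("section_data_set_id must be a single non-empty id",
               "cadhesion_error_query")
  }
  ids <- paste(structure_ids, collapse = ",")
  rma <- paste0(
    "http://api.brain-map.org/api/v2/data/query.csv?criteria=",
    "model::StructureUnionize,rma::criteria,",
    "[section_data_set_id$eq", section_data_set_id, "],",
    "structure[id$in", ids, "],",
    "rma::include,structure,",
    "rma::options[tabular$eq'structures.acronym,structure_unionizes.expression_energy,",
    "structure_unionizes.expression_density,structure_unionizes.sum_expressing_pixel_intensity']"
  )
  browse <- paste0("http://developingmouse.brain-map.org/experiment/show/",
                   section_data_set_id)
  list(rma_url = rma, browse_url = browse)
}
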