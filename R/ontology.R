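#' Ontology of developing-CNS structures
#'
#' A `structure_graph` holds the ontology-based neuroanatomy used to index
#' every expression and adhesion computation: transverse neuromeric segments
#' ordered along the anterior--posterior axis, the four longitudinal plates
#' (roof/alar/basal/floor), the radial strata and divisions of the
#' subpallium, and cortical (area, layer) units. Structures live on
#' ontological levels 1--13; lower levels are coarser. The graph is a forest:
#' each structure names at most one parent, and a parent is always on a
#' strictly lower level than its children.
#'
#' @param structures A data frame with columns `id`, `acronym`, `name`,
#'   `level`, `parent_id`, `ap_index`, `plate`, `stratum`, `division`,
#'   `area`, `layer`. `parent_id` is `NA` for roots; `ap_index` is `NA`
#'   except for transverse segments; `area`/`layer` are `NA` except for
#'   cortical units.
#' @param age_stages Ordered character vector of developmental stages;
#'   defaults to the seven stages in [AGE_STAGES].
#'
#' @return An object of class `structure_graph`.
#' @export
#' @examples
#' g <- structure_graph(tibble::tibble(
#'   id = c("root", "s1"), acronym = c("CNS", "r1"),
#'   name = c("central nervous system", "rhombomere 1"),
#'   level = c(1L, 3L), parent_id = c(NA, "root"),
#'   ap_index = c(NA, 1L), plate = "none", stratum = "none",
#'   division = "none", area = NA_character_, layer = NA_character_
#' ))
#' segments_at_level(g, 3)
structure_graph <- function(structures, age_stages = AGE_STAGES) {
  cols <- c("id", "acronym", "name", "level", "parent_id", "ap_index",
            "plate", "stratum", "division", "area", "layer")
  structures <- tibble::as_tibble(structures)
  missing_cols <- setdiff(cols, names(structures))
  for (cc in missing_cols) {
    structures[[cc]] <- if (cc %in% c("level", "ap_index")) NA_integer_ else NA_character_
  }
  structures <- structures[, cols]
  structures$level <- as.integer(structures$level)
  structures$ap_index <- as.integer(structures$ap_index)
  for (cc in c("plate", "stratum", "division")) {
    structures[[cc]][is.na(structures[[cc]])] <- "none"
  }
  g <- structure(list(structures = structures, age_stages = age_stages),
                 class = "structure_graph")
  validate_structure_graph(g)
  g
}

validate_structure_graph <- function(g) {
  s <- g$structures
  if (nrow(s) == 0L) return(invisible(g))
  if (anyNA(s$id) || anyDuplicated(s$id)) {
    cadh_abort("structure ids must be unique and non-missing",
               "cadhesion_error_parse")
  }
  if (any(s$level < 1L, na.rm = TRUE) || anyNA(s$level)) {
    cadh_abort("ontological level must be an integer >= 1",
               "cadhesion_error_parse")
  }
  has_parent <- !is.na(s$parent_id) & s$parent_id != ""
  dangling <- s$parent_id[has_parent][!s$parent_id[has_parent] %in% s$id]
  if (length(dangling) > 0L) {
    cadh_abort(
      paste0("dangling parent_id: ", paste(unique(dangling), collapse = ", ")),
      "cadhesion_error_dangling_parent"
    )
  }
  # cycle check by following parent links from every node
  parent <- setNames(ifelse(has_parent, s$parent_id, NA_character_), s$id)
  for (start in s$id) {
    seen <- character()
    node <- start
    while (!is.na(node)) {
      if (node %in% seen) {
        cadh_abort(paste0("cycle detected through structure '", node, "'"),
                   "cadhesion_error_cycle")
      }
      seen <- c(seen, node)
      node <- parent[[node]]
    }
  }
  lev <- setNames(s$level, s$id)
  bad <- has_parent & lev[s$parent_id] >= s$level
  if (any(bad, na.rm = TRUE)) {
    cadh_abort(
      paste0("parent must be on a lower level than child: ",
             paste(s$id[which(bad)], collapse = ", ")),
      "cadhesion_error_parse"
    )
  }
  dup <- duplicated(s[, c("level", "acronym")])
  if (any(dup)) {
    cadh_abort(
      paste0("duplicate acronym within a level: ",
             paste(unique(s$acronym[dup]), collapse = ", ")),
      "cadhesion_error_duplicate_acronym"
    )
  }
  for (cc in list(c("plate", PLATE_LEVELS), c("stratum", STRATUM_LEVELS),
                  c("division", DIVISION_LEVELS))) {
    vals <- s[[cc[1]]]
    bad_vals <- setdiff(unique(vals[!is.na(vals)]), cc[-1])
    if (length(bad_vals) > 0L) {
      cadh_abort(
        paste0("unknown ", cc[1], " value: ", paste(bad_vals, collapse = ", ")),
        "cadhesion_error_vocab"
      )
    }
  }
  invisible(g)
}

#' @export
print.structure_graph <- function(x, ...) {
  s <- x$structures
  cat("<structure_graph> ", nrow(s), " structures on level(s) ",
      paste(sort(unique(s$level)), collapse = ", "), "\n", sep = "")
  cat("age stages: ", paste(x$age_stages, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.structure_graph <- function(x, ...) as.data.frame(x$structures)

#' Read an ontology from its JSON representation
#'
#' The on-disk format is a JSON object with an `age_stages` array and a
#' `structures` array of objects carrying the fields of
#' [structure_graph()]. All graph invariants (forest shape, unique
#' acronyms per level, parent ordering) are checked on load, each failure
#' raising a distinct error class.
#'
#' @param path Path to a UTF-8 JSON ontology file.
#' @return A validated [structure_graph()].
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) {
    cadh_abort(paste0("ontology file not found: ", path),
               "cadhesion_error_parse")
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) {
      cadh_abort(paste0("ontology JSON parse failure: ", conditionMessage(e)),
                 "cadhesion_error_parse")
    }
  )
  structures <- parsed$structures
  if (is.null(structures) || length(structures) == 0L) {
    structures <- tibble::tibble(
      id = character(), acronym = character(), name = character(),
      level = integer(), parent_id = character(), ap_index = integer(),
      plate = character(), stratum = character(), division = character(),
      area = character(), layer = character()
    )
  }
  ages <- parsed$age_stages %||% AGE_STAGES
  structure_graph(structures, age_stages = ages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ontology to JSON (and optionally a companion CSV)
#'
#' @param graph A [structure_graph()].
#' @param path Output JSON path.
#' @param csv_path Optional path for a one-row-per-structure CSV export with
#'   identical columns.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(graph, path, csv_path = NULL) {
  stopifnot(inherits(graph, "structure_graph"))
  out <- list(age_stages = graph$age_stages, structures = graph$structures)
  jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    write.csv(graph$structures, csv_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' The packaged developing-mouse-CNS ontology fixture
#'
#' Loads the ontology shipped with the package: the 19 transverse segments
#' of ontological level 3 (rostral/caudal secondary prosencephalon,
#' prosomeres p3--p1, mesomeres m1--m2, isthmus, rhombomeres r1--r11) in
#' anterior-to-posterior order, their alar/basal/roof/floor plate
#' subdivisions at level 5, a set of subpallial nuclei with stratum and
#' division attributes, and the 9 x 6 cortical (area, layer) units.
#'
#' @return A [structure_graph()].
#' @export
atlas_ontology <- function() {
  load_ontology(system.file("extdata", "ontology.json", package = "cadhesion"))
}

#' Transverse segments at an ontological level
#'
#' Returns the structures of one level ordered along the anterior--posterior
#' axis (ascending `ap_index`, anterior first), with a stable alphabetical
#' tie-break on acronym. Structures without an `ap_index` sort after ranked
#' ones.
#'
#' @param graph A [structure_graph()].
#' @param level Integer level, 1--13.
#' @return A tibble of structures (possibly empty).
#' @export
segments_at_level <- function(graph, level) {
  stopifnot(inherits(graph, "structure_graph"))
  if (length(level) != 1L || is.na(level) || level < 1 || level > 13) {
    cadh_abort("level must be a single integer in 1..13",
               "cadhesion_error_level")
  }
  s <- graph$structures[graph$structures$level == as.integer(level), ]
  s[order(s$ap_index, s$acronym, na.last = TRUE), ]
}

#' Select structures by plate, stratum, division, area or layer
#'
#' All and only the structures matching every supplied filter are returned;
#' with no filters the whole structure table is returned. Filter values are
#' validated against the enumerated vocabularies where one exists.
#'
#' @param graph A [structure_graph()].
#' @param plate,stratum,division Optional single values from the plate
#'   (roof/alar/basal/floor/none), stratum
#'   (ventricular/periventricular/intermediate/superficial/none) and
#'   division (septal/paraseptal/central/amygdaloid/none) vocabularies.
#' @param area,layer Optional cortical area and layer labels.
#' @param level Optional level restriction.
#' @return A tibble of structures.
#' @export
select_structures <- function(graph, plate = NULL, stratum = NULL,
                              division = NULL, area = NULL, layer = NULL,
                              level = NULL) {
  stopifnot(inherits(graph, "structure_graph"))
  check_vocab <- function(value, vocab, what) {
    if (!is.null(value) && !all(value %in% vocab)) {
      cadh_abort(paste0("unknown ", what, " value: ",
                        paste(setdiff(value, vocab), collapse = ", ")),
                 "cadhesion_error_vocab")
    }
  }
  check_vocab(plate, PLATE_LEVELS, "plate")
  check_vocab(stratum, STRATUM_LEVELS, "stratum")
  check_vocab(division, DIVISION_LEVELS, "division")
  s <- graph$structures
  if (!is.null(level)) s <- s[s$level %in% as.integer(level), ]
  if (!is.null(plate)) s <- s[s$plate %in% plate, ]
  if (!is.null(stratum)) s <- s[s$stratum %in% stratum, ]
  if (!is.null(division)) s <- s[s$division %in% division, ]
  if (!is.null(area)) s <- s[!is.na(s$area) & s$area %in% area, ]
  if (!is.null(layer)) s <- s[!is.na(s$layer) & s$layer %in% layer, ]
  s
}
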