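#' Parameters of the relative-adhesion model
#'
#' Bundles every constant of the biophysical model converting surface
#' molecule counts into a work of separation between two apposed cells:
#'
#' * `molecules_per_energy_unit`: calibration equating 1 unit of expression
#'   energy to a surface molecule count (default 25,000).
#' * `cell_diameter`: diameter of the idealized spherical cell, meters
#'   (default 10 um).
#' * `contact_thickness`: thickness of the intermembrane slab in which the
#'   adhesive EC1 domains reside, meters (default 12 nm, from membrane
#'   spacing and EC-domain crystal geometry).
#' * `n_neighbors` / `contact_fraction`: a close-packed sphere touches 12
#'   neighbors, so one contact holds 1/12 (about 8%) of the surface
#'   molecules (default fraction exactly 1/12).
#' * `participation_fraction`: fraction of the molecules within a contact
#'   assumed to engage in trans-dimers (default 0.5, i.e. about 4% of the
#'   cell total).
#' * `count_both_cells`: whether molecules contributed by both membranes
#'   enter the contact concentration (default `FALSE`; only the ratio
#'   C_T/K_D matters for relative quantities, so this is a labeling choice).
#' * `temperature` (K), `gas_constant` (cal/mol/K), `avogadro` (1/mol):
#'   thermodynamic constants. Relative adhesion is provably temperature
#'   invariant.
#' * `reference_cadherin`, `reference_molecules`, `reference_kd`: the
#'   normalization anchor — 25,000 molecules of Cdh2 with homophilic
#'   K_D = 25.8 uM.
#' * `kd_reference_state`: 1 M standard state making ln(K_D) dimensionless.
#'
#' @param molecules_per_energy_unit,cell_diameter,contact_thickness,n_neighbors,contact_fraction,participation_fraction,count_both_cells,temperature,gas_constant,avogadro,reference_cadherin,reference_molecules,reference_kd,kd_reference_state
#'   See description.
#' @return An `adhesion_params` list.
#' @export
adhesion_params <- function(molecules_per_energy_unit = 25000,
                            cell_diameter = 10e-6,
                            contact_thickness = 12e-9,
                            n_neighbors = 12L,
                            contact_fraction = 1 / 12,
                            participation_fraction = 0.5,
                            count_both_cells = FALSE,
                            temperature = 310.15,
                            gas_constant = 1.987,
                            avogadro = 6.022e23,
                            reference_cadherin = "Cdh2",
                            reference_molecules = 25000,
                            reference_kd = 25.8e-6,
                            kd_reference_state = 1.0) {
  p <- list(
    molecules_per_energy_unit = molecules_per_energy_unit,
    cell_diameter = cell_diameter,
    contact_thickness = contact_thickness,
    n_neighbors = as.integer(n_neighbors),
    contact_fraction = contact_fraction,
    participation_fraction = participation_fraction,
    count_both_cells = isTRUE(count_both_cells),
    temperature = temperature,
    gas_constant = gas_constant,
    avogadro = avogadro,
    reference_cadherin = reference_cadherin,
    reference_molecules = reference_molecules,
    reference_kd = reference_kd,
    kd_reference_state = kd_reference_state
  )
  num <- p[!names(p) %in% c("count_both_cells", "reference_cadherin")]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(vapply(num, function(v) !is.finite(v) || v <= 0, logical(1)))) {
    cadh_abort("all numeric adhesion parameters must be positive and finite",
               "cadhesion_error_params")
  }
  if (p$contact_fraction > 1 || p$participation_fraction > 1) {
    cadh_abort("contact_fraction and participation_fraction must lie in (0, 1]",
               "cadhesion_error_params")
  }
  structure(p, class = "adhesion_params")
}

#' Surface molecule count from expression energy
#'
#' Linear calibration: molecules = energy x `molecules_per_energy_unit`.
#' By convention one unit of expression energy corresponds to 25,000
#' molecules on the cell surface.
#'
#' @param energy Non-negative expression energy.
#' @param params An [adhesion_params()].
#' @return Molecule count (real-valued).
#' @export
molecules_from_energy <- function(energy, params = adhesion_params()) {
  if (any(!is.finite(energy)) || any(energy < 0)) {
    cadh_abort("expression energy must be finite and non-negative",
               "cadhesion_error_energy")
  }
  energy * params$molecules_per_energy_unit
}

#' Total EC1 concentration in one cell-cell contact
#'
#' The contact zone between two apposed spherical cells is modeled as a
#' slab: area = `contact_fraction` x sphere surface (pi d^2), thickness =
#' `contact_thickness`. Of the molecules on one cell surface, a fraction
#' `contact_fraction` lies within the contact and `participation_fraction`
#' of those engage in adhesion; their molarity in the slab volume is the
#' total concentration C_T entering the dimer equilibrium. Note that
#' `contact_fraction` cancels between molecule count and volume, so C_T
#' depends only on surface density, thickness, and participation.
#'
#' @param molecules Molecules on the whole cell surface.
#' @param params An [adhesion_params()].
#' @return List with `c_total` (molar) and `contact_volume` (liters).
#' @export
contact_concentration <- function(molecules, params = adhesion_params()) {
  if (any(!is.finite(molecules)) || any(molecules < 0)) {
    cadh_abort("molecule count must be finite and non-negative",
               "cadhesion_error_energy")
  }
  area_m2 <- params$contact_fraction * pi * params$cell_diameter^2
  volume_l <- area_m2 * params$contact_thickness * 1000  # m^3 -> liters
  participating <- molecules * params$contact_fraction *
    params$participation_fraction
  if (params$count_both_cells) participating <- 2 * participating
  c_total <- participating / (params$avogadro * volume_l)
  list(c_total = c_total, contact_volume = volume_l)
}

#' Monomer/dimer equilibrium of trans-cadherin binding
#'
#' Solves the homophilic dimerization equilibrium
#' K_D = C_M^2 / C_D under conservation C_M + 2 C_D = C_T for the unique
#' non-negative root, using the rationalized quadratic form
#' C_M = 2 C_T / (1 + sqrt(1 + 8 C_T / K_D)), which is numerically stable
#' in the dilute limit.
#'
#' @param c_total Total EC1 concentration C_T, molar.
#' @param kd Homophilic dissociation constant, molar.
#' @return An `adhesion_state` list with `c_total`, `c_monomer`, `c_dimer`.
#' @export
#' @examples
#' st <- solve_dimer_equilibrium(25.8e-6, 25.8e-6)
#' all.equal(st$c_monomer, 25.8e-6 / 2) # C_T = K_D gives C_M = K_D/2
solve_dimer_equilibrium <- function(c_total, kd) {
  if (!is.finite(c_total) || !is.finite(kd) || c_total < 0 || kd <= 0) {
    cadh_abort("c_total must be finite non-negative and kd finite positive",
               "cadhesion_error_equilibrium")
  }
  c_monomer <- 2 * c_total / (1 + sqrt(1 + 8 * c_total / kd))
  c_dimer <- c_monomer^2 / kd
  structure(
    list(c_total = c_total, c_monomer = c_monomer, c_dimer = c_dimer),
    class = "adhesion_state"
  )
}

#' Gibbs free energy of adhesion per trans-dimer
#'
#' Per-dimer free energy released on binding,
#' delta_g = -(R T / N_A) ln(K_D / c0), with c0 the 1 M reference state
#' keeping the logarithm dimensionless. Positive whenever K_D < 1 M; a
#' lower K_D (tighter binding) gives a larger delta_g.
#'
#' @param kd Dissociation constant, molar.
#' @param params An [adhesion_params()].
#' @return Free energy per dimer, calories.
#' @export
free_energy_per_dimer <- function(kd, params = adhesion_params()) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    cadh_abort("kd must be finite and positive", "cadhesion_error_kd")
  }
  -(params$gas_constant * params$temperature / params$avogadro) *
    log(kd / params$kd_reference_state)
}

#' Work of separation between two cells
#'
#' Composes the full model: molecules -> contact concentration ->
#' monomer/dimer equilibrium -> number of trans-dimers in the contact
#' (N = C_D x V x N_A) -> work W = N x delta_g, normalized to the work of
#' the reference configuration (`reference_molecules` of the reference
#' cadherin at `reference_kd`) to give the dimensionless relative adhesion.
#'
#' @param molecules Surface molecule count of the cadherin under study.
#' @param kd Its homophilic dissociation constant, molar.
#' @param params An [adhesion_params()].
#' @param cadherin Label carried through to the result.
#' @return An `adhesion_result` list: `cadherin`, `molecules`, `state`
#'   (with `contact_volume` and `n_dimers`), `delta_g` (cal/dimer),
#'   `work` (cal), `relative_adhesion`.
#' @export
#' @examples
#' adhesion_work(25000, 25.8e-6)$relative_adhesion # 1 by construction
adhesion_work <- function(molecules, kd, params = adhesion_params(),
                          cadherin = NA_character_) {
  work_unnormalized <- function(m, k) {
    cc <- contact_concentration(m, params)
    st <- solve_dimer_equilibrium(cc$c_total, k)
    n_dimers <- st$c_dimer * cc$contact_volume * params$avogadro
    dg <- free_energy_per_dimer(k, params)
    list(state = st, contact_volume = cc$contact_volume,
         n_dimers = n_dimers, delta_g = dg, work = n_dimers * dg)
  }
  w <- work_unnormalized(molecules, kd)
  ref <- work_unnormalized(params$reference_molecules, params$reference_kd)
  if (ref$work <= 0) {
    cadh_abort("reference configuration yields non-positive work; check reference_kd",
               "cadhesion_error_reference")
  }
  structure(
    list(
      cadherin = cadherin,
      molecules = molecules,
      state = c(w$state,
                list(contact_volume = w$contact_volume, n_dimers = w$n_dimers)),
      delta_g = w$delta_g,
      work = w$work,
      relative_adhesion = w$work / ref$work
    ),
    class = "adhesion_result"
  )
}

#' @export
print.adhesion_result <- function(x, ...) {
  cat("<adhesion_result>",
      if (!is.na(x$cadherin)) paste0(" ", x$cadherin) else "", "\n",
      sprintf("  molecules: %.6g  C_T: %.4g M  C_D: %.4g M\n",
              x$molecules, x$state$c_total, x$state$c_dimer),
      sprintf("  n_dimers: %.6g  delta_g: %.4g cal  W: %.4g cal\n",
              x$state$n_dimers, x$delta_g, x$work),
      sprintf("  relative adhesion: %.4g\n", x$relative_adhesion),
      sep = "")
  invisible(x)
}

#' Read a homophilic dissociation-constant table
#'
#' CSV dialect `cadherin,kd_molar,cadherin_type,specificity_group,source`.
#' Values are treated as replaceable inputs with per-row source tags, never
#' as constants of the package. Specificity-group assignments are validated
#' against the canonical type II grouping (A: Cdh6/9/10; B:
#' Cdh7/12/18/20/22; C: Cdh8/11/24).
#'
#' @param path CSV path; defaults to the packaged table, in which only the
#'   Cdh2 entry is anchored to the measured analytical-ultracentrifugation
#'   value (25.8 uM) and all other rows are synthetic placeholders (so
#'   tagged in their `source` field) to be replaced with curated
#'   affinities.
#' @return A tibble with validated columns.
#' @export
read_kd_table <- function(path = system.file("extdata", "kd_table_synthetic.csv",
                                             package = "cadhesion")) {
  if (!file.exists(path)) {
    cadh_abort(paste0("K_D table not found: ", path), "cadhesion_error_parse")
  }
  df <- tibble::as_tibble(read.csv(path, colClasses = c(
    cadherin = "character", kd_molar = "numeric", cadherin_type = "character",
    specificity_group = "character", source = "character"
  ), comment.char = "#"))
  if (any(!is.finite(df$kd_molar) | df$kd_molar <= 0)) {
    cadh_abort("kd_molar must be positive", "cadhesion_error_kd")
  }
  if (anyDuplicated(df$cadherin)) {
    cadh_abort("duplicate cadherin in K_D table", "cadhesion_error_duplicate_key")
  }
  groups <- list(A = c("Cdh6", "Cdh9", "Cdh10"),
                 B = c("Cdh7", "Cdh12", "Cdh18", "Cdh20", "Cdh22"),
                 C = c("Cdh8", "Cdh11", "Cdh24"))
  for (gname in names(groups)) {
    bad <- df$cadherin[df$specificity_group == gname &
                         !df$cadherin %in% groups[[gname]]]
    if (length(bad) > 0L) {
      cadh_abort(paste0("specificity group ", gname,
                        " wrongly assigned to: ", paste(bad, collapse = ", ")),
                 "cadhesion_error_kd")
    }
  }
  df
}

#' Relative adhesion for every (cadherin, structure) pair
#'
#' Runs the adhesion model over a gene-by-structure energy matrix: each
#' non-missing energy is converted to molecules and to a work of
#' separation using that cadherin's homophilic K_D. Genes absent from the
#' K_D table are skipped with a warning.
#'
#' @param matrix Gene-by-structure energy matrix (see
#'   [expression_matrix()]).
#' @param kd_table Tibble from [read_kd_table()].
#' @param params An [adhesion_params()].
#' @return A tibble with one row per (cadherin, structure): energy,
#'   molecules, c_total, c_monomer, c_dimer, n_dimers, delta_g_cal,
#'   work_cal, relative_adhesion, in deterministic (gene, structure) order.
#' @export
adhesion_profile <- function(matrix, kd_table = read_kd_table(),
                             params = adhesion_params()) {
  genes <- intersect(rownames(matrix), kd_table$cadherin)
  skipped <- setdiff(rownames(matrix), kd_table$cadherin)
  if (length(genes) == 0L) {
    cadh_abort("no gene in the matrix has a K_D entry",
               "cadhesion_error_reference")
  }
  if (length(skipped) > 0L) {
    rlang::warn(paste0("skipping genes without K_D entry: ",
                       paste(skipped, collapse = ", ")))
  }
  kd <- setNames(kd_table$kd_molar, kd_table$cadherin)
  rows <- list()
  for (g in sort(genes)) {
    for (s in sort(colnames(matrix))) {
      e <- matrix[g, s]
      if (is.na(e)) next
      res <- adhesion_work(molecules_from_energy(e, params), kd[[g]],
                           params, cadherin = g)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cadherin = g, structure_id = s, energy = e,
        molecules = res$molecules,
        c_total = res$state$c_total, c_monomer = res$state$c_monomer,
        c_dimer = res$state$c_dimer, n_dimers = res$state$n_dimers,
        delta_g_cal = res$delta_g, work_cal = res$work,
        relative_adhesion = res$relative_adhesion
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Fold changes of adhesion between adjacent segments
#'
#' Given a per-segment relative-adhesion (or expression) profile ordered
#' anterior-to-posterior, computes the symmetric fold change
#' max(a, b)/min(a, b) across each adjacent boundary and flags boundaries
#' at or above the threshold. A boundary with one zero side has infinite
#' fold (flagged); two zero sides give fold 1.
#'
#' @param values Numeric profile ordered by `ap_index` (length >= 2).
#' @param labels Optional segment labels (length of `values`).
#' @param threshold Flagging threshold, default 4 (the fold difference
#'   observed between adjacent neuromeres for several cadherins).
#' @return Tibble with `boundary`, `anterior`, `posterior`, `fold`,
#'   `flagged`.
#' @export
#' @examples
#' adjacent_fold_changes(c(1, 4, 4))
adjacent_fold_changes <- function(values, labels = NULL, threshold = 4.0) {
  if (length(values) < 2L) {
    cadh_abort("need at least two segments to form a boundary",
               "cadhesion_error_profile")
  }
  if (any(values < 0, na.rm = TRUE)) {
    cadh_abort("adhesion profile values must be non-negative",
               "cadhesion_error_profile")
  }
  if (is.null(labels)) labels <- as.character(seq_along(values))
  a <- values[-length(values)]
  b <- values[-1]
  fold <- ifelse(a == 0 & b == 0, 1, pmax(a, b) / pmin(a, b))
  tibble::tibble(
    boundary = paste0(labels[-length(labels)], "|", labels[-1]),
    anterior = a, posterior = b,
    fold = fold,
    flagged = fold >= threshold
  )
}
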