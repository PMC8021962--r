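# Independent oracles and tiny fixture builders shared across tests.

# Bisection root of the conservation residual f(cm) = 2 cm^2 / kd + cm - ct
# on [0, ct]; independent of the closed-form solver under test.
bisect_equilibrium <- function(c_total, kd, iter = 200L) {
  if (c_total == 0) return(list(c_monomer = 0, c_dimer = 0))
  f <- function(cm) 2 * cm^2 / kd + cm - c_total
  lo <- 0
  hi <- c_total
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  cm <- (lo + hi) / 2
  list(c_monomer = cm, c_dimer = cm^2 / kd)
}

# 95% Fisher-z interval around a target correlation at sample size n.
fisher_z_interval <- function(r, n) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  tanh(c(z - 1.96 * se, z + 1.96 * se))
}

# Minimal two-level graph: one root plus level-3 segments in given order.
tiny_graph <- function(acronyms = c("a", "b", "c")) {
  structure_graph(tibble::tibble(
    id = c("root", acronyms),
    acronym = c("CNS", acronyms),
    name = c("root", acronyms),
    level = c(1L, rep(3L, length(acronyms))),
    parent_id = c(NA, rep("root", length(acronyms))),
    ap_index = c(NA, seq_along(acronyms)),
    plate = "none", stratum = "none", division = "none",
    area = NA_character_, layer = NA_character_
  ))
}

# Expression records for one gene/age over given structures and energies.
records_for <- function(gene, structure_ids, energies, age = "P56") {
  tibble::tibble(
    gene = gene, structure_id = structure_ids, age = age,
    energy = energies, density = NA_real_, intensity = NA_real_,
    experiment_id = NA_character_
  )
}
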