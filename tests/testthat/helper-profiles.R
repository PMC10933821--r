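# Programmatic fixtures: small exactly-additive profiles.

# Two atoms, three points, complete V_cl/V_xc partition, stored E_tot equal
# to the term sum by construction.
toy_terms <- function(m = 3) {
  rows <- lapply(seq_len(m), function(p) {
    e <- c(
      e_a1 = -1.0 - 0.10 * p,
      e_b2 = -2.0 + 0.05 * p,
      vcl = -0.50 + 0.02 * p,
      vxc = -0.10 - 0.01 * p
    )
    tibble::tibble(
      point_index = p, s = p / 10,
      term_type = c("E_intra", "E_intra", "V_cl", "V_xc", "E_tot"),
      atom_a = c("a1", "b2", "a1", "a1", NA),
      atom_b = c(NA, NA, "b2", "b2", NA),
      energy = c(e, sum(e))
    )
  })
  dplyr::bind_rows(rows)
}

toy_profile <- function(m = 3) energy_profile(toy_terms(m), system = "toy")

# Profile whose non-total terms are exact affine images of E_tot, for
# closed-form REG checks: term i has slope slopes[i] and offset offsets[i].
affine_profile <- function(slopes, offsets = rep(0, length(slopes)),
                           e_tot = c(0.02, 0.012, 0.006, 0.001)) {
  stopifnot(length(slopes) == length(offsets))
  atoms <- paste0(rep_len(c("a", "b", "c", "d"), length(slopes)),
                  seq_along(slopes))
  m <- length(e_tot)
  rows <- lapply(seq_len(m), function(p) {
    tibble::tibble(
      point_index = p, s = p,
      term_type = c(rep("E_intra", length(slopes)), "E_tot"),
      atom_a = c(atoms, NA), atom_b = NA_character_,
      energy = c(slopes * e_tot[p] + offsets, e_tot[p])
    )
  })
  energy_profile(dplyr::bind_rows(rows), system = "affine")
}

# Write a profile (and atoms table, if present) to temp files; returns paths.
write_temp_profile <- function(profile) {
  path <- tempfile(fileext = ".csv")
  atoms_path <- if (is.null(profile_atoms(profile))) NULL
                else tempfile(fileext = ".csv")
  write_profile(profile, path, atoms_path = atoms_path)
  list(terms = path, atoms = atoms_path)
}

# Core columns of a profile, free of metadata attributes, for equality
# comparisons across construction routes.
profile_data <- function(profile) {
  tibble::as_tibble(as.data.frame(profile)[, c("point_index", "s",
                                               "term_type", "atom_a",
                                               "atom_b", "energy")])
}

# Canonical rendering of a term label written in any participant order.
canon_term <- function(x) {
  p <- parse_term(x)
  term_label(p$term_type, p$atom_a, p$atom_b)
}

extdata <- function(name) {
  system.file("extdata", name, package = "regiqa", mustWork = TRUE)
}
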