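# Seeded synthetic energy profiles with known ground truth. The generator
# emulates the statistical structure a REG analysis relies on — an additive
# partition whose terms sum exactly to the total at every point, a
# monotone barrier-shaped total-energy segment (transition state first,
# low-energy conformer last), prescribed regression slopes summing to 1,
# per-term offsets (to exercise translation invariance) and per-term noise
# projected so the partition stays exact. It does not emulate wavefunction
# physics: magnitudes are realistic, couplings between terms are not.

#' Generate a synthetic energy profile with known REG structure
#'
#' Builds a complete IQA-like term set (`E_intra` per atom; `V_cl`, `V_xc`,
#' `V_D3` per pair) where each term follows
#' `slope_i * E_shape(s) + offset_i + noise`, with noise mean-projected per
#' point so that the terms sum exactly to the stored `E_tot`, and offsets
#' summing to zero. Regenerating with the same seed is bit-identical
#' (Mersenne-Twister, inversion normals).
#'
#' @param n_atoms Number of atoms (>= 2).
#' @param m_points Number of PES points (>= 3).
#' @param shape Total-energy profile shape over the segment: `"barrier"`
#'   (quadratic in s, monotone from the barrier top at the first point to
#'   the minimum at the last) or `"linear"`; or supply `e_tot` directly.
#' @param amplitude Barrier height in hartree.
#' @param e_tot Optional explicit total-energy samples (length `m_points`).
#' @param true_slopes Optional named vector of ground-truth slopes (names
#'   are term labels); must cover every term and sum to 1 within 1e-12.
#'   Default: seeded draws shifted to sum to exactly 1.
#' @param noise_sigma Per-term noise standard deviation in hartree.
#' @param seed Integer seed; all randomness derives from it.
#' @param with_atoms Attach per-point charges and jittered chain
#'   coordinates (needed for the charge-transfer split).
#' @return A list with elements `profile` (an [energy_profile()]) and
#'   `truth` (slopes, offsets, the noiseless shape, the stored totals).
#' @export
synthetic_profile <- function(n_atoms = 6, m_points = 15,
                              shape = c("barrier", "linear"),
                              amplitude = 0.02, e_tot = NULL,
                              true_slopes = NULL, noise_sigma = 0,
                              seed = 1, with_atoms = TRUE) {
  shape <- match.arg(shape)
  if (n_atoms < 2) stop_precondition("n_atoms must be >= 2.")
  if (m_points < 3) stop_precondition("m_points must be >= 3.")
  if (noise_sigma < 0) stop_precondition("noise_sigma must be >= 0.")

  atoms <- synthetic_atom_labels(n_atoms)
  keys <- synthetic_term_keys(atoms)
  k <- nrow(keys)
  s <- seq(0, 1, length.out = m_points)
  if (is.null(e_tot)) {
    e_shape <- switch(shape,
                      barrier = amplitude * (1 - s^2),
                      linear = amplitude * (1 - s))
  } else {
    if (length(e_tot) != m_points) {
      stop_precondition("e_tot must have length m_points.")
    }
    e_shape <- as.numeric(e_tot)
  }

  with_seed(seed, {
    if (is.null(true_slopes)) {
      raw <- rnorm(k, sd = 0.5)
      slopes <- raw - (sum(raw) - 1) / k
    } else {
      if (!setequal(names(true_slopes), keys$term)) {
        stop_precondition("true_slopes must name exactly the full term set.")
      }
      slopes <- unname(true_slopes[keys$term])
      if (abs(sum(slopes) - 1) > 1e-12) {
        stop_precondition(sprintf(
          "true_slopes must sum to 1 (got %.15g).", sum(slopes)))
      }
    }
    offsets <- rnorm(k, sd = 0.05)
    offsets <- offsets - mean(offsets)

    term_mat <- outer(e_shape, slopes) +
      matrix(offsets, m_points, k, byrow = TRUE)
    if (noise_sigma > 0) {
      eps <- matrix(rnorm(m_points * k, sd = noise_sigma), m_points, k)
      eps <- eps - rowMeans(eps) # partition stays exact
      term_mat <- term_mat + eps
    }
    stored_tot <- rowSums(term_mat)

    atoms_tbl <- if (with_atoms) synthetic_atoms(atoms, m_points) else NULL
  })

  terms <- tibble(
    point_index = rep(seq_len(m_points), each = k),
    s = rep(s, each = k),
    term_type = rep(keys$term_type, m_points),
    atom_a = rep(keys$atom_a, m_points),
    atom_b = rep(keys$atom_b, m_points),
    energy = as.vector(t(term_mat))
  )
  totals <- tibble(point_index = seq_len(m_points), s = s,
                   term_type = "E_tot", atom_a = NA_character_,
                   atom_b = NA_character_, energy = stored_tot)
  profile <- energy_profile(dplyr::bind_rows(terms, totals),
                            atoms = atoms_tbl,
                            system = paste0("synthetic-", seed),
                            segment = "TS (first point) to minimum (last)")
  truth <- list(n_atoms = n_atoms, m_points = m_points, shape = shape,
                amplitude = amplitude, noise_sigma = noise_sigma,
                seed = seed,
                slopes = setNames(slopes, keys$term),
                offsets = setNames(offsets, keys$term),
                e_shape = e_shape, e_tot = stored_tot)
  list(profile = profile, truth = truth)
}

synthetic_atom_labels <- function(n_atoms) {
  paste0(rep_len(c("c", "n", "o", "h"), n_atoms), seq_len(n_atoms))
}

synthetic_term_keys <- function(atoms) {
  intra <- tibble(term_type = "E_intra", atom_a = atoms,
                  atom_b = NA_character_)
  if (length(atoms) > 1) {
    idx <- utils::combn(length(atoms), 2)
    pairs <- tibble(atom_a = atoms[idx[1, ]], atom_b = atoms[idx[2, ]])
    inter <- dplyr::bind_rows(
      dplyr::mutate(pairs, term_type = "V_cl"),
      dplyr::mutate(pairs, term_type = "V_xc"),
      dplyr::mutate(pairs, term_type = "V_D3")
    )[, c("term_type", "atom_a", "atom_b")]
    keys <- dplyr::bind_rows(intra, inter)
  } else {
    keys <- intra
  }
  keys <- canonicalise_pairs(keys)
  keys$term <- with(keys, term_label(term_type, atom_a, atom_b))
  keys
}

# Jittered chain geometry with per-point charges summing to ~0.
synthetic_atoms <- function(atoms, m_points) {
  n <- length(atoms)
  base_q <- runif(n, -0.8, 0.8)
  base_q <- base_q - mean(base_q)
  base_x <- 2.8 * seq_len(n)
  purrr::map_dfr(seq_len(m_points), function(p) {
    tibble(point_index = p, atom = atoms,
           q = base_q + rnorm(n, sd = 0.005),
           x = base_x + rnorm(n, sd = 0.05),
           y = rnorm(n, sd = 0.3),
           z = rnorm(n, sd = 0.3))
  })
}

#' Generate a molecular-balance-like synthetic system
#'
#' A 12-atom profile shaped like the closing segment of a conformational
#' balance: one dominant positive electrostatic pair term (the amide-bond
#' analogue, `V_cl(n1,c4)`), one dominant negative intra-atomic term (the
#' nitrogen de-pyramidalisation analogue, `E_intra(n1)`), and two
#' counterbalancing carbonyl-like pair terms (`V_cl(o5,c22)` positive,
#' `V_cl(c4,c22)` negative). Comes with a fragment scheme containing
#' singleton groups (`A`, `B`) and multi-atom groups (`E`, `F`) so
#' fragment-level analyses and ratio reports can be exercised end to end.
#'
#' @param seed Integer seed.
#' @param m_points PES points.
#' @param noise_sigma Per-term noise standard deviation in hartree.
#' @return A list with `profile`, `scheme` (a [fragment_scheme()]) and
#'   `truth`.
#' @export
synthetic_balance <- function(seed = 1, m_points = 15, noise_sigma = 0) {
  atoms <- c("n1", "c2", "c3", "c4", "o5", "h6", "h7", "c8",
             "c22", "o23", "h24", "h25")
  # the generator works in its own label space; map the designated
  # balance-like terms into it, then relabel the finished profile
  default_atoms <- synthetic_atom_labels(length(atoms))
  to_default <- setNames(default_atoms, atoms)
  keys <- synthetic_term_keys(default_atoms)
  designated <- c("V_cl(n1,c4)" = 4.0, "E_intra(n1)" = -2.5,
                  "V_cl(o5,c22)" = 0.7, "V_cl(c4,c22)" = -0.7)
  p <- parse_term(names(designated))
  designated_balance <- setNames(designated,
                                 term_label(p$term_type, p$atom_a, p$atom_b))
  dd <- canonicalise_pairs(tibble(
    term_type = p$term_type,
    atom_a = unname(to_default[p$atom_a]),
    atom_b = unname(to_default[p$atom_b])
  ))
  names(designated) <- term_label(dd$term_type, dd$atom_a, dd$atom_b)
  slopes <- with_seed(seed + 1L, {
    sl <- rnorm(nrow(keys), sd = 0.03)
    names(sl) <- keys$term
    sl[names(designated)] <- designated
    free <- setdiff(keys$term, names(designated))
    sl[free] <- sl[free] + (1 - sum(sl)) / length(free)
    sl
  })
  gen <- synthetic_profile(n_atoms = 12, m_points = m_points,
                           shape = "barrier", amplitude = 0.02,
                           true_slopes = slopes, noise_sigma = noise_sigma,
                           seed = seed, with_atoms = TRUE)
  prof <- relabel_atoms(gen$profile, atoms)
  scheme <- fragment_scheme(list(A = "o5", B = "c22",
                                 E = c("n1", "c3", "c4"),
                                 F = c("o23", "h24", "h25")),
                            profile = prof)
  truth <- gen$truth
  truth$designated <- designated_balance
  list(profile = prof, scheme = scheme, truth = truth)
}

# Replace the generator's default atom labels by a custom set, preserving
# order of first appearance.
relabel_atoms <- function(profile, new_labels) {
  old <- synthetic_atom_labels(length(new_labels))
  map <- setNames(new_labels, old)
  swap <- function(x) ifelse(is.na(x), x, unname(map[x]))
  terms <- dplyr::mutate(as_tibble(profile),
                         atom_a = swap(.data$atom_a),
                         atom_b = swap(.data$atom_b))
  atoms <- profile_atoms(profile)
  if (!is.null(atoms)) atoms <- dplyr::mutate(atoms, atom = swap(.data$atom))
  energy_profile(terms, atoms = atoms, system = attr(profile, "system"),
                 segment = attr(profile, "segment"))
}
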