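# IQA energy algebra: totals from the additive partition, composition of
# the interatomic energy, the monopolar charge-transfer/polarisation split
# of the classical term, and aggregation of atomic terms into fragments.

#' Total energy from the additive partition
#'
#' Sums all intra-atomic terms and all unordered-pair interatomic terms at
#' each PES point. Pairs are stored once, so the 1/2 double-counting factor
#' of the ordered-pair formulation is implicit. When explicit `V_inter`
#' rows are present they are used; otherwise the interatomic energy is
#' taken as `V_cl + V_xc + V_D3` (dispersion defaulting to zero).
#'
#' @param profile An [energy_profile()].
#' @param point Optional single `point_index`; when given, returns the
#'   scalar total at that point.
#' @return A tibble `point_index`, `s`, `e_tot` (hartree), or a scalar.
#' @export
total_energy <- function(profile, point = NULL) {
  intra <- profile[profile$term_type == "E_intra", ]
  if (nrow(intra) == 0) {
    stop_schema("Profile has no E_intra terms; cannot reconstruct E_tot.")
  }
  have <- unique(profile$term_type)
  if ("V_inter" %in% have) {
    inter <- profile[profile$term_type == "V_inter", ]
  } else {
    inter <- profile[profile$term_type %in% c("V_cl", "V_xc", "V_D3"), ]
  }
  contrib <- dplyr::bind_rows(intra, inter)
  out <- dplyr::summarise(dplyr::group_by(contrib, .data$point_index),
                          e_tot = sum(.data$energy), .groups = "drop")
  out <- dplyr::left_join(profile_points(profile), out, by = "point_index")
  if (is.null(point)) return(out)
  if (!point %in% out$point_index) {
    stop_precondition(paste0("No point with index ", point, " in profile."))
  }
  out$e_tot[out$point_index == point]
}

#' Compose the interatomic energy from its components
#'
#' `V_inter = V_cl + V_xc + V_D3`, with the dispersion term optional.
#' When raw components are supplied, the classical and exchange-correlation
#' identities (`V_cl = Vnn + Ven + Vne + Vcoul`, `V_xc = Vx + Vc`) are
#' cross-checked and a residual above `tolerance` raises a consistency
#' error.
#'
#' @param v_cl,v_xc Classical and exchange-correlation energies (hartree).
#' @param v_d3 Pairwise dispersion energy; defaults to 0.
#' @param raw Optional named list with elements among `v_nn`, `v_en`,
#'   `v_ne`, `v_coul`, `v_x`, `v_c` (hartree).
#' @param tolerance Consistency tolerance in hartree.
#' @return `v_cl + v_xc + v_d3`.
#' @export
compose_inter <- function(v_cl, v_xc, v_d3 = 0, raw = NULL,
                          tolerance = 1e-8) {
  if (!is.null(raw)) {
    cl_parts <- c("v_nn", "v_en", "v_ne", "v_coul")
    if (all(cl_parts %in% names(raw))) {
      res <- v_cl - (raw$v_nn + raw$v_en + raw$v_ne + raw$v_coul)
      if (any(abs(res) > tolerance)) {
        stop_inconsistency(sprintf(
          "V_cl does not match Vnn+Ven+Vne+Vcoul (max residual %.3e hartree).",
          max(abs(res))), residual = max(abs(res)))
      }
    }
    if (all(c("v_x", "v_c") %in% names(raw))) {
      res <- v_xc - (raw$v_x + raw$v_c)
      if (any(abs(res) > tolerance)) {
        stop_inconsistency(sprintf(
          "V_xc does not match Vx+Vc (max residual %.3e hartree).",
          max(abs(res))), residual = max(abs(res)))
      }
    }
  }
  v_cl + v_xc + v_d3
}

#' Charge-transfer / polarisation split of the classical term
#'
#' The monopolar charge-transfer part is `V_ct = q_A * q_B / r_AB` (atomic
#' units); the polarisation part is defined as the remainder
#' `V_pl = V_cl - V_ct`, so the split restores `V_cl` exactly.
#'
#' @param v_cl Classical electrostatic energy (hartree); vectorised.
#' @param q_a,q_b Atomic charges (e).
#' @param r_ab Internuclear distance (bohr), strictly positive.
#' @return Tibble with columns `v_ct`, `v_pl`, `v_cl`.
#' @export
ct_pl_split <- function(v_cl, q_a, q_b, r_ab) {
  if (any(!is.finite(r_ab)) || any(r_ab <= 0)) {
    stop_precondition("r_ab must be a positive finite distance in bohr.")
  }
  v_ct <- q_a * q_b / r_ab
  tibble(v_ct = v_ct, v_pl = v_cl - v_ct, v_cl = v_cl)
}

#' Add charge-transfer and polarisation terms to a profile
#'
#' For every `V_cl` pair term, computes `V_ct` from the per-point charges
#' and internuclear distances in the profile's atoms table and appends
#' `V_ct` and `V_pl` rows. Requires the atoms table.
#'
#' @param profile An [energy_profile()] with an atoms table.
#' @return A new `energy_profile` including `V_ct` and `V_pl` terms.
#' @export
add_ct_pl <- function(profile) {
  atoms <- profile_atoms(profile)
  if (is.null(atoms)) {
    stop_precondition("Profile has no atoms table; charges and coordinates are needed for the charge-transfer split.")
  }
  vcl <- profile[profile$term_type == "V_cl" & !is.na(profile$atom_b), ]
  if (nrow(vcl) == 0) {
    stop_precondition("Profile has no V_cl pair terms to split.")
  }
  a <- dplyr::select(atoms, "point_index", atom_a = "atom",
                     q_a = "q", xa = "x", ya = "y", za = "z")
  b <- dplyr::select(atoms, "point_index", atom_b = "atom",
                     q_b = "q", xb = "x", yb = "y", zb = "z")
  j <- dplyr::inner_join(vcl, a, by = c("point_index", "atom_a"))
  j <- dplyr::inner_join(j, b, by = c("point_index", "atom_b"))
  r <- sqrt((j$xa - j$xb)^2 + (j$ya - j$yb)^2 + (j$za - j$zb)^2)
  split <- ct_pl_split(j$energy, j$q_a, j$q_b, r)
  new_rows <- dplyr::bind_rows(
    dplyr::mutate(j[, names(profile)], term_type = "V_ct",
                  energy = split$v_ct),
    dplyr::mutate(j[, names(profile)], term_type = "V_pl",
                  energy = split$v_pl)
  )
  energy_profile(dplyr::bind_rows(as_tibble(profile), new_rows),
                 atoms = atoms, system = attr(profile, "system"),
                 segment = attr(profile, "segment"))
}

#' Aggregate atomic pair terms into fragment-pair terms
#'
#' For every unordered pair of groups and every interatomic term type
#' present, the fragment term at each point is the sum of the member
#' pairwise terms with one atom in each group. Within-group pair terms and
#' intra-atomic terms are excluded from the between-group energies. `E_tot`
#' rows are carried through so the result can feed the REG engine directly.
#'
#' @param profile An [energy_profile()].
#' @param scheme A [fragment_scheme()] (validated against the profile).
#' @param term_types Interatomic term types to aggregate; defaults to every
#'   pair type present.
#' @return An `energy_profile` whose participants are group names.
#' @export
aggregate_fragments <- function(profile, scheme, term_types = NULL) {
  scheme <- fragment_scheme(unclass(scheme), profile = profile)
  pair_types <- setdiff(intersect(unique(profile$term_type), TYPES_INTER),
                        character(0))
  if (is.null(term_types)) term_types <- pair_types
  unknown <- setdiff(term_types, pair_types)
  if (length(unknown) > 0) {
    stop_precondition(paste0("Term type(s) not present as pair terms: ",
                             paste(unknown, collapse = ", ")))
  }
  atom_group <- setNames(rep(names(scheme), lengths(scheme)),
                         unlist(scheme, use.names = FALSE))
  pairs <- profile[profile$term_type %in% term_types &
                     !is.na(profile$atom_b), ]
  ga <- atom_group[pairs$atom_a]
  gb <- atom_group[pairs$atom_b]
  keep <- !is.na(ga) & !is.na(gb) & ga != gb
  frag <- tibble(point_index = pairs$point_index[keep], s = pairs$s[keep],
                 term_type = pairs$term_type[keep],
                 atom_a = pmin(ga[keep], gb[keep]),
                 atom_b = pmax(ga[keep], gb[keep]),
                 energy = pairs$energy[keep])
  frag <- dplyr::summarise(
    dplyr::group_by(frag, .data$point_index, .data$s, .data$term_type,
                    .data$atom_a, .data$atom_b),
    energy = sum(.data$energy), .groups = "drop")
  if (nrow(frag) == 0) {
    stop_precondition("No between-group pair terms found for this scheme.")
  }
  e_tot <- profile[profile$term_type == "E_tot", ]
  energy_profile(dplyr::bind_rows(frag, as_tibble(e_tot)),
                 system = attr(profile, "system"),
                 segment = attr(profile, "segment"))
}
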