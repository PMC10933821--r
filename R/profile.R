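# An energy profile is a long tibble with one row per (PES point, term):
#   point_index  integer, 1-based position along the control coordinate
#   s            numeric control-coordinate value, strictly monotonic
#   term_type    one of the recognised IQA term types
#   atom_a/atom_b participant labels (NA where the arity is lower)
#   energy       term value in hartree
# plus attributes: `atoms` (optional per-point charge/coordinate tibble),
# `system` (name) and `segment` (free-text description).

#' Construct a validated energy profile
#'
#' Assembles per-geometry IQA energy terms into an `energy_profile`: a
#' tibble (one row per PES point per term) carrying optional per-point
#' atomic charges and coordinates. Pair participants are put in canonical
#' order, term types are normalised, and the completeness invariant (every
#' term present at every point) is enforced.
#'
#' @param terms Data frame with columns `point_index`, `s`, `term_type`,
#'   `atom_a`, `atom_b`, `energy` (hartree). `atom_b` is `NA` for
#'   intra-atomic terms, both labels `NA` for `E_tot` rows.
#' @param atoms Optional data frame with columns `point_index`, `atom`,
#'   `q` (e), `x`, `y`, `z` (bohr) covering every atom named in `terms`.
#' @param system,segment Metadata strings.
#' @return An `energy_profile` tibble.
#' @seealso [read_profile()], [validate_profile()], [reg_values()]
#' @export
energy_profile <- function(terms, atoms = NULL, system = "system",
                           segment = NULL) {
  terms <- as_tibble(terms)
  required <- c("point_index", "s", "term_type", "atom_a", "atom_b", "energy")
  missing_cols <- setdiff(required, names(terms))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("Term table is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (nrow(terms) == 0) {
    stop_schema("Term table has no rows; a profile needs at least one point.")
  }
  terms <- dplyr::mutate(
    terms,
    point_index = as.integer(.data$point_index),
    s = as.numeric(.data$s),
    term_type = normalise_term_type(.data$term_type),
    atom_a = normalise_label(as.character(.data$atom_a)),
    atom_b = normalise_label(as.character(.data$atom_b)),
    energy = as.numeric(.data$energy)
  )
  check_arity(terms)
  terms <- canonicalise_pairs(terms)

  key <- with(terms, term_label(term_type, atom_a, atom_b))
  dup <- duplicated(paste(terms$point_index, key))
  if (any(dup)) {
    stop_schema(paste0("Duplicate (point, term) rows: ",
                       paste(unique(paste0(key[dup], " at point ",
                                           terms$point_index[dup])),
                             collapse = "; ")))
  }

  pts <- dplyr::distinct(terms, .data$point_index, .data$s)
  if (anyDuplicated(pts$point_index) > 0) {
    stop_schema("A point_index maps to more than one control-coordinate value.")
  }
  pts <- dplyr::arrange(pts, .data$point_index)
  ds <- diff(pts$s)
  if (length(ds) > 0 && !(all(ds > 0) || all(ds < 0))) {
    stop_schema("Control coordinate s must be strictly monotonic over points.")
  }

  # Completeness: every term key at every point.
  counts <- table(key)
  m <- nrow(pts)
  incomplete <- names(counts)[counts != m]
  if (length(incomplete) > 0) {
    missing_at <- vapply(incomplete, function(k) {
      pt <- setdiff(pts$point_index, terms$point_index[key == k])
      paste0(k, " missing at point(s) ", paste(pt, collapse = ","))
    }, "")
    stop_schema(paste0("Term(s) absent at some points: ",
                       paste(missing_at, collapse = "; ")))
  }

  terms <- dplyr::arrange(terms, .data$point_index,
                          .data$term_type, label_sort_key(.data$atom_a),
                          label_sort_key(.data$atom_b))

  if (!is.null(atoms)) {
    atoms <- as_tibble(atoms)
    need <- c("point_index", "atom", "q", "x", "y", "z")
    miss <- setdiff(need, names(atoms))
    if (length(miss) > 0) {
      stop_schema(paste0("Atom table is missing column(s): ",
                         paste(miss, collapse = ", ")))
    }
    atoms <- dplyr::mutate(atoms,
                           point_index = as.integer(.data$point_index),
                           atom = normalise_label(as.character(.data$atom)))
    prof_atoms <- profile_atom_labels(terms)
    for (p in pts$point_index) {
      here <- atoms$atom[atoms$point_index == p]
      uncovered <- setdiff(prof_atoms, here)
      if (length(uncovered) > 0) {
        stop_schema(paste0("Atom table does not cover atom(s) ",
                           paste(uncovered, collapse = ", "),
                           " at point ", p))
      }
    }
  }

  structure(terms,
            atoms = atoms, system = system, segment = segment,
            class = c("energy_profile", class(tibble())))
}

# Atom labels (not fragment names) appearing in any term key.
profile_atom_labels <- function(terms) {
  labs <- unique(c(terms$atom_a, terms$atom_b))
  labs <- labs[!is.na(labs)]
  sort(labs[is_atom_label(labs)])
}

#' @export
print.energy_profile <- function(x, ...) {
  pts <- profile_points(x)
  cat(sprintf("<energy_profile: %s | %d points, %d terms%s>\n",
              attr(x, "system") %||% "unnamed", nrow(pts),
              nrow(profile_term_keys(x)),
              if (is.null(attr(x, "atoms"))) "" else ", with atoms table"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Profile accessors
#'
#' @param profile An `energy_profile`.
#' @return `profile_points()`: tibble of `point_index`, `s`;
#'   `profile_term_keys()`: tibble of distinct term keys with a `term`
#'   label column; `profile_atoms()`: the atoms tibble or `NULL`;
#'   `n_points()`: integer.
#' @export
profile_points <- function(profile) {
  dplyr::arrange(dplyr::distinct(profile, .data$point_index, .data$s),
                 .data$point_index)
}

#' @rdname profile_points
#' @export
profile_term_keys <- function(profile) {
  keys <- dplyr::distinct(profile, .data$term_type, .data$atom_a, .data$atom_b)
  keys$term <- with(keys, term_label(term_type, atom_a, atom_b))
  keys
}

#' @rdname profile_points
#' @export
profile_atoms <- function(profile) attr(profile, "atoms")

#' @rdname profile_points
#' @export
n_points <- function(profile) nrow(profile_points(profile))

# Wide matrix of term series: rows = points in order, columns = term labels.
profile_matrix <- function(profile, include_total = TRUE) {
  key <- with(profile, term_label(term_type, atom_a, atom_b))
  keep <- if (include_total) rep(TRUE, nrow(profile)) else profile$term_type != "E_tot"
  df <- tibble(point_index = profile$point_index[keep],
               term = key[keep], energy = profile$energy[keep])
  wide <- tidyr::pivot_wider(df, names_from = "term", values_from = "energy")
  wide <- dplyr::arrange(wide, .data$point_index)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$point_index
  m
}

# Restrict a profile to a set of point indices (segment), keeping attributes.
profile_subset <- function(profile, points) {
  keep <- profile$point_index %in% points
  atoms <- profile_atoms(profile)
  if (!is.null(atoms)) atoms <- atoms[atoms$point_index %in% points, ]
  energy_profile(profile[keep, ], atoms = atoms,
                 system = attr(profile, "system"),
                 segment = attr(profile, "segment"))
}
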