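# CSV interchange schema
# ----------------------
# Term table: header `point_index,s,term_type,atom_a,atom_b,energy_hartree`;
# `atom_b` empty for intra-atomic terms, both atom columns empty for E_tot.
# Atom table: header `point_index,atom,q,x,y,z` (charge in e, bohr coords).
# Fragment scheme: YAML mapping group name -> list of atom labels.
# Energies are written as decimal text with 15 significant digits so a
# written profile re-reads bit-identically.

#' Read an energy profile from the CSV interchange format
#'
#' @param path Path to the term-table CSV.
#' @param atoms_path Optional path to the companion atoms CSV.
#' @param system Name recorded in the profile metadata; defaults to the
#'   file name.
#' @param quiet Suppress the once-per-file note emitted when a profile has
#'   classical/exchange-correlation pair terms but no dispersion (`V_D3`)
#'   rows; absent dispersion is treated as zero for every pair.
#' @return An [energy_profile()].
#' @export
read_profile <- function(path, atoms_path = NULL, system = NULL,
                         quiet = FALSE) {
  if (!file.exists(path)) stop_schema(paste0("No such file: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("point_index", "s", "term_type", "atom_a", "atom_b",
                "energy_hartree")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("Profile file ", path, " is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  terms <- tibble(
    point_index = as.integer(raw$point_index),
    s = as.numeric(raw$s),
    term_type = raw$term_type,
    atom_a = raw$atom_a,
    atom_b = raw$atom_b,
    energy = as.numeric(raw$energy_hartree)
  )
  atoms <- NULL
  if (!is.null(atoms_path)) {
    if (!file.exists(atoms_path)) {
      stop_schema(paste0("No such file: ", atoms_path))
    }
    atoms <- readr::read_csv(atoms_path, show_col_types = FALSE,
                             col_types = "icdddd")
  }
  prof <- energy_profile(terms, atoms = atoms,
                         system = system %||% basename(path))
  if (!quiet) {
    tt <- unique(prof$term_type)
    if (any(c("V_cl", "V_xc") %in% tt) && !("V_D3" %in% tt)) {
      inform(paste0("Profile ", basename(path), " has no V_D3 rows; ",
                    "dispersion is taken as 0 for every pair."),
             class = "regiqa_no_dispersion")
    }
  }
  prof
}

#' Write an energy profile in the CSV interchange format
#'
#' Energies are serialised with 17 significant digits so that
#' `read_profile(write_profile(p))` reproduces `p` bit-identically.
#'
#' @param profile An [energy_profile()].
#' @param path Output path for the term table.
#' @param atoms_path Output path for the atoms table; required when the
#'   profile carries charges/coordinates.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path, atoms_path = NULL) {
  if (!inherits(profile, "energy_profile")) {
    stop_schema("write_profile() needs an energy_profile.")
  }
  if (n_points(profile) == 0 || nrow(profile) == 0) {
    stop_schema("Refusing to write an empty profile.")
  }
  out <- tibble(
    point_index = profile$point_index,
    s = format_num(profile$s),
    term_type = profile$term_type,
    atom_a = ifelse(is.na(profile$atom_a), "", profile$atom_a),
    atom_b = ifelse(is.na(profile$atom_b), "", profile$atom_b),
    energy_hartree = format_num(profile$energy)
  )
  readr::write_csv(out, path)
  atoms <- profile_atoms(profile)
  if (!is.null(atoms)) {
    if (is.null(atoms_path)) {
      stop_schema("Profile has an atoms table; supply atoms_path as well.")
    }
    aout <- dplyr::mutate(atoms, dplyr::across(c("q", "x", "y", "z"),
                                               format_num))
    readr::write_csv(aout, atoms_path)
  }
  invisible(path)
}

# 17 significant digits: enough for an exact double round-trip
format_num <- function(x) sprintf("%.17g", x)

#' Fragment schemes: named disjoint groups of atoms
#'
#' A fragment scheme names disjoint groups of atom labels (the A-F groups
#' of a fragment-level analysis). `fragment_scheme()` validates disjointness
#' and non-emptiness; `read_fragment_scheme()`/`write_fragment_scheme()`
#' exchange the scheme as YAML (`group: [atom, ...]`).
#'
#' @param groups Named list of character vectors of atom labels.
#' @param profile Optional [energy_profile()]; when given, every listed atom
#'   must appear in the profile's term keys.
#' @return A named list of lowercase atom-label vectors, class
#'   `fragment_scheme`.
#' @export
fragment_scheme <- function(groups, profile = NULL) {
  if (length(groups) == 0 || is.null(names(groups)) ||
      any(names(groups) == "")) {
    stop_schema("Fragment scheme needs at least one named group.")
  }
  groups <- lapply(groups, function(g) normalise_label(as.character(g)))
  sizes <- vapply(groups, length, 1L)
  if (any(sizes == 0)) {
    stop_schema(paste0("Empty group(s): ",
                       paste(names(groups)[sizes == 0], collapse = ", ")))
  }
  all_atoms <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_atoms) > 0) {
    dup <- unique(all_atoms[duplicated(all_atoms)])
    stop_schema(paste0("Groups overlap on atom(s): ",
                       paste(dup, collapse = ", ")))
  }
  if (!is.null(profile)) {
    known <- profile_atom_labels(profile)
    unknown <- setdiff(all_atoms, known)
    if (length(unknown) > 0) {
      stop_schema(paste0("Scheme references atom(s) not in the profile: ",
                         paste(unknown, collapse = ", ")))
    }
  }
  structure(groups, class = "fragment_scheme")
}

#' @rdname fragment_scheme
#' @param path YAML file path.
#' @export
read_fragment_scheme <- function(path, profile = NULL) {
  if (!file.exists(path)) stop_schema(paste0("No such file: ", path))
  fragment_scheme(yaml::read_yaml(path), profile = profile)
}

#' @rdname fragment_scheme
#' @param scheme A `fragment_scheme`.
#' @export
write_fragment_scheme <- function(scheme, path) {
  yaml::write_yaml(lapply(unclass(scheme), as.list), path)
  invisible(path)
}
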