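# Term identity: an energy term is identified by its type plus zero, one or
# two participants. Participants are atom labels ("n1", "c4") or, after
# fragment aggregation, group names ("A", "E"). Unordered pairs are stored in
# a canonical order so that V_cl(n1,c4) and V_cl(c4,n1) are the same key.

# Term-type arity classes. Vee and Ven are dual-arity: with one participant
# they are the intra-atomic electron-electron / electron-nucleus pieces of
# E_intra; with two they are interatomic raw components.
TYPES_INTRA <- c("E_intra", "T")
TYPES_DUAL <- c("Vee", "Ven")
TYPES_INTER <- c("V_inter", "V_cl", "V_xc", "V_D3", "V_ct", "V_pl",
                 "Vne", "Vnn", "Vcoul", "Vx", "Vc")
TYPES_TOTAL <- "E_tot"
TYPES_ALL <- c(TYPES_INTRA, TYPES_DUAL, TYPES_INTER, TYPES_TOTAL)

# Directional pair types: Ven(a,b) is "electrons of a with nucleus of b", so
# swapping the participants turns Ven into Vne and vice versa.
TYPES_DIRECTIONAL <- c("Ven", "Vne")

ATOM_LABEL_RE <- "^([a-z]{1,2})([0-9]+)$"

# Normalise a term-type string: accepts the canonical spelling plus common
# undecorated variants such as "Eintra", "Vcl", "vxc", "VD3".
normalise_term_type <- function(x) {
  lookup <- setNames(TYPES_ALL, tolower(gsub("_", "", TYPES_ALL)))
  key <- tolower(gsub("[_ ]", "", x))
  out <- unname(lookup[key])
  bad <- unique(x[is.na(out) & !is.na(x)])
  if (length(bad) > 0) {
    stop_schema(paste0("Unknown term type(s): ", paste(bad, collapse = ", "),
                       ". Known types: ", paste(TYPES_ALL, collapse = ", ")))
  }
  out
}

is_atom_label <- function(x) {
  !is.na(x) & grepl(ATOM_LABEL_RE, tolower(trimws(x)))
}

# Sort key giving a deterministic total order: parsed atom labels order by
# (element, index); anything else (fragment group names) orders after them
# alphabetically, case-insensitively.
label_sort_key <- function(x) {
  x_low <- tolower(trimws(x))
  atom <- grepl(ATOM_LABEL_RE, x_low)
  key <- character(length(x))
  el <- sub(ATOM_LABEL_RE, "\\1", x_low[atom])
  idx <- as.integer(sub(ATOM_LABEL_RE, "\\2", x_low[atom]))
  key[atom] <- sprintf("0:%-2s:%08d", el, idx)
  key[!atom] <- paste0("1:", x_low[!atom])
  key[is.na(x)] <- NA_character_
  key
}

normalise_label <- function(x) {
  x <- trimws(x)
  x[!is.na(x) & x == ""] <- NA_character_
  ifelse(is_atom_label(x), tolower(x), x)
}

# Put pair participants of a term table into canonical order, swapping the
# directional Ven/Vne types when the participants swap.
canonicalise_pairs <- function(df) {
  has_pair <- !is.na(df$atom_a) & !is.na(df$atom_b)
  if (!any(has_pair)) return(df)
  ka <- label_sort_key(df$atom_a)
  kb <- label_sort_key(df$atom_b)
  swap <- has_pair & kb < ka
  if (any(swap)) {
    tmp <- df$atom_a[swap]
    df$atom_a[swap] <- df$atom_b[swap]
    df$atom_b[swap] <- tmp
    dir_swap <- swap & df$term_type %in% TYPES_DIRECTIONAL
    df$term_type[dir_swap] <- ifelse(df$term_type[dir_swap] == "Ven",
                                     "Vne", "Ven")
  }
  eq <- has_pair & label_sort_key(df$atom_a) == label_sort_key(df$atom_b)
  if (any(eq)) {
    stop_schema(paste0("Pair terms with identical participants: ",
                       paste(unique(df$atom_a[eq]), collapse = ", ")))
  }
  df
}

# Validate term_type / participant-arity combinations.
check_arity <- function(df) {
  n_part <- (!is.na(df$atom_a)) + (!is.na(df$atom_b))
  a_only_b <- is.na(df$atom_a) & !is.na(df$atom_b)
  if (any(a_only_b)) {
    stop_schema("Rows with atom_b set but atom_a empty.")
  }
  bad <- (df$term_type %in% TYPES_TOTAL & n_part != 0) |
    (df$term_type %in% TYPES_INTRA & n_part != 1) |
    (df$term_type %in% TYPES_INTER & n_part != 2) |
    (df$term_type %in% TYPES_DUAL & n_part == 0)
  if (any(bad)) {
    offender <- df[which(bad)[1], ]
    stop_schema(sprintf(
      "Term type %s used with %d participant(s) (row with point %s).",
      offender$term_type,
      (!is.na(offender$atom_a)) + (!is.na(offender$atom_b)),
      format(offender$point_index)))
  }
  invisible(df)
}

#' Render and parse term labels
#'
#' A term label is the field's usual rendering of one partitioned energy
#' term: `"E_intra(n1)"`, `"V_cl(c4,n1)"`, `"V_xc(E,F)"` or `"E_tot"`.
#' `parse_term()` accepts undecorated type spellings (`"Eintra"`, `"Vcl"`)
#' as printed in the literature and canonicalises pair order.
#'
#' @param term_type Character vector of term types.
#' @param atom_a,atom_b Participant labels (`NA` where absent).
#' @param x Character vector of term labels to parse.
#' @return `term_label()` a character vector; `parse_term()` a tibble with
#'   columns `term_type`, `atom_a`, `atom_b`.
#' @examples
#' term_label("V_cl", "c4", "n1")
#' parse_term(c("Eintra(n1)", "Vcl(n1,c4)"))
#' @export
term_label <- function(term_type, atom_a = NA, atom_b = NA) {
  out <- character(length(term_type))
  none <- is.na(atom_a)
  one <- !is.na(atom_a) & is.na(atom_b)
  two <- !is.na(atom_a) & !is.na(atom_b)
  out[none] <- term_type[none]
  out[one] <- paste0(term_type[one], "(", atom_a[one], ")")
  out[two] <- paste0(term_type[two], "(", atom_a[two], ",", atom_b[two], ")")
  out
}

#' @rdname term_label
#' @export
parse_term <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^([^()]+)(\\(([^,()]+)(,([^,()]+))?\\))?$", x))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad)) {
    stop_schema(paste0("Unparseable term label(s): ",
                       paste(x[bad], collapse = ", ")))
  }
  df <- tibble(
    term_type = normalise_term_type(vapply(m, `[`, "", 2L)),
    atom_a = normalise_label(vapply(m, `[`, "", 4L)),
    atom_b = normalise_label(vapply(m, `[`, "", 6L))
  )
  df$point_index <- NA_integer_ # for error messages in check_arity
  check_arity(df)
  df$point_index <- NULL
  canonicalise_pairs(df)
}
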