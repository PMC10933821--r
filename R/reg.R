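# The REG engine. For each partitioned term E_i over the M points of a PES
# segment, the REG value is the ordinary least-squares slope of E_i
# regressed on E_tot after mean-centring both series:
#
#   m_REG,i = <E_tot - mean, E_i - mean> / <E_tot - mean, E_tot - mean>
#
# The control coordinate s orders the segment but never enters the
# numerics. Because least squares is linear in the response, the REG
# values of a complete additive partition sum to exactly 1, and the REG of
# a fragment term equals the sum of the REGs of its member terms.

#' Compute REG values over a PES segment
#'
#' Regresses every partitioned energy term on the total energy over the
#' selected segment and returns slopes, Pearson correlations, the R²
#' admissibility flag and a most-positive-first ranking.
#'
#' The profile must be ordered so that the final point is the conformer
#' whose formation is under study (e.g. transition state first, closed
#' conformer last): positive REG values then favour formation of that
#' conformer.
#'
#' @param profile An [energy_profile()] (atomistic or fragment-level).
#' @param segment Optional point selection: a length-2 `c(from, to)` range
#'   of `point_index`, or a vector of point indices. Default: all points.
#' @param r2_threshold Minimum R² for a term's regression to be considered
#'   admissible (linearity criterion; conventionally 0.8).
#' @param include_total Also report the `E_tot` term itself (slope 1 by
#'   construction). Excluded by default so that the table covers exactly
#'   the additive partition.
#' @return A `reg_table`: a tibble with columns `term_type`, `atom_a`,
#'   `atom_b`, `term`, `reg`, `pearson_r`, `r_squared`, `admissible`,
#'   `rank`, sorted most positive first, with attributes `m_points`,
#'   `segment`, `r2_threshold`, `system`.
#' @examples
#' syn <- synthetic_profile(n_atoms = 4, m_points = 8, seed = 1)
#' reg_values(syn$profile)
#' @export
reg_values <- function(profile, segment = NULL, r2_threshold = 0.8,
                       include_total = FALSE) {
  pts <- profile_points(profile)
  sel <- resolve_segment(pts$point_index, segment)
  if (length(sel) < 3) {
    stop_precondition(paste0("REG regression needs at least 3 points; ",
                             "segment has ", length(sel), "."))
  }
  sub <- profile[profile$point_index %in% sel, ]

  e_tot_rows <- sub[sub$term_type == "E_tot", ]
  if (nrow(e_tot_rows) > 0) {
    tot <- dplyr::arrange(e_tot_rows, .data$point_index)$energy
  } else {
    tot <- total_energy(profile_subset(profile, sel))$e_tot
  }
  ct <- tot - mean(tot)
  denom <- sum(ct * ct)
  if (denom == 0) {
    stop_precondition("Total energy has zero variance over the segment; REG is undefined.")
  }

  keys <- profile_term_keys(sub)
  if (!include_total) keys <- keys[keys$term_type != "E_tot", ]

  mat <- profile_matrix(sub, include_total = TRUE)
  res <- purrr::pmap_dfr(keys, function(term_type, atom_a, atom_b, term) {
    y <- mat[, term]
    cy <- y - mean(y)
    reg <- sum(ct * cy) / denom
    r <- if (sd(y) == 0) NA_real_ else cor(tot, y)
    tibble(term_type = term_type, atom_a = atom_a, atom_b = atom_b,
           term = term, reg = reg, pearson_r = r, r_squared = r^2)
  })
  res$admissible <- !is.na(res$r_squared) & res$r_squared >= r2_threshold
  ord <- order(-res$reg, res$term_type, label_sort_key(res$atom_a),
               label_sort_key(res$atom_b))
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  structure(res,
            m_points = length(sel), segment = range(sel),
            r2_threshold = r2_threshold,
            system = attr(profile, "system"),
            class = c("reg_table", class(tibble())))
}

resolve_segment <- function(points, segment) {
  if (is.null(segment)) return(points)
  segment <- as.integer(segment)
  if (length(segment) == 2 && segment[2] >= segment[1]) {
    sel <- points[points >= segment[1] & points <= segment[2]]
  } else {
    sel <- intersect(points, segment)
  }
  if (length(sel) == 0) {
    stop_precondition("Segment selects no points of the profile.")
  }
  sel
}

#' Select the most important REG entries
#'
#' Returns the `top_k` most positive and `top_k` most negative admissible
#' entries of a REG table (the layout used to report the "10 most
#' important" terms), preserving the most-positive-first order.
#'
#' @param table A `reg_table` from [reg_values()] or [as_reg_table()].
#' @param top_k Entries to keep on each side.
#' @param keep_inadmissible Keep entries failing the R² criterion (they are
#'   excluded by default but remain flagged in the full table).
#' @return A tibble of at most `2 * top_k` rows.
#' @export
rank_and_filter <- function(table, top_k = 5, keep_inadmissible = FALSE) {
  if (!is.numeric(top_k) || length(top_k) != 1 || top_k < 1) {
    stop_precondition("top_k must be a positive integer.")
  }
  adm <- if (keep_inadmissible) table else table[table$admissible, ]
  if (nrow(adm) == 0) {
    warn("No admissible entries at this R² threshold; selection is empty.")
    return(adm)
  }
  idx <- unique(c(head(seq_len(nrow(adm)), top_k),
                  tail(seq_len(nrow(adm)), top_k)))
  adm[idx, ]
}

#' @export
print.reg_table <- function(x, ...) {
  cat(sprintf("<reg_table: %s | M = %s points, %d terms, R² threshold %s>\n",
              attr(x, "system") %||% "unnamed",
              attr(x, "m_points") %||% "?", nrow(x),
              format(attr(x, "r2_threshold") %||% NA)))
  NextMethod()
}

#' Broom-style accessors for REG tables
#'
#' `tidy()` returns the per-term estimates; `glance()` a one-row summary
#' including the partition sum of REG values (exactly 1 for a complete
#' additive partition).
#'
#' @param x A `reg_table`.
#' @param ... Unused.
#' @method tidy reg_table
#' @export
tidy.reg_table <- function(x, ...) {
  as_tibble(x)[, c("term", "term_type", "atom_a", "atom_b", "reg",
                   "pearson_r", "r_squared", "admissible", "rank")]
}

#' @rdname tidy.reg_table
#' @method glance reg_table
#' @export
glance.reg_table <- function(x, ...) {
  tibble(
    m_points = attr(x, "m_points") %||% NA_integer_,
    n_terms = nrow(x),
    n_admissible = sum(x$admissible),
    r2_threshold = attr(x, "r2_threshold") %||% NA_real_,
    reg_max = if (nrow(x)) max(x$reg) else NA_real_,
    reg_min = if (nrow(x)) min(x$reg) else NA_real_,
    sum_reg = sum(x$reg)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
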