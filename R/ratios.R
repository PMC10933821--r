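# REG Ratios: the most positive atomistic REG value (REG_max) divided by
# each REG value of interest. A ratio near 1 marks a term as prominent as
# the strongest one; a large ratio marks it as many times less relevant; a
# negative ratio marks a term working against the barrier.

#' Compute REG Ratios against a reference REG maximum
#'
#' Divides `reference_reg` (the highest positive REG value of the fully
#' atomistic analysis) by each entry's REG value. Printed reports round
#' the ratio to the nearest integer; full precision is retained in the
#' `ratio` column.
#'
#' @param table A `reg_table` (typically fragment-level entries).
#' @param reference_reg The reference REG maximum, strictly positive. When
#'   `NULL`, the most positive admissible entry of `table` itself is used.
#' @param floor Entries with `|reg|` below this are flagged `unstable`
#'   (their ratio is reported but dominated by noise).
#' @return A `ratio_table` tibble with columns `term`, `reg`, `ratio`,
#'   `ratio_printed`, `unstable`; attributes `reference_reg`,
#'   `reference_term`.
#' @examples
#' tab <- as_reg_table(data.frame(term = c("V_cl(a1,b2)", "V_xc(a1,b2)"),
#'                                reg = c(4.7, 0.67), pearson_r = c(0.99, 0.9)))
#' reg_ratio(tab, reference_reg = 4.7)
#' @export
reg_ratio <- function(table, reference_reg = NULL, floor = 1e-6) {
  reference_term <- NA_character_
  if (is.null(reference_reg)) {
    adm <- table[table$admissible & table$reg > 0, ]
    if (nrow(adm) == 0) {
      stop_precondition("No positive admissible REG value to use as reference.")
    }
    reference_reg <- adm$reg[1]
    reference_term <- adm$term[1]
  }
  if (!is.numeric(reference_reg) || length(reference_reg) != 1 ||
      !is.finite(reference_reg) || reference_reg <= 0) {
    stop_precondition("reference_reg must be a single positive REG value.")
  }
  out <- tibble(
    term = table$term,
    term_type = table$term_type,
    atom_a = table$atom_a,
    atom_b = table$atom_b,
    reg = table$reg,
    ratio = reference_reg / table$reg,
    unstable = abs(table$reg) < floor
  )
  out$ratio_printed <- round_half_up(out$ratio)
  structure(out, reference_reg = reference_reg,
            reference_term = reference_term,
            class = c("ratio_table", class(tibble())))
}

#' Compare REG Ratios of shared terms across systems
#'
#' Lines up the ratios of the requested term keys across several systems
#' (one `ratio_table` each, in a meaningful order, e.g. most
#' electron-withdrawing to most electron-donating substituent) and labels
#' the per-term trend along that order.
#'
#' @param tables Named list of `ratio_table` objects, in comparison order.
#' @param keys Character vector of term labels each system must provide;
#'   defaults to the terms of the first table.
#' @return A tibble with one row per term, one ratio column per system,
#'   and a `trend` column (`"increasing"`, `"decreasing"`, `"mixed"`, or
#'   `NA` for a single system).
#' @export
cross_system_compare <- function(tables, keys = NULL) {
  if (length(tables) == 0 || is.null(names(tables)) ||
      any(names(tables) == "")) {
    stop_precondition("tables must be a non-empty named list of ratio tables.")
  }
  canon <- function(x) {
    p <- parse_term(x)
    term_label(p$term_type, p$atom_a, p$atom_b)
  }
  if (is.null(keys)) keys <- tables[[1]]$term
  keys <- canon(keys)
  cols <- purrr::imap(tables, function(tab, sys) {
    tab_terms <- canon(tab$term)
    missing_keys <- setdiff(keys, tab_terms)
    if (length(missing_keys) > 0) {
      stop_schema(paste0("System ", sys, " lacks term(s): ",
                         paste(missing_keys, collapse = ", ")))
    }
    tab$ratio[match(keys, tab_terms)]
  })
  out <- tibble(term = keys)
  for (sys in names(cols)) out[[sys]] <- cols[[sys]]
  ratio_mat <- as.matrix(out[, names(cols), drop = FALSE])
  out$trend <- apply(ratio_mat, 1, function(r) {
    if (length(r) < 2) return(NA_character_)
    d <- diff(r)
    if (all(d > 0)) "increasing"
    else if (all(d < 0)) "decreasing"
    else "mixed"
  })
  out
}

#' Build a REG table from already-computed values
#'
#' Wraps externally obtained REG values (e.g. a published table) in the
#' `reg_table` structure so that ranking, ratio and report functions apply
#' to them unchanged.
#'
#' @param df Data frame with columns `term` (labels such as
#'   `"V_cl(n1,c4)"`), `reg`, and optionally `pearson_r`.
#' @param r2_threshold Admissibility threshold applied to `pearson_r^2`.
#' @param m_points Number of points behind the values, if known.
#' @return A `reg_table` sorted most positive first.
#' @export
as_reg_table <- function(df, r2_threshold = 0.8, m_points = NA_integer_) {
  df <- as_tibble(df)
  if (!all(c("term", "reg") %in% names(df))) {
    stop_schema("as_reg_table() needs columns term and reg.")
  }
  keys <- parse_term(df$term)
  res <- tibble(
    term_type = keys$term_type, atom_a = keys$atom_a, atom_b = keys$atom_b,
    term = term_label(keys$term_type, keys$atom_a, keys$atom_b),
    reg = as.numeric(df$reg),
    pearson_r = if ("pearson_r" %in% names(df)) as.numeric(df$pearson_r)
                else NA_real_
  )
  res$r_squared <- res$pearson_r^2
  res$admissible <- is.na(res$r_squared) | res$r_squared >= r2_threshold
  ord <- order(-res$reg, res$term_type, label_sort_key(res$atom_a),
               label_sort_key(res$atom_b))
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  structure(res, m_points = m_points, segment = NULL,
            r2_threshold = r2_threshold, system = NULL,
            class = c("reg_table", class(tibble())))
}
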