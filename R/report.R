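# Report writers. Printed REG values are rounded to 1 decimal and Pearson
# R to 2 decimals (the presentation convention of the literature's REG
# tables); REG Ratios print as integers. Full precision is always
# retained in the underlying objects and available via full_precision.

#' Write a ranked REG report
#'
#' Emits the selected most-positive/most-negative entries in a TERM / REG /
#' R layout, most negative first, as aligned text or CSV.
#'
#' @param table A `reg_table`.
#' @param file Optional output path; when `NULL` the report is returned
#'   (and printed for text format).
#' @param top_k Entries kept on each side after admissibility filtering.
#' @param format `"text"` or `"csv"`.
#' @param full_precision Disable presentation rounding.
#' @return The report lines (text) or the written tibble (csv), invisibly.
#' @export
write_reg_report <- function(table, file = NULL, top_k = 5,
                             format = c("text", "csv"),
                             full_precision = FALSE) {
  format <- match.arg(format)
  sel <- rank_and_filter(table, top_k = top_k)
  sel <- sel[order(sel$reg), ] # most negative first, as conventionally printed
  out <- tibble(
    term = sel$term,
    reg = if (full_precision) sel$reg else round_half_up(sel$reg, 1),
    pearson_r = if (full_precision) sel$pearson_r
                else round_half_up(sel$pearson_r, 2)
  )
  if (format == "csv") {
    if (!is.null(file)) readr::write_csv(out, file)
    return(invisible(out))
  }
  lines <- c(
    sprintf("%-18s %8s %8s", "TERM", "REG", "R"),
    sprintf("%-18s %8s %8s", out$term,
            formatC(out$reg, format = if (full_precision) "g" else "f",
                    digits = if (full_precision) 10 else 1),
            formatC(out$pearson_r, format = if (full_precision) "g" else "f",
                    digits = if (full_precision) 10 else 2))
  )
  emit_lines(lines, file)
}

#' Write a fragment REG-Ratio report across systems
#'
#' One row per fragment term, one REG / REG-Ratio column pair per system,
#' ratios printed as integers.
#'
#' @param tables Named list of `ratio_table` objects in column order.
#' @param file Optional output path.
#' @param format `"text"` or `"csv"`.
#' @param keys Term labels to report; defaults to the first table's terms.
#' @return Report lines or written tibble, invisibly.
#' @export
write_ratio_report <- function(tables, file = NULL,
                               format = c("text", "csv"), keys = NULL) {
  format <- match.arg(format)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop_precondition("tables must be a named list of ratio tables.")
  }
  if (is.null(keys)) keys <- tables[[1]]$term
  wide <- tibble(term = keys)
  for (sys in names(tables)) {
    tab <- tables[[sys]]
    idx <- match(keys, tab$term)
    if (anyNA(idx)) {
      stop_schema(paste0("System ", sys, " lacks term(s): ",
                         paste(keys[is.na(idx)], collapse = ", ")))
    }
    wide[[paste0(sys, "_reg")]] <- round_half_up(tab$reg[idx], 2)
    wide[[paste0(sys, "_ratio")]] <- tab$ratio_printed[idx]
  }
  if (format == "csv") {
    if (!is.null(file)) readr::write_csv(wide, file)
    return(invisible(wide))
  }
  header <- sprintf("%-14s %s", "TERM",
                    paste(sprintf("%10s %7s", paste0(names(tables), ":REG"),
                                  "RATIO"), collapse = " "))
  body <- vapply(seq_len(nrow(wide)), function(i) {
    cells <- vapply(names(tables), function(sys) {
      sprintf("%10.2f %7d", wide[[paste0(sys, "_reg")]][i],
              as.integer(wide[[paste0(sys, "_ratio")]][i]))
    }, "")
    sprintf("%-14s %s", wide$term[i], paste(cells, collapse = " "))
  }, "")
  emit_lines(c(header, body), file)
}

#' Write an experiment-vs-computation agreement report
#'
#' @param stats Tibble from [compare_experiment()].
#' @param file Optional output path.
#' @param format `"text"` or `"csv"`.
#' @param full_precision Disable presentation rounding (RMSE to 1 decimal,
#'   R-squared to 2).
#' @return Report lines or written tibble, invisibly.
#' @export
write_compare_report <- function(stats, file = NULL,
                                 format = c("text", "csv"),
                                 full_precision = FALSE) {
  format <- match.arg(format)
  out <- stats
  if (!full_precision) {
    out$rmse <- round_half_up(out$rmse, 1)
    out$r_squared <- round_half_up(out$r_squared, 2)
  }
  if (format == "csv") {
    if (!is.null(file)) readr::write_csv(out, file)
    return(invisible(out))
  }
  lines <- c(
    sprintf("%-20s %6s %12s %8s", "COLUMN", "N", "RMSE(kJ/mol)", "R2"),
    sprintf("%-20s %6d %12s %8s", out$column, out$n,
            formatC(out$rmse, format = "f",
                    digits = if (full_precision) 6 else 1),
            ifelse(is.na(out$r_squared), "-",
                   formatC(out$r_squared, format = "f",
                           digits = if (full_precision) 6 else 2)))
  )
  emit_lines(lines, file)
}

emit_lines <- function(lines, file) {
  if (is.null(file)) {
    cat(lines, sep = "\n")
    cat("\n")
  } else {
    writeLines(lines, file)
  }
  invisible(lines)
}

#' Read back a CSV REG report
#'
#' Inverse of `write_reg_report(..., format = "csv")`; returns a
#' `reg_table` built with [as_reg_table()].
#'
#' @param path CSV path with columns `term`, `reg`, `pearson_r`.
#' @param r2_threshold Admissibility threshold to apply.
#' @return A `reg_table`.
#' @export
read_reg_report <- function(path, r2_threshold = 0.8) {
  if (!file.exists(path)) stop_schema(paste0("No such file: ", path))
  as_reg_table(readr::read_csv(path, show_col_types = FALSE),
               r2_threshold = r2_threshold)
}
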