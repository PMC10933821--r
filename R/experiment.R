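# Experiment-vs-computation agreement for conformer energy differences:
# RMSE and squared Pearson correlation between the experimentally fitted
# energy differences and each computed column, plus the NMR free-energy
# relation dG = -RT ln([closed]/[open]).

#' Root mean squared error between paired vectors
#'
#' @param a,b Numeric vectors of equal length (same units).
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) {
    stop_precondition("rmse(): vectors differ in length.")
  }
  if (length(a) == 0) stop_precondition("rmse(): empty vectors.")
  sqrt(mean((a - b)^2))
}

#' Squared Pearson correlation
#'
#' @param a,b Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Pearson R² in `[0, 1]`.
#' @export
squared_correlation <- function(a, b) {
  if (length(a) != length(b)) {
    stop_precondition("squared_correlation(): vectors differ in length.")
  }
  if (length(a) < 3) {
    stop_precondition("squared_correlation(): need at least 3 paired values.")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop_precondition("squared_correlation(): a vector has zero variance.")
  }
  cor(a, b)^2
}

#' Free energy from an NMR conformer population ratio
#'
#' `dG = -RT ln(K)` with `K = [closed]/[open]`, returned in kJ/mol
#' (R = 8.31446 J mol⁻¹ K⁻¹).
#'
#' @param ratio_closed_open Population ratio, strictly positive.
#' @param temperature Temperature in kelvin, strictly positive.
#' @return Free-energy difference in kJ/mol.
#' @examples
#' free_energy_from_populations(0.5, 300) # +1.73 kJ/mol, open favoured
#' @export
free_energy_from_populations <- function(ratio_closed_open,
                                         temperature = 298.15) {
  if (any(ratio_closed_open <= 0) || any(!is.finite(ratio_closed_open))) {
    stop_precondition("Population ratio must be strictly positive.")
  }
  if (any(temperature <= 0)) {
    stop_precondition("Temperature must be strictly positive (kelvin).")
  }
  -GAS_CONSTANT_J * temperature * log(ratio_closed_open) / 1000
}

#' Read a set of paired energy differences
#'
#' Expects a CSV with a `label` column, a `de_exp` column (experimental
#' energy difference, kJ/mol) and one or more computed columns.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_energy_differences <- function(path) {
  if (!file.exists(path)) stop_schema(paste0("No such file: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"label" %in% names(df) || !"de_exp" %in% names(df)) {
    stop_schema("Energy-difference file needs columns label and de_exp.")
  }
  if (nrow(df) < 2) {
    stop_schema("Energy-difference set needs at least 2 rows.")
  }
  df
}

#' Agreement statistics between experiment and computation
#'
#' For each computed column, reports the RMSE against the experimental
#' column and, when at least 3 rows are available, the squared Pearson
#' correlation.
#'
#' @param diffs Data frame from [read_energy_differences()] (or of the
#'   same shape).
#' @param exp_col Name of the experimental column.
#' @return A tibble with columns `column`, `n`, `rmse`, `r_squared`.
#' @examples
#' path <- system.file("extdata", "table1_energy_differences.csv",
#'                     package = "regiqa")
#' compare_experiment(read_energy_differences(path))
#' @export
compare_experiment <- function(diffs, exp_col = "de_exp") {
  if (!exp_col %in% names(diffs)) {
    stop_schema(paste0("No experimental column ", exp_col, " in input."))
  }
  calc_cols <- setdiff(names(diffs)[vapply(diffs, is.numeric, TRUE)], exp_col)
  if (length(calc_cols) == 0) {
    stop_schema("No computed numeric columns to compare.")
  }
  a <- diffs[[exp_col]]
  purrr::map_dfr(calc_cols, function(col) {
    b <- diffs[[col]]
    tibble(column = col, n = length(a), rmse = rmse(a, b),
           r_squared = if (length(a) >= 3) squared_correlation(a, b)
                       else NA_real_)
  })
}
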