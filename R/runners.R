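# Workflow runners behind the command-line interface. Each runner is an
# ordinary R function over the package's building blocks; the `regiqa`
# script (inst/scripts/regiqa) is a thin argument-parsing shell around
# them. Error conditions map onto exit codes: 2 input/schema, 3
# statistical precondition, 4 internal inconsistency.

#' Run a ranked REG analysis on a profile file
#'
#' Reads a profile, computes REG values over the requested segment and
#' writes/prints the ranked report.
#'
#' @param input Path to a profile CSV (interchange schema).
#' @param atoms Optional path to the companion atoms CSV.
#' @param segment Optional `c(from, to)` point range.
#' @param r2_threshold Admissibility threshold on R².
#' @param top_k Entries per side in the report.
#' @param output Optional report path (CSV when it ends in `.csv`).
#' @param full_precision Disable presentation rounding.
#' @return The full `reg_table`, invisibly.
#' @export
run_reg <- function(input, atoms = NULL, segment = NULL, r2_threshold = 0.8,
                    top_k = 5, output = NULL, full_precision = FALSE) {
  profile <- read_profile(input, atoms_path = atoms, quiet = TRUE)
  table <- reg_values(profile, segment = segment,
                      r2_threshold = r2_threshold)
  write_reg_report(table, file = output, top_k = top_k,
                   format = report_format(output),
                   full_precision = full_precision)
  invisible(table)
}

#' Run a fragment (IQF) REG-Ratio analysis
#'
#' Aggregates the profile over a fragment scheme, computes fragment REG
#' values and divides the atomistic REG maximum by each of them.
#'
#' @param input,atoms Profile file paths as in [run_reg()].
#' @param scheme Path to a fragment-scheme YAML, or a [fragment_scheme()].
#' @param reference Reference REG maximum; default: the most positive
#'   admissible REG value of the fully atomistic analysis of `input`.
#' @param segment,r2_threshold As in [run_reg()].
#' @param output Optional report path.
#' @return A list with `atomistic` (reg_table), `fragment` (reg_table) and
#'   `ratios` (ratio_table), invisibly.
#' @export
run_iqf <- function(input, scheme, atoms = NULL, reference = NULL,
                    segment = NULL, r2_threshold = 0.8, output = NULL) {
  profile <- read_profile(input, atoms_path = atoms, quiet = TRUE)
  if (is.character(scheme)) {
    scheme <- read_fragment_scheme(scheme, profile = profile)
  }
  atomistic <- reg_values(profile, segment = segment,
                          r2_threshold = r2_threshold)
  if (is.null(reference)) {
    adm <- atomistic[atomistic$admissible & atomistic$reg > 0, ]
    if (nrow(adm) == 0) {
      stop_precondition("Atomistic analysis has no positive admissible REG value to serve as reference.")
    }
    reference <- adm$reg[1]
  }
  frag_profile <- aggregate_fragments(profile, scheme)
  fragment <- reg_values(frag_profile, segment = segment,
                         r2_threshold = r2_threshold)
  ratios <- reg_ratio(fragment, reference_reg = reference)
  sys_name <- attr(profile, "system") %||% "system"
  write_ratio_report(setNames(list(ratios), sys_name), file = output,
                     format = report_format(output))
  invisible(list(atomistic = atomistic, fragment = fragment,
                 ratios = ratios))
}

#' Run the experiment-vs-computation comparison
#'
#' @param input CSV with `label`, `de_exp` and computed columns (kJ/mol).
#' @param output Optional report path.
#' @param full_precision Disable presentation rounding.
#' @return The statistics tibble, invisibly.
#' @export
run_compare <- function(input, output = NULL, full_precision = FALSE) {
  diffs <- read_energy_differences(input)
  stats <- compare_experiment(diffs)
  write_compare_report(stats, file = output, format = report_format(output),
                       full_precision = full_precision)
  invisible(stats)
}

#' Validate a profile's energy-partition consistency
#'
#' @param input,atoms Profile file paths.
#' @param tolerance Residual tolerance in hartree.
#' @return The validation report, invisibly; raises an inconsistency error
#'   when any residual exceeds tolerance.
#' @export
run_validate <- function(input, atoms = NULL, tolerance = 1e-8) {
  profile <- read_profile(input, atoms_path = atoms, quiet = TRUE)
  report <- validate_profile(profile, tolerance = tolerance)
  print(report)
  if (!validation_passed(report)) {
    stop_inconsistency(sprintf(
      "%d residual(s) exceed %g hartree.", sum(!report$pass), tolerance))
  }
  invisible(report)
}

#' Simulate a balance-like system to files
#'
#' Writes the synthetic profile CSV, atoms CSV, fragment-scheme YAML and a
#' ground-truth JSON into `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param m_points PES points.
#' @param noise_sigma Per-term noise in hartree.
#' @return Named vector of the written paths, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1, m_points = 15,
                         noise_sigma = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- synthetic_balance(seed = seed, m_points = m_points,
                           noise_sigma = noise_sigma)
  paths <- c(profile = file.path(out_dir, "profile.csv"),
             atoms = file.path(out_dir, "atoms.csv"),
             scheme = file.path(out_dir, "fragments.yaml"),
             truth = file.path(out_dir, "ground_truth.json"))
  write_profile(gen$profile, paths["profile"], atoms_path = paths["atoms"])
  write_fragment_scheme(gen$scheme, paths["scheme"])
  truth <- gen$truth
  truth$slopes <- as.list(truth$slopes)
  truth$offsets <- as.list(truth$offsets)
  truth$designated <- as.list(truth$designated)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

report_format <- function(output) {
  if (!is.null(output) && grepl("\\.csv$", output, ignore.case = TRUE)) {
    "csv"
  } else {
    "text"
  }
}

#' Command-line entry point
#'
#' Dispatches the `regiqa` subcommands (`reg`, `iqf`, `compare`,
#' `validate`, `simulate`) and returns the process exit status instead of
#' quitting, so it is directly testable. The installed script
#' `system.file("scripts", "regiqa", package = "regiqa")` wraps this.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status: 0 success, 2 input/schema error, 3
#'   precondition error, 4 internal inconsistency.
#' @export
regiqa_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: regiqa <reg|iqf|compare|validate|simulate> [options]",
    "  common options: --input PATH --atoms PATH --output PATH",
    "  reg/iqf: --segment FROM:TO --r2-threshold X --top-k K --full-precision",
    "  iqf:     --scheme PATH --reference X",
    "  validate: --tolerance X",
    "  simulate: --out-dir DIR --seed N --m-points M --noise-sigma X",
    sep = "\n")
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(0L)
  }
  cmd <- args[1]
  opt <- parse_cli_options(args[-1])
  status <- tryCatch({
    switch(cmd,
      reg = run_reg(req(opt, "input"), atoms = opt$atoms,
                    segment = opt_segment(opt),
                    r2_threshold = opt_num(opt, "r2-threshold", 0.8),
                    top_k = opt_num(opt, "top-k", 5),
                    output = opt$output,
                    full_precision = isTRUE(opt$`full-precision`)),
      iqf = run_iqf(req(opt, "input"), scheme = req(opt, "scheme"),
                    atoms = opt$atoms,
                    reference = if (is.null(opt$reference)) NULL
                                else as.numeric(opt$reference),
                    segment = opt_segment(opt),
                    r2_threshold = opt_num(opt, "r2-threshold", 0.8),
                    output = opt$output),
      compare = run_compare(req(opt, "input"), output = opt$output,
                            full_precision = isTRUE(opt$`full-precision`)),
      validate = run_validate(req(opt, "input"), atoms = opt$atoms,
                              tolerance = opt_num(opt, "tolerance", 1e-8)),
      simulate = run_simulate(opt[["out-dir"]] %||% "simulated",
                              seed = opt_num(opt, "seed", 1),
                              m_points = opt_num(opt, "m-points", 15),
                              noise_sigma = opt_num(opt, "noise-sigma", 0)),
      stop_schema(paste0("Unknown subcommand: ", cmd))
    )
    0L
  }, regiqa_error = function(e) {
    message("regiqa: ", conditionMessage(e))
    exit_code_for(e)
  })
  status
}

parse_cli_options <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop_schema(paste0("Unexpected argument: ", a))
    }
    key <- substring(a, 3)
    if (key %in% c("full-precision")) {
      opt[[key]] <- TRUE
      i <- i + 1
    } else {
      if (i == length(args)) stop_schema(paste0("Missing value for --", key))
      opt[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  opt
}

req <- function(opt, key) {
  if (is.null(opt[[key]])) stop_schema(paste0("Missing required --", key))
  opt[[key]]
}

opt_num <- function(opt, key, default) {
  if (is.null(opt[[key]])) default else as.numeric(opt[[key]])
}

opt_segment <- function(opt) {
  if (is.null(opt$segment)) return(NULL)
  parts <- as.integer(strsplit(opt$segment, ":")[[1]])
  if (length(parts) != 2 || anyNA(parts)) {
    stop_schema("--segment must have the form FROM:TO.")
  }
  parts
}
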