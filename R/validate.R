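#' Check the additivity of an IQA energy partition
#'
#' Reports, per PES point, the residual of every energy identity the
#' profile's term set allows one to check:
#'
#' * `total`: `E_tot` minus the sum of all intra-atomic terms and all
#'   unordered-pair interatomic terms (pairs are stored once, so no 1/2
#'   factor applies);
#' * `intra_raw`: `E_intra(A)` minus `T(A) + Vee(A) + Ven(A)`;
#' * `inter_composition`: `V_inter(A,B)` minus `V_cl + V_xc [+ V_D3]`;
#' * `cl_raw`: `V_cl(A,B)` minus `Vnn + Ven + Vne + Vcoul`;
#' * `xc_raw`: `V_xc(A,B)` minus `Vx + Vc`.
#'
#' @param profile An [energy_profile()].
#' @param tolerance Energy tolerance in hartree above which a residual is
#'   flagged. The default reflects typical atomic-basin integration error,
#'   which exceeds machine precision.
#' @return A tibble of class `iqa_validation` with columns `point_index`,
#'   `check`, `key`, `residual`, `pass`.
#' @export
validate_profile <- function(profile, tolerance = 1e-8) {
  pts <- profile_points(profile)$point_index
  rows <- list()

  e_tot <- profile[profile$term_type == "E_tot", ]
  if (nrow(e_tot) > 0) {
    recon <- total_energy(profile)
    tot <- dplyr::arrange(e_tot, .data$point_index)
    rows$total <- tibble(point_index = tot$point_index, check = "total",
                         key = "E_tot",
                         residual = tot$energy - recon$e_tot)
  }

  intra1 <- function(tt) {
    profile[profile$term_type == tt & is.na(profile$atom_b) &
              !is.na(profile$atom_a), ]
  }
  te <- intra1("T"); vee <- intra1("Vee"); ven <- intra1("Ven")
  ei <- profile[profile$term_type == "E_intra", ]
  if (nrow(te) > 0 && nrow(vee) > 0 && nrow(ven) > 0 && nrow(ei) > 0) {
    j <- Reduce(function(a, b) dplyr::inner_join(a, b,
                                                 by = c("point_index", "atom_a")),
                list(
                  dplyr::select(ei, "point_index", "atom_a", e_intra = "energy"),
                  dplyr::select(te, "point_index", "atom_a", t = "energy"),
                  dplyr::select(vee, "point_index", "atom_a", vee = "energy"),
                  dplyr::select(ven, "point_index", "atom_a", ven = "energy")
                ))
    rows$intra <- tibble(point_index = j$point_index, check = "intra_raw",
                         key = term_label("E_intra", j$atom_a),
                         residual = j$e_intra - (j$t + j$vee + j$ven))
  }

  pair_tbl <- function(tt, nm) {
    x <- profile[profile$term_type == tt & !is.na(profile$atom_b), ]
    dplyr::select(x, "point_index", "atom_a", "atom_b", !!nm := "energy")
  }
  vin <- pair_tbl("V_inter", "v_inter")
  vcl <- pair_tbl("V_cl", "v_cl")
  vxc <- pair_tbl("V_xc", "v_xc")
  vd3 <- pair_tbl("V_D3", "v_d3")
  pair_by <- c("point_index", "atom_a", "atom_b")
  if (nrow(vin) > 0 && nrow(vcl) > 0 && nrow(vxc) > 0) {
    j <- dplyr::inner_join(vin, vcl, by = pair_by)
    j <- dplyr::inner_join(j, vxc, by = pair_by)
    j <- dplyr::left_join(j, vd3, by = pair_by)
    j$v_d3[is.na(j$v_d3)] <- 0
    rows$inter <- tibble(point_index = j$point_index,
                         check = "inter_composition",
                         key = term_label("V_inter", j$atom_a, j$atom_b),
                         residual = j$v_inter - (j$v_cl + j$v_xc + j$v_d3))
  }
  raw_cl <- list(pair_tbl("Vnn", "vnn"),
                 pair_tbl("Ven", "ven_ab"), pair_tbl("Vne", "vne"),
                 pair_tbl("Vcoul", "vcoul"))
  if (nrow(vcl) > 0 && all(vapply(raw_cl, nrow, 1L) > 0)) {
    j <- Reduce(function(a, b) dplyr::inner_join(a, b, by = pair_by),
                c(list(vcl), raw_cl))
    rows$cl <- tibble(point_index = j$point_index, check = "cl_raw",
                      key = term_label("V_cl", j$atom_a, j$atom_b),
                      residual = j$v_cl - (j$vnn + j$ven_ab + j$vne + j$vcoul))
  }
  vx <- pair_tbl("Vx", "vx"); vc <- pair_tbl("Vc", "vc")
  if (nrow(vxc) > 0 && nrow(vx) > 0 && nrow(vc) > 0) {
    j <- dplyr::inner_join(vxc, vx, by = pair_by)
    j <- dplyr::inner_join(j, vc, by = pair_by)
    rows$xc <- tibble(point_index = j$point_index, check = "xc_raw",
                      key = term_label("V_xc", j$atom_a, j$atom_b),
                      residual = j$v_xc - (j$vx + j$vc))
  }

  report <- dplyr::bind_rows(rows)
  if (nrow(report) == 0) {
    report <- tibble(point_index = integer(), check = character(),
                     key = character(), residual = numeric())
  }
  report$pass <- abs(report$residual) <= tolerance
  structure(dplyr::arrange(report, .data$check, .data$point_index),
            tolerance = tolerance,
            class = c("iqa_validation", class(tibble())))
}

#' @rdname validate_profile
#' @param report An `iqa_validation` report.
#' @return `validation_passed()`: `TRUE` when every checked residual is
#'   within tolerance.
#' @export
validation_passed <- function(report) {
  nrow(report) == 0 || all(report$pass)
}

#' @export
print.iqa_validation <- function(x, ...) {
  tol <- attr(x, "tolerance")
  n_bad <- sum(!x$pass)
  cat(sprintf("<iqa_validation: %d residual(s) checked at tolerance %g; %s>\n",
              nrow(x), tol,
              if (n_bad == 0) "all pass" else paste0(n_bad, " FLAGGED")))
  if (n_bad > 0) {
    bad <- x[!x$pass, ]
    print(as_tibble(bad), n = min(nrow(bad), 20))
  }
  invisible(x)
}
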