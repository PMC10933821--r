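tab_1x <- function() readr::read_csv(extdata("reg_iqa_1x.csv"),
                                     show_col_types = FALSE)
tab_2y <- function() readr::read_csv(extdata("reg_iqa_2y.csv"),
                                     show_col_types = FALSE)
iqf_1x <- function() readr::read_csv(extdata("reg_iqf_1x.csv"),
                                     show_col_types = FALSE)
iqf_2y <- function() readr::read_csv(extdata("reg_iqf_2y.csv"),
                                     show_col_types = FALSE)

published_reg <- function(df, balance) {
  as_reg_table(df[df$balance == balance, c("term", "reg", "pearson_r")])
}

test_that("published atomistic tables rank with the amide term on top", {
  t1h <- published_reg(tab_1x(), "1-H")
  sel <- rank_and_filter(t1h, top_k = 5)
  expect_equal(sel$term[1], canon_term("V_cl(n1,c4)"))
  expect_equal(sel$reg[1], 4.7)
  expect_equal(sel$pearson_r[1], 0.99)
  expect_equal(sel$term[nrow(sel)], "E_intra(n1)")
  expect_equal(sel$reg[nrow(sel)], -2.3)

  t2h <- published_reg(tab_2y(), "2-H")
  sel2 <- rank_and_filter(t2h, top_k = 5)
  expect_equal(sel2$term[1], canon_term("V_cl(n1,c3)"))
  expect_equal(sel2$reg[1], 6.9)
  expect_equal(sel2$reg[nrow(sel2)], -4.1)
})

test_that("inadmissible entries are excluded, with a warning when none remain", {
  df <- tibble::tibble(term = c("V_cl(a1,b2)", "V_xc(a1,b2)"),
                       reg = c(1, -1), pearson_r = c(0.5, -0.4))
  tab <- as_reg_table(df, r2_threshold = 0.8)
  expect_warning(sel <- rank_and_filter(tab, top_k = 3), "admissible")
  expect_equal(nrow(sel), 0)
  expect_error(rank_and_filter(tab, top_k = 0),
               class = "regiqa_precondition_error")
})

test_that("REG Ratios reproduce the worked integer examples", {
  tab <- as_reg_table(tibble::tibble(term = c("V_cl(A,B)", "V_xc(A,B)"),
                                     reg = c(0.67, 0.21)))
  r1 <- reg_ratio(tab, reference_reg = 4.7)
  expect_equal(r1$ratio[r1$term == "V_cl(A,B)"], 4.7 / 0.67)
  expect_equal(r1$ratio_printed[r1$term == "V_cl(A,B)"], 7)
  r2 <- reg_ratio(tab, reference_reg = 3.6)
  expect_equal(r2$ratio_printed[r2$term == "V_xc(A,B)"], 17)
  # self-ratio of the reference term is exactly 1
  self <- reg_ratio(as_reg_table(tibble::tibble(term = "V_cl(a1,b2)",
                                                reg = 2.34)),
                    reference_reg = 2.34)
  expect_identical(self$ratio, 1)
  expect_error(reg_ratio(tab, reference_reg = -1),
               class = "regiqa_precondition_error")
  expect_error(reg_ratio(tab, reference_reg = 0),
               class = "regiqa_precondition_error")
})

test_that("near-zero REG values are flagged unstable but still reported", {
  tab <- as_reg_table(tibble::tibble(term = c("V_cl(A,B)", "V_xc(A,B)"),
                                     reg = c(1e-9, 0.5)))
  r <- reg_ratio(tab, reference_reg = 2)
  expect_true(r$unstable[r$term == "V_cl(A,B)"])
  expect_false(r$unstable[r$term == "V_xc(A,B)"])
  expect_equal(r$ratio[r$term == "V_cl(A,B)"], 2e9)
})

test_that("cross-system comparison recovers the published substituent trend", {
  # ratios recomputed from the published fragment REG values and each
  # balance's atomistic REG maximum, ordered from electron-withdrawing
  # NO2 to electron-donating NMe2
  order_2y <- c("2-NO2", "2-CN", "2-H", "2-OMe", "2-NMe2")
  iqf <- iqf_2y()
  atom <- tab_2y()
  tables <- lapply(order_2y, function(b) {
    ref <- max(published_reg(atom, b)$reg)
    frag <- as_reg_table(iqf[iqf$balance == b, c("term", "reg")])
    reg_ratio(frag, reference_reg = ref)
  })
  names(tables) <- order_2y
  cmp <- cross_system_compare(tables, keys = "V_xc(E,F)")
  expect_equal(cmp$trend, "increasing")
  expect_equal(round(unlist(cmp[1, order_2y]), 0) >= c(20, 23, 31, 40, 76),
               setNames(rep(TRUE, 5), order_2y))

  # degenerate single-system comparison
  single <- cross_system_compare(tables["2-H"], keys = "V_xc(E,F)")
  expect_true(is.na(single$trend))

  # constructed three-system fixture
  mk <- function(r) tibble::tibble(term = "V_cl(A,B)", ratio = r)
  expect_equal(cross_system_compare(list(s1 = mk(2), s2 = mk(4),
                                         s3 = mk(8)))$trend,
               "increasing")
  expect_equal(cross_system_compare(list(s1 = mk(8), s2 = mk(4),
                                         s3 = mk(2)))$trend,
               "decreasing")
  expect_equal(cross_system_compare(list(s1 = mk(2), s2 = mk(8),
                                         s3 = mk(4)))$trend,
               "mixed")
  expect_error(cross_system_compare(list(s1 = mk(2),
                                         s2 = mk(4)[0, ]),
                                    keys = "V_cl(A,B)"),
               "s2", class = "regiqa_schema_error")
})
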