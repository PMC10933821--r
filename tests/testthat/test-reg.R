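test_that("exact affine terms recover their slopes with perfect correlation", {
  prof <- affine_profile(slopes = c(0.3, 0.7), offsets = c(1.5, -2.0))
  tab <- reg_values(prof)
  expect_equal(sort(tab$reg), c(0.3, 0.7))
  expect_equal(tab$pearson_r, c(1, 1))
  expect_true(all(tab$admissible))
  expect_equal(tab$rank, 1:2)
})

test_that("the total regressed on itself has slope and correlation one", {
  prof <- affine_profile(slopes = c(0.4, 0.6))
  tab <- reg_values(prof, include_total = TRUE)
  tot <- tab[tab$term_type == "E_tot", ]
  expect_equal(tot$reg, 1)
  expect_equal(tot$pearson_r, 1)
})

test_that("closed-form slope agrees with an independent least-squares fit", {
  for (seed in 1:100) {
    gen <- synthetic_profile(n_atoms = 3, m_points = 6,
                             noise_sigma = 1e-4, seed = seed,
                             with_atoms = FALSE)
    tab <- reg_values(gen$profile)
    lbl <- term_label(gen$profile$term_type, gen$profile$atom_a,
                      gen$profile$atom_b)
    e_tot <- gen$truth$e_tot
    for (i in seq_len(nrow(tab))) {
      y <- gen$profile$energy[lbl == tab$term[i]] # rows are point-ordered
      fit <- stats::lm(y ~ e_tot)
      expect_equal(tab$reg[i], unname(stats::coef(fit)[2]),
                   tolerance = 1e-10)
    }
  }
})

test_that("REG values are invariant to constant offsets of any series", {
  gen <- synthetic_profile(n_atoms = 4, m_points = 8, noise_sigma = 1e-5,
                           seed = 17, with_atoms = FALSE)
  tab0 <- reg_values(gen$profile)
  shifted <- tibble::as_tibble(gen$profile)
  bump <- shifted$term_type == "V_cl" & shifted$atom_a == "c1" &
    shifted$atom_b == "n2"
  shifted$energy[bump] <- shifted$energy[bump] + 123.456
  tab1 <- reg_values(energy_profile(shifted))
  expect_equal(tab1$reg[match(tab0$term, tab1$term)], tab0$reg)
})

test_that("scaling one term scales its REG value by the same factor", {
  gen <- synthetic_profile(n_atoms = 4, m_points = 8, noise_sigma = 1e-5,
                           seed = 19, with_atoms = FALSE)
  tab0 <- reg_values(gen$profile)
  scaled <- tibble::as_tibble(gen$profile)
  hit <- scaled$term_type == "V_xc" & scaled$atom_a == "c1" &
    scaled$atom_b == "n2"
  scaled$energy[hit] <- scaled$energy[hit] * 3.5
  # E_tot rows are kept as an independent input series
  tab1 <- reg_values(energy_profile(scaled))
  key <- "V_xc(c1,n2)"
  expect_equal(tab1$reg[tab1$term == key], 3.5 * tab0$reg[tab0$term == key],
               tolerance = 1e-12)
})

test_that("fragment REG equals the sum of member-pair REG values", {
  gen <- synthetic_profile(n_atoms = 6, m_points = 10, noise_sigma = 1e-4,
                           seed = 23, with_atoms = FALSE)
  scheme <- fragment_scheme(list(G1 = c("c1", "n2", "o3"),
                                 G2 = c("h4", "c5", "n6")))
  atom_tab <- reg_values(gen$profile)
  frag_tab <- reg_values(aggregate_fragments(gen$profile, scheme))
  for (tt in c("V_cl", "V_xc", "V_D3")) {
    members <- atom_tab$term_type == tt &
      ((atom_tab$atom_a %in% scheme$G1 & atom_tab$atom_b %in% scheme$G2) |
         (atom_tab$atom_a %in% scheme$G2 & atom_tab$atom_b %in% scheme$G1))
    frag_val <- frag_tab$reg[frag_tab$term_type == tt]
    expect_equal(frag_val, sum(atom_tab$reg[members]), tolerance = 1e-10)
  }
})

test_that("degenerate segments and inputs are refused", {
  prof <- toy_profile()
  expect_error(reg_values(prof, segment = c(1, 2)),
               "3", class = "regiqa_precondition_error")
  flat <- tibble::as_tibble(affine_profile(c(0.5, 0.5),
                                           e_tot = c(0.01, 0.01, 0.01, 0.01)))
  expect_error(reg_values(energy_profile(flat)),
               "variance", class = "regiqa_precondition_error")
})

test_that("zero-variance terms get slope 0 and an undefined correlation", {
  df <- toy_terms()
  df$energy[df$term_type == "V_xc"] <- -0.123
  tab <- reg_values(energy_profile(df))
  row <- tab[tab$term_type == "V_xc", ]
  expect_equal(row$reg, 0)
  expect_true(is.na(row$pearson_r))
  expect_false(row$admissible)
})

test_that("segment selection restricts the points used", {
  gen <- synthetic_profile(n_atoms = 3, m_points = 10, noise_sigma = 1e-4,
                           seed = 31, with_atoms = FALSE)
  whole <- reg_values(gen$profile)
  part <- reg_values(gen$profile, segment = c(4, 10))
  expect_equal(attr(part, "m_points"), 7)
  expect_false(isTRUE(all.equal(whole$reg, part$reg[match(whole$term,
                                                          part$term)])))
})

test_that("glance reports the partition sum and table shape", {
  gen <- synthetic_profile(n_atoms = 4, m_points = 6, seed = 37,
                           with_atoms = FALSE)
  tab <- reg_values(gen$profile)
  g <- glance(tab)
  expect_equal(g$sum_reg, 1, tolerance = 1e-10)
  expect_equal(g$n_terms, nrow(tab))
  td <- tidy(tab)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "term_type", "atom_a", "atom_b", "reg",
                     "pearson_r", "r_squared", "admissible", "rank"))
})
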