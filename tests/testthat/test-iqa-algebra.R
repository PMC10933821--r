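test_that("total_energy sums intra and unordered-pair inter terms", {
  df <- tibble::tibble(
    point_index = rep(1:3, each = 3), s = rep(1:3, each = 3),
    term_type = rep(c("E_intra", "E_intra", "V_inter"), 3),
    atom_a = rep(c("a1", "b2", "a1"), 3),
    atom_b = rep(c(NA, NA, "b2"), 3),
    energy = rep(c(-1.0, -2.0, -0.5), 3)
  )
  expect_equal(total_energy(energy_profile(df), point = 1), -3.5)
  # single atom: no interatomic contribution
  single <- tibble::tibble(point_index = 1:3, s = 1:3,
                           term_type = "E_intra", atom_a = "a1",
                           atom_b = NA_character_, energy = -0.5)
  expect_equal(total_energy(energy_profile(single), point = 2), -0.5)
})

test_that("reconstructed totals match the generator's stored E_tot", {
  gen <- synthetic_profile(n_atoms = 10, m_points = 5, noise_sigma = 1e-4,
                           seed = 3)
  tot <- total_energy(gen$profile)
  expect_equal(tot$e_tot, gen$truth$e_tot, tolerance = 1e-12)
  # 10 atoms -> 45 pairs of each interatomic type behind each total
  expect_equal(sum(gen$profile$term_type == "V_cl") / 5, 45)
})

test_that("compose_inter sums components and cross-checks raw identities", {
  expect_equal(compose_inter(-0.010, -0.004, -0.001), -0.015)
  expect_equal(compose_inter(-0.010, -0.004), -0.014)
  raw <- list(v_nn = 0.5, v_en = -0.3, v_ne = -0.25, v_coul = 0.04,
              v_x = -0.003, v_c = -0.001)
  expect_equal(compose_inter(-0.010, -0.004, raw = raw, tolerance = 1e-10),
               -0.014)
  raw$v_coul <- raw$v_coul + 1e-6
  expect_error(compose_inter(-0.010, -0.004, raw = raw, tolerance = 1e-8),
               class = "regiqa_inconsistency_error")
})

test_that("charge-transfer split follows q_A q_B / r and closes exactly", {
  split <- ct_pl_split(-0.200, 0.5, -0.5, 2.0)
  expect_equal(split$v_ct, -0.125)
  expect_equal(split$v_pl, -0.075)
  # zero-charge limit
  z <- ct_pl_split(-0.2, 0, 0.7, 3.1)
  expect_equal(z$v_ct, 0)
  expect_equal(z$v_pl, -0.2)
  expect_error(ct_pl_split(-0.2, 0.5, -0.5, 0),
               class = "regiqa_precondition_error")
  # closure property over random draws: the remainder definition closes
  # to within one ulp of v_cl
  set.seed(99)
  n <- 1000
  s <- ct_pl_split(rnorm(n), rnorm(n), rnorm(n), runif(n, 0.5, 10))
  gap <- abs((s$v_ct + s$v_pl) - s$v_cl)
  expect_lt(max(gap / pmax(abs(s$v_cl), abs(s$v_ct), 1)),
            .Machine$double.eps)
})

test_that("add_ct_pl augments a profile consistently with its atoms table", {
  gen <- synthetic_profile(n_atoms = 4, m_points = 5, seed = 8)
  aug <- add_ct_pl(gen$profile)
  atoms <- profile_atoms(aug)
  vct <- aug[aug$term_type == "V_ct", ]
  vpl <- aug[aug$term_type == "V_pl", ]
  vcl <- aug[aug$term_type == "V_cl", ]
  expect_equal(nrow(vct), nrow(vcl))
  expect_equal(vct$energy + vpl$energy, vcl$energy)
  # spot-check one pair against a direct evaluation
  a1 <- atoms[atoms$point_index == 3 & atoms$atom == "c1", ]
  a2 <- atoms[atoms$point_index == 3 & atoms$atom == "n2", ]
  r <- sqrt((a1$x - a2$x)^2 + (a1$y - a2$y)^2 + (a1$z - a2$z)^2)
  got <- vct$energy[vct$point_index == 3 & vct$atom_a == "c1" &
                      vct$atom_b == "n2"]
  expect_equal(got, a1$q * a2$q / r)
})

test_that("fragment aggregation matches singleton, two-term and brute-force sums", {
  prof <- toy_profile()
  frag <- aggregate_fragments(prof, fragment_scheme(list(G1 = "a1",
                                                         G2 = "b2")))
  expect_equal(frag$energy[frag$term_type == "V_xc"],
               prof$energy[prof$term_type == "V_xc"])

  # two-pair sum into one fragment term
  df <- tibble::tibble(
    point_index = rep(1:3, each = 3), s = rep(1:3, each = 3),
    term_type = "V_cl",
    atom_a = rep(c("a1", "b2", "a1"), 3),
    atom_b = rep(c("b2", "c3", "c3"), 3),
    energy = rep(c(-0.01, -0.02, -0.07), 3)
  )
  fr <- aggregate_fragments(energy_profile(df),
                            fragment_scheme(list(G1 = c("a1", "c3"),
                                                 G2 = "b2")))
  expect_equal(unique(fr$energy[fr$term_type == "V_cl"]), -0.03)

  # brute-force double loop oracle on a seeded 8-atom profile
  gen <- synthetic_profile(n_atoms = 8, m_points = 4, noise_sigma = 1e-4,
                           seed = 21)
  g1 <- c("c1", "h4", "c5")
  g2 <- c("n2", "o3", "n6")
  frag <- aggregate_fragments(gen$profile,
                              fragment_scheme(list(G1 = g1, G2 = g2)))
  prof <- tibble::as_tibble(gen$profile)
  for (tt in c("V_cl", "V_xc", "V_D3")) {
    for (p in 1:4) {
      brute <- 0
      for (a in g1) for (b in g2) {
        hit <- prof$term_type == tt & prof$point_index == p &
          ((prof$atom_a == a & prof$atom_b == b) |
             (prof$atom_a == b & prof$atom_b == a))
        brute <- brute + sum(prof$energy[hit], na.rm = TRUE)
      }
      got <- frag$energy[frag$term_type == tt & frag$point_index == p]
      expect_equal(got, brute, tolerance = 1e-14)
    }
  }
})

test_that("aggregation is symmetric in group order and rejects bad schemes", {
  gen <- synthetic_profile(n_atoms = 5, m_points = 4, seed = 5)
  s1 <- fragment_scheme(list(P = c("c1", "n2"), Q = c("o3", "h4")))
  s2 <- fragment_scheme(list(Q = c("o3", "h4"), P = c("c1", "n2")))
  f1 <- aggregate_fragments(gen$profile, s1)
  f2 <- aggregate_fragments(gen$profile, s2)
  expect_equal(tibble::as_tibble(f1), tibble::as_tibble(f2))
  expect_error(
    aggregate_fragments(gen$profile,
                        structure(list(P = "c1", Q = c("c1", "n2")),
                                  class = "fragment_scheme")),
    class = "regiqa_schema_error")
})

test_that("group terms plus within-group terms reproduce E_tot", {
  gen <- synthetic_profile(n_atoms = 6, m_points = 5, noise_sigma = 1e-5,
                           seed = 13)
  groups <- list(G1 = c("c1", "n2", "o3"), G2 = c("h4", "c5", "n6"))
  frag <- aggregate_fragments(gen$profile, fragment_scheme(groups))
  prof <- tibble::as_tibble(gen$profile)
  in_group <- function(a, b, g) a %in% g & b %in% g
  for (p in 1:5) {
    at <- prof[prof$point_index == p, ]
    within <- at$term_type %in% c("V_cl", "V_xc", "V_D3") &
      (in_group(at$atom_a, at$atom_b, groups$G1) |
         in_group(at$atom_a, at$atom_b, groups$G2))
    total <- sum(at$energy[at$term_type == "E_intra"]) +
      sum(at$energy[within]) +
      sum(frag$energy[frag$point_index == p & frag$term_type != "E_tot"])
    expect_equal(total, at$energy[at$term_type == "E_tot"],
                 tolerance = 1e-10)
  }
})
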