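test_that("omega_0_10 is the first 10 m ring of the profile", {
  p <- random_pattern(200, seed = 111)
  expect_equal(omega_0_10(p),
               omega_profile(p, ring_ladder(10, 5))$values[1])
})

test_that("duplicating a species shifts genus Omega_0-10 by exactly the coincident-pair term", {
  # Pooling a species with an exact copy of itself doubles counts,
  # areas and lambda, which alone would leave Omega fixed; but every
  # stem also gains its own zero-distance copy as a neighbour (the
  # package counts coincident stems, by design), adding exactly
  # n / (2 * A1 * lambda1) to the pooled value.
  w <- plot_window()
  p <- simulate_thomas(20, 8, 400, w, seed = 121)
  df <- rbind(data.frame(species = "S1", genus = "G", x = p$x, y = p$y,
                         dbh = 2),
              data.frame(species = "S2", genus = "G", x = p$x, y = p$y,
                         dbh = 2))
  tab <- census_table(df, w)
  g <- omega_0_10(select_group(tab, "genus", "G"))
  s <- omega_0_10(select_group(tab, "species", "S1"))
  a1 <- ring_counts(p, p, ring_ladder(10, 1), exclude_self = TRUE)$areas
  expect_equal(g, s + npoints(p) / (2 * a1 * intensity(p)),
               tolerance = 1e-9)
})

test_that("a single-species genus row equals its species row", {
  w <- plot_window()
  p <- simulate_thomas(20, 10, 300, w, seed = 131)
  tab <- census_table(data.frame(species = "S1", genus = "G1",
                                 x = p$x, y = p$y, dbh = 3), w)
  agg <- aggregation_table(tab)
  expect_equal(agg$omega_0_10[agg$level == "genus"],
               agg$omega_0_10[agg$level == "species"])
  expect_error(aggregation_table(tab, species_codes = "nope"), "unknown")
})

test_that("pooling segregated congeners dilutes aggregation intensity", {
  w <- plot_window()
  s1 <- simulate_thomas(25, 8, 600, w, parent_placement = "left_half",
                        seed = 141)
  s2 <- simulate_thomas(25, 8, 400, w, parent_placement = "right_half",
                        seed = 142)
  tab <- census_table(rbind(
    data.frame(species = "S1", genus = "G", x = s1$x, y = s1$y, dbh = 2),
    data.frame(species = "S2", genus = "G", x = s2$x, y = s2$y, dbh = 2)),
    w)
  agg <- aggregation_table(tab)
  g <- agg$omega_0_10[agg$level == "genus"]
  sp <- agg$omega_0_10[agg$level == "species"]
  expect_lt(g, min(sp))
})

test_that("omega_by_dbh applies the class floor and reduces to omega_0_10", {
  w <- plot_window()
  p <- simulate_thomas(25, 10, 300, w, seed = 151)
  # all stems in one 3 cm class
  tab1 <- census_table(data.frame(species = "S", genus = "G",
                                  x = p$x, y = p$y, dbh = 2), w)
  ser <- omega_by_dbh(tab1, "species", "S", min_count = 50)
  expect_equal(nrow(ser), 1)
  expect_equal(ser$omega_0_10, omega_0_10(p))
  expect_equal(ser$n_stems, 300)

  # a 49-stem class is dropped under the 50-stem floor
  dbh <- c(rep(2, 251), rep(5, 49))
  tab2 <- census_table(data.frame(species = "S", genus = "G",
                                  x = p$x, y = p$y, dbh = dbh), w)
  ser2 <- omega_by_dbh(tab2, "species", "S", min_count = 50)
  expect_equal(ser2$dbh_lo, 1)
  ser3 <- omega_by_dbh(tab2, "species", "S", min_count = 20)
  expect_equal(ser3$dbh_lo, c(1, 4))

  # no qualifying class -> empty series, not an error
  expect_equal(nrow(omega_by_dbh(tab1, "species", "S",
                                 min_count = 1000)), 0)
})

test_that("group-lambda mode rescales class Omega by relative density", {
  w <- plot_window()
  p <- simulate_thomas(25, 10, 400, w, seed = 161)
  dbh <- rep(c(2, 5), each = 200)
  tab <- census_table(data.frame(species = "S", genus = "G",
                                 x = p$x, y = p$y, dbh = dbh), w)
  cls <- omega_by_dbh(tab, "species", "S", min_count = 50,
                      lambda = "class")
  grp <- omega_by_dbh(tab, "species", "S", min_count = 50,
                      lambda = "group")
  # classes hold half the stems each, so group-lambda halves the values
  expect_equal(grp$omega_0_10, cls$omega_0_10 / 2, tolerance = 1e-9)
})

test_that("size-stratified clustering yields a declining Omega-DBH series", {
  # small stems dispersed tightly around parents, large stems widely
  cfg <- community_config(
    plot_window(),
    list(species_spec("S1", "G1", 2400, kappa = 30, sigma = 5,
                      dbh_shape = "l_shaped", dbh_scale = 4,
                      sigma_by_dbh = c(3, 120))),
    seed = 171)
  tab <- generate_community(cfg)
  ser <- omega_by_dbh(tab, "genus", "G1", bin_width = 3, min_count = 50)
  expect_gte(nrow(ser), 3)
  first3 <- ser$omega_0_10[1:3]
  expect_true(all(diff(first3) < 0))
})

test_that("association matrices hold one classified cell per pair", {
  com <- generate_community(default_community_config(seed = 9))
  genera <- sort(unique(com$records$genus))
  cmb <- utils::combn(genera, 2)
  pairs <- data.frame(code_a = cmb[1, ], code_b = cmb[2, ],
                      level = "genus")
  am <- association_matrix(com, pairs, ring_ladder(10, 3),
                           n_sim = 19, seed = 181)
  expect_equal(nrow(am$pairs), 6)  # C(4,2)
  expect_length(am$cells, 6)
  expect_s3_class(am$cells[[1]], "classified_profile")
  expect_equal(am$pairs$n_positive + am$pairs$n_independent +
                 am$pairs$n_negative, rep(3L, 6))
  dup <- rbind(pairs, data.frame(code_a = pairs$code_b[1],
                                 code_b = pairs$code_a[1],
                                 level = "genus"))
  expect_error(association_matrix(com, dup, ring_ladder(10, 2),
                                  n_sim = 9, seed = 1), "distinct")
})
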