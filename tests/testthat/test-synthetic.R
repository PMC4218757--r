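test_that("thomas clusters honour abundance, placement and boundaries", {
  w <- plot_window()
  expect_equal(npoints(simulate_thomas(5, 10, 0, w, seed = 1)), 0)
  p <- simulate_thomas(30, 10, 750, w, seed = 2)
  expect_equal(npoints(p), 750)
  expect_true(all(in_window <- p$x >= 0 & p$x <= 400 &
                    p$y >= 0 & p$y <= 500))

  # degenerate cluster: one parent, sd 1 cm -> everything within 1 m
  d <- simulate_thomas(1, 0.01, 200, w, seed = 3)
  par <- attr(d, "parents")
  expect_true(all(sqrt((d$x - par[1, 1])^2 +
                         (d$y - par[1, 2])^2) < 1))
  expect_gt(omega_0_10(d), 100)

  # parent placement restricts the parents, not the offspring
  ph <- simulate_thomas(20, 5, 300, w, parent_placement = "left_half",
                        seed = 4)
  expect_true(all(attr(ph, "parents")[, 1] <= 200))
  pc <- simulate_thomas(20, 5, 300, w, parent_placement = "corner_se",
                        seed = 5)
  expect_true(all(attr(pc, "parents")[, 1] >= 200 &
                    attr(pc, "parents")[, 2] <= 250))
  expect_error(simulate_thomas(20, 5, 300, w,
                               parent_placement = "middle", seed = 6),
               "placement")
})

test_that("tighter clusters are more aggregated", {
  med_omega <- function(sigma) {
    vals <- vapply(1:20, function(i)
      omega_0_10(simulate_thomas(50, sigma, 1000, plot_window(),
                                 seed = 1000 + i)), 0)
    median(vals)
  }
  expect_gt(med_omega(5), med_omega(20))
})

test_that("diameter samples respect the floor, cap and declining shape", {
  expect_length(sample_dbh("l_shaped", 2, 0), 0)
  x <- sample_dbh("l_shaped", 2, 1e4, seed = 11)
  expect_true(all(x >= 1 & x <= 60))
  counts <- table(cut(x, breaks = seq(1, 11, by = 2), right = FALSE))
  expect_true(all(diff(as.numeric(counts)) < 0))

  y <- sample_dbh("reverse_j", 10, 1e4, seed = 12, weibull_shape = 0.9)
  expect_true(all(y >= 1 & y <= 60))
  # reverse-J keeps a heavier large-stem tail than the L shape
  expect_gt(mean(y > 20), mean(x > 20))
})

test_that("generated communities carry exact abundances and seeds govern everything", {
  cfg <- default_community_config(seed = 1)
  tab <- generate_community(cfg)
  expect_equal(nrow(tab$records), 13362)
  want <- c(A1 = 4478, A2 = 2557, B1 = 2118, B2 = 1302,
            C1 = 800, C2 = 532, D1 = 1352, D2 = 223)
  got <- table(tab$records$species)
  expect_equal(as.numeric(got[names(want)]), as.numeric(want))

  tab2 <- generate_community(default_community_config(seed = 1))
  expect_identical(tab$records, tab2$records)
  tab3 <- generate_community(default_community_config(seed = 2))
  expect_false(identical(tab$records$x, tab3$records$x))
  expect_equal(table(tab3$records$species), got)
})

test_that("a csr species spec routes through simulate_csr exactly", {
  w <- plot_window()
  cfg <- community_config(
    w, list(species_spec("S1", "G1", 150, process = "csr"),
            species_spec("S2", "G1", 80, process = "csr")),
    seed = 21)
  tab <- generate_community(cfg)
  seeds <- derive_seeds(21, 4)
  ref1 <- simulate_csr(150, w, seed = seeds[1])
  ref2 <- simulate_csr(80, w, seed = seeds[3])
  expect_identical(tab$records$x[1:150], ref1$x)
  expect_identical(tab$records$y[151:230], ref2$y)
})

test_that("shared parents put congeners on the same cluster centers", {
  w <- plot_window()
  cfg <- community_config(
    w, list(species_spec("S1", "G1", 300, kappa = 15, sigma = 6),
            species_spec("S2", "G1", 200, sigma = 6,
                         parent_placement = list(shared_with = "S1"))),
    seed = 31)
  tab <- generate_community(cfg)
  p1 <- select_group(tab, "species", "S1")
  p2 <- select_group(tab, "species", "S2")
  # congeners sharing parents attract instead of repelling
  expect_gt(g12_profile(p1, p2, ring_ladder(10, 1))$values, 2)
  bad <- community_config(
    w, list(species_spec("S2", "G1", 100,
                         parent_placement = list(shared_with = "S9"))),
    seed = 32)
  expect_error(generate_community(bad), "S9")
})

test_that("clustered species read as aggregated nearly always", {
  hits <- vapply(1:30, function(i)
    omega_0_10(simulate_thomas(50, 5, 1000, plot_window(),
                               seed = 3000 + i)) > 1, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("the packaged community reproduces the community-level headline", {
  # every species aggregated within 10 m; pooling dilutes aggregation
  # for the segregated genera; the half-plot congener pair repels
  cfg <- default_community_config(seed = 1)
  tab <- generate_community(cfg)
  la <- ring_ladder(10, 1)
  env_seeds <- derive_seeds(401, 9)
  omegas <- c()
  for (s in c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2")) {
    p <- select_group(tab, "species", s)
    cp <- univariate_envelope(p, la, n_sim = 99,
                              seed = env_seeds[match(s, c("A1", "A2",
                                "B1", "B2", "C1", "C2", "D1", "D2"))])
    expect_identical(cp$labels[1], "aggregated")
    omegas[s] <- cp$profile$values[1]
  }
  for (g in cfg$segregated_genera) {
    sp <- unique(tab$records$species[tab$records$genus == g])
    gp <- omega_0_10(select_group(tab, "genus", g))
    expect_lt(gp, min(omegas[sp]))
  }
  cp12 <- bivariate_envelope(select_group(tab, "species", "B1"),
                             select_group(tab, "species", "B2"),
                             ring_ladder(10, 5), n_sim = 99,
                             seed = env_seeds[9])
  expect_true(all(cp12$labels[1:3] == "negative"))
})
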