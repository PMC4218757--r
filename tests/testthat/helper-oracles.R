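# Independent oracles and fixture builders shared across the suite.

plot_window <- function() census_window(0, 0, 400, 500)

# Brute-force per-ring counts/areas: plain R distance loop, one focal
# point at a time.  Deliberately independent of the compiled kernels
# (areas go through the exported scalar annulus_area_in_window, whose
# own correctness is checked against dart throwing).
oracle_ring_counts <- function(focal, neighbor, ladder,
                               exclude_self = FALSE) {
  counts <- numeric(ladder$n_rings)
  areas <- numeric(ladder$n_rings)
  for (i in seq_along(focal$x)) {
    d <- sqrt((neighbor$x - focal$x[i])^2 + (neighbor$y - focal$y[i])^2)
    if (exclude_self) d <- d[-i]
    for (k in seq_len(ladder$n_rings)) {
      counts[k] <- counts[k] +
        sum(d >= ladder$r_lo[k] & d < ladder$r_hi[k])
      areas[k] <- areas[k] +
        annulus_area_in_window(c(focal$x[i], focal$y[i]),
                               ladder$r_lo[k], ladder$r_hi[k],
                               focal$window)
    }
  }
  list(counts = counts, areas = areas)
}

oracle_omega <- function(p, ladder) {
  rc <- oracle_ring_counts(p, p, ladder, exclude_self = TRUE)
  (rc$counts / rc$areas) / intensity(p)
}

oracle_g12 <- function(p1, p2, ladder) {
  rc <- oracle_ring_counts(p1, p2, ladder, exclude_self = FALSE)
  (rc$counts / rc$areas) / intensity(p2)
}

# Rejection-sampling (dart-throwing) annulus area: uniform darts over
# the bounding box of the annulus clipped to the window.
dart_annulus_area <- function(center, r_in, r_out, window,
                              n_darts = 1e6, seed = 1, chunk = 2e6) {
  bx0 <- max(window$x_min, center[1] - r_out)
  bx1 <- min(window$x_max, center[1] + r_out)
  by0 <- max(window$y_min, center[2] - r_out)
  by1 <- min(window$y_max, center[2] + r_out)
  box <- (bx1 - bx0) * (by1 - by0)
  set.seed(seed)
  hits <- 0; thrown <- 0
  while (thrown < n_darts) {
    m <- min(chunk, n_darts - thrown)
    x <- runif(m, bx0, bx1); y <- runif(m, by0, by1)
    d2 <- (x - center[1])^2 + (y - center[2])^2
    hits <- hits + sum(d2 >= r_in^2 & d2 < r_out^2)
    thrown <- thrown + m
  }
  box * hits / thrown
}

random_pattern <- function(n, window = plot_window(), seed = 1) {
  simulate_csr(n, window, seed = seed)
}

# small census data.frame used by several io tests
toy_census_df <- function() {
  data.frame(species = c("A1", "A1", "A1", "A2", "A2"),
             genus = "GenA",
             x = c(10, 20, 30, 40, 50),
             y = c(10, 20, 30, 40, 50),
             dbh = c(1, 2.5, 4, 8, 16))
}
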