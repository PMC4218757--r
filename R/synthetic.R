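#' Specification of one synthetic species
#'
#' Describes how the stems of one species are generated: total
#' abundance, the spatial process (CSR or a conditional-total Thomas
#' cluster process), where the cluster parents may sit (to build
#' within-genus segregation: opposite plot halves, opposite corners, a
#' shared parent set, or the whole plot), and the diameter
#' distribution shape (monotone-declining "L-shaped" or heavier-tailed
#' "reverse-J").
#'
#' @param species,genus Short code strings.
#' @param abundance Exact number of stems to generate.
#' @param process `"thomas"` (default) or `"csr"`.
#' @param kappa Number of cluster parents (Thomas only).
#' @param sigma Isotropic Gaussian dispersal scale around parents, m.
#' @param parent_placement One of `"uniform"`, `"left_half"`,
#'   `"right_half"`, `"corner_sw"`, `"corner_se"`, `"corner_nw"`,
#'   `"corner_ne"` (`"corner"` is an alias for `"corner_sw"`), or
#'   `list(shared_with = "<species code>")` to reuse another species'
#'   parents.
#' @param dbh_shape `"l_shaped"` (1 + truncated exponential) or
#'   `"reverse_j"` (1 + truncated Weibull with shape < 1).
#' @param dbh_scale Scale of the diameter distribution, cm.
#' @param weibull_shape Weibull shape parameter for `"reverse_j"`
#'   (< 1 for a declining size structure).
#' @param sigma_by_dbh Optional length-2 vector `c(sd_small, sd_large)`:
#'   per-stem dispersal sd interpolated linearly in DBH between the
#'   1 cm census floor and the 60 cm cap, producing size-dependent
#'   aggregation (small stems tight, large stems diffuse).
#' @return A `species_spec` list.
#' @export
species_spec <- function(species, genus, abundance,
                         process = c("thomas", "csr"),
                         kappa = 25, sigma = 10,
                         parent_placement = "uniform",
                         dbh_shape = c("l_shaped", "reverse_j"),
                         dbh_scale = 3, weibull_shape = 0.9,
                         sigma_by_dbh = NULL) {
  process <- match.arg(process)
  dbh_shape <- match.arg(dbh_shape)
  stopifnot(abundance >= 0, sigma > 0, kappa >= 1, dbh_scale > 0)
  structure(list(species = as.character(species),
                 genus = as.character(genus),
                 abundance = as.integer(abundance), process = process,
                 kappa = as.integer(kappa), sigma = sigma,
                 parent_placement = parent_placement,
                 dbh_shape = dbh_shape, dbh_scale = dbh_scale,
                 weibull_shape = weibull_shape,
                 sigma_by_dbh = sigma_by_dbh),
            class = "species_spec")
}

# sub-rectangle of the window where cluster parents may sit
placement_region <- function(placement, window) {
  w <- window
  mx <- (w$x_min + w$x_max) / 2
  my <- (w$y_min + w$y_max) / 2
  switch(placement,
    uniform    = w,
    left_half  = census_window(w$x_min, w$y_min, mx, w$y_max),
    right_half = census_window(mx, w$y_min, w$x_max, w$y_max),
    corner     = ,
    corner_sw  = census_window(w$x_min, w$y_min, mx, my),
    corner_se  = census_window(mx, w$y_min, w$x_max, my),
    corner_nw  = census_window(w$x_min, my, mx, w$y_max),
    corner_ne  = census_window(mx, my, w$x_max, w$y_max),
    stop("unknown parent placement '", placement, "'"))
}

# reflect coordinates into [lo, hi] (repeated reflection at the walls)
reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  lo + ifelse(v > span, 2 * span - v, v)
}

#' Conditional-total Thomas cluster process
#'
#' `kappa` parent locations are placed uniformly in the region given
#' by `parent_placement`; each of exactly `abundance` offspring picks
#' a parent uniformly and is displaced by an isotropic Gaussian of sd
#' `sigma`, then reflected at the window boundaries.  Fixing the total
#' (rather than drawing Poisson cluster sizes) departs from the
#' textbook Thomas process so that generated communities carry exact
#' prescribed abundances.
#'
#' @param kappa Number of parents (>= 1).
#' @param sigma Gaussian dispersal sd, m (ignored per-stem when
#'   `sigma_each` is given).
#' @param abundance Number of offspring returned.
#' @param window A [census_window()].
#' @param parent_placement See [species_spec()].
#' @param seed Optional seed.
#' @param boundary `"reflect"` (default, keeps abundance exact) or
#'   `"torus"` (wraps displacements).
#' @param sigma_each Optional per-offspring dispersal sd vector
#'   (length `abundance`), e.g. to make aggregation decay with stem
#'   size.
#' @param parents Optional 2-column matrix of parent coordinates to
#'   reuse (overrides `kappa`/`parent_placement`).
#' @return A [ppattern()]; the parent coordinates are attached as
#'   attribute `"parents"`.
#' @export
simulate_thomas <- function(kappa, sigma, abundance, window,
                            parent_placement = "uniform", seed = NULL,
                            boundary = c("reflect", "torus"),
                            sigma_each = NULL, parents = NULL) {
  boundary <- match.arg(boundary)
  stopifnot(abundance >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(parents)) {
    stopifnot(kappa >= 1)
    reg <- placement_region(parent_placement, window)
    parents <- cbind(runif(kappa, reg$x_min, reg$x_max),
                     runif(kappa, reg$y_min, reg$y_max))
  }
  n <- abundance
  sd_i <- if (is.null(sigma_each)) rep(sigma, n) else {
    stopifnot(length(sigma_each) == n)
    sigma_each
  }
  idx <- if (n) sample.int(nrow(parents), n, replace = TRUE) else integer()
  x <- parents[idx, 1] + rnorm(n, 0, sd_i)
  y <- parents[idx, 2] + rnorm(n, 0, sd_i)
  if (boundary == "reflect") {
    x <- reflect_into(x, window$x_min, window$x_max)
    y <- reflect_into(y, window$y_min, window$y_max)
  } else {
    wx <- window$x_max - window$x_min
    wy <- window$y_max - window$y_min
    x <- window$x_min + (x - window$x_min) %% wx
    y <- window$y_min + (y - window$y_min) %% wy
  }
  p <- ppattern(x, y, window)
  attr(p, "parents") <- parents
  p
}

#' Sample stem diameters
#'
#' Draws DBH values (cm) at or above the 1 cm census floor with a
#' monotone-declining size-class histogram.  `"l_shaped"` is 1 + an
#' exponential of the given scale; `"reverse_j"` is 1 + a Weibull with
#' shape < 1, which keeps a heavier tail of large stems.  Both are
#' truncated at 60 cm (a desk-scale cap) by inverse-CDF sampling.
#'
#' @param shape `"l_shaped"` or `"reverse_j"`.
#' @param scale Distribution scale, cm.
#' @param n Number of draws.
#' @param seed Optional seed.
#' @param weibull_shape Weibull shape for `"reverse_j"`.
#' @param cap Upper truncation, cm.
#' @return Numeric vector of length `n`, values in `[1, cap]`.
#' @export
sample_dbh <- function(shape = c("l_shaped", "reverse_j"), scale, n,
                       seed = NULL, weibull_shape = 0.9, cap = 60) {
  shape <- match.arg(shape)
  stopifnot(n >= 0, scale > 0, cap > 1)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric())
  u <- runif(n)
  if (shape == "l_shaped") {
    fmax <- stats::pexp(cap - 1, rate = 1 / scale)
    1 + stats::qexp(u * fmax, rate = 1 / scale)
  } else {
    fmax <- stats::pweibull(cap - 1, shape = weibull_shape, scale = scale)
    1 + stats::qweibull(u * fmax, shape = weibull_shape, scale = scale)
  }
}

#' Full parameterization of a synthetic community
#'
#' @param window A [census_window()].
#' @param species A list of [species_spec()]s with unique species
#'   codes.
#' @param seed Master seed; every species' positions and diameters get
#'   deterministic derived streams.
#' @param segregated_genera Codes of genera whose member species are
#'   generated on disjoint plot regions (used by reporting and tests
#'   of the genus-pooling inequality).
#' @return A `community_config` list.
#' @export
community_config <- function(window, species, seed = 1,
                             segregated_genera = character()) {
  codes <- vapply(species, function(s) s$species, "")
  if (anyDuplicated(codes)) stop("species codes must be unique")
  structure(list(window = window, species = species, seed = seed,
                 segregated_genera = segregated_genera),
            class = "community_config")
}

#' Default eight-species, four-genus community
#'
#' The packaged study community: eight clustered species in four
#' genera inside a 400 x 500 m (20 ha) window, with abundances 4478,
#' 2557, 2118, 1302, 800, 532, 1352 and 223 (13362 stems in total,
#' spanning the ~200-4500 range of a real congeneric guild).  Genus
#' GenB's two species occupy opposite plot halves and GenD's two
#' species opposite southern corners (strong within-genus
#' segregation); GenA's species overlap across the whole plot and
#' GenC mixes a corner-bound and a plot-wide species.  Size
#' structures are L-shaped for small-stemmed species and reverse-J for
#' the ones retaining large stems.
#'
#' @param seed Master seed.
#' @return A [community_config()].
#' @export
default_community_config <- function(seed = 1) {
  w <- census_window(0, 0, 400, 500)
  sp <- list(
    species_spec("A1", "GenA", 4478, kappa = 60, sigma = 12,
                 dbh_shape = "l_shaped", dbh_scale = 1.5),
    species_spec("A2", "GenA", 2557, kappa = 50, sigma = 12,
                 dbh_shape = "reverse_j", dbh_scale = 8),
    species_spec("B1", "GenB", 2118, kappa = 50, sigma = 10,
                 parent_placement = "left_half",
                 dbh_shape = "l_shaped", dbh_scale = 3),
    species_spec("B2", "GenB", 1302, kappa = 40, sigma = 10,
                 parent_placement = "right_half",
                 dbh_shape = "l_shaped", dbh_scale = 3),
    species_spec("C1", "GenC", 800, kappa = 25, sigma = 12,
                 parent_placement = "corner_sw",
                 dbh_shape = "reverse_j", dbh_scale = 10),
    species_spec("C2", "GenC", 532, kappa = 20, sigma = 12,
                 dbh_shape = "reverse_j", dbh_scale = 12),
    species_spec("D1", "GenD", 1352, kappa = 40, sigma = 8,
                 parent_placement = "corner_sw",
                 dbh_shape = "l_shaped", dbh_scale = 2),
    species_spec("D2", "GenD", 223, kappa = 15, sigma = 8,
                 parent_placement = "corner_se",
                 dbh_shape = "l_shaped", dbh_scale = 2))
  community_config(w, sp, seed = seed,
                   segregated_genera = c("GenB", "GenD"))
}

#' Generate a stem-mapped synthetic community
#'
#' Runs every [species_spec()] of the config -- positions first
#' (Thomas or CSR), diameters second -- on deterministic streams
#' derived from the master seed, and assembles one validated census
#' table.  Per-species abundances are exact.  A `"csr"` species'
#' coordinates are identical to [simulate_csr()] called on that
#' species' derived position seed.
#'
#' @param config A [community_config()].
#' @return A [census_table()].
#' @examples
#' tab <- generate_community(default_community_config(seed = 1))
#' nrow(tab$records)  # 13362
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  nsp <- length(config$species)
  seeds <- derive_seeds(config$seed, 2 * nsp)
  parents_store <- list()
  parts <- vector("list", nsp)
  for (i in seq_len(nsp)) {
    sp <- config$species[[i]]
    s_pos <- seeds[2 * i - 1]; s_dbh <- seeds[2 * i]
    dbh <- sample_dbh(sp$dbh_shape, sp$dbh_scale, sp$abundance,
                      seed = s_dbh, weibull_shape = sp$weibull_shape)
    if (sp$process == "csr") {
      p <- simulate_csr(sp$abundance, config$window, seed = s_pos)
    } else {
      shared <- if (is.list(sp$parent_placement))
        sp$parent_placement$shared_with else NULL
      parents <- NULL
      if (!is.null(shared)) {
        parents <- parents_store[[shared]]
        if (is.null(parents))
          stop("shared_with refers to species '", shared,
               "' which has no generated parents yet")
      }
      sigma_each <- if (!is.null(sp$sigma_by_dbh)) {
        rng <- sp$sigma_by_dbh
        rng[1] + (rng[2] - rng[1]) * pmin(1, (dbh - 1) / 59)
      } else NULL
      p <- simulate_thomas(sp$kappa, sp$sigma, sp$abundance,
                           config$window,
                           parent_placement =
                             if (is.list(sp$parent_placement)) "uniform"
                             else sp$parent_placement,
                           seed = s_pos, sigma_each = sigma_each,
                           parents = parents)
      parents_store[[sp$species]] <- attr(p, "parents")
    }
    parts[[i]] <- data.frame(species = sp$species, genus = sp$genus,
                             x = p$x, y = p$y, dbh = dbh)
  }
  census_table(do.call(rbind, parts), config$window)
}
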