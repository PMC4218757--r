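#' Per-ring neighbour counts and edge-corrected areas
#'
#' For every ring of the ladder, sums over focal points the number of
#' neighbour points falling in that ring, and sums the in-window
#' annulus areas centred on the focal points.  Self pairs are dropped
#' when `exclude_self = TRUE` (the univariate case, where focal and
#' neighbour are the same collection in the same order); zero-distance
#' pairs between distinct stems land in the first ring.
#'
#' @param focal,neighbor [ppattern()]s sharing one window.
#' @param ladder A [ring_ladder()].
#' @param exclude_self Drop index-equal pairs (use only when `focal`
#'   and `neighbor` are the same point set).
#' @return A list with integer vector `counts` and numeric vector
#'   `areas` (m^2), one entry per ring.
#' @export
ring_counts <- function(focal, neighbor, ladder, exclude_self = FALSE) {
  stopifnot(inherits(focal, "ppattern"), inherits(neighbor, "ppattern"),
            inherits(ladder, "ring_ladder"))
  if (!same_window(focal$window, neighbor$window))
    stop("focal and neighbor patterns must share a window")
  counts <- cpp_ring_counts(focal$x, focal$y, neighbor$x, neighbor$y,
                            ladder$ring_width, ladder$n_rings,
                            exclude_self)
  areas <- colSums(ladder_areas(focal, ladder))
  list(counts = as.integer(counts), areas = areas)
}

new_ring_profile <- function(ladder, values, counts, areas, lambda_ref,
                             statistic, pooling) {
  structure(list(ladder = ladder, values = values,
                 neighbor_counts = counts, areas = areas,
                 lambda_ref = lambda_ref, statistic = statistic,
                 pooling = pooling),
            class = "ring_profile")
}

#' Relative neighborhood density profile (univariate O-ring)
#'
#' For each annulus, the conspecific density around trees divided by
#' the species' plot-wide mean density lambda:
#' `Omega_r = D_r / lambda` with `D_r = N_r / A_r`, where `N_r` is the
#' number of conspecifics in the annulus and `A_r` its in-window area.
#' Under complete spatial randomness `Omega_r = 1`; values above 1
#' indicate aggregation, below 1 regularity.
#'
#' Two pooling conventions are available: `"ratio_of_sums"` (default)
#' divides the summed counts by the summed areas before scaling by
#' lambda, which is stable when some focal annuli have near-zero
#' in-window area; `"mean_of_ratios"` averages per-focal densities.
#'
#' @param p A [ppattern()] with at least 2 points.
#' @param ladder A [ring_ladder()]; the reference analysis uses 10 m
#'   rings.
#' @param pooling `"ratio_of_sums"` or `"mean_of_ratios"`.
#' @return An object of class `ring_profile`.
#' @examples
#' w <- census_window(0, 0, 400, 500)
#' p <- ppattern(c(200, 205), c(250, 250), w)
#' omega_profile(p, ring_ladder(10, 1))$values  # ~318.3 for 2 stems 5 m apart
#' @export
omega_profile <- function(p, ladder = ring_ladder(),
                          pooling = c("ratio_of_sums", "mean_of_ratios")) {
  stopifnot(inherits(p, "ppattern"), inherits(ladder, "ring_ladder"))
  pooling <- match.arg(pooling)
  if (npoints(p) < 2)
    stop("omega_profile needs at least 2 points")
  lambda <- intensity(p)
  if (pooling == "ratio_of_sums") {
    rc <- ring_counts(p, p, ladder, exclude_self = TRUE)
    values <- (rc$counts / rc$areas) / lambda
    counts <- rc$counts; areas <- rc$areas
  } else {
    w <- p$window
    cm <- cpp_ring_counts_by_focal(p$x, p$y, p$x, p$y,
                                   ladder$ring_width, ladder$n_rings, TRUE)
    am <- ladder_areas(p, ladder)
    values <- colMeans(cm / am) / lambda
    counts <- as.integer(colSums(cm)); areas <- colSums(am)
  }
  new_ring_profile(ladder, values, counts, areas, lambda,
                   statistic = "omega", pooling = pooling)
}

#' Bivariate ring pair-correlation profile g12(r)
#'
#' The ring-based analogue of Ripley's K12: for each annulus, the mean
#' density of pattern-2 points in rings centred on pattern-1 points,
#' divided by pattern 2's plot-wide mean density.  `g12 = 1` indicates
#' independence (non-association), `> 1` positive association, `< 1`
#' repulsion or segregation.  No self-exclusion: the two patterns are
#' distinct species.
#'
#' @param p1,p2 [ppattern()]s sharing one window, both nonempty.
#' @param ladder A [ring_ladder()].
#' @param pooling As in [omega_profile()].
#' @return A `ring_profile` with `lambda_ref` equal to pattern 2's
#'   intensity.
#' @export
g12_profile <- function(p1, p2, ladder = ring_ladder(),
                        pooling = c("ratio_of_sums", "mean_of_ratios")) {
  stopifnot(inherits(p1, "ppattern"), inherits(p2, "ppattern"))
  pooling <- match.arg(pooling)
  if (!same_window(p1$window, p2$window))
    stop("patterns must share a window")
  if (npoints(p1) < 1 || npoints(p2) < 1)
    stop("g12_profile needs both patterns nonempty")
  lambda2 <- intensity(p2)
  if (pooling == "ratio_of_sums") {
    rc <- ring_counts(p1, p2, ladder, exclude_self = FALSE)
    values <- (rc$counts / rc$areas) / lambda2
    counts <- rc$counts; areas <- rc$areas
  } else {
    cm <- cpp_ring_counts_by_focal(p1$x, p1$y, p2$x, p2$y,
                                   ladder$ring_width, ladder$n_rings, FALSE)
    am <- ladder_areas(p1, ladder)
    values <- colMeans(cm / am) / lambda2
    counts <- as.integer(colSums(cm)); areas <- colSums(am)
  }
  new_ring_profile(ladder, values, counts, areas, lambda2,
                   statistic = "g12", pooling = pooling)
}

#' Aggregation intensity within 10 m of a tree
#'
#' The scalar index Omega_0-10: the relative neighborhood density for
#' the first 10 m ring, i.e. mean conspecific density within 10 m of a
#' tree scaled by the species' plot-wide density.
#'
#' @param p A [ppattern()] with at least 2 points.
#' @param pooling As in [omega_profile()].
#' @return Numeric scalar.
#' @export
omega_0_10 <- function(p, pooling = "ratio_of_sums") {
  omega_profile(p, ring_ladder(ring_width = 10, n_rings = 1),
                pooling = pooling)$values[1]
}

#' @export
print.ring_profile <- function(x, ...) {
  lab <- if (x$statistic == "omega") "Omega_r" else "g12(r)"
  cat(sprintf("%s ring profile: %d rings of %g m (%s pooling)\n",
              lab, x$ladder$n_rings, x$ladder$ring_width, x$pooling))
  df <- as.data.frame(x)
  print(head(df, 10))
  if (nrow(df) > 10) cat("...", nrow(df) - 10, "more rings\n")
  invisible(x)
}

#' @export
as.data.frame.ring_profile <- function(x, ...) {
  data.frame(ring_lo = x$ladder$r_lo, ring_hi = x$ladder$r_hi,
             n_pairs = x$neighbor_counts, area_sum = x$areas,
             statistic = x$values)
}

#' Export a ring profile as delimited text
#' @param profile A `ring_profile`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path, delim = ",") {
  stopifnot(inherits(profile, "ring_profile"))
  utils::write.table(as.data.frame(profile), path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.ring_profile <- function(x, ylab = NULL, ...) {
  if (is.null(ylab))
    ylab <- if (x$statistic == "omega") expression(Omega[r]) else
      expression(g[12](r))
  plot(x$ladder$r_mid, x$values, type = "l", lwd = 2,
       xlab = "r (m)", ylab = ylab, ...)
  abline(h = 1, lty = 3, col = "grey50")
  invisible(x)
}
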