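#' Ladder of concentric annuli
#'
#' The ring statistics are evaluated on contiguous half-open annuli
#' `[k*w, (k+1)*w)`, `k = 0 .. n_rings - 1`, starting at radius 0.  The
#' defaults (10 m rings, 25 rings, i.e. 0--250 m) match the scales over
#' which forest-plot pattern transitions are typically reported.
#'
#' @param ring_width Annulus width in meters (> 0).
#' @param n_rings Number of annuli.
#' @return An object of class `ring_ladder` with elements `ring_width`,
#'   `n_rings`, `r_lo`, `r_hi`, `r_mid`.
#' @export
ring_ladder <- function(ring_width = 10, n_rings = 25) {
  stopifnot(ring_width > 0, n_rings >= 1)
  k <- seq_len(n_rings) - 1
  structure(list(ring_width = ring_width, n_rings = as.integer(n_rings),
                 r_lo = k * ring_width, r_hi = (k + 1) * ring_width,
                 r_mid = (k + 0.5) * ring_width),
            class = "ring_ladder")
}

same_ladder <- function(a, b) {
  a$n_rings == b$n_rings && isTRUE(all.equal(a$ring_width, b$ring_width))
}

#' Exact in-window annulus area
#'
#' Area of the annulus `r_in <= |q - center| < r_out` clipped to the
#' rectangular window.  Computed by closed-form circle--rectangle
#' intersection (inclusion--exclusion of circular-segment areas over
#' the window's corners), so boundary trees contribute exact edge
#' correction rather than an approximation.
#'
#' @param center Length-2 numeric, `(x, y)` in meters; must lie in the
#'   window.
#' @param r_in,r_out Inner and outer radii, `0 <= r_in < r_out`.
#' @param window A [census_window()].
#' @return Area in m^2.
#' @examples
#' w <- census_window(0, 0, 400, 500)
#' annulus_area_in_window(c(200, 250), 0, 10, w)  # 100 * pi, interior
#' annulus_area_in_window(c(0, 0), 0, 10, w)      # 25 * pi, corner
#' @export
annulus_area_in_window <- function(center, r_in, r_out, window) {
  stopifnot(inherits(window, "census_window"), length(center) == 2)
  if (!(r_in >= 0 && r_out > r_in))
    stop("need 0 <= r_in < r_out")
  if (!in_window(center[1], center[2], window))
    stop("annulus center must lie in the window")
  a <- cpp_disc_rect_area(rep(center[1], 2), rep(center[2], 2),
                          c(r_in, r_out),
                          window$x_min, window$y_min,
                          window$x_max, window$y_max)
  a[2] - a[1]
}

# n_focal x n_rings matrix of per-focal in-window annulus areas
ladder_areas <- function(p, ladder) {
  w <- p$window
  cpp_ladder_areas(p$x, p$y, ladder$ring_width, ladder$n_rings,
                   w$x_min, w$y_min, w$x_max, w$y_max)
}
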