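#' Planar point pattern inside a plot window
#'
#' The unit the ring statistics operate on: the mapped stems of one
#' species (or one pooled genus) plus the plot window.  Duplicate
#' coordinates are allowed -- multi-stemmed recruits can share a map
#' point -- and are handled by the statistics (zero-distance neighbour
#' pairs fall into the first ring).
#'
#' @param x,y Numeric coordinate vectors (meters), equal length.
#' @param window A [census_window()]; all points must lie inside or on
#'   its boundary.
#' @return An object of class `ppattern`.
#' @examples
#' w <- census_window(0, 0, 400, 500)
#' p <- ppattern(c(100, 105), c(250, 250), w)
#' npoints(p)
#' intensity(p)  # stems per m^2
#' @export
ppattern <- function(x, y, window) {
  stopifnot(inherits(window, "census_window"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) && !all(in_window(x, y, window)))
    stop("all points must lie inside the (closed) window")
  structure(list(x = x, y = y, window = window), class = "ppattern")
}

#' Number of points in a pattern
#' @param p A [ppattern()].
#' @return Integer count.
#' @export
npoints <- function(p) {
  stopifnot(inherits(p, "ppattern"))
  length(p$x)
}

#' Plot-wide mean density (intensity) of a pattern
#'
#' The intensity lambda is the pattern size divided by the window area:
#' the mean density of the species across the whole plot, the
#' denominator of the relative neighborhood density statistic.
#'
#' @param p A [ppattern()].
#' @return Stems per square meter.
#' @export
intensity <- function(p) {
  stopifnot(inherits(p, "ppattern"))
  npoints(p) / window_area(p$window)
}

#' @export
print.ppattern <- function(x, ...) {
  cat(sprintf("planar point pattern: %d points\n", npoints(x)))
  print(x$window)
  invisible(x)
}

#' @export
plot.ppattern <- function(x, pch = 16, cex = 0.4, main = NULL, ...) {
  w <- x$window
  plot(NA, xlim = c(w$x_min, w$x_max), ylim = c(w$y_min, w$y_max),
       asp = 1, xlab = "x (m)", ylab = "y (m)", main = main, ...)
  rect(w$x_min, w$y_min, w$x_max, w$y_max, border = "grey40")
  points(x$x, x$y, pch = pch, cex = cex)
  invisible(x)
}

#' @export
as.data.frame.ppattern <- function(x, ...) {
  data.frame(x = x$x, y = x$y)
}
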