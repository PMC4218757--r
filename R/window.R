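#' Rectangular plot window
#'
#' A census plot is an axis-aligned rectangle in metric coordinates,
#' typically with the origin at one corner (the reference design is a
#' 400 x 500 m, 20 ha plot).  Points on the boundary count as inside:
#' stems are mapped on the closed plot.
#'
#' @param x_min,y_min,x_max,y_max Rectangle bounds in meters;
#'   `x_max > x_min`, `y_max > y_min`.
#' @return An object of class `census_window`.
#' @examples
#' w <- census_window(0, 0, 400, 500)
#' window_area(w)  # 200000 m^2 = 20 ha
#' @export
census_window <- function(x_min = 0, y_min = 0, x_max, y_max) {
  vals <- c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  if (!all(is.finite(vals)))
    stop("window bounds must be finite numbers")
  if (x_max <= x_min || y_max <= y_min)
    stop("degenerate window: need x_max > x_min and y_max > y_min")
  structure(as.list(vals), class = "census_window")
}

#' Area of a plot window in square meters
#' @param window A [census_window()].
#' @return Numeric scalar, m^2.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "census_window"))
  (window$x_max - window$x_min) * (window$y_max - window$y_min)
}

#' Read a window definition from a YAML/JSON key-value file
#'
#' The file must define `x_min`, `y_min`, `x_max`, `y_max` (meters).
#'
#' @param path Path to the config file.
#' @return A [census_window()].
#' @export
read_window <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("window config is missing field(s): ", paste(miss, collapse = ", "))
  census_window(cfg$x_min, cfg$y_min, cfg$x_max, cfg$y_max)
}

#' @export
print.census_window <- function(x, ...) {
  cat(sprintf("census window: [%g, %g] x [%g, %g] m (%g m^2)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, window_area(x)))
  invisible(x)
}

# TRUE where (x, y) lies inside or on the boundary of the window
in_window <- function(x, y, window) {
  x >= window$x_min & x <= window$x_max &
    y >= window$y_min & y <= window$y_max
}

same_window <- function(a, b, tol = 1e-9) {
  all(abs(unlist(a) - unlist(b)) <= tol)
}
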