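#' Derive reproducible sub-stream seeds from a master seed
#'
#' One master seed governs every source of randomness in a run;
#' replicate-level streams are derived deterministically from it so
#' results do not depend on evaluation order.
#'
#' @param seed Master seed (integer).
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate complete spatial randomness
#'
#' `n` points placed independently and uniformly over the window: the
#' homogeneous Poisson null conditioned on the observed abundance.
#'
#' @param n Number of points (>= 0).
#' @param window A [census_window()].
#' @param seed Optional seed for reproducibility.
#' @return A [ppattern()].
#' @export
simulate_csr <- function(n, window, seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  ppattern(runif(n, window$x_min, window$x_max),
           runif(n, window$y_min, window$y_max), window)
}

# envelope ranks: k-th smallest / k-th largest with k = ceiling(0.025 n_sim)
envelope_ranks <- function(n_sim) {
  k <- ceiling(0.025 * n_sim)
  c(lo = k, hi = n_sim + 1 - k)
}

new_envelope <- function(ladder, lo, hi, n_sim, seed) {
  structure(list(ladder = ladder, lo = lo, hi = hi,
                 n_sim = as.integer(n_sim), seed = seed),
            class = "ring_envelope")
}

# build an envelope from an n_sim x n_rings matrix of null profiles
envelope_from_sims <- function(sims, ladder, n_sim, seed) {
  rk <- envelope_ranks(n_sim)
  lo <- apply(sims, 2, function(v) sort(v)[rk["lo"]])
  hi <- apply(sims, 2, function(v) sort(v)[rk["hi"]])
  new_envelope(ladder, lo, hi, n_sim, seed)
}

#' Classify a ring profile against a null envelope
#'
#' The three-way rule of the Monte Carlo test: a ring whose observed
#' value lies above the upper (97.5%) bound is significantly
#' aggregated (univariate) or positively associated (bivariate); below
#' the lower (2.5%) bound, regular / negative; otherwise random /
#' independent.  A value exactly equal to a bound is classified as
#' random / independent (documented tie rule).
#'
#' @param profile A `ring_profile`.
#' @param envelope A `ring_envelope` on the same ladder.
#' @param mode `"univariate"` or `"bivariate"` (chooses the label
#'   vocabulary).
#' @return Character vector of per-ring labels.
#' @export
classify <- function(profile, envelope,
                     mode = c("univariate", "bivariate")) {
  stopifnot(inherits(profile, "ring_profile"),
            inherits(envelope, "ring_envelope"))
  mode <- match.arg(mode)
  if (!same_ladder(profile$ladder, envelope$ladder))
    stop("profile and envelope must share a ring ladder")
  labs <- if (mode == "univariate")
    c("aggregated", "random", "regular")
  else c("positive", "independent", "negative")
  v <- profile$values
  out <- rep(labs[2], length(v))
  out[v > envelope$hi] <- labs[1]
  out[v < envelope$lo] <- labs[3]
  out
}

new_classified_profile <- function(profile, envelope, labels, mode) {
  structure(list(profile = profile, envelope = envelope,
                 labels = labels, mode = mode),
            class = "classified_profile")
}

#' Monte Carlo CSR test of a univariate pattern
#'
#' Simulates `n_sim` complete-spatial-randomness patterns with the
#' observed abundance and window, computes the relative neighborhood
#' density profile of each, and takes pointwise rank-based 2.5% / 97.5%
#' bounds (for `n_sim = 999`, the 25th smallest and 25th largest null
#' value per ring).  Rings are then classified aggregated / random /
#' regular.  The envelopes are pointwise; no simultaneous correction is
#' applied, so labels at individual rings carry the usual
#' multiple-testing caveat.
#'
#' @param p A [ppattern()] with >= 2 points.
#' @param ladder A [ring_ladder()].
#' @param n_sim Number of Monte Carlo replicates (default 999).
#' @param seed Master seed; replicate streams are derived with
#'   [derive_seeds()].
#' @param pooling As in [omega_profile()].
#' @return A `classified_profile`.
#' @export
univariate_envelope <- function(p, ladder = ring_ladder(), n_sim = 999,
                                seed = 1, pooling = "ratio_of_sums") {
  stopifnot(inherits(p, "ppattern"))
  if (npoints(p) < 2)
    stop("univariate envelope needs at least 2 points")
  obs <- omega_profile(p, ladder, pooling = pooling)
  seeds <- derive_seeds(seed, n_sim)
  n <- npoints(p)
  sims <- matrix(NA_real_, n_sim, ladder$n_rings)
  for (i in seq_len(n_sim)) {
    q <- simulate_csr(n, p$window, seed = seeds[i])
    sims[i, ] <- omega_profile(q, ladder, pooling = pooling)$values
  }
  env <- envelope_from_sims(sims, ladder, n_sim, seed)
  new_classified_profile(obs, env, classify(obs, env, "univariate"),
                         "univariate")
}

# toroidal shift of a pattern by a uniform random translation
toroidal_shift <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- p$window
  wx <- w$x_max - w$x_min; wy <- w$y_max - w$y_min
  dx <- runif(1, 0, wx); dy <- runif(1, 0, wy)
  ppattern(w$x_min + (p$x - w$x_min + dx) %% wx,
           w$y_min + (p$y - w$y_min + dy) %% wy, w)
}

#' Monte Carlo test of a bivariate association
#'
#' Holds pattern 1 fixed and, per replicate, re-simulates pattern 2 --
#' by default as complete spatial randomness with the observed
#' abundance (testing departure from independence-plus-homogeneity
#' jointly, the null the reference analysis uses).  `null = "toroidal"`
#' instead shifts pattern 2 rigidly on the torus, preserving its
#' internal structure and testing independence alone.  Rings are
#' classified positive / independent / negative.
#'
#' @param p1,p2 Nonempty [ppattern()]s sharing a window.
#' @param ladder A [ring_ladder()].
#' @param n_sim Number of replicates (default 999).
#' @param seed Master seed.
#' @param null `"csr"` (default) or `"toroidal"`.
#' @param pooling As in [omega_profile()].
#' @return A `classified_profile`.
#' @export
bivariate_envelope <- function(p1, p2, ladder = ring_ladder(),
                               n_sim = 999, seed = 1,
                               null = c("csr", "toroidal"),
                               pooling = "ratio_of_sums") {
  null <- match.arg(null)
  obs <- g12_profile(p1, p2, ladder, pooling = pooling)
  seeds <- derive_seeds(seed, n_sim)
  n2 <- npoints(p2)
  sims <- matrix(NA_real_, n_sim, ladder$n_rings)
  for (i in seq_len(n_sim)) {
    q2 <- if (null == "csr") simulate_csr(n2, p2$window, seed = seeds[i])
          else toroidal_shift(p2, seed = seeds[i])
    sims[i, ] <- g12_profile(p1, q2, ladder, pooling = pooling)$values
  }
  env <- envelope_from_sims(sims, ladder, n_sim, seed)
  new_classified_profile(obs, env, classify(obs, env, "bivariate"),
                         "bivariate")
}

#' @export
print.classified_profile <- function(x, ...) {
  cat(sprintf("%s Monte Carlo classification (%d simulations)\n",
              x$mode, x$envelope$n_sim))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
summary.classified_profile <- function(object, ...) {
  tab <- table(factor(object$labels,
                      levels = if (object$mode == "univariate")
                        c("aggregated", "random", "regular")
                      else c("positive", "independent", "negative")))
  cat(sprintf("%s classification over %d rings (width %g m):\n",
              object$mode, object$profile$ladder$n_rings,
              object$profile$ladder$ring_width))
  print(tab)
  invisible(tab)
}

#' @export
as.data.frame.classified_profile <- function(x, ...) {
  data.frame(ring_lo = x$profile$ladder$r_lo,
             ring_hi = x$profile$ladder$r_hi,
             observed = x$profile$values,
             lo = x$envelope$lo, hi = x$envelope$hi,
             label = x$labels)
}

#' Export a classified profile (observed curve, envelope, labels)
#' @param cp A `classified_profile`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_envelope <- function(cp, path, delim = ",") {
  stopifnot(inherits(cp, "classified_profile"))
  utils::write.table(as.data.frame(cp), path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.classified_profile <- function(x, main = NULL, ...) {
  pr <- x$profile
  r <- pr$ladder$r_mid
  ylim <- range(c(pr$values, x$envelope$lo, x$envelope$hi), finite = TRUE)
  plot(r, pr$values, type = "n", xlab = "r (m)",
       ylab = if (pr$statistic == "omega") expression(Omega[r]) else
         expression(g[12](r)),
       ylim = ylim, main = main, ...)
  polygon(c(r, rev(r)), c(x$envelope$lo, rev(x$envelope$hi)),
          col = adjustcolor("grey60", 0.4), border = NA)
  lines(r, x$envelope$lo, lty = 2); lines(r, x$envelope$hi, lty = 2)
  lines(r, pr$values, lwd = 2)
  abline(h = 1, lty = 3, col = "grey40")
  invisible(x)
}
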