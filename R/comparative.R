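#' Omega_0-10 aggregation table at species and genus level
#'
#' One row per species and one per genus (the pooled congeneric
#' stems), each with its abundance and Omega_0-10.  The genus rows
#' quantify how far pooling congeners dilutes aggregation intensity:
#' when congeners occupy disjoint parts of the plot, the pooled
#' pattern's plot-wide density rises while within-10-m neighbours stay
#' mostly conspecific, so genus values fall below the member species'.
#'
#' @param table A [census_table()].
#' @param species_codes Species to include (default: all in the table).
#' @param genus_codes Genera to include (default: all in the table).
#' @param pooling As in [omega_profile()].
#' @return A data.frame with columns `level`, `code`, `genus`,
#'   `n_stems`, `omega_0_10`, species rows grouped under their genus.
#' @export
aggregation_table <- function(table, species_codes = NULL,
                              genus_codes = NULL,
                              pooling = "ratio_of_sums") {
  stopifnot(inherits(table, "census"))
  rec <- table$records
  if (is.null(species_codes)) species_codes <- sort(unique(rec$species))
  if (is.null(genus_codes)) genus_codes <- sort(unique(rec$genus))
  row_for <- function(level, code) {
    p <- select_group(table, level, code)
    g <- if (level == "genus") code else
      rec$genus[match(code, rec$species)]
    data.frame(level = level, code = code, genus = g,
               n_stems = npoints(p),
               omega_0_10 = omega_0_10(p, pooling = pooling))
  }
  out <- list()
  for (g in genus_codes) {
    out[[length(out) + 1]] <- row_for("genus", g)
    for (s in intersect(species_codes,
                        unique(rec$species[rec$genus == g])))
      out[[length(out) + 1]] <- row_for("species", s)
  }
  # species whose genus was not requested
  left <- setdiff(species_codes,
                  rec$species[rec$genus %in% genus_codes])
  for (s in left) out[[length(out) + 1]] <- row_for("species", s)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregation intensity by DBH class
#'
#' Splits a species or genus into half-open DBH classes from the 1 cm
#' census floor (3 cm classes by default) and computes Omega_0-10 for
#' every class holding at least `min_count` stems (default 50).  By
#' default each class is treated as its own pattern: both the
#' neighbour counts and the reference density lambda come from the
#' class's stems (`lambda = "class"`).  `lambda = "group"` instead
#' scales class neighbour densities by the whole group's plot-wide
#' density.
#'
#' @param table A [census_table()].
#' @param level `"species"` or `"genus"`.
#' @param code Group code.
#' @param bin_width Class width, cm.
#' @param min_count Minimum stems for a class to be evaluated.
#' @param lambda `"class"` or `"group"` reference density.
#' @param pooling As in [omega_profile()].
#' @return A data.frame with columns `dbh_lo`, `dbh_hi`, `n_stems`,
#'   `omega_0_10` (possibly zero rows).
#' @export
omega_by_dbh <- function(table, level = c("species", "genus"), code,
                         bin_width = 3, min_count = 50,
                         lambda = c("class", "group"),
                         pooling = "ratio_of_sums") {
  level <- match.arg(level)
  lambda <- match.arg(lambda)
  bins <- bin_by_dbh(table, level, code, bin_width = bin_width,
                     min_count = max(min_count, 2L))
  lam_group <- if (lambda == "group")
    intensity(select_group(table, level, code)) else NULL
  rows <- lapply(bins, function(b) {
    om <- omega_0_10(b$pattern, pooling = pooling)
    if (lambda == "group")
      om <- om * intensity(b$pattern) / lam_group
    data.frame(dbh_lo = b$lo, dbh_hi = b$hi, n_stems = b$n,
               omega_0_10 = om)
  })
  if (!length(rows))
    return(data.frame(dbh_lo = numeric(), dbh_hi = numeric(),
                      n_stems = integer(), omega_0_10 = numeric()))
  res <- do.call(rbind, rows)
  res[order(res$dbh_lo), , drop = FALSE]
}

#' Pairwise spatial association matrix
#'
#' Runs the bivariate Monte Carlo association test for every requested
#' pair of groups -- typically the congeneric pairs within each genus
#' and all genus pairs -- and collects the classified profiles plus
#' per-label ring counts.
#'
#' @param table A [census_table()].
#' @param pairs A data.frame with columns `code_a`, `code_b`, `level`
#'   (`"species"` or `"genus"`), one row per unordered pair.
#' @param ladder A [ring_ladder()].
#' @param n_sim Monte Carlo replicates per pair.
#' @param seed Master seed; each pair gets a derived stream.
#' @param null,pooling Passed to [bivariate_envelope()].
#' @return An object of class `association_matrix`: a list with the
#'   pair table (augmented with per-label ring counts) and the list of
#'   `classified_profile` cells.
#' @export
association_matrix <- function(table, pairs, ladder = ring_ladder(),
                               n_sim = 999, seed = 1, null = "csr",
                               pooling = "ratio_of_sums") {
  stopifnot(inherits(table, "census"), is.data.frame(pairs),
            all(c("code_a", "code_b", "level") %in% names(pairs)))
  key <- apply(pairs[c("code_a", "code_b")], 1,
               function(r) paste(sort(r), collapse = "|"))
  if (anyDuplicated(key)) stop("pairs must be distinct (unordered)")
  seeds <- derive_seeds(seed, nrow(pairs))
  cells <- vector("list", nrow(pairs))
  summ <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    lv <- match.arg(pairs$level[i], c("species", "genus"))
    p1 <- select_group(table, lv, pairs$code_a[i])
    p2 <- select_group(table, lv, pairs$code_b[i])
    cp <- bivariate_envelope(p1, p2, ladder, n_sim = n_sim,
                             seed = seeds[i], null = null,
                             pooling = pooling)
    cells[[i]] <- cp
    summ[[i]] <- data.frame(
      code_a = pairs$code_a[i], code_b = pairs$code_b[i], level = lv,
      n_positive = sum(cp$labels == "positive"),
      n_independent = sum(cp$labels == "independent"),
      n_negative = sum(cp$labels == "negative"))
  }
  structure(list(pairs = do.call(rbind, summ), cells = cells,
                 ladder = ladder, n_sim = n_sim, seed = seed),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("pairwise association matrix: %d pairs, %d rings, %d sims\n",
              nrow(x$pairs), x$ladder$n_rings, x$n_sim))
  print(x$pairs)
  invisible(x)
}
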