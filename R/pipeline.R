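#' Assemble a full analysis configuration
#'
#' Collects every analysis constant in one validated list: 10 m rings,
#' 999 Monte Carlo iterations, 2 cm size-structure classes, 3 cm
#' aggregation-by-DBH classes and the 50-stem class floor are the
#' defaults of the reference design.
#'
#' @param census Path to a census file, or a [census_table()], or
#'   `NULL` to generate `synthetic`.
#' @param synthetic A [community_config()] used when `census` is NULL.
#' @param window A [census_window()] (needed only with a census path).
#' @param ring_width,n_rings Ring ladder (default 10 m x 25 rings).
#' @param n_sim Monte Carlo iterations (default 999).
#' @param min_count DBH-class floor (default 50 stems).
#' @param dbh_bin_width Aggregation-by-DBH class width (default 3 cm).
#' @param structure_bin_width Size-structure histogram width (2 cm).
#' @param seed Master seed.
#' @param pooling,bivariate_null,dbh_lambda Estimator switches, see
#'   [omega_profile()], [bivariate_envelope()], [omega_by_dbh()].
#' @param out_dir Report directory.
#' @param plots Also draw PDF figures (profiles with envelope bands,
#'   stem maps).
#' @return A `run_config` list.
#' @export
run_config <- function(census = NULL, synthetic = NULL, window = NULL,
                       ring_width = 10, n_rings = 25, n_sim = 999,
                       min_count = 50, dbh_bin_width = 3,
                       structure_bin_width = 2, seed = 1,
                       pooling = "ratio_of_sums",
                       bivariate_null = "csr", dbh_lambda = "class",
                       out_dir = "oring-report", plots = TRUE) {
  stopifnot(ring_width > 0, n_rings >= 1, n_sim >= 1, min_count >= 0,
            dbh_bin_width > 0, structure_bin_width > 0)
  if (is.null(census) && is.null(synthetic))
    stop("provide a census (path or table) or a synthetic community config")
  structure(list(census = census, synthetic = synthetic, window = window,
                 ring_width = ring_width, n_rings = n_rings,
                 n_sim = n_sim, min_count = min_count,
                 dbh_bin_width = dbh_bin_width,
                 structure_bin_width = structure_bin_width, seed = seed,
                 pooling = pooling, bivariate_null = bivariate_null,
                 dbh_lambda = dbh_lambda, out_dir = out_dir,
                 plots = plots),
            class = "run_config")
}

stage_log <- function(stage, t0) {
  message(sprintf("[oring] %-28s %6.1f s", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the complete species-vs-genus analysis and write a report
#'
#' Pipeline: load or simulate the census; per species and genus,
#' compute the relative-neighborhood-density profile with its Monte
#' Carlo CSR envelope and classification; tabulate Omega_0-10 at both
#' levels; profile Omega_0-10 across DBH classes per genus; and run
#' the bivariate association test for every congeneric pair within a
#' genus and every genus pair.  All tables are delimited text; a JSON
#' manifest records the configuration and seed, and rerunning with
#' the same seed reproduces every number bit-for-bit.
#'
#' @param config A [run_config()].
#' @return Invisibly, the report directory path.  Files written:
#'   `census.csv`, `population_structure.csv`, `dbh_structure.csv`,
#'   `profile_<level>_<code>.csv`, `aggregation_table.csv`,
#'   `omega_by_dbh_<genus>.csv`, `associations_within_genera.csv`,
#'   `associations_among_genera.csv`, `assoc_<a>_<b>.csv`,
#'   `manifest.json` (+ PDF figures when `plots = TRUE`).
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  tab <- if (inherits(config$census, "census")) {
    config$census
  } else if (is.character(config$census)) {
    if (is.null(config$window))
      stop("stage census_io: a census path needs a window")
    read_census(config$census, config$window)
  } else {
    generate_community(config$synthetic)
  }
  write_census(tab, out("census.csv"))
  stage_log("census", t0)

  rec <- tab$records
  species <- sort(unique(rec$species))
  genera <- sort(unique(rec$genus))
  ladder <- ring_ladder(config$ring_width, config$n_rings)
  groups <- rbind(data.frame(level = "species", code = species),
                  data.frame(level = "genus", code = genera))

  # (a) population structure: abundances and DBH class histograms
  utils::write.table(summary(tab), out("population_structure.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  hist_rows <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    bins <- bin_by_dbh(tab, groups$level[i], groups$code[i],
                       bin_width = config$structure_bin_width,
                       min_count = 0)
    do.call(rbind, lapply(bins, function(b)
      data.frame(level = groups$level[i], code = groups$code[i],
                 dbh_lo = b$lo, dbh_hi = b$hi, n_stems = b$n)))
  }))
  utils::write.table(hist_rows, out("dbh_structure.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  stage_log("population structure", t0)

  # (b) omega profiles + envelopes for every species and genus
  env_seeds <- derive_seeds(config$seed, nrow(groups))
  cps <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    p <- select_group(tab, groups$level[i], groups$code[i])
    cp <- univariate_envelope(p, ladder, n_sim = config$n_sim,
                              seed = env_seeds[i],
                              pooling = config$pooling)
    cps[[i]] <- cp
    write_envelope(cp, out(sprintf("profile_%s_%s.csv",
                                   groups$level[i], groups$code[i])))
  }
  stage_log("omega profiles + envelopes", t0)

  # (c) aggregation intensity at species and genus level
  agg <- aggregation_table(tab, pooling = config$pooling)
  utils::write.table(agg, out("aggregation_table.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  stage_log("aggregation table", t0)

  # (d) omega_0_10 across DBH classes, per genus
  for (g in genera) {
    ser <- omega_by_dbh(tab, "genus", g,
                        bin_width = config$dbh_bin_width,
                        min_count = config$min_count,
                        lambda = config$dbh_lambda,
                        pooling = config$pooling)
    utils::write.table(ser, out(sprintf("omega_by_dbh_%s.csv", g)),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  stage_log("omega by DBH class", t0)

  # (e) associations: congeneric pairs within genera, then genus pairs
  within <- do.call(rbind, lapply(genera, function(g) {
    sp <- sort(unique(rec$species[rec$genus == g]))
    if (length(sp) < 2) return(NULL)
    cmb <- utils::combn(sp, 2)
    data.frame(code_a = cmb[1, ], code_b = cmb[2, ], level = "species")
  }))
  among <- if (length(genera) >= 2) {
    cmb <- utils::combn(genera, 2)
    data.frame(code_a = cmb[1, ], code_b = cmb[2, ], level = "genus")
  } else NULL
  assoc_seeds <- derive_seeds(config$seed + 1L, 2)
  for (set in list(list(pairs = within, name = "within_genera",
                        seed = assoc_seeds[1]),
                   list(pairs = among, name = "among_genera",
                        seed = assoc_seeds[2]))) {
    if (is.null(set$pairs)) next
    am <- association_matrix(tab, set$pairs, ladder,
                             n_sim = config$n_sim, seed = set$seed,
                             null = config$bivariate_null,
                             pooling = config$pooling)
    utils::write.table(am$pairs,
                       out(sprintf("associations_%s.csv", set$name)),
                       sep = ",", row.names = FALSE, quote = FALSE)
    for (i in seq_len(nrow(am$pairs)))
      write_envelope(am$cells[[i]],
                     out(sprintf("assoc_%s_%s.csv",
                                 am$pairs$code_a[i], am$pairs$code_b[i])))
  }
  stage_log("association matrices", t0)

  # (f) manifest
  manifest <- list(
    seed = config$seed, n_sim = config$n_sim,
    ring_width = config$ring_width, n_rings = config$n_rings,
    min_count = config$min_count, dbh_bin_width = config$dbh_bin_width,
    structure_bin_width = config$structure_bin_width,
    pooling = config$pooling, bivariate_null = config$bivariate_null,
    dbh_lambda = config$dbh_lambda,
    n_stems = nrow(rec), species = species, genera = genera,
    package = as.character(utils::packageVersion("oring")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  if (isTRUE(config$plots)) {
    grDevices::pdf(out("profiles.pdf"), width = 7, height = 5)
    for (i in seq_len(nrow(groups)))
      plot(cps[[i]], main = sprintf("%s %s", groups$level[i],
                                    groups$code[i]))
    grDevices::dev.off()
    grDevices::pdf(out("maps.pdf"), width = 6, height = 7)
    for (g in genera) {
      sp <- sort(unique(rec$species[rec$genus == g]))
      plot(select_group(tab, "genus", g), main = g, cex = 0.3)
      for (k in seq_along(sp)) {
        pk <- select_group(tab, "species", sp[k])
        points(pk$x, pk$y, pch = k, cex = 0.3, col = k + 1)
      }
      legend("topright", legend = sp, pch = seq_along(sp),
             col = seq_along(sp) + 1, cex = 0.8)
    }
    grDevices::dev.off()
    stage_log("figures", t0)
  }
  stage_log("report complete", t0)
  invisible(config$out_dir)
}
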