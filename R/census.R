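#' Stem-mapped census table
#'
#' One record per stem: species code, genus code, map coordinates
#' (meters) and diameter at breast height (DBH, cm).  The census floor
#' is 1 cm DBH; every coordinate must lie inside the (closed) plot
#' window, and each species code must map to exactly one genus code.
#'
#' @param records A data.frame with columns `species`, `genus`, `x`,
#'   `y`, `dbh`.
#' @param window A [census_window()].
#' @return An object of class `census`.
#' @seealso [read_census()], [select_group()], [bin_by_dbh()]
#' @export
census_table <- function(records, window) {
  stopifnot(inherits(window, "census_window"))
  need <- c("species", "genus", "x", "y", "dbh")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("census records are missing column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[need]
  records$species <- as.character(records$species)
  records$genus <- as.character(records$genus)
  for (col in c("x", "y", "dbh")) {
    records[[col]] <- as.numeric(records[[col]])
    bad <- which(!is.finite(records[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric or missing '%s' at row %d", col, bad[1]))
  }
  bad <- which(!in_window(records$x, records$y, window))
  if (length(bad))
    stop(sprintf("coordinate outside the plot window at row %d (x=%g, y=%g)",
                 bad[1], records$x[bad[1]], records$y[bad[1]]))
  bad <- which(records$dbh < 1)
  if (length(bad))
    stop(sprintf("dbh below the 1 cm census floor at row %d (dbh=%g)",
                 bad[1], records$dbh[bad[1]]))
  # species -> genus must be a function
  map <- unique(records[c("species", "genus")])
  dup <- map$species[duplicated(map$species)]
  if (length(dup))
    stop("species mapped to more than one genus: ",
         paste(unique(dup), collapse = ", "))
  rownames(records) <- NULL
  structure(list(records = records, window = window), class = "census")
}

#' Read a stem-mapped census from delimited text
#'
#' Expects a header naming (at least) the columns `species`, `genus`,
#' `x`, `y`, `dbh`; comma-delimited by default, tab accepted.  The
#' table is validated against the window and the 1 cm DBH floor; errors
#' cite the offending row.
#'
#' @param path Path to the file.
#' @param window A [census_window()], e.g. from [read_window()].
#' @param delim Field delimiter (default `","`).
#' @return A [census_table()].
#' @export
read_census <- function(path, window, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE)
  census_table(df, window)
}

#' Write a census table as delimited text
#'
#' Emits a file re-readable by [read_census()]; numeric columns keep
#' full double precision (up to 17 significant digits).
#'
#' @param table A [census_table()].
#' @param path Output path.
#' @param delim Field delimiter (default `","`).
#' @return Invisibly, `path`.
#' @export
write_census <- function(table, path, delim = ",") {
  stopifnot(inherits(table, "census"))
  rec <- table$records
  out <- data.frame(species = rec$species, genus = rec$genus,
                    x = sprintf("%.17g", rec$x),
                    y = sprintf("%.17g", rec$y),
                    dbh = sprintf("%.17g", rec$dbh))
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.census <- function(x, ...) {
  rec <- x$records
  cat(sprintf("stem-mapped census: %d stems, %d species, %d genera\n",
              nrow(rec), length(unique(rec$species)),
              length(unique(rec$genus))))
  print(x$window)
  invisible(x)
}

#' @export
summary.census <- function(object, ...) {
  rec <- object$records
  tab <- do.call(rbind, lapply(split(rec, rec$species), function(d) {
    data.frame(species = d$species[1], genus = d$genus[1],
               n_stems = nrow(d), mean_dbh = mean(d$dbh))
  }))
  tab <- tab[order(tab$genus, tab$species), ]
  rownames(tab) <- NULL
  tab
}

# rows of the census matching a species or genus code
group_rows <- function(table, level, code) {
  level <- match.arg(level, c("species", "genus"))
  key <- table$records[[level]]
  if (!code %in% key)
    stop(sprintf("unknown %s code '%s'; known codes: %s", level, code,
                 paste(sort(unique(key)), collapse = ", ")))
  which(key == code)
}

#' Extract the point pattern of one species or genus
#'
#' Genus selection pools all congeneric species ("mixed congeneric
#' species individuals"): the union of the member species' stems, with
#' duplicate coordinates kept.
#'
#' @param table A [census_table()].
#' @param level `"species"` or `"genus"`.
#' @param code The species or genus code to extract.
#' @return A [ppattern()] carrying the census window.
#' @export
select_group <- function(table, level = c("species", "genus"), code) {
  stopifnot(inherits(table, "census"))
  level <- match.arg(level)
  i <- group_rows(table, level, code)
  ppattern(table$records$x[i], table$records$y[i], table$window)
}

#' Split a group into DBH classes
#'
#' Bins are half-open intervals `[lo, lo + width)` starting at the 1 cm
#' census floor.  Only classes holding at least `min_count` stems are
#' returned (the reference analysis examines classes of 50+ stems);
#' `min_count = 0` keeps every nonempty class.
#'
#' @param table A [census_table()].
#' @param level `"species"` or `"genus"`.
#' @param code Group code.
#' @param bin_width Class width in cm (2 for size-structure histograms,
#'   3 for aggregation-by-DBH profiles).
#' @param min_count Minimum stems per returned class.
#' @return A list of elements `list(lo, hi, n, pattern)` in ascending
#'   DBH order.
#' @export
bin_by_dbh <- function(table, level = c("species", "genus"), code,
                       bin_width = 2, min_count = 0) {
  stopifnot(inherits(table, "census"), bin_width > 0, min_count >= 0)
  level <- match.arg(level)
  i <- group_rows(table, level, code)
  dbh <- table$records$dbh[i]
  k <- floor((dbh - 1) / bin_width)  # half-open classes from 1 cm
  out <- list()
  for (kk in sort(unique(k))) {
    j <- i[k == kk]
    if (length(j) < min_count) next
    out[[length(out) + 1]] <- list(
      lo = 1 + kk * bin_width, hi = 1 + (kk + 1) * bin_width,
      n = length(j),
      pattern = ppattern(table$records$x[j], table$records$y[j],
                         table$window))
  }
  out
}
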