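#' Rectangular observation window
#'
#' A plot window is the rectangle `[0, width] x [0, height]` (metres), with
#' the origin at the plot's lower-left corner. All mapped stems must fall
#' inside it; its area enters the intensity terms of the second-order
#' estimators.
#'
#' @param width,height Plot dimensions in metres; both must be positive.
#' @return An object of class `pp_window` with elements `width`, `height`
#'   and `area`.
#' @examples
#' pp_window(100, 100)
#' @export
pp_window <- function(width, height) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1,
            length(height) == 1)
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("window dimensions must be positive finite numbers")
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 area = as.numeric(width) * as.numeric(height)),
            class = "pp_window")
}

#' @export
print.pp_window <- function(x, ...) {
  cat(sprintf("window: %g m x %g m (area %g m^2)\n", x$width, x$height,
              x$area))
  invisible(x)
}

same_window <- function(a, b) {
  isTRUE(all.equal(a$width, b$width)) && isTRUE(all.equal(a$height, b$height))
}

CENSUS_COLS <- c("plot_id", "tree_id", "species", "x", "y", "dbh", "height")

#' Construct a validated census table
#'
#' One row per free-standing woody plant: plot label, tree label, species
#' code, map coordinates (metres), diameter at breast height (cm) and total
#' height (m). Duplicate coordinates are allowed (two stems can share a
#' mapped point); each row is treated as one individual.
#'
#' @param df A data frame with columns `plot_id`, `tree_id`, `species`,
#'   `x`, `y`, `dbh`, `height` (`height` may be `NA`).
#' @param window A single [pp_window()] shared by all plots, or a named
#'   list of windows keyed by plot id.
#' @return A `census_table`: the validated data frame with a `windows`
#'   attribute (named list of `pp_window`, one per plot).
#' @export
census_table <- function(df, window) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CENSUS_COLS, names(df))
  if (length(missing_cols))
    stop("census is missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[CENSUS_COLS]
  for (col in c("x", "y", "dbh")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at row %d", col, bad[1]))
    if (anyNA(v))
      stop(sprintf("missing value in column '%s' at row %d", col,
                   which(is.na(v))[1]))
    df[[col]] <- v
  }
  df$height <- suppressWarnings(as.numeric(df$height))
  df$plot_id <- as.character(df$plot_id)
  df$tree_id <- as.character(df$tree_id)
  df$species <- as.character(df$species)

  plots <- unique(df$plot_id)
  if (inherits(window, "pp_window")) {
    windows <- stats::setNames(rep(list(window), length(plots)), plots)
  } else {
    windows <- window
    miss <- setdiff(plots, names(windows))
    if (length(miss))
      stop("no window supplied for plot(s): ", paste(miss, collapse = ", "))
  }
  for (p in plots) {
    w <- windows[[p]]
    rows <- which(df$plot_id == p)
    out <- rows[df$x[rows] < 0 | df$x[rows] > w$width |
                  df$y[rows] < 0 | df$y[rows] > w$height]
    if (length(out))
      stop(sprintf(
        "stem outside the %g x %g window in plot '%s' at row %d (x=%g, y=%g)",
        w$width, w$height, p, out[1], df$x[out[1]], df$y[out[1]]))
    if (anyDuplicated(df$tree_id[rows]))
      stop(sprintf("duplicate tree_id within plot '%s'", p))
  }
  if (any(df$dbh <= 0))
    stop(sprintf("non-positive dbh at row %d", which(df$dbh <= 0)[1]))
  structure(df, windows = windows, class = c("census_table", "data.frame"))
}

#' Read a stem-mapped census from delimited text
#'
#' Reads a comma-separated census with a header row and validates it into a
#' [census_table()]. Source files with other column names are accommodated
#' through `schema`, a named character vector mapping canonical names
#' (`plot_id`, `tree_id`, `species`, `x`, `y`, `dbh`, `height`) to the
#' file's column names.
#'
#' @param path Path to a CSV file.
#' @param window A [pp_window()] or named list of windows per plot.
#' @param schema Optional named character vector renaming source columns,
#'   e.g. `c(x = "gx", y = "gy")`.
#' @param sep Field separator (default comma).
#' @return A `census_table`.
#' @export
read_census <- function(path, window, schema = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"", fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop(sprintf("schema maps '%s' to missing column '%s'", canon, src))
      names(df)[names(df) == src] <- canon
    }
  }
  if (!"tree_id" %in% names(df)) df$tree_id <- as.character(seq_len(nrow(df)))
  if (!"plot_id" %in% names(df)) df$plot_id <- "plot1"
  if (!"height" %in% names(df)) df$height <- NA_real_
  census_table(df, window)
}

#' Write a census table to CSV
#'
#' @param census A `census_table`.
#' @param path Output path.
#' @export
write_census <- function(census, path) {
  utils::write.csv(as.data.frame(census)[CENSUS_COLS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a species trait table
#'
#' Expected columns: `species`, `life_form`, `shade_tolerance`,
#' `dispersal`; an optional `habitat` column is kept when present. One row
#' per species.
#'
#' @param path Path to a CSV file.
#' @return A data frame of class `trait_table`.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "life_form", "shade_tolerance", "dispersal")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$species))
    stop("trait table has duplicate species rows")
  structure(df, class = c("trait_table", "data.frame"))
}

#' Abundance-based species inclusion filter
#'
#' A species enters the pairwise analysis only if it has more than `min_n`
#' individuals (strictly greater) in at least `min_plots` of the censused
#' plots. For an included species, any plot where its count does not exceed
#' `min_n` is flagged unusable: that plot is dropped from the species'
#' replicate set rather than excluding the species.
#'
#' @param census A `census_table`.
#' @param min_n Minimum per-plot abundance threshold (default 60; a plot
#'   counts only when the species has *more than* `min_n` stems there).
#' @param min_plots Number of plots that must individually exceed `min_n`.
#'   Defaults to `n_plots - 1` (so with three replicate plots a species may
#'   be deficient in one), and to 1 for single-plot data.
#' @return A list with `included` (character vector of retained species,
#'   sorted), `usable` (logical species x plot matrix), `counts` (integer
#'   species x plot matrix for all species) and `coverage` (fraction of all
#'   censused individuals belonging to included species).
#' @export
filter_species <- function(census, min_n = 60, min_plots = NULL) {
  stopifnot(min_n >= 1)
  plots <- sort(unique(census$plot_id))
  if (is.null(min_plots)) min_plots <- max(1L, length(plots) - 1L)
  if (nrow(census) == 0 || length(plots) == 0)
    return(list(included = character(0),
                usable = matrix(logical(0), 0, 0),
                counts = matrix(integer(0), 0, 0), coverage = NA_real_))
  counts <- table(factor(census$species), factor(census$plot_id, plots))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  enough <- counts > min_n
  included <- rownames(counts)[rowSums(enough) >= min_plots]
  included <- sort(included)
  usable <- enough[included, , drop = FALSE]
  coverage <- sum(counts[included, , drop = FALSE]) / sum(counts)
  list(included = included, usable = usable, counts = counts,
       coverage = coverage)
}
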