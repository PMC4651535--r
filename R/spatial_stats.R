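#' Marked point pattern for one species
#'
#' Holds the mapped stems of one species within a rectangular window, with
#' DBH (cm) as a continuous mark. The intensity `n / area` enters the
#' intertype L-type estimator.
#'
#' @param x,y Stem coordinates in metres.
#' @param marks DBH marks (cm), same length as `x`.
#' @param window A [pp_window()].
#' @param species Optional species label carried through outputs.
#' @return An object of class `marked_pattern`.
#' @export
marked_pattern <- function(x, y, marks, window, species = NA_character_) {
  stopifnot(inherits(window, "pp_window"))
  x <- as.numeric(x); y <- as.numeric(y); marks <- as.numeric(marks)
  if (length(x) != length(y) || length(x) != length(marks))
    stop("x, y and marks must have equal length")
  if (length(x) && (any(x < 0 | x > window$width) ||
                    any(y < 0 | y > window$height)))
    stop("points outside the window")
  structure(list(x = x, y = y, marks = marks, window = window,
                 n = length(x), intensity = length(x) / window$area,
                 species = species),
            class = "marked_pattern")
}

#' @export
print.marked_pattern <- function(x, ...) {
  cat(sprintf("marked pattern '%s': %d points in %g x %g m window\n",
              x$species, x$n, x$window$width, x$window$height))
  invisible(x)
}

#' Split a census plot into per-species marked patterns
#'
#' @param census A `census_table`.
#' @param plot_id Plot to extract.
#' @param species Character vector of species to extract (default: all in
#'   the plot).
#' @return Named list of [marked_pattern()] objects.
#' @export
census_patterns <- function(census, plot_id, species = NULL) {
  windows <- attr(census, "windows")
  if (!plot_id %in% names(windows))
    stop(sprintf("unknown plot '%s'", plot_id))
  sub <- census[census$plot_id == plot_id, , drop = FALSE]
  if (is.null(species)) species <- sort(unique(sub$species))
  out <- lapply(species, function(sp) {
    rows <- sub$species == sp
    marked_pattern(sub$x[rows], sub$y[rows], sub$dbh[rows],
                   windows[[plot_id]], species = sp)
  })
  stats::setNames(out, species)
}

#' Distance grid for second-order summaries
#'
#' Equally spaced distance lags `step, 2*step, ..., max_d`. The default is
#' 0.5 m steps up to 50 m (half the shorter side of a 1-ha square plot,
#' the usual upper bound for second-order analysis).
#'
#' @param max_d Largest lag in metres (default 50).
#' @param step Lag spacing in metres (default 0.5).
#' @param lags Alternatively, an explicit strictly increasing positive
#'   vector of lags.
#' @return Object of class `distance_grid` with elements `lags`, `max_d`.
#' @export
distance_grid <- function(max_d = 50, step = 0.5, lags = NULL) {
  if (is.null(lags)) lags <- seq(step, max_d, by = step)
  lags <- as.numeric(lags)
  if (any(lags <= 0) || is.unsorted(lags, strictly = TRUE))
    stop("lags must be strictly increasing and positive")
  structure(list(lags = lags, max_d = lags[length(lags)]),
            class = "distance_grid")
}

check_bivariate <- function(a, b, grid, corr) {
  stopifnot(inherits(a, "marked_pattern"), inherits(b, "marked_pattern"),
            inherits(grid, "distance_grid"))
  if (!same_window(a$window, b$window))
    stop("patterns must share one observation window")
  corr <- match.arg(corr, c("ripley_isotropic", "none"))
  if (corr == "ripley_isotropic" &&
      grid$max_d > min(a$window$width, a$window$height) / 2 + 1e-9)
    stop("isotropic edge correction requires max_d <= half the shorter window side")
  corr
}

#' Directional intertype pair-weight sums at one distance
#'
#' Sums the second-order weights \eqn{\omega_{ij}(d)} over ordered
#' intertype pairs with `d_ij <= d`, in each direction. With `corr =
#' "none"` the weight is the plain indicator, so each sum is the intertype
#' pair count within `d`. With `corr = "ripley_isotropic"` each indicator
#' is divided by the fraction of the circle of radius `d_ij` centred on
#' the focal point that lies inside the window.
#'
#' @param a,b Two [marked_pattern()]s sharing a window.
#' @param d A single distance (m).
#' @param corr `"ripley_isotropic"` (default) or `"none"`.
#' @return List with `sum_ab` (focal points in `a`) and `sum_ba` (focal
#'   points in `b`).
#' @export
cross_pair_weights <- function(a, b, d, corr = "ripley_isotropic") {
  grid <- distance_grid(lags = d)
  corr <- check_bivariate(a, b, grid, corr)
  if (a$n == 0 || b$n == 0) return(list(sum_ab = 0, sum_ba = 0))
  pp <- cross_pairs_cpp(a$x, a$y, b$x, b$y, a$window$width, a$window$height,
                        d, corr == "ripley_isotropic")
  list(sum_ab = sum(pp$wa), sum_ba = sum(pp$wb))
}

# Canonical argument order so the estimators are exactly symmetric in
# (a, b): the summation order, and hence the floating-point result, is
# fixed regardless of how the caller ordered the pair.
canonical_pair <- function(a, b) {
  key <- function(p) paste(p$species, p$n,
                           format(sum(p$x) + 2 * sum(p$y), digits = 17),
                           format(sum(p$marks), digits = 17))
  if (key(b) < key(a)) list(a = b, b = a) else list(a = a, b = b)
}

new_curve <- function(grid, values, statistic, edge_mode) {
  structure(list(grid = grid, values = values, statistic = statistic,
                 edge_mode = edge_mode), class = "assoc_curve")
}

#' @export
print.assoc_curve <- function(x, ...) {
  cat(sprintf("%s curve on %d lags up to %g m (edge: %s)\n", x$statistic,
              length(x$grid$lags), x$grid$max_d, x$edge_mode))
  invisible(x)
}

#' Intertype L-type function
#'
#' The bivariate second-order summary
#' \deqn{\hat L_{rs}(d) = \frac{1}{(\lambda_r+\lambda_s)(n_r+n_s)\pi}
#'   \left(\frac{\sum_i\sum_j \omega_{ij}(d)}{n_r} +
#'         \frac{\sum_i\sum_j \omega_{ji}(d)}{n_s}\right)}
#' where the first double sum runs over focal points of species `r` and
#' the second over focal points of species `s`, \eqn{\lambda = n/A}, and
#' \eqn{\omega} is the indicator of `d_ij <= d`, optionally divided by the
#' Ripley isotropic boundary fraction of the focal point. For two
#' independent completely random patterns the expectation is close to
#' \eqn{d^2/(n_r+n_s)}, so excursions above (below) a null band indicate
#' intertype attraction (repulsion).
#'
#' @param a,b Two [marked_pattern()]s sharing a window; both non-empty.
#' @param grid A [distance_grid()].
#' @param corr Edge-correction mode, `"ripley_isotropic"` (default) or
#'   `"none"`.
#' @return An `assoc_curve` with one value per lag.
#' @export
lrs_hat <- function(a, b, grid = distance_grid(),
                    corr = "ripley_isotropic") {
  corr <- check_bivariate(a, b, grid, corr)
  if (a$n == 0) stop(sprintf("empty pattern for species '%s'", a$species))
  if (b$n == 0) stop(sprintf("empty pattern for species '%s'", b$species))
  cp <- canonical_pair(a, b); a <- cp$a; b <- cp$b
  v <- lrs_curve_cpp(a$x, a$y, b$x, b$y, a$window$width, a$window$height,
                     grid$lags, corr == "ripley_isotropic")
  new_curve(grid, v, "lrs", corr)
}

standardise_marks <- function(p) {
  if (p$n < 2) stop(sprintf("species '%s' needs >= 2 marked stems", p$species))
  s <- stats::sd(p$marks)
  if (s == 0) stop(sprintf("marks constant for species '%s'", p$species))
  (p$marks - mean(p$marks)) / s
}

#' Intertype mark-correlation function
#'
#' For every intertype pair within distance `d`, the product of the two
#' stems' standardised DBH marks (each mark centred and scaled by its own
#' species' per-plot mean and sample standard deviation) is averaged with
#' the same bidirectional \eqn{\omega} weights as [lrs_hat()], normalised
#' by the summed weights:
#' \deqn{\hat K^{mm}_{rs}(d) = \frac{\sum\sum \omega_{ij}(d)
#'   \tilde m_i \tilde m_j + \sum\sum \omega_{ji}(d) \tilde m_i \tilde m_j}
#'   {\sum\sum \omega_{ij}(d) + \sum\sum \omega_{ji}(d)}}
#' Positive values at a lag mean similarly sized (similar-stage) stems of
#' the two species co-occur at that scale; negative values mean large
#' stems of one species sit near small stems of the other. Lags closer
#' than the nearest intertype pair are undefined (`NA`), not zero.
#'
#' @inheritParams lrs_hat
#' @return An `assoc_curve`; undefined lags are `NA`.
#' @export
kmm_hat <- function(a, b, grid = distance_grid(),
                    corr = "ripley_isotropic") {
  corr <- check_bivariate(a, b, grid, corr)
  cp <- canonical_pair(a, b); a <- cp$a; b <- cp$b
  za <- standardise_marks(a)
  zb <- standardise_marks(b)
  pp <- kmm_pairs_cpp(a$x, a$y, b$x, b$y, a$window$width, a$window$height,
                      grid$lags, corr == "ripley_isotropic")
  v <- kmm_curves_cpp(pp$bin, pp$w, pp$i, pp$j, matrix(za), matrix(zb),
                      length(grid$lags))[1, ]
  new_curve(grid, v, "kmm", corr)
}
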