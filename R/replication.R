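#' Standardise an empirical curve onto its null band
#'
#' Maps an envelope's empirical curve through the affine transform
#' `F_st(d) = a(d) + b(d) F(d)` with
#' `b(d) = 2 / (N_sup(d) - N_inf(d))` and `a(d) = 1 - b(d) N_sup(d)`,
#' where `N_sup`, `N_inf` are the envelope's upper and lower quantile
#' bounds. The null band becomes exactly `[-1, 1]` at every lag, making
#' curves comparable across replicate plots with different abundances.
#' Lags where the band is degenerate (`N_sup == N_inf`) or the statistic
#' is undefined carry `NA`.
#'
#' @param env An `assoc_envelope`.
#' @return A `standardized_curve`: list with `grid`, `values` (the
#'   standardised empirical curve), `a`, `b`, and the envelope metadata.
#' @export
standardize <- function(env) {
  stopifnot(inherits(env, "assoc_envelope"))
  rng <- env$upper - env$lower
  b <- ifelse(is.na(rng) | rng <= 0, NA_real_, 2 / rng)
  a <- 1 - b * env$upper
  values <- a + b * env$empirical
  structure(list(grid = env$grid, values = values, a = a, b = b,
                 statistic = env$statistic, species = env$species,
                 n_sim = env$n_sim, alpha = env$alpha),
            class = "standardized_curve")
}

#' Pool standardised curves across replicate plots
#'
#' The overall function for a species pair observed in several replicate
#' plots is the per-lag arithmetic mean of the per-plot standardised
#' curves, taken over the replicates with a defined value at that lag.
#' Because each replicate's null band was mapped to `[-1, 1]`, a pooled
#' value of 1 means every contributing replicate sat on its upper bound.
#'
#' @param replicates Non-empty list of `standardized_curve`s on one grid.
#' @return A `pooled_curve`: list with `grid`, `values` (pooled curve),
#'   `per_replicate` (lags x replicates matrix), `n_rep` (contributing
#'   replicates per lag) and the statistic label.
#' @export
pool <- function(replicates) {
  if (!length(replicates)) stop("no replicates to pool")
  stopifnot(all(vapply(replicates, inherits, TRUE, "standardized_curve")))
  grid <- replicates[[1]]$grid
  for (r in replicates)
    if (!isTRUE(all.equal(r$grid$lags, grid$lags)))
      stop("replicates must share one distance grid")
  m <- vapply(replicates, function(r) r$values, numeric(length(grid$lags)))
  m <- matrix(m, nrow = length(grid$lags))
  n_rep <- rowSums(!is.na(m))
  pooled <- ifelse(n_rep > 0, rowMeans(m, na.rm = TRUE), NA_real_)
  structure(list(grid = grid, values = pooled, per_replicate = m,
                 n_rep = n_rep, statistic = replicates[[1]]$statistic,
                 species = replicates[[1]]$species),
            class = "pooled_curve")
}
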