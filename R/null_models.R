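#' @useDynLib interspat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic 31-bit sub-seed from a top-level seed and a string key, so
# any (pair, plot, statistic) unit can be re-run in isolation
# bit-identically. Plain polynomial rolling hash mod 2^31 - 1.
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(paste(key, collapse = "|"))) h <- (h * 31 + c) %% m
  as.integer(max(1, h))
}

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Toroidal shift of a marked pattern
#'
#' Rigidly translates every point by `(dx, dy)` treating the rectangular
#' window as a torus (coordinates wrap modulo the window dimensions).
#' Marks travel with their points, so each marginal pattern's internal
#' structure is exactly preserved under the toroidal metric. This is the
#' null model for spatial independence of two species: one pattern is held
#' fixed and the other is shifted by a uniform random vector.
#'
#' @param pattern A [marked_pattern()].
#' @param shift Numeric length-2 vector `(dx, dy)` in metres.
#' @return The shifted `marked_pattern`.
#' @export
toroidal_shift <- function(pattern, shift) {
  stopifnot(inherits(pattern, "marked_pattern"), length(shift) == 2)
  w <- pattern$window
  x <- (pattern$x + shift[1]) %% w$width
  y <- (pattern$y + shift[2]) %% w$height
  marked_pattern(x, y, pattern$marks, w, species = pattern$species)
}

#' Random marking of two patterns
#'
#' Null model for mark independence: point locations of both species stay
#' fixed and the DBH marks are permuted uniformly at random *within* each
#' species separately, preserving each species' mark multiset (and hence
#' its per-species standardisation) while destroying any spatial structure
#' in the marks.
#'
#' @param a,b Two [marked_pattern()]s.
#' @return List with permuted-`a` and permuted-`b` patterns.
#' @export
random_marking <- function(a, b) {
  stopifnot(a$n >= 1, b$n >= 1)
  pa <- marked_pattern(a$x, a$y, a$marks[sample.int(a$n)], a$window,
                       species = a$species)
  pb <- marked_pattern(b$x, b$y, b$marks[sample.int(b$n)], b$window,
                       species = b$species)
  list(a = pa, b = pb)
}

# Rank used for the pointwise bounds: k-th smallest / k-th largest of
# n_sim simulated values. With 399 simulations and alpha = 0.05 this is
# the 10th-lowest and 10th-highest value.
envelope_rank <- function(n_sim, alpha) {
  max(1L, as.integer(floor(alpha * (n_sim + 1) / 2)))
}

#' Monte Carlo simulation envelope for an intertype statistic
#'
#' Simulates the statistic's null model (`toroidal_shift` for `lrs`,
#' `random_marking` for `kmm`) `n_sim` times and takes pointwise
#' rank-based quantile bounds at each lag: the k-th smallest and k-th
#' largest simulated value with `k = floor(alpha * (n_sim + 1) / 2)`
#' (so 399 simulations at `alpha = 0.05` give the 10th-lowest and
#' 10th-highest curves). For the toroidal-shift model the species with
#' fewer individuals is the one shifted. Lags where the mark-correlation
#' statistic is undefined (no intertype pair yet) are excluded from bound
#' computation, i.e. carried as `NA`.
#'
#' @param a,b Two [marked_pattern()]s sharing a window.
#' @param statistic `"lrs"` or `"kmm"`.
#' @param n_sim Number of null simulations (>= 19; default 399).
#' @param alpha Two-sided envelope level (default 0.05 for a 95% band).
#' @param seed Integer seed; the envelope is bit-reproducible given it.
#' @param grid A [distance_grid()].
#' @param corr Edge-correction mode.
#' @return An `assoc_envelope`: list with `grid`, `empirical`, `lower`,
#'   `upper`, `sims` (n_sim x lags matrix), `n_sim`, `alpha`, `statistic`,
#'   `edge_mode`, `null_model`, `shifted` (species shifted, lrs only) and
#'   `seed`.
#' @export
envelope <- function(a, b, statistic = c("lrs", "kmm"), n_sim = 399,
                     alpha = 0.05, seed = 1L, grid = distance_grid(),
                     corr = "ripley_isotropic") {
  statistic <- match.arg(statistic)
  corr <- check_bivariate(a, b, grid, corr)
  if (n_sim < 19) stop("n_sim must be at least 19")
  ripley <- corr == "ripley_isotropic"
  W <- a$window$width; H <- a$window$height
  nl <- length(grid$lags)
  shifted <- NA_character_

  if (statistic == "lrs") {
    emp <- lrs_hat(a, b, grid, corr)$values
    # shift the sparser species; the statistic is symmetric in (a, b)
    if (a$n < b$n) { fixed <- b; mobile <- a } else { fixed <- a; mobile <- b }
    shifted <- mobile$species
    sh <- with_seed(seed,
                    cbind(stats::runif(n_sim, 0, W), stats::runif(n_sim, 0, H)))
    sims <- lrs_toroidal_sims_cpp(fixed$x, fixed$y, mobile$x, mobile$y,
                                  W, H, grid$lags, ripley,
                                  sh[, 1], sh[, 2])
  } else {
    za <- standardise_marks(a)
    zb <- standardise_marks(b)
    pp <- kmm_pairs_cpp(a$x, a$y, b$x, b$y, W, H, grid$lags, ripley)
    emp <- kmm_curves_cpp(pp$bin, pp$w, pp$i, pp$j, matrix(za), matrix(zb),
                          nl)[1, ]
    perms <- with_seed(seed, list(
      za = vapply(seq_len(n_sim), function(k) za[sample.int(a$n)],
                  numeric(a$n)),
      zb = vapply(seq_len(n_sim), function(k) zb[sample.int(b$n)],
                  numeric(b$n))))
    sims <- kmm_curves_cpp(pp$bin, pp$w, pp$i, pp$j,
                           matrix(perms$za, nrow = a$n),
                           matrix(perms$zb, nrow = b$n), nl)
  }

  k <- envelope_rank(n_sim, alpha)
  lower <- upper <- rep(NA_real_, nl)
  for (l in seq_len(nl)) {
    v <- sims[, l]
    if (anyNA(v)) next  # undefined lag (kmm before the first pair)
    v <- sort.int(v)
    lower[l] <- v[k]
    upper[l] <- v[n_sim + 1 - k]
  }
  structure(list(grid = grid, empirical = emp, lower = lower, upper = upper,
                 sims = sims, n_sim = n_sim, alpha = alpha,
                 statistic = statistic, edge_mode = corr,
                 null_model = if (statistic == "lrs") "toroidal_shift"
                              else "random_marking",
                 shifted = shifted, seed = as.integer(seed),
                 species = c(a$species, b$species)),
            class = "assoc_envelope")
}

#' @export
print.assoc_envelope <- function(x, ...) {
  cat(sprintf(
    "%s envelope (%s vs %s): %d sims, alpha %.3f, %d lags to %g m\n",
    x$statistic, x$species[1], x$species[2], x$n_sim, x$alpha,
    length(x$grid$lags), x$grid$max_d))
  invisible(x)
}

#' Pointwise Monte Carlo quasi p-value
#'
#' The rank-based p-value at one lag:
#' `p = (1 + number of simulated values at least as extreme as the
#' empirical value, on the side of the empirical deviation) / (n_sim + 1)`.
#' The side is taken as "high" when the empirical value is at or above the
#' simulated median, "low" otherwise.
#'
#' @param env An `assoc_envelope`.
#' @param at A lag on the envelope's grid (m).
#' @return A probability in `[1/(n_sim+1), 1]`.
#' @export
quasi_p <- function(env, at) {
  stopifnot(inherits(env, "assoc_envelope"))
  idx <- which(abs(env$grid$lags - at) < 1e-9)
  if (length(idx) != 1) stop(sprintf("lag %g is not on the grid", at))
  e <- env$empirical[idx]
  v <- env$sims[, idx]
  v <- v[!is.na(v)]
  if (is.na(e) || !length(v))
    stop(sprintf("statistic undefined at lag %g", at))
  cnt <- if (e >= stats::median(v)) sum(v >= e) else sum(v <= e)
  (1 + cnt) / (env$n_sim + 1)
}
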