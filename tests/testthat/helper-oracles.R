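# Shared fixtures and independent reference implementations used across
# the test files. The oracles are deliberately naive: plain double loops
# over ordered pairs, plus a numerical arc-integration version of the
# isotropic edge weight, so they share no code path with the package's
# C++ estimators.

rpat <- function(n, w = pp_window(100, 100), species = "sp",
                 marks = NULL) {
  if (is.null(marks)) marks <- stats::rlnorm(n, 2.3, 0.6)
  marked_pattern(stats::runif(n, 0, w$width), stats::runif(n, 0, w$height),
                 marks, w, species = species)
}

# closed-form fraction of the circle of radius r centred at (px, py)
# inside [0,W]x[0,H]; independent R derivation of the rectangle-window
# isotropic correction (edge arcs minus doubly counted corner wedges)
edge_frac_r <- function(px, py, r, W, H) {
  if (r <= 0) return(1)
  e <- c(px, W - px, py, H - py)
  ext <- sum(2 * acos(pmin(e, r) / r))
  for (cr in list(c(1, 3), c(1, 4), c(2, 3), c(2, 4))) {
    e1 <- e[cr[1]]; e2 <- e[cr[2]]
    if (e1 < r && e2 < r && e1^2 + e2^2 < r^2)
      ext <- ext - (acos(e1 / r) + acos(e2 / r) - pi / 2)
  }
  1 - ext / (2 * pi)
}

# brute-force numerical version: sample the circle densely and count the
# fraction of arc inside the window
arc_frac_numeric <- function(px, py, r, W, H, k = 200001) {
  th <- seq(0, 2 * pi, length.out = k)[-1]
  x <- px + r * cos(th); y <- py + r * sin(th)
  mean(x >= 0 & x <= W & y >= 0 & y <= H)
}

oracle_lrs <- function(a, b, lags, corr = "none") {
  A <- a$window$area; W <- a$window$width; H <- a$window$height
  N <- a$n + b$n
  vapply(lags, function(d) {
    sab <- 0; sba <- 0
    for (i in seq_len(a$n)) for (j in seq_len(b$n)) {
      dij <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
      if (dij <= d) {
        if (corr == "ripley_isotropic") {
          sab <- sab + 1 / edge_frac_r(a$x[i], a$y[i], dij, W, H)
          sba <- sba + 1 / edge_frac_r(b$x[j], b$y[j], dij, W, H)
        } else {
          sab <- sab + 1; sba <- sba + 1
        }
      }
    }
    A / (N^2 * pi) * (sab / a$n + sba / b$n)
  }, numeric(1))
}

oracle_kmm <- function(a, b, lags, corr = "none") {
  W <- a$window$width; H <- a$window$height
  za <- (a$marks - mean(a$marks)) / stats::sd(a$marks)
  zb <- (b$marks - mean(b$marks)) / stats::sd(b$marks)
  vapply(lags, function(d) {
    num <- 0; den <- 0
    for (i in seq_len(a$n)) for (j in seq_len(b$n)) {
      dij <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
      if (dij <= d) {
        w <- if (corr == "ripley_isotropic")
          1 / edge_frac_r(a$x[i], a$y[i], dij, W, H) +
            1 / edge_frac_r(b$x[j], b$y[j], dij, W, H)
        else 2
        num <- num + w * za[i] * zb[j]
        den <- den + w
      }
    }
    if (den > 0) num / den else NA_real_
  }, numeric(1))
}

# pairwise toroidal distances between two coordinate sets
toroidal_dists <- function(x1, y1, x2, y2, W, H) {
  dx <- abs(outer(x1, x2, "-")); dx <- pmin(dx, W - dx)
  dy <- abs(outer(y1, y2, "-")); dy <- pmin(dy, H - dy)
  sqrt(dx^2 + dy^2)
}

# small census data frame builder for filter tests
toy_census <- function(counts, window = pp_window(100, 100)) {
  # counts: named list species -> vector of per-plot counts
  rows <- list()
  for (sp in names(counts)) {
    for (p in seq_along(counts[[sp]])) {
      n <- counts[[sp]][p]
      if (n == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        plot_id = paste0("plot", p), tree_id = NA_character_, species = sp,
        x = stats::runif(n, 0, window$width),
        y = stats::runif(n, 0, window$height),
        dbh = stats::rlnorm(n, 2.3, 0.6), height = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$tree_id <- as.character(seq_len(nrow(df)))
  census_table(df, window)
}
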