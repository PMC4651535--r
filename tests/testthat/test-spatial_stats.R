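test_that("closed-form isotropic edge weight matches numeric arc integration", {
  set.seed(10)
  W <- 100; H <- 60
  for (k in 1:25) {
    px <- runif(1, 0, W); py <- runif(1, 0, H); r <- runif(1, 0.5, H / 2)
    expect_equal(interspat:::interior_fraction_cpp(px, py, r, W, H),
                 arc_frac_numeric(px, py, r, W, H),
                 tolerance = 1e-4)
  }
  # interior point with the circle fully inside: no correction
  expect_equal(interspat:::interior_fraction_cpp(50, 30, 10, W, H), 1)
  # corner point, small radius: quarter of the circle inside
  expect_equal(interspat:::interior_fraction_cpp(0, 0, 5, W, H), 0.25)
})

test_that("cross pair weights count intertype pairs directionally", {
  w <- pp_window(100, 100)
  a <- marked_pattern(40, 50, 10, w, "A")
  b <- marked_pattern(50, 50, 12, w, "B")
  expect_equal(cross_pair_weights(a, b, 5, "none"),
               list(sum_ab = 0, sum_ba = 0))
  expect_equal(cross_pair_weights(a, b, 15, "none"),
               list(sum_ab = 1, sum_ba = 1))

  # 3+3 layout near the boundary: Ripley weights from the arc oracle
  set.seed(11)
  a3 <- marked_pattern(c(2, 10, 95), c(3, 50, 97), c(1, 2, 3), w, "A")
  b3 <- marked_pattern(c(8, 15, 90), c(1, 55, 99), c(1, 2, 3), w, "B")
  got <- cross_pair_weights(a3, b3, 20, "ripley_isotropic")
  sab <- 0; sba <- 0
  for (i in 1:3) for (j in 1:3) {
    dij <- sqrt((a3$x[i] - b3$x[j])^2 + (a3$y[i] - b3$y[j])^2)
    if (dij <= 20) {
      sab <- sab + 1 / arc_frac_numeric(a3$x[i], a3$y[i], dij, 100, 100)
      sba <- sba + 1 / arc_frac_numeric(b3$x[j], b3$y[j], dij, 100, 100)
    }
  }
  expect_equal(got$sum_ab, sab, tolerance = 1e-4)
  expect_equal(got$sum_ba, sba, tolerance = 1e-4)

  wb <- pp_window(50, 50)
  expect_error(cross_pair_weights(a, marked_pattern(10, 10, 1, wb), 5),
               "share one observation window")
})

test_that("intertype L matches the hand-expanded double-loop oracle", {
  w <- pp_window(100, 100)
  g <- distance_grid(max_d = 50, step = 2.5)
  # toy 2+2 layout, both edge modes
  a <- marked_pattern(c(20, 30), c(20, 35), c(5, 9), w, "A")
  b <- marked_pattern(c(22, 80), c(24, 90), c(4, 11), w, "B")
  expect_equal(lrs_hat(a, b, g, "none")$values,
               oracle_lrs(a, b, g$lags, "none"), tolerance = 1e-12)
  expect_equal(lrs_hat(a, b, g, "ripley_isotropic")$values,
               oracle_lrs(a, b, g$lags, "ripley_isotropic"),
               tolerance = 1e-10)

  # no intertype pair within 50 m: identically zero curve
  a2 <- marked_pattern(c(1, 2), c(1, 2), c(5, 6), w, "A")
  b2 <- marked_pattern(c(99, 98), c(99, 98), c(5, 6), w, "B")
  expect_true(all(lrs_hat(a2, b2, g, "none")$values == 0))

  # empty pattern errors name the species
  expect_error(lrs_hat(marked_pattern(numeric(0), numeric(0), numeric(0),
                                      w, "Empty"), b, g),
               "Empty")
})

test_that("uncorrected intertype L is monotone and exactly symmetric", {
  set.seed(12)
  g <- distance_grid()
  for (k in 1:5) {
    a <- rpat(sample(5:40, 1), species = "A")
    b <- rpat(sample(5:40, 1), species = "B")
    v <- lrs_hat(a, b, g, "none")$values
    expect_true(all(diff(v) >= 0))
    expect_identical(lrs_hat(a, b, g)$values, lrs_hat(b, a, g)$values)
    expect_identical(kmm_hat(a, b, g)$values, kmm_hat(b, a, g)$values)
  }
})

test_that("intertype L under CSR independence matches its analytic expectation", {
  # for two independent uniform patterns in an L x L window the exact
  # expectation without edge correction is G(d) / (2 n pi L^2) with
  # G(d) = pi d^2 L^2 - (8/3) d^3 L + d^4 / 2 (disc-window overlap
  # integral); with isotropic correction the estimator is unbiased for
  # d^2 / (n_r + n_s). Verified by Monte Carlo at two lags.
  set.seed(13)
  w <- pp_window(100, 100); L <- 100; n <- 100
  g <- distance_grid(lags = c(5, 10))
  reps <- 1000
  none <- matrix(0, reps, 2); rip <- matrix(0, reps, 2)
  for (r in seq_len(reps)) {
    a <- rpat(n, w, "A"); b <- rpat(n, w, "B")
    none[r, ] <- lrs_hat(a, b, g, "none")$values
    rip[r, ] <- lrs_hat(a, b, g, "ripley_isotropic")$values
  }
  G <- function(d) pi * d^2 * L^2 - (8 / 3) * d^3 * L + d^4 / 2
  expected_none <- G(g$lags) / (2 * n * pi * L^2)
  expected_rip <- g$lags^2 / (2 * n)
  for (k in 1:2) {
    expect_lt(abs(mean(none[, k]) - expected_none[k]),
              4 * sd(none[, k]) / sqrt(reps))
    expect_lt(abs(mean(rip[, k]) - expected_rip[k]),
              4 * sd(rip[, k]) / sqrt(reps))
  }
})

test_that("mark correlation matches its oracle and mark invariances", {
  w <- pp_window(100, 100)
  g <- distance_grid(max_d = 50, step = 5)
  a <- marked_pattern(c(20, 30), c(20, 35), c(1, 3), w, "A")
  b <- marked_pattern(c(22, 80), c(24, 90), c(2, 6), w, "B")
  expect_equal(kmm_hat(a, b, g, "none")$values,
               oracle_kmm(a, b, g$lags, "none"), tolerance = 1e-12)
  expect_equal(kmm_hat(a, b, g, "ripley_isotropic")$values,
               oracle_kmm(a, b, g$lags, "ripley_isotropic"),
               tolerance = 1e-10)
  # lags before the closest intertype pair are undefined, not zero
  mind <- min(sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2))
  g2 <- distance_grid(max_d = 50, step = 2)
  vals <- kmm_hat(a, b, g2, "none")$values
  expect_true(all(is.na(vals[g2$lags < mind])))
  expect_true(all(!is.na(vals[g2$lags >= mind])))

  set.seed(14)
  a <- rpat(25, w, "A"); b <- rpat(30, w, "B")
  base <- kmm_hat(a, b, g)$values
  # positive affine transform of one species' marks: unchanged
  a2 <- marked_pattern(a$x, a$y, 2 * a$marks + 5, w, "A")
  expect_equal(kmm_hat(a2, b, g)$values, base, tolerance = 1e-12)
  # negating one species' marks flips the sign
  a3 <- marked_pattern(a$x, a$y, -a$marks, w, "A")
  expect_equal(kmm_hat(a3, b, g)$values, -base, tolerance = 1e-12)
  # constant marks are an error naming the species
  a4 <- marked_pattern(a$x, a$y, rep(7, a$n), w, "Aconst")
  expect_error(kmm_hat(a4, b, g), "marks constant for species 'Aconst'")
})

test_that("mark correlation is centred under random relabelling", {
  set.seed(15)
  w <- pp_window(100, 100)
  g <- distance_grid(lags = c(10, 25, 50))
  a <- rpat(50, w, "A"); b <- rpat(50, w, "B")
  perm <- replicate(1000, {
    ap <- marked_pattern(a$x, a$y, sample(a$marks), w, "A")
    bp <- marked_pattern(b$x, b$y, sample(b$marks), w, "B")
    kmm_hat(ap, bp, g, "none")$values
  })
  m <- rowMeans(perm)
  se <- apply(perm, 1, sd) / sqrt(ncol(perm))
  expect_true(all(abs(m) < 4 * se + 1e-3))
})
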