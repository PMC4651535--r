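fake_pooled <- function(values, per_replicate = NULL) {
  g <- distance_grid(max_d = length(values) / 2, step = 0.5)
  if (is.null(per_replicate))
    per_replicate <- matrix(values, ncol = 1)
  structure(list(grid = g, values = values,
                 per_replicate = per_replicate,
                 n_rep = rowSums(!is.na(per_replicate)),
                 statistic = "lrs", species = c("A", "B")),
            class = "pooled_curve")
}

test_that("significant intervals are maximal signed excursions", {
  v <- rep(0, 100)
  expect_equal(nrow(significant_intervals(fake_pooled(v))), 0)

  # above the band on lags 8..20 m only -> one positive interval
  lags <- distance_grid(max_d = 50, step = 0.5)$lags
  v <- rep(0, 100); v[lags >= 8 & lags <= 20] <- 1.5
  iv <- significant_intervals(fake_pooled(v))
  expect_equal(iv, data.frame(d_min = 8, d_max = 20, sign = "+"))

  # two runs with opposite signs
  v2 <- rep(0, 100); v2[1:4] <- -1.2; v2[50:60] <- 1.3
  iv2 <- significant_intervals(fake_pooled(v2))
  expect_equal(iv2$sign, c("-", "+"))
  expect_equal(iv2$d_min, c(0.5, 25))

  # strict coincidence: a lag counts only if every defined replicate
  # exits the band on the pooled side
  v3 <- rep(0, 100); v3[10] <- 1.5
  pr <- cbind(rep(0, 100), rep(0, 100))
  pr[10, ] <- c(2.5, 0.5)  # one replicate inside the band
  expect_equal(nrow(significant_intervals(fake_pooled(v3, pr), "strict")), 0)
  expect_equal(nrow(significant_intervals(fake_pooled(v3, pr), "pooled")), 1)
  pr[10, ] <- c(2, 1.1)
  expect_equal(nrow(significant_intervals(fake_pooled(v3, pr), "strict")), 1)
})

test_that("the representative distance maximises band exceedance", {
  lags <- distance_grid(max_d = 50, step = 0.5)$lags
  v <- rep(0, 100)
  v[lags == 5] <- 2.2   # exceedance 1.2
  v[lags == 12] <- 2.9  # exceedance 1.9
  pc <- fake_pooled(v)
  iv <- significant_intervals(pc)
  r <- representative_distance(pc, iv)
  expect_equal(r$d_star, 12)
  expect_equal(r$exceedance, 1.9)
  expect_equal(r$sign, "+")

  # single-lag exceedance -> that lag
  v1 <- rep(0, 100); v1[lags == 30] <- -1.4
  pc1 <- fake_pooled(v1)
  r1 <- representative_distance(pc1, significant_intervals(pc1))
  expect_equal(r1$d_star, 30)
  expect_equal(r1$sign, "-")

  # exact tie at 5 m and 30 m breaks toward the smaller distance
  v2 <- rep(0, 100); v2[lags == 5] <- 1.7; v2[lags == 30] <- 1.7
  pc2 <- fake_pooled(v2)
  expect_equal(representative_distance(pc2,
                                       significant_intervals(pc2))$d_star, 5)

  expect_error(representative_distance(pc, iv[0, ]), "no significant")
})

test_that("association matrices fill opposite triangles and count cells", {
  sp <- c("A", "B", "C", "D")
  empty <- build_matrix(data.frame(), sp)
  expect_true(all(is.na(empty$matrix)))
  expect_true(all(empty$counts == 0))

  rec <- data.frame(species_a = c("A", "A", "B"),
                    species_b = c("B", "C", "C"),
                    statistic = c("lrs", "kmm", "lrs"),
                    sign = c("+", "-", "+"),
                    d_star = c(7, 12, 3), stringsAsFactors = FALSE)
  m <- build_matrix(rec, sp)
  # lrs in the lower-left triangle as signed distances
  expect_equal(m$matrix["B", "A"], 7)
  expect_equal(m$matrix["C", "B"], 3)
  # kmm in the upper-right triangle
  expect_equal(m$matrix["A", "C"], -12)
  expect_true(is.na(m$matrix["C", "A"]))
  expect_equal(unname(m$counts[, "lrs"]), c(1L, 2L, 1L, 0L))
  expect_equal(unname(m$counts[, "kmm"]), c(1L, 0L, 1L, 0L))
  # the per-species count equals the filled cells of its row + column
  for (s in sp) {
    lower <- m$matrix; lower[upper.tri(lower, diag = TRUE)] <- NA
    expect_equal(unname(m$counts[s, "lrs"]),
                 sum(!is.na(lower[s, ])) + sum(!is.na(lower[, s])))
  }

  dup <- rbind(rec, data.frame(species_a = "B", species_b = "A",
                               statistic = "lrs", sign = "-", d_star = 1))
  expect_error(build_matrix(dup, sp), "duplicate")
  expect_error(build_matrix(rec, c("A", "B")), "not in the species list")
})

test_that("guild cross-tabs tally trait similarity by sign", {
  traits <- structure(data.frame(
    species = c("A", "B", "C", "D"),
    life_form = c("canopy", "canopy", "under", "under"),
    shade_tolerance = c("tol", "intol", "tol", NA),
    dispersal = c("bird", "wind", "bird", "bird"),
    stringsAsFactors = FALSE), class = c("trait_table", "data.frame"))

  rec <- data.frame(species_a = "A", species_b = "B", statistic = "lrs",
                    sign = "+", d_star = 5, stringsAsFactors = FALSE)
  ct <- guild_crosstab(rec, traits)
  hit <- ct$counts[ct$counts$count > 0, ]
  expect_equal(nrow(hit), 3)
  expect_equal(hit$count, rep(1L, 3))
  expect_true(all(hit$sign == "+"))
  expect_equal(hit$same[hit$trait == "life_form"], TRUE)
  expect_equal(hit$same[hit$trait == "dispersal"], FALSE)

  # a record with a missing trait is excluded from that tab only
  rec2 <- data.frame(species_a = "C", species_b = "D", statistic = "lrs",
                     sign = "-", d_star = 2, stringsAsFactors = FALSE)
  ct2 <- guild_crosstab(rec2, traits)
  expect_equal(unname(ct2$excluded["shade_tolerance"]), 1L)
  expect_equal(sum(ct2$counts$count[ct2$counts$trait == "shade_tolerance"]),
               0L)
  expect_equal(sum(ct2$counts$count[ct2$counts$trait == "life_form"]), 1L)

  # brute-force tally oracle on a batch of synthetic records
  set.seed(50)
  sp <- traits$species
  recs <- data.frame(t(combn(sp, 2)), stringsAsFactors = FALSE)
  names(recs) <- c("species_a", "species_b")
  recs$statistic <- "lrs"
  recs$sign <- sample(c("+", "-"), nrow(recs), replace = TRUE)
  recs$d_star <- 1
  ct3 <- guild_crosstab(recs, traits)
  for (tr in c("life_form", "dispersal")) {
    va <- traits[[tr]][match(recs$species_a, traits$species)]
    vb <- traits[[tr]][match(recs$species_b, traits$species)]
    for (sgn in c("+", "-")) for (same in c(TRUE, FALSE)) {
      expect_equal(
        ct3$counts$count[ct3$counts$trait == tr & ct3$counts$same == same &
                           ct3$counts$sign == sgn],
        sum((va == vb) == same & recs$sign == sgn))
    }
  }
})

test_that("habitat concordance follows the attraction/avoidance rules", {
  hab <- data.frame(
    species = c("A", "B", "C", "D", "D"),
    habitat = c("gap", "gap", "stream", "gap", "stream"),
    relation = c("association", "association", "association",
                 "avoidance", "association"),
    stringsAsFactors = FALSE)
  rec <- function(a, b, sgn)
    data.frame(species_a = a, species_b = b, statistic = "lrs", sign = sgn,
               d_star = 1, stringsAsFactors = FALSE)
  # + pair sharing an associated habitat: concordant
  expect_equal(habitat_concordance(rec("A", "B", "+"), hab)$concordant, 1)
  # + pair with disjoint habitats: discordant
  expect_equal(habitat_concordance(rec("A", "C", "+"), hab)$concordant, 0)
  # - pair where one avoids the habitat the other is associated with
  expect_equal(habitat_concordance(rec("A", "D", "-"), hab)$concordant, 1)
  # species absent from the table: treated as no habitat relation
  expect_equal(habitat_concordance(rec("A", "Z", "+"), hab)$concordant, 0)

  # fraction over a toy batch: 2 concordant of 4 records
  recs <- rbind(rec("A", "B", "+"), rec("A", "C", "+"),
                rec("A", "D", "-"), rec("B", "D", "+"))
  hc <- habitat_concordance(recs, hab)
  expect_equal(hc$total, 4)
  expect_equal(hc$fraction, hc$concordant / 4)
  expect_equal(hc$is_concordant, c(TRUE, FALSE, TRUE, FALSE))
})
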