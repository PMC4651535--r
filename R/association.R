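curve_values <- function(curve) {
  stopifnot(inherits(curve, "standardized_curve") ||
              inherits(curve, "pooled_curve"))
  curve$values
}

#' Scales of significant deviation from the null band
#'
#' Finds the maximal runs of consecutive lags at which a standardised
#' curve exits the `[-1, 1]` null band on one side; each run is one
#' signed interval of spatial association (`+` above the band, `-` below).
#' For a pooled curve the default `rule = "strict"` additionally requires
#' every contributing replicate to exit the band on the same side at the
#' lag (only coincident deviations across replicate plots are kept,
#' suppressing casual single-plot excursions); `rule = "pooled"` uses the
#' pooled curve alone.
#'
#' @param curve A `standardized_curve` or `pooled_curve`.
#' @param rule Coincidence rule for pooled curves, `"strict"` (default)
#'   or `"pooled"`.
#' @return Data frame with columns `d_min`, `d_max`, `sign` (`"+"`/`"-"`),
#'   possibly empty.
#' @export
significant_intervals <- function(curve, rule = c("strict", "pooled")) {
  rule <- match.arg(rule)
  v <- curve_values(curve)
  side <- ifelse(is.na(v), 0L, ifelse(v > 1, 1L, ifelse(v < -1, -1L, 0L)))
  if (inherits(curve, "pooled_curve") && rule == "strict") {
    m <- curve$per_replicate
    for (l in which(side != 0L)) {
      reps <- m[l, !is.na(m[l, ])]
      if (!length(reps) || !all(side[l] * reps > 1)) side[l] <- 0L
    }
  }
  lags <- curve$grid$lags
  out <- data.frame(d_min = numeric(0), d_max = numeric(0),
                    sign = character(0), stringsAsFactors = FALSE)
  r <- rle(side)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0L
  if (any(keep))
    out <- data.frame(d_min = lags[starts[keep]], d_max = lags[ends[keep]],
                      sign = ifelse(r$values[keep] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  out
}

#' Single representative distance of an association
#'
#' Reduces a pair's significant intervals to the one distance at which the
#' association is strongest: the lag maximising the exceedance beyond the
#' standardised band, `|F_st(d)| - 1`. Because the standardisation already
#' rescales by the local null-band width, this weighs the deviation by the
#' width of the acceptance region at each distance. Ties break toward the
#' smallest distance.
#'
#' @param curve The standardised (or pooled) curve the intervals came from.
#' @param intervals Output of [significant_intervals()]; must be non-empty.
#' @param envelopes Optional list of the per-replicate `assoc_envelope`s;
#'   when given, a pointwise quasi p-value at the chosen distance is
#'   computed by ranking the pooled standardised empirical value against
#'   the pooled standardised null simulations (simulation k of each
#'   replicate mapped through its own band transform, then averaged over
#'   the replicates where the lag is defined). With a single replicate
#'   this is identical to [quasi_p()] on that envelope, because the band
#'   transform is strictly increasing.
#' @return List with `d_star`, `exceedance` (`|F_st| - 1` there), `sign`,
#'   and `quasi_p` (`NA` when no envelopes supplied).
#' @export
representative_distance <- function(curve, intervals, envelopes = NULL) {
  if (is.null(intervals) || nrow(intervals) == 0)
    stop("no significant intervals to summarise")
  v <- curve_values(curve)
  lags <- curve$grid$lags
  in_int <- rep(FALSE, length(lags))
  for (r in seq_len(nrow(intervals)))
    in_int <- in_int | (lags >= intervals$d_min[r] &
                          lags <= intervals$d_max[r])
  exc <- ifelse(in_int & !is.na(v), abs(v) - 1, -Inf)
  idx <- which.max(exc)  # first maximum = smallest distance on ties
  p <- NA_real_
  if (!is.null(envelopes) && length(envelopes)) {
    # pooled null at this lag: each replicate's simulated curves mapped
    # through its own band transform, averaged across the replicates
    # where the lag is defined (a plot with no intertype pair yet at
    # this distance contributes nothing)
    std_sims <- lapply(envelopes, function(e) {
      rng <- e$upper[idx] - e$lower[idx]
      if (is.na(rng) || rng <= 0 || is.na(e$empirical[idx]))
        return(NULL)
      b <- 2 / rng
      (1 - b * e$upper[idx]) + b * e$sims[, idx]
    })
    std_sims <- std_sims[!vapply(std_sims, is.null, logical(1))]
    if (length(std_sims)) {
      pooled_null <- rowMeans(do.call(cbind, std_sims))
      emp <- v[idx]
      cnt <- if (emp >= stats::median(pooled_null)) sum(pooled_null >= emp)
             else sum(pooled_null <= emp)
      p <- (1 + cnt) / (length(pooled_null) + 1)
    }
  }
  list(d_star = lags[idx], exceedance = exc[idx],
       sign = if (v[idx] > 0) "+" else "-", quasi_p = p)
}

#' Assemble the pairwise association matrix
#'
#' Builds the species-by-species summary matrix: the lower-left triangle
#' holds signed representative distances from the intertype L analysis,
#' the upper-right triangle those from the intertype mark-correlation
#' analysis. An entry's sign encodes the association direction (for `lrs`:
#' attraction/repulsion of stems; for `kmm`: attraction among similar- vs
#' opposite-stage stems) and its magnitude the representative distance in
#' metres. Per-species association counts per statistic are the number of
#' filled cells in that species' row and column of the triangle.
#'
#' @param records Data frame of association records with columns
#'   `species_a`, `species_b`, `statistic` (`"lrs"`/`"kmm"`), `sign`
#'   (`"+"`/`"-"`) and `d_star`.
#' @param species Character vector of all analysed species (matrix order).
#' @return An `assoc_matrix`: list with `species`, `matrix` (numeric,
#'   `NA` = no association) and `counts` (species x statistic).
#' @export
build_matrix <- function(records, species) {
  species <- as.character(species)
  n <- length(species)
  m <- matrix(NA_real_, n, n, dimnames = list(species, species))
  counts <- matrix(0L, n, 2, dimnames = list(species, c("lrs", "kmm")))
  if (nrow(records)) {
    if (!all(records$species_a %in% species) ||
        !all(records$species_b %in% species))
      stop("records reference species not in the species list")
    key <- paste(pmin(records$species_a, records$species_b),
                 pmax(records$species_a, records$species_b),
                 records$statistic)
    if (anyDuplicated(key))
      stop("duplicate association record for a (pair, statistic)")
    for (r in seq_len(nrow(records))) {
      i <- match(records$species_a[r], species)
      j <- match(records$species_b[r], species)
      lo <- max(i, j); hi <- min(i, j)
      val <- records$d_star[r] * if (records$sign[r] == "+") 1 else -1
      if (records$statistic[r] == "lrs") m[lo, hi] <- val else m[hi, lo] <- val
      counts[c(i, j), records$statistic[r]] <-
        counts[c(i, j), records$statistic[r]] + 1L
    }
  }
  structure(list(species = species, matrix = m, counts = counts),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf(
    "association matrix: %d species, %d lrs and %d kmm associations\n",
    length(x$species), sum(x$counts[, "lrs"]) / 2,
    sum(x$counts[, "kmm"]) / 2))
  invisible(x)
}

#' Cross-tabulate associations by guild similarity
#'
#' Counts detected pairwise associations by whether the two species share
#' a trait value (life form, shade tolerance, dispersal mode), split by
#' association sign. A record whose species lack a value for a trait is
#' excluded from that trait's tabulation only, and reported.
#'
#' @param records Association-record data frame (see [build_matrix()]).
#' @param traits A `trait_table` (see [read_traits()]).
#' @return List with `counts` (data frame: `trait`, `same`, `sign`,
#'   `count`) and `excluded` (per-trait records dropped for missing trait
#'   values).
#' @export
guild_crosstab <- function(records, traits) {
  trait_cols <- c("life_form", "shade_tolerance", "dispersal")
  counts <- expand.grid(trait = trait_cols, same = c(TRUE, FALSE),
                        sign = c("+", "-"), stringsAsFactors = FALSE)
  counts$count <- 0L
  excluded <- stats::setNames(integer(length(trait_cols)), trait_cols)
  for (r in seq_len(nrow(records))) {
    ta <- traits[match(records$species_a[r], traits$species), ]
    tb <- traits[match(records$species_b[r], traits$species), ]
    for (tr in trait_cols) {
      va <- if (nrow(ta)) ta[[tr]] else NA
      vb <- if (nrow(tb)) tb[[tr]] else NA
      if (is.na(va) || is.na(vb) || !nzchar(va) || !nzchar(vb)) {
        excluded[tr] <- excluded[tr] + 1L
        next
      }
      row <- counts$trait == tr & counts$same == (va == vb) &
        counts$sign == records$sign[r]
      counts$count[row] <- counts$count[row] + 1L
    }
  }
  list(counts = counts, excluded = excluded)
}

#' Concordance of spatial associations with habitat associations
#'
#' Checks each detected association against an externally supplied table
#' of species-habitat relations: a positive spatial association is
#' concordant when both species are associated with a common habitat; a
#' negative one when one species is associated with a habitat the other
#' avoids. Species absent from the table are treated as having no habitat
#' relation.
#'
#' @param records Association-record data frame.
#' @param habitat_table Data frame with columns `species`, `habitat`,
#'   `relation` (`"association"` or `"avoidance"`).
#' @return List with `concordant` (count), `total`, `fraction` and a
#'   per-record logical vector `is_concordant`.
#' @export
habitat_concordance <- function(records, habitat_table) {
  stopifnot(all(c("species", "habitat", "relation") %in%
                  names(habitat_table)))
  rel <- function(sp, what)
    habitat_table$habitat[habitat_table$species == sp &
                            habitat_table$relation == what]
  conc <- logical(nrow(records))
  for (r in seq_len(nrow(records))) {
    a <- records$species_a[r]; b <- records$species_b[r]
    conc[r] <- if (records$sign[r] == "+") {
      length(intersect(rel(a, "association"), rel(b, "association"))) > 0
    } else {
      length(intersect(rel(a, "association"), rel(b, "avoidance"))) > 0 ||
        length(intersect(rel(a, "avoidance"), rel(b, "association"))) > 0
    }
  }
  list(concordant = sum(conc), total = nrow(records),
       fraction = if (nrow(records)) sum(conc) / nrow(records) else NA_real_,
       is_concordant = conc)
}
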