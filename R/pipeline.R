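#' Analysis configuration for a full pairwise run
#'
#' Collects every tunable of the end-to-end analysis. Defaults follow the
#' standard protocol for 1-ha stem maps: 399 null simulations, 95%
#' pointwise envelopes, quasi p-value acceptance at 0.01, distances to
#' 50 m in 0.5 m steps, Ripley isotropic edge correction, abundance
#' threshold of more than 60 stems per plot, and the strict
#' across-replicate coincidence rule.
#'
#' @param n_sim Null simulations per envelope (>= 19).
#' @param alpha Envelope level (0.05 = 95% band).
#' @param p_threshold Pointwise quasi p-value required to accept an
#'   association (default 0.01); `NA` disables the p filter (envelope
#'   exceedance alone decides).
#' @param grid A [distance_grid()].
#' @param corr Edge-correction mode.
#' @param rule Replicate coincidence rule (see
#'   [significant_intervals()]).
#' @param min_n,min_plots Species filter settings (see
#'   [filter_species()]).
#' @param seed Top-level seed; every (pair, plot, statistic) unit uses a
#'   sub-seed derived from it, so single pairs re-run bit-identically.
#' @return A `run_config`.
#' @export
run_config <- function(n_sim = 399, alpha = 0.05, p_threshold = 0.01,
                       grid = distance_grid(), corr = "ripley_isotropic",
                       rule = "strict", min_n = 60, min_plots = NULL,
                       seed = 1L) {
  stopifnot(n_sim >= 19, alpha > 0, alpha < 1,
            is.na(p_threshold) || (p_threshold > 0 && p_threshold < 1))
  structure(list(n_sim = n_sim, alpha = alpha, p_threshold = p_threshold,
                 grid = grid, corr = corr, rule = rule, min_n = min_n,
                 min_plots = min_plots, seed = as.integer(seed)),
            class = "run_config")
}

empty_records <- function() {
  data.frame(species_a = character(0), species_b = character(0),
             statistic = character(0), sign = character(0),
             d_min = numeric(0), d_max = numeric(0), d_star = numeric(0),
             exceedance = numeric(0), quasi_p = numeric(0),
             n_plots = integer(0), stringsAsFactors = FALSE)
}

#' Analyse one species pair
#'
#' Runs both intertype statistics for a single pair across every plot
#' where both species pass the abundance filter: per-plot envelopes
#' (toroidal shift for the L-type function, random marking for the mark
#' correlation), standardisation onto the `[-1, 1]` band, pooling,
#' interval detection under the configured coincidence rule, and the
#' representative distance with its quasi p-value (the largest across
#' contributing plots). Results are bit-identical to the same pair's
#' slice of [run_all()] because sub-seeds are keyed by the sorted pair,
#' plot and statistic.
#'
#' @param census A `census_table`.
#' @param species_a,species_b The pair (order does not matter).
#' @param cfg A [run_config()].
#' @param filter Optional precomputed [filter_species()] result.
#' @param keep_curves Keep pooled/standardised curves in the result.
#' @return List with `records` (accepted associations, possibly empty),
#'   `candidates` (envelope exceedances before the p filter) and, when
#'   requested, `curves`.
#' @export
run_pair <- function(census, species_a, species_b, cfg = run_config(),
                     filter = NULL, keep_curves = FALSE) {
  if (is.null(filter))
    filter <- filter_species(census, cfg$min_n, cfg$min_plots)
  sp <- sort(c(species_a, species_b))
  for (s in sp)
    if (!s %in% filter$included)
      stop(sprintf(
        "species '%s' is not in the filtered set (needs > %d stems in enough plots)",
        s, cfg$min_n))
  plots <- colnames(filter$usable)
  usable <- plots[filter$usable[sp[1], ] & filter$usable[sp[2], ]]
  if (!length(usable))
    stop(sprintf("no plot usable for pair %s - %s", sp[1], sp[2]))

  records <- empty_records()
  candidates <- empty_records()
  curves <- list()
  for (statistic in c("lrs", "kmm")) {
    envs <- lapply(usable, function(pl) {
      pats <- census_patterns(census, pl, sp)
      envelope(pats[[1]], pats[[2]], statistic, n_sim = cfg$n_sim,
               alpha = cfg$alpha,
               seed = derive_seed(cfg$seed,
                                  paste(sp[1], sp[2], pl, statistic)),
               grid = cfg$grid, corr = cfg$corr)
    })
    pooled <- pool(lapply(envs, standardize))
    if (keep_curves) curves[[statistic]] <- pooled
    ints <- significant_intervals(pooled, rule = cfg$rule)
    if (!nrow(ints)) next
    rep <- representative_distance(pooled, ints, envelopes = envs)
    iv <- ints[ints$d_min <= rep$d_star & ints$d_max >= rep$d_star, ][1, ]
    rec <- data.frame(species_a = sp[1], species_b = sp[2],
                      statistic = statistic, sign = rep$sign,
                      d_min = iv$d_min, d_max = iv$d_max,
                      d_star = rep$d_star, exceedance = rep$exceedance,
                      quasi_p = rep$quasi_p, n_plots = length(usable),
                      stringsAsFactors = FALSE)
    candidates <- rbind(candidates, rec)
    if (is.na(cfg$p_threshold) || rep$quasi_p <= cfg$p_threshold)
      records <- rbind(records, rec)
  }
  out <- list(records = records, candidates = candidates,
              plots_used = usable)
  if (keep_curves) out$curves <- curves
  out
}

#' Run the full pairwise association analysis
#'
#' Applies the abundance filter, analyses every pair of included species
#' with both statistics via [run_pair()], and assembles the association
#' matrix plus, when trait/habitat tables are supplied, the guild
#' cross-tabulation and habitat-concordance summary. The manifest records
#' all parameter decisions and the expected number of false-positive
#' associations per statistic (`alpha` times the number of analysed
#' pairs) implied by the pointwise envelopes.
#'
#' @param census A `census_table`.
#' @param cfg A [run_config()].
#' @param traits Optional `trait_table`.
#' @param habitat Optional habitat-relation table (see
#'   [habitat_concordance()]).
#' @param progress Print one line per pair.
#' @return A `run_result`: list with `records`, `candidates`, `matrix`,
#'   `filter`, `crosstab`, `habitat`, `manifest`.
#' @export
run_all <- function(census, cfg = run_config(), traits = NULL,
                    habitat = NULL, progress = FALSE) {
  filter <- filter_species(census, cfg$min_n, cfg$min_plots)
  if (!length(filter$included))
    stop(sprintf("no species passes the filter (> %d stems per plot)",
                 cfg$min_n))
  pairs <- utils::combn(sort(filter$included), 2)
  records <- empty_records()
  candidates <- empty_records()
  for (k in seq_len(ncol(pairs))) {
    if (progress)
      message(sprintf("pair %d/%d: %s - %s", k, ncol(pairs),
                      pairs[1, k], pairs[2, k]))
    res <- run_pair(census, pairs[1, k], pairs[2, k], cfg, filter = filter)
    records <- rbind(records, res$records)
    candidates <- rbind(candidates, res$candidates)
  }
  mat <- build_matrix(records, sort(filter$included))
  crosstab <- if (!is.null(traits)) guild_crosstab(records, traits)
  habitat_res <- if (!is.null(habitat)) habitat_concordance(records, habitat)
  manifest <- list(
    n_species = length(filter$included), n_pairs = ncol(pairs),
    n_sim = cfg$n_sim, alpha = cfg$alpha, p_threshold = cfg$p_threshold,
    max_d = cfg$grid$max_d, n_lags = length(cfg$grid$lags),
    edge_mode = cfg$corr, rule = cfg$rule, min_n = cfg$min_n,
    seed = cfg$seed,
    expected_false_positives_per_statistic = cfg$alpha * ncol(pairs))
  structure(list(records = records, candidates = candidates, matrix = mat,
                 filter = filter, crosstab = crosstab,
                 habitat = habitat_res, manifest = manifest),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  with(x$manifest, cat(sprintf(
    "pairwise association run: %d species, %d pairs, n_sim %d, alpha %.2f\n",
    n_species, n_pairs, n_sim, alpha)))
  for (s in c("lrs", "kmm")) {
    r <- x$records[x$records$statistic == s, ]
    cat(sprintf("  %s: %d associations (%d positive, %d negative)\n", s,
                nrow(r), sum(r$sign == "+"), sum(r$sign == "-")))
  }
  invisible(x)
}

#' Write run outputs as delimited text
#'
#' Emits `associations.csv` (one accepted record per row),
#' `candidates.csv`, `matrix.csv` (the signed-distance matrix, L-type
#' lower triangle / mark-correlation upper triangle), `crosstab.csv` when
#' available, and `manifest.json`.
#'
#' @param run A `run_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$records, file.path(dir, "associations.csv"),
                   row.names = FALSE)
  utils::write.csv(run$candidates, file.path(dir, "candidates.csv"),
                   row.names = FALSE)
  utils::write.csv(run$matrix$matrix, file.path(dir, "matrix.csv"))
  if (!is.null(run$crosstab))
    utils::write.csv(run$crosstab$counts, file.path(dir, "crosstab.csv"),
                     row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Reproduce a three-plot replicated census analysis from a census file
#'
#' Convenience wrapper for users holding a real replicated stem-mapped
#' census as CSV (e.g. the publicly deposited three-plot cloud-forest
#' census this package's protocol follows): reads the file into 100 m x
#' 100 m plot windows and runs the full pairwise analysis at the standard
#' settings.
#'
#' @param census_path Census CSV path.
#' @param traits_path,habitat_path Optional trait / habitat CSVs.
#' @param width,height Plot window dimensions (m).
#' @param schema Optional column mapping for [read_census()].
#' @param cfg A [run_config()].
#' @param ... Passed to [run_all()].
#' @return A `run_result`.
#' @export
run_bnc <- function(census_path, traits_path = NULL, habitat_path = NULL,
                    width = 100, height = 100, schema = NULL,
                    cfg = run_config(), ...) {
  census <- read_census(census_path, pp_window(width, height),
                        schema = schema)
  traits <- if (!is.null(traits_path)) read_traits(traits_path)
  habitat <- if (!is.null(habitat_path)) utils::read.csv(habitat_path)
  run_all(census, cfg, traits = traits, habitat = habitat, ...)
}
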