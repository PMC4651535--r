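#' Configuration for a synthetic multi-species stand
#'
#' Describes a stand with known ground truth: per-species point processes
#' (complete spatial randomness or Thomas clusters), pairwise interactions
#' (independent, linked clusters sharing parent locations = planted
#' attraction, or hardcore repulsion = planted inhibition), and per-species
#' DBH mark models (lognormal marginals with independent, cohort or
#' nursery spatial structure).
#'
#' @param window A [pp_window()] (default 100 m x 100 m, i.e. 1 ha).
#' @param species List of species specs from [species_spec()].
#' @param interactions List of interaction specs from [interaction_spec()].
#' @param n_plots Number of replicate plots generated by
#'   [generate_replicates()].
#' @param seed Top-level seed; all randomness derives from it.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(window = pp_window(100, 100), species,
                             interactions = list(), n_plots = 1, seed = 1) {
  labels <- vapply(species, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate species labels")
  for (ia in interactions) {
    if (!all(ia$pair %in% labels))
      stop("interaction references undeclared species")
    if (ia$type == "repulsion_hardcore" &&
        ia$scale >= min(window$width, window$height) / 4)
      stop("hardcore distance must be below a quarter of the window side")
  }
  for (sp in species)
    if (!is.na(sp$mark_partner) && !sp$mark_partner %in% labels)
      stop("mark structure references undeclared partner species")
  structure(list(window = window, species = species,
                 interactions = interactions, n_plots = n_plots,
                 seed = seed, labels = labels),
            class = "synthetic_config")
}

#' Species specification for the synthetic generator
#'
#' @param label Species code.
#' @param n Number of stems to place.
#' @param process `"thomas"` (clustered: Poisson number of uniformly
#'   placed parents, offspring displaced by an isotropic Gaussian and
#'   wrapped toroidally) or `"csr"` (uniform).
#' @param parents Expected parent count for the Thomas process.
#' @param sigma Gaussian cluster spread in metres.
#' @param mark_mu,mark_sigma Lognormal DBH parameters on the log-cm scale
#'   (defaults 2.3 and 0.6, a right-skewed stand diameter distribution
#'   with median ~10 cm).
#' @param mark_structure `"independent"`, `"cohort"` (marks follow a
#'   smooth random field shared with `mark_partner`, so similarly sized
#'   stems of the two species co-occur) or `"nursery"` (this species is
#'   large where the shared field is high while `mark_partner` is small
#'   there: large stems of one species sit among small stems of the
#'   other).
#' @param mark_partner Partner species for cohort/nursery structure.
#' @param mark_range Correlation range of the shared mark field (m).
#' @return A species spec list.
#' @export
species_spec <- function(label, n, process = c("thomas", "csr"),
                         parents = 25, sigma = 5, mark_mu = 2.3,
                         mark_sigma = 0.6,
                         mark_structure = c("independent", "cohort",
                                            "nursery"),
                         mark_partner = NA_character_, mark_range = 10) {
  process <- match.arg(process)
  mark_structure <- match.arg(mark_structure)
  if (mark_structure != "independent" && is.na(mark_partner))
    stop("cohort/nursery mark structure needs a partner species")
  stopifnot(n >= 1, sigma > 0, mark_range > 0)
  list(label = label, n = as.integer(n), process = process,
       parents = parents, sigma = sigma, mark_mu = mark_mu,
       mark_sigma = mark_sigma, mark_structure = mark_structure,
       mark_partner = mark_partner, mark_range = mark_range)
}

#' Pairwise interaction specification
#'
#' @param pair Character vector of the two species labels.
#' @param type `"independent"`, `"linked_clusters"` (the two species share
#'   one set of Thomas parents: planted intertype attraction at the
#'   cluster scale) or `"repulsion_hardcore"` (stems of the second species
#'   are rejected within `scale` metres of any stem of the first: planted
#'   repulsion).
#' @param scale Interaction scale in metres (cluster spread for linked
#'   clusters, hardcore distance for repulsion).
#' @return An interaction spec list.
#' @export
interaction_spec <- function(pair,
                             type = c("independent", "linked_clusters",
                                      "repulsion_hardcore"),
                             scale = 5) {
  type <- match.arg(type)
  stopifnot(length(pair) == 2, scale > 0)
  list(pair = as.character(pair), type = type, scale = scale)
}

wrap_coords <- function(v, lim) {
  v <- v %% lim
  v[v == lim] <- 0
  v
}

# Thomas-like cluster locations: exactly n offspring assigned to Poisson
# parents, Gaussian offsets, toroidal wrap (preserves intensity).
rthomas_n <- function(n, parents, sigma, window) {
  np <- max(1L, stats::rpois(1, parents))
  px <- stats::runif(np, 0, window$width)
  py <- stats::runif(np, 0, window$height)
  list(n = n, sigma = sigma, px = px, py = py,
       pts = thomas_offspring(n, px, py, sigma, window))
}

thomas_offspring <- function(n, px, py, sigma, window) {
  par <- sample.int(length(px), n, replace = TRUE)
  data.frame(x = wrap_coords(px[par] + stats::rnorm(n, 0, sigma),
                             window$width),
             y = wrap_coords(py[par] + stats::rnorm(n, 0, sigma),
                             window$height))
}

# Smooth Gaussian-bump random field evaluated at points, for spatially
# structured marks.
mark_field <- function(window, range, n_centres = 40) {
  cx <- stats::runif(n_centres, 0, window$width)
  cy <- stats::runif(n_centres, 0, window$height)
  amp <- stats::rnorm(n_centres)
  function(x, y) {
    f <- numeric(length(x))
    for (k in seq_len(n_centres))
      f <- f + amp[k] * exp(-((x - cx[k])^2 + (y - cy[k])^2) /
                              (2 * range^2))
    f
  }
}

#' Generate one synthetic stand with known ground truth
#'
#' Draws stem locations per species (CSR or Thomas clusters), applies the
#' declared pairwise interactions (linked clusters share parent
#' locations; hardcore repulsion rejection-samples the second species
#' outside the exclusion distance of the first), then draws DBH marks:
#' independent lognormal, or driven by a smooth shared random field for
#' cohort (`+` intertype mark signal) and nursery (`-` signal) structure.
#' Deterministic given `seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Seed overriding `cfg$seed`.
#' @param plot_id Plot label for the emitted census.
#' @return List with `census` (a `census_table`) and `truth` (the planted
#'   interaction and mark structure, sufficient to score detection).
#' @export
generate_stand <- function(cfg, seed = cfg$seed, plot_id = "plot1") {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(seed, {
    w <- cfg$window
    labels <- cfg$labels
    linked <- list()
    for (ia in cfg$interactions)
      if (ia$type == "linked_clusters")
        linked[[ia$pair[2]]] <- list(with = ia$pair[1], scale = ia$scale)
    hardcore <- list()
    for (ia in cfg$interactions)
      if (ia$type == "repulsion_hardcore")
        hardcore[[ia$pair[2]]] <- list(with = ia$pair[1], scale = ia$scale)

    pts <- list()
    clusters <- list()
    for (sp in cfg$species) {
      lab <- sp$label
      if (!is.null(linked[[lab]])) {
        src <- clusters[[linked[[lab]]$with]]
        if (is.null(src))
          stop("linked_clusters partner must be a Thomas species declared first")
        pts[[lab]] <- thomas_offspring(sp$n, src$px, src$py,
                                       linked[[lab]]$scale, w)
      } else if (!is.null(hardcore[[lab]])) {
        other <- pts[[hardcore[[lab]]$with]]
        if (is.null(other))
          stop("repulsion partner must be declared first")
        h <- hardcore[[lab]]$scale
        keep <- data.frame(x = numeric(0), y = numeric(0))
        tries <- 0
        while (nrow(keep) < sp$n) {
          tries <- tries + 1
          if (tries > 200)
            stop(sprintf(
              "infeasible hardcore thinning for species '%s' (h = %g m)",
              lab, h))
          cand <- if (sp$process == "csr")
            data.frame(x = stats::runif(sp$n, 0, w$width),
                       y = stats::runif(sp$n, 0, w$height))
          else rthomas_n(sp$n, sp$parents, sp$sigma, w)$pts
          ok <- vapply(seq_len(nrow(cand)), function(i)
            min((cand$x[i] - other$x)^2 + (cand$y[i] - other$y)^2) > h^2,
            logical(1))
          keep <- rbind(keep, cand[ok, ])
        }
        pts[[lab]] <- keep[seq_len(sp$n), ]
      } else if (sp$process == "csr") {
        pts[[lab]] <- data.frame(x = stats::runif(sp$n, 0, w$width),
                                 y = stats::runif(sp$n, 0, w$height))
      } else {
        th <- rthomas_n(sp$n, sp$parents, sp$sigma, w)
        clusters[[lab]] <- th
        pts[[lab]] <- th$pts
      }
    }

    # marks: shared fields for cohort / nursery pairs, iid normal scores
    # otherwise; marks are exp(mu + sigma * z) so marginals stay lognormal
    fields <- list()
    z <- list()
    for (sp in cfg$species) {
      lab <- sp$label
      if (sp$mark_structure == "independent") {
        if (is.null(z[[lab]])) z[[lab]] <- stats::rnorm(sp$n)
      } else {
        key <- paste(sort(c(lab, sp$mark_partner)), collapse = "|")
        if (is.null(fields[[key]]))
          fields[[key]] <- mark_field(w, sp$mark_range)
        f <- fields[[key]]
        zs <- f(pts[[lab]]$x, pts[[lab]]$y)
        z[[lab]] <- as.numeric(scale(zs))
        partner <- sp$mark_partner
        zp <- f(pts[[partner]]$x, pts[[partner]]$y)
        zp <- as.numeric(scale(zp))
        z[[partner]] <- if (sp$mark_structure == "nursery") -zp else zp
      }
    }

    rows <- do.call(rbind, lapply(cfg$species, function(sp) {
      lab <- sp$label
      data.frame(plot_id = plot_id, tree_id = NA_character_, species = lab,
                 x = pts[[lab]]$x, y = pts[[lab]]$y,
                 dbh = exp(sp$mark_mu + sp$mark_sigma * z[[lab]]),
                 height = NA_real_, stringsAsFactors = FALSE)
    }))
    rows$tree_id <- paste0(plot_id, "-", seq_len(nrow(rows)))
    truth <- list(
      interactions = cfg$interactions,
      marks = lapply(cfg$species, function(sp)
        list(species = sp$label, structure = sp$mark_structure,
             partner = sp$mark_partner, range = sp$mark_range)),
      seed = seed)
    list(census = census_table(rows, w), truth = truth)
  })
}

#' Generate replicate synthetic plots
#'
#' Independent stands from one configuration with distinct deterministic
#' sub-seeds, mirroring replicate census plots of the same ecological
#' process.
#'
#' @param cfg A [synthetic_config()].
#' @param n_plots Number of replicates (default from `cfg`).
#' @param seed Top-level seed (default from `cfg`).
#' @return List with `census` (all plots combined into one
#'   `census_table`), `stands` (per-plot results) and `truth`.
#' @export
generate_replicates <- function(cfg, n_plots = cfg$n_plots,
                                seed = cfg$seed) {
  stands <- lapply(seq_len(n_plots), function(i)
    generate_stand(cfg, seed = derive_seed(seed, paste0("plot", i)),
                   plot_id = paste0("plot", i)))
  rows <- do.call(rbind, lapply(stands, function(s) as.data.frame(s$census)))
  list(census = census_table(rows, cfg$window), stands = stands,
       truth = stands[[1]]$truth)
}

#' Synthetic surrogate for a three-plot montane cloud-forest census
#'
#' Builds a SYNTHETIC stand-in for a three-plot, 1-ha stem-mapped cloud
#' forest census whose real counterpart is distributed as supplementary
#' data and is not shipped here. The surrogate reproduces the study
#' conditions reported for that census: three 100 m x 100 m replicate
#' plots; about 50 woody species of which 20 are abundant (more than 60
#' stems per plot, one of them deficient in a single plot) while the
#' remaining rare species carry roughly 7% of stems, so the abundant
#' species comprise 40% of species and ~93% of individuals; clustered
#' (Thomas) per-species patterns and lognormal DBH marks. It carries no
#' planted interspecific interactions. Use it to exercise the pipeline at
#' realistic scale, never as a source of ecological conclusions.
#'
#' @param seed Integer seed.
#' @param n_common,n_rare Number of abundant and rare species.
#' @return A `census_table` with three plots.
#' @export
simulate_bnc_like_census <- function(seed = 1, n_common = 20, n_rare = 30) {
  with_seed(derive_seed(seed, "bnc-surrogate"), {
    w <- pp_window(100, 100)
    lambda_common <- seq(75, 360, length.out = n_common)
    # expected rare total tuned so abundant species hold ~93% of stems
    lambda_rare <- sum(lambda_common) * (7 / 93) / n_rare
    plots <- paste0("plot", 1:3)
    counts <- matrix(0L, n_common + n_rare, 3)
    for (p in 1:3) {
      counts[seq_len(n_common), p] <-
        pmax(63L, as.integer(round(lambda_common *
                                     stats::runif(n_common, 0.92, 1.08))))
      counts[n_common + seq_len(n_rare), p] <-
        pmin(55L, stats::rpois(n_rare, lambda_rare))
    }
    counts[5, 3] <- 45L  # one abundant species deficient in one plot
    labels <- c(sprintf("common%02d", seq_len(n_common)),
                sprintf("rare%02d", seq_len(n_rare)))
    sigma <- stats::runif(n_common + n_rare, 3, 8)
    rows <- list()
    for (p in 1:3) {
      for (s in seq_along(labels)) {
        n <- counts[s, p]
        if (n == 0) next
        pts <- rthomas_n(n, parents = max(3, n / 10), sigma = sigma[s],
                         window = w)$pts
        rows[[length(rows) + 1]] <- data.frame(
          plot_id = plots[p], tree_id = NA_character_, species = labels[s],
          x = pts$x, y = pts$y,
          dbh = stats::rlnorm(n, meanlog = 2.3, sdlog = 0.6),
          height = NA_real_, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df$tree_id <- paste0(df$plot_id, "-", seq_len(nrow(df)))
    census_table(df, w)
  })
}
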