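# interspat

Pairwise interspecific spatial associations in stem-mapped forest
censuses.

`interspat` is for forest and community ecologists holding fully mapped
censuses (every free-standing woody stem with coordinates, species and
DBH) who want to know, for every pair of sufficiently abundant species,
whether the two species attract or repel each other in space, at what
distances, and whether similarly sized (same developmental stage) or
oppositely sized stems of the two species co-occur. It implements the
complete protocol: intertype second-order statistics, Monte Carlo null
models with pointwise quantile envelopes, standardisation and pooling
of replicate plots, and summary tables of the detected associations by
guild and habitat.

## The statistics

**Intertype L-type function.** For species *r* and *s* with *n_r*, *n_s*
stems in a plot of area *A* (intensities λ = n/A),

    L̂_rs(d) = 1 / ((λ_r + λ_s)(n_r + n_s)π) ×
              ( Σ_i Σ_j ω_ij(d) / n_r  +  Σ_j Σ_i ω_ji(d) / n_s )

where ω_ij(d) indicates an intertype pair with d_ij ≤ d, optionally
divided by Ripley's isotropic boundary fraction of the focal stem (the
default). For two independent completely random patterns its
expectation is ≈ d²/(n_r + n_s); values above a null band indicate
intertype attraction, below it repulsion.

**Intertype mark-correlation function.** With DBH marks standardised
per species (m̃ = (m − m̄)/s, sample SD),

    K̂mm_rs(d) = Σ ω(d) m̃_i m̃_j  /  Σ ω(d)

summed over intertype pairs within d in both directions. Positive
values mean similar-stage stems of the two species co-occur at that
scale (cohorts); negative values mean large stems of one species sit
among small stems of the other (nurseries).

**Null models and inference.** Spatial independence is tested by
toroidal shift (one pattern rigidly translated on the torus, 399
simulations, pointwise 95% quantile envelopes); mark independence by
random marking (marks permuted within species, locations fixed). Each
plot's empirical curve is standardised so its null band becomes exactly
[−1, 1] (`F̂_st = a(d) + b(d) F̂` with `b = 2/(N_sup − N_inf)`,
`a = 1 − b N_sup`), replicate plots are pooled by averaging, and an
association is reported where the pooled curve leaves the band in every
usable plot on the same side, with a Monte Carlo quasi p-value at the
single most significant distance (acceptance at 0.01).

## Worked example

Three replicate 1-ha plots, four species, with a planted attraction
between `cecropia` and `miconia` (shared Thomas-cluster parents,
σ = 5 m):

```r
library(interspat)

cfg <- synthetic_config(
  species = list(
    species_spec("cecropia", 100, "thomas", parents = 25, sigma = 5),
    species_spec("miconia",  100, "thomas", parents = 25, sigma = 5),
    species_spec("piper",     80, "csr"),
    species_spec("solanum",   80, "csr")),
  interactions = list(
    interaction_spec(c("cecropia", "miconia"), "linked_clusters", scale = 5)),
  n_plots = 3, seed = 42)

reps <- generate_replicates(cfg)
res  <- run_all(reps$census, run_config(n_sim = 199, seed = 1))
print(res)
res$records[, c("species_a", "species_b", "statistic", "sign",
                "d_min", "d_max", "d_star", "quasi_p")]
round(res$matrix$matrix, 1)
```

prints

```
pairwise association run: 4 species, 6 pairs, n_sim 199, alpha 0.05
  lrs: 1 associations (1 positive, 0 negative)
  kmm: 0 associations (0 positive, 0 negative)
  species_a species_b statistic sign d_min d_max d_star quasi_p
1  cecropia   miconia       lrs    +     3    16      8   0.005

         cecropia miconia piper solanum
cecropia       NA      NA    NA      NA
miconia         8      NA    NA      NA
piper          NA      NA    NA      NA
solanum        NA      NA    NA      NA
```

The planted pair — and only the planted pair — is recovered: spatial
attraction over 3–16 m, strongest at 8 m (the cluster scale), with the
smallest attainable p at 199 simulations. The matrix holds signed
representative distances: L-type associations in the lower-left
triangle, mark-correlation associations in the upper-right. With trait
and habitat tables, `run_all()` additionally returns guild
cross-tabulations (`guild_crosstab`) and habitat-concordance counts
(`habitat_concordance`).

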