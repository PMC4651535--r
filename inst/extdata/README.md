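# extdata

No census data ships with the package. To reproduce the published
three-plot association tables, place the deposited census here as
`bnc_census.csv` with columns `plot_id, tree_id, species, x, y, dbh,
height` (or use the `schema` argument of `read_census()` /
`run_bnc()` to map the file's own column names), then run
`run_bnc(system.file("extdata", "bnc_census.csv", package = "interspat"))`
or re-run the two reproduction tests in the test suite.
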