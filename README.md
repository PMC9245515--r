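# colptm

Motif-constrained identification and quantitation of collagen
post-translational modifications (PTMs) from bottom-up proteomics data.

## What it does, and for whom

Collagens are (Gly-Xaa-Yaa)n triple-helical ECM proteins whose prolines
and lysines are heavily modified during biosynthesis. Yaa-position
prolines are almost completely 4-hydroxylated; a subset of Xaa prolines
are 3-hydroxylated; lysines in the Gly-Xaa-Lys context can be
hydroxylated (HyK) and O-glycosylated with one or two hexoses (G-HyK,
GG-HyK), so one lysine site is distributed over four states
("microheterogeneity"). Because 3-HyP and 4-HyP are mass-identical
(both +15.994915 Da), they can only be distinguished positionally: a
hydroxyproline is 3-HyP when it occupies the Xaa slot of a G-Xaa-HyP
triplet.

`colptm` is for proteomics researchers who want that motif-constrained
strategy as transparent, scriptable R functions rather than a chain of
GUI tools:

* **chain model** — FASTA input, Gly-Xaa-Yaa / G-X-K motif annotation,
  propeptide cleavage-site transfer by ortholog alignment (BLOSUM62,
  affine gaps), full-length ↔ mature coordinate conversion;
* **mass & digestion** — fully tryptic digestion (K/R, never before P),
  monoisotopic masses to 9 decimals, modification deltas derived from
  elemental composition (HyP/HyK = +O; G-HyK = +O + C6H10O5 =
  178.047738 Da; GG-HyK = +O + 2×C6H10O5 = 340.100562 Da);
* **search** — motif-constrained peptidoform enumeration, b/y-ion HCD
  matching with a binomial-tail score, reversed-decoy FDR control with
  monotone q-values;
* **site catalog** — the positional 3-HyP/4-HyP/ambiguous assignment
  rule, Table-style per-chain tallies, sequence coverage, conserved-site
  mapping across species;
* **quantitation** — normalized spectral counts, row-standardized
  heatmap matrices, fold changes, MS1-area site occupancy and lysine
  microheterogeneity with replicate dispersion and one-way ANOVA;
* **synthetic data** — a seeded generator of collagen-like chains,
  planted occupancy profiles over 4 conditions × 2 replicates, MS1
  feature tables with log-normal noise, and MGF spectra with dropout
  and noise peaks, so the entire pipeline is testable offline.

The package also ships machine-readable transcriptions of a published
zebrafish heart ECM collagen PTM catalog (23 chains; 95 3-HyP, 108 HyK,
29 G-HyK and 128 GG-HyK site entries), its conserved-site lists and its
two quantitation tables, used by the verification utilities.

## Worked example

Simulate a synthetic study, search it, catalog the sites and quantify a
planted lysine site:

```r
library(colptm)

cfg <- sim_config(seed = 1)          # 4 conditions x 2 replicates
ds  <- simulate_dataset(cfg)         # chain + spectra + MS1 features

params <- sim_search_params(cfg)
idx    <- build_search_index(list(ds$chain), params)
psms   <- fdr_filter(search_spectra(ds$spectra, idx, params), 0.01)

catalog <- assign_sites(psms, setNames(list(ds$chain), ds$chain$id))
evaluate_recovery(catalog, ds$planted_sites)
#> $recall      : 1
#> $precision   : 0.789...
#> $n_planted   : 15
#> $n_recovered : 15

k1 <- unique(ds$truth$position[ds$truth$residue == "K"])[1]
occ <- site_occupancy(ds$features, ds$chain$id, k1, dispersion = "sem")
subset(occ, condition == "sham")
#>   condition  state  mean dispersion n_replicates    nd
#>        sham  unmod 62.6…       …              2 FALSE
#>        sham    HyK 34.6…       …              2 FALSE
#>        sham  G-HyK  0.0        …              2 FALSE
#>        sham GG-HyK  2.7…       …              2 FALSE
```

All 15 planted modified sites are recovered at 1% FDR, and the
recovered sham microheterogeneity of the first planted lysine is within
noise of its planted profile (62.44 / 34.82 / 0 / 2.74 percent). The
fixture checks are bundled in one report:

```r
verify_fixtures()
#>  check                         value expected pass
#>  total 3-HyP sites             95    95       TRUE
#>  total HyK sites               108   108      TRUE
#>  ...
```

A thin command-line wrapper with `simulate`, `digest`, `search`,
`sites`, `quant` and `verify` subcommands is installed at
`system.file("cli", "colptm.R", package = "colptm")`.

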