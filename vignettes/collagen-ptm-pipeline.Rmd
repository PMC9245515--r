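---
title: "Mapping and quantifying collagen PTMs with colptm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and quantifying collagen PTMs with colptm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colptm)
```

## The problem

Fibrillar collagens are built from (Gly-Xaa-Yaa)n triple-helical chains
that are heavily modified during biosynthesis: prolines in the Yaa slot
are almost completely 4-hydroxylated, a subset of Xaa prolines are
3-hydroxylated, and lysines in the Gly-Xaa-Lys context can be
hydroxylated and then O-glycosylated with one (galactosyl) or two
(glucosylgalactosyl) hexoses. A single lysine position is therefore
distributed across four states — K, HyK, G-HyK, GG-HyK — a phenomenon
called microheterogeneity. Because 3-HyP and 4-HyP are mass-identical,
bottom-up mass spectrometry can only distinguish them positionally:
a hydroxyproline is called 3-HyP when it sits in the Xaa slot of a
G-Xaa-HyP triplet, i.e. when the Yaa proline of the same triplet is
itself observed hydroxylated.

`colptm` implements that motif-constrained identification strategy as a
reusable, fully testable pipeline: chain annotation, in-silico tryptic
digestion, motif-constrained peptidoform enumeration, a transparent HCD
b/y-ion scorer with target-decoy FDR control, site cataloging with the
positional 3-HyP rule, and MS1-area occupancy statistics across
experimental conditions. Because raw instrument data for real ECM
preparations is far beyond desk scale, the package also ships a seeded
synthetic-data generator that emulates the study design (four
conditions — sham and 7/14/30 days post-amputation — with two
biological replicates), plus machine-readable transcriptions of the
published zebrafish heart ECM site catalogs for the arithmetic and
tally checks.

## Chain model and coordinates

Chains are stored in full-length, 1-based coordinates including the
signal peptide, matching the convention of published site labels such as
K1017; the mature (processed) chain is a coordinate view obtained after
removing the signal peptide and the N-/C-propeptides. Propeptide
boundaries are transferred from an annotated ortholog through a global
alignment (Needleman-Wunsch, BLOSUM62, gap open 10 / extend 0.5 — the
alignment algorithm and parameters are a package choice, recorded in the
alignment object, since orthologous collagen chains are highly similar
and the boundaries are insensitive to reasonable settings). A boundary
that falls opposite an alignment gap snaps to the nearest aligned
reference residue within ±3 positions; beyond that the transfer fails
loudly rather than guess.

Motif annotation classifies every proline and lysine by its triplet
role. A proline that is simultaneously Yaa of one frame and Xaa of an
overlapping frame is classified Yaa (4-HyP eligible), because Yaa
4-hydroxylation is the dominant, near-complete modification; its Xaa
context remains visible in the triplet annotation. The G-X-K context is
always evaluated on the full chain, so peptides whose first residues
lack the upstream glycine still inherit the correct motif context.

## Masses and modifications

Monoisotopic residue masses are stated to nine decimals; modification
delta masses are derived at run time from elemental composition —
hydroxylation is one oxygen (15.994915 Da), each glycan step adds a
hexose (C6H10O5, 162.052823 Da) — rather than being hard-coded, and the
commonly quoted printed strings are kept alongside for traceability.
The quoted hydroxylysine delta (+15.994916) differs from the oxygen
mass by 1 µDa; internally all single-oxygen deltas share the oxygen
mass. Carbamidomethylation of cysteine is static; hydroxyproline and
methionine oxidation are unconstrained dynamic modifications;
hydroxylysine and its glycoforms are restricted to the G-X-K context.

Digestion is fully tryptic (cleavage after K/R, never before P) with
configurable missed cleavages; peptide candidacy for search is bounded
at 5–60 residues (a conventional bottom-up window; configurable).

## Search, scoring and FDR

Peptidoform enumeration expands each peptide over the per-residue state
spaces (P: unmodified/HyP; G-X-K lysine: four states; M: ± oxidation),
capped at a configurable number of dynamic modifications (default 10,
with a 5-mod "wide" preset at 50/25 ppm tolerances mirroring a second
common engine parameterization; the default preset uses 10/20 ppm and
4 missed cleavages). Glycosylated lysine is disallowed at the peptide
C-terminus — a bulky glycan blocks tryptic cleavage, a standard
glycoproteomics convention — while plain hydroxylysine is allowed
anywhere; a flag relaxes this. A combinatorial guard errors before
expanding state spaces beyond 10^6.

The scorer is a transparent stand-in for production search engines:
theoretical b/y ions are matched to the nearest peak inside the
fragment tolerance (greedy by ascending ppm error, each peak usable
once), and the score is the −log10 binomial tail probability of the
match count given a per-ion match probability estimated from the
tolerance window and the spectrum's peak density. It is deterministic,
and on synthetic spectra the generating peptidoform dominates its
enumerated siblings. Decoys are whole-protein sequence reversals;
peptides shared between target and decoy count as target only. One best
PSM is kept per spectrum (ties break toward target, then to the
lexicographically smallest peptidoform string — reproducibility over
optimism), q-values are the minimum decoy/target ratio over score
cutoffs (monotone in score), and the default threshold is 1%.

Because the search competes mass-identical positional isomers that can
differ in only a few fragment ions, the realized error of the
target-decoy procedure is assessed at the peptidoform-identity level on
planted-truth simulations; localization quality is exercised separately
by the end-to-end site-recall check.

## Site catalog

Filtered target PSMs collapse into per-position sites. Hydroxylated
Yaa prolines are 4-HyP; hydroxylated Xaa prolines are 3-HyP only when
the Yaa proline of the same triplet is hydroxylated *on the same
peptidoform* (strict reading of the G-Xaa-HyP rule; a flag relaxes the
co-occurrence requirement to "observed at that position in any
peptidoform", since the operational choice is not fully explicit in
practice). An Xaa hydroxyproline whose Yaa partner is not a
hydroxylated proline — the catalogs contain such sites with Ala, Val,
Ser and other residues in Yaa — is reported as positionally ambiguous.
Lysine sites carry their observed state sets, so one site can appear in
several columns of a Table-1-style tally (microheterogeneity). Sites
are reported in full-length coordinates with mature coordinates
alongside; sequence coverage is the fraction of distinct mature
positions covered by at least one identified peptide. Minimum per-state
PSM support defaults to 1 (production studies add manual spectral
validation, which is out of scope here); a stricter threshold is a
parameter.

## Quantitation

Spectral counts are normalized to the mean file depth (count ×
mean-total / file-total), keeping values on the counts scale so the
"≥ 3 normalized counts" heatmap-eligibility threshold stays meaningful;
a fraction-of-total alternative is provided. Heatmap rows are
z-standardized with the population SD and clipped to ±2; constant rows
map to 0. Fold changes are condition-mean over baseline-mean, with
percent change defined by the formula (1 − ratio) × 100 — a 0.93 ratio
is reported as a 7% decrease even where rounded prose might say 6.2%.

Site occupancy is the fraction of summed MS1 area per modification
state, per replicate, within a condition; replicates with zero total
area are "not detected" and propagate as ND, never as silent zeros.
Ambiguous-localization peptidoforms are excluded by default
(conservative); equal apportioning is available behind a flag.
Dispersion is SD for occupancy-style outputs and SEM for
microheterogeneity-style outputs, matching the two published table
conventions. Co-resident site clusters are quantified jointly by
collapsing states to "any modification in the cluster", so the cluster
percent bounds each member site's percent from above. Condition effects
are tested with classical one-way ANOVA at p < 0.05; degenerate inputs
follow fixed conventions (zero variance → p = 1; fewer than two groups
with two replicates → untestable).

## The synthetic study

The generator emulates a procollagen chain — 22-residue signal peptide,
40-residue N- and C-propeptides, and a 100-triplet (Gly-Xaa-Yaa) core
with proline enriched in both Xaa (30%) and Yaa (45%) slots, periodic
Yaa lysines creating G-X-K motifs, and arginines guaranteeing a tryptic
site at least every 40 residues. Segment lengths compress the real
chains (1447 residues with a 124-residue N-propeptide) to roughly a
quarter scale so the full pipeline runs in seconds at a realistic
motif density; coordinates, not size, carry the scientific content.
Four lysine sites receive microheterogeneity profiles and four
3-HyP-eligible Gly-Pro-Pro prolines receive occupancy profiles, with
per-condition true values templated on the published dynamics
(including a K1017-like GG-HyK rise from ~2.7% to ~15.5% and a
P1148-like occupancy collapse at 30 DPA; template rows are adjusted by
at most 0.2 points where the printed originals do not sum to exactly
100). MS1 areas are base abundance × true fraction × log-normal noise
scaled to unit mean (default CV 10%, the scale of replicate agreement
seen in well-behaved MS1 quantitation; the paper states no noise
model), and spectra carry b/y peaks with ±10 ppm uniform jitter, 10%
dropout, log-normal intensities and 20 uniform noise peaks. One global
seed fans out to fixed per-component child seeds, so every artifact is
byte-for-byte reproducible and components can be regenerated
independently.

What passing the synthetic suite does and does not show: it
demonstrates that the implementation is internally correct — digestion
and enumeration match brute force, occupancy estimation is unbiased at
low noise, FDR control holds when the spectrum generator matches the
scorer's assumptions, and planted sites are recovered end to end. It
does not demonstrate robustness to the pathologies of real data
(chimeric spectra, co-eluting isobaric forms, retention-time-dependent
ionization, isotope-envelope errors), which the simulator deliberately
omits.

## Numerical and design choices

* Proton 1.00727646688 Da, water 18.010564686 Da; ppm error is
  (observed − theoretical)/theoretical × 10^6.
* The per-ion match probability in the scorer is capped at 0.5 and
  floored at machine epsilon to keep the binomial tail defined on
  degenerate spectra; an empty peak list scores 0.
* The enumeration order (ascending modification count, then
  lexicographic modification string) is the canonical output order,
  making every table deterministic.
* Alignment-boundary snapping uses ±3 residues with ties broken toward
  the upstream side; outer segment boundaries are pinned to the chain
  termini, since signal and C-propeptide segments are terminal by
  construction.
* The synthetic study searches with the digestion bounds its spectra
  were generated under (≤ 2 missed cleavages, ≤ 40 residues, the
  general-search convention), keeping the peptidoform index compact;
  the default 4-missed/10-mod parameterization remains available for
  real searches.
* The two published microheterogeneity rows whose printed percents sum
  to 99.80 and 100.59 (COL1A1a K261 at 14 and 30 DPA) are carried
  verbatim in the fixture; the self-check reports them rather than
  normalizing them away. All package-computed occupancies sum to 100
  exactly by construction.

## Known limitations

The scorer is intentionally simple (no intensity weighting, no neutral
losses, no machine-learned rescoring); open or mass-offset searches,
semi-tryptic digestion, isotope-averaged masses and chromatographic
peak picking are out of scope. Chemical discrimination of 3- vs 4-HyP
is impossible by mass — only the positional inference is implemented,
as in practice. The human/mouse reference positions used by the
conserved-site fixture are a synthetic identity mapping standing in for
unpublished ortholog coordinates and are labelled as such.
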