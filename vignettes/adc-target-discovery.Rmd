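---
title: "ADC target discovery: ranking model, ORA and SPR kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ADC target discovery: ranking model, ORA and SPR kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcvault)
```

## The problem

An antibody–drug conjugate (ADC) delivers a cytotoxic payload through a
monoclonal antibody bound to a cell-surface antigen. A useful target must
therefore (i) sit in the plasma membrane with an antibody-accessible
extracellular domain, (ii) be highly expressed in the tumour, and
(iii) be minimally expressed in healthy tissue, where payload delivery is
toxicity. `adcvault` implements the computational side of that selection:
a queryable store of protein annotation and immunohistochemistry (IHC)
expression evidence, a transmembrane-topology consensus filter, a
lexicographic candidate ranking, pathway overrepresentation analysis
(ORA) of the top candidates, and surface plasmon resonance (SPR) kinetic
analysis of candidate antibody/antigen pairs.

Because the public annotation sources (UniProt-, Ensembl- and Human
Protein Atlas-style tables) change over time and are not shipped, every
input is produced by seeded generators that emulate their structure and
plant a known ground truth. The pipeline is validated by recovering that
truth, not by reproducing any particular database snapshot.

## The ranking model

IHC expression is ordinal: `NotDetected < Low < Medium < High`. For each
candidate protein the ranking uses four keys:

* `K1` — number of healthy tissues whose level is High **or** Medium;
* `K2` — number of healthy tissues at High;
* `K3` — number of healthy tissues at Medium;
* `K4` — fraction of cancer patients scoring High or Medium.

A protein enters the candidate set only if `K4 > 0.5` — strictly greater,
so a protein with exactly half its cohort at High/Medium is excluded —
and, by default, only if it passes the transmembrane consensus filter:
at least five of the six topology predictors must report **exactly one**
membrane-spanning segment. A missing predictor output counts as
disagreement, which is the conservative reading for a safety-driven
screen. Candidates are then sorted lexicographically: `K1` ascending,
then `K2`, then `K3` ascending, then `K4` descending. The criteria are
stated as an ordered list without weights, and a lexicographic order is
the only parameter-free reading of such a list; a weighted-sum
alternative is deliberately not implemented. Residual ties are broken by
gene symbol purely so output is deterministic.

Healthy tissues are typically scored in several cell types. A tissue's
level is taken as the **maximum** over its cell types: if any cell
population in an organ expresses the target highly, that organ is at
risk, so the maximum is the conservative collapse. The alternative
(`collapse = "per_cell_type"` in `healthy_level_by_tissue()`) is exposed
for sensitivity analyses. A protein with no healthy observations at all
contributes zero to `K1`–`K3` and is flagged `data_gap = TRUE` rather
than dropped — absence of evidence is treated as no detected expression,
but visibly so. Under the max-collapse convention `K1 = K2 + K3` holds
identically; it is asserted by test rather than assumed.

The expression threshold and the TM filter are both filters, so applying
them in either order gives the same candidate set; the tests assert this
commutation explicitly.

## The store

The vault is an embedded, indexed store: keyed `data.table`s with
indexes on `protein_id`, `tissue` and `cancer_type`, persistable as a
single file. Ingestion validates referential integrity (every child row
must join to a protein, offenders are listed), normalizes IHC level
strings case-insensitively, and rejects malformed levels and zero-patient
summaries with line numbers. Export reproduces the input tables up to row
order, and query results do not depend on ingestion order.

## Overrepresentation analysis

The genes encoding the 100 highest-ranked targets (fewer if the candidate
list is shorter, with a warning) are tested against gene-set collections
in GMT format. For a universe of `N` genes, a set of size `m`, a query of
size `q` and an overlap `k`, the p-value is the hypergeometric upper tail
`P[X >= k]` — the observed overlap is included, the standard ORA
convention. Genes outside the universe are dropped with a message, not an
error, mirroring how reference ("genome protein-coding") lists are used
in practice. Benjamini–Hochberg FDR is computed across the sets of each
collection — matching a per-database presentation of results — and
significance is declared at FDR < 0.1. Set-size bounds (defaults 5 and
2000, applied after restriction to the universe) are configurable because
upstream web tools differ in their defaults.

## SPR kinetics

The 1:1 Langmuir interaction model solves
`dR/dt = ka*C*(Rmax - R) - kd*R` in closed form:

* association: `R(t) = Req + (R_init - Req) exp(-(ka*C + kd) t)` with
  `Req = ka*C*Rmax / (ka*C + kd)`;
* dissociation: `R(t') = R0 exp(-kd t')`, with `t'` re-zeroed at
  injection end.

`KD = kd/ka`. The simulator emits, per analyte concentration, an active
and a reference flow-cell trace plus one buffer-only blank cycle pair per
series — one blank is the minimal requirement for double referencing, and
instrument protocols vary in how often blanks are run. Artefacts follow
the standard sensorgram error model: linear per-cycle baseline drift, a
rectangular bulk refractive-index pulse spanning the injection, and
i.i.d. Gaussian noise. Double referencing computes
`(active - reference) - (blank_active - blank_reference)` per phase and
time point, which cancels shared drift and bulk terms algebraically;
traces on different grids are aligned by linear interpolation and
non-overlapping ranges are an alignment error, not a silent
extrapolation.

Two fitters are provided. `fit_full_kinetics()` fits global
`(ka, kd, Rmax)` to all phases of a multi-cycle series simultaneously
(at least two concentrations; one concentration is ill-posed and warns).
`fit_dissociation()` is the off-rate screen: a single global `kd` with
one free `R0` per cycle, fitted to the dissociation phases only — the
right tool when association is confounded or only the off-rate matters
for candidate triage. Both fit log-parameters (positivity by
construction) with Levenberg–Marquardt least squares (`minpack.lm`),
convergence at relative cost change or gradient norm below 1e-10, at most
500 iterations; non-convergence sets `converged = FALSE` with
diagnostics instead of throwing. Initialization is deterministic and
data-driven: `kd` from the terminal slope of the log dissociation signal,
`(KD, Rmax)` from the equilibrium-response-versus-concentration
relationship, and (for the full fit) a small grid of perturbed starts
whose best final cost wins, ties resolved to the lowest `kd`. The first
2 s after each phase boundary are excluded from fitting by default to
avoid bulk-shift transients; the width is configurable.

Fit quality is summarised by `chi2 = SSR/(n - p)` (the
degrees-of-freedom convention of commercial evaluation software; raw SSR
is available via `chi2_norm = "raw"` since vendors are not explicit) and
by the Chi²% statistic `chi2 / Rmax * 100`, with values below 5% flagged
as high-significance fits. Chi²% mixes units (RU² over RU); it is
implemented literally as defined rather than "corrected", because that is
the statistic practitioners threshold. For dissociation-only fits, which
have no fitted `Rmax`, the companion full-fit `Rmax` is used when
supplied and otherwise the maximum fitted `R0` stands in as the closest
proxy, flagged via `rmax_source`.

## What the generators emulate — and what they do not

The fixture generator plants `n_planted_targets` ideal targets: single-TM
consensus by construction, healthy levels confined to
`NotDetected`/`Low`, and cancer cohorts in which the High+Medium count is
drawn uniformly from the integers strictly above half the cohort — so the
>50% rule holds in every seed, not merely in expectation. Decoys draw
levels from configurable per-stratum probability vectors. Defaults follow
the emulated sources: a 44-tissue healthy panel, 22 patients per cancer
cohort, six predictors, 50 proteins with 5 planted targets. The number of
healthy tissues contributed per protein by the real atlas varies and is
not documented per release; 44 named tissues is a fixture choice (only
counts matter to the ranking, so tissue names are arbitrary labels).

What the generators do **not** emulate: correlated expression between
related proteins, annotation errors and missingness patterns of real
databases, realistic protein sequence composition, mass-transport
limitation, analyte bivalency or surface heterogeneity in sensorgrams.
Passing tests therefore demonstrate that the computations are correct and
the planted truth is recoverable under the stated error model — not that
real-database snapshots would yield any particular candidate list.

## Numerical and design notes

* Every generator is a pure function of its configuration, including the
  seed; pipeline artifacts are bitwise-reproducible (the run report
  stores relative paths and a config hash, and timings go to the log
  stream only).
* Hypergeometric tails come from `stats::phyper`, BH adjustment from
  `stats::p.adjust`; tests check both against direct pmf summation and
  hand-computed step-up values.
* The closed-form association model is verified against independent
  Runge–Kutta integration of the rate ODE to 1e-8 across the antibody
  regime (ka ~ 3.6e5 1/(M s), kd in [8e-5, 4e-4] 1/s).
* Noiseless round trips (simulate, double-reference, fit) recover
  `(ka, kd, Rmax)` to relative error below 1e-6; at a signal-to-noise of
  100 the off-rate screen recovers `kd` within 5% in at least 95 of 100
  seeded replicates.
* Problem sizes in the test-suite property checks — 100 random stores of
  up to 200 proteins, 100 planted-recovery seeds, 1000 hypergeometric
  spot checks, 2000 null replicates, 100 noisy fit replicates — were
  chosen to exercise the combinatorics while keeping a full run around a
  minute on a laptop core.

## Known limitations

Only the 1:1 interaction model is implemented; heterogeneous or
transport-limited data are detected through inflated Chi²% rather than
modelled. The ranking reproduces the stated ordered criteria exactly and
does not attempt the manual curation (antibody availability,
multi-indication priority) that follows in practice. The ORA stage is
classical overrepresentation; ranked (GSEA-style) and topology-aware
methods are out of scope.
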