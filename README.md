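# adcvault

Target discovery for antibody–drug conjugate (ADC) development, as an R
package. ADCs kill tumour cells by delivering a cytotoxic payload through
an antibody bound to a cell-surface antigen, so a good target must be a
single-pass membrane protein, highly expressed in the tumour, and near
absent from healthy tissue. `adcvault` implements the computational
pipeline that screens for such targets and characterises candidate
antibody/antigen pairs:

* **Target vault** — an embedded, indexed store of proteome annotation,
  transmembrane (TM) topology predictions and immunohistochemistry (IHC)
  expression evidence, ingested from TSV tables with full validation.
* **Candidate ranking** — a TM consensus filter (≥ 5 of 6 predictors
  reporting exactly one membrane-spanning segment), a strict > 50%
  cancer-patient expression threshold, and a four-key lexicographic sort:
  healthy tissues at High-or-Medium (`K1`, ascending), at High (`K2`), at
  Medium (`K3`), then the fraction of patients at High-or-Medium (`K4`,
  descending).
* **Pathway overrepresentation** — hypergeometric upper-tail tests
  (`P[X ≥ k]`) of the top-ranked genes against GMT gene-set collections,
  with Benjamini–Hochberg FDR and significance at FDR < 0.1.
* **SPR kinetics** — 1:1 Langmuir model
  (`dR/dt = ka·C·(Rmax − R) − kd·R`), Biacore-style double referencing
  `(active − reference) − (blank_active − blank_reference)`, global
  multi-cycle fits of `(ka, kd, Rmax)` with `KD = kd/ka`, a
  dissociation-only off-rate screen, and the Chi²% quality statistic
  (`Chi²/Rmax·100`, < 5% = high significance).
* **Synthetic data** — seeded generators for every input (annotation and
  IHC tables with planted ideal targets, gene sets with planted
  enrichment, multi-cycle sensorgrams with known rate constants), so the
  whole pipeline runs and is tested with no external databases.

## Worked example

```r
library(adcvault)

cfg <- pipeline_config(out_dir = "demo", top_n = 10,
                       spr = sim_sensorgram_config(noise_sd = 0.5, seed = 1))
run_pipeline(cfg)

head(data.table::fread("demo/ranking.csv"), 6)
#>   rank protein_id gene_symbol K1 K2 K3     K4 passed_tm_filter data_gap
#> 1    1    SP00001      GS0001  0  0  0 1.0000             TRUE    FALSE
#> 2    2    SP00005      GS0005  0  0  0 0.9545             TRUE    FALSE
#> 3    3    SP00004      GS0004  0  0  0 0.6364             TRUE    FALSE
#> 4    4    SP00002      GS0002  0  0  0 0.5909             TRUE    FALSE
#> 5    5    SP00003      GS0003  0  0  0 0.5455             TRUE    FALSE
#> 6    6    SP00038      GS0038 17  6 11 0.5455             TRUE    FALSE
```

The five planted ideal targets (`SP00001`–`SP00005`) occupy ranks 1–5:
they have no healthy tissue at High or Medium (`K1 = K2 = K3 = 0`) and
are separated only by `K4`, the fraction of the 22-patient cohort at
High-or-Medium expression. The first decoy (`SP00038`) expresses in 17
healthy tissues and ranks accordingly.

```r
fit <- fit_full_kinetics(correct_sensorgram(
  read_sensorgram_csv("demo/sensorgram.csv")))
fit
#> <kinetic_fit: full_kinetics>
#>   ka = 3.678e+05 1/(M s)   kd = 0.0003971 1/s   KD = 1.079e-09 M
#>   Rmax = 99.97 RU
#>   chi2 = 1.049 RU^2   chi2% = 1.049% (high significance)   converged: TRUE
```

The sensorgram was simulated at `ka = 3.68e5 1/(M s)`, `kd = 4e-4 1/s`,
`Rmax = 100 RU` with 0.5 RU noise, drift and bulk artefacts; double
referencing removes the artefacts and the global fit recovers the rate
constants (true `KD = kd/ka = 1.087 nM`) with a Chi²% of about 1%, well
inside the < 5% high-significance band.

See the methods vignette (`vignettes/adc-target-discovery.Rmd`) for the
model, its assumptions and the design decisions.

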