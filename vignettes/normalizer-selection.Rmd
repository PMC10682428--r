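---
title: "Selecting reference miRNAs for plasma RT-qPCR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting reference miRNAs for plasma RT-qPCR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnorm)
```

## The problem

Relative quantification of circulating miRNAs by RT-qPCR divides each
target's signal by that of one or more reference ("normalizer") miRNAs.
In blood plasma there is no universally stable reference: candidate
normalizers drift with disease state, age, sex, haemolysis and technical
batch. Choosing them badly changes which targets appear regulated. This
package treats the choice as an explicit, exhaustive optimization over a
declared candidate panel, wrapped in the sample-quality checks that plasma
work requires (haemolysis detection, exogenous spike-in monitoring).

## The normalization model

All computation happens on the quantification cycle (Cq) scale, which is
log2 of template amount up to sign, assuming perfect doubling per cycle.
For a target $t$, a normalizer combination $C$ and sample $s$:

$$\Delta Cq_{t,s} = Cq_{t,s} - \frac{1}{|C|}\sum_{c \in C} Cq_{c,s},$$

the arithmetic mean over members being the log-scale equivalent of the
geometric mean of their relative quantities. Subtracting the mean
$\Delta Cq$ of the control group (the default reference; a grand-mean
reference is available) gives $\Delta\Delta Cq$, and the reported value is
$-\Delta\Delta Cq = \log_2\!\left(2^{-\Delta\Delta Cq}\right)$: log2
relative expression. Two consequences are used as internal checks
throughout the test suite: the control group's mean value is exactly zero
for every target, and a target normalized only to itself is identically
zero. No per-assay amplification efficiency is modelled; with efficiencies
other than 2 the values shift but the ranking machinery is unchanged.

Missing Cq ("Undetermined" wells) stay missing — they are never imputed to
a maximal cycle, because any imputation constant would leak directly into
the stability metrics. Samples missing any needed Cq are dropped pairwise
per (combination, target) with counts reported.

## The combinatorial ranking

For a panel of $n$ candidates (capped at 11 by default) every non-empty
subset — $2^n - 1$ combinations, identified by the bitmask code over the
declared panel order — is scored on three statistics of the normalized
values, each computed per evaluation target between two declared groups
(e.g. disease vs control) and averaged over targets:

* **KS** — the two-sample Kolmogorov–Smirnov distance between the case and
  control value distributions. A good normalizer combination should not
  separate the groups for candidate normalizers.
* **deviation** — the mean over the two groups of the absolute group mean
  of $-\Delta\Delta Cq$ (displacement from zero).
* **SD** — the mean of the two group standard deviations (sample, $n-1$
  denominator).

Lower is better on all three. The evaluation target set defaults to the
full candidate panel, including members of the combination under test, so
every combination — including the full panel — is scored against the same
targets (`exclude_self_targets` flips this). Within each metric the
combinations are rank-scored: best $= n_c - 1$ points, worst $= 0$, ties
averaged, so each metric distributes exactly $n_c(n_c-1)/2$ points. Points
are multiplied by user weights $(w_{KS}, w_{dev}, w_{SD})$, summed, and the
final ranking is by descending total with deterministic tie-breaks (lower
KS, then lower SD, then smaller code). Scaling all weights by one constant
cannot change the result, which is why the weight-sensitivity grid
`{1,2,3}^3` omits `(2,2,2)` and `(3,3,3)` — 25 informative weightings.

The rank-point convention needs one word: with $n_c$ items and unit steps
one cannot simultaneously give the best $n_c$ points and the worst 0.
This package gives the best $n_c - 1$ and the worst 0; under uniform
weights any common offset or scale of the points is immaterial to the
ordering.

## Quality control

**Haemolysis.** Red-cell lysis floods plasma with miR-451a and with
haemoglobin. The ΔCq rule scores
$Cq(\text{miR-23a-3p}) - Cq(\text{miR-451a})$ and calls a sample
contaminated when the difference strictly exceeds 7 cycles; strictly below
7 is clear, and equality is reported with a boundary warning rather than a
flag, preserving the information without inventing a side for the
boundary. The absorbance route scores the oxyhaemoglobin Soret band:
`peak414` is raw absorbance at 414 nm; the two three-wavelength schemes
(`shkurnikov`: 415 nm against references 450 and 700 nm; `kahn`: 578 nm
against 562 and 598 nm) are computed as baseline-corrected peak heights —
the primary absorbance minus the straight line through the two reference
wavelengths. The original publications' exact equation coefficients are
not embedded; a named coefficient map can supply them, and the
baseline-corrected form preserves the structure (shift-invariant, linear
in spectrum scale) without inventing constants. Spectra are linearly
interpolated between grid points; on ~1 nm grids higher-order schemes
would change nothing. `method_concordance()` reports Pearson r and the
least-squares line of each score against a reference score, the standard
way these methods are compared.

**Spike-ins.** Exogenous C. elegans miRNAs added before isolation
(cel-miR-39-3p, cel-miR-2-3p) and before reverse transcription
(cel-miR-238-3p, cel-miR-54-3p) monitor those two stages. Each spike-in is
z-scored within a stratum (default: cohort, deliberately not diagnosis —
flagging is a technical judgement), and a stage is flagged when any of its
spike-ins exceeds $|z| > 2$: single spike-ins are known to fail
idiosyncratically, so the ANY rule is the conservative choice. The
threshold 2 is this package's default, not a published constant.
Correction of target Cq by spike-in deviations is available
(`subtract_stage_deviation`, median batch reference for robustness) but
off by default: the recommendation to correct comes without a canonical
formula, and data should not be altered silently on a convention.

**Age and sex.** Cq can drift with age differently per sex. The
adjustment fits, per sex stratum and assay, ordinary least squares of Cq
on age and replaces Cq by residual plus the stratum mean — the simplest
defensible reading of "age-adjusted within sex groupings" that preserves
the Cq scale, so haemolysis thresholds and plausibility gates keep their
units. Strata with fewer than 3 samples or constant age pass through with
a warning. The pipeline default applies QC exclusions before adjustment.

## Baseline algorithms

For benchmarking, three classical single-candidate stability measures are
re-implemented in their simple forms:

* **geNorm**: $M_j$ = mean over other candidates $k$ of the sample SD of
  $Cq_j - Cq_k$, with stepwise exclusion of the highest $M$.
* **BestKeeper**: per-candidate SD and CV of Cq plus Pearson correlation
  to the per-sample mean of all candidates (the index); the SD serves as
  the stability value when a single number is needed.
* **NormFinder**: after centering each sample on its mean across
  candidates, the stability of candidate $i$ is the mean over groups of
  $|d_{ig}| + \sqrt{v_{ig}/n_g}$, where $d_{ig}$ is the deviation of the
  group mean from the candidate's overall mean and $v_{ig}$ the
  within-group variance. This is the uncorrected estimator; no
  small-sample shrinkage of the bias term is applied.

`aggregate_and_compare()` ranks all size-k combinations under each method
(single-candidate methods score a combination as the mean of member
stabilities — a convention of this package, stated as such), adds the mean
of per-method ranks as an aggregate, and reports pairwise Spearman
correlations between the method rankings.

## The synthetic cohort generator

Because no raw cohort is distributed, every analysis is exercised on
seeded synthetic data with known ground truth (`gt_*` metadata columns).
The generator emulates a two-group aging cohort: default 40 samples per
group (HC vs AD), seven endogenous candidate normalizers at baseline Cq
22–27 with within-group SD 0.3, uniform ages 55–85, optional per-assay age
slopes and sex effects, four spike-ins (SD 0.25) with a 2% planted outlier
fraction at +3 Cq, and a 10% haemolysed fraction whose contamination level
drops the miR-451a Cq by 5 per unit level (clean samples sit near
ΔCq ≈ 3, so levels above the declared detectability bound of 1.3 exceed
the threshold of 7 even against noise). Paired absorbance spectra are a
smooth plasma baseline (protein band near 280 nm) plus the level times a
haemoglobin signature — Gaussian bands at 414, 541 and 577 nm — plus OD
noise of SD 0.005. The bands are structural stand-ins, not measured
extinction curves: they support monotonicity and correlation tests, not
absolute haemoglobin quantification. Cq noise is Gaussian because Cq is a
log scale on which multiplicative expression noise is approximately
additive. What passing tests on these cohorts do **not** show: robustness
to non-Gaussian heavy-tailed Cq noise, plate effects, or efficiency
differences between assays.

## Numerical choices and test scale

The KS distance is computed exactly from the pooled jump points of the two
empirical CDFs (no asymptotic approximation); `stats::ks.test` is used
only as an independent oracle in the test suite. The scoring path is
validated against a naive brute-force re-implementation to $10^{-12}$ on
panels of up to 4 candidates, and the property suite runs the full
pipeline at the cohort scale above: 20-seed recovery runs with 7
candidates, and a scaling check up to 11 candidates (2047 combinations,
80 samples), sizes chosen so the whole suite completes in well under a
minute per file while still exercising every code path at realistic
cohort dimensions.

## Known limitations

* The group-SD metric decreases with combination size (averaging more
  members shrinks reference noise by $1/\sqrt{|C|}$), so rank aggregation
  has a structural preference for larger combinations. When only a
  minority of the panel is unstable this is harmless — planted stable
  subsets are recovered as the top combination. When three or more of
  seven candidates carry strong group shifts, a large combination that
  dilutes one shifted member can overtake the pure stable subset, which
  then ranks just below the top (within the top 4 in the test suite's
  fixed-seed runs). Up-weighting the KS or deviation component counters
  the effect; the weight-grid scan exists to make exactly this kind of
  sensitivity visible.
* Amplification efficiency is fixed at 2; Pfaffl-style calibrated
  quantification is out of scope.
* Absorbance scores are relative: converting them to haemoglobin
  concentration requires the published coefficients and a calibration
  that this package deliberately does not invent.
* The ΔCq haemolysis rule and the spike-in z-rule are per-sample marginal
  checks; they do not model joint failure modes (e.g. a whole failed
  plate), for which the batch metadata should be inspected directly.

## A worked run

```{r example, eval = FALSE}
spec <- sim_spec(seed = 7)
ds <- simulate_cq_dataset(spec)
spectra <- simulate_spectra(spec, ds)

qc <- haemolysis_report(ds$cq, spectra)
keep <- qc$sample_id[!qc$dcq_flag]

res <- run_bestmirnorm(ds, control_label = "HC", case_label = "AD",
                       exclude_samples = setdiff(ds$meta$sample_id, keep))
res$rank_table[1:5, c("final_rank", "code", "members", "total")]

scan <- weight_grid_scan(ds, "HC", "AD", top_k = 10)
head(scan$stability)

cmp <- aggregate_and_compare(ds, "HC", "AD", k = 3)
cmp$spearman
```
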