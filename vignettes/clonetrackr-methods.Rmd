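---
title: "Models and methods behind clonetrackr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonetrackr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrackr)
```

`clonetrackr` analyses lentiviral cellular-barcoding experiments that track
clonal hematopoietic stem cell (HSC) behaviour through ex vivo expansion
and transplantation, together with repopulating-unit (RU) quantification of
competitive transplants and dye-dilution division counting. This vignette
documents the models, the numerical choices, and the assumptions a user
should know before trusting a green test suite.

## 1. The generative model of a barcoding experiment

A simulated experiment proceeds in four stages, all parameterised by
`expansion_model()` and driven by a single integer seed (per-stage and
per-recipient sub-streams keep the pipeline reproducible and byte-stable):

1. **Clonal expansion.** Each founder HSC yields a clone whose cell count
   at harvest is lognormal: `log size ~ Normal(log_expansion_mean,
   log_expansion_sd)`, rounded to an integer. The standard deviation
   (sigma) is the *heterogeneity* parameter: sigma = 0 makes all expected
   clone sizes equal, while sigma around 1.5 reproduces the observed
   situation where a recipient's clone contributions span 0.1% to tens of
   percent. The lognormal was chosen because the real distribution is
   heavy-tailed but unnamed, and two parameters with closed-form moments
   make oracle tests possible. Note that only clone *frequencies* matter
   downstream, so the absolute scale (`log_expansion_mean`, default ~1e4
   cells per clone) only needs to be realistic enough for integer effects
   and thinning noise to be in proportion; bulk culture counts suggest
   per-founder progenies of 1e4-1e5 cells after three weeks.
2. **Transduction and barcodes.** Each founder is transduced with
   probability `transduction_efficiency` (0.35 pre-culture, 0.15
   post-culture in the published designs); a transduced clone draws one
   barcode uniformly *with replacement* from the library (5737 barcodes of
   8 bp, or 10,090 of 21 bp). Collisions are simulated rather than
   prevented, precisely so the downstream multi-parental exclusion rule has
   something real to do.
3. **Splitting and engraftment.** A `split_design` assigns each recipient a
   fraction of each well's harvest. The pre-culture design sends half of
   each of five wells to its dedicated parental recipient and one fifth of
   the pooled remaining halves to each of five daughters; the post-culture
   design pools one culture into recipients of one tenth each (the study
   transplanted five and analysed four, so four is the default). Cells are
   allocated by a multinomial draw per clone with per-recipient
   probability `fraction x engraftment_fraction`, so marginally each
   recipient sees a binomial thinning and allocations never exceed the
   harvest. The engraftment fraction defaults to 0.1 — a typical order of
   magnitude for homing and engraftment of transplanted HSCs in irradiated
   recipients; the experimental design does not pin it down.
4. **Sequencing.** Within a recipient, clones sharing a barcode merge;
   each barcode's read count is negative-binomial with mean proportional
   to its engrafted cells (total about `reads_per_recipient`, default 1e6 —
   an assumption, as real per-recipient depths are not reported) and
   dispersion `pcr_dispersion` (default 0.05). The negative-binomial
   captures PCR jackpots; dispersion 0 recovers Poisson/multinomial
   sampling, which the tests use as a closed-form limit. FASTQ output
   (100 nt single-end, Phred+33) embeds each barcode between constant
   flanks with uniform substitution errors (`seq_error_rate`, default
   0.001); indels are excluded because amplicon reads have fixed structure.

What the generator does **not** emulate: in vivo differentiation kinetics
and lineage output per clone, host conditioning, index hopping, chimeric
reads, and real library sequence composition (synthetic libraries are drawn
uniformly at random). A green test therefore establishes correctness of the
analysis pipeline under this stated noise model, not robustness to every
artefact of real sequencing.

## 2. The filtering pipeline

`run_pipeline()` applies three rules in a fixed order, matching the order
in which they are described for the original analysis:

1. **Background filter.** Per recipient, a barcode whose share of assigned
   reads is strictly below `threshold` (default 0.001, i.e. 0.1% — an
   explicitly arbitrary cut-off) is zeroed. The comparison is strict
   (`<`), so a barcode exactly at the threshold survives; the denominator
   is the recipient's assigned reads (the original description leaves the
   denominator implicit).
2. **Multi-parental exclusion.** A barcode with nonzero *post-filter*
   counts in two or more parental recipients is removed from every
   recipient. Presence is assessed after filtering so that a sub-threshold
   spillover in a second parental — already declared noise — does not
   trigger exclusion. Parental-daughter sharing never triggers exclusion;
   it is the signal.
3. **Normalization.** Surviving counts are rescaled to sum to `scale`
   (default 1e6) per recipient, left as real numbers.

One subtlety documented here because it is easy to mistake for a bug: the
*composite* kept set is not monotone in the threshold. Raising the
threshold can push a barcode below background in one parental, which
removes its multi-parental status and re-admits it everywhere else. The
monotonicity property holds for the background-filter survivor set, and the
tests assert exactly that, plus that the composite kept set is always a
subset of the survivors.

## 3. Clone statistics

*Clone size* is a barcode's normalized frequency within a recipient,
reported as percent. Summaries pool nonzero (barcode, recipient)
observations across recipients of a role, mirroring how pre- and
post-culture distributions are compared across recipients. Distribution
comparisons use the two-sided Mann-Whitney U test: exact (via the null
distribution of U) for untied samples up to n = 20 per group, exact by
enumeration of group assignments when ties are present and the assignment
count is at most 2e5, and the tie-corrected normal approximation with
continuity correction otherwise. Two-sided p-values are defined
symmetrically around `n1 n2 / 2`, which coincides with the usual doubled
tail for the symmetric untied null. The dominance profile bins clone
frequencies with left-closed intervals (a clone exactly at an edge falls in
the upper bin); no default binning is claimed as canonical, since the
original figure does not state one.

### Heterogeneity estimation

The scientifically interesting parameter is sigma, the lognormal spread of
clone expansion. The naive statistic — the pooled within-recipient standard
deviation of log normalized clone sizes — is biased in three ways:

* left truncation by the background filter (at sigma = 1.5 about half the
  clones fall below 0.1% and are unobservable, shrinking the naive sd to
  roughly 0.6 sigma);
* measurement noise from engraftment thinning and overdispersed read
  sampling (inflating the naive sd, dominant at low sigma: at sigma = 0 the
  naive sd is about 0.26 under the default model);
* barcode collisions, which merge distinct clones into apparent double-size
  clones at a rate set by the library size.

`estimate_heterogeneity()` therefore calibrates the statistic against the
generative model (indirect inference): the same naive statistic is computed
on lean count-level re-simulations of the full experiment — collisions,
thinning, negative-binomial reads, background filtering, multi-parental
exclusion, renormalisation — over a grid of sigma values (step 0.25, common
random numbers across grid points, isotonic pooling of the mean curve), and
the monotone response curve is inverted at the observed value. The 95%
interval is by test inversion through a parametric bootstrap: sigma0 is
retained when the observed statistic lies within mean +/- 1.96 sd of the
statistic simulated at sigma0, with the spread estimated from the grid
replicates, rescaled by a denser bootstrap at the calibrated sigma, and
inflated for the Monte-Carlo error of the mean curve. Test inversion rather
than a percentile bootstrap was chosen because it keeps near-nominal
coverage at the sigma = 0 boundary, where the sampling distribution of the
estimate piles up at zero. An early implementation fitted a left-truncated
normal by maximum likelihood instead; with mild truncation that fit is
disproportionately sensitive to the mass just above the cut-off and has
heavy-tailed sampling error, so it remains only as the model-free fallback
(`model = NULL`), where it corrects truncation but not noise or collisions.

Estimation defaults to parental recipients: daughters receive one tenth of
each clone at a mean frequency (1/clones per pool) that sits *below* the
background threshold, so daughter detection is itself the strongly
size-dependent event that `sharing_analysis()` quantifies — which is also
why the number of daughters a clone reaches correlates positively with its
true size at high sigma.

## 4. RU quantification

`repopulating_units()` implements the standard competitive-repopulation
formula `RU = p/(100 - p) * C/1e5`; its algebraic inverse
(`chimerism_from_ru()`) round-trips to machine precision, and the anchor
`RU(50%, C) = C/1e5` is exact. Chimerism of 100% saturates the assay (RU is
infinite); cohort folds (`functional_expansion_fold()`) therefore drop
recipients at or above 99.9% chimerism by default, mirroring how saturated
recipients fall out of the quantifiable range. Cohort activity is averaged
arithmetically per recipient (the original wording does not name the
averaging; a geometric option is exposed). Phenotypic folds are plain
arithmetic — final cells x phenotype frequency / input cells — and the
tests pin the printed-average example (13.6e6 cells x 0.1% / 50 input =
272-fold); a ratio of printed means legitimately differs from the printed
mean of per-culture ratios (291-fold), because a ratio of means is not a
mean of ratios.

## 5. Division counting

A proliferation dye halves per division, so divisions are unit steps in
log2 intensity below an undivided anchor (in the transplantation setting,
co-transplanted CD4+ spleen cells). `assign_divisions()` uses nearest-bin
assignment `d = round(anchor - log2 intensity)` clipped to `[0, d_max]`,
with halves rounding toward more divisions, so a cell is undivided exactly
when its log2 intensity is within half a division of the anchor. The
detection limit `d_max` defaults to 6 divisions — a typical dye limit, and
an assumption, as is the binning rule itself (the original work reports
division numbers without stating its binning). Cells beyond `d_max`, or
below an explicit negative-control floor, are censored at `d_max`.
Nearest-bin assignment rather than Gaussian-mixture fitting is the default
because with a control-anchored grid and peak spreads around 0.2 log2
units it assigns at least 95% of cells correctly while remaining exactly
reproducible; a mixture fit would add parameters the anchor already
provides. The "fewer than three divisions" summary is the sum of bins 0-2.

## 6. Numerical and interface choices

* All randomness flows from one integer seed; sub-stream seeds stay below
  2^31.
* Row/column conventions: barcodes are rows, recipients columns, in both
  `count_matrix` objects and their TSV form (roles and read accounting
  travel in `#` header lines).
* Barcode matching tolerates at most one substitution (`max_mismatch = 1`)
  and requires a unique nearest library barcode; ties are unassigned.
  Exact matching is the default because both library designs are defined
  sets and no error-correction step is part of the documented analysis.
* Empty inputs degrade gracefully: empty FASTQ gives an empty matrix with
  a warning; an empty count matrix gives an empty clone table; a recipient
  with no surviving reads keeps a zero column with a warning.
* The package exposes functions rather than a command-line tool: the
  analyses are interactive R workflows, and `scripts/acceptance.R` shows
  the end-to-end composition.

## 7. Known limitations

* The heterogeneity calibration assumes the supplied `expansion_model`
  describes the data; misspecified dispersion or engraftment biases
  sigma accordingly. The model-free fallback corrects truncation only.
* Within-well barcode collisions are unidentifiable from data and are
  handled only through calibration, not deconvolved per barcode.
* The Mann-Whitney enumeration cap (2e5 assignments) keeps exact p-values
  for small tied samples only; beyond it the tie-corrected normal
  approximation is used.
* RU quantification inherits the sigmoidal sensitivity of the competitive
  assay: near saturation, small chimerism errors translate into enormous
  RU errors, which is why saturated recipients are excluded rather than
  extrapolated.
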