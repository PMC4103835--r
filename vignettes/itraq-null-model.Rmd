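---
title: "A Gaussian null model for iTRAQ reporter-ion ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Gaussian null model for iTRAQ reporter-ion ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itraqde)
```

## The problem

In a 4-plex isobaric-labelling (iTRAQ) experiment, four pooled samples are
labelled, mixed and fragmented together; the MS/MS reporter ions at m/z
114–117 carry one peak area per sample for every identified peptide. The
design emulated by this package places four pooled epithelial lining fluid
samples on the four channels — two subject groups, each sampled before and
after an acute exposure — and the whole experiment is run twice on the same
pooled material. The question per protein is whether its abundance ratio
between two channels differs from what random technical variation alone
would produce.

There are no per-subject replicates inside one run (the samples are pools),
so significance cannot come from a t-test across subjects. Instead the
thousands of peptide-level ratios themselves estimate the technical null:
most proteins are unchanged, so the bulk of ln-ratios forms a null
distribution, and a peptide is called *discriminatory* when its ln-ratio is
an outlier relative to that bulk.

## The null-model procedure

For a contrast (numerator channel over denominator channel):

1. **ln-ratios.** For every peptide with both areas strictly positive,
   $r = \ln(A_\mathrm{num} / A_\mathrm{den})$. Rows with a zero area are
   excluded and logged (`compute_ln_ratios()`).
2. **Histogram.** The $r$ values are binned on $[-1, +1]$ in 200 equal bins
   (width 0.01, half-open, final bin closed). Values outside the range do
   not enter the fit but remain scorable (`build_histogram()`).
3. **Savitzky–Golay smoothing.** The bin counts are smoothed by local
   least-squares polynomial fits: each interior point takes the value, at
   the window centre, of the degree-$p$ polynomial fitted to its window;
   edges use a truncated one-sided window. A polynomial signal of degree
   $\le p$ passes through unchanged (`savgol_smooth()`).
4. **Gaussian fit.** $A \exp\!\big(-(x-\mu)^2 / 2\sigma^2\big)$ is fitted
   to the smoothed counts by Levenberg–Marquardt least squares
   (`fit_gaussian()`); $\sigma$ is the estimate of random technical
   ln-ratio variation.
5. **Calling.** A peptide is significant when
   $|r - \mu| \ge k\,\sigma$ with $k = 2.5$ by default — a two-sided
   confidence of $2\Phi(2.5) - 1 = 98.8\%$. The boundary is inclusive. A
   two-sided Gaussian p-value $2(1 - \Phi(|r-\mu|/\sigma))$ accompanies
   every peptide (`peptide_pvalue()`, `call_significant()`).

Protein-level results (`aggregate_proteins()`) report the median ratio of
the discriminatory peptides only, computed on the ln scale and
exponentiated; non-discriminatory peptides count toward the peptide total
only. With no discriminatory peptide the call is "none" and no ratio is
reported. A single discriminatory peptide is reported but flagged.

Candidates (`replicate_overlap()`, `select_candidates()`) must be
significant in the **same direction in both duplicate experiments** and
carry at least 2 peptides with p < 0.02 in each experiment.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| histogram range | $[-1, +1]$ | ln-ratio span of the null fit; $e^{\pm 1} \approx$ 2.7-fold |
| bins | 200 | bin width 0.01 ln-units |
| Savitzky–Golay window | 11 | 0.11 ln-units at default binning |
| Savitzky–Golay order | 3 | cubic local fits |
| $k$ | 2.5 | SD multiplier of the calling rule (98.8% confidence) |
| centre policy | fitted $\mu$ | `"zero"` available for sensitivity analysis |
| peptide p cutoff | 0.02 | candidate-selection rule, strict inequality |
| min. significant peptides | 2 | per experiment, for candidates |

The smoother's window and order are design choices: the procedure's source
convention fixes the histogram (200 bins on $[-1,+1]$) and the smoother
family but not its parameters. An 11-point cubic window suppresses
count-level noise while leaving a Gaussian peak of SD 0.1–0.3 essentially
undistorted (the fitted $\sigma$ on 50,000 simulated null ratios of SD 0.15
comes back within 1%); both are configurable and recorded in the run
manifest. The Gaussian centre is left free because a fitted curve has a
free centre unless stated otherwise; a systematic labelling bias then does
not inflate $\sigma$. One null is fitted per contrast per experiment, since
technical variance can differ between channels and runs.

## Numerical choices

- **Gaussian fit**: moment initialisation (weighted mean/SD of the smoothed
  counts); on failure a zero-centred two-parameter fit is retried; fewer
  than 5 positive bins or constant counts raise a fit error rather than
  returning a meaningless $\sigma$.
- **Savitzky–Golay edges**: a truncated window with fewer points than
  $p + 1$ has its degree reduced to the window size minus one, keeping the
  fit determined.
- **Boundary ties**: a deviation of exactly $k\sigma$ is significant
  ("at least"); a protein whose discriminatory peptides split evenly
  between directions is called "none" with a conflict note.
- **Out-of-range ratios**: excluded from the fit, still scored — strongly
  changed proteins (ratios of 10+ on the natural scale) must remain
  callable even though the histogram is bounded.
- **Determinism**: the generator derives per-experiment noise streams from
  one master seed; the pipeline is bit-reproducible given inputs and
  configuration.

## The synthetic-data generator

`simulation_config()` / `generate_replicate_pair()` emulate the study
design, not the instrument: peptides per protein are shifted-Poisson
(minimum 1, long-tailed like real identification tables); reporter areas
are a shared log-normal peptide abundance times per-channel multiplicative
noise with ln-SD $\sigma_0/\sqrt{2}$, so every between-channel ln-ratio has
SD $\sigma_0$ — exactly the Gaussian structure the null model assumes. The
technical ln-ratio SD of the original data is not published;
the default $\sigma_0 = 0.15$ is a plausible mid-range value for isobaric
reporter-ion data and is configurable. A fraction of proteins receives a
true ln fold-change of magnitude `effect_ln_fc` (sign Rademacher(1/2)) by
scaling the affected channel; both duplicate experiments share the truth
and differ only in noise.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: isotope-impurity cross-talk between
channels, ratio compression from co-isolated precursors, intensity-
dependent variance (variance shrinking with reporter intensity),
shared-peptide ambiguity between proteins, and missingness correlated with
abundance. The dropout option injects zero areas at random, which tests the
degenerate-input paths but is not a model of real missingness.

## The validation-arm statistics

Per-subject concentration comparisons use rank tests: paired
before/after-exposure changes within a group by the Wilcoxon signed-rank
test, and between-group differences (baseline values, or per-subject
changes) by the Mann–Whitney U test. The exact variants enumerate the full
permutation distribution (all $2^n$ sign assignments, or all
$\binom{n_1+n_2}{n_1}$ assignments), implemented as a convolution over
doubled midranks so tied observations are handled exactly, conditional on
the observed tie pattern; enumeration is bounded at $n \le 20$
(signed-rank) and $n_1 + n_2 \le 14$ (rank-sum), beyond which the test
falls back to the normal approximation with a warning. The normal
approximations use the tie-corrected variance and **no continuity
correction** — the convention of classic commercial statistics packages,
and the one consistent with reference small-sample values (five paired
all-positive differences give $z = 7.5/\sqrt{13.75}$, p = 0.043; six give
$z = 10.5/\sqrt{22.75}$, p = 0.028). Zero differences are dropped and
counted. No multiple-testing adjustment is applied, matching the emulated
analysis; note the approximation's worst-case error against the exact p is
about 0.03 at $n = 15$ mid-distribution and below 0.01 where exact
p $\le$ 0.1.

## Worked example

```{r example}
cfg <- simulation_config(n_proteins = 400, peptides_per_protein_mean = 5,
                         de_fraction = 0.08, effect_ln_fc = 1.2,
                         null_sigma = 0.15, seed = 42)
pair <- generate_replicate_pair(cfg)
bundle <- run_quantification(
  list(exp1 = pair$exp1, exp2 = pair$exp2),
  contrasts = list("115/114" = channel_contrast(115, 114)))

bundle$nulls$exp1[["115/114"]]
nrow(bundle$candidates)

truth <- pair$truth
mean(truth$protein_accession[truth$is_changed & truth$n_peptides >= 2] %in%
       bundle$candidates$protein_accession)
```

The fitted $\sigma$ recovers the generating 0.15 closely, and most truly
changed proteins with at least two peptides are selected while the
duplicate-concordance requirement keeps false candidates near zero (with
no changed proteins the expected candidate count is below one: the
per-protein false-call probability must be paid twice, in both
experiments, with matching direction).

## Problem sizes used in the checks

The package's own calibration checks run at desk scale: 50,000 simulated
null peptides for the coverage check of the $\pm 2.5\sigma$ interval
(98.8% expected), 5,000–10,000 peptides for $\sigma$-recovery within 2–5%,
replicate pairs of 300–2,000 proteins for recall/false-discovery checks,
and full enumeration oracles up to $n = 10$ for the exact tests.

## Known limitations

- The null model assumes a unimodal, approximately Gaussian bulk of
  ln-ratios; a dataset where most proteins change violates it.
- Channel-bias correction is limited to the fitted centre; no
  isotope-impurity matrix or intensity normalisation is applied.
- Peptides are assigned to one accession; shared peptides are not
  re-apportioned.
- The exact rank tests are conditional on observed ties (midranks); for
  heavily tied data the reported "exact" p is a permutation p, not the
  continuous-distribution one.
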