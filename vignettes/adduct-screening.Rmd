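---
title: "Screening digested DNA for xenobiotic adducts by LC-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening digested DNA for xenobiotic adducts by LC-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnadduct)
```

## The problem

Electrophilic xenobiotics — usually after metabolic activation by
cytochrome P450 and phase-II enzymes — bind covalently to DNA bases,
preferentially at the N-7 positions of guanine and adenine. The resulting
DNA adducts are initiating lesions of chemical carcinogenesis. After
enzymatic digestion of DNA to 2'-deoxynucleosides, adducts can be detected
by LC-MS, but most assays are targeted at a handful of known lesions.
`dnadduct` implements an untargeted screening workflow for
data-dependent-acquisition (DDA) LC-MS runs of digested DNA: find
treatment-specific features, verify that they behave like DNA adducts,
annotate them by subunit mass arithmetic, derive targeted MRM transitions
from them, and report quantities normalized to deoxyguanosine.

The key chemical fact the workflow exploits is that every intact
(nucleoside-level) DNA adduct is built from three chemically stable
subunits — deoxyribose, a DNA base, and the (transformed) xenobiotic — so
its fragmentation is predictable even when no reference compound exists:

* cleavage of the sugar gives a neutral loss of C5H8O3
  (`monoisotopic_mass("C5H8O3")` = 116.0473 Da), both in MS2 spectra and
  as in-source fragmentation in MS1;
* the protonated base (guanine 152.0567, adenine 136.0618), nucleoside
  (dG 268.1040, dA 252.1091) and deoxyribose oxocarbenium (117.0546) ions
  appear as diagnostic fragments;
* depurinated (base-level) adducts such as those released from N-7
  positions show the base fragment but no sugar chemistry.

## Mass arithmetic and hypothesis enumeration

All masses are monoisotopic, from CODATA/IUPAC isotope masses with carbon
fixed at 12 exactly; ion m/z uses the electron-corrected proton mass
1.00727646688 Da, singly protonated positive mode only. Printed
comparisons happen at presentation time (4 d.p. for accurate masses).

A candidate adduct ("hypothesis") is

```
adduct = parent + sum(biotransformation deltas) + target - binding_loss
```

where the target is a DNA base (depurinated adduct) or 2'-deoxynucleoside
(intact adduct) and the binding loss is empty (direct addition, e.g.
epoxide ring opening) or H2O (condensation). The default biotransformation
library holds the phase-I steps that commonly precede DNA binding:
epoxidation/hydroxylation (+O), hydration (+H2O), dehydration (-H2O),
desaturation (-H2), and dihydrodiol formation (+O +H2O). Sulfation is
deliberately absent: it acts as a leaving-group activation whose mass
trace is lost before DNA binding, so it would only duplicate the
direct-addition arithmetic. The default chain limit of three steps covers
the deepest commonly reported activation cascade (epoxidation, hydrolysis,
second epoxidation).

```{r}
h <- enumerate_hypotheses("C12H16O3", targets = c("dA", "dG"),
                          max_chain = 1, parent_name = "AS")
head(h[, c("name", "adduct_formula", "expected_mz")])
```

Enumeration deduplicates by adduct formula, keeping the variant with the
fewest steps. This matters chemically: an adduct of the oxidized parent on
dA has exactly the formula of the unmodified parent on dG (dG = dA + O),
so a single m/z cannot distinguish the two isomers. The enumeration keeps
the fewer-step interpretation and leaves the ambiguity to fragmentation
evidence; this is a genuine limitation of mass-only annotation, not of the
implementation.

## Simulated studies

Because no public raw data accompany this workflow, the package ships a
deterministic study simulator that generates the structure the screen
assumes, and the tests treat it as a first-class module. A simulated run
contains:

* the four 2'-deoxynucleosides as dominant background, dG highest, so
  that diagnostic ions and dG normalization are exercised realistically;
* optional random matrix species shared across all runs of a study;
* spiked adducts with Gaussian elution profiles (peak sigma 5 s by
  default), a configurable fraction of in-source deoxyribose loss
  producing a co-eluting ion 116.0473 Da lower, and configured MS2
  fragments;
* qToF-like mass jitter (Gaussian, 2 ppm sigma per peak), 10%
  replicate-to-replicate area variation, 2% per-scan intensity noise;
* DDA MS2: up to two precursors per cycle above an intensity threshold,
  one fragmentation event per species per elution peak, at or after the
  apex;
* a 600 s gradient sampled at 1 s MS1 intervals, 3 treated and 3 control
  replicates by default, spike multiplier 0 in controls.

These conditions emulate a well-behaved small-molecule LC-MS experiment.
They deliberately omit retention-time drift between runs, peak tailing,
isotope envelopes, chimeric MS2 spectra and detector saturation, so
passing tests demonstrate the correctness of the screening logic under
its stated assumptions, not robustness to every pathology of real data.
Runs serialize to standard mzML (written by the package's own minimal
serializer, read back via `mzR`), with a JSON ground-truth manifest.

## Feature finding

The feature finder replaces the commercial software used with the
original instrument workflow:

1. candidate m/z centroids come from greedy ppm-linkage clustering of all
   MS1 peaks of a run (a cluster breaks where the sorted m/z gap exceeds
   the tolerance), avoiding an arbitrary m/z grid;
2. an extracted ion chromatogram (EIC) is built per centroid — one point
   per MS1 scan, summing intensity within +/-5 ppm (the usual qToF mass
   accuracy; an absolute +/-0.01 Da window is available for verification
   EICs);
3. peaks are local maxima above `min_snr` (default 3) times the noise,
   estimated as the median absolute deviation of the trace scaled by
   1.4826. Adjacent maxima are merged when the valley between them stays
   above half the lower maximum — noise ripples must not split a peak,
   while a 4-sigma-separated pair (valley about 0.14 of peak height)
   still resolves. Peak boundaries extend to where the trace falls to the
   noise floor, capped at the valley minimum between retained maxima.
   The apex is the intensity-weighted centroid of the points above half
   height (a 3-point parabola vertex when the top is narrower than three
   points): for Gaussian peaks the centroid is unbiased and much less
   noise-sensitive than a vertex fit. Areas are trapezoidal;
4. features are aligned across runs by pooled m/z gap clustering
   (5 ppm) and, within an m/z group, retention-time gap clustering (6 s,
   i.e. 0.1 min — matched retention times are conventionally reported to
   2 d.p. minutes). Consensus m/z and rt are area-weighted means. The
   procedure is pooled and sorted, hence symmetric in run order.

A feature absent from a sample is `NA`, never zero; imputation is an
explicit, documented step of the statistics.

## Statistics

Two-group comparisons use a volcano selection: absent areas are imputed
at 0.2 times the smallest positive area in the matrix (adducts are
typically completely absent from controls, and the fold change would
otherwise be undefined), the fold change is `log2(mean_treated /
mean_control)` on imputed areas, and the p-value is a two-sided Welch
t-test on log2 areas. Selection defaults to fold change >= 2 at raw
p <= 0.05; Benjamini-Hochberg adjustment is available behind a flag but
off by default, matching the common practice of raw-p volcano selection
in this field. Multi-group comparisons use one-way ANOVA with Tukey's
honest significant difference at p = 0.05 (`stats::aov` +
`stats::TukeyHSD`; Tukey-Kramer for unequal group sizes). With zero total
variance the F statistic is undefined and the contract returns p = 1
everywhere with a warning.

## Verification evidence

Selected, treatment-elevated features collect three independent kinds of
adduct evidence:

* **diagnostic MS2 fragments** — DDA spectra whose precursor matches the
  feature (within the isolation half-width or 0.5 Da, whichever is
  larger) are searched for the diagnostic ion set above a relative
  intensity floor of 1% of the MS2 base peak;
* **MS2 neutral loss** — any fragment at precursor minus 116.0473 Da
  (+/-0.01 Da);
* **in-source pairing** — all ordered (heavy, light) feature pairs with a
  mass difference of 116.0473 +/- 0.01 Da, apex retention times within
  6 s, and Pearson correlation of their EICs of at least 0.90 in a
  reference run (the sample with the largest heavy-feature area). The
  0.90 default makes "high correlation" concrete; co-eluting profiles of
  one compound correlate near 1 even under per-scan noise.

Evidence is combinable but never mandatory — a candidate with only a
volcano hit is still reported, with a rank penalty — because real cases
exist where an adduct yields no usable high-resolution evidence and is
only recovered by targeted follow-up. Only the heavier member of an
in-source pair is treated as the intact species for annotation; the
lighter member is reported as a fragment. Candidates are ranked by
evidence count, then ascending p, then descending area. Annotation
assigns the nearest hypothesis within 5 ppm; ties go to the smaller
absolute error, then the shorter biotransformation chain.

## MRM design

From an annotated (or purely theoretical) hypothesis, the subunit logic
yields targeted transitions: deoxyribose loss (`[M+H]+ ->
[M+H-116.0473]+`), the protonated nucleoside, base and transformed
xenobiotic, and — because depurinated species co-occur in the ion source —
the base-cleavage transition of the in-source species
(`[M+H-116.0473]+ -> [M+H-116.0473-base]+`). Fragments with no subunit
rule (e.g. further side-chain losses reported in the literature for
specific compounds) are not generated; that is a documented limitation.
Unit-resolution export truncates each q value to the integer below and
prints one decimal (444.19 becomes 444.0), reproducing the convention of
vendor unit-resolution method tables; accurate export prints 4 d.p.

## Quantification

External calibration is unweighted ordinary least squares by default
(1/x weighting behind a flag); inverse prediction flags responses outside
the calibrated range extended by 20%. Adduct levels are reported as
adducts per 10^8 dG: the dG aliquot is measured after a 100-fold dilution
(the default `dilution_factor`), so the normalization is
`adduct / (dG * dilution) * 1e8`. Isotope-dilution quantification is out
of scope; without isotopically labeled internal standards these numbers
are comparative, not absolute.

## Numerical choices and degenerate inputs

* Retention time is seconds internally; reports print minutes (2 d.p.).
* EIC noise on an all-zero or constant trace has MAD 0; the noise floor
  falls back to machine epsilon, making any nonzero structure detectable
  (signal-to-noise ratios are then nominal, not physical).
* Welch tests on constant data return p = 1 when means are equal and 0
  otherwise rather than erroring feature-wise.
* Formula subtraction that would drive an element count negative is an
  error (impossible chemistry) and silently skips the affected
  combination during enumeration.
* All simulator randomness derives from one integer seed; run-level seeds
  are drawn deterministically from it, so studies are bit-reproducible
  including the serialized mzML.

## Problem sizes used in the test-suite

The shipped tests run a scaled version of a screening study: 3 treated
vs 3 control runs, a 600 s gradient at 1 s scan intervals, about 200
random matrix features over the four deoxynucleosides, and three spiked
adducts carrying MS2 and in-source evidence. Property suites use 100
random single-run configurations (150 s gradient) for the
generator/finder closure, 500-feature null matrices for the volcano
type-I check, and 1e5-4e5 draws for the permutation and Monte-Carlo
studentized-range references. These sizes give stable statistics while
keeping the default suite fast on a single CPU.

One statistical subtlety: a label-permutation reference for Tukey's test
on nine discrete values has a granular null tail (the smallest achievable
tail mass is set by the 1680 distinct label assignments), so it can
reproduce the significance pattern but not arbitrarily small p-values.
The numeric agreement check for Tukey p-values therefore uses a
Monte-Carlo sample of the studentized-range null itself, which is the
distribution the test actually references.

## Known limitations

* Positive mode, singly protonated ions only; no isotope-pattern or
  multiple-charge handling.
* No retention-time warping across runs; alignment assumes a stable
  gradient.
* Annotation is mass-only; isomeric adducts (oxidized-parent-on-dA vs
  parent-on-dG) need fragmentation evidence to distinguish.
* Centroided data only; profile spectra are rejected, not centroided.
* The simulator's Gaussian, drift-free peaks are sufficient for testing
  pairing and correlation logic, not for benchmarking peak-shape-robust
  integration.
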