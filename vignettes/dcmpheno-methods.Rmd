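---
title: "Methods: genetic mapping and iPSC-cardiomyocyte phenotyping for recessive DCM"
author: "dcmpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic mapping and iPSC-cardiomyocyte phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmpheno)
```

# Overview

`dcmpheno` implements the computational chain used to map an autosomal
recessive dilated-cardiomyopathy (DCM) locus in a consanguineous family
and to phenotype engineered iPSC-derived cardiomyocytes (iPSC-CMs):

1. **Locus mapping** — exact two-locus pedigree likelihoods and
   two-point Lod scores under a recessive penetrance model; shared
   runs-of-homozygosity (ROH) detection; recessive candidate-variant
   filtering.
2. **Cell phenotyping** — sarcomere length (SL) and sarcomere packing
   density (SPD) from 2D Fourier spectra of immunofluorescence images;
   calcium-transient kinetics from paced ratiometric traces;
   block-matching motion analysis of beating monolayers; and
   engineered-heart-tissue (EHT) contractile force from post deflection.
3. **Synthetic data** — seeded generators for every input, each
   emitting ground truth, so the whole chain is testable without any
   raw data.

The `analysis/` scripts in the repository run these stages end to end
and write their tables under `results/`.

# Sarcomere packing density

For an image of alpha-actinin-stained cardiomyocytes with pixel size
$p$ (µm/px), a 200×200 px region of interest (ROI) is mean-subtracted,
tapered with a 2D Hann window, and Fourier transformed. The 1D profile
$\Gamma(f)$ is the mean power per radial-frequency bin over a 30°
wedge (±15°) centred on the dominant striation orientation, and is
modelled as an aperiodic decay plus Gaussian peaks at the fundamental
spatial frequency $f_0$ and its second harmonic:

$$\Gamma(f,\zeta) = a_0 e^{-f/b_0}
  + \sum_{k=1}^{2} a_k \, e^{-(f-kf_0)^2/b_k},
  \qquad \zeta = \{a_i, b_i, f_0\}.$$

The metrics are the sarcomere length $SL = 1/f_0$ and the sarcomere
packing density

$$SPD = \frac{\int_0^\infty \Gamma_p\,df}{\int_0^\infty \Gamma\,df}
  \in [0, 1],$$

the fraction of spectral power attributable to periodic sarcomeric
structure. Organized cells approach 1; punctate, disorganized staining
drives it toward 0.

Design choices (`compute_power_spectrum()`, `wedge_profile()`,
`fit_spd_model()`, `sarcomere_metrics()`):

* **Windowing.** A 2D Hann taper suppresses edge leakage that would
  otherwise inflate the aperiodic term; it can be disabled (Parseval
  checks in the test-suite run unwindowed).
* **DC handling.** The ROI mean is subtracted and frequencies below
  0.05 cycles/µm are excluded from the profile and fit.
* **Orientation.** Estimated as the argmax of a 1°-binned angular
  histogram of mean power in the 0.3–0.8 cycles/µm band (the
  physiological sarcomere-frequency range); ties break to the smallest
  angle. Angles are taken modulo 180°, which folds the two Hermitian
  halves of the spectrum together. Confidence is the share of band
  power inside the chosen wedge: an isotropic spectrum puts 1/6 of it
  there, so a share below 1.8×(1/6) = 0.3 flags the orientation as
  low-confidence (the analysis still proceeds).
* **Profile binning.** Mean (not summed) power per radial bin, bin
  width equal to the 200-px ROI's spectral resolution, so bins with
  different point counts are comparable.
* **Fit.** Bounded Levenberg–Marquardt least squares in linear power,
  restricted to $f \le 2.2$ cycles/µm — the band containing the
  fundamental (SL 1.3–3.0 µm, i.e. $f_0 \in [0.33, 0.77]$), its second
  harmonic, and the background that matters for them; beyond it the
  noise floor of real and synthetic spectra no longer follows the
  single-exponential background model. Peak widths are bounded at
  $b_k \le 0.05$ (sd ≈ 0.16 cycles/µm): sarcomere peaks are narrow, and
  unbounded Gaussians would absorb the aperiodic background and push
  SPD to 1. Multistart: $f_0$ is seeded at the strongest local maxima
  of the profile in band, $a_0, b_0$ from a log-linear fit to off-peak
  bins, plus one background-anchored start with near-zero peaks; the
  lowest residual wins, ties to smaller $f_0$. The profile is
  normalized to its median before fitting so the background is O(1) in
  fit units.
* **Integration.** SPD integrals are evaluated by adaptive quadrature
  of the fitted analytic model on $[0, \infty)$. Truncating at the
  profile's Nyquist frequency would leave an $e^{-f_{max}/b_0}$ tail
  error in the aperiodic integral that is far larger than the 1e-6
  agreement the closed forms $\int\Gamma_{ap} = a_0 b_0$ and
  $\int\Gamma_p = \sum_k a_k\sqrt{\pi b_k}$ otherwise provide, so the
  model — not the sampled profile — is integrated.
* **ROI choice.** The highest-variance 200×200 window on a coarse grid
  (integral-image search), overridable with explicit coordinates.

# Calcium-transient kinetics

Traces are 340/380 excitation ratios of field-stimulated (0.5 Hz)
cells. Each pacing window is analyzed by `transient_metrics()`:

* **Baseline**: mean of the window's lowest-decile samples — robust to
  noise and to the decaying tail of the previous beat.
* **Peak location**: argmax of a lightly smoothed copy (moving median
  of 3, then a narrow Gaussian). Smoothing is used for detection only.
* **Amplitude and decay constant**: a least-squares fit of the
  transient model — a saturating rise times a monoexponential decay,
  $s(t) \propto (1 - e^{-t/\tau_r})\,e^{-t/\tau_d}$, normalized to unit
  peak — with free baseline, amplitude, onset, $\tau_r$ and $\tau_d$.
  The raw maximum minus baseline systematically overestimates the
  amplitude at realistic noise levels because the maximum selects the
  largest noise excursion, and a monoexponential fit anchored at the
  peak overestimates $\tau_d$ because the rise factor still grows just
  after the peak; the model fit has neither defect, and the test suite
  verifies ≤5% recovery error for both quantities at 20 dB SNR
  (amplitude-to-noise-sd ratio of 10). The onset is allowed to precede
  the window so decay-only windows remain fittable.
* **t50/t90**: interpolated times from the observed peak to 50% and
  90% recovery of the observed peak height; computed even when the fit
  fails (then tau is reported missing and the amplitude falls back to
  the smoothed peak).
* **Per-cell summary**: median across analyzable beats plus beat count
  and MAD; cells without an analyzable beat are excluded with a
  recorded reason.

An optional per-window linear detrend (off by default) handles
photobleaching-style drift.

# Contractility

**Block matching** (`block_match_motion()`): for every complete 16×16
block (default), the displacement within ±8 px (default) maximizing the
normalized cross-correlation with the next frame. Ties break to the
smallest displacement magnitude, then raster order. Blocks are invalid
if their texture variance is below 1e-4 of the frame variance (nothing
to match, and a relative threshold keeps results invariant to global
intensity scaling) or if their full search window leaves the frame
(they could not report every candidate, which would bias averages).
Displacements at the search bound are flagged saturated.

**Beat metrics** (`motion_beat_metrics()`): the mean displacement
vector over valid blocks is projected on the dominant motion axis
(principal direction of the velocity cloud) and integrated into a
displacement trace; each excursion above 30% of its maximum is one
contraction. This is robust to the zero-speed plateaus that whole-pixel
motion produces, which fragment speed-trace-based stroke detection.
Peak contraction (relaxation) velocity is the largest projected speed
toward (from) each displacement peak, in µm/s.

**EHT force** (`deflection_to_force()`): the end-loaded cantilever
relation

$$F = \frac{3\pi\, d\, E\, r^4}{4 L^3}$$

with standard silicone-post parameters as defaults: $E$ = 1.7 MPa,
$r$ = 0.5 mm, $L$ = 10 mm; at $d$ = 0.1 mm this gives 25.03 µN.
Per-cycle rests are the pre-onset minimum of the smoothed trace over
the second half of the preceding inter-beat gap, so slow baseline
drift is tracked per cycle rather than counted as deflection.

# Linkage and variant filtering

**Model.** A biallelic disease locus (risk-allele frequency $q$,
penetrance by risk-allele count, default $(0, 0, 0.99)$ — recessive,
99% penetrance, no phenocopies) linked at recombination fraction
$\theta$ to a codominant multi-allelic marker. Rare-disease mapping
conventionally assumes $q$ = 0.01 or 0.001; 0.001 is the default and
0.01 is available. Marker allele frequencies are
user-supplied (founder priors depend on them); without them a uniform
distribution over observed alleles is assumed.

**Likelihood** (`pedigree_likelihood()`). Each individual's latent
state is an unordered pair of two-locus haplotypes; founders carry
Hardy–Weinberg/linkage-equilibrium priors, transmissions are Mendelian
with recombination, phenotypes are penetrance factors, and observed
marker genotypes restrict each individual's state set (genotype
elimination). The joint likelihood is contracted exactly by greedy
variable elimination on the factor graph — exact on looped,
consanguineous pedigrees without loop-breaking. An independent
`method = "enumeration"` sums every configuration directly (bounded by
`max_states`, default 1e7) and serves as the cross-check oracle in the
test suite. `two_point_lod()` reports
$\mathrm{Lod}(\theta) = \log_{10} L(\theta) - \log_{10} L(0.5)$ on the
grid $\{0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4\}$ with the grid argmax
$\hat\theta$ (ties to the smallest $\theta$). Multipoint Lod scores
are out of scope.

**Shared ROH** (`shared_roh()`): maximal runs of consecutive markers
at which every affected is homozygous for the same allele (a
homozygosity-by-descent proxy; a flag relaxes to per-individual
homozygosity). Runs shorter than 4 cM (the mapping threshold) are
dropped; surviving runs are annotated with unaffected individuals
sharing the homozygous haplotype — exclusion evidence against the
segment.

**Variant filter** (`filter_variants()`), rules applied in order, the
first failure logged per variant: (1) inside the linkage interval;
(2) homozygous-alt in all affecteds; (3) not homozygous-alt in any
unaffected; (4) population allele frequency ≤ 0.01 — a missing
annotation passes, mirroring how an unreported variant cannot be
excluded by frequency; (5) healthy-homozygote count ≤ 0 (missing
passes).

**Group comparison** (`compare_groups()`): pooled-variance Student's
t-test (two-sided, α = 0.05); Welch by
flag. The degenerate both-groups-constant case is defined as p = 1
for equal means, p = 0 otherwise.

# Synthetic data: what it emulates, what it does not

All generators take a seed and return ground truth next to the data.

* **Striated images**: a periodic comb of Gaussian bands (sd =
  period/6) — chosen over a pure cosine so the spectrum carries a real
  second harmonic that exercises $a_2, b_2$ — at a configurable
  orientation and period (default 1.8 µm at 0.1 µm/px, 512×512;
  the test suite uses 220×220 for speed), covering a tile-assigned
  `organized_fraction` of the field; the remainder holds isotropic
  Gaussian puncta mean-matched to the stripes, mimicking punctate
  staining of disorganized sarcomeres. Not emulated: cell boundaries
  and segmentation, out-of-focus light, photobleaching, shot noise
  (noise is additive Gaussian).
* **Calcium traces**: baseline + per-stimulus transients (saturating
  rise × monoexponential decay; the generator's $\tau_d$ is the scored
  ground truth), additive Gaussian noise, 50 Hz sampling. Specs whose
  transients would overlap (pacing period ≤ $\tau_r + \tau_d$) are
  rejected. Not emulated: alternans, spontaneous activity, Fura-2
  saturation.
* **Beating videos**: a fixed smooth random texture translated by a
  raised-cosine pulse train (defaults 0.5 Hz, 75 fps, 10 s) rounded to
  whole pixels, cropped from a wider canvas so every frame is an exact
  translation; per-frame displacement, per-pulse peak speeds and a
  search-radius-exceeded flag are recorded. Not emulated: non-rigid
  deformation, sub-pixel motion, illumination drift — so passing tests
  show correctness of the matcher, not robustness to deformable
  motion.
* **Gene drop**: founders from Hardy–Weinberg at $q$, meioses with
  recombination $\theta$, penetrance phenotype draws. Genotyping error
  is not simulated.
* **ROH panels and variant tables**: a planted autozygous interval
  (affecteds homozygous, unaffecteds heterozygous) on an evenly spaced
  map; candidate tables with one causal variant built to pass every
  filter and decoys each built to violate at least one.

# Numerical choices and problem sizes

Random-number use is seeded everywhere; each generator derives its
stream from the user seed plus a fixed offset so streams stay
independent. The validation suite uses desk-scale sizes chosen to keep
estimator error well inside the asserted tolerances: 220×220 px images
(50 per period for SL recovery, 20 per level over six organized
fractions for monotonicity), 50 traces at 20 dB SNR and 30 cells per
population for calcium, 64×64 frames for the block-matching oracle,
200 random looped pedigrees for the peeling/enumeration identity, and
200 gene-drop replicates (each pooling three families ascertained for
≥2 affected and ≥1 unaffected children — phenotype ascertainment does
not bias the recombination estimate) for $\hat\theta$ consistency at
$\theta$ = 0.05. `scripts/acceptance.R` recomputes the same quantities
at moderately smaller sizes and writes them as JSON.

# Known limitations

* Published family Lod tables generally cannot be reproduced without
  the underlying marker genotypes, which are rarely deposited. The Lod
  machinery here is instead validated against
  analytic single-meiosis values, the enumeration oracle, and
  simulation consistency.
* SPD of strongly organized, low-noise images saturates near 1; the
  aperiodic amplitude is then weakly identified in linear-power least
  squares (its contribution to the residual is negligible), so
  comparisons should rely on SPD itself rather than on $a_0$.
* Block matching reports whole-pixel displacements; velocities are
  quantized to pixel/frame steps.
* The cantilever force formula assumes small deflections and a
  uniform cylindrical post; post tracking from video is not included
  (deflection traces are the interface).
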