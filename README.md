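# dcmpheno

Genetic mapping and iPSC-cardiomyocyte phenotyping for autosomal
recessive dilated cardiomyopathy (DCM).

Recessive DCM mutations are typically mapped in consanguineous
families — the disease locus is a region homozygous-by-descent in all
affected relatives — and validated functionally in genome-edited
iPSC-derived cardiomyocytes (iPSC-CMs), which recapitulate the DCM
hallmarks: sarcomeric disarray, aberrant calcium handling, and
impaired contractility. `dcmpheno` implements that whole computational
chain as a tested R package for geneticists and stem-cell
physiologists, with seeded synthetic-data generators (ground truth
included) standing in for raw images, traces, and genotypes.

## What it computes

**Locus mapping**

- Exact two-locus pedigree likelihoods and two-point Lod scores,
  `Lod(θ) = log₁₀ L(θ) − log₁₀ L(0.5)`, under a recessive model
  (risk-allele frequency q ∈ {0.001, 0.01}, penetrance (0, 0, 0.99)),
  by variable elimination on the pedigree factor graph — exact on
  consanguineous (looped) pedigrees, with an independent enumeration
  cross-check.
- Shared runs of homozygosity: maximal marker runs at which every
  affected is homozygous for the same allele, thresholded at 4 cM,
  annotated with exclusion evidence from unaffected relatives.
- Recessive candidate-variant filtering: interval membership,
  homozygosity in affecteds, absence of homozygous unaffecteds,
  population allele frequency ≤ 0.01, healthy-homozygote count = 0 —
  each rejection logged with its first failing rule.

**iPSC-CM phenotyping**

- Sarcomere length and sarcomere packing density (SPD) from the 2D
  Fourier power spectrum of an alpha-actinin image: a 30° wedge
  profile Γ(f) is fitted with
  `Γ = a₀·exp(−f/b₀) + Σₖ aₖ·exp(−(f−k·f₀)²/bₖ)` (k = 1, 2), giving
  `SL = 1/f₀` and `SPD = ∫Γₚ / ∫Γ ∈ [0, 1]`.
- Calcium-transient kinetics of paced (0.5 Hz) Fura-2 ratio traces:
  amplitude, time to peak, decay constant τ (from a transient-model
  fit), t50/t90 recovery times, per-cell medians.
- Monolayer contractility via block-matching motion vectors
  (normalized cross-correlation, exhaustive integer search) and beat
  metrics from the integrated displacement trace.
- Engineered-heart-tissue force from post deflection,
  `F = 3π·d·E·r⁴ / (4L³)` with E = 1.7 MPa, r = 0.5 mm, L = 10 mm.
- Group comparisons with the unpaired Student's t-test (α = 0.05).

## Worked example

```r
library(dcmpheno)

# sarcomere organization of a synthetic well-organized cell
img <- generate_sarcomere_image(sarcomere_image_spec(
  size_px = c(220, 220), organized_fraction = 0.9, seed = 1))
res <- analyze_image(img)
cat(sprintf("SL = %.2f um, SPD = %.3f (orientation %d deg)\n",
            res$metrics$SL_um, res$metrics$SPD, res$qc$orientation_deg))
#> SL = 1.78 um, SPD = 1.000 (orientation 30 deg)

# calcium kinetics of a paced trace (true tau = 0.4 s)
tr <- generate_calcium_trace(calcium_trace_spec(tau_decay_s = 0.4,
                                                noise_sd = 0.03, seed = 1))
analyze_calcium_trace(tr)$cell[, c("amplitude", "tau_decay_s", "t50_decay_s")]
#>   amplitude tau_decay_s t50_decay_s
#> 1      0.51       0.392       0.348

# EHT force for a 0.1 mm post deflection
deflection_to_force(1e-4)
#> [1] 2.503457e-05   # newtons

# recessive filter on the four exome candidates in the linkage interval
vt <- read_variants_tsv(system.file("extdata",
        "speg_family_candidate_variants.tsv", package = "dcmpheno"))
res <- filter_variants(vt, list(chrom = "2", start = 218317008,
                                end = 227728735),
                       affected_ids = c("III3", "III5", "III6"),
                       unaffected_ids = c("II4", "II5"), pos_col = "pos")
res$audit
#>   row    gene                 rule
#> 1   1 C2orf24 population_frequency
#> 2   2   DNPEP population_frequency
#> 3   3    SPEG                 pass
#> 4   4  DOCK10  healthy_homozygotes
```

The generated image has SL within 1.5% of the generator's 1.8 µm period
and an SPD near 1, as expected for well-registered striations; the
fitted decay constant is within 2% of the generator's τ; the force
matches the cantilever formula analytically; and of the four candidate
variants only the SPEG missense variant survives — the two common
polymorphisms fail on population frequency and the DOCK10 variant on
its nine healthy homozygous carriers.

The `analysis/` directory contains numbered drivers that run each
stage on synthetic cohorts and write tables under `results/`:
`01_map_disease_locus.R`, `02_filter_candidate_variants.R`,
`03_sarcomere_organization.R`, `04_calcium_kinetics.R`,
`05_contractility_and_force.R`.

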