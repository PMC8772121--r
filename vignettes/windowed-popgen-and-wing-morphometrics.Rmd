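---
title: "Windowed population genomics and wing morphometrics: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed population genomics and wing morphometrics: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`apiscan` re-implements, at desk scale, the statistical core of a
population-genomic and morphometric characterisation of honeybee
(*Apis cerana*) cohorts: sliding-window nucleotide diversity and
Weir–Cockerham Fst, pairwise-Fst matrices, heterozygosity and inbreeding,
linkage-disequilibrium decay, genotype PCA, a joint Fst × θπ-ratio
selective-sweep scan, and landmark-based wing geometric morphometrics.
Upstream steps (read alignment, variant calling, functional annotation) and
downstream interpretation (ancestry models, demographic inference, GO/KEGG
enrichment) are out of scope; the package starts from a genotyped VCF and a
TPS landmark file.

Because genome-scale resequencing data cannot be shipped or recomputed at
desk scale, every stage is paired with a simulator that produces data with
*known* ground truth. All empirical statements below are the ones the test
suite and `scripts/acceptance.R` themselves compute.

# Genotype model and statistics

## Containers and conventions

Genotypes live in a sites × samples matrix of alternate-allele dosages
(0/1/2, `NA` for missing), anchored to sorted genomic coordinates.
Internally all interval arithmetic is 0-based half-open; VCF and GFF3
ingestion converts from their 1-based inclusive dialects and all printed
reports convert back. Half-called genotypes (`./1`) are treated as fully
missing so that every retained call is a whole-individual dosage — the
alternative (fractional dosages) would complicate every downstream estimator
for negligible information gain.

SNP quality filtering retains sites with missing ratio strictly below 10%
and minor allele frequency strictly above 1% (both configurable), the
conventional post-calling thresholds for resequencing cohorts. MAF is
computed over non-missing alleles only. The read-depth support filter that
precedes genotype matrices in a calling pipeline is a caller-level concern
and deliberately not reproduced here.

## Nucleotide diversity

Per site, π is the expected pairwise difference among the `n` non-missing
alleles, `n_ref · n_alt / C(n, 2)`; a window's value is the per-site sum
divided by the window length in bp. The bp denominator (rather than the
number of variant sites) matches the windowed-π convention of VCFtools'
`--window-pi`, which the default window geometry (40 kb windows, 20 kb
step) is taken from; a per-variant-site denominator is available via a
flag. Windows with no usable site report π = 0 with `n_sites = 0` so that
downstream tabulation need not special-case them.

## Weir–Cockerham Fst

Differentiation uses the Weir & Cockerham (1984) variance-component
estimator for diploid data: per site, among-population (a),
among-individual-within-population (b) and within-individual (c) components
are formed from per-population sample sizes, allele frequencies and observed
heterozygote proportions; a window (or the genome) reports
`Σa / Σ(a+b+c)` — the ratio of sums, not the mean of per-site ratios. The
ratio-of-sums form is the stable standard and is what makes small negative
estimates possible for essentially undifferentiated pairs; such negatives
are reported as-is, never clamped, because they are informative (they also
appear in the published tables the package carries as fixtures). A window
whose component sum is zero (e.g. no polymorphism) reports `NaN` and is
flagged rather than silently dropped.

The test suite checks the implementation against an independent
transcription of the estimator via the nested-ANOVA mean-squares route
(`MSP`/`MSI`/`MSG` with the `n_c` correction) at tolerance 1e-12, and
against a closed-form truth oracle under simulation (below).

Pairwise population matrices default to genome-wide ratio-of-sums over all
retained sites, with window-averaging available as an option; published
tables do not always state which convention produced them, and the two
differ only in weighting. Matrix summaries (`fst_matrix_summary`) are exact
unweighted arithmetic means over the selected unordered pairs, which is the
convention that reproduces the published region-level averages carried in
`inst/extdata/`.

## Heterozygosity and inbreeding

Per site, expected heterozygosity is `He = 2p(1−p)` with `p` estimated in
the individual's own population, without small-sample correction. The
per-individual inbreeding coefficient is the method-of-moments
`F = (O − E) / (N − E)` on homozygote counts over the sites at which that
individual is genotyped. Population summaries are unweighted means across
sites (He) and individuals (Ho, F). Under a Hardy–Weinberg simulation
(50 diploids, 5000 SNPs) the population mean F is within ±0.02 of zero.
Published per-individual heterozygote columns formatted as large counts are
not targeted; the package reports Ho as a proportion.

## LD decay

r² is the squared Pearson correlation of dosage vectors over samples
non-missing at both sites — composite (genotype) LD, the right quantity for
unphased data; no phasing or EM haplotype estimation is attempted, and the
curve is therefore not numerically identical to one computed from phased
haplotypes. Pairs are binned by physical distance; the decay distance is
the midpoint of the first bin whose mean r² drops below the conventional
0.1 threshold (NaN if never crossed). For independent loci the sampling
floor is `E[r²] ≈ 1/n`; the tests verify this at n = 100. Because the
Balding–Nichols generator produces unlinked sites, LD-decay demonstrations
use a dedicated linked-site generator: a per-haplotype latent Gaussian
process with correlation `exp(−d/L)` thresholded at each site's allele
frequency (a Gaussian copula), giving smooth distance-dependent decay with
configurable length scale `L`.

## Genotype PCA

Missing dosages are mean-imputed per site; each site is centred by `2p̂`
and scaled by `sqrt(2p̂(1−p̂))` (the usual genotype standardisation);
the SVD of the standardised samples × sites matrix gives scores and
variance fractions. Monomorphic sites are dropped (zero variance carries no
structure). Two populations simulated at F = 0.3 separate completely on
PC1 at 20+20 samples and 2000 SNPs.

# The sweep scan

The scan contrasts a candidate cohort against a reference cohort in 20-kb
windows with 10-kb step: per window, Weir–Cockerham Fst between cohorts and
π within each. Fst values are Z-transformed (sample sd, n−1) across
rankable windows; diversity contrast is `log2(π_reference / π_candidate)`,
oriented so that diversity *loss in the candidate* is positive — the
orientation is configurable since the convention is not universal. A window
is selected when both statistics lie at or above their marginal empirical
(1−q) quantiles, q = 0.05 by default. Quantiles use the "higher"
order-statistic convention so the threshold is always an observed value and
ties at the threshold are included; selection is then monotone in q and
either single criterion alone selects `⌈q·n⌉` windows up to ties.

Design choices worth stating explicitly:

* Thresholds are marginal with intersection, not joint; the Z-transform does
  not change ranks, so thresholding z-Fst is equivalent to thresholding raw
  Fst at the same quantile.
* The π criterion is one-tailed (candidate-depleted) by default with a
  two-tailed option, since depletion is the sweep signature but an elevated
  tail can be of interest.
* Windows with fewer than 10 SNPs or zero π in either cohort are excluded
  from ranking (and counted), rather than pseudocounted: a log-ratio against
  a zero denominator is not a statistic worth ranking.

Selected windows are merged into disjoint regions (overlapping or abutting,
with an optional gap) and genes are attached by ≥ 1 bp overlap, strand
ignored, using half-open interval arithmetic throughout; a gene abutting a
region boundary exactly is not counted.

# Wing geometric morphometrics

Landmark configurations (20 forewing / 10 hindwing landmarks in the
workflow this package mirrors) are read from plain-text TPS files; `SCALE=`
records are applied multiplicatively so coordinates are in calibrated
units. Centroid size `CS = sqrt(Σ‖x_i − centroid‖²)` is the size measure;
it is computed on raw calibrated coordinates, before any normalisation.

Generalized Procrustes Analysis centres every configuration, scales to unit
centroid size, and iteratively rotates each onto the GLS consensus (the
coordinate-wise mean, re-centred and re-scaled to unit CS), using the
closed-form orthogonal-Procrustes rotation restricted to determinant +1 —
reflections are never introduced by alignment. Iteration stops when the
consensus moves less than `tol = 1e-8` (root-sum-square); the objective
(total squared distance to consensus) is non-increasing across iterations
and its converged value is invariant to specimen order. Full-Procrustes
scaling is used because size is analysed separately through CS; shape and
size are thus cleanly split. Bookstein two-point baseline registration is
provided for parity with digitising workflows (forewing baseline landmarks
1 and 7, hindwing 2 and 10, in file numbering), but GPA operates on raw
coordinates by default — the two routes differ only by a similarity
transform.

Shape variation is summarised by PCA of the flattened aligned coordinates.
Size differences across groups use one-way ANOVA followed by Fisher's LSD
pairwise tests on the pooled within-group mean square; LSD applies no
multiplicity correction *by definition* (a corrected variant is exposed but
off by default). The compact letter display is built by the
insert-and-absorb algorithm on the pairwise significance matrix. A
numerically zero within-group mean square (relative to the total) is an
error: F is undefined on degenerate data.

Mean centroid size per sampling site is regressed on latitude, longitude
and altitude by forward-stepwise OLS with backward checks: enter the
smallest partial-F p-value below 0.05, then remove any term above 0.10.
These thresholds are the common defaults; the source workflow reports only
"P < 0.05" significance. Two numerical guards matter: a perfectly collinear
candidate produces no RSS reduction and never enters, and selection stops
when the fit is numerically saturated (RSS below 1e-12 of the total), so a
noiseless generating model is recovered with exact coefficients rather than
having later noise terms admitted on floating-point residue. One property
of this procedure should be understood when reading null behaviour: with
three independent null covariates and per-step entry at 0.05, the final
model is empty with probability ≈ 0.95³ ≈ 0.86, not 0.95 — the
acceptance suite measures exactly this.

# The synthetic generators

The genotype generator is Balding–Nichols: ancestral frequencies uniform on
(0.05, 0.95); each population's frequency Beta-distributed with divergence
parameter F (so the expected Weir–Cockerham Fst equals F); diploid dosages
binomial; missingness i.i.d. The truth record stores every realised
frequency, so the model-predicted Fst (`true_fst`, the large-sample limit
of the estimator: `Σs² / Σ(p̄(1−p̄) + s²/r)`) can be computed without
re-simulation. Balding–Nichols was chosen over coalescent simulation
because it gives closed-form control of the target Fst at trivial cost; the
price is that sites are unlinked, which is why LD demonstrations use the
separate copula generator described above.

Sweep injection modifies frequencies, not haplotypes: inside a sweep
interval the swept population's frequency is redrawn at an elevated local
divergence and then pushed to the nearest fixation with the probability
that makes the expected within-population heterozygosity, relative to that
population's own background, exactly `1/factor` — the compensation for the
diversity already removed by the local redraw is what makes the stated
reduction factor the realised one. Frequency-level injection is sufficient
because every statistic in the scan is frequency-based.

The landmark generator adds group shape offsets and isotropic Gaussian
noise to a template (an elongated ellipse; any non-degenerate template can
be supplied), scales each specimen to a true CS drawn from a linear model
on its site's latitude and altitude, and applies nuisance rotation,
translation and image scale; the image scale is recorded as the TPS
`SCALE=` calibration, exactly as digitising software does, so reading the
file recovers calibrated units and the true CS.

What passing these tests does *not* show about real data: no linkage or
recombination structure in the sweep scan's background (real window
statistics are autocorrelated, so real false-positive rates differ), no
genotyping-error model beyond missingness, no allometry or measurement
operator variance in the landmark model, and Beta-distributed frequencies
rather than a demographic history. The simulators validate the estimators
and the selection machinery, not the biology.

# Problem sizes and reproducibility

Default study conditions, chosen once as realistic desk-scale analogues of
a resequencing cohort: 2–5 populations of 20 diploids, 5000 SNPs on a 2-Mb
chromosome, background F = 0.05 with one 100-kb sweep (diversity ×10
reduction, local F = 0.6); five wing-sampling regions at two sites each,
five specimens per site, landmark noise sd 0.01 on a unit-size shape,
centroid-size slopes 0.02 per degree latitude and 2×10⁻⁴ per metre
altitude. Sweep operating characteristics are averaged over 20 replicates.
Every generator is a pure function of its spec (which includes the seed);
`analysis/01_simulate.R` through `analysis/04_morphometrics.R` rerun the
whole workflow from these conditions, and `scripts/acceptance.R --seed N`
recomputes the headline quantities from scratch.

# Known limitations

* Fst windowing follows the ratio-of-sums convention only; Hudson-style or
  haplotype-based estimators are not provided.
* LD is composite genotype r²; phased r² and D' are out of scope.
* The sweep scan ranks marginal quantiles; no joint density or FDR model.
* GPA assumes 2-D landmarks and no missing landmarks.
* The stepwise procedure is the classical p-value heuristic, provided for
  fidelity to the workflow it mirrors — not a model-selection
  recommendation; its null behaviour is quantified above.
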