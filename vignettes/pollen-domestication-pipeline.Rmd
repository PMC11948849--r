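---
title: "Methods: from pollen images to selection inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pollen images to selection inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryepollen)
```

This vignette documents the models behind each stage of the pipeline, the
parameters that matter, and the design decisions taken where more than one
defensible choice existed. The running example is a domestication study in a
wind-pollinated outcrossing crop (rye is the motivating system): a
"domesticated" and a "feral" subpopulation are contrasted genomically and
phenotypically, and pollen/anther morphology is the trait family of
interest.

## The synthetic-data generator

All validation rests on `sim_config()` + `simulate_*()`, so the generative
model is documented first.

**Genotypes.** Ancestral allele frequencies are uniform on [0.05, 0.95];
each population's frequency is Beta-distributed around the ancestral one
with variance `drift_F * p * (1 - p)` — the Balding–Nichols model. This is
the simplest drift model whose expected Weir–Cockerham theta equals the
differentiation parameter, which gives the F_ST machinery an analytic
oracle: simulating at `drift_F = 0.05` must return a genome-wide estimate
near 0.05. Genotypes are binomial(2, p), read depths Poisson (default mean
19, a realistic reduced-representation coverage), missingness Bernoulli
(default 2%). Selective sweeps are planted deterministically: within
±1 Mb of a sweep position, the domesticated-population frequency is pushed
toward fixation by `strength * (1 - d / 1 Mb)`. This produces localized
differentiation, diversity loss and XP-CLR signal with the ±5 Mb screening
geometry of the analysis, without coalescent machinery; it does not emulate
haplotype structure, so haplotype-based statistics are out of scope.
Tetraploids are emulated solely through a doubled heterozygote probability
(capped at 1) with diploid-coded calls, because the ploidy classifier uses
heterozygosity proportion alone.

**Phenotypes.** `y = X beta + shift + e` with `n_qtl` causal SNPs (default
100, a polygenic architecture of small effects), standard-normal effects,
and the noise variance scaled so the realized additive fraction equals the
target `h2`. The domesticated group can be shifted by `group_shift_sd`
phenotypic SDs to emulate directional selection on the trait. Effects are
scaled against the realized genetic variance, so the target h2 is met in
expectation over the noise draw only — heritability-recovery checks
therefore average over seeds.

**Particle tables.** Fertile particles carry features drawn strictly inside
every gate; each contaminant class violates exactly one designated gate
step and is otherwise in range (aborted → median pixel; stacked →
symmetry 3; debris → diameter; blurred → gradient RMS). This construction
makes gate fidelity exactly testable (precision = recall = 1 by design),
which is also its limitation: real contaminants violate gates continuously
and jointly, so passing these tests shows the cascade implements its rules
correctly, not that the published gate values are optimal for any
instrument. Per-individual mean pollen length is uniform on 39–57 µm
(the span observed across a diverse panel), elongatedness uniform on
~1.0–1.3, and the four fluorescence channels are correlated log-normals
(pairwise r ≈ 0.9) — a phenomenological choice; no biochemical realism is
claimed for fluorescence.

Determinism: every generator seeds the global RNG from `seed` plus a fixed
per-component offset, so identical configs give byte-identical outputs and
the three generators can be used independently.

## MIFC gating

Gates are applied in a fixed cascade order (diameter; brightfield +
median pixel; symmetry 3 + 4; correlation mean + gradient RMS), each range
a **closed** interval — the boundary semantics follow typical cytometry
region tools, and a particle with diameter exactly 20 µm passes.
Individuals need ≥ 50 retained particles; the 1%/99% pollen-length trim is
computed on the **pooled** retained particles with linear-interpolation
quantiles (R type 7). Whether the trim should be pooled or per-individual
is genuinely ambiguous in practice; pooled is the default and
`gate_config(trim_scope = "per_individual")` switches the alternative.
Particles exactly at a trim quantile are kept (strictly-outside removal),
so `trim_quantiles = c(0, 1)` removes nothing. The instrument's acquisition
stop rule (5000 particles or 6 minutes) is an acquisition property, not an
analysis step, and is deliberately not modelled. Anther length enters as a
tabular input (six anthers from one flower per individual is the intended
design; other counts trigger a warning, not an error).

## Variant QC

Filter order matters and is fixed: per-genotype depth masking first, then
biallelic/indel restriction, then the site callrate floor, then the MAF
floor computed on the remaining calls. Masking before the callrate filter
means a site can be lost purely through low-depth genotypes — the semantics
of applying per-genotype `minDP` and per-site `max-missing` in one
VCFtools invocation. The two presets (`qc_preset("gwas")`:
minDP 4 / callrate 0.9 / MAF 0.05; `qc_preset("popgen")`: minDP 10 /
maxDP 100 / callrate 0.7 / MAF 0.01) encode the two chains used for
association scans and population-genomic statistics respectively.
Filtering is idempotent, and per-rule removal counts sum to the site
deficit. Ploidy classification assigns each individual the ploidy of the
nearest reference-class mean heterozygosity; an exact midpoint breaks
toward the lower ploidy (the conservative call). LD decay uses squared
Pearson correlation of dosages on pairwise-complete observations for
intra-chromosomal pairs at 1–20 Mb; under independence the expected r² is
the 1/(n−1) small-sample floor, which the tests assert.

## Population structure

The genetic covariance standardizes genotypes per site by `2p` and
`sqrt(2p(1-p))` and sets missing values to zero **after** centering —
mean imputation, unbiased under missingness at random and the common
choice of genotype-PCA tools. Monomorphic sites are an error (with advice
to MAF-filter), never silently skipped. Eigendecomposition is exact for
these matrix sizes; each component is oriented so its largest-magnitude
loading is positive, making outputs deterministic up to machine precision.

## Heritability and association scans

`compute_grm()` is the GCTA-style GRM. `reml_h2()` fits the one-component
model by average-information REML with an EM fallback: an AI proposal is
clamped to the parameter floor and accepted only if the restricted
likelihood does not decrease; otherwise an EM step (guaranteed ascent) is
taken. Convergence is a relative log-likelihood change below 1e-6, capped
at 100 iterations with the trajectory reported on failure. The h² standard
error comes from the inverse AI matrix via the delta method. A GRM
numerically proportional to the identity makes σ²_g and σ²_e
non-separable and is rejected explicitly. The whole fit operates in the
GRM eigenbasis, which makes each iteration O(n) after one
eigendecomposition.

`farmcpu_scan()` follows the fixed/random two-model loop: a vectorized
per-marker least-squares test (iteration 0), then pseudo-QTL candidates —
the most significant SNP per 10 Mb bin among those with p < 1e-4 — screened
by maximizing the restricted likelihood of `y = kinship + e` with kinship
built from the top-k candidates, then re-testing all SNPs with the selected
pseudo-QTLs as fixed covariates, excluding any pseudo-QTL in the tested
SNP's own bin. Bin size and candidacy threshold are configurable; 10 Mb
and 1e-4 are defaults chosen for sparse reduced-representation marker maps
(~100 SNPs/10 Mb here). This is deliberately *FarmCPU-style*, not a
re-implementation of any specific package's internals (no bin-size ladder,
no SUPER kinship): the reproducible contribution is the loop plus the
validation wrappers. Significance is Bonferroni at 0.05/m; PVE is defined
as the R² increment of adding the SNP to the final covariate model (no
standard formula exists for this quantity; the definition is recorded here
as the package's convention). Covariates default to none; principal
components can be passed explicitly. One known property of this class of
methods: conditioning on true pseudo-QTLs shrinks residual variance and
can push a marginally-associated null SNP past the threshold. The
permutation wrapper shows the experiment-wise error stays at the nominal
level; the subsampling wrapper reports per-marker detection rates so such
SNPs are visible rather than hidden.

`subsample_detection_rate()` (default 95% of individuals, seeded runs) and
`permutation_null()` implement the two validation procedures; a permuted
constant phenotype cannot be significant by construction and is counted as
a clean run.

## Selection scans

All four statistics share one window tiling: 1 Mb windows, 250 Kb overlap
read literally (step 750 Kb), tiled from position 1, last window
truncated. Weir–Cockerham per-site components keep their sign (no negative
clipping) and windows aggregate as ratio of sums; sites where the
estimator is undefined (no called genotypes in a group, or a monomorphic
pooled sample without heterozygotes) are skipped. Per-site π uses the
n/(n−1) unbiasedness correction and windows divide by window length in bp;
DRI windows with zero domesticated diversity are flagged undefined and
excluded from percentile ranking rather than becoming infinities.

XP-CLR follows the composite-likelihood idea of the cross-population scan:
the object-population frequency given the reference frequency is truncated
normal with variance `omega * p(1-p)`, `omega` estimated genome-wide by
method of moments; under a sweep at the window centre an allele at genetic
distance r·d escapes with probability `1 - exp(-r d / s)`, otherwise it
hitchhikes to fixation of one allele (a mixture with mass split p and
1−p between the two fixed states, smoothed by the same drift kernel). The
window score is twice the likelihood gain over s = 0, profiled over a grid
{0, 1e-4, 1e-3, 1e-2, 1e-1} with a uniform 1 cM/Mb map (no genetic map is
assumed available). Scores are therefore comparable within a run — which
is all percentile-based outlier calling needs — but not across runs or
against other XP-CLR implementations, whose normalizations differ.

Significance for each statistic is "strictly above the genome-wide 95th
percentile", requiring ≥ 20 SNP-containing windows for a stable
percentile; Z(F_ST) is computed over windows (not sites). QTL screening
asks whether any flagged window overlaps ±5 Mb of the QTL, per statistic,
and reports the fraction of QTL with at least one signature.

## P_ST–F_ST

Variance components come from the one-way ANOVA mean squares with the
standard unbalanced-design coefficient n0; a negative between-group
component is truncated to zero and flagged. P_ST applies the closed form
`csh σ²_b / (csh σ²_b + 2 σ²_w)`; `csh = 1` is the default on the
common-garden argument that the between-population additive proportion c
and the within-population h² cancel. The bootstrap resamples
**individuals within groups** (the resampling unit is a recorded choice;
residual resampling would understate group-mean uncertainty), uses the
percentile interval (no BCa correction), takes the point estimate from the
unresampled data, and redraws degenerate resamples in which a group
collapses to a constant. The verdict compares the interval to genome-wide
F_ST computed on the same two groups: `selection` when the lower bound
exceeds it, `drift` when the interval contains it, `inconclusive`
(flagged, unexpected) when even the upper bound is below it.

## Pollen dispersal

Stokes' law with defaults g = 9.81 m/s², ρ_m = 1.225 kg/m³,
µ = 1.78e-5 Pa·s, ρ_p = 988 kg/m³ (0.988 g/cm³ converted once to SI),
ū = 3 m/s. The viscosity is dimensionally Pa·s = kg m⁻¹ s⁻¹ — source
texts sometimes misprint this unit string, but the numeric value is the
standard air viscosity near 15 °C and is used as such. `d` is a diameter
in metres, as Stokes' law requires; callers holding pollen *length* for
elongated grains must decide on an effective diameter explicitly — no
silent conversion is performed. The model is valid in the Stokes regime
only (no Reynolds correction, no turbulence or plume dispersal): for a
40 µm grain, V_set ≈ 0.048 m/s and a 1.5 m release travels ≈ 93 m; the
quadratic diameter dependence means D(40 µm)/D(55 µm) = (55/40)² ≈ 1.89
at any height, which is why modest pollen-size changes have ecologically
large dispersal consequences.

```{r dispersal}
settling_velocity(40e-6)
dispersal_distance(40e-6, dispersal_params(h_r = 1.5))
round(distance_grid(c(40, 47, 55) * 1e-6, c(0.5, 1, 1.5)), 1)
```

## Validation problem sizes

The test suite and `scripts/acceptance.R` run everything at sizes chosen to
make Monte-Carlo error small relative to the asserted bands while staying
desk-scale: F_ST calibration at 2 × 50 individuals × 2000 SNPs;
heritability recovery at n = 400, m = 2000, 10 seeds (mean estimate within
0.8 ± 0.1); sweep detection at 2 × 30 × 4000 SNPs on two 20 Mb
chromosomes, 10 seeds; GWAS validation with 100 subsample and 200
permutation runs; P_ST–F_ST verdicts over 10–20 seeds with 1000 bootstrap
replicates. Passing these shows the machinery is correct under the
generator's assumptions (unlinked biallelic sites, Balding–Nichols drift,
Gaussian polygenic traits, gate-respecting particle features); it does not
by itself validate the biological conclusions on any real panel.

## Known limitations

* No coalescent or recombination-explicit simulation; LD exists only
  through population structure, so LD-decay curves on synthetic data are
  flat rather than distance-decaying.
* XP-CLR scores are run-internal quantities; only their ranks are used.
* Single-trait, single-component REML; no dominance or epistasis.
* FCS binary ingestion is out of scope; particle features arrive as
  tables.
* The dispersal model is deterministic ballistics — a first-order tool for
  "how far can grains of this size travel", not a dispersal-kernel fit.
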