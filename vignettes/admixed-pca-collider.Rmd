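---
title: "PC adjustment, pre-processing, and collider bias in admixed-population GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PC adjustment, pre-processing, and collider bias in admixed-population GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixpca)
```

## The problem

Genome-wide association studies in admixed populations (for example African
Americans, whose genomes mix African and European ancestral segments) must
adjust for *global ancestry* — the genome-wide fraction $\pi_i$ of each
individual's genome inherited from one ancestral population. Heterogeneous
$\pi$ confounds associations whenever a tested variant differs in frequency
between the ancestral populations and ancestry is also connected to the
trait. The standard fix is to include top principal components (PCs) of the
genotype matrix as covariates, on the premise that they proxy for $\pi$.

That premise can fail. Beyond the first PC, components often capture *local
genomic features* — small regions of strong, long-range, or otherwise
atypical linkage disequilibrium (LD), such as inversions — rather than
genome-wide ancestry. In admixed cohorts a single such PC frequently loads
on *several* regions on *different* chromosomes. Including such a PC in the
association model makes it a **collider**: if the PC is correlated with the
causal variant and with an unlinked variant elsewhere, conditioning on it
manufactures an association between the trait and the unlinked variant.
This package implements the full study of that phenomenon: a synthetic
admixed-cohort generator, the pre-PCA filtering protocols and PC
diagnostics, a marginal-regression GWAS engine with a chromosome-level
spurious-association statistic, and an analytic module that computes the
expected effect-size estimate under each adjustment strategy.

## Generating model

Traits are generated from a single causal variant plus an optional direct
ancestry effect:

$$y_i = \beta_1 g_{i1} + \beta_\pi \pi_i + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, 1),$$

where $g_{i1} \in \{0,1,2\}$ is the causal dosage. Genotypes arise from a
two-population admixture model: each of the two allele copies at variant
$j$ descends from ancestral population 1 with probability $\pi_i$ and then
carries the allele with that population's frequency ($p_{j1}$, else
$p_{j0}$). Association models are marginal regressions

$$E[y_i \mid g_{ij}, w_i] = \alpha + \beta_j g_{ij} + \gamma^T w_i,$$

fit at every variant with a Wald test of $\beta_j = 0$ against the
standard normal, with covariates $w_i$ one of: nothing, $\hat\pi_i$, the
first $k$ PC scores, or $[\pi_i, z_i]$ with $z$ an extraneous component.

## The synthetic cohort generator

No real genotypes ship with the package (the motivating cohorts are
controlled-access), so the generator reproduces the *statistical structure*
the analysis depends on, not any particular dataset:

* **Admixture proportions** are Beta-distributed, parameterized by mean
  and sd; defaults 0.8 / 0.1 emulate the wide ancestry heterogeneity seen
  in African-American cohorts.
* **Local ancestry** comes in two modes. `independent` draws each copy's
  ancestry independently across variants — sufficient for every moment
  -level result, since all derivations condition only on $\pi$. `block`
  adds realism: per haplotype and chromosome, crossovers form a Poisson
  process at `generations` per Morgan on a uniform 1 cM/Mb map (no
  interference), and each segment's ancestry is Bernoulli($\pi_i$). Both
  modes satisfy $E[a_{ij}] = 2\pi_i$.
* **Ancestral allele frequencies** follow a Balding–Nichols model. The
  default differentiation (`fst = 0.35`) is deliberately higher than the
  genome-wide African/European value ($\approx 0.15$): a desk-scale panel
  has thousands of variants where an array has hundreds of thousands, and
  the ancestry information available to PCA scales with both. The default
  is calibrated so the clean desk-scale cohort reproduces the empirical
  regime of real admixed cohorts — $|\mathrm{cor}(PC_1, \pi)| > 0.99$ —
  rather than an artifact of the reduced variant count.
* **Localized LD features** are latent diploid factors: inside the
  feature's regions, each variant's genotype is replaced by the latent
  dosage with probability `coupling`. Latent alleles have their own
  ancestral frequencies, so a feature can be ancestry-informative or (the
  default) ancestry-neutral pure local structure. Feature regions may be
  locally densified in the panel, mirroring the fact that real high-LD
  regions contain many mutually correlated variants.

`simulate_feature_cohort()` is the canonical contaminated scenario: three
*independent* 0.4-Mb features on chromosomes 2, 6, 9 — two inside bundled
high-LD regions, one not. Independence matters: the three region factors
have nearly equal variance, so their eigenvalues are close to degenerate
and the eigenvectors mix regions, which is exactly the multi-peak loading
pattern that creates colliders. (A single latent shared across regions
would instead create genuine cross-chromosome LD, and a hit at the partner
region would not be spurious.)

What the generator does **not** emulate: coalescent haplotype structure,
realistic recombination maps, background LD decay between neighbouring
variants, more than two ancestral populations, phased data. Tests passing
on these cohorts therefore validate the *mechanisms* (confounding,
collider bias, the effect of pruning on feature eigenvalues), not absolute
spurious-association counts on any real dataset.

## Pre-processing regimes

Four regimes precede PCA, composed in the fixed order MAF filter →
region exclusion → LD pruning:

* a minor-allele-frequency filter (default 0.01) in every regime;
* `exclude`: removal of the bundled list of 18 regions with high,
  long-range, or unusual LD (build 38; 1-based closed intervals; includes
  LCT, HLA, and the 8p23 and 17q21 inversions);
* `prune`: deterministic greedy windowed pruning — a forward pass in
  position order drops a candidate iff its dosage $r^2$ with any retained
  same-chromosome variant within the window exceeds the threshold.
  Defaults $r^2 = 0.1$ and 0.5 Mb: stricter than the common 0.2, which is
  what admixed cohorts typically need. The post-condition (no retained
  within-window pair above the threshold) is exhaustively testable.
* `both`: exclusion then pruning.

Design choices the data formats left open: region intervals are treated as
1-based closed (matching how physical positions are printed; BED export
performs the 0-based half-open shift), $r^2$ is computed on unphased
dosages (composite LD), the window is physical distance anchored at the
candidate, and ties go to the earlier-position variant so the pass is
deterministic.

Why pruning works here is worth stating precisely: a feature with $q$
coupled variants contributes an eigenvalue of roughly $q \bar r^2 n/m$ to
the GRM $XX^\top/m$, against a Marchenko–Pastur noise bulk of
$(1+\sqrt{n/m})^2$. Exclusion deletes listed regions but leaves unlisted
features untouched; pruning thins *every* dense correlated set to about
one variant per window, pushing $q$ below the bulk so no PC can form on
the feature. This is also why the cohort's feature regions must be
densified for the phenomenon to exist at desk scale at all.

## PCA and diagnostics

PCA is the SVD of the standardized genotype matrix,
$x_{ij} = (g_{ij} - 2\hat p_j)/\sqrt{2\hat p_j(1-\hat p_j)}$, computed via
the $n \times n$ eigendecomposition of $XX^\top/m$ when variants outnumber
individuals. Eigenvalues are reported on the $XX^\top/m$ scale (free of
the variant count); each PC's sign is fixed so its largest-magnitude score
is positive, making outputs reproducible. Loadings are reported both as
$V$ columns and — the diagnostic of record — as the per-variant
correlation $|r|$ between PC scores and dosages.

`flag_local_feature_pcs()` operationalizes the visual inspection of
loading plots: a PC is flagged iff its peak $|r|$ over variants is at
least $\tau = 0.3$ *and* its ancestry correlation is below $\rho = 0.5$.
The thresholds are package choices (the original inspection was visual):
an ancestry PC at desk scale tops out near $|r| \approx \sqrt{2 F
V_\pi \cdot n}$-driven values around 0.3–0.45 while feature PCs sit at
$\sqrt{\bar r^2} \approx 0.8$, and ancestry correlations separate cleanly
(> 0.99 vs < 0.1), so the defaults sit in wide margins on both axes.

## Expected effect sizes and the bias algebra

`expected_coefficients()` computes the large-sample expectation of
$\hat\beta$ for any adjustment and either target variant by solving the
population normal equations built from exact model moments:
$E[g_k] = 2(p_{k0} + d_k\mu)$ with $d_k = p_{k1} - p_{k0}$,
$\mathrm{Var}(g_k)$ by total variance over $\pi$,
$\mathrm{Cov}(g_k,\pi) = 2 d_k V_\pi$, and — because variants on distinct
chromosomes are independent given $\pi$ —
$\mathrm{Cov}(g_1,g_2) = 4 d_1 d_2 V_\pi$. The extraneous component is
modeled as $z = w_1\,\mathrm{std}(g_1) + w_2\,\mathrm{std}(g_2) + e$,
matching the GWAS engine's construction, so theory and simulation test the
same object. Higher moments of $\pi$ (needed for $\mathrm{Var}(g)$) come
from the Beta assumption. This moment-equation route is exact under the
generating model and is cross-checked two ways: re-derived closed forms
for the unadjusted cases, and a Monte-Carlo OLS oracle
(`simulate_ols_means()`) over thousands of replicates.

The qualitative logic it reproduces:

* **Unadjusted, causal variant**: bias $\beta_\pi \cdot 2 d_1 V_\pi /
  \mathrm{Var}(g_1)$ — zero iff $V_\pi = 0$, $\beta_\pi = 0$, or $d_1 = 0$.
* **Unadjusted, neutral variant**: bias $2 d_2 V_\pi (2\beta_1 d_1 +
  \beta_\pi)/\mathrm{Var}(g_2)$ — confounding *even with*
  $\beta_\pi = 0$, provided both variants are ancestry-differentiated;
  increasing in $V_\pi$.
* **$\pi$-adjusted** (or the idealized ancestry PC): exactly unbiased at
  both variants.
* **$[\pi, z]$-adjusted, causal variant**: still unbiased.
* **$[\pi, z]$-adjusted, neutral variant**: collider bias, exactly linear
  in $\beta_1$, increasing in the coupling weights, zero iff $\beta_1 = 0$
  or either conditional covariance $\mathrm{Cov}(g_k, z \mid \pi)$
  vanishes.

One deliberate deviation from a natural reading of the collider
conditions: under this fixed-weight $z$ construction the collider bias
does *not* vanish as $V_\pi \to 0$, and is in fact weakly decreasing in
$V_\pi$ (the $\pi$ covariate absorbs part of $z$). Ancestral heterogeneity
governs the *confounding* pathway and, in real data, the strength of the
PC–variant correlations themselves; with $z$'s coupling held fixed it is
not an additional dial on the collider pathway.
`bias_magnitude_surface()` therefore reports both pathways, and the
zero-bias condition list for the extraneous model contains $\beta_1 = 0$
and the two decoupling conditions, not $V_\pi = 0$.

Two modelling idealizations are worth naming. The `pcs` adjustment is
treated in theory (and in the simulation oracle) as the idealized
global-ancestry PC — an affine transform of $\pi$, hence identical
expected coefficients to the $\pi$ adjustment; PC1 estimated from a
genome-wide panel correlates with $\pi$ above 0.99, so the idealization is
accurate and avoids a full PCA inside every oracle replicate. And $z$
standardizes genotypes by population moments in theory but sample moments
in simulation; the difference is $O_p(n^{-1/2})$ and invisible at the
oracle's scale.

## Replicate experiment designs

`run_array_design()` mirrors the array-style design: one cohort, PCs per
regime, fresh trait noise per replicate with the genotype realization held
fixed, strategies {none, $\hat\pi$, $k$ PCs per regime}, effect sizes
swept over a grid (default $\{0, 0.25, 0.5, 1, 2, 4, 8\}$), spurious
associations counted as the number of chromosomes other than the causal
one carrying at least one variant past the threshold (chromosome-level,
because neighbouring variants in LD hit together; strict inequality at the
boundary). Causal variants can be stratified by loading and ancestral
frequency difference (`select_causal_variants()`, cutoffs
$|p_1 - p_0| > 0.6$ and $< 0.005$; the low-loading cutoff defaults to
$|r| < 0.05$, a desk-scale re-expression of "negligible loading" —
absolute loading values depend on the variant count, so the array-scale
figure does not transfer). `run_sequence_design()` mirrors the
sequence-style design: covariates $[\pi]$ versus $[\pi, z]$ at the
sequence-scale threshold $5 \times 10^{-9}$, recording per replicate the
spurious count, whether the partner variant's chromosome fires, and the
genomic-control $\lambda = \mathrm{median}(W^2)/\mathrm{qchisq}(0.5, 1)$.
The reported summaries average per-replicate chromosome counts; mean
counts are also emitted per causal variant so either reduction (average
within stratum before or after replicates) can be formed.

Desk-scale defaults — $n$ in the hundreds to 2000, $m \approx$ 2000–5000
variants over 10 synthetic chromosomes, tens to hundreds of trait
replicates — are chosen so the full suite and the acceptance script
re-run comfortably on a single CPU. Absolute spurious counts at these
sizes are not comparable to an 8000-sample, 551k-variant study; orderings
among strategies, calibration under the null, and the theory–simulation
agreement are the reproducible contract.

## Numerical and interface choices

* Wald statistics use the standard normal (large-sample) reference, not a
  $t$; standard errors are classical homoskedastic OLS, matching the
  unit-variance generating model.
* The genome scan residualizes trait and dosages on $[1, w]$
  (Frisch–Waugh), which reproduces the per-variant OLS fit exactly and is
  verified against it; variants collinear with covariates are reported
  with missing statistics rather than dropped, keeping per-chromosome
  bookkeeping stable. Monomorphic variants must be filtered before
  standardization or pruning, and the errors say so.
* Degenerate theory inputs ($V_\pi = 0$, zero-variance $z$) drop the
  degenerate covariate rather than failing, so limits behave continuously.
* All randomness flows from one seed through `child_seed()` streams;
  every simulating function also accepts `seed = NULL` to join the
  caller's RNG stream.
* Chromosome labels are normalized (`"chr6"` ≡ `"6"`) before any
  region or chromosome comparison.
* Cohorts round-trip through a minimal VCFv4.2 (unphased GT, single ALT,
  placeholder alleles) plus tab-separated sidecars; parsing uses vcfR.

## Known limitations

The generator's independence of variants given $\pi$ (outside injected
features) means background LD is absent, so pruning removes almost nothing
on clean cohorts — real panels lose > 90% of variants. Feature PCs at desk
scale need locally densified regions; with array-density panels they would
not. The theory module covers one causal variant and one neutral variant;
polygenic architectures aggregate these effects but are not modelled.
$\lambda$ insensitivity is demonstrated for localized contamination; broad
stratification would inflate $\lambda$ as usual.
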