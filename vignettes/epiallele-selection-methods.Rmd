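---
title: "Methods: epiallele frequency spectra and selection on gene body methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epiallele frequency spectra and selection on gene body methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `episfs`, the
assumptions it rests on, the decisions taken where the design was genuinely
open, and the numerical choices that make the likelihood usable at sample
sizes in the hundreds. It is the package's authoritative account of *why*
the code does what it does; the README shows *how* to run it.

## 1. The biological setting

Gene body methylation (gbM) is CG-context methylation confined to coding
sequence, heritable through mitosis and meiosis, and gained or lost at
rates orders of magnitude above DNA point-mutation rates. Treating the
methylation state of a gene in an accession as an allele — an *epiallele* —
opens the standard population-genetic toolbox: across a panel of natural
accessions, the frequency distribution of the unmethylated (UM) state over
genes is an unfolded site-frequency spectrum (SFS), and its shape carries
information about epimutation rates and selection.

The pipeline has four stages, each exposed as plain functions:

1. **Cytosine calling** (`call_sites`): one-sided binomial test of the
   methylated read count against the bisulfite no-conversion rate,
   Benjamini–Hochberg corrected per accession; corrected p < 0.001 calls a
   site methylated; sites with ≤ 2 reads are unmethylated by fiat.
2. **Gene classification** (`classify_genes`): per accession, per-context
   binomial enrichment of a gene's CDS cytosines against the genome-wide
   CDS background, BH-corrected across genes; decision rules yield
   gbM / UM / mCHG / mCHH / undetermined.
3. **Spectrum construction** (`build_gene_sfs`, `build_cytosine_sfs`):
   hypergeometric projection to a common sample size `n′`, with filters
   against TE-like genes.
4. **Selection inference** (`run_mcmc`): MCMC fit of the stationary
   sampling distribution; the population-scaled selection coefficient
   `γ = 4Ne·s` is the quantity of interest.

## 2. The stationary sampling distribution

The model assumes a randomly mating diploid population of constant
effective size `Ne` at mutation–selection–drift equilibrium, semi-dominant
alleles, and independence among genes. Epimutation is reversible: UM → gbM
at rate μ, gbM → UM at rate ν. With `α = 4Ne·μ`, `β = 4Ne·ν` and genic
selection `γ = 4Ne·s` for the UM state, the stationary density of the UM
frequency `x` is Wright's

$$\phi(x) \propto e^{\gamma x}\, x^{\beta-1} (1-x)^{\alpha-1},$$

and binomial sampling of `n` gene copies gives the probability that `k` are
UM:

$$p_k = \binom{n}{k}
  \frac{{}_1F_1(\beta+k,\; \alpha+\beta+n,\; \gamma)\,
        (\beta)_k\, (\alpha)_{n-k}}
       {{}_1F_1(\beta,\; \alpha+\beta,\; \gamma)\, (\alpha+\beta)_n}.$$

At `γ = 0` the ₁F₁ factors are 1 and `p_k` is beta-binomial — a limit the
tests exploit as an exact oracle. When the gbM state is the favored one,
α and β exchange roles; on the UM-count axis this is the reflection
`p(k; α, β, γ) = p(n−k; β, α, −γ)`, which is how `sfs_log_likelihood`
implements the `gbM_advantage` orientation without a second code path.

The likelihood of a projected spectrum `d` is `∑_k d_k log p_k`, including
the fixed classes `k = 0` and `k = n′`. Projected `d_k` are real-valued and
are used as such (no rounding): they are expected counts, and the
likelihood is linear in them.

### Numerical evaluation

Naively composing `choose`, `gamma` and ₁F₁ overflows far below `n = 600`.
`episfs` instead expands the Kummer integral of the numerator as a
Poisson-weighted mixture of beta functions,

$$\int_0^1 x^{\beta+k-1}(1-x)^{\alpha+n-k-1} e^{\gamma x}\,dx
  = \sum_{j\ge 0} \frac{\gamma^j}{j!}\, B(\beta+k+j,\; \alpha+n-k),$$

evaluated entirely in log space with a log-sum-exp over `j`. Negative γ is
routed through the reflection identity so the expansion only ever sees
γ ≥ 0, keeping every term positive (no cancellation). The series is
truncated at `j ≤ γ + 10√(γ+1) + 25`; the summand is log-concave in `j`
with mode near γ, so this window overshoots the point where terms are
~40 nats below the maximum. The whole vector `p_0..p_n` is produced in one
`(n+1) × J` matrix operation, which is what makes a 100,000-generation MCMC
affordable in pure R (about 0.8 ms per likelihood at `n′ = 100`).

Accuracy is verified in the test suite against an independent quadrature
oracle — `E[e^{γx}]` under the relevant beta distributions via the
inverse-CDF substitution `∫ exp(γ·qbeta(u)) du`, which is bounded and
smooth — to 10⁻⁸ relative error over a grid spanning `α, β ∈ [10⁻³, 10]`,
`γ ∈ [−10, 10]`, `n ≤ 600`, and normalization is checked to 10⁻⁹. The
representation remains finite for |γ| in the thousands, so no
arbitrary-precision fallback is needed anywhere in the supported domain;
out-of-domain inputs raise an explicit error rather than returning
nonsense.

## 3. MCMC design

The fit targets `log μ, log ν, log s` with a random-walk Metropolis
sampler. Choices the method description leaves open, and what the package
does:

* **Priors.** None are stated for the original fit; `episfs` uses
  log-uniform priors with hard bounds `[10⁻¹², 10⁻³]` per rate — scale
  invariant, and generous around the reported 10⁻⁸–10⁻⁶ estimates. The
  bounds act as rejection barriers.
* **Proposal.** Independent Gaussian steps on the log scale, one parameter
  per generation in rotation. The per-parameter scales λ are tuned by
  Robbins–Monro toward 40% acceptance *during burn-in only* and frozen
  afterwards, so the post-burn-in chain is a valid fixed-kernel sampler;
  the original tuned λ by hand to land acceptance in (20%, 70%), and the
  summary flags any parameter outside that interval.
* **Defaults.** 100,000 generations, 25% burn-in, thinning 100 (≈ 750
  posterior samples), three chains from random starting points drawn
  log-uniformly on `[10⁻⁹, 10⁻⁵]`. Posterior means and 95% credible
  intervals (2.5/97.5 percentiles) are computed on pooled post-burn-in
  samples; per-chain means are kept as a dispersion diagnostic.
* **Ne is fixed**, not estimated: it comes from Watterson's θ
  (`watterson_theta`, using the 2-chromosomes-per-diploid convention,
  which reproduces the published θ = 0.00955 where the haploid convention
  does not) and a per-base mutation rate (`ne_from_theta`). `γ = 4Ne·s` is
  a derived statistic of the chain, never a free parameter.
* **Verdict rule** (`significance_verdict`): selection is called when both
  the posterior mean of γ and the lower credible bound exceed 1; "no
  selection" when mean and upper bound are below 1; anything straddling 1
  is nonsignificant.
* **Guard rails.** 1,000 consecutive rejections abort with a
  proposal-scale diagnostic rather than silently freezing the chain.

A stationarity caveat: both selection orientations are fitted
(`fit_both_orientations`) and the one with the higher posterior-mean γ is
reported, mirroring how the published tables choose between `4Ne·s_UM` and
`4Ne·s_gbM`.

## 4. Classification and spectrum filters

Decisions where the method description is silent or ambiguous:

* **BH family for cytosine calls** = all sites of one accession with
  coverage ≥ 3. Sites at ≤ 2 reads are unmethylated by rule and excluded
  from the family (they were never tested); whether the original included
  them is unknown, and the choice only affects the correction denominator.
* **Gene-level test denominators** count only sites with coverage ≥ 3,
  consistent with the cytosine-level analysis; the classification
  thresholds are applied to *corrected* p-values by default
  (`use_corrected = FALSE` restores raw thresholding, since the original
  is not fully explicit).
* **Contexts absent from a gene** carry no evidence of enrichment (p = 1),
  so e.g. a gene without CHH sites can still be classified gbM; a context
  whose genome-wide background is undefined makes the gene undetermined.
* **mCHG does not require CG significance** — followed literally from the
  stated categorization.
* **The 70% mCHG/mCHH filter** needs a denominator; `episfs` uses
  accessions with any *determined* state (undetermined and missing cells
  are excluded). The SFS sample size `n` itself counts only UM + gbM
  accessions.
* **SFS orientation**: `k` counts UM copies for every spectrum, including
  "all genes" where ancestry is partly unknown; conditioning on ancestral
  state happens by subsetting genes, not by repolarizing the axis.
* **Ancestral states** other than gbM/UM shared by both outgroups map to
  `ambiguous` (they cannot polarize a gbM/UM spectrum); any absent
  replicate call maps to `missing`.
* **χ² pooling**: classes are cumulated along the k axis until each pooled
  cell reaches an expected count of 5 (a short final cell folds into its
  neighbour), df = cells − 1. The original states only that a Pearson test
  was used.
* **Median sign test ties** are dropped from both numerator and
  denominator (standard sign-test convention). The published 61.56%
  proportion implies a denominator that is not reconstructible from the
  stated gene counts, so the package reports counts and proportion
  explicitly rather than targeting that figure.
* **Contrast multiplicity**: the three adjacent-pair contrasts
  (gbM−UM, UM−mCHG, mCHG−mCHH) are Bonferroni-adjusted; the adjustment
  method behind the published "corrected" p-values is unnamed. Contrasts
  use asymptotic z tests (the published tables report z-ratios).

## 5. The synthetic-data generator

`simulate_state_matrix` draws each gene's UM count from the *same*
stationary pmf used for inference (per ancestral class, with class-specific
selection), assigns UM accessions at random, and overlays mCHG (2%), mCHH
(1%) and missing (5%) cells. `simulate_methylomes` expands states into
allc-style read counts: per-gene site counts uniform on 20–80 per context,
Poisson(20) coverage, truly methylated sites read at 0.95, truly
unmethylated sites at the 0.0041 no-conversion rate; within-gene CG
methylation probability is 0.85 for gbM epialleles and 0.05 (the CG
background) for UM. `simulate_expression` adds gene random intercepts
(SD 1 around log-mean 4) and state shifts chosen to reproduce the published
hierarchy (gbM−UM = 0.0563, UM−mCHG = 0.1093, mCHG−mCHH = 0.2275 log
units); default noise is negative binomial (size 10) — deliberately
heavier-tailed than the Gaussian-on-log fit model to test robustness — with
a `gaussian_log` option for exact-recovery tests. Values not stated
anywhere (site counts, within-gene methylation probabilities, coverage,
expression baselines, contamination/missingness rates, outgroup
discordance 2%) are fixed once at what a practitioner would call realistic
for leaf methylomes and are exposed in `simulation_config`.

What the generator deliberately does *not* emulate: linkage and population
structure (genes and accessions are exchangeable), selfing (the model
itself treats accessions as haploid samples), batch effects between
sequencing centers, C→T hypermutability of methylated cytosines, partial
within-gene methylation mosaics, and DMR-scale spatial structure.
Consequently, passing round-trip tests demonstrates the *statistical
machinery* is correct under the model's own assumptions — not that those
assumptions hold in any real panel.

## 6. Problem sizes and determinism

The test suite and the acceptance script scale the study design down to
what a laptop-class CPU finishes comfortably: parameter-recovery runs use
20,000 genes at `n′ = 100` with 25,000-generation chains; the end-to-end
pipeline uses 200 accessions × 2,000 genes at `n′ = 100`; permutation
calibration uses 50 accessions × 150 genes × 1,001 permutations. These
sizes were chosen as the package's own test design; the stationary pmf
itself is exercised at the full `n = 600`. Every stochastic function takes
an explicit seed, chains derive per-chain seeds from it, and the
per-accession methylome generator derives per-accession seeds so that any
chunking of accessions yields bit-identical output.

## 7. Known limitations

* `Ne` enters as a constant; uncertainty in θ and the mutation rate does
  not propagate into the credible interval of `s` (γ is unaffected, being
  estimated on its own scale).
* The equilibrium assumption is strong: a recent shift to selfing or a
  bottleneck distorts the SFS in ways the model will absorb into biased
  rate estimates rather than flag.
* Gene-level states discretize a quantitative phenotype; borderline genes
  oscillate between UM and undetermined across accessions, which inflates
  missingness rather than biasing `k`.
* The cytosine-level track inherits the gene-level ancestral polarization
  by design (individual-site ancestry is not conserved enough to polarize
  sites directly), so its spectra are conditional on gene ancestry, not
  site ancestry.
* The expression mixed model assumes homoscedastic Gaussian residuals on
  the log scale; the permutation calibration is the guard against
  miscalibration from that approximation.
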