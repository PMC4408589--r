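---
title: "Dense-marker local ancestry inference with aldmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense-marker local ancestry inference with aldmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aldmix)
```

## The problem

When two populations mix, each admixed genome is a mosaic of long chromosomal
segments inherited from the founding populations. The linkage disequilibrium
created by this mosaic (admixture LD) extends over tens of centimorgans and
decays with each generation of recombination, while the *ancestral* LD carried
inside the founding haplotypes rarely extends beyond a tenth of a centimorgan.
Local ancestry inference asks, for every position of every phased haplotype of
an admixed individual, which founding population that segment came from.
Admixture mapping (MALD) then tests local ancestry against a phenotype to
locate disease loci whose risk differs between the founding populations.

Dense SNP panels are informative but dangerous here: naive models that treat
markers as independent given ancestry mistake ancestral LD for admixture
signal, inflating divergence estimates and inventing ancestry switches. This
package models local ancestral LD *indirectly*, through principal components
of surrogate-panel haplotypes in fixed-width windows, which keeps the state
space small while still using every marker.

## The model

**Windows.** Each chromosome is tiled into fixed-width windows (default
0.1 cM), anchored at its first marker; empty windows are dropped. Working in
genetic rather than physical distance keeps the window's recombination
behavior constant across the genome. A window's midpoint is defined as the
mean cM position of its member markers — robust for one-marker windows, where
the geometric interval center can sit far from the only observed marker — and
`d_j` is the distance between consecutive midpoints, missing at each
chromosome start.

**Emissions.** For each window and each ancestral population `k`, the
surrogate panel's haplotypes over a flanking support region (all markers
within a 2 cM total span, excluding the window's own members) are reduced by
PCA to the smallest number of components explaining 80% of the variance.
Each member marker's allele is then modeled by a logistic principal-component
regression (PCR) on those scores, fitted within population `k`. The emission
probability of allele `x` mixes this PCR prediction with the plain
population allele frequency `p`:

    f = p * P(crossover in support) + logit^-1(b0 + b · PC(support)) * P(no crossover),

where `P(crossover) = 1 - exp(-lambda * w / 100)` for a support span of `w`
cM. The logic: if a crossover since admixture has disrupted the support
haplotype, it no longer looks like any single ancestral haplotype and only
the allele frequency is trustworthy. Windows with a single marker, no usable
support, or a degenerate (monomorphic) support PCA fall back to the allele
frequency alone.

Two regressions coexist deliberately. The emission PCR above regresses a
*member allele* on support PCs within each population — this is the object
whose coefficient priors (`H`, `Sigma`), prior means (`B`) and per-iteration
refits (`beta`) the sampler updates. A second, ancestry-label PCR (logistic
for K = 2, multinomial otherwise, on the reference population's loadings)
classifies window haplotypes directly and provides the quick frequentist
initialization of the chain.

**Hidden Markov chain.** Ancestral state probabilities are propagated along
each haplotype copy in both directions. The transition prior into window `j`
is the convex combination `A * P(r) + gamma_{j-1} * (1 - P(r))`, with
`P(r) = 1 - ((1 + exp(-2 d / 100)) / 2)^lambda` the probability of an
observed recombination over `d` cM after `lambda` generations; the first
window of each chromosome is treated as if a recombination were known
(`P(r) = 1`), so its prior is the copy's global ancestry `A`. Both chains
are filtered with per-window renormalization (the textbook scaled-forward
recursion; the unscaled recursion underflows within a few hundred dense
windows), and the final per-window probabilities are the normalized
elementwise product of the two chains. Note that this product convention —
kept exactly as the method defines it — includes the emission and prior in
*both* chains, so an uninformative window returns the normalized square of
the prior rather than the prior itself; the exhaustive-enumeration oracle in
the test suite is configured with the same convention and the two agree to
1e-10.

**Parameter sampling.** All parameters are updated by
Metropolis-within-Gibbs steps of a common shape: a data-informed independence
proposal (usually the conjugate update built from the sampled ancestral
states) accepted with `min(1, w(proposal) / w(current))`, where `w` is the
prior kernel (for `A`, `A^X`, `lambda`, `p`, `beta`) or the likelihood under
the proposed hyperparameter (for `P`, `B`, `tau`, `omega`, `alpha`). The
stationary law of such a step is proportional to proposal-density times `w`,
which is what the distributional tests integrate numerically. The update
order is fixed for reproducibility: `A`, `A^X`, crossover augmentation and
`lambda`, `p`, `beta`, `P`, `B`, `tau`, `omega`/`omega_X`, `alpha`.

**Sampling ancestral states.** Between the state step and the parameter
step, hard ancestral states `G` are drawn. Drawing each window independently
from its marginal probabilities looks natural but fails on dense window
grids: with ~1,000 windows per chromosome, even 99% per-window confidence
produces tens of spurious ancestry switches per haplotype copy, each of
which the crossover augmentation below must count as a real crossover —
inflating the inferred number of generations without bound (we measured ~27
sampled switches against ~2 true switches per copy, with the admixture-age
trace drifting upward monotonically). The driver therefore draws `G` as a
joint path sample from the forward filter (standard backward sampling
through the convex transition kernel), whose switch counts are coherent
with the chain's own transition prior; the test suite checks the sampled
path distribution against exhaustive path enumeration. The exported
`sample_states()` retains the simple independent-marginal contract for
users who want marginal draws.

Crossover counts are imputed by augmentation: per window, a uniform draw on
`(P(0 crossovers), 1)` is inverted through the Poisson CDF (rate
`lambda * d / 100`), and the resulting count is retained with the posterior
probability that at least one crossover occurred given the sampled states —
1 when ancestry switched between adjacent windows, and the small posterior
odds of a hidden same-state crossover otherwise. `lambda` then gets a
conjugate Gamma proposal from the retained counts and the summed distance in
Morgans (the same /100 scale used by every recombination formula; the
method's equations mix cM and Morgan units and this package standardizes on
Morgans inside all exponents).

**Defaults and units.**

| parameter | meaning | default | rationale |
|---|---|---|---|
| `window_cm` | HMM window width | 0.1 cM | below ancestral-LD range, above marker spacing |
| `support_cm` | PCR support span | 2 cM | captures local haplotype structure |
| `var_threshold` | PCA variance retained | 0.8 | dimension-reduction rule of the method |
| `lambda_init` | generations since admixture | 6 | African-American-like admixture age |
| `tau_init` | surrogate concentration | 300 | middle of the range seen with good surrogates (200-1000) |
| `omega`, `omega_X` init | ancestry concentration | 10 | prior median of `log10 ~ N(1, 0.5)` |
| `alpha` init | Gamma(shape, rate) of lambda | (9, 1.5) | mean 6, variance 4 |
| `n_burn`, `n_iter` | iterations | 100, 200 | traces flat well before 100 on the scales below |

**Parallel chains.** Multiple chains run in lockstep inside one process and,
during burn-in only, each chain blends its parameters with the across-chain
mean using the weight `iter / n_burn` on its own state — chains start at the
shared average and separate smoothly into independent samplers by the end of
burn-in. Implementing the exchange in-process (rather than across OS
processes) keeps single-chain runs bit-reproducible under a fixed seed and
makes the blending logic directly testable; the exchange contract is
unchanged.

## The synthetic data generator

No external reference data are required anywhere in the package. The
generator emulates the essential features the method exploits:

* **Allele-frequency divergence.** Per marker, an ancestral frequency is
  drawn uniformly on (0.1, 0.9), and each population's frequency from the
  Balding-Nichols Beta with divergence parameter `F` (default 0.15, the
  African/European range). Hudson's estimator on 10,000 simulated markers
  recovers `F` within 0.02.
* **Within-population LD.** Haplotypes come from a latent Gaussian AR(1)
  process along the genetic map (correlation `exp(-d / ld_decay_cm)`,
  default 0.3 cM) thresholded at each marker's frequency. Marginals are
  exactly Balding-Nichols; adjacent-marker correlation is ~0.45 at 0.05 cM
  spacing and decays with distance.
* **Admixed chromosomes.** Per chromosome copy, generations since admixture
  are Gamma(mean 6, sd 2) and the first population's global proportion is
  Beta(mean 0.82, sd 0.1) — an African-American-like sample. Breakpoints are
  a Poisson process with rate `lambda` per Morgan; each segment copies a
  uniformly chosen panel haplotype from a population drawn by the global
  proportions; the per-marker truth is recorded. Consecutive chromosome
  pairs form diploid individuals.
* **Imperfect surrogates.** `perturb_priors()` adds `N(0, (scale * SE)^2)`
  noise to every emission-PCR coefficient, mimicking surrogate panels that
  do not perfectly represent the founders.
* **Phenotypes.** Liability rises with the true diploid ancestry dosage at a
  chosen risk window; quantitative, case-control and case-only designs are
  supported, with `effect_size = 0` giving an exact null.

What the generator does **not** emulate: genotyping error, allele miscoding
or strand flips (exercised separately through the QC fixtures), mutation
since admixture, phase-switch errors, and the deep coalescent structure of
real haplotypes (LD here is stationary and single-scale). Passing the
synthetic experiments therefore demonstrates correct inference under the
model's own generating assumptions — it does not certify performance on real
cohorts with phasing artifacts or mis-specified surrogate panels.

## Numerical choices and degenerate inputs

* Emission probabilities are clamped to `[1e-12, 1 - 1e-12]`; a non-finite
  emission aborts with the window named.
* Monomorphic member markers get an intercept-only PCR at the smoothed
  frequency; Jeffreys 0.5 pseudocounts keep every prior frequency strictly
  inside (0, 1).
* Complete separation in a logistic fit first retries nothing — the
  unpenalized fit is used whenever it converges; on separation the
  initialization fit adds an L2 penalty of `1e-4 * n`, while per-iteration
  refits simply retain the current coefficients for that sweep.
* Windows with fewer assigned haplotypes than coefficients plus five skip
  the `beta` refit that iteration.
* Missing alleles contribute emission factor 1; a fully missing window
  leaves the chain prior untouched.
* Ties in maximum-posterior ancestry calls resolve to the first population,
  deterministically.

## Design decisions that were genuinely open

* **Window midpoint** = mean member cM (not the interval center): stable for
  sparse windows and what the inter-window distances `d_j` are built from.
* **Tiling anchor** = first marker per chromosome, so no leading empty
  windows exist.
* **Case-only statistic.** The case-only model is described as comparing
  local with global ancestry, but written as a regression of global on
  local. Under random case sampling that regression has a nonzero
  coefficient at every window (local dosage tracks global ancestry
  genome-wide), so its null rejection rate cannot be nominal. The default
  statistic therefore tests the covariate-adjusted mean of
  `local - 2 * global` against zero, which is calibrated; the literal
  regression remains available as `statistic = "regression"`.
* **Allele-frequency orientation.** `P` and `p` are variant-allele
  frequencies throughout (`Omega` counts variants first); the conjugate
  proposal adds variant counts to the variant shape.
* **Hyperparameter acceptance ratios** use full density ratios (normalizing
  constants included) for `P`, `tau`, `omega`, `alpha` — the only reading
  under which the four families are mutually consistent.
* **Initialization.** The "quick frequentist" start is window-wise
  maximum-likelihood classification under the ancestry-label PCR with a
  uniform prior; both copies of an individual start at their average
  ancestry fraction, and chains start from identical states.

## Known limitations

* Phased input is required; there is no genotype (unphased) emission model.
* The chain-product posterior double-counts the emission by construction
  (see above); it is the method's definition, and all oracles match it, but
  the resulting `gamma` are better read as sharpened scores than as exact
  posterior probabilities.
* The prior-ratio acceptance step means weakly informed parameters
  equilibrate between prior and conditional posterior rather than at the
  exact conditional posterior; with dense data (the regimes exercised here)
  ancestry estimates are unaffected, but per-copy `lambda` should be
  interpreted with its prior in mind.
* The inferred number of generations since admixture is biased upward
  wherever local ancestry is not called with near certainty: posterior
  wobble around segment boundaries adds spurious ancestry switches to the
  sampled paths, each of which the crossover augmentation must count. At
  the shipped synthetic data strength (window accuracy ~97%) the upward
  bias on mean `lambda` is on the order of 20%; global ancestry recovery is
  unaffected (~2%). Treat absolute admixture-age estimates with caution
  unless window calls are essentially certain.
* Sex chromosomes are handled as one more chromosome with their own
  ancestry parameter `A^X`; no dosage-compensation or male-hemizygosity
  modeling.
* Time-to-event phenotype links are not implemented.

## Problem sizes used in the shipped experiments

The package's self-contained experiments run at a desk scale chosen to keep
the full test suite comfortably reproducible on a single CPU: panels of 120
haplotypes per population over 2,000 markers on one 100 cM chromosome
(window tiling of ~1,000 windows), 50 admixed diploid individuals, 100
burn-in plus 200 kept iterations, and calibration scans over 1,000
*unlinked* null windows (one two-marker window on each of 1,000 tiny
chromosomes, 200 diploid individuals): placing each null window on its own
chromosome makes window dosages independent given global ancestry, so the
scan's rejection rate has its nominal binomial spread — on one long
chromosome, neighboring windows share ancestry segments and the rate's
sampling variance would be dominated by a handful of effectively
independent blocks. The smaller unit-test fixtures use 300 markers
over 15 cM with 20 individuals. On these sizes the window-level accuracy of
the fit against simulation truth is the headline quantity recomputed by
`scripts/acceptance.R`, alongside global-ancestry and generations-since-
admixture recovery and the type-I error of the phenotype scan.
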