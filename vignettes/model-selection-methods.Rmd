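---
title: "Structurally constrained substitution-model selection by ABC: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structurally constrained substitution-model selection by ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why likelihood-free model selection

Empirical amino-acid models (Dayhoff, JTT, WAG, LG, ...) assume every site
evolves independently under one exchangeability matrix, which makes their
likelihood factorise over sites and standard selection criteria applicable.
Structurally constrained substitution (SCS) models instead score a mutation
by the folding free energy of the *whole* mutated sequence on a
representative structure. Sites become interdependent, the likelihood no
longer factorises, and comparison against empirical models requires a
likelihood-free route. `scsabc` implements that route: simulate under each
candidate model, compress alignments to a small summary vector, and let
approximate Bayesian computation (ABC) turn distances in summary space into
posterior model probabilities.

## The stability model

Every ΔG prediction uses four ingredients held in an `scs_stability_model`:

* a **contact map**: residue pairs with minimum heavy-atom distance at most
  `cutoff` (default 4.5 Å) and sequence separation at least `s_min`
  (default 3). These are conventional contact-potential settings; both are
  arguments. For Cα-only traces (including the synthetic lattice fixture) a
  4.5 Å heavy-atom cutoff is too strict, so the fixture generator uses the
  usual Cα–Cα convention of 6 Å.
* a **contact potential** U. No published 20×20 statistical potential ships
  with the package: the bundled default is a *synthetic*
  hydrophobicity-product potential, U(a,b) = −h(a)h(b) with h the
  Kyte–Doolittle scale rescaled to [−1, 1]. It reproduces the dominant
  feature of knowledge-based potentials (favourable hydrophobic–hydrophobic
  contacts) and is clearly labelled synthetic; any symmetric 20×20 matrix
  can be supplied via `contact_potential()`.
* a **misfolded ensemble** of `M = 1000` decoys built by circular-shift
  threading of the chain through its own contact topology (plus a direction
  flip once the L−1 distinct shifts are exhausted), each restored to the
  native contact count by uniform resampling of admissible pairs. The
  ensemble free energy uses the random-energy-model (REM) estimate
  G_misf = Ē − σ²/2T − T log M, with σ² the sample variance of decoy
  energies. Below the freezing temperature T_f = σ/√(2 log M) the REM
  expression is non-physical (it dives to −∞), so G_misf is held at the
  ground-state value Ē − σ√(2 log M). The resulting G_misf(T) is continuous
  and non-increasing in T; tests assert the clamp engages exactly when
  T < T_f.
* an **unfolded state** G_unf = −T·s_U·L: a contact-free chain whose only
  contribution is a per-residue conformational entropy s_U (default 0.065,
  dimensionless, k_B = 1). This is a tunable default, not a literature
  constant.

ΔG = E_nat − (−T log(e^(−G_unf/T) + e^(−G_misf/T))), so negative values mean
the native state beats both competitors. Gaps and `X` at mapped positions
contribute the mean potential value over the 20 amino acids — missing data
should not bias ΔG in either direction; whether the original C
implementations strip gaps instead is unknown, so this choice is documented
rather than inherited.

## Simulation

**Genealogies.** The standard n-coalescent with E[T₂] = 2N generations;
exponential growth is a deterministic time change of the coalescent clock
(N(t) = N·e^(−gt) backwards in time), which keeps a single exponential draw
per coalescence and hence exact seedability. The growth parameterisation is
an assumption — per-generation exponential rate — since only "population
growth rate" is specified upstream. Branch lengths are converted to expected
substitutions per site by μ = θ/(4Nl); θ carries the usual Watterson-style
meaning. A user Newick tree (already in substitutions/site) is reused
unchanged by every simulation; coalescent mode redraws a genealogy per
simulation. Polytomies are resolved arbitrarily with zero-length branches
and a warning.

**Empirical models.** Exchangeabilities come from phangorn's bundled
matrices (the canonical published versions; `JonesDCMUT` = JTT-DCMut,
`Mtrev24` = mtREV24). The generator is built as Q_ij = S_ij·π_j, scaled to
one expected substitution per site per unit branch length, and each site
evolves by exp(Qbr_i) using one symmetric eigendecomposition per model.
Gamma rate variation (mean 1, renormalised over variable sites) and a
proportion of invariable sites apply to empirical models only; SCS
simulations default to homogeneous proposal rates, since rate heterogeneity
is attached to the empirical models upstream.

**SCS models.** Forward along each branch, proposal events arrive as a
Poisson process with per-site rate r_i; each proposal draws a uniform
alternative residue. θ therefore calibrates the *attempted* mutation rate —
acceptance thinning makes realized substitution rates model-dependent, and
realized counts are returned per branch so users can inspect the thinning.
The *Neutral* model accepts a proposal iff the mutant ΔG is at or below the
viability threshold (default 0). The *Fitness* model computes the two-state
native occupancy f = 1/(1 + e^(ΔG/T)) and accepts with probability
min(1, Ne·P_Moran(f_old, f_new, Ne)). The factor Ne is deliberate: the raw
Moran fixation probability is 1/Ne for a neutral change, so accepting with
P_Moran alone would make the Fitness model thin *all* mutations by 1/Ne and
it would not reduce to the Neutral model at low temperature. Scaling by Ne
(the origination-process convention: substitution rate = mutation rate ×
P_fix/P_fix,neutral) makes the cold-temperature limit a step function —
accept viable, reject lethal — exactly the advertised Neutral limit, which
the acceptance suite verifies at T = 10⁻⁴ on a shared proposal stream. All
fixation arithmetic runs in log-fitness space so nearly-lethal variants do
not overflow.

The root sequence is the structure's native sequence (or a user sequence),
equilibrated by default with 10·L *accepted* moves along a virtual stem so
tip statistics do not reflect the PDB sequence itself; whether the original
simulator equilibrates its root is not documented, so this is a package
choice (set `burnin_proposals = 0` to disable). A Neutral run whose root
violates the threshold aborts with the root ΔG in the message.

ΔG is maintained incrementally during simulation — a mutation at site i
touches only the native and decoy contacts of i — and the contract that
incremental and from-scratch recomputation agree within 10⁻⁹ is tested on
10⁴ random steps.

## Summary statistics

Seven numbers per alignment, in fixed order: mean and SD of per-sequence ΔG
(computed with the *same* stability model for the query and for every
simulation, including empirical-model simulations); the number of
segregating sites (gaps/X are missing data); and the mean, SD, skewness and
excess kurtosis of pooled Grantham distances. The pool collects D(a,b) over
every column and unordered sequence pair whose residues are canonical and
*different*: identical pairs would flood the pool with zeros and the
statistic is meant to measure the physicochemical magnitude of observed
changes. Whether the original pools per site and averages, or pools
globally, is unspecified; pooling is global here and documented. Degenerate
pools (monomorphic alignments) return zeros so every simulation yields a
finite vector. The Grantham table itself is generated from the published
composition/polarity/volume formula (α = 1.833, β = 0.1018, γ = 0.000399,
ρ = 50.723) rounded to integers; a couple of cells differ by ±1 from some
typeset versions of the matrix, a known rounding artefact.

## ABC estimation

Distances are Euclidean after dividing each statistic by its median absolute
deviation over all simulations (statistics with zero MAD are dropped with a
warning); the retained set is the ⌈tolerance·n⌉ smallest distances with ties
broken by row index. These are conventional defaults — the upstream
description does not fix a metric, standardisation or tie rule — and are
labelled as such. Rejection posteriors are retained-set label frequencies.
The regression adjustment is a weighted multinomial logistic fit (damped
Newton on the convex objective, ridge 0.01) with Epanechnikov weights
1 − (d/d_max)²; the neural-network method is an ensemble of ten
single-hidden-layer (5 tanh units) softmax classifiers trained by full-batch
Adam with weight decay 0.05 — the decay is set so that label-free
(permutation-null) tables yield near-uniform posteriors, a calibration the
test suite checks; no suitable neural-network package is available in the
target environment, so the classifier is implemented in the package. Both
adjusted methods refuse to run when fewer than 10 × (number of models)
simulations are retained, turning the known small-tolerance non-convergence
of these methods into an explicit error instead of a silent bad fit.

Cross-validation draws pseudo-observed rows per model without replacement,
estimates each against the table minus itself, and reports the confusion
matrix and mean posterior of the true model (argmax ties go to the first
label alphabetically). Goodness of fit reports, per model, the distribution
of distances to that model's retained simulations and whether the observed
value of each statistic falls inside the [1%, 99%] quantile envelope.

## The synthetic world, and what green tests do not establish

`generate_fixture()` builds the entire validation world in code: a compact
self-avoiding chain snaking through a cubic lattice at 3.8 Å spacing (≥ 2
contacts per residue on average), a native sequence obtained by greedy
site-wise ΔG minimisation, and a query alignment simulated under a chosen
ground-truth model. Defaults mirror the published validation design scaled
down: N = 1000, uniform θ prior, three candidate models
{Dayhoff, Neutral, Fitness}, rejection at tolerance 0.05 with 1000
training simulations per model, 12 tips and 60 residues (the original
validation used 27 sequences × 316 residues, 10 000 simulations and
tolerances down to 0.005 — sizes chosen here to keep the full suite inside a
CI budget, and said so). Ne = 100 and T = 0.5 for the Fitness simulations
are package choices; the upstream text specifies neither. The fixture
records all ground truth, and for very small chains, where even the
optimised native sits above ΔG = 0, the recorded viability threshold is
lifted to the native ΔG so the stated Neutral world remains simulable.

A green model-selection test on this fixture establishes that the seven
statistics carry enough signal to separate stability-constrained from
site-independent evolution *in this stated world*. It does not establish
performance on real proteins: a lattice Cα chain has no side chains, the
synthetic potential is not a fitted knowledge-based potential, there are no
indels, no among-site proposal-rate heterogeneity in the SCS runs, and one
structure represents all sequences (a stated assumption of the SCS approach
itself). The acceptance suite's other criteria are exact or law-based
(brute-force equivalence, closed forms, matrix-exponential laws) and carry
over to real inputs unchanged.

## Numerical and engineering notes

* One amino-acid index order (alphabetical single-letter) everywhere;
  PAML/Dayhoff-ordered inputs are permuted on read.
* `-T log(e^(-G_unf/T) + e^(-G_misf/T))` is evaluated by log-sum-exp.
* Determinism: every public simulation function takes a seed and restores
  the caller's RNG state; the pipeline derives one seed per simulation from
  the master seed, so results are bit-identical for any worker count
  (criterion-tested for 1 vs 4 workers). Derived seeds stay below 2³¹.
* SCS branch simulation, decoy energetics and the incremental-vs-full ΔG
  probe are compiled (Rcpp) and consume R's RNG, so C++ and R share one
  stream; every proposal consumes exactly three uniforms regardless of
  model, which is what makes neutral/fitness proposal streams comparable
  under a common seed.
* Known limitations: no mmCIF or multi-chain structures; no codon layer
  under the uniform proposal distribution (an exchangeability-weighted
  proposal mode is the natural extension); no posterior estimation of θ; no
  SMC/sequential ABC.
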