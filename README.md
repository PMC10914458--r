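# scsabc

Selection among substitution models of protein evolution — including
site-dependent, structurally constrained (SCS) models that have no tractable
likelihood — by approximate Bayesian computation (ABC).

## The problem

Choosing a substitution model is a standard first step of protein
phylogenetics. Likelihood-based selection (LRT/AIC/BIC) only works for
site-independent models such as the empirical exchangeability matrices
(Dayhoff, JTT, WAG, LG, ...). SCS models are more realistic — the fate of a
mutation depends on the folding stability ΔG of the whole sequence threaded
onto a representative structure, which couples sites — but exactly that
coupling removes the factorised likelihood. `scsabc` sidesteps the
likelihood: it simulates alignments under every candidate model along
coalescent (or user) genealogies, summarises query and simulated data with
seven statistics, and estimates each model's posterior probability by ABC.

## The method in brief

* **Stability model.** ΔG = E_nat − (−T log(e^(−G_unf/T) + e^(−G_misf/T)))
  with E_nat = Σ_(i,j)∈contacts U(a_i, a_j), G_unf = −T·s_U·L, and G_misf the
  random-energy-model free energy of an ensemble of M threading decoys
  (mean Ē, variance σ²): G_misf = Ē − σ²/2T − T log M above the freezing
  temperature σ/√(2 log M), frozen at Ē − σ√(2 log M) below it.
* **SCS simulation.** Forward along the genealogy; proposals arrive as a
  Poisson process (branch lengths calibrate the *attempted* substitution
  rate; θ = 4Nμl with a uniform prior). *Neutral*: a mutant is accepted iff
  ΔG ≤ threshold (binary viability). *Fitness*: fitness is the native-state
  occupancy f = 1/(1 + e^(ΔG/T)); a mutant fixes with probability
  min(1, Ne·P_Moran) where P_Moran = (1 − ρ)/(1 − ρ^Ne), ρ = f_old/f_new —
  at low T this collapses onto the Neutral rule.
* **Summary statistics.** ΔG mean and SD across sequences; number of
  segregating sites; mean, SD, skewness and excess kurtosis of pooled
  Grantham distances of observed residue changes.
* **ABC.** Euclidean distance on MAD-standardised statistics; rejection
  (default), multinomial logistic regression or a small neural-network
  ensemble on the retained set; cross-validation (confusion matrix) and
  goodness-of-fit (distance distributions + 1–99% envelopes) reports.

## Worked example

A fully synthetic scenario (no external data needed): a 60-residue compact
lattice chain, a greedily stabilised native sequence, and a 12-taxon query
alignment simulated under the Neutral SCS model (θ = 60, N = 1000):

```r
library(scsabc)
fx <- generate_fixture(seed = 42, L = 60, n = 12, truth = "Neutral", theta = 60)
delta_g(fx$stab$native_seq, fx$stab)$dG   # -31.87 : a stable native fold
compute_summary_vector(fx$alignment, fx$stab)
#>  dg_mean    dg_sd seg_sites  gr_mean    gr_sd  gr_skew  gr_kurt
#>   -0.366    0.424    51.000   94.066   51.556    0.552   -0.458

cfg <- run_config(
  list(model_empirical("Dayhoff"),
       model_neutral(dG_threshold = 0),
       model_fitness(Ne = 100)),
  fx$stab, n_tips = 12, N = 1000, theta_prior = c(0, 300),
  n_sims_per_model = 300, abc = abc_config("rejection", 0.05), seed = 1)
res <- run_pipeline(cfg, fx$alignment)
res$posterior
#> posterior model probabilities:
#>   Neutral      0.5556
#>   Fitness      0.4444
#>   Dayhoff      0.0000
```

The tip sequences sit just below the viability threshold (`dg_mean` −0.37),
far from what a site-independent Dayhoff simulation produces, so the
empirical model gets probability 0; Neutral (the truth) edges out Fitness.
At the recommended scale (10 000 simulations/model) the separation
sharpens. For a real analysis, read the query with `read_alignment()`, the
template with `read_pdb()`, map columns to residues with
`map_alignment_to_structure()` (use `$threaded`), and check the prior with
`calibrate_prior()` — or drive everything through the CLI:

```sh
Rscript -e 'scsabc::scs_cli()' run --alignment query.fasta --pdb template.pdb \
    --models Dayhoff,Neutral,Fitness --sims 10000 --tolerance 0.005 --seed 1
```

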