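---
title: "seqbayesr: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqbayesr: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`seqbayesr` fits the Bayes R mixture model to dairy-style phenotypic
records (trait deviations for cows, daughter trait deviations for bulls,
or simulated phenotypes):

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Za} + \mathbf{Wv} + \mathbf{e},$$

where $\mathbf{X}$ carries fixed effects (mean, breed/cluster, sex),
$\mathbf{a} \sim N(0, \mathbf{A}\sigma_a^2)$ is a polygenic term with
$\mathbf{A}$ the pedigree numerator relationship matrix, $\mathbf{W}$
holds centered genotype dosages, and
$\mathbf{e} \sim N(0, \mathbf{E}\sigma_e^2)$ with
$\mathbf{E} = \mathrm{diag}(1/w_j)$ for record weights $w_j$ (defaulting
to 1 when no record counts are available). Each variant effect $v_i$ is
drawn from one of four normal distributions with variances
$\gamma_k \sigma_g^2$, $\gamma = (0, 10^{-4}, 10^{-3}, 10^{-2})$, and the
mixing proportions carry a $\mathrm{Dirichlet}(\alpha)$ prior with
$\alpha = (1,1,1,1)$.

$\sigma_g^2$, the additive genetic variance scaling the class variances,
is held fixed during fitting (the Bayes R convention). When not supplied
it defaults to `h2_prior` (default 0.5) times the weighted phenotypic
variance *after adjusting for fixed effects* — breed means are not
genetic variance, and using the raw variance of a multi-breed trait with
a large breed effect would inflate every class variance and cause severe
overfitting.

### Genotype coding

Dosages are centered by twice the counted-allele frequency of the
training panel, i.e. by the column mean, and left unscaled: the class
variances of Bayes R are per-effect, not per-standardized-effect.
Centering constants are stored with every effect table so that validation
genotypes are placed on the training scale when computing GEBVs.

## The hybrid fit: EM warm start, then Gibbs

The fitting protocol runs an expectation–maximization module to obtain
point estimates of $\mathbf{b}, \mathbf{a}, \mathbf{v}, \mathbf{P},
\sigma_e^2$, and then starts a Gibbs chain from those values, by default
for 10,000 iterations with *no burn-in*: the warm start replaces the
burn-in phase.

The EM equations are a reconstruction (the originating software is not
public). We implement it as variational coordinate ascent: for each
variant the E-step computes class responsibilities from the
class-conditional marginal likelihoods of the current residual, and the
effect estimate is updated to its responsibility-weighted conditional
posterior mean; $\mathbf{b}$ is updated by exact GLS, $\mathbf{P}$ by the
Dirichlet-MAP closed form, and $\sigma_e^2$ by its maximizer. Every step
is an exact coordinate maximization of an evidence lower bound (ELBO),
so the tracked objective is non-decreasing by construction — this is the
objective audited by the tests. $\sigma_a^2$ is *not* an EM target (the
warm start estimates $a, P, b, v, \sigma_e^2$ only); updating it jointly
with a point estimate of $\mathbf{a}$ has a degenerate mode at zero, the
classic argument for REML over ML in variance-component estimation. It
stays at its starting value (half the genetic prior variance) and is
sampled properly in the MCMC phase.

The Gibbs sampler visits variants in ascending genome order, samples each
active variant's class with probability proportional to $P_k$ times the
marginal likelihood under $v_i \sim N(0, \gamma_k\sigma_g^2)$, then the
effect from its conditional normal (exactly zero in class 1), maintaining
a running residual. $\mathbf{P}$ is drawn from
$\mathrm{Dirichlet}(\alpha + \text{class counts})$, polygenic values by
single-site updates exploiting the sparse $\mathbf{A}^{-1}$ built
directly from the pedigree, fixed effects jointly from their multivariate
normal conditional, and both variances from scaled inverse chi-square
conditionals with flat scale priors ($\nu = -2$), which are not stated by
the protocol and are our conjugate default. Single-site (rather than
joint Cholesky) polygenic updates are a deliberate choice: they scale to
large pedigrees and match the sparse-inverse structure.

All randomness flows through R's RNG, so a `set.seed()` makes every fit
bit-reproducible; per-chromosome stages derive deterministic child seeds
from the master seed so chromosomes can be run in any order (or in
parallel) with identical results.

## Dropping variants and prior compensation

A `drop_schedule(d, drop_after)` removes the proportion `d` of active
variants with the lowest posterior inclusion probability (PIP — the
fraction of iterations a variant spends outside the zero class, or the
summed class-2..4 responsibility when dropping directly after EM). Ties
are broken by ascending variant index for determinism. When variants are
dropped, the Dirichlet prior is compensated so the dropped mass remains
accounted for: $\alpha'_k = \alpha_k + n_{\text{dropped}} \bar P_k$ with
$\bar P$ the mixing proportions at drop time. We read the compensation as
*pseudo-counts* — Dirichlet parameters count variants, and adding bare
proportions (which sum to 1) could not "account for" thousands of dropped
variants; the literal-proportion alternative is available behind
`literal_prior = TRUE` in `drop_variants()`.

Dropping at the final scheduled iteration extends the chain by a
post-drop phase of equal length (the run-10,000, drop, run-10,000
protocol). Posterior summaries always average over the post-drop window;
with no drop they cover the whole chain. Dropped variants report the PIP
they had at drop time. The reported class occupancy counts the *whole
panel*, with dropped/inactive variants in the zero class (their effects
are exactly zero by construction) — this is the "number of variants per
distribution" that downstream stages receive as prior pseudo-counts, and
counting only active variants here would hand the re-analysis a badly
non-zero-heavy prior.

## Analysis strategies

* `HD_FULL` / `S_FULL` — one genome-wide run over the HD or sequence
  panel (`run_full()`).
* `S_CHR` — each chromosome analysed separately against phenotypes
  corrected by the HD-estimated effects of all *other* chromosomes,
  $y_c = y - \sum_{c' \ne c} W_{c'}\hat v^{HD}_{c'}$; fixed effects and
  the polygenic term are re-estimated in every sub-model (only the other
  chromosomes' marker effects are corrected out). Genome-wide GEBVs are,
  by default, the sum of the per-chromosome re-estimated marker terms
  (`chr_gebv = "reestimated_only"`); the alternative
  (`"reestimated_plus_hd_correction"`) averages the per-chromosome
  models' full predictions, which works out to
  $(\sum_c W_c \hat v_c + (C-1)\,\text{GEBV}_{HD})/C$. The protocol we
  follow does not state which assembly was used, so both are provided and
  the default is the more conservative sequence-only sum.
* `S_KEPT` — the variants retained by the per-chromosome stage are
  re-analysed genome-wide, with the Dirichlet prior initialized from the
  posterior class counts of a designated earlier run, rescaled so the
  pseudo-counts sum to the number of analysed variants.
* `S_KEPT_HD` — as `S_KEPT` with the HD variants added to the selection
  (union, duplicates collapsed).

`run_scenario()` chains the prerequisite stages for a named scenario
(e.g. `S_KEPT_D0.9` first fits `HD_FULL`, then the per-chromosome stage,
then the genome-wide re-analysis), and the `pipeline` CLI subcommand
exposes this with a run manifest recording seeds and input hashes.

## The synthetic world

The simulator emulates the statistical structure of the multi-breed
cattle study the package is designed around, without requiring any
external data:

* **Haplotypes.** Breeds share an ancestral allele-frequency spectrum
  (uniform on 0.05–0.95); breed frequencies drift via a Balding–Nichols
  Beta distribution whose F-coefficient is the `divergence` parameter
  (default 0.1, typical of taurine cattle breed pairs), so the expected
  Hudson $F_{ST}$ between breeds equals `divergence` up to a
  founder-sampling term of order $1/n_{\text{founders}}$ (default 100
  founders per breed, keeping that bias under 0.01). Within-breed LD has
  two sources: founder haplotypes are generated with an AR(1) Gaussian
  copula along each chromosome (decay scale `ld_scale`, default 250 kb at
  the default marker spacing), and individuals are recombinant mosaics of
  the founder pool at `recomb_rate` per bp (default $10^{-8}$, one
  Morgan per 100-Mb chromosome).
* **QTL.** By default 4,000 causal variants: 3,485 small, 500 medium and
  15 large, with effects drawn from mean-zero normals with variances
  $10^{-4}, 10^{-3}, 10^{-2} \times \sigma_g^2$ and $\sigma_g^2 = 1$.
  TBVs are the exact dosage–effect sums, unstandardized.
* **Phenotypes.** Environmental deviations are
  $N(0, \mathrm{var}_w(TBV)\,(1-h^2)/h^2)$ where $\mathrm{var}_w$ is the
  pooled *within-breed* TBV variance, making the target $h^2$ (default
  0.6) a within-breed quantity; the breed effect (Holstein-analog
  $N(10,1)$) is modelled separately, as in the data the study analyses.
  Whether the breed effect was drawn once per breed or per individual is
  ambiguous in the source protocol; the default is one draw per breed per
  replicate, with `draw = "per_individual"` available.
* **Imputation errors.** Each allele of each genotype flips independently
  with probability $e = r/\sqrt{MAF}$ (capped at 1), using the pre-error
  whole-panel MAF — the error model is defined on true frequencies. The
  conventional $r$ grid is 0.0013, 0.0027, 0.0066, 0.0132, 0.0264. The
  realized mean $e$ is reported instead of the source's tabulated
  averages, which depend on a MAF spectrum we do not possess.
* **Annotation classes.** NSC/REG/HD labels are assigned at the filtered
  sequence-panel proportions (4.5% / 58.3% / 37.2%).

What the simulator does **not** emulate: coalescent-accurate demography,
sequencing or imputation mechanics (errors are injected, not produced by
an imputation algorithm), pedigree relationships among the simulated
individuals (they are unrelated founders — consequently the polygenic
term is omitted in synthetic-data analyses and $h_A^2 = 0$ there; the
pedigree machinery is exercised by constructed-pedigree tests instead),
and breed-by-QTL interactions. A green directional test on this world
therefore establishes that the machinery reproduces the qualitative
findings *given* shared QTL effects across breeds and causal variants
present in the sequence panel; it cannot certify behaviour under
model-misspecification the simulator does not generate.

## Filters

The MAF filter removes variants strictly below the threshold (a literal
"lower than": the boundary variant is kept); conventional thresholds are
0.0002 for the simulated sequence panel and 0.002 for real panels. LD
pruning is two-phase: greedy windowed pruning within each annotation tier
(window 50 variants, step 5 — pinned-down stand-ins for PLINK defaults;
the later-positioned variant of a conflicting pair is removed), then a
cross-tier pass removing REG variants in $r^2 > 0.9$ with a retained NSC
variant, HD variants against NSC or REG, and OTHER variants against NSC.
Monomorphic pairs have undefined correlation and are treated as $r^2 = 0$.

## Numerical and scale choices

* Variance conditionals use flat-scale scaled-inverse-chi-square priors
  (posterior degrees of freedom $n-2$, $q-2$); $\sigma_a^2$ has a small
  floor ($10^{-10}\,\mathrm{var}(y)$) against numerical collapse.
* EM stops when the relative ELBO change falls below `tol` (default
  $10^{-5}$; the warm start does not need tight convergence) or
  `max_iter` (100), warning on non-convergence.
* `round(d * n_active)` variants are dropped — exactly, with index
  tie-breaks.
* The package's scaled acceptance experiments (about 1,000 training
  individuals over two breeds, 5,000 variants, 200 QTL in proportions
  170/25/5, a third breed for validation) use 4,000-iteration chains
  rather than 10,000 purely to fit continuous-integration time budgets.
  At this scale the posterior-mean marker variance
  $h_M^2 = \mathrm{var}(W\hat v)/\mathrm{var}(y_{adj})$ is noticeably
  chain-length dependent: short chains retain the optimistic EM start
  (inflating $h_M^2$), long chains shrink uncertain effects toward zero
  (deflating it). At 1/20 of the original cohort size the per-QTL power
  is far lower, so posterior-mean effects are heavily shrunk and the
  replicate spread is large; at the budgeted chain length the scaled
  design recovers $h^2 \approx 0.46$ rather than the simulated 0.6 — a
  genuine property of the posterior-mean estimator in the scaled world,
  not of the sampler, which matches conjugate closed forms exactly on
  degenerate single-class instances and recovers both occupancy and
  marker variance on correctly-specified designs.
* Shortened chains also degrade the per-chromosome PIP ranking that
  selects the variants for the genome-wide re-analysis: with 4,000
  instead of 10,000 pre-drop iterations, the re-analysis of retained
  variants recovers most but not all of the full-sequence accuracy
  (about 0.04–0.05 below the same-drop full analysis at this scale,
  against the ~0.02 seen at full scale and chain length; it remains
  clearly above the per-chromosome stage itself). Lengthening the
  pre-drop chain demonstrably shrinks this gap, consistent with the
  protocol's own observation that later dropping is safer dropping.

## Known limitations

* The EM module is a reconstruction; it matches the published *protocol*
  (what is estimated, and that MCMC starts from it) but not necessarily
  the original update equations.
* Chromosome codes are normalized to integers (cattle-style 1–29, X→30);
  arbitrary labels pass through the dosage-matrix path only.
* The CLI `pipeline` uses the HD-stage posterior as the KEPT prior (the
  real-data convention); the simulated-data convention (posterior of the
  FULL sequence run) is available programmatically via `run_kept()`.
* Multi-trait models, dominance, and BayesB/C variants are out of scope.
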