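# seqbayesr

Multi-breed genomic prediction from sequence-scale genotype data with the
**Bayes R** mixture model, fitted by an EM warm start followed by Gibbs
sampling ("hybrid" Bayes R), with two devices that make whole-sequence
analysis tractable:

1. **Scheduled variant dropping** — rank variants by posterior inclusion
   probability (PIP) during the analysis, drop the lowest-PIP proportion,
   and compensate the Dirichlet prior with the dropped variants'
   pseudo-counts so the mixture stays calibrated.
2. **Split-and-merge per chromosome** — analyse each chromosome
   separately against phenotypes corrected by HD-chip effects of all
   other chromosomes, then re-analyse the retained variants genome-wide.

The package is aimed at quantitative geneticists working on multi-breed /
across-breed dairy prediction, and at anyone who needs a self-contained,
testable implementation of these strategies: it ships a multi-breed
genotype/phenotype **simulator** (drifted breeds with within-breed LD, a
QTL architecture of 3,485 small / 500 medium / 15 large effects,
heritability 0.6, a Holstein-style breed effect N(10, 1), and
MAF-dependent allele errors `e = r / sqrt(MAF)` mimicking imputation), so
every claim is reproducible without any external data.

## Model

```
y = Xb + Za + Wv + e
```

with fixed effects `b`; polygenic values `a ~ N(0, A sigma_a2)` (`A` the
pedigree numerator relationship matrix, built by Henderson's tabular
method with a sparse direct inverse); centered dosages `W`; residuals
`e ~ N(0, E sigma_e2)`, `E = diag(1/w_j)` for record weights; and each
variant effect drawn from one of four normals with variances
`(0, 1e-4, 1e-3, 1e-2) * sigma_g2` under a `Dirichlet(1,1,1,1)` prior on
the mixing proportions. The sampler core is C++ (Rcpp/RcppArmadillo) and
is bit-reproducible under `set.seed()`.

## Worked example

```r
library(seqbayesr)

## simulate a two-breed reference plus a third validation breed
ds <- simulate_dataset(
  n_per_breed = c(HOL = 300, JER = 200, RED = 150),
  n_variants = 2000, n_chromosomes = 2,
  qtl = list(n_small = 70, n_medium = 10, n_large = 3,
             exclude_classes = "HD"),
  seed = 42)
ds$panel
#> geno_panel: 650 individuals x 1997 variants
#> classes: HD=717, NSC=97, REG=1183
#> breeds: HOL=300, JER=200, RED=150

train <- ds$panel$breed %in% c("HOL", "JER")
dat <- model_data(ds$trait$phenotype[train],
                  panel = subset_panel(ds$panel, which(train)),
                  fixed = data.frame(breed = ds$panel$breed[train]))

## Bayes R hybrid: EM warm start + 2,000 Gibbs iterations
fit <- bayesr_hybrid(dat, mixture_spec(), n_iter = 2000, seed = 1)
fit
#> bayesr_fit: 1997 variants ( 0 dropped ), 2000 MCMC iterations
#> h_M2 = 0.386  h_A2 = 0.000  h2 = 0.386

## predict the unseen breed and evaluate against true breeding values
val <- subset_panel(ds$panel, which(!train))
gebv <- predict_gebv(val, effects_table(fit))
round(c(accuracy = accuracy(gebv, ds$trait$tbv[!train]),
        bias = bias(gebv, ds$trait$tbv[!train])), 3)
#> accuracy     bias
#>    0.906    1.574

## drop 90% of the variants after the chain, keep re-estimating
cfg <- scenario_config("S_FULL", d = 0.9, drop_after = 2000,
                       n_iter = 2000, seed = 1)
full9 <- run_full(dat, mixture_spec(), cfg, validation = val)
c(retained = length(full9$retained),
  accuracy = round(accuracy(full9$gebv, ds$trait$tbv[!train]), 3))
#> retained accuracy
#>  200.000    0.896
```

Accuracy here is the correlation between GEBV and the simulated true
breeding values of the breed that was absent from training; a bias
(regression of reference on GEBV) of 1 means no over/under-dispersion.
Dropping 90% of the variants after the full chain retains 200 of 1,997
variants at nearly unchanged across-breed accuracy — the point of the
dropping strategy.

Strategies `HD_FULL`, `S_FULL`, `S_CHR`, `S_KEPT`, `S_KEPT_HD` are
available through `run_full()` / `run_per_chromosome()` / `run_kept()` /
`run_kept_plus_hd()` or the scenario runner `run_scenario()`, and an
imputation-error sensitivity experiment through
`error_sensitivity_report()`.

## Command line

```sh
Rscript inst/scripts/seqbayesr simulate --config sim.yaml --out-prefix out/sim --seed 1
Rscript inst/scripts/seqbayesr fit      --config run.yaml --out-prefix out/fit
Rscript inst/scripts/seqbayesr pipeline --config run.yaml --scenario S_KEPT_D0.9 --out-prefix out/run
```

Readers/writers cover PLINK `.bed/.bim/.fam` (variant-major), plain
dosage-matrix text, pedigree/phenotype/annotation CSV, effect-table CSV,
variance-component JSON, and a run manifest with input hashes. YAML
configs reject unknown keys.

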