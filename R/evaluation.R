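#' Genomic estimated breeding values
#'
#' `GEBV_j = sum_i (x_ij - c_i) v_i` using the effect table's stored
#' training centering constants `c_i`, so validation genotypes are placed
#' on the training scale. Effects for variants absent from the panel are an
#' error; dropped variants (effect 0) contribute nothing.
#'
#' @param panel a [geno_panel] of the individuals to predict.
#' @param effects effect table (see [effects_table()]) with columns `id`,
#'   `effect` and `center`.
#' @param polygenic optional named vector of posterior-mean polygenic
#'   values (e.g. `fit$a_mean` named by pedigree id) to add for matching
#'   individuals; the marker term alone is the default.
#' @return named numeric vector of GEBVs.
#' @export
predict_gebv <- function(panel, effects, polygenic = NULL) {
  stopifnot(inherits(panel, "geno_panel"))
  if (is.null(effects$center)) stop("effect table lacks centering constants")
  idx <- match(effects$id, panel$map$id)
  if (anyNA(idx)) stop("effects reference variants absent from the panel")
  Wv <- sweep(panel$dosage[, idx, drop = FALSE], 2, effects$center)
  g <- drop(Wv %*% effects$effect)
  names(g) <- rownames(panel$dosage)
  if (!is.null(polygenic)) {
    m <- match(names(g), names(polygenic))
    if (anyNA(m)) stop("polygenic values missing for some individuals")
    g <- g + polygenic[m]
  }
  g
}

#' Prediction accuracy
#'
#' Pearson correlation of the GEBV with the reference value (TBV in
#' simulation; TD/DTD for real-style validation), overall and optionally
#' per group (breed/cluster x sex).
#'
#' @param gebv numeric vector of predictions.
#' @param reference numeric vector of reference values, same length.
#' @param group optional grouping labels for per-group correlations.
#' @param min_n smallest group size reported (default 3).
#' @return a single correlation, or a named vector (`overall` first) when
#'   `group` is given.
#' @export
accuracy <- function(gebv, reference, group = NULL, min_n = 3) {
  stopifnot(length(gebv) == length(reference))
  if (stats::sd(gebv) == 0 || stats::sd(reference) == 0)
    stop("zero variance in predictions or reference values")
  overall <- stats::cor(gebv, reference)
  if (is.null(group)) return(overall)
  out <- c(overall = overall)
  for (g in unique(group)) {
    sel <- group == g
    if (sum(sel) < min_n)
      stop("fewer than ", min_n, " individuals in group ", g)
    out[g] <- stats::cor(gebv[sel], reference[sel])
  }
  out
}

#' Prediction bias (dispersion)
#'
#' Least-squares regression slope of the reference value on the GEBV;
#' 1 means no over- or under-dispersion of the predictions.
#'
#' @inheritParams accuracy
#' @return the regression slope.
#' @export
bias <- function(gebv, reference) {
  stopifnot(length(gebv) == length(reference))
  vg <- stats::var(gebv)
  if (vg == 0) stop("zero variance in predictions")
  stats::cov(gebv, reference) / vg
}

#' Imputation-error sensitivity experiment
#'
#' Replicated simulation study of how prediction accuracy and bias respond
#' to MAF-dependent allele errors injected into the reference population,
#' the validation population, or both, over a grid of error-rate
#' parameters `r` (allele error probability `e = r / sqrt(MAF)`). Each
#' replicate simulates a fresh multi-breed dataset, trains on
#' `train_breeds` and validates on the remaining breed(s) against TBV.
#' Fits are reused where genotypes are unchanged (validation-only errors
#' leave the training fit identical), which keeps the experiment exact but
#' affordable.
#'
#' @param r_grid error-rate parameters; the conventional grid is 0.0013,
#'   0.0027, 0.0066, 0.0132, 0.0264. A 0 entry reproduces the error-free
#'   scenario.
#' @param targets subset of `c("both", "reference", "validation")`.
#' @param replicates number of seeded replicates (>= 2).
#' @param sim_args list of arguments for [simulate_dataset()].
#' @param train_breeds breeds forming the reference population; all other
#'   breeds are validation.
#' @param n_iter,spec fitting controls passed to [bayesr_hybrid()].
#' @param seed master seed; replicate s uses `seed + s`.
#' @return data.frame with one row per (r, target): mean and sd of
#'   accuracy and mean bias over replicates, plus the realized mean allele
#'   error probability.
#' @export
error_sensitivity_report <- function(r_grid = c(0, 0.0013, 0.0027, 0.0066,
                                                0.0132, 0.0264),
                                     targets = c("both", "reference",
                                                 "validation"),
                                     replicates = 2,
                                     sim_args = list(),
                                     train_breeds = c("HOL", "JER"),
                                     n_iter = 1000,
                                     spec = mixture_spec(),
                                     seed = 1) {
  if (replicates < 2) stop("at least 2 replicates are required")
  if (any(r_grid < 0)) stop("invalid r")
  targets <- match.arg(targets, several.ok = TRUE)
  cells <- expand.grid(r = r_grid, target = targets,
                       stringsAsFactors = FALSE)
  acc <- matrix(NA_real_, nrow(cells), replicates)
  bia <- matrix(NA_real_, nrow(cells), replicates)
  mean_e <- numeric(nrow(cells))

  for (s in seq_len(replicates)) {
    ds <- do.call(simulate_dataset, c(sim_args, list(seed = seed + s)))
    tr <- ds$panel$breed %in% train_breeds
    if (!any(tr) || all(tr)) stop("train/validation split is degenerate")
    ref_idx <- which(tr); val_idx <- which(!tr)
    tbv_val <- ds$trait$tbv[val_idx]

    fit_cache <- new.env()
    train_fit <- function(panel_ref, key, fit_seed) {
      if (!is.null(fit_cache[[key]])) return(fit_cache[[key]])
      dat <- model_data(ds$trait$phenotype[ref_idx], panel = panel_ref,
                        fixed = data.frame(breed = panel_ref$breed))
      f <- bayesr_hybrid(dat, spec, n_iter = n_iter, seed = fit_seed)
      fit_cache[[key]] <- f
      f
    }

    for (ce in seq_len(nrow(cells))) {
      r <- cells$r[ce]; tg <- cells$target[ce]
      ## same reference corruption draw for targets "reference" and "both";
      ## e always uses the clean whole-panel MAF (true frequencies)
      err_seed <- child_seed(seed + s, round(r * 1e6))
      fit_seed <- child_seed(seed + s, 0)
      pan_use <- ds$panel
      if (r > 0) {
        em <- error_model(r, tg)
        clean_maf <- ds$panel$map$maf
        mean_e[ce] <- mean_e[ce] +
          mean(error_prob(em, clean_maf)) / replicates
        if (tg %in% c("reference", "both"))
          pan_use <- inject_errors(pan_use, em, individuals = ref_idx,
                                   maf = clean_maf, seed = err_seed)
        if (tg %in% c("validation", "both"))
          pan_use <- inject_errors(pan_use, em, individuals = val_idx,
                                   maf = clean_maf, seed = err_seed + 1)
      }
      panel_ref <- subset_panel(pan_use, individuals = ref_idx)
      panel_val <- subset_panel(pan_use, individuals = val_idx)
      key <- if (r > 0 && cells$target[ce] %in% c("reference", "both"))
        sprintf("r%g_ref", r) else "clean"
      f <- train_fit(panel_ref, key, fit_seed)
      gebv <- predict_gebv(panel_val, effects_table(f))
      acc[ce, s] <- accuracy(gebv, tbv_val)
      bia[ce, s] <- bias(gebv, tbv_val)
    }
  }

  data.frame(r = cells$r, target = cells$target,
             mean_accuracy = rowMeans(acc),
             sd_accuracy = apply(acc, 1, stats::sd),
             mean_bias = rowMeans(bia),
             sd_bias = apply(bia, 1, stats::sd),
             mean_e = mean_e, stringsAsFactors = FALSE)
}
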