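#' Scenario configuration
#'
#' Describes one analysis strategy of the scenario table: `HD_FULL` /
#' `S_FULL` (all variants together), `S_CHR` (per-chromosome analyses with
#' HD-effect phenotype correction), `S_KEPT` (variants retained by the
#' per-chromosome stage reanalysed genome-wide) and `S_KEPT_HD` (the
#' retained variants plus all HD variants).
#'
#' @param strategy one of `"HD_FULL"`, `"S_FULL"`, `"S_CHR"`, `"S_KEPT"`,
#'   `"S_KEPT_HD"`.
#' @param d drop proportion in \[0, 1).
#' @param drop_after `"em"` or an iteration count (see [drop_schedule()]).
#' @param n_iter MCMC iterations per stage (default 10000).
#' @param seed master seed; per-chromosome stages derive child seeds from
#'   it so chromosomes can run in any order.
#' @param prior_source `NULL` for the default Dirichlet `[1,1,1,1]`, or a
#'   length-4 vector of posterior class counts from an earlier run
#'   (rescaled to the analysed variant count by [run_kept()]).
#' @param chr_gebv how `S_CHR` assembles genome-wide GEBV:
#'   `"reestimated_only"` (sum of per-chromosome re-estimated marker terms)
#'   or `"reestimated_plus_hd_correction"` (average of the per-chromosome
#'   models' full predictions, each adding the HD-effect contribution of
#'   the other chromosomes).
#' @return a `scenario_config` object.
#' @export
scenario_config <- function(strategy = c("S_FULL", "HD_FULL", "S_CHR",
                                         "S_KEPT", "S_KEPT_HD"),
                            d = 0, drop_after = 10000, n_iter = 10000,
                            seed = 1, prior_source = NULL,
                            chr_gebv = c("reestimated_only",
                                         "reestimated_plus_hd_correction")) {
  strategy <- match.arg(strategy)
  if (d < 0 || d >= 1) stop("drop proportion must be in [0, 1)")
  structure(list(strategy = strategy, d = d, drop_after = drop_after,
                 n_iter = n_iter, seed = as.integer(seed),
                 prior_source = prior_source,
                 chr_gebv = match.arg(chr_gebv)),
            class = "scenario_config")
}

config_schedule <- function(config) {
  if (config$d == 0) NULL else
    drop_schedule(config$d, config$drop_after)
}

## deterministic child stream per chromosome, independent of run order
child_seed <- function(seed, chr) {
  as.integer((as.numeric(seed) * 7919 + chr * 104729) %% 2147483629L + 1)
}

#' Posterior effect table of a fit
#'
#' @param fit a `bayesr_fit`.
#' @return data.frame with `id`, `chrom`, `pos`, `effect` (posterior mean),
#'   `pip`, mean class probabilities, `dropped` flag and the centering
#'   constant used in training (needed to reproduce GEBVs).
#' @export
effects_table <- function(fit) {
  stopifnot(inherits(fit, "bayesr_fit"))
  cp <- fit$class_prob
  colnames(cp) <- paste0("class", 1:4)
  data.frame(id = fit$map$id, chrom = fit$map$chrom, pos = fit$map$pos,
             effect = unname(fit$v_mean), pip = fit$pip,
             cp, dropped = fit$dropped, center = fit$centers,
             stringsAsFactors = FALSE)
}

stage_result <- function(stage, fit, retained, gebv = NULL,
                         parent = NULL, fits = NULL) {
  structure(list(stage = stage, fit = fit, fits = fits,
                 effects = if (is.null(fits)) effects_table(fit) else fit,
                 retained = retained, gebv = gebv, parent = parent),
            class = "stage_result")
}

#' @exportS3Method base::print
print.stage_result <- function(x, ...) {
  cat("stage_result [", x$stage, "]:", length(x$retained),
      "retained variants\n")
  invisible(x)
}

#' FULL strategy: one genome-wide analysis
#'
#' A single EM warm start plus Gibbs run over all variants of the supplied
#' panel (HD or sequence), with the configured drop schedule.
#'
#' @param data a [model_data] over the analysis panel.
#' @param spec a [mixture_spec].
#' @param config a [scenario_config].
#' @param validation optional [geno_panel] of validation individuals for
#'   which GEBVs are computed from the posterior mean effects.
#' @return a `stage_result`.
#' @export
run_full <- function(data, spec, config, validation = NULL) {
  st <- run_em(data, spec)
  fit <- run_mcmc(st, data, spec, n_iter = config$n_iter,
                  schedule = config_schedule(config), seed = config$seed)
  gebv <- if (!is.null(validation))
    predict_gebv(validation, effects_table(fit))
  stage_result(config$strategy, fit, retained = fit$map$id[fit$active],
               gebv = gebv)
}

#' CHR strategy: per-chromosome analyses with HD-effect correction
#'
#' Each chromosome is analysed separately against phenotypes corrected by
#' the HD-estimated marker effects of all *other* chromosomes
#' (`y_c = y - sum_{c' != c} W_c' v_hd_c'`); fixed effects and the
#' polygenic term are retained in every sub-model. Chromosomes use child
#' seeds derived from the master seed, so they are independently runnable
#' and order-invariant. Per-chromosome retained variants and effects are
#' concatenated; genome-wide GEBVs are assembled per `config$chr_gebv`.
#'
#' @inheritParams run_full
#' @param hd_effects effect table (from [effects_table()] of a completed
#'   HD `run_full`) whose variant ids must be present in `data`.
#' @param prior_counts optional length-4 posterior class counts from an
#'   earlier run, rescaled to each chromosome's variant count and used as
#'   the Dirichlet prior of the sub-models (the real-data convention
#'   passes the HD stage's posterior here).
#' @return a `stage_result`; `$fits` holds the per-chromosome fits.
#' @export
run_per_chromosome <- function(data, spec, config, hd_effects,
                               prior_counts = NULL, validation = NULL) {
  chroms <- sort(unique(data$map$chrom))
  if (length(chroms) == 0 || anyNA(data$map$chrom))
    stop("variants must carry chromosome labels")
  hd_idx <- match(hd_effects$id, data$map$id)
  if (anyNA(hd_idx))
    stop("hd_effects contain variants absent from the analysis panel")
  hd_chr <- data$map$chrom[hd_idx]
  if (length(chroms) > 1 && !all(chroms %in% c(hd_chr, NA)))
    stop("hd_effects do not cover all other chromosomes")

  hd_contrib <- hd_contributions(data, hd_effects)
  total_hd <- rowSums(hd_contrib)

  fits <- vector("list", length(chroms))
  names(fits) <- as.character(chroms)
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    vidx <- which(data$map$chrom == ch)
    y_c <- data$y - (total_hd - hd_contrib[, ci])
    sub <- subset_model_data(data, vidx, y = y_c)
    spec_c <- spec
    if (!is.null(prior_counts))
      spec_c$alpha <- pmax(prior_counts / sum(prior_counts) *
                             length(vidx), 1e-6)
    cfg_c <- config
    cfg_c$seed <- child_seed(config$seed, ch)
    st <- run_em(sub, spec_c)
    fits[[ci]] <- run_mcmc(st, sub, spec_c, n_iter = config$n_iter,
                           schedule = config_schedule(config),
                           seed = cfg_c$seed)
  }

  eff <- do.call(rbind, lapply(fits, effects_table))
  rownames(eff) <- NULL
  retained <- eff$id[!eff$dropped]
  gebv <- NULL
  if (!is.null(validation)) {
    gebv <- predict_gebv(validation, eff)
    if (config$chr_gebv == "reestimated_plus_hd_correction") {
      ## average of the C per-chromosome models' full predictions,
      ## each being W_c v_c + sum_{c' != c} W_c' v_hd_c':
      ## = (sum_c W_c v_c + (C - 1) * hd_gebv) / C
      hd_val <- predict_gebv(validation, hd_effects)
      C <- length(chroms)
      gebv <- (gebv + (C - 1) * hd_val) / C
    }
  }
  stage_result("S_CHR", eff, retained = retained, gebv = gebv,
               fits = fits)
}

#' KEPT strategy: genome-wide reanalysis of retained variants
#'
#' A fresh EM + Gibbs run restricted to the selected variants. The
#' Dirichlet prior is initialized from the posterior class counts of a
#' designated earlier run, rescaled so the pseudo-counts sum to the number
#' of analysed variants; with `prior_counts = NULL` the default prior of
#' the supplied spec is used.
#'
#' @inheritParams run_full
#' @param selection variant ids (or indices) to reanalyse.
#' @param prior_counts length-4 posterior class counts (e.g.
#'   `fit$class_occupancy` of the source run), or `NULL`.
#' @return a `stage_result`.
#' @export
run_kept <- function(data, spec, config, selection, prior_counts = NULL,
                     validation = NULL) {
  if (length(selection) == 0) stop("empty variant selection")
  vidx <- if (is.character(selection))
    match(selection, data$map$id) else as.integer(selection)
  if (anyNA(vidx)) stop("selection contains unknown variant ids")
  vidx <- sort(vidx)
  sub <- subset_model_data(data, vidx)
  if (!is.null(prior_counts)) {
    stopifnot(length(prior_counts) == 4, all(prior_counts >= 0))
    spec$alpha <- prior_counts / sum(prior_counts) * length(vidx)
    spec$alpha <- pmax(spec$alpha, 1e-6)  # Dirichlet needs positive mass
  }
  st <- run_em(sub, spec)
  fit <- run_mcmc(st, sub, spec, n_iter = config$n_iter,
                  schedule = config_schedule(config), seed = config$seed)
  gebv <- if (!is.null(validation))
    predict_gebv(validation, effects_table(fit))
  stage_result("S_KEPT", fit, retained = fit$map$id[fit$active],
               gebv = gebv)
}

#' KEPT+HD strategy: retained variants plus the HD panel
#'
#' [run_kept()] over the union of the selection and the HD variant ids
#' (duplicates collapsed, genome order preserved).
#'
#' @inheritParams run_kept
#' @param hd_ids ids of the HD variants (must be present in the panel).
#' @return a `stage_result`.
#' @export
run_kept_plus_hd <- function(data, spec, config, selection, hd_ids,
                             prior_counts = NULL, validation = NULL) {
  if (!all(hd_ids %in% data$map$id))
    stop("hd_ids contain variants absent from the panel")
  sel_ids <- if (is.character(selection)) selection else
    data$map$id[selection]
  un <- union(sel_ids, hd_ids)
  if (length(un) == 0) stop("empty variant union")
  res <- run_kept(data, spec, config, un, prior_counts = prior_counts,
                  validation = validation)
  res$stage <- "S_KEPT_HD"
  res
}

## HD marker contribution per chromosome on the training scale; the
## corrected phenotype for chromosome c is y - rowSums(contrib[, -c])
hd_contributions <- function(data, hd_effects) {
  chroms <- sort(unique(data$map$chrom))
  hd_idx <- match(hd_effects$id, data$map$id)
  hd_chr <- data$map$chrom[hd_idx]
  contrib <- matrix(0, length(data$y), length(chroms),
                    dimnames = list(NULL, chroms))
  for (ci in seq_along(chroms)) {
    sel <- which(hd_chr == chroms[ci])
    if (length(sel))
      contrib[, ci] <- data$W[, hd_idx[sel], drop = FALSE] %*%
        hd_effects$effect[sel]
  }
  contrib
}

## restrict a model_data to a variant subset, optionally replacing y
subset_model_data <- function(data, variants, y = NULL) {
  stopifnot(inherits(data, "model_data"))
  out <- data
  out$W <- data$W[, variants, drop = FALSE]
  out$map <- data$map[variants, , drop = FALSE]
  out$centers <- data$centers[variants]
  if (!is.null(y)) out$y <- as.numeric(y)
  out
}
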