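#' Four-component mixture specification
#'
#' Variant effects are modelled as draws from a mixture of four normal
#' distributions with variances `gamma * sigma_g2`, where
#' `gamma = c(0, 1e-4, 1e-3, 1e-2)` and `sigma_g2` is the additive genetic
#' variance, with a Dirichlet(alpha) prior on the mixing proportions
#' (default `alpha = c(1, 1, 1, 1)`). `sigma_g2` is held fixed during
#' fitting; when left `NULL` it defaults to `h2_prior` times the weighted
#' phenotypic variance at fit time.
#'
#' @param gamma non-decreasing class variance multipliers, `gamma[1] == 0`.
#' @param sigma_g2 additive genetic variance, or `NULL` to derive from the
#'   data.
#' @param alpha Dirichlet prior parameters (pseudo-counts), all > 0.
#' @param h2_prior prior heritability used when `sigma_g2` is `NULL`.
#' @return a `mixture_spec` object.
#' @export
mixture_spec <- function(gamma = c(0, 1e-4, 1e-3, 1e-2), sigma_g2 = NULL,
                         alpha = c(1, 1, 1, 1), h2_prior = 0.5) {
  if (length(gamma) != 4 || gamma[1] != 0 || any(diff(gamma) < 0))
    stop("gamma must be 4 non-decreasing multipliers starting at 0")
  if (length(alpha) != 4 || any(alpha <= 0))
    stop("alpha must be 4 positive pseudo-counts")
  structure(list(gamma = gamma, sigma_g2 = sigma_g2, alpha = alpha,
                 h2_prior = h2_prior),
            class = "mixture_spec")
}

#' Assemble model data for the Bayes R hybrid
#'
#' Builds the design of `y = Xb + Za + Wv + e`: centered genotype
#' covariates `W` (dosage minus twice the counted-allele frequency, so
#' columns are mean-centered; centering constants are stored for
#' prediction), the fixed-effect design `X` from a data.frame of covariates
#' (reference-level coding, intercept included), record weights `w_j`
#' (residual variance of record j is `sigma_e2 / w_j`), and, when a
#' pedigree is supplied, the sparse inverse numerator relationship matrix
#' for the polygenic term.
#'
#' @param y numeric phenotype vector (TD/DTD-style records).
#' @param panel a [geno_panel] holding the genotypes of the phenotyped
#'   individuals (rows aligned with `y`), or `NULL` when `W` is given.
#' @param W alternatively, a pre-centered numeric matrix.
#' @param fixed data.frame of fixed-effect covariates (breed/cluster, sex,
#'   ...) aligned with `y`; `NULL` gives an intercept-only design, `FALSE`
#'   drops fixed effects entirely (used by oracle tests).
#' @param weights positive record weights, default all 1.
#' @param pedigree a sorted `pedigree` ([sort_pedigree()]) enabling the
#'   polygenic term; `NULL` omits it.
#' @param ids individual ids linking records to pedigree entries (defaults
#'   to the panel's rownames).
#' @param centers optional centering constants to reuse (training centers).
#' @return a `model_data` object.
#' @export
model_data <- function(y, panel = NULL, W = NULL, fixed = NULL,
                       weights = NULL, pedigree = NULL, ids = NULL,
                       centers = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  map <- NULL
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "geno_panel"))
    if (nrow(panel$dosage) != n)
      stop("panel and phenotype dimensions disagree")
    if (is.null(centers)) centers <- colMeans(panel$dosage)
    W <- sweep(panel$dosage, 2, centers)
    map <- panel$map
    if (is.null(ids)) ids <- rownames(panel$dosage)
  } else {
    W <- as.matrix(W)
    if (is.null(centers)) centers <- rep(0, ncol(W))
    if (is.null(map))
      map <- data.frame(id = colnames(W) %||% paste0("v", seq_len(ncol(W))),
                        chrom = 1L, pos = seq_len(ncol(W)))
  }
  if (nrow(W) != n) stop("genotype and phenotype dimensions disagree")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be positive")

  if (isFALSE(fixed)) {
    X <- matrix(0, n, 0)
  } else if (is.null(fixed)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    fixed <- as.data.frame(fixed)
    fixed[] <- lapply(fixed, function(col)
      if (is.character(col)) factor(col) else col)
    ## drop single-level factors (e.g. one breed only) to keep X full rank
    keep <- vapply(fixed, function(col)
      !is.factor(col) || nlevels(droplevels(col)) > 1, logical(1))
    X <- stats::model.matrix(~ ., fixed[, keep, drop = FALSE])
  }
  if (ncol(X) > 0 && qr(X)$rank < ncol(X))
    stop("fixed-effect design is singular after reference-level coding")

  use_poly <- !is.null(pedigree)
  Ainv <- NULL; rec_ptr <- integer(1); rec_idx <- integer(0)
  ped_ids <- NULL
  if (use_poly) {
    if (!inherits(pedigree, "pedigree"))
      pedigree <- sort_pedigree(pedigree)
    if (is.null(ids)) stop("ids are required to link records to the pedigree")
    zidx <- match(as.character(ids), pedigree$id)
    if (anyNA(zidx)) stop("some record ids are missing from the pedigree")
    Ainv <- build_Ainv(pedigree)
    qped <- nrow(pedigree)
    recs <- split(seq_len(n) - 1L, factor(zidx, levels = seq_len(qped)))
    rec_ptr <- c(0L, cumsum(lengths(recs)))
    rec_idx <- unlist(recs, use.names = FALSE)
    ped_ids <- pedigree$id
  }

  structure(list(y = y, W = W, X = X, weights = weights,
                 Ainv = Ainv, rec_ptr = as.integer(rec_ptr),
                 rec_idx = as.integer(rec_idx), use_poly = use_poly,
                 ped_ids = ped_ids, ids = ids, map = map,
                 centers = centers),
            class = "model_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## default sigma_g2 = h2_prior x weighted phenotypic variance, taken after
## adjusting for the fixed effects (breed means etc. are not genetic)
resolve_sigma_g2 <- function(spec, data) {
  if (!is.null(spec$sigma_g2)) return(spec$sigma_g2)
  r <- if (ncol(data$X) > 0)
    stats::lm.wfit(data$X, data$y, data$weights)$residuals
  else data$y - stats::weighted.mean(data$y, data$weights)
  vw <- sum(data$weights * r^2) / max(length(data$y) - ncol(data$X), 1)
  spec$h2_prior * vw
}

precompute_designs <- function(data) {
  w <- data$weights
  Ww <- data$W * w               # rows scaled by record weight
  ww <- colSums(Ww * data$W)
  XtEX <- if (ncol(data$X) > 0) crossprod(data$X, data$X * w) else
    matrix(0, 0, 0)
  list(Ww = Ww, ww = ww, XtEX = XtEX)
}

empty_sp <- function() Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                            x = numeric(0), dims = c(1, 1))

#' EM warm start for the Bayes R hybrid
#'
#' Variational expectation-maximization estimating `b`, `a`, `P`, `v` and
#' `sigma_e2` (and `sigma_a2` when a polygenic term is present): the E-step
#' computes per-variant class responsibilities under the current residual,
#' the M-step updates each effect to its responsibility-weighted conditional
#' posterior mean and updates `P`, `b` and the variances in closed form.
#' Every update is an exact coordinate maximization of an evidence lower
#' bound, so the tracked objective is non-decreasing; iteration stops when
#' its relative change falls below `tol`. The result is the starting state
#' for [run_mcmc()].
#'
#' @param data a [model_data].
#' @param spec a [mixture_spec].
#' @param max_iter,tol convergence controls.
#' @param fix_P optional length-4 simplex fixing the mixing proportions
#'   (degenerate single-class runs for oracle checks).
#' @param fix_sigma_e2,fix_sigma_a2 optional fixed variances.
#' @return a `bayesr_state`: point estimates plus EM responsibilities and
#'   the objective trace (attribute `elbo`).
#' @export
run_em <- function(data, spec, max_iter = 100, tol = 1e-5, fix_P = NULL,
                   fix_sigma_e2 = NA, fix_sigma_a2 = NA) {
  stopifnot(inherits(data, "model_data"), inherits(spec, "mixture_spec"))
  if (tol <= 0) stop("tol must be positive")
  sg2 <- resolve_sigma_g2(spec, data)
  tau <- spec$gamma * sg2
  pre <- precompute_designs(data)
  ## sigma_a2 is not an EM target; start it at half the genetic prior
  sa2_init <- 0.5 * spec$h2_prior * stats::var(data$y)
  fit <- em_fit_cpp(data$W, pre$Ww, pre$ww, data$X, pre$XtEX, data$y,
                    data$weights, data$rec_ptr, data$rec_idx,
                    if (data$use_poly) data$Ainv else empty_sp(),
                    data$use_poly, tau, spec$alpha,
                    if (is.null(fix_P)) NULL else as.numeric(fix_P),
                    as.numeric(fix_sigma_e2), as.numeric(fix_sigma_a2),
                    sa2_init, as.integer(max_iter), tol)
  if (!fit$converged)
    warning("EM did not converge in ", max_iter, " iterations")
  state <- structure(list(
    b = drop(fit$b), a = drop(fit$a), v = drop(fit$v),
    resp = fit$resp, cls = max.col(fit$resp), P = drop(fit$P),
    sigma_e2 = fit$sigma_e2, sigma_a2 = fit$sigma_a2,
    active = rep(TRUE, ncol(data$W)), alpha = spec$alpha,
    sigma_g2 = sg2,
    fix_P = fix_P, fix_sigma_e2 = fix_sigma_e2,
    fix_sigma_a2 = fix_sigma_a2), class = "bayesr_state")
  attr(state, "elbo") <- drop(fit$elbo)
  attr(state, "em_iterations") <- fit$iterations
  state
}

#' A fresh (zero) model state
#'
#' Used to start the Gibbs sampler without an EM warm start.
#'
#' @param data a [model_data].
#' @param spec a [mixture_spec].
#' @return a `bayesr_state` with all effects zero.
#' @export
initial_state <- function(data, spec) {
  sg2 <- resolve_sigma_g2(spec, data)
  structure(list(
    b = rep(0, ncol(data$X)),
    a = rep(0, if (data$use_poly) nrow(data$Ainv) else 0),
    v = rep(0, ncol(data$W)), resp = NULL, cls = rep(1L, ncol(data$W)),
    P = spec$alpha / sum(spec$alpha),
    sigma_e2 = stats::var(data$y) * 0.5,
    sigma_a2 = stats::var(data$y) * 0.05,
    active = rep(TRUE, ncol(data$W)), alpha = spec$alpha, sigma_g2 = sg2,
    fix_P = NULL, fix_sigma_e2 = NA, fix_sigma_a2 = NA),
    class = "bayesr_state")
}

#' Drop schedule for in-analysis variant removal
#'
#' A proportion `d` of the active variants is dropped at the scheduled
#' point: `"em"` (directly after the EM warm start, using EM
#' responsibilities as inclusion evidence) or after `drop_after` MCMC
#' iterations. When `drop_after` equals the chain length the chain is
#' extended by a post-drop phase (`post_drop_iter`, default the same
#' length), mirroring the run-10,000-drop-run-10,000 protocol; posterior
#' summaries always average over the post-drop window.
#'
#' @param d proportion of active variants to drop, in \[0, 1).
#' @param drop_after `"em"` or a positive iteration count.
#' @param post_drop_iter iterations after a terminal drop (default: chain
#'   length).
#' @return a `drop_schedule` object.
#' @export
drop_schedule <- function(d = 0, drop_after = "em", post_drop_iter = NULL) {
  if (d < 0 || d >= 1) stop("drop proportion must be in [0, 1)")
  if (!identical(drop_after, "em")) {
    drop_after <- as.integer(drop_after)
    if (is.na(drop_after) || drop_after < 1)
      stop("drop_after must be 'em' or a positive iteration count")
  }
  structure(list(d = d, drop_after = drop_after,
                 post_drop_iter = post_drop_iter),
            class = "drop_schedule")
}

#' Posterior inclusion probabilities
#'
#' PIP of a variant is the evidence that its effect comes from a non-zero
#' variance class: the fraction of MCMC iterations spent outside class 1
#' (given a trace matrix of class assignments, iterations x variants), or
#' the summed responsibility over classes 2-4 (given an EM `bayesr_state`).
#'
#' @param x a `bayesr_state` with responsibilities, or an integer matrix of
#'   class assignments in 1..4 with one row per iteration.
#' @return numeric vector of PIPs in \[0, 1\].
#' @export
compute_pip <- function(x) {
  if (inherits(x, "bayesr_state")) {
    if (is.null(x$resp)) stop("state carries no EM responsibilities")
    return(rowSums(x$resp[, 2:4, drop = FALSE]))
  }
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty class trace")
  colMeans(x != 1)
}

#' Drop the lowest-PIP variants from a model state
#'
#' Deactivates exactly `round(d * n_active)` variants, chosen as the
#' lowest-PIP set with ties broken by ascending variant index, zeroing
#' their effects. The Dirichlet prior is compensated with the expected
#' pseudo-counts of the dropped variants:
#' `alpha'_k = alpha_k + n_dropped * P_k` at the mixing proportions current
#' at drop time, so the dropped mass stays accounted for. (`literal_prior =
#' TRUE` instead adds the bare proportions, the most literal reading.)
#'
#' @param state a `bayesr_state`.
#' @param spec the [mixture_spec] in force.
#' @param pip PIP vector aligned with the state's variants.
#' @param d drop proportion in \[0, 1).
#' @param literal_prior add `P_k` itself rather than `n_dropped * P_k`.
#' @return list with elements `state` and `spec` (alpha compensated in
#'   both).
#' @export
drop_variants <- function(state, spec, pip, d, literal_prior = FALSE) {
  stopifnot(inherits(state, "bayesr_state"))
  if (d < 0 || d >= 1) stop("drop proportion must be in [0, 1)")
  if (d == 0) return(list(state = state, spec = spec))
  act <- which(state$active)
  n_drop <- round(d * length(act))
  if (n_drop > 0) {
    ord <- act[order(pip[act], act)]
    drop_idx <- ord[seq_len(n_drop)]
    state$active[drop_idx] <- FALSE
    state$v[drop_idx] <- 0
    add <- if (literal_prior) state$P else n_drop * state$P
    state$alpha <- state$alpha + add
    spec$alpha <- state$alpha
  }
  list(state = state, spec = spec)
}

#' Gibbs sampler of the Bayes R hybrid
#'
#' Runs the MCMC module from a warm-start state: per iteration each active
#' variant's mixture class is sampled with probability proportional to
#' `P_k` times the marginal likelihood of the current residual under
#' `v_i ~ N(0, gamma_k * sigma_g2)`, then its effect from the conditional
#' normal (exactly 0 in class 1), maintaining a running residual; `P` is
#' drawn from `Dirichlet(alpha + class counts)`, the polygenic values by
#' single-site updates exploiting the sparse inverse relationship matrix,
#' fixed effects jointly, and both variances from scaled inverse chi-square
#' conditionals with record weights. No burn-in is discarded: posterior
#' means average over all retained iterations (the post-drop window when a
#' drop is scheduled).
#'
#' @param state a `bayesr_state` (from [run_em()] or [initial_state()]).
#' @param data a [model_data].
#' @param spec a [mixture_spec].
#' @param n_iter number of iterations (default 10000).
#' @param schedule optional [drop_schedule()].
#' @param seed optional integer seed (applied via `set.seed`).
#' @return a `bayesr_fit` with per-variant posterior means, PIPs, mean
#'   class occupancy, variance components and full traces.
#' @export
run_mcmc <- function(state, data, spec, n_iter = 10000, schedule = NULL,
                     seed = NULL) {
  stopifnot(inherits(state, "bayesr_state"), inherits(data, "model_data"),
            inherits(spec, "mixture_spec"))
  if (n_iter < 0) stop("n_iter must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  sg2 <- state$sigma_g2 %||% resolve_sigma_g2(spec, data)
  tau <- spec$gamma * sg2

  drop_at_em_pip <- NULL
  drop_iter <- -1L; d <- 0; total_iter <- n_iter
  if (!is.null(schedule) && schedule$d > 0) {
    d <- schedule$d
    if (identical(schedule$drop_after, "em")) {
      pip <- compute_pip(state)
      dr <- drop_variants(state, spec, pip, d)
      state <- dr$state; spec <- dr$spec
      drop_at_em_pip <- pip
      d <- 0  # no in-chain drop remains
    } else {
      k <- schedule$drop_after
      if (k > n_iter) stop("drop point lies beyond the chain length")
      if (k == n_iter) {
        post <- schedule$post_drop_iter %||% n_iter
        total_iter <- n_iter + post
      }
      drop_iter <- k
    }
  }

  if (n_iter == 0) return(fit_from_state(state, data, spec))

  pre <- precompute_designs(data)
  res <- gibbs_cpp(data$W, pre$Ww, pre$ww, data$X, pre$XtEX, data$y,
                   data$weights, data$rec_ptr, data$rec_idx,
                   if (data$use_poly) data$Ainv else empty_sp(),
                   data$use_poly, tau, state$alpha,
                   if (is.null(state$fix_P)) NULL else
                     as.numeric(state$fix_P),
                   as.numeric(state$fix_sigma_e2),
                   as.numeric(state$fix_sigma_a2),
                   state$b, state$a, state$v, state$P,
                   state$sigma_e2, state$sigma_a2,
                   state$active, as.integer(total_iter),
                   as.integer(drop_iter), d,
                   1e-10 * stats::var(data$y))

  pip <- drop(res$pip)
  pip_at_drop <- drop(res$pip_at_drop)
  dropped <- !res$active
  if (!is.null(drop_at_em_pip))
    pip_at_drop[dropped] <- drop_at_em_pip[dropped]
  pip[dropped] <- NA_real_

  vm <- drop(res$v_mean)
  names(vm) <- data$map$id
  fit <- structure(list(
    v_mean = vm, pip = pip, pip_at_drop = pip_at_drop,
    class_prob = res$class_prob, active = drop(res$active),
    dropped = dropped, n_dropped = sum(dropped),
    b_mean = drop(res$b_mean), a_mean = drop(res$a_mean),
    P_mean = drop(res$P_mean),
    sigma_e2 = res$sigma_e2_mean, sigma_a2 = res$sigma_a2_mean,
    alpha_final = drop(res$alpha_final),
    class_occupancy = colMeans(res$occ_trace[
      (res$total_iter - res$n_window + 1):res$total_iter, , drop = FALSE]),
    traces = list(occupancy = res$occ_trace, P = res$P_trace,
                  sigma_e2 = drop(res$se2_trace),
                  sigma_a2 = drop(res$sa2_trace)),
    n_window = res$n_window, n_iter_total = res$total_iter,
    map = data$map, centers = data$centers, sigma_g2 = sg2,
    final_state = res$state), class = "bayesr_fit")
  fit$varcomp <- variance_components(fit, data)
  fit
}

## degenerate zero-iteration summary: the initial state, PIPs all 0
fit_from_state <- function(state, data, spec) {
  vm <- state$v
  names(vm) <- data$map$id
  fit <- structure(list(
    v_mean = vm, pip = rep(0, length(vm)), pip_at_drop = rep(NA_real_,
                                                             length(vm)),
    class_prob = matrix(0, length(vm), 4), active = state$active,
    dropped = !state$active, n_dropped = sum(!state$active),
    b_mean = state$b, a_mean = state$a, P_mean = state$P,
    sigma_e2 = state$sigma_e2, sigma_a2 = state$sigma_a2,
    alpha_final = state$alpha, class_occupancy = rep(0, 4),
    traces = NULL, n_window = 0L, n_iter_total = 0L,
    map = data$map, centers = data$centers, sigma_g2 = state$sigma_g2,
    final_state = state), class = "bayesr_fit")
  fit$varcomp <- variance_components(fit, data)
  fit
}

#' @exportS3Method base::print
print.bayesr_fit <- function(x, ...) {
  cat("bayesr_fit:", length(x$v_mean), "variants (", x$n_dropped,
      "dropped ),", x$n_iter_total, "MCMC iterations\n")
  vc <- x$varcomp
  cat(sprintf("h_M2 = %.3f  h_A2 = %.3f  h2 = %.3f\n",
              vc["h_M2"], vc["h_A2"], vc["h2"]))
  invisible(x)
}

#' Variance components explained by the fit
#'
#' `h_M2` is the variance of the fitted marker term `W v_hat` over the
#' reference individuals divided by the variance of the phenotypes adjusted
#' for fixed effects; `h_A2` is the posterior mean polygenic variance on the
#' same scale; `h2 = h_M2 + h_A2` by construction.
#'
#' @param fit a `bayesr_fit`.
#' @param data the [model_data] it was fitted on.
#' @return named vector `c(h_M2, h_A2, h2, sigma_e2, sigma_a2)`.
#' @export
variance_components <- function(fit, data) {
  stopifnot(inherits(fit, "bayesr_fit"))
  yadj <- data$y - if (ncol(data$X) > 0) drop(data$X %*% fit$b_mean) else 0
  vy <- stats::var(yadj)
  if (vy <= 0) stop("zero phenotypic variance")
  g <- drop(data$W %*% fit$v_mean)
  h_M2 <- stats::var(g) / vy
  h_A2 <- if (data$use_poly) fit$sigma_a2 / vy else 0
  c(h_M2 = h_M2, h_A2 = h_A2, h2 = h_M2 + h_A2,
    sigma_e2 = fit$sigma_e2, sigma_a2 = fit$sigma_a2)
}

#' Fit the Bayes R hybrid (EM warm start + Gibbs)
#'
#' Convenience wrapper: [run_em()] followed by [run_mcmc()].
#'
#' @inheritParams run_mcmc
#' @param em_control list of EM controls (`max_iter`, `tol`).
#' @return a `bayesr_fit`.
#' @export
bayesr_hybrid <- function(data, spec = mixture_spec(), n_iter = 10000,
                          schedule = NULL, seed = NULL,
                          em_control = list()) {
  st <- run_em(data, spec,
               max_iter = em_control$max_iter %||% 100,
               tol = em_control$tol %||% 1e-5)
  run_mcmc(st, data, spec, n_iter = n_iter, schedule = schedule,
           seed = seed)
}
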