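test_that("mixture_spec and drop_schedule validate their invariants", {
  expect_error(mixture_spec(gamma = c(0.1, 1e-4, 1e-3, 1e-2)), "gamma")
  expect_error(mixture_spec(gamma = c(0, 1e-3, 1e-4, 1e-2)), "gamma")
  expect_error(mixture_spec(alpha = c(1, 1, 1, 0)), "alpha")
  expect_error(drop_schedule(1), "proportion")
  expect_error(drop_schedule(-0.1), "proportion")
  expect_error(drop_schedule(0.5, 0), "positive iteration")
})

test_that("EM shrinks pure-noise data into the zero class", {
  set.seed(1)
  W <- matrix(rnorm(60 * 30), 60, 30)
  y <- rnorm(60)
  dat <- model_data(y, W = W, fixed = NULL)
  st <- quiet_em(run_em(dat, mixture_spec(sigma_g2 = var(y))))
  ## classes 1-3 are hard to separate at null (class-2/3 sds are 1-3% of
  ## sd(y)); the defining null behaviour is that effects vanish and the
  ## large class empties
  expect_gt(st$P[1] + st$P[2], 0.7)
  expect_lt(st$P[4], 0.05)
  expect_lt(max(abs(st$v)), 0.05)
})

test_that("EM matches the scalar conjugate ridge oracle", {
  set.seed(2)
  n <- 40
  W <- matrix(rnorm(n), n, 1)
  y <- drop(W * 0.3 + rnorm(n, 0, 0.5))
  se2 <- 0.25; sg2 <- 2
  dat <- model_data(y, W = W, fixed = FALSE)
  st <- quiet_em(run_em(dat, mixture_spec(sigma_g2 = sg2),
                        fix_P = c(0, 0, 0, 1), fix_sigma_e2 = se2,
                        tol = 1e-12, max_iter = 500))
  ridge <- sum(W * y) / (sum(W * W) + se2 / (0.01 * sg2))
  expect_equal(unname(st$v), ridge, tolerance = 1e-8)
})

test_that("EM objective is non-decreasing on random instances", {
  for (s in 1:20) {
    set.seed(s)
    n <- 30; p <- 10
    W <- matrix(rnorm(n * p), n, p)
    v <- rnorm(p, 0, 0.2) * rbinom(p, 1, 0.3)
    y <- drop(W %*% v + rnorm(n))
    fixed <- if (s %% 2 == 0) NULL else FALSE
    dat <- model_data(y, W = W, fixed = fixed,
                      weights = if (s %% 3 == 0) runif(n, 0.5, 2))
    st <- quiet_em(run_em(dat, mixture_spec(sigma_g2 = 1), max_iter = 60))
    elbo <- attr(st, "elbo")
    expect_gt(length(elbo), 2)
    expect_true(all(diff(elbo) >= -1e-6 * (1 + abs(elbo[-1]))))
  }
})

test_that("zero-iteration MCMC returns the initial state with zero PIPs", {
  set.seed(3)
  dat <- model_data(rnorm(20), W = matrix(rnorm(20 * 5), 20, 5),
                    fixed = NULL)
  spec <- mixture_spec(sigma_g2 = 1)
  st <- initial_state(dat, spec)
  fit <- run_mcmc(st, dat, spec, n_iter = 0)
  expect_equal(unname(fit$v_mean), st$v)
  expect_equal(fit$pip, rep(0, 5))
  expect_equal(fit$sigma_e2, st$sigma_e2)
  expect_error(run_mcmc(st, dat, spec, n_iter = -1), "non-negative")
})

test_that("degenerate single-class Gibbs matches the conjugate closed form", {
  set.seed(4)
  n <- 50
  ## single variant
  W <- matrix(rnorm(n), n, 1)
  y <- drop(W * 0.4 + rnorm(n, 0, 0.5))
  se2 <- 0.25; sg2 <- 2; tau4 <- 0.01 * sg2
  dat <- model_data(y, W = W, fixed = FALSE)
  spec <- mixture_spec(sigma_g2 = sg2)
  st <- initial_state(dat, spec)
  st$fix_P <- c(0, 0, 0, 1); st$fix_sigma_e2 <- se2
  Tn <- 3000
  fit <- run_mcmc(st, dat, spec, n_iter = Tn, seed = 11)
  C <- sum(W * W) + se2 / tau4
  post_mean <- sum(W * y) / C
  mcse <- sqrt(se2 / C / Tn)  # independent draws here
  expect_lt(abs(fit$v_mean - post_mean), 3 * mcse)
  expect_equal(unname(fit$pip), 1)

  ## 8-variant Bayesian ridge: posterior mean vs normal-equations oracle
  p <- 8
  W8 <- matrix(rnorm(n * p), n, p)
  y8 <- drop(W8 %*% rnorm(p, 0, 0.15) + rnorm(n, 0, 0.5))
  dat8 <- model_data(y8, W = W8, fixed = FALSE)
  st8 <- initial_state(dat8, spec)
  st8$fix_P <- c(0, 0, 0, 1); st8$fix_sigma_e2 <- se2
  fit8 <- run_mcmc(st8, dat8, spec, n_iter = 6000, seed = 12)
  Cm <- crossprod(W8) + diag(se2 / tau4, p)
  mu <- solve(Cm, crossprod(W8, y8))
  sd_post <- sqrt(diag(solve(Cm)) * se2)
  ## Gibbs draws are autocorrelated; allow a conservative ESS of T/20
  expect_true(all(abs(fit8$v_mean - mu) <
                    3 * sd_post / sqrt(6000 / 20)))
})

test_that("null information yields class occupancy at the Dirichlet prior expectation", {
  set.seed(5)
  p <- 40
  dat <- model_data(rnorm(30), W = matrix(0, 30, p), fixed = NULL)
  spec <- mixture_spec(sigma_g2 = 1)
  st <- initial_state(dat, spec)
  fit <- run_mcmc(st, dat, spec, n_iter = 2000, seed = 6)
  occ <- fit$class_occupancy
  ## with zero-information columns each class has expectation p / 4 = 10
  expect_true(all(abs(occ - p / 4) < 2.5))
  ## mixing proportions stay on the simplex at every iteration
  expect_equal(unname(rowSums(fit$traces$P)), rep(1, 2000),
               tolerance = 1e-12)
})

test_that("compute_pip counts non-zero-class evidence", {
  trace <- rbind(c(4, 1, 1), c(4, 1, 2), c(4, 1, 1), c(4, 1, 3),
                 c(4, 1, 1), c(4, 1, 1), c(4, 1, 2), c(4, 1, 1),
                 c(4, 1, 1), c(4, 1, 1))
  pip <- compute_pip(trace)
  ## counting oracle
  expect_equal(pip, colMeans(trace != 1))
  expect_equal(pip[1], 1)  # class 4 every iteration
  expect_equal(pip[2], 0)  # never leaves class 1
  expect_error(compute_pip(trace[0, , drop = FALSE]), "empty")
})

test_that("drop_variants selects the lowest-PIP set with index tie-breaks", {
  dat <- model_data(rnorm(5), W = matrix(0, 5, 1000), fixed = NULL)
  spec <- mixture_spec(sigma_g2 = 1)
  st <- initial_state(dat, spec)
  set.seed(7)
  pip <- runif(1000)
  dr <- drop_variants(st, spec, pip, 0.9)
  expect_equal(sum(dr$state$active), 100)
  ## rank-threshold oracle: retained = top 100 by (pip, -index)
  oracle_keep <- order(pip, seq_along(pip), decreasing = FALSE)[901:1000]
  expect_setequal(which(dr$state$active), oracle_keep)
  ## prior compensation adds n_dropped pseudo-counts split by P
  expect_equal(sum(dr$spec$alpha) - sum(spec$alpha), 900)
  expect_equal(dr$spec$alpha - spec$alpha, 900 * st$P)

  ## ties broken by ascending variant index
  pip_t <- rep(c(0.1, 0.9), each = 500)
  dr2 <- drop_variants(st, spec, pip_t, 0.6)
  expect_equal(which(!dr2$state$active), 1:600)

  ## d = 0 is the identity
  dr0 <- drop_variants(st, spec, pip, 0)
  expect_identical(dr0$state, st)
  expect_error(drop_variants(st, spec, pip, 1), "proportion")
})

test_that("d = 0 chains are bit-identical to unscheduled runs", {
  set.seed(8)
  ds <- small_dataset(seed = 8, n_per_breed = c(HOL = 60, JER = 40),
                      n_variants = 120, n_chromosomes = 1)
  sp <- split_dataset(ds)
  spec <- mixture_spec()
  st <- quiet_em(run_em(sp$data, spec))
  f1 <- run_mcmc(st, sp$data, spec, n_iter = 150, seed = 21)
  f2 <- run_mcmc(st, sp$data, spec, n_iter = 150, seed = 21,
                 schedule = drop_schedule(0, 50))
  expect_identical(f1$v_mean, f2$v_mean)
  expect_identical(f1$traces$sigma_e2, f2$traces$sigma_e2)
  expect_identical(f1$pip, f2$pip)
})

test_that("in-chain dropping deactivates the scheduled count and zeroes effects", {
  set.seed(9)
  ds <- small_dataset(seed = 9, n_per_breed = c(HOL = 60, JER = 40),
                      n_variants = 200, n_chromosomes = 1)
  sp <- split_dataset(ds)
  spec <- mixture_spec()
  st <- quiet_em(run_em(sp$data, spec))
  p <- ncol(sp$data$W)
  fit <- run_mcmc(st, sp$data, spec, n_iter = 200, seed = 31,
                  schedule = drop_schedule(0.9, 100))
  expect_equal(sum(fit$active), p - round(0.9 * p))
  expect_true(all(fit$v_mean[fit$dropped] == 0))
  expect_true(all(is.na(fit$pip[fit$dropped])))
  expect_true(all(!is.na(fit$pip_at_drop[fit$dropped])))
  ## compensation accounted the dropped count as pseudo-counts
  expect_equal(sum(fit$alpha_final) - 4, fit$n_dropped)

  ## dropping after the EM warm start uses EM responsibilities
  fit_em <- run_mcmc(st, sp$data, spec, n_iter = 100, seed = 32,
                     schedule = drop_schedule(0.5, "em"))
  expect_equal(sum(fit_em$active), p - round(0.5 * p))
  em_pip <- compute_pip(st)
  worst <- order(em_pip, seq_len(p))[seq_len(round(0.5 * p))]
  expect_setequal(which(fit_em$dropped), worst)
})

test_that("planted high-PIP QTL survive a 50% drop", {
  set.seed(10)
  n <- 150; p <- 80
  W <- matrix(rbinom(n * p, 2, 0.5), n, p)
  qtl <- seq(5, 80, by = 16)  # 5 planted large QTL
  v <- rep(0, p); v[qtl] <- 0.8
  y <- drop(W %*% v + rnorm(n, 0, 1))
  dat <- model_data(y, W = sweep(W, 2, colMeans(W)), fixed = NULL)
  spec <- mixture_spec(sigma_g2 = var(y) * 0.6)
  fit <- quiet_em(bayesr_hybrid(dat, spec, n_iter = 400, seed = 41,
                                schedule = drop_schedule(0.5, 200)))
  expect_true(all(fit$active[qtl]))
  expect_true(all(fit$pip[qtl] > 0.9))
})

test_that("class occupancy is conserved across a drop event", {
  set.seed(12)
  ds <- small_dataset(seed = 12, n_per_breed = c(HOL = 80, JER = 60),
                      n_variants = 250, n_chromosomes = 1)
  sp <- split_dataset(ds)
  spec <- mixture_spec()
  st <- quiet_em(run_em(sp$data, spec))
  fit <- run_mcmc(st, sp$data, spec, n_iter = 800, seed = 51,
                  schedule = drop_schedule(0.7, 400))
  occ <- fit$traces$occupancy
  pre <- colMeans(occ[200:400, ])    # settled pre-drop window
  post <- colMeans(occ[401:800, ])
  absorbed <- fit$alpha_final - c(1, 1, 1, 1)  # n_dropped * P at drop
  ## expected class-2..4 occupancy: active posterior + prior-absorbed mass
  pre24 <- sum(pre[2:4])
  post24 <- sum(post[2:4]) + sum(absorbed[2:4])
  expect_lt(abs(post24 - pre24), 0.35 * pre24 + 5)
})

test_that("variance components: zero fit gives zeros, identity holds", {
  set.seed(13)
  dat <- model_data(rnorm(30), W = matrix(rnorm(30 * 10), 30, 10),
                    fixed = NULL)
  spec <- mixture_spec(sigma_g2 = 1)
  fit0 <- run_mcmc(initial_state(dat, spec), dat, spec, n_iter = 0)
  expect_equal(unname(fit0$varcomp[c("h_M2", "h_A2", "h2")]), c(0, 0, 0))

  fit <- run_mcmc(initial_state(dat, spec), dat, spec, n_iter = 50,
                  seed = 61)
  vc <- fit$varcomp
  expect_equal(vc[["h2"]], vc[["h_M2"]] + vc[["h_A2"]])
  expect_error(variance_components(fit, model_data(rep(1, 5),
                                                   W = matrix(0, 5, 2),
                                                   fixed = NULL)),
               "zero phenotypic variance")
})

test_that("polygenic term recovers family structure through A", {
  ## 20 sires x 8 progeny each; phenotype = polygenic + noise
  set.seed(14)
  n_sires <- 20; n_prog <- 8
  sires <- paste0("s", 1:n_sires)
  kids <- paste0("k", 1:(n_sires * n_prog))
  ped <- data.frame(id = c(sires, kids),
                    sire = c(rep("0", n_sires), rep(sires, each = n_prog)),
                    dam = "0")
  sped <- sort_pedigree(ped)
  A <- build_A(sped)
  sa2 <- 2; se2 <- 1
  L <- chol(A + diag(1e-8, nrow(A)))
  a_true <- drop(t(L) %*% rnorm(nrow(A))) * sqrt(sa2)
  names(a_true) <- rownames(A)
  y <- a_true[kids] + rnorm(length(kids), 0, sqrt(se2))
  dat <- model_data(y, W = matrix(0, length(kids), 2), fixed = NULL,
                    pedigree = sped, ids = kids)
  spec <- mixture_spec(sigma_g2 = 1)
  st <- quiet_em(run_em(dat, spec))
  fit <- run_mcmc(st, dat, spec, n_iter = 800, seed = 71)
  ## posterior mean polygenic values track the simulated ones
  expect_gt(cor(fit$a_mean, a_true), 0.55)
  expect_gt(fit$sigma_a2, 0.5)
  expect_lt(fit$sigma_a2, 6)
})

test_that("EM effects are permutation-equivariant", {
  set.seed(15)
  n <- 40; p <- 12
  W <- matrix(rnorm(n * p), n, p)
  y <- drop(W[, 3] * 0.8 + rnorm(n))
  dat <- model_data(y, W = W, fixed = NULL)
  spec <- mixture_spec(sigma_g2 = 1)
  st <- quiet_em(run_em(dat, spec, tol = 1e-10, max_iter = 300))
  perm <- sample(p)
  dat2 <- model_data(y, W = W[, perm], fixed = NULL)
  st2 <- quiet_em(run_em(dat2, spec, tol = 1e-10, max_iter = 300))
  expect_equal(unname(st2$v), unname(st$v[perm]), tolerance = 1e-5)
  expect_equal(compute_pip(st2), compute_pip(st)[perm], tolerance = 1e-5)
})
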