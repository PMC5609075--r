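## one shared small dataset for the strategy equivalences
strat_ds <- small_dataset(seed = 17)
strat_sp <- split_dataset(strat_ds)
strat_spec <- mixture_spec()

test_that("run_full is deterministic under a fixed config and seed", {
  cfg <- scenario_config("S_FULL", d = 0, n_iter = 120, seed = 77)
  r1 <- quiet_em(run_full(strat_sp$data, strat_spec, cfg,
                          validation = strat_sp$validation))
  r2 <- quiet_em(run_full(strat_sp$data, strat_spec, cfg,
                          validation = strat_sp$validation))
  expect_identical(r1$gebv, r2$gebv)
  expect_identical(r1$fit$v_mean, r2$fit$v_mean)
})

test_that("post-drop phase leaves only the retained fraction active", {
  cfg <- scenario_config("S_FULL", d = 0.9, drop_after = 150,
                         n_iter = 150, seed = 78)
  res <- quiet_em(run_full(strat_sp$data, strat_spec, cfg))
  p <- ncol(strat_sp$data$W)
  expect_equal(length(res$retained), p - round(0.9 * p))
  expect_true(all(res$effects$effect[res$effects$dropped] == 0))
  ## drop at the chain end extends the run by a post-drop phase
  expect_equal(res$fit$n_iter_total, 300)
  expect_equal(res$fit$n_window, 150)
})

test_that("KEPT with identity selection reproduces FULL bit-for-bit", {
  cfg <- scenario_config("S_FULL", d = 0, n_iter = 100, seed = 79)
  full <- quiet_em(run_full(strat_sp$data, strat_spec, cfg,
                            validation = strat_sp$validation))
  kept <- quiet_em(run_kept(strat_sp$data, strat_spec, cfg,
                            selection = strat_sp$data$map$id,
                            validation = strat_sp$validation))
  expect_identical(kept$fit$v_mean, full$fit$v_mean)
  expect_identical(kept$gebv, full$gebv)
  expect_error(run_kept(strat_sp$data, strat_spec, cfg, character(0)),
               "empty")
})

test_that("single-chromosome CHR -> KEPT with d = 0 reproduces FULL exactly", {
  ds1 <- small_dataset(seed = 18, n_variants = 200, n_chromosomes = 1)
  sp1 <- split_dataset(ds1)
  cfg <- scenario_config("S_CHR", d = 0, n_iter = 100, seed = 80)
  ## HD effects: zero-effect table over the HD variants (single chromosome,
  ## so the cross-chromosome correction is vacuous)
  hd_ids <- sp1$data$map$id[ds1$panel$map$class[match(sp1$data$map$id,
                                                      ds1$panel$map$id)] == "HD"]
  hd_eff <- data.frame(id = hd_ids, effect = 0,
                       center = sp1$data$centers[match(hd_ids,
                                                       sp1$data$map$id)])
  chr <- quiet_em(run_per_chromosome(sp1$data, strat_spec, cfg, hd_eff))
  expect_setequal(chr$retained, sp1$data$map$id)
  kept <- quiet_em(run_kept(sp1$data, strat_spec, cfg, chr$retained,
                            validation = sp1$validation))
  full <- quiet_em(run_full(sp1$data, strat_spec, cfg,
                            validation = sp1$validation))
  expect_identical(kept$gebv, full$gebv)
})

test_that("per-chromosome phenotype correction matches the algebraic oracle", {
  ds2 <- small_dataset(seed = 19, n_variants = 120, n_chromosomes = 2)
  sp2 <- split_dataset(ds2)
  dat <- sp2$data
  ## synthetic HD effect table covering both chromosomes
  hd_idx <- which(seq_len(ncol(dat$W)) %% 4 == 0)
  hd_eff <- data.frame(id = dat$map$id[hd_idx],
                       effect = rnorm(length(hd_idx), 0, 0.05),
                       center = dat$centers[hd_idx])
  contrib <- seqbayesr:::hd_contributions(dat, hd_eff)
  ## oracle: corrected phenotype for chr 1 removes chr-2 HD contributions
  on2 <- hd_idx[dat$map$chrom[hd_idx] == 2]
  y1_oracle <- dat$y - unname(drop(dat$W[, on2, drop = FALSE] %*%
                                     hd_eff$effect[match(dat$map$id[on2],
                                                         hd_eff$id)]))
  expect_equal(unname(dat$y - (rowSums(contrib) - contrib[, "1"])),
               y1_oracle, tolerance = 1e-12)
  expect_error(run_per_chromosome(dat, strat_spec,
                                  scenario_config("S_CHR", n_iter = 10),
                                  data.frame(id = "nope", effect = 1,
                                             center = 0)),
               "absent")
})

test_that("chromosomes are independently runnable with order-invariant results", {
  ds2 <- small_dataset(seed = 20, n_variants = 160, n_chromosomes = 2)
  sp2 <- split_dataset(ds2)
  cfg <- scenario_config("S_CHR", d = 0.7, drop_after = 80, n_iter = 80,
                         seed = 81)
  hd_idx <- which(seq_len(ncol(sp2$data$W)) %% 5 == 0)
  hd_eff <- data.frame(id = sp2$data$map$id[hd_idx], effect = 0,
                       center = sp2$data$centers[hd_idx])
  chr <- quiet_em(run_per_chromosome(sp2$data, strat_spec, cfg, hd_eff))
  ## re-run chromosome 2 alone from its child seed: identical sub-fit
  vidx <- which(sp2$data$map$chrom == 2)
  contrib <- seqbayesr:::hd_contributions(sp2$data, hd_eff)
  y2 <- sp2$data$y - (rowSums(contrib) - contrib[, "2"])
  sub <- seqbayesr:::subset_model_data(sp2$data, vidx, y = y2)
  st <- quiet_em(run_em(sub, strat_spec))
  alone <- run_mcmc(st, sub, strat_spec, n_iter = 80,
                    schedule = drop_schedule(0.7, 80),
                    seed = seqbayesr:::child_seed(81, 2))
  expect_identical(alone$v_mean, chr$fits[["2"]]$v_mean)
})

test_that("run_kept rescales prior pseudo-counts to the retained count", {
  cfg <- scenario_config("S_KEPT", d = 0, n_iter = 30, seed = 82)
  sel <- strat_sp$data$map$id[1:50]
  counts <- c(300, 60, 30, 10)
  kept <- quiet_em(run_kept(strat_sp$data, strat_spec, cfg, sel,
                            prior_counts = counts))
  ## normalization audit: alpha passed downstream sums to |selection|
  a0 <- kept$fit$alpha_final  # d = 0, so alpha unchanged during the chain
  expect_equal(sum(a0), 50)
  expect_equal(a0 / sum(a0), counts / sum(counts), tolerance = 1e-9)
})

test_that("KEPT+HD takes the union; selection inside HD collapses to HD", {
  cfg <- scenario_config("S_KEPT_HD", d = 0, n_iter = 40, seed = 83)
  ids <- strat_sp$data$map$id
  hd_ids <- ids[seq(1, length(ids), by = 3)]
  sel <- hd_ids[1:10]  # subset of HD
  u1 <- quiet_em(run_kept_plus_hd(strat_sp$data, strat_spec, cfg, sel,
                                  hd_ids))
  u2 <- quiet_em(run_kept(strat_sp$data, strat_spec, cfg, hd_ids))
  expect_identical(u1$fit$v_mean, u2$fit$v_mean)

  ## set-arithmetic oracle on a partially overlapping selection
  sel2 <- ids[c(2, 3, 4, 7)]
  u3 <- quiet_em(run_kept_plus_hd(strat_sp$data, strat_spec,
                                  scenario_config("S_KEPT_HD", d = 0,
                                                  n_iter = 10, seed = 1),
                                  sel2, hd_ids))
  expect_equal(length(u3$fit$v_mean),
               length(sel2) + length(hd_ids) -
                 length(intersect(sel2, hd_ids)))
  expect_error(run_kept_plus_hd(strat_sp$data, strat_spec, cfg, sel2,
                                c("ghost")), "absent")
})
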