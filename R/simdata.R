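#' Simulate a multi-breed haplotype panel
#'
#' Generates phased haplotypes for one or more breeds that share an ancestral
#' allele-frequency spectrum. Breed divergence is induced by Balding-Nichols
#' drift: breed frequencies are drawn from a Beta distribution centred on the
#' ancestral frequency with F-coefficient `divergence`, so the expected
#' Hudson F_ST between any two breeds equals `divergence` (plus a small
#' founder-sampling term of order `1 / n_founders`). Within-breed LD has two
#' sources: (i) founder haplotypes are generated with an AR(1) Gaussian
#' copula along each chromosome, giving allelic correlation that decays with
#' physical distance (scale `ld_scale` bp), and (ii) individual haplotypes
#' are recombinant mosaics of the breed's founder pool, switching founders at
#' rate `recomb_rate` per bp.
#'
#' @param n_per_breed named integer vector, individuals per breed.
#' @param n_variants total number of variants (split evenly over
#'   chromosomes).
#' @param n_chromosomes number of chromosomes.
#' @param divergence F_ST-like drift parameter in \[0, 0.5).
#' @param recomb_rate recombination rate per bp (default 1e-8, about one
#'   crossover per 100-Mb chromosome).
#' @param n_founders founder haplotypes per breed (default 100).
#' @param chrom_length chromosome length in bp (default 1e8).
#' @param ld_scale decay length (bp) of the founder-level AR(1) allele
#'   correlation (default 2.5e5).
#' @param freq_range range of ancestral allele frequencies (uniform draw).
#' @param seed optional integer seed; fixed seed gives a bit-identical panel.
#' @return a [hap_panel].
#' @export
simulate_panel <- function(n_per_breed, n_variants, n_chromosomes = 1,
                           divergence = 0.1, recomb_rate = 1e-8,
                           n_founders = 100, chrom_length = 1e8,
                           ld_scale = 2.5e5, freq_range = c(0.05, 0.95),
                           seed = NULL) {
  if (any(n_per_breed < 1)) stop("breed counts must be >= 1")
  if (n_variants < 1) stop("variant count must be positive")
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(n_per_breed)))
    names(n_per_breed) <- LETTERS[seq_along(n_per_breed)]

  ## variant map: even split over chromosomes, strictly increasing positions
  chrom <- sort(rep_len(seq_len(n_chromosomes), n_variants))
  pos <- integer(n_variants)
  for (ch in seq_len(n_chromosomes)) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(chrom_length, length(idx)))
  }
  p0 <- stats::runif(n_variants, freq_range[1], freq_range[2])

  breeds <- names(n_per_breed)
  hap_list <- vector("list", length(breeds))
  for (b in seq_along(breeds)) {
    ## breed-level drifted frequencies (Balding-Nichols)
    if (divergence > 0) {
      k <- (1 - divergence) / divergence
      pb <- stats::rbeta(n_variants, p0 * k, (1 - p0) * k)
    } else pb <- p0
    thr <- stats::qnorm(pb)  # latent threshold giving marginal freq pb

    ## founder haplotypes with AR(1) latent correlation along each chromosome
    fh <- matrix(0L, n_founders, n_variants)
    for (ch in seq_len(n_chromosomes)) {
      idx <- which(chrom == ch)
      rho <- exp(-diff(pos[idx]) / ld_scale)
      u <- matrix(0, n_founders, length(idx))
      u[, 1] <- stats::rnorm(n_founders)
      for (j in seq_along(rho))
        u[, j + 1] <- rho[j] * u[, j] +
          sqrt(1 - rho[j]^2) * stats::rnorm(n_founders)
      fh[, idx] <- (u < rep(thr[idx], each = n_founders)) + 0L
    }

    ## individual haplotypes: recombinant founder mosaics
    H <- 2L * n_per_breed[b]
    hap <- matrix(0L, H, n_variants)
    for (ch in seq_len(n_chromosomes)) {
      idx <- which(chrom == ch)
      pc <- length(idx)
      gap_pr <- 1 - exp(-recomb_rate * diff(pos[idx]))
      ## switch indicator per haplotype per interval; cumulate column-wise
      sw <- matrix(0L, H, pc)
      if (pc > 1)
        sw[, -1] <- (matrix(stats::runif(H * (pc - 1)), H) <
                       rep(gap_pr, each = H)) + 0L
      seg <- sw  # becomes the segment index per (hap, variant)
      for (j in seq_len(pc)[-1]) seg[, j] <- seg[, j - 1L] + sw[, j]
      max_seg <- max(seg)
      founder_draw <- matrix(sample.int(n_founders, H * (max_seg + 1L),
                                        replace = TRUE), H)
      fid <- founder_draw[cbind(rep(seq_len(H), pc),
                                as.vector(seg) + 1L)]
      hap[, idx] <- fh[cbind(fid, rep(idx, each = H))]
    }
    hap_list[[b]] <- hap
  }

  hap <- do.call(rbind, hap_list)
  breed <- rep(breeds, times = n_per_breed)
  map <- data.frame(id = paste0("v", seq_len(n_variants)), chrom = chrom,
                    pos = pos, ancestral_freq = p0)
  hap_panel(hap, breed, map)
}

#' Collapse haplotypes to genotype dosages
#'
#' Dosage of each individual is the sum of its two haplotype alleles; MAF is
#' computed over all individuals in the panel.
#'
#' @param panel a [hap_panel].
#' @return a [geno_panel] (annotation class `OTHER` until assigned).
#' @export
genotypes_from_haplotypes <- function(panel) {
  stopifnot(inherits(panel, "hap_panel"))
  n <- nrow(panel$hap) / 2L
  odd <- seq(1L, 2L * n, by = 2L)
  dos <- panel$hap[odd, , drop = FALSE] + panel$hap[odd + 1L, , drop = FALSE]
  geno_panel(dos, panel$map, breed = panel$breed,
             sex = rep("F", n))
}

#' Sample a QTL architecture
#'
#' Draws QTL without replacement from the panel's variants and assigns
#' additive effects from mean-zero normal distributions with class variances
#' 1e-4, 1e-3 and 1e-2 times `sigma_g2` for small, medium and large QTL.
#' Defaults give the 4000-QTL architecture (3485 small, 500 medium, 15
#' large).
#'
#' @param panel a [geno_panel].
#' @param n_small,n_medium,n_large QTL counts per size class.
#' @param sigma_g2 additive genetic variance scaling the class variances.
#' @param exclude_classes annotation classes QTL may not fall in (e.g. `"HD"`
#'   to keep causal variants off the HD chip).
#' @param seed optional integer seed.
#' @return a `qtl_set` data.frame with columns `index`, `id`, `class`,
#'   `effect`.
#' @export
sample_qtl <- function(panel, n_small = 3485, n_medium = 500, n_large = 15,
                       sigma_g2 = 1, exclude_classes = NULL, seed = NULL) {
  stopifnot(inherits(panel, "geno_panel"))
  if (!is.null(seed)) set.seed(seed)
  pool <- seq_len(ncol(panel$dosage))
  if (!is.null(exclude_classes))
    pool <- pool[!(panel$map$class %in% exclude_classes)]
  n_tot <- n_small + n_medium + n_large
  if (n_tot > length(pool))
    stop("requested QTL count exceeds the number of eligible variants")
  counts <- c(small = n_small, medium = n_medium, large = n_large)
  vars <- c(small = 1e-4, medium = 1e-3, large = 1e-2) * sigma_g2
  idx <- if (n_tot > 0) sample(pool, n_tot) else integer(0)
  cls <- rep(names(counts), times = counts)
  eff <- stats::rnorm(n_tot, 0, sqrt(vars[cls]))
  out <- data.frame(index = idx, id = panel$map$id[idx], class = cls,
                    effect = eff, stringsAsFactors = FALSE)
  class(out) <- c("qtl_set", "data.frame")
  out
}

#' True breeding values from a QTL set
#'
#' `TBV_j = sum_i x_ij a_i` over the QTL, where `x_ij` is the raw dosage.
#'
#' @param panel a [geno_panel].
#' @param qtl a `qtl_set` from [sample_qtl()].
#' @return numeric vector of TBVs, one per individual.
#' @export
compute_tbv <- function(panel, qtl) {
  stopifnot(inherits(panel, "geno_panel"))
  if (nrow(qtl) == 0) return(rep(0, nrow(panel$dosage)))
  if (any(qtl$index < 1 | qtl$index > ncol(panel$dosage)))
    stop("QTL indices out of range")
  drop(panel$dosage[, qtl$index, drop = FALSE] %*% qtl$effect)
}

#' Simulate phenotypes at a target heritability
#'
#' Environmental deviations are sampled from
#' `N(0, var_w(TBV) * (1 - h2) / h2)` where `var_w(TBV)` is the pooled
#' within-breed variance of the TBVs, so the target `h2` is a within-breed
#' heritability (the breed effect is modelled separately, as in dairy-style
#' multi-breed data). Breed effects are drawn from per-breed normal
#' distributions; the default draws one effect per breed per call (a breed
#' mean), `draw = "per_individual"` draws one per individual.
#'
#' @param tbv numeric vector of true breeding values.
#' @param h2 target heritability in (0, 1].
#' @param breed character vector of breed labels, same length as `tbv`.
#' @param breed_effect_spec named list `breed -> c(mean, sd)`; breeds absent
#'   from the list get effect 0. Default: Holstein-analog `HOL = c(10, 1)`.
#' @param draw `"per_breed"` (one draw shared by all members of a breed) or
#'   `"per_individual"`.
#' @param seed optional integer seed.
#' @return a `trait_sim` data.frame with columns `tbv`, `env`,
#'   `breed_effect`, `phenotype` (= tbv + env + breed_effect exactly) and
#'   `breed`; attribute `h2` stores the target.
#' @export
simulate_phenotype <- function(tbv, h2 = 0.6, breed = rep("A", length(tbv)),
                               breed_effect_spec = list(HOL = c(10, 1)),
                               draw = c("per_breed", "per_individual"),
                               seed = NULL) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  draw <- match.arg(draw)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tbv)
  stopifnot(length(breed) == n)

  var_w <- pooled_within_var(tbv, breed)
  env <- if (h2 == 1) rep(0, n) else
    stats::rnorm(n, 0, sqrt(var_w * (1 - h2) / h2))

  be <- rep(0, n)
  for (b in names(breed_effect_spec)) {
    sel <- breed == b
    if (!any(sel)) next
    ms <- breed_effect_spec[[b]]
    be[sel] <- if (draw == "per_breed") stats::rnorm(1, ms[1], ms[2]) else
      stats::rnorm(sum(sel), ms[1], ms[2])
  }

  out <- data.frame(breed = breed, tbv = tbv, env = env, breed_effect = be,
                    phenotype = tbv + env + be, stringsAsFactors = FALSE)
  attr(out, "h2") <- h2
  class(out) <- c("trait_sim", "data.frame")
  out
}

pooled_within_var <- function(x, group) {
  ss <- 0; df <- 0
  for (g in unique(group)) {
    xi <- x[group == g]
    if (length(xi) > 1) {
      ss <- ss + sum((xi - mean(xi))^2)
      df <- df + length(xi) - 1
    }
  }
  if (df == 0) stats::var(x) else ss / df
}

#' MAF-dependent allele-error model
#'
#' Imputation-style genotype errors: each of the two alleles of a genotype is
#' flipped independently with probability `e = r / sqrt(MAF)` (capped at 1),
#' so rare variants are more error-prone. `target` selects which population
#' the errors are injected into.
#'
#' @param r error rate parameter, `r >= 0`. The stated grid is 0.0013,
#'   0.0027, 0.0066, 0.0132, 0.0264.
#' @param target `"reference"`, `"validation"` or `"both"`.
#' @return an `error_model` object.
#' @export
error_model <- function(r, target = c("both", "reference", "validation")) {
  if (r < 0) stop("r must be non-negative")
  structure(list(r = r, target = match.arg(target)), class = "error_model")
}

#' Per-variant allele error probability
#'
#' @param model an [error_model].
#' @param maf vector of minor allele frequencies (must be > 0).
#' @return vector of flip probabilities `min(r / sqrt(maf), 1)`.
#' @export
error_prob <- function(model, maf) {
  stopifnot(inherits(model, "error_model"))
  if (any(maf <= 0)) stop("error model needs MAF > 0; filter first")
  pmin(model$r / sqrt(maf), 1)
}

#' Inject allele-level genotype errors into a panel
#'
#' Each genotype's two alleles are flipped independently with the variant's
#' error probability computed from the *pre-error* panel MAF. Only
#' individuals in `individuals` (default: all, i.e. the model's target
#' population resolved by the caller) are perturbed; the input panel is not
#' modified.
#'
#' @param panel a [geno_panel].
#' @param model an [error_model].
#' @param individuals integer/logical index of individuals to perturb
#'   (default all).
#' @param maf per-variant MAF used in the error formula; defaults to the
#'   panel's own (pre-error) MAF. Supplying the full-panel MAF keeps the
#'   error model on true frequencies when perturbing a subpopulation or
#'   an already-perturbed panel.
#' @param seed optional integer seed.
#' @return a new [geno_panel] with perturbed dosages (MAF recomputed).
#' @export
inject_errors <- function(panel, model, individuals = NULL, maf = NULL,
                          seed = NULL) {
  stopifnot(inherits(panel, "geno_panel"), inherits(model, "error_model"))
  if (!is.null(seed)) set.seed(seed)
  if (model$r == 0) return(panel)
  e <- error_prob(model, maf %||% panel$map$maf)
  dos <- panel$dosage
  if (is.null(individuals)) individuals <- seq_len(nrow(dos))
  sub <- dos[individuals, , drop = FALSE]
  n <- nrow(sub); p <- ncol(sub)
  em <- matrix(rep(e, each = n), n, p)
  ## flips of '1' alleles (1 -> 0) and of '0' alleles (0 -> 1)
  f1 <- matrix(stats::rbinom(n * p, as.vector(sub), as.vector(em)), n, p)
  f0 <- matrix(stats::rbinom(n * p, 2L - as.vector(sub), as.vector(em)), n, p)
  dos[individuals, ] <- sub - f1 + f0
  geno_panel(dos, panel$map[setdiff(names(panel$map), "maf")],
             breed = panel$breed, sex = panel$sex)
}

#' Simulate a complete multi-breed dataset
#'
#' Convenience wrapper tying the generators together: haplotype panel ->
#' genotypes -> annotation classes -> QTL -> TBV -> phenotypes. Defaults
#' emulate the stated simulation world: heritability 0.6, Holstein-analog
#' breed effect N(10, 1), the 3485/500/15 QTL architecture (scaled via the
#' `qtl` argument for desk-size runs), breed divergence 0.1.
#'
#' @param n_per_breed named integer vector of individuals per breed; the
#'   default 2-breed panel has a Holstein-analog (`HOL`) majority.
#' @param n_variants,n_chromosomes,divergence passed to [simulate_panel()].
#' @param qtl list with `n_small`, `n_medium`, `n_large` (default full
#'   3485/500/15 architecture) and optional `exclude_classes`.
#' @param h2 target within-breed heritability.
#' @param breed_effect_spec see [simulate_phenotype()].
#' @param class_props annotation class proportions, see [assign_classes()].
#' @param min_maf MAF filter applied before QTL sampling (default 0.0002,
#'   the sequence-panel filter); monomorphic variants are always removed.
#' @param seed integer seed driving the whole generation.
#' @param ... further arguments to [simulate_panel()].
#' @return list with `panel` ([geno_panel]), `qtl`, `trait` (`trait_sim`),
#'   and `pedigree` (founders-only pedigree data.frame).
#' @export
simulate_dataset <- function(n_per_breed = c(HOL = 1200, JER = 800),
                             n_variants = 4500, n_chromosomes = 5,
                             divergence = 0.1,
                             qtl = list(n_small = 3485, n_medium = 500,
                                        n_large = 15),
                             h2 = 0.6,
                             breed_effect_spec = list(HOL = c(10, 1)),
                             class_props = c(NSC = 0.045, REG = 0.583,
                                             HD = 0.372),
                             min_maf = 2e-4, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  hp <- simulate_panel(n_per_breed, n_variants, n_chromosomes, divergence,
                       ...)
  panel <- genotypes_from_haplotypes(hp)
  panel <- maf_filter(panel, max(min_maf, .Machine$double.eps))
  panel <- assign_classes(panel, class_props)
  qs <- sample_qtl(panel, n_small = qtl$n_small, n_medium = qtl$n_medium,
                   n_large = qtl$n_large,
                   exclude_classes = qtl$exclude_classes)
  tbv <- compute_tbv(panel, qs)
  trait <- simulate_phenotype(tbv, h2 = h2, breed = panel$breed,
                              breed_effect_spec = breed_effect_spec)
  trait$id <- rownames(panel$dosage)
  ped <- data.frame(id = rownames(panel$dosage), sire = "0", dam = "0",
                    stringsAsFactors = FALSE)
  list(panel = panel, qtl = qs, trait = trait, pedigree = ped)
}
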