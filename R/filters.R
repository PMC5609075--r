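#' Minor-allele-frequency filter
#'
#' Removes variants whose MAF is strictly below `min_maf` (a literal
#' "lower than" rule, so a variant exactly at the threshold is kept).
#' Variant order is preserved. The conventional thresholds are 0.0002 for
#' the simulated sequence panel and 0.002 for real-data panels.
#'
#' @param panel a [geno_panel].
#' @param min_maf threshold; 0 is the identity.
#' @return filtered [geno_panel].
#' @export
maf_filter <- function(panel, min_maf) {
  stopifnot(inherits(panel, "geno_panel"))
  keep <- which(panel$map$maf >= min_maf)
  if (length(keep) == ncol(panel$dosage)) return(panel)
  subset_panel(panel, variants = keep)
}

#' Annotation-tiered LD pruning
#'
#' Two-phase greedy pruning of variants in high LD (squared Pearson
#' correlation of dosages above `r2_max`):
#'
#' 1. *Within-tier*: for each annotation class separately, a sliding window
#'    of `window` variants advancing by `step` removes, from every pair with
#'    `r^2 > r2_max`, the later-positioned variant.
#' 2. *Cross-tier*: REG variants are removed when exceeding `r2_max` against
#'    a retained NSC variant; HD variants against a retained NSC or REG
#'    variant; OTHER variants against a retained NSC variant.
#'
#' Monomorphic pairs have undefined correlation and are never pruned against
#' each other (their r^2 is treated as 0). Deterministic for a given panel.
#'
#' @param panel a [geno_panel] with annotation classes assigned.
#' @param r2_max prune threshold in (0, 1]; pairs with r^2 strictly above it
#'   conflict (default 0.9).
#' @param tier_order annotation priority, highest first.
#' @param window,step greedy window size and step, in variants.
#' @return pruned [geno_panel] (variant order preserved).
#' @export
ld_prune <- function(panel, r2_max = 0.9,
                     tier_order = c("NSC", "REG", "HD", "OTHER"),
                     window = 50, step = 5) {
  stopifnot(inherits(panel, "geno_panel"))
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must be in (0, 1]")
  if (!all(panel$map$class %in% tier_order))
    stop("unknown annotation class")
  dos <- panel$dosage
  map <- panel$map
  keep <- rep(TRUE, ncol(dos))

  ## phase 1: within-tier windowed pruning, per chromosome
  for (tier in tier_order) {
    for (ch in unique(map$chrom)) {
      idx <- which(map$class == tier & map$chrom == ch & keep)
      keep[idx] <- prune_window(dos, idx, r2_max, window, step)
    }
  }

  ## phase 2: cross-tier rules (lower tier pruned against retained higher)
  cross <- list(REG = "NSC", HD = c("NSC", "REG"), OTHER = "NSC")
  for (tier in intersect(tier_order, names(cross))) {
    against <- cross[[tier]]
    for (ch in unique(map$chrom)) {
      lo <- which(map$class == tier & map$chrom == ch & keep)
      hi <- which(map$class %in% against & map$chrom == ch & keep)
      if (!length(lo) || !length(hi)) next
      r2 <- suppressWarnings(stats::cor(dos[, lo, drop = FALSE],
                                        dos[, hi, drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      keep[lo[apply(r2 > r2_max, 1, any)]] <- FALSE
    }
  }
  subset_panel(panel, variants = which(keep))
}

## greedy windowed pruning over the variant indices `idx` (position order);
## returns logical keep-vector aligned with idx
prune_window <- function(dos, idx, r2_max, window, step) {
  m <- length(idx)
  keep <- rep(TRUE, m)
  if (m < 2) return(keep)
  start <- 1
  repeat {
    end <- min(start + window - 1, m)
    act <- which(keep[start:end]) + start - 1
    if (length(act) > 1) {
      r2 <- suppressWarnings(stats::cor(dos[, idx[act], drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      for (a in seq_along(act)) {
        if (!keep[act[a]]) next
        for (b in seq_len(a - 1)) {
          if (keep[act[b]] && r2[a, b] > r2_max) {
            keep[act[a]] <- FALSE  # later-positioned variant removed
            break
          }
        }
      }
    }
    if (end == m) break
    start <- start + step
  }
  keep
}
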