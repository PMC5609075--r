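## Shared fixtures and independent oracles, all built in code.

## small random genotype panel with given dimensions
toy_panel <- function(n = 20, p = 50, seed = 1, maf_min = 0.1,
                      n_chromosomes = 1, breed = NULL) {
  set.seed(seed)
  f <- runif(p, maf_min, 1 - maf_min)
  dos <- sapply(f, function(pf) rbinom(n, 2, pf))
  chrom <- sort(rep_len(seq_len(n_chromosomes), p))
  pos <- unlist(lapply(split(seq_len(p), chrom),
                       function(i) sort(sample.int(1e6, length(i)))))
  geno_panel(dos, data.frame(id = paste0("v", 1:p), chrom = chrom,
                             pos = unname(pos)),
             breed = breed)
}

## Hudson F_ST estimator from allele counts (ratio-of-averages form)
hudson_fst <- function(hap, breed, b1, b2) {
  ib <- rep(breed, each = 2)
  h1 <- hap[ib == b1, , drop = FALSE]
  h2 <- hap[ib == b2, , drop = FALSE]
  n1 <- nrow(h1); n2 <- nrow(h2)
  p1 <- colMeans(h1); p2 <- colMeans(h2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

## recursive coancestry (kinship) oracle; A = 2 * phi
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  memo <- new.env()
  phi <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == j) 0.5 * (1 + phi(si[i], di[i])) else
      0.5 * (phi(i, si[j]) + phi(i, di[j]))
    memo[[key]] <- v
    v
  }
  A <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) A[i, j] <- A[j, i] <- 2 * phi(i, j)
  dimnames(A) <- list(ped$id, ped$id)
  A
}

## random valid pedigree: founders plus descendants with parents drawn
## from earlier individuals
random_pedigree <- function(n = 50, n_founders = 10, seed = 1) {
  set.seed(seed)
  id <- paste0("a", 1:n)
  sire <- dam <- rep("0", n)
  for (j in (n_founders + 1):n) {
    pp <- sample(j - 1, 2)
    sire[j] <- id[pp[1]]; dam[j] <- id[pp[2]]
  }
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

## small simulated multi-breed dataset for strategy tests
small_dataset <- function(seed = 5, n_per_breed = c(HOL = 120, JER = 80,
                                                    RED = 60),
                          n_variants = 400, n_chromosomes = 2,
                          qtl = list(n_small = 15, n_medium = 6,
                                     n_large = 3)) {
  simulate_dataset(n_per_breed = n_per_breed, n_variants = n_variants,
                   n_chromosomes = n_chromosomes, qtl = qtl, seed = seed)
}

## model_data + validation split for a simulated dataset
split_dataset <- function(ds, train_breeds = c("HOL", "JER")) {
  tr <- ds$panel$breed %in% train_breeds
  dat <- model_data(ds$trait$phenotype[tr],
                    panel = subset_panel(ds$panel, which(tr)),
                    fixed = data.frame(breed = ds$panel$breed[tr]))
  list(data = dat,
       validation = if (any(!tr)) subset_panel(ds$panel, which(!tr)),
       tbv_val = ds$trait$tbv[!tr],
       train = which(tr))
}

quiet_em <- function(expr) suppressWarnings(expr)
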