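#' Haplotype panel container
#'
#' Holds phased binary haplotypes for a set of diploid individuals together
#' with per-individual breed labels and per-variant map information. Rows
#' `2i - 1` and `2i` of the haplotype matrix are the two haplotypes of
#' individual `i`.
#'
#' @param hap integer matrix of 0/1 alleles, `2 * n_ind` rows, one column per
#'   variant.
#' @param breed character or factor of length `n_ind`.
#' @param map data.frame with columns `id`, `chrom` (integer >= 1), `pos`
#'   (1-based bp, strictly increasing within a chromosome) and
#'   `ancestral_freq` in \[0, 1\].
#' @return an object of class `hap_panel`.
#' @export
hap_panel <- function(hap, breed, map) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  n_ind <- nrow(hap) / 2L
  if (nrow(hap) %% 2L != 0L)
    stop("haplotype matrix must have an even number of rows (2 per individual)")
  if (length(breed) != n_ind)
    stop("breed labels must match the number of individuals")
  if (!all(hap %in% c(0L, 1L))) stop("haplotype alleles must be 0/1")
  stopifnot(ncol(hap) == nrow(map))
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within a chromosome")
  }
  structure(list(hap = hap, breed = as.character(breed), map = map),
            class = "hap_panel")
}

#' @exportS3Method base::print
print.hap_panel <- function(x, ...) {
  cat("hap_panel:", nrow(x$hap) / 2L, "individuals x", ncol(x$hap),
      "variants on", length(unique(x$map$chrom)), "chromosome(s)\n")
  cat("breeds:", paste(names(table(x$breed)), table(x$breed),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Genotype panel container
#'
#' Dosage genotypes (0/1/2 copies of the counted allele) with per-variant
#' map metadata (chromosome, position, MAF, functional annotation class) and
#' per-individual breed and sex labels. MAF is always recomputed from the
#' stored dosages so it cannot drift out of sync.
#'
#' @param dosage integer matrix, individuals x variants; dimnames used as
#'   individual and variant ids when present.
#' @param map data.frame with columns `id`, `chrom`, `pos` and optionally
#'   `class` (one of `"NSC"`, `"REG"`, `"HD"`, `"OTHER"`).
#' @param breed,sex per-individual labels; recycled defaults `"A"` and `"F"`.
#' @return an object of class `geno_panel`; `map$maf` holds the realized
#'   minor allele frequency per variant.
#' @export
geno_panel <- function(dosage, map, breed = NULL, sex = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!all(dosage %in% 0:2)) stop("dosages must be 0, 1 or 2")
  stopifnot(ncol(dosage) == nrow(map))
  if (is.null(map$class)) map$class <- "OTHER"
  if (!all(map$class %in% c("NSC", "REG", "HD", "OTHER")))
    stop("unknown annotation class; expected NSC, REG, HD or OTHER")
  n <- nrow(dosage)
  if (is.null(breed)) breed <- rep("A", n)
  if (is.null(sex)) sex <- rep("F", n)
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("ind", seq_len(n))
  if (is.null(map$id)) map$id <- paste0("var", seq_len(nrow(map)))
  colnames(dosage) <- map$id
  map$maf <- panel_maf(dosage)
  structure(list(dosage = dosage, map = map, breed = as.character(breed),
                 sex = as.character(sex)),
            class = "geno_panel")
}

panel_maf <- function(dosage) {
  f <- colMeans(dosage) / 2
  pmin(f, 1 - f)
}

#' @exportS3Method base::print
print.geno_panel <- function(x, ...) {
  cat("geno_panel:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "variants\n")
  cat("classes:", paste(names(table(x$map$class)), table(x$map$class),
                        sep = "=", collapse = ", "), "\n")
  cat("breeds:", paste(names(table(x$breed)), table(x$breed),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype panel
#'
#' @param panel a `geno_panel`.
#' @param individuals,variants integer or logical indices (variants may also
#'   be variant ids). Missing means keep all.
#' @return a new `geno_panel`; MAF is recomputed on the subset.
#' @export
subset_panel <- function(panel, individuals = NULL, variants = NULL) {
  stopifnot(inherits(panel, "geno_panel"))
  if (is.null(individuals)) individuals <- seq_len(nrow(panel$dosage))
  if (is.null(variants)) variants <- seq_len(ncol(panel$dosage))
  if (is.character(variants)) variants <- match(variants, panel$map$id)
  if (anyNA(variants)) stop("unknown variant ids in subset")
  geno_panel(panel$dosage[individuals, variants, drop = FALSE],
             panel$map[variants, setdiff(names(panel$map), "maf"),
                       drop = FALSE],
             breed = panel$breed[individuals], sex = panel$sex[individuals])
}

#' Assign functional annotation classes to a panel
#'
#' Variants are labelled NSC / REG / HD / OTHER at the given proportions,
#' uniformly at random. Default proportions follow the composition of a
#' filtered whole-sequence cattle panel (about 4.5% non-synonymous coding,
#' 58% regulatory-region, 37% HD-chip variants).
#'
#' @param panel a `geno_panel`.
#' @param props named numeric vector of class proportions (normalized
#'   internally).
#' @param seed optional integer seed.
#' @return the panel with `map$class` filled in.
#' @export
assign_classes <- function(panel,
                           props = c(NSC = 0.045, REG = 0.583, HD = 0.372),
                           seed = NULL) {
  stopifnot(inherits(panel, "geno_panel"))
  if (!all(names(props) %in% c("NSC", "REG", "HD", "OTHER")))
    stop("unknown annotation class in props")
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(panel$dosage)
  panel$map$class <- sample(names(props), p, replace = TRUE,
                            prob = props / sum(props))
  panel
}
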