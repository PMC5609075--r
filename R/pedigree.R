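#' Topologically sort a pedigree
#'
#' Orders records so every parent precedes its offspring (Kahn's algorithm);
#' founders keep their relative input order, as do any set of individuals
#' whose parents are already placed. Unknown parents are coded `"0"`.
#' Cycles (an individual being its own ancestor) and duplicate ids are
#' rejected.
#'
#' @param records data.frame with columns `id`, `sire`, `dam` (character or
#'   coercible); `"0"` (or NA) marks an unknown parent.
#' @return a `pedigree` data.frame (columns `id`, `sire`, `dam`),
#'   topologically ordered.
#' @export
sort_pedigree <- function(records) {
  id <- as.character(records$id)
  sire <- as.character(records$sire); sire[is.na(sire)] <- "0"
  dam <- as.character(records$dam); dam[is.na(dam)] <- "0"
  if (anyDuplicated(id)) stop("duplicate id in pedigree")
  known <- c("0", id)
  if (!all(sire %in% known) || !all(dam %in% known))
    stop("pedigree references parents that are not listed")
  n <- length(id)
  placed <- character(0)
  remaining <- seq_len(n)
  out <- integer(0)
  while (length(remaining)) {
    ready <- remaining[(sire[remaining] %in% c("0", placed)) &
                       (dam[remaining] %in% c("0", placed))]
    if (!length(ready)) stop("cycle detected in pedigree")
    out <- c(out, ready)
    placed <- c(placed, id[ready])
    remaining <- setdiff(remaining, ready)
  }
  ped <- data.frame(id = id[out], sire = sire[out], dam = dam[out],
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Numerator relationship matrix (Henderson's tabular method)
#'
#' Builds the additive relationship matrix A by the tabular recursion:
#' `A[j, j] = 1 + 0.5 * A[sire(j), dam(j)]` (0 when a parent is unknown) and
#' `A[i, j] = 0.5 * (A[i, sire(j)] + A[i, dam(j)])` for `i < j`. Inbreeding
#' is handled implicitly by the recursion.
#'
#' @param ped a sorted `pedigree` from [sort_pedigree()] (an unsorted
#'   data.frame is rejected).
#' @return symmetric matrix with dimnames = pedigree ids.
#' @export
build_A <- function(ped) {
  if (!inherits(ped, "pedigree"))
    stop("build_A needs a sorted pedigree from sort_pedigree()")
  n <- nrow(ped)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  if (any(si >= seq_len(n) & si > 0) || any(di >= seq_len(n) & di > 0))
    stop("pedigree is not topologically sorted")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1) {
      i <- seq_len(j - 1)
      cs <- if (s > 0) A[i, s] else 0
      cd <- if (d > 0) A[i, d] else 0
      A[i, j] <- A[j, i] <- 0.5 * (cs + cd)
    }
    A[j, j] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Direct construction of `A^-1` from the pedigree (Quaas), using the
#' Mendelian-sampling variances `d_j = A[j,j] ... ` computed from the
#' tabular diagonal: `d_j = 1 - 0.25 * (A[s,s] + A[d,d])` with terms for
#' unknown parents omitted. The sparse structure is what makes single-site
#' Gibbs updates of the polygenic term cheap.
#'
#' @param ped a sorted `pedigree`.
#' @return a symmetric sparse `Matrix::dsCMatrix` with dimnames =
#'   pedigree ids.
#' @export
build_Ainv <- function(ped) {
  if (!inherits(ped, "pedigree"))
    stop("build_Ainv needs a sorted pedigree from sort_pedigree()")
  n <- nrow(ped)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  ## diagonal of A (with inbreeding) via the tabular method restricted to
  ## ancestors: reuse build_A for exactness (pedigrees here are modest)
  A <- build_A(ped)
  dj <- numeric(n)
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    dj[j] <- 1 - (if (s > 0) 0.25 * A[s, s] else 0) -
                 (if (d > 0) 0.25 * A[d, d] else 0)
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (j in seq_len(n)) {
    w <- 1 / dj[j]
    add(j, j, w)
    s <- si[j]; d <- di[j]
    for (p in c(s, d)) if (p > 0) {
      add(j, p, -0.5 * w); add(p, j, -0.5 * w)
      add(p, p, 0.25 * w)
    }
    if (s > 0 && d > 0) { add(s, d, 0.25 * w); add(d, s, 0.25 * w) }
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(M)
}

#' Read a pedigree CSV
#'
#' Expects columns `id`, `sire`, `dam` with `"0"` for unknown parents;
#' returns the records topologically sorted.
#'
#' @param path CSV file path.
#' @return a sorted `pedigree`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns id, sire, dam")
  sort_pedigree(df[need])
}

#' Write a relationship matrix as sparse triplet text
#'
#' @param A matrix (from [build_A()]).
#' @param path output path; whitespace-delimited `i j value` rows (1-based,
#'   upper triangle including diagonal), preceded by a `# ids:` header line.
#' @export
write_A_triplet <- function(A, path) {
  nz <- which(upper.tri(A, diag = TRUE) & A != 0, arr.ind = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ids: ", paste(rownames(A), collapse = " ")), con)
  utils::write.table(data.frame(nz[, 1], nz[, 2], A[nz]), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
}
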