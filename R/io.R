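#' Write a genotype panel as PLINK .bed/.bim/.fam
#'
#' Variant-major binary .bed (magic bytes `0x6c 0x1b`, mode byte `0x01`),
#' two bits per genotype with individuals packed four per byte in .fam
#' order: `00` = two copies of allele A1, `10` = heterozygote, `11` = zero
#' copies, `01` = missing. Dosages here count the A1 allele. The .bim file
#' gets chromosome, id, 0 cM, 1-based position and alleles `A`/`B`; the
#' .fam file gets breed as family id and sex codes M=1/F=2.
#'
#' @param panel a [geno_panel].
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "geno_panel"))
  dos <- panel$dosage
  n <- nrow(dos); p <- ncol(dos)
  ## .fam
  fam <- data.frame(panel$breed, rownames(dos), 0, 0,
                    ifelse(panel$sex == "M", 1, 2), -9)
  utils::write.table(fam, paste0(prefix, ".fam"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  ## .bim
  bim <- data.frame(panel$map$chrom, panel$map$id, 0, panel$map$pos,
                    "A", "B")
  utils::write.table(bim, paste0(prefix, ".bim"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  ## .bed: dosage -> 2-bit code (counting A1): 2 -> 00, 1 -> 10, 0 -> 11
  code <- matrix(3L - dos - (dos == 2L), n, p)  # 2->0, 1->2, 0->3
  nb <- ceiling(n / 4)
  pad <- nb * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, p))
  dim(code) <- c(4, nb * p)
  bytes <- colSums(code * c(1L, 4L, 16L, 64L))
  con <- file(paste0(prefix, ".bed"), "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read genotypes from PLINK or a plain dosage matrix
#'
#' PLINK input validates the .bed magic bytes and variant-major mode byte
#' and checks .bim/.fam dimension consistency. Missing genotypes (code
#' `01`) are mean-imputed to the rounded per-variant mean dosage and
#' flagged; variants with more than `max_missing` missingness are an
#' error. A dosage matrix is whitespace-delimited text with a header row
#' of variant ids and one row per individual (first column = id).
#'
#' @param path file prefix (PLINK) or file path (dosage matrix).
#' @param format `"plink_bed"` or `"dosage_matrix"`.
#' @param max_missing per-variant missingness cap (default 0.05).
#' @return a [geno_panel]; attribute `n_imputed` counts imputed entries.
#' @export
read_genotypes <- function(path, format = c("plink_bed", "dosage_matrix"),
                           max_missing = 0.05) {
  format <- match.arg(format)
  if (format == "dosage_matrix") return(read_dosage(path))
  bim <- utils::read.table(paste0(path, ".bim"),
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character",
                                          "numeric", "integer",
                                          "character", "character"))
  if (nrow(bim) == 0) stop("empty variant file")
  fam <- utils::read.table(paste0(path, ".fam"),
                           col.names = c("fid", "iid", "father", "mother",
                                         "sex", "pheno"),
                           colClasses = "character")
  if (nrow(fam) == 0) stop("empty individual file")
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(paste0(path, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * p)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (magic-byte mismatch)")
  if (raw[3] != as.raw(0x01))
    stop("only variant-major .bed files are supported")
  body <- as.integer(raw[-(1:3)])
  nb <- ceiling(n / 4)
  if (length(body) != nb * p)
    stop(".bed size inconsistent with .bim/.fam dimensions")
  ## unpack 2-bit codes, low bits first within each byte
  q <- matrix(body, nb, p)
  codes <- matrix(0L, nb * 4, p)
  codes[seq(1, 4 * nb, by = 4), ] <- q %% 4
  codes[seq(2, 4 * nb, by = 4), ] <- (q %/% 4) %% 4
  codes[seq(3, 4 * nb, by = 4), ] <- (q %/% 16) %% 4
  codes[seq(4, 4 * nb, by = 4), ] <- q %/% 64
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(0L, n, p)
  dos[codes == 0] <- 2L
  dos[codes == 2] <- 1L
  dos[codes == 3] <- 0L
  miss <- codes == 1
  n_imputed <- sum(miss)
  if (n_imputed > 0) {
    mr <- colMeans(miss)
    if (any(mr > max_missing))
      stop(sum(mr > max_missing), " variant(s) exceed the missingness cap")
    for (j in which(colSums(miss) > 0)) {
      m <- miss[, j]
      dos[m, j] <- as.integer(round(mean(dos[!m, j])))
    }
    message("mean-imputed ", n_imputed, " missing genotype(s)")
  }
  rownames(dos) <- fam$iid
  chrom <- suppressWarnings(as.integer(sub("^X$", "30", bim$chrom)))
  if (anyNA(chrom)) stop("unknown chromosome codes in .bim")
  panel <- geno_panel(dos, data.frame(id = bim$id, chrom = chrom,
                                      pos = bim$pos),
                      breed = fam$fid,
                      sex = ifelse(fam$sex == "1", "M", "F"))
  attr(panel, "n_imputed") <- n_imputed
  panel
}

#' Write a plain-text dosage matrix
#'
#' @param panel a [geno_panel].
#' @param path output file; whitespace-delimited, header row of variant
#'   ids, first column `id`.
#' @export
write_dosage <- function(panel, path) {
  stopifnot(inherits(panel, "geno_panel"))
  df <- data.frame(id = rownames(panel$dosage), panel$dosage,
                   check.names = FALSE)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_dosage <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty or malformed dosage file")
  ids <- as.character(df[[1]])
  dos <- as.matrix(df[, -1, drop = FALSE])
  if (!all(dos %in% 0:2)) stop("dosage file contains values outside 0..2")
  rownames(dos) <- ids
  geno_panel(dos, data.frame(id = colnames(dos),
                             chrom = 1L, pos = seq_len(ncol(dos))))
}

#' Read phenotypes with weights and fixed-effect levels
#'
#' CSV with columns `id`, a trait column (`y`, `phenotype` or `trait`),
#' optional `weight` (record counts; defaults to 1) and any further
#' columns, which become fixed-effect covariates (e.g. breed/cluster,
#' sex). Row order does not matter: records are returned matched to
#' `panel_ids` when given, and unmatched ids are reported.
#'
#' @param path CSV path.
#' @param panel_ids optional individual ids to align the records with.
#' @return list with `y`, `weights`, `fixed` (data.frame or NULL), `ids`.
#' @export
read_phenotypes <- function(path, panel_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("phenotype file must have an id column")
  trait_col <- intersect(c("y", "phenotype", "trait"), names(df))[1]
  if (is.na(trait_col)) stop("no trait column (y/phenotype/trait) found")
  if (anyDuplicated(df$id)) stop("duplicate ids in phenotype file")
  y <- df[[trait_col]]
  if (!is.numeric(y)) stop("non-numeric trait values")
  if (!is.null(panel_ids)) {
    m <- match(panel_ids, df$id)
    if (anyNA(m)) {
      warning(sum(is.na(m)), " panel id(s) without phenotype records")
      m <- m[!is.na(m)]
    }
    df <- df[m, , drop = FALSE]
    y <- df[[trait_col]]
  }
  w <- if ("weight" %in% names(df)) as.numeric(df$weight) else
    rep(1, nrow(df))
  fx_cols <- setdiff(names(df), c("id", trait_col, "weight"))
  fixed <- if (length(fx_cols)) df[fx_cols] else NULL
  list(y = y, weights = w, fixed = fixed, ids = as.character(df$id))
}

#' Read a variant annotation table
#'
#' @param path CSV with columns `variant_id` (or `id`) and `class`.
#' @return data.frame with `id` and `class`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  idc <- intersect(c("variant_id", "id"), names(df))[1]
  if (is.na(idc) || !"class" %in% names(df))
    stop("annotation file must have variant_id and class columns")
  if (!all(df$class %in% c("NSC", "REG", "HD", "OTHER")))
    stop("unknown annotation class")
  data.frame(id = df[[idc]], class = df$class, stringsAsFactors = FALSE)
}

#' Write an effect table CSV
#' @param effects from [effects_table()].
#' @param path output CSV path.
#' @export
write_effects <- function(effects, path) {
  utils::write.csv(effects, path, row.names = FALSE)
  invisible(path)
}

#' Read an effect table CSV
#' @param path CSV written by [write_effects()].
#' @return data.frame.
#' @export
read_effects <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write variance components as JSON
#' @param fit a `bayesr_fit`.
#' @param path output path.
#' @export
write_varcomp <- function(fit, path) {
  vc <- as.list(fit$varcomp)
  vc$class_occupancy <- unname(fit$class_occupancy)
  jsonlite::write_json(vc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the subcommand, config, seeds and md5 content hashes of all
#' input files, so every output is attributable to (config, seed, inputs).
#'
#' @param path output JSON path.
#' @param command subcommand name.
#' @param config the parsed configuration list.
#' @param inputs character vector of input file paths.
#' @export
write_manifest <- function(path, command, config, inputs = character(0)) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(list(command = command, config = config,
                            input_md5 = hashes,
                            timestamp = format(Sys.time(), tz = "UTC")),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
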