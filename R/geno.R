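#' Genotype matrix container
#'
#' Bundles an individuals-by-variants dosage matrix with its variant map and
#' the allele frequencies of the dosage-counted allele. Dosages are the count
#' of allele `a1` (0, 1 or 2; imputed real dosages in \[0, 2\] are accepted).
#' Missing dosages are mean-imputed on construction so downstream linear
#' algebra never sees `NA`.
#'
#' @param X numeric matrix, individuals in rows, variants in columns.
#' @param map data.frame with one row per variant and columns `chrom`
#'   (integer), `id` (character, unique), `bp` (integer, 1-based position),
#'   `a1`, `a2` (allele labels; `a1` is the dosage-counted allele).
#' @param ids character vector of individual ids (defaults to rownames of
#'   `X` or `ind_1..ind_n`).
#' @return An object of class `geno_matrix`: a list with elements `X`, `map`,
#'   `ids` and `p` (allele frequency of `a1`, computed from the sample).
#' @export
geno_matrix <- function(X, map, ids = NULL) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  req <- c("chrom", "id", "bp", "a1", "a2")
  if (!all(req %in% names(map))) {
    stop("variant map must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(map) != ncol(X)) {
    stop("map has ", nrow(map), " rows but X has ", ncol(X), " columns")
  }
  if (anyDuplicated(map$id)) stop("variant ids must be unique")
  if (is.null(ids)) {
    ids <- rownames(X)
    if (is.null(ids)) ids <- paste0("ind_", seq_len(nrow(X)))
  }
  stopifnot(length(ids) == nrow(X))
  if (anyNA(X)) {
    for (j in which(colSums(is.na(X)) > 0L)) {
      xj <- X[, j]
      xj[is.na(xj)] <- mean(xj, na.rm = TRUE)
      X[, j] <- xj
    }
  }
  dimnames(X) <- list(ids, map$id)
  structure(
    list(X = X, map = map, ids = as.character(ids), p = colMeans(X) / 2),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "geno_matrix: %d individuals x %d variants on %d chromosome(s)\n",
    nrow(x$X), ncol(x$X), length(unique(x$map$chrom))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$X)

#' Subset a genotype matrix
#'
#' @param G a [geno_matrix].
#' @param individuals individual ids or indices (default: all).
#' @param variants variant ids or indices (default: all).
#' @param recompute_freq recompute allele frequencies on the subset
#'   (default `TRUE`); set `FALSE` to carry the parent frequencies.
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(G, individuals = NULL, variants = NULL,
                        recompute_freq = TRUE) {
  stopifnot(inherits(G, "geno_matrix"))
  ri <- seq_len(nrow(G$X))
  ci <- seq_len(ncol(G$X))
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) match(individuals, G$ids) else individuals
    if (anyNA(ri)) stop("unknown individual id(s)")
  }
  if (!is.null(variants)) {
    ci <- if (is.character(variants)) match(variants, G$map$id) else variants
    if (anyNA(ci)) {
      bad <- variants[is.na(if (is.character(variants)) match(variants, G$map$id) else variants)]
      stop("unknown variant id(s): ", paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  out <- geno_matrix(G$X[ri, ci, drop = FALSE], G$map[ci, , drop = FALSE],
                     ids = G$ids[ri])
  if (!recompute_freq) out$p <- G$p[ci]
  out
}

# ---- PLINK bed/bim/fam ------------------------------------------------------

#' Write a genotype matrix as a PLINK binary fileset
#'
#' Writes `prefix.bed` (v1.00 magic, SNP-major), `prefix.bim`
#' (chrom, id, 0 cM, bp, a1, a2) and `prefix.fam`. Dosages are rounded to the
#' nearest integer genotype for the two-bit encoding; `a1` is the counted
#' allele (PLINK's A1), so dosage 2 encodes the A1/A1 homozygote.
#'
#' @param G a [geno_matrix].
#' @param prefix output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "geno_matrix"))
  n <- nrow(G$X); m <- ncol(G$X)
  # two-bit codes, A1-dosage: 2 -> 00, missing -> 01, 1 -> 10, 0 -> 11
  code <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  D <- round(G$X)
  if (any(D < 0 | D > 2)) stop("dosages outside [0,2] cannot be written")
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  nbytes <- ceiling(n / 4)
  pad <- nbytes * 4L
  shift <- c(1L, 4L, 16L, 64L)  # 4^(0:3): within-byte sample offsets
  for (j in seq_len(m)) {
    g <- code[as.character(D[, j])]
    g <- c(g, integer(pad - n))
    byte <- colSums(matrix(g * shift, nrow = 4L))
    writeBin(as.raw(byte), con)
  }
  bim <- data.frame(G$map$chrom, G$map$id, 0, G$map$bp, G$map$a1, G$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(G$ids, G$ids, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK binary fileset into a genotype matrix
#'
#' Reads `prefix.bed`/`.bim`/`.fam` (bed v1.00, SNP-major). Missing genotypes
#' are mean-imputed per variant by the [geno_matrix] constructor.
#'
#' @param prefix path prefix of the fileset.
#' @return a [geno_matrix].
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK bed v1.00 file: ", prefix, ".bed")
  }
  nbytes <- ceiling(n / 4)
  raw <- readBin(con, "raw", nbytes * m)
  if (length(raw) < nbytes * m) stop("truncated .bed file")
  b <- as.integer(raw)
  # unpack 4 samples per byte: codes 0,1,2,3 -> dosage 2, NA, 1, 0
  q <- matrix(0L, nrow = 4L * nbytes, ncol = m)
  bm <- matrix(b, nrow = nbytes, ncol = m)
  for (k in 0:3) {
    q[seq.int(k + 1L, by = 4L, length.out = nbytes), ] <- bm %% 4L
    bm <- bm %/% 4L
  }
  decode <- c(2, NA, 1, 0)
  X <- matrix(decode[q[seq_len(n), , drop = FALSE] + 1L], nrow = n, ncol = m)
  map <- data.frame(chrom = bim[[1]], id = as.character(bim[[2]]),
                    bp = bim[[4]], a1 = as.character(bim[[5]]),
                    a2 = as.character(bim[[6]]), stringsAsFactors = FALSE)
  geno_matrix(X, map, ids = as.character(fam[[2]]))
}

# ---- GCTA GRM binary triplet ------------------------------------------------

#' Write a relationship matrix in GCTA binary GRM format
#'
#' Emits `prefix.grm.bin` (float32 lower triangle, row-major, diagonal
#' included), `prefix.grm.N.bin` (per-pair variant counts, here the constant
#' `N` of the matrix) and `prefix.grm.id`.
#'
#' @param K a [grm_matrix].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_gcta_grm <- function(K, prefix) {
  stopifnot(inherits(K, "grm_matrix"))
  n <- nrow(K$K)
  lt <- K$K[upper.tri(K$K, diag = TRUE)]  # column-major upper == row-major lower
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lt), con, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(K$N), length(lt)), con, size = 4L)
  close(con)
  utils::write.table(data.frame(K$ids, K$ids), paste0(prefix, ".grm.id"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary GRM triplet
#'
#' @param prefix path prefix of `prefix.grm.bin` / `.grm.N.bin` / `.grm.id`.
#' @return a [grm_matrix] (with `N` the rounded median per-pair count).
#' @export
read_gcta_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  np <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  lt <- readBin(con, "numeric", np, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "rb")
  Np <- readBin(con, "numeric", np, size = 4L)
  close(con)
  K <- matrix(0, n, n)
  K[upper.tri(K, diag = TRUE)] <- lt
  K <- K + t(K) - diag(diag(K))
  grm_matrix(K, N = round(stats::median(Np)), diag_mode = "unknown",
             source = "all", ids = as.character(ids))
}

#' Read or write a variant-set file (one id per line)
#'
#' @param ids character vector of variant ids.
#' @param path file path.
#' @return `write_variant_set`: `path` invisibly; `read_variant_set`: a
#'   character vector.
#' @export
write_variant_set <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' @rdname write_variant_set
#' @export
read_variant_set <- function(path) readLines(path)
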