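#' Genomic relationship matrix container
#'
#' @param K symmetric numeric matrix over individuals.
#' @param N number of variants the matrix was built from.
#' @param diag_mode `"yang"` (distinct diagonal formula) or `"crossprod"`
#'   (`W W' / N` everywhere).
#' @param source construction provenance: `"all"`, `"selected"` or
#'   `"complementary"`.
#' @param ids individual ids.
#' @return an object of class `grm_matrix`.
#' @export
grm_matrix <- function(K, N, diag_mode = c("yang", "crossprod", "unknown"),
                       source = c("all", "selected", "complementary"),
                       ids = NULL) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  if (max(abs(K - t(K))) > 1e-8 * (1 + max(abs(K)))) {
    stop("K must be symmetric")
  }
  K <- (K + t(K)) / 2
  if (is.null(ids)) ids <- rownames(K)
  if (is.null(ids)) ids <- paste0("ind_", seq_len(nrow(K)))
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, N = as.integer(N),
                 diag_mode = match.arg(diag_mode),
                 source = match.arg(source),
                 ids = as.character(ids), bent = FALSE),
            class = "grm_matrix")
}

#' @export
print.grm_matrix <- function(x, ...) {
  cat(sprintf("grm_matrix: %d individuals, N = %d variants (%s diagonal, %s set)%s\n",
              nrow(x$K), x$N, x$diag_mode, x$source,
              if (isTRUE(x$bent)) ", bent to PD" else ""))
  invisible(x)
}

#' @export
dim.grm_matrix <- function(x) dim(x$K)

#' Filter variants on minor allele frequency
#'
#' Retains variants with `min(p, 1 - p) > min_maf`, frequencies computed on
#' the retained sample (so monomorphic variants are always removed).
#'
#' @param G a [geno_matrix].
#' @param min_maf threshold in \[0, 0.5).
#' @return a [geno_matrix] with the surviving variants.
#' @export
filter_maf <- function(G, min_maf = 0.01) {
  stopifnot(inherits(G, "geno_matrix"))
  if (min_maf < 0 || min_maf >= 0.5) stop("min_maf must be in [0, 0.5)")
  p <- colMeans(G$X) / 2
  keep <- pmin(p, 1 - p) > min_maf
  if (!any(keep)) stop("MAF filter removed every variant")
  if (all(keep)) return(G)
  subset_geno(G, variants = which(keep))
}

#' Build a genomic relationship matrix
#'
#' Off-diagonals average `(x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over the `N` variants. With `diag_mode = "yang"` the diagonal uses the
#' distinct estimator `1 + (1/N) sum_i (x_ij^2 - (1 + 2 p_i) x_ij +
#' 2 p_i^2) / (2 p_i (1 - p_i))`, which is unbiased for the self-relationship
#' under Hardy-Weinberg; with `diag_mode = "crossprod"` the whole matrix is
#' `W W' / N` with `w_ij = (x_ij - 2 p_i)/sqrt(2 p_i (1 - p_i))`, which is
#' positive semi-definite by construction and is the form required for exact
#' back-solving of marker effects.
#'
#' @param G a [geno_matrix]; all frequencies must be strictly inside (0, 1)
#'   (apply [filter_maf] first).
#' @param diag_mode `"yang"` (default) or `"crossprod"`.
#' @param source provenance label stored on the result.
#' @return a [grm_matrix].
#' @export
build_grm <- function(G, diag_mode = c("yang", "crossprod"), source = "all") {
  stopifnot(inherits(G, "geno_matrix"))
  diag_mode <- match.arg(diag_mode)
  p <- G$p
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic variants present (p in {0,1}); apply filter_maf first")
  }
  X <- G$X
  N <- ncol(X)
  s <- sqrt(2 * p * (1 - p))
  W <- sweep(sweep(X, 2, 2 * p), 2, s, "/")
  K <- tcrossprod(W) / N
  if (diag_mode == "yang") {
    d <- 1 + colMeans(t(X^2 - sweep(X, 2, 1 + 2 * p, "*")) / (2 * p * (1 - p)) +
                        (2 * p^2) / (2 * p * (1 - p)))
    diag(K) <- d
  }
  grm_matrix(K, N = N, diag_mode = diag_mode, source = source, ids = G$ids)
}

#' Squared-correlation linkage disequilibrium between two variants
#'
#' @param G a [geno_matrix].
#' @param i,k variant ids or indices.
#' @return squared Pearson correlation of the dosage vectors, in \[0, 1\].
#' @export
ld_r2 <- function(G, i, k) {
  stopifnot(inherits(G, "geno_matrix"))
  if (is.character(i)) i <- match(i, G$map$id)
  if (is.character(k)) k <- match(k, G$map$id)
  if (anyNA(c(i, k))) stop("unknown variant id")
  xi <- G$X[, i]; xk <- G$X[, k]
  if (stats::var(xi) == 0 || stats::var(xk) == 0) {
    stop("zero-variance dosage vector: LD undefined")
  }
  stats::cor(xi, xk)^2
}

#' Variants in significant LD with a selected set, within a window
#'
#' For each selected variant, scans same-chromosome variants within
#' `window_bp` on either side (closed interval) and flags those whose
#' allelic-correlation test `n r^2 ~ chi-square(1)` gives `p < p_thresh`.
#' The selected variants themselves are always in the returned set. This is
#' the exclusion list used to build a complementary GRM that is not
#' contaminated by LD with the selected variants.
#'
#' @param G a [geno_matrix].
#' @param selected variant ids.
#' @param window_bp window half-width in bp (default 2 Mb).
#' @param p_thresh significance level for the LD test (default 0.01).
#' @return character vector of variant ids (selected plus LD partners).
#' @export
ld_exclusion_set <- function(G, selected, window_bp = 2e6, p_thresh = 0.01) {
  stopifnot(inherits(G, "geno_matrix"), window_bp > 0,
            p_thresh > 0, p_thresh < 1)
  if (length(selected) == 0) return(character(0))
  si <- match(selected, G$map$id)
  if (anyNA(si)) {
    stop("selected id(s) absent from genotypes: ",
         paste(selected[is.na(si)], collapse = ", "))
  }
  n <- nrow(G$X)
  chi_crit <- stats::qchisq(p_thresh, df = 1, lower.tail = FALSE)
  excl <- logical(ncol(G$X))
  excl[si] <- TRUE
  for (s in si) {
    cand <- which(G$map$chrom == G$map$chrom[s] &
                    abs(G$map$bp - G$map$bp[s]) <= window_bp)
    cand <- cand[!excl[cand]]
    if (length(cand) == 0) next
    r <- suppressWarnings(
      stats::cor(G$X[, s], G$X[, cand, drop = FALSE])
    )
    r[is.na(r)] <- 0
    excl[cand[n * r[1, ]^2 >= chi_crit]] <- TRUE
  }
  G$map$id[excl]
}

#' Complementary variant set
#'
#' Restricts a genotype matrix to the variants not in the selected set nor
#' in an additional exclusion list (e.g. LD partners of the selected set).
#'
#' @param G a [geno_matrix].
#' @param selected variant ids to drop.
#' @param extra_excluded further ids to drop (default none).
#' @return a [geno_matrix] with the remaining variants.
#' @export
complement_geno <- function(G, selected, extra_excluded = character(0)) {
  stopifnot(inherits(G, "geno_matrix"))
  if (length(selected) > 0 && !all(selected %in% G$map$id)) {
    stop("selected ids not all present in G")
  }
  drop_ids <- union(selected, extra_excluded)
  keep <- !(G$map$id %in% drop_ids)
  if (!any(keep)) stop("complement is empty")
  if (all(keep)) return(G)
  subset_geno(G, variants = which(keep))
}

#' Bend a relationship matrix to positive definiteness
#'
#' Floors the eigenvalues at `eps * mean(diag)` and reassembles the matrix;
#' matrices already satisfying the bound are returned unchanged. Bending is
#' reported via `message()` and recorded in the `bent` field, since variance
#' components estimated on a bent matrix deserve scrutiny.
#'
#' @param K a [grm_matrix] (or plain symmetric matrix).
#' @param eps relative eigenvalue floor (default `1e-6`).
#' @return same class as the input, positive definite.
#' @export
ensure_pd <- function(K, eps = 1e-6) {
  is_grm <- inherits(K, "grm_matrix")
  A <- if (is_grm) K$K else as.matrix(K)
  bound <- eps * mean(diag(A))
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) >= bound) return(K)
  vals <- pmax(e$values, bound)
  A2 <- e$vectors %*% (vals * t(e$vectors))
  A2 <- (A2 + t(A2)) / 2
  message(sprintf(
    "ensure_pd: floored %d eigenvalue(s) below %.3g (smallest was %.3g)",
    sum(e$values < bound), bound, min(e$values)))
  if (is_grm) {
    out <- K
    out$K <- A2
    dimnames(out$K) <- list(K$ids, K$ids)
    out$bent <- TRUE
    out
  } else A2
}
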