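#' Fit the null mixed model for an association scan
#'
#' Estimates `sigma_g^2` and `sigma_e^2` once under the no-variant model
#' `y = 1 mu + g + e`, `g ~ N(0, K sigma_g^2)`, then freezes them: every
#' per-variant test is a generalized least squares fit under the fixed
#' covariance `V = K sigma_g^2 + I sigma_e^2`. The returned object carries a
#' symmetric inverse square root of `V` so variants can be tested by cheap
#' whitened ordinary regression.
#'
#' @param y response vector (de-regressed proofs).
#' @param K structure [grm_matrix] (typically built from a genotyping-array
#'   subset of the variants, which accounts for population structure).
#' @param ... passed to [reml].
#' @return object of class `null_model`: `fit` (the [reml] fit), `Wh`
#'   (inverse square root of `V`), `sigma2_g`, `sigma2_e`, `n`, `ids`.
#' @export
fit_null <- function(y, K, ...) {
  stopifnot(inherits(K, "grm_matrix"))
  fit <- reml(y, K, ...)
  n <- length(y)
  V <- fit$sigma2[["g1"]] * K$K
  diag(V) <- diag(V) + fit$sigma2[["e"]]
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) <= 0) stop("null covariance not positive definite")
  Wh <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  structure(list(fit = fit, Wh = Wh, sigma2_g = fit$sigma2[["g1"]],
                 sigma2_e = fit$sigma2[["e"]], n = n, ids = K$ids),
            class = "null_model")
}

#' Mixed-linear-model association scan with fixed variance components
#'
#' Tests each variant's additive effect by GLS under the fixed null
#' covariance: with whitened response and dosages, the intercept is projected
#' out and `b = (x'x)^{-1} x'y`, `se = sqrt(1/(x'x))` (the covariance is
#' fully specified, so no residual variance is re-estimated), with a Wald
#' chi-square(1) p-value. Zero-variance variants are reported with `p = 1`
#' and flagged degenerate. Estimates are invariant to adding a constant to
#' `y` or centering the dosages, since the intercept is projected out.
#'
#' @param y response vector, aligned with `null`.
#' @param G a [geno_matrix] of candidate variants (MAF-filtered).
#' @param null a [fit_null] result.
#' @return data.frame of class `assoc_table` with columns `Chr`, `SNP`,
#'   `bp`, `A1`, `A2`, `Freq`, `b`, `se`, `p`, `degenerate`, `n`.
#' @export
mlma_scan <- function(y, G, null) {
  stopifnot(inherits(G, "geno_matrix"), inherits(null, "null_model"))
  n <- length(y)
  if (n != null$n || nrow(G$X) != n) stop("dimensions do not conform")
  yw <- drop(null$Wh %*% y)
  ow <- drop(null$Wh %*% rep(1, n))
  Gw <- null$Wh %*% G$X
  # project the whitened intercept out of response and predictors
  o2 <- sum(ow^2)
  yw <- yw - ow * sum(ow * yw) / o2
  Gw <- Gw - outer(ow, colSums(ow * Gw) / o2)
  xx <- colSums(Gw^2)
  xy <- colSums(Gw * yw)
  degen <- apply(G$X, 2, function(col) stats::var(col) == 0)
  b <- ifelse(degen, 0, xy / xx)
  se <- ifelse(degen, NA_real_, sqrt(1 / xx))
  chi <- ifelse(degen, 0, b^2 * xx)
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  p[degen] <- 1
  p[p == 0] <- .Machine$double.xmin  # keep -log10(p) finite
  out <- data.frame(Chr = G$map$chrom, SNP = G$map$id, bp = G$map$bp,
                    A1 = G$map$a1, A2 = G$map$a2, Freq = unname(G$p),
                    b = unname(b), se = unname(se), p = unname(p),
                    degenerate = unname(degen), n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Expected number of null exceedances of a -log10(p) threshold
#'
#' Under the null, `n_tests * 10^(-logp_threshold)` tests are expected past
#' the threshold by chance; comparing this with the observed count is the
#' usual sanity check on a dense scan.
#'
#' @param n_tests number of tests performed.
#' @param logp_threshold threshold on `-log10(p)` (>= 0).
#' @return expected count (not rounded).
#' @export
expected_null_exceedances <- function(n_tests, logp_threshold) {
  stopifnot(n_tests >= 1, logp_threshold >= 0)
  n_tests * 10^(-logp_threshold)
}

#' Plot-ready association export (Manhattan / QQ)
#'
#' Emits a TSV with `-log10(p)` and uniform-quantile columns, optionally
#' dropping rows with `-log10(p)` below a floor to keep dense-scan files
#' small.
#'
#' @param assoc an [mlma_scan] table.
#' @param path output TSV path.
#' @param min_logp drop variants with `-log10(p)` below this (default `NULL`,
#'   keep all; dense scans conventionally use 1).
#' @return the exported data.frame, invisibly.
#' @export
export_manhattan <- function(assoc, path, min_logp = NULL) {
  stopifnot(inherits(assoc, "assoc_table"))
  d <- assoc[order(assoc$p), ]
  d$logp <- -log10(d$p)
  d$exp_logp <- -log10(stats::ppoints(nrow(d)))
  if (!is.null(min_logp)) d <- d[d$logp >= min_logp, ]
  utils::write.table(d[, c("Chr", "SNP", "bp", "Freq", "b", "se", "p",
                           "logp", "exp_logp")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}
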