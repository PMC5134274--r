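#' Average-information REML for one or two genomic relationship matrices
#'
#' Fits `y = X b + sum_k g_k + e` with `g_k ~ N(0, K_k sigma_k^2)` and
#' `e ~ N(0, I sigma_e^2)` by restricted maximum likelihood. Updates use the
#' average-information (AI) algorithm with an expectation-maximisation (EM)
#' first step and EM fallback whenever the AI step proposes an inadmissible
#' update or the AI matrix is numerically singular. Components that would go
#' negative are floored at `1e-6 * var(y)`; every floor activation is
#' recorded, because variance partitions that hit the boundary (as happens
#' when a handful of selected variants is asked to carry a polygenic trait)
#' should not pass silently.
#'
#' @param y numeric response (de-regressed proofs or phenotypes).
#' @param K_list a [grm_matrix], plain matrix, or list of one or two of them.
#' @param X fixed-effects design matrix (default: intercept only).
#' @param weights optional positive per-record weights (e.g. effective
#'   daughter contributions): the residual covariance becomes
#'   `diag(1/weights) * sigma_e^2`. Default `NULL` (unweighted), the
#'   conventional choice when the weighting is impractical.
#' @param init optional initial components `c(sigma_g..., sigma_e)`;
#'   default splits `var(y)` equally.
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default `1e-8`).
#' @param maxit maximum iterations (default 100).
#' @param verbose print the iteration trace.
#' @return object of class `reml_fit`: `sigma2` (named vector, one per GRM
#'   plus `e`), `se`, `h2` and `h2_se` per genetic component, `h2_total`,
#'   `h2_total_se`, `loglik`, `converged`, `n_iter`, `floored` (counts of
#'   floor activations per component), `aliased` (TRUE when the AI matrix
#'   was singular at the optimum, e.g. `K = I`), `n`, `vary`.
#' @export
reml <- function(y, K_list, X = NULL, weights = NULL, init = NULL,
                 tol = 1e-8, maxit = 100L, verbose = FALSE) {
  if (inherits(K_list, "grm_matrix") || is.matrix(K_list)) K_list <- list(K_list)
  K_list <- lapply(K_list, function(k) if (inherits(k, "grm_matrix")) k$K else k)
  nK <- length(K_list)
  if (nK < 1 || nK > 2) stop("K_list must hold one or two relationship matrices")
  y <- as.numeric(y)
  n <- length(y)
  if (n < 30) stop("need at least 30 records for REML")
  for (K in K_list) stopifnot(nrow(K) == n, ncol(K) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  vary <- stats::var(y)
  floor_val <- 1e-6 * vary
  nc <- nK + 1L
  theta <- if (is.null(init)) rep(vary / nc, nc) else as.numeric(init)
  if (length(theta) != nc) stop("init must have one entry per component")
  theta <- pmax(theta, floor_val)
  R <- if (is.null(weights)) diag(n) else {
    stopifnot(length(weights) == n, all(weights > 0))
    diag(1 / weights)
  }
  Ks <- c(K_list, list(R))
  floored <- integer(nc)

  eval_parts <- function(theta) {
    V <- theta[nc] * R
    for (k in seq_len(nK)) V <- V + theta[k] * Ks[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    chx <- chol(XtViX)
    P <- Vi - t(XtVi) %*% chol2inv(chx) %*% XtVi
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(P = P, Py = Py, ll = ll)
  }

  pt <- eval_parts(theta)
  if (is.null(pt)) stop("initial variance matrix is not positive definite")
  ll_old <- -Inf
  converged <- FALSE
  aliased <- FALSE
  AI <- NULL
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    P <- pt$P; Py <- pt$Py
    KPy <- lapply(Ks, function(K) drop(K %*% Py))
    PKPy <- lapply(KPy, function(v) drop(P %*% v))
    # score: dl/dtheta_k = -0.5 (tr(P K_k) - y' P K_k P y)
    trPK <- vapply(seq_len(nc), function(k) sum(P * Ks[[k]]), numeric(1))
    yPKPy <- vapply(KPy, function(v) sum(Py * v), numeric(1))
    score <- -0.5 * (trPK - yPKPy)
    AI <- 0.5 * outer(seq_len(nc), seq_len(nc), Vectorize(function(k, l)
      sum(KPy[[k]] * PKPy[[l]])))
    AI <- (AI + t(AI)) / 2
    step_em <- theta + theta^2 / n * (yPKPy - trPK)
    if (it == 1L) {
      prop <- step_em
    } else {
      delta <- tryCatch(solve(AI, score), error = function(e) NULL)
      prop <- if (is.null(delta)) step_em else theta + delta
      if (any(!is.finite(prop))) prop <- step_em
    }
    hit <- prop < floor_val
    if (any(hit)) floored[hit] <- floored[hit] + 1L
    prop <- pmax(prop, floor_val)
    pt_new <- eval_parts(prop)
    if (is.null(pt_new) || (it > 1L && pt_new$ll < pt$ll - 1e-6)) {
      # AI overshoot: retreat to the EM proposal
      prop <- pmax(step_em, floor_val)
      pt_new <- eval_parts(prop)
      if (is.null(pt_new)) break
    }
    theta <- prop
    ll_old <- pt$ll
    pt <- pt_new
    if (verbose) {
      cat(sprintf("it %2d  ll = %.6f  theta = %s\n", it, pt$ll,
                  paste(signif(theta, 5), collapse = " ")))
    }
    if (it > 1L && abs(pt$ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
  }
  Vc <- tryCatch(solve(AI), error = function(e) NULL)
  if (is.null(Vc) || any(!is.finite(Vc)) ||
      kappa(AI, exact = TRUE) > 1e12) {
    aliased <- TRUE
    if (is.null(Vc)) Vc <- matrix(Inf, nc, nc)
  }
  se <- sqrt(pmax(diag(Vc), 0))
  nm <- c(paste0("g", seq_len(nK)), "e")
  names(theta) <- names(se) <- nm
  S <- sum(theta)
  h2 <- theta[seq_len(nK)] / S
  # delta method on h_k = theta_k / sum(theta)
  h2_se <- vapply(seq_len(nK), function(k) {
    gr <- rep(-theta[k] / S^2, nc)
    gr[k] <- gr[k] + 1 / S
    sqrt(max(drop(t(gr) %*% Vc %*% gr), 0))
  }, numeric(1))
  gr_tot <- rep((S - sum(theta[seq_len(nK)])) / S^2, nc)
  gr_tot[nc] <- -sum(theta[seq_len(nK)]) / S^2
  h2_total_se <- sqrt(max(drop(t(gr_tot) %*% Vc %*% gr_tot), 0))
  structure(list(sigma2 = theta, se = se,
                 h2 = stats::setNames(h2, nm[seq_len(nK)]),
                 h2_se = stats::setNames(h2_se, nm[seq_len(nK)]),
                 h2_total = sum(h2), h2_total_se = h2_total_se,
                 loglik = pt$ll, converged = converged, n_iter = it,
                 floored = stats::setNames(floored, nm), aliased = aliased,
                 n = n, vary = vary),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML variance components (", x$n_iter, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  tab <- data.frame(component = names(x$sigma2),
                    estimate = round(x$sigma2, 4), se = round(x$se, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("h2 total = %.4f (se %.4f)\n", x$h2_total, x$h2_total_se))
  if (x$aliased) cat("warning: AI matrix singular; components aliased\n")
  invisible(x)
}

#' Genomic heritability from a REML fit
#'
#' Per-component and total proportions of phenotypic variance attributed to
#' the fitted relationship matrices, with delta-method standard errors.
#'
#' @param est a [reml] fit.
#' @param force report even when the fit did not converge.
#' @return data.frame with rows per genetic component plus a `total` row;
#'   columns `component`, `h2`, `se`.
#' @export
genomic_h2 <- function(est, force = FALSE) {
  stopifnot(inherits(est, "reml_fit"))
  if (!est$converged && !force) {
    stop("REML did not converge; pass force = TRUE to report anyway")
  }
  if (sum(est$sigma2) <= 0) stop("total variance is zero")
  data.frame(
    component = c(names(est$h2), "total"),
    h2 = c(unname(est$h2), est$h2_total),
    se = c(unname(est$h2_se), est$h2_total_se),
    stringsAsFactors = FALSE
  )
}

#' Write variance-component estimates in an hsq-style layout
#'
#' @param est a [reml] fit.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hsq <- function(est, path) {
  stopifnot(inherits(est, "reml_fit"))
  nK <- length(est$h2)
  tab <- data.frame(
    Source = c(paste0("V(G", seq_len(nK), ")"), "V(e)", "Vp",
               paste0("V(G", seq_len(nK), ")/Vp"), "Sum of V(G)/Vp",
               "logL", "n"),
    Variance = c(unname(est$sigma2), sum(est$sigma2), unname(est$h2),
                 est$h2_total, est$loglik, est$n),
    SE = c(unname(est$se), NA, unname(est$h2_se), est$h2_total_se, NA, NA)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
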