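#' Train a GBLUP model on the discovery animals
#'
#' Mixed-model BLUP with variance components fixed at a [reml] estimate:
#' `V = sum_k K_k sigma_k^2 + I sigma_e^2`, GLS intercept
#' `beta = (X'V^-1 X)^-1 X'V^-1 y`, and per-component breeding values
#' `g_k = sigma_k^2 K_k V^-1 (y - X beta)`. The multi-component genomic
#' estimated breeding value is the sum over components.
#'
#' @param y_train response for the training individuals.
#' @param K_list one or two [grm_matrix] (training-by-training blocks), in
#'   the component order of `est`.
#' @param est a [reml] fit supplying `sigma2`.
#' @param X fixed-effects design (default intercept).
#' @return object of class `trained_predictor`: `ghat` (list per component),
#'   `gebv` (component sum), `beta`, `sigma2`, `ids`.
#' @export
gblup_train <- function(y_train, K_list, est, X = NULL) {
  if (inherits(K_list, "grm_matrix")) K_list <- list(K_list)
  stopifnot(inherits(est, "reml_fit"),
            length(K_list) == length(est$h2))
  n <- length(y_train)
  if (is.null(X)) X <- matrix(1, n, 1)
  Ks <- lapply(K_list, function(k) if (inherits(k, "grm_matrix")) k$K else k)
  V <- matrix(0, n, n)
  for (k in seq_along(Ks)) V <- V + est$sigma2[[k]] * Ks[[k]]
  diag(V) <- diag(V) + est$sigma2[["e"]]
  ch <- tryCatch(chol(V), error = function(e)
    stop("training covariance is singular; bend the GRM with ensure_pd"))
  Vi <- chol2inv(ch)
  XtVi <- crossprod(X, Vi)
  beta <- drop(solve(XtVi %*% X, XtVi %*% y_train))
  r <- drop(Vi %*% (y_train - drop(X %*% beta)))
  ghat <- lapply(seq_along(Ks), function(k)
    drop(est$sigma2[[k]] * (Ks[[k]] %*% r)))
  ids <- if (inherits(K_list[[1]], "grm_matrix")) K_list[[1]]$ids else
    paste0("ind_", seq_len(n))
  for (k in seq_along(ghat)) names(ghat[[k]]) <- ids
  structure(list(ghat = ghat, gebv = Reduce(`+`, ghat), beta = beta,
                 sigma2 = est$sigma2, ids = ids),
            class = "trained_predictor")
}

#' Back-solve per-variant effects from genomic breeding values
#'
#' Converts the training-animal breeding values of each component into
#' variant effects on the standardized scale, `u = (1/N) W' K^+ g`, then to
#' per-dosage effects `a_i = u_i / sqrt(2 p_i (1 - p_i))` using the training
#' allele frequencies. Exact reconstruction (`W u = g`) requires the
#' component GRM to be the crossprod form `W W'/N` and full rank; with a
#' Yang-diagonal GRM the crossprod form is used for the back-solve, a
#' warning is issued and the maximum training-GEBV reconstruction error is
#' reported in the result.
#'
#' @param pred a [gblup_train] result.
#' @param G_list training [geno_matrix] per component (the variants each
#'   GRM was built from), in component order.
#' @return data.frame of class `effect_table` with columns `id`, `a1`,
#'   `effect` (per counted-allele dosage), `freq` (training frequency of the
#'   counted allele), `component`; attributes `mean_offset` (the GLS
#'   intercept) and `recon_error` (max training reconstruction error per
#'   component).
#' @export
backsolve_effects <- function(pred, G_list) {
  stopifnot(inherits(pred, "trained_predictor"))
  if (inherits(G_list, "geno_matrix")) G_list <- list(G_list)
  if (length(G_list) != length(pred$ghat)) {
    stop("need one training geno_matrix per fitted component")
  }
  out <- vector("list", length(G_list))
  recon <- numeric(length(G_list))
  for (k in seq_along(G_list)) {
    G <- G_list[[k]]
    stopifnot(inherits(G, "geno_matrix"))
    if (!identical(G$ids, pred$ids)) stop("individual ids do not match")
    p <- G$p
    s <- sqrt(2 * p * (1 - p))
    W <- sweep(sweep(G$X, 2, 2 * p), 2, s, "/")
    N <- ncol(W)
    K <- tcrossprod(W) / N
    e <- eigen(K, symmetric = TRUE)
    tol <- max(e$values) * 1e-10
    pos <- e$values > tol
    if (!all(pos)) {
      message(sprintf(
        "backsolve_effects: component %d GRM rank %d/%d; using pseudo-inverse",
        k, sum(pos), length(e$values)))
    }
    g <- pred$ghat[[k]]
    Kpg <- e$vectors[, pos, drop = FALSE] %*%
      (crossprod(e$vectors[, pos, drop = FALSE], g) / e$values[pos])
    u <- drop(crossprod(W, Kpg)) / N
    recon[k] <- max(abs(drop(W %*% u) - g))
    out[[k]] <- data.frame(id = G$map$id, a1 = G$map$a1,
                           effect = u / s, freq = p, component = k,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  eff <- do.call(rbind, out)
  class(eff) <- c("effect_table", "data.frame")
  attr(eff, "mean_offset") <- unname(pred$beta[1])
  attr(eff, "recon_error") <- recon
  eff
}

#' Score genotypes with back-solved variant effects
#'
#' `GEBV_j = sum_i a_i (x_ij - 2 p_i) + mean_offset`, centering each variant
#' with the training allele frequency it was back-solved under, so scores
#' for new animals are on the training scale. Effects from several
#' components (e.g. a selected-set GRM and its complement) are summed.
#'
#' @param G_any a [geno_matrix] containing at least the effect variants.
#' @param effects an [backsolve_effects] table (or any data.frame with `id`,
#'   `effect`, `freq`).
#' @param mean_offset additive constant (default: the `mean_offset`
#'   attribute of `effects`, else 0).
#' @return named numeric vector of GEBV.
#' @export
score_gebv <- function(G_any, effects, mean_offset = NULL) {
  stopifnot(inherits(G_any, "geno_matrix"))
  if (is.null(mean_offset)) {
    mean_offset <- attr(effects, "mean_offset")
    if (is.null(mean_offset)) mean_offset <- 0
  }
  miss <- setdiff(unique(effects$id), G_any$map$id)
  if (length(miss) > 0) {
    stop("variants absent from genotypes: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  }
  gebv <- rep(mean_offset, nrow(G_any$X))
  for (k in unique(effects$component %||% 1L)) {
    ek <- if (is.null(effects$component)) effects else
      effects[effects$component == k, , drop = FALSE]
    ci <- match(ek$id, G_any$map$id)
    Xc <- sweep(G_any$X[, ci, drop = FALSE], 2, 2 * ek$freq)
    gebv <- gebv + drop(Xc %*% ek$effect)
  }
  names(gebv) <- G_any$ids
  gebv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validation accuracy and bias of genomic predictions
#'
#' Accuracy is the Pearson correlation between the validation animals'
#' de-regressed proofs and their GEBV; bias is assessed by the ordinary
#' regression of DRP on GEBV, whose slope is 1 for unbiased predictions and
#' below 1 when predictions are over-dispersed.
#'
#' @param drp_val DRP vector of the validation animals.
#' @param gebv_val GEBV vector, aligned.
#' @return list of class `validation_metrics`: `accuracy`, `slope`,
#'   `intercept`, `n`, `degenerate` (TRUE when GEBV had no variance, in
#'   which case the metrics are `NA`).
#' @export
validate_predictions <- function(drp_val, gebv_val) {
  stopifnot(length(drp_val) == length(gebv_val))
  n <- length(drp_val)
  if (n < 3) stop("need at least 3 validation records")
  if (stats::var(gebv_val) == 0) {
    warning("zero-variance GEBV: metrics undefined")
    return(structure(list(accuracy = NA_real_, slope = NA_real_,
                          intercept = NA_real_, n = n, degenerate = TRUE),
                     class = "validation_metrics"))
  }
  fit <- stats::lm(drp_val ~ gebv_val)
  structure(list(accuracy = stats::cor(drp_val, gebv_val),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = n, degenerate = FALSE),
            class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf("validation (n = %d): accuracy = %.3f, slope = %.3f, intercept = %.3f\n",
              x$n, x$accuracy, x$slope, x$intercept))
  invisible(x)
}

#' Write a PLINK-scoreable effects file
#'
#' Three columns (variant id, counted allele, per-dosage effect), the layout
#' `--score` expects.
#'
#' @param effects a [backsolve_effects] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_file <- function(effects, path) {
  agg <- stats::aggregate(effect ~ id + a1, data = effects, FUN = sum)
  utils::write.table(agg[, c("id", "a1", "effect")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
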