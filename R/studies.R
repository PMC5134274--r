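#' Replicated GREML heritability-recovery study
#'
#' Simulates unrelated Hardy-Weinberg populations with a fully polygenic
#' trait at a known heritability, fits a single-GRM REML model to each
#' replicate and reports the estimate, its standard error and whether the
#' truth lies within 3 SE.
#'
#' @param n individuals per replicate.
#' @param m variants per replicate.
#' @param h2 simulated (and target) heritability.
#' @param n_reps number of replicates.
#' @param seed integer seed; replicate seeds are derived from it.
#' @return data.frame with one row per replicate: `rep`, `h2_hat`, `se`,
#'   `covered` (truth within 3 SE), `converged`.
#' @export
study_greml_recovery <- function(n = 1000, m = 5000, h2 = 0.5, n_reps = 20,
                                 seed = 1L) {
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    s <- seed + 1000L * r
    set.seed(s)
    p <- stats::runif(m, 0.05, 0.5)
    X <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    G <- geno_matrix(X, data.frame(chrom = 1L, id = paste0("v", seq_len(m)),
                                   bp = seq_len(m) * 100L, a1 = "A",
                                   a2 = "B"))
    W <- sweep(sweep(G$X, 2, 2 * G$p), 2, sqrt(2 * G$p * (1 - G$p)), "/")
    g <- drop(W %*% stats::rnorm(m, sd = sqrt(1 / m)))
    y <- g + stats::rnorm(n, sd = sqrt(stats::var(g) * (1 - h2) / h2))
    fit <- reml(y, build_grm(G))
    out[[r]] <- data.frame(rep = r, h2_hat = fit$h2_total,
                           se = fit$h2_total_se,
                           covered = abs(fit$h2_total - h2) <=
                             3 * fit$h2_total_se,
                           converged = fit$converged)
  }
  do.call(rbind, out)
}

#' Association-scan type-I-error calibration study
#'
#' Scans pure-noise phenotypes on an unrelated population, with the null
#' mixed model fitted to the same genotypes, and reports the fraction of
#' tests significant at `alpha`.
#'
#' @param n individuals.
#' @param m variants.
#' @param alpha nominal level (default 0.05).
#' @param seed integer seed.
#' @return list: `type1` (empirical rejection rate), `n_tests`, `assoc`
#'   (the scan table).
#' @export
study_mlma_calibration <- function(n = 500, m = 5000, alpha = 0.05,
                                   seed = 1L) {
  set.seed(seed)
  p <- stats::runif(m, 0.05, 0.5)
  X <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  G <- geno_matrix(X, data.frame(chrom = 1L, id = paste0("v", seq_len(m)),
                                 bp = seq_len(m) * 100L, a1 = "A", a2 = "B"))
  y <- stats::rnorm(n)
  null <- fit_null(y, ensure_pd(build_grm(G)))
  assoc <- mlma_scan(y, G, null)
  list(type1 = mean(assoc$p < alpha), n_tests = m, assoc = assoc)
}

#' Preselection bias-direction study
#'
#' The reuse-of-discovery pathology: a family-structured population is
#' split into discovery and validation cohorts; the discovery cohort is
#' used both to select variants (by a stringent marginal p-value threshold)
#' and to train GBLUP; predictions are validated in the related validation
#' cohort. Each replicate contrasts the all-variant model with the
#' selected-variant model on validation accuracy and regression slope
#' (DRP on GEBV). Stringent preselection is expected to lower both.
#'
#' @param n_reps replicates.
#' @param seed integer seed.
#' @param n_sires,sons_per_sire,n_generations pedigree design per replicate.
#' @param n_chrom,variants_per_chrom genome size.
#' @param n_qtl,h2 trait architecture.
#' @param sel_logp stringent threshold (default 5).
#' @return data.frame per replicate: `rep`, `acc_all`, `slope_all`,
#'   `acc_sel`, `slope_sel`, `n_selected`.
#' @export
study_bias_direction <- function(n_reps = 10, seed = 1L, n_sires = 20,
                                 sons_per_sire = 25, n_generations = 2,
                                 n_chrom = 4, variants_per_chrom = 5000,
                                 n_qtl = 50, h2 = 0.6, sel_logp = 5) {
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sim <- sim_dataset(n_sires = n_sires, sons_per_sire = sons_per_sire,
                       n_generations = n_generations, n_chrom = n_chrom,
                       variants_per_chrom = variants_per_chrom,
                       n_qtl = n_qtl, h2 = h2,
                       seed = seed + 10000L * r)
    rep_all <- run_scenario(sim, source = "ISQ", selection = "NONE",
                            model = "GRM_ONLY")
    rep_sel <- run_scenario(sim, source = "ISQ",
                            selection = if (sel_logp >= 5) "PVAL5" else "PVAL3",
                            model = "GRM_ONLY")
    out[[r]] <- data.frame(rep = r,
                           acc_all = rep_all$metrics$accuracy,
                           slope_all = rep_all$metrics$slope,
                           acc_sel = rep_sel$metrics$accuracy,
                           slope_sel = rep_sel$metrics$slope,
                           n_selected = rep_sel$counts$n_selected)
    rm(sim, rep_all, rep_sel)
    gc(FALSE)  # dense replicates are several hundred MB each
  }
  do.call(rbind, out)
}
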