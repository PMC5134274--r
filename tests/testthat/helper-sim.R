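# Shared fixtures, built once per test run.

# unrelated Hardy-Weinberg population: independent binomial dosages
hw_geno <- function(n, m, seed, p_range = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, p_range[1], p_range[2])
  X <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  geno_matrix(X, data.frame(chrom = 1L, id = paste0("v", seq_len(m)),
                            bp = seq_len(m) * 1000L, a1 = "A", a2 = "B"))
}

# polygenic trait on a genotype matrix at heritability h2
polygenic_y <- function(G, h2, seed, n_qtl = ncol(G$X)) {
  set.seed(seed)
  qtl <- sort(sample.int(ncol(G$X), n_qtl))
  W <- sweep(G$X[, qtl, drop = FALSE], 2, 2 * G$p[qtl])
  W <- sweep(W, 2, sqrt(2 * G$p[qtl] * (1 - G$p[qtl])), "/")
  g <- drop(W %*% rnorm(n_qtl, sd = sqrt(1 / n_qtl)))
  vg <- var(g)
  e <- rnorm(nrow(G$X), sd = sqrt(vg * (1 - h2) / h2))
  list(y = g + e, g = g, qtl = qtl)
}

# a fixed identity-covariance null model (sigma_g = 0, sigma_e = 1), used
# where a test needs GLS to collapse to OLS
identity_null <- function(n) {
  structure(list(fit = NULL, Wh = diag(n), sigma2_g = 0, sigma2_e = 1,
                 n = n, ids = paste0("ind_", seq_len(n))),
            class = "null_model")
}

# memoised medium family-structured dataset shared across test files
.sim_cache <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- sim_dataset(n_sires = 8, sons_per_sire = 15,
                                  n_generations = 2, n_chrom = 2,
                                  variants_per_chrom = 400, n_qtl = 8,
                                  h2 = 0.5, seed = 42)
  }
  .sim_cache$sim
}
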