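# small scan helper under the identity null (unstructured population)
scan0 <- function(y, G) mlma_scan(y, G, identity_null(length(y)))

test_that("mode defaults encode the selection rules", {
  c3 <- selection_config("COJO3")
  expect_equal(c3$logp_enter, 3)
  expect_equal(c3$r2_cap, 0.8)
  expect_equal(c3$prefilter_logp, 3)
  expect_equal(c3$max_ld_dist_bp, Inf)
  c5ld <- selection_config("COJO5LD")
  expect_equal(c5ld$r2_cap, 0.5)
  expect_equal(c5ld$max_ld_dist_bp, 100e6)
  expect_null(c5ld$prefilter_logp)
  ctop <- selection_config("COJO_TOPN", top_n = 7)
  expect_equal(ctop$top_n, 7)
  expect_error(selection_config("COJO3", r2_cap = 0), "r2_cap")
})

test_that("p-value thresholding counts exceedances", {
  assoc <- data.frame(SNP = c("a", "b", "c"), p = c(1e-2, 1e-4, 1e-6))
  class(assoc) <- c("assoc_table", "data.frame")
  expect_setequal(select_pval(assoc, 3), c("b", "c"))
  expect_equal(length(select_pval(assoc, 0)), 3)
  expect_warning(sel <- select_pval(assoc, 10), "no variant")
  expect_equal(length(sel), 0)
})

test_that("a null scan selects about the chance-expected number", {
  G <- hw_geno(400, 20000, seed = 70)
  set.seed(71)
  assoc <- scan0(rnorm(400), G)
  n_sel <- length(select_pval(assoc, 3))
  expect_lt(abs(n_sel - 20), 3 * sqrt(20))
})

test_that("single-candidate selection returns the marginal fit", {
  set.seed(72)
  n <- 300
  G <- hw_geno(n, 30, seed = 73)
  y <- 0.8 * (G$X[, 5] - mean(G$X[, 5])) + rnorm(n, sd = 0.5)
  assoc <- scan0(y, G)
  # only v5 passes the prefilter by construction at these sizes
  expect_equal(select_pval(assoc, 3), "v5")
  sel <- cojo_select(assoc, G, y, identity_null(n), selection_config("COJO5"))
  expect_equal(sel$selected, "v5")
  expect_equal(sel$table$b_cond, sel$table$b_marginal, tolerance = 1e-8)
  expect_equal(sel$table$b_joint, sel$table$b_marginal, tolerance = 1e-8)
})

test_that("a perfect-LD duplicate is rejected with an LD-cap reason", {
  set.seed(74)
  n <- 400
  x <- rbinom(n, 2, 0.4)
  X <- cbind(x, x, rbinom(n, 2, 0.3))
  G <- geno_matrix(X, data.frame(chrom = 1, id = c("dup1", "dup2", "bg"),
                                 bp = c(1e6, 2e6, 9e6), a1 = "A", a2 = "B"))
  y <- 0.9 * (x - mean(x)) + rnorm(n, sd = 0.6)
  assoc <- scan0(y, G)
  sel <- cojo_select(assoc, G, y, identity_null(n), selection_config("COJO5"))
  expect_equal(sel$selected, "dup1")
  rej <- sel$audit[sel$audit$action == "rejected", ]
  expect_true("dup2" %in% rej$id)
  expect_equal(rej$reason[rej$id == "dup2"], "LD cap")
})

test_that("planted QTL on a linkage-equilibrium panel are recovered", {
  hits <- 0L
  for (s in 1:10) {
    G <- hw_geno(1000, 500, seed = 700 + s)
    set.seed(800 + s)
    qtl <- sort(sample.int(500, 3))
    Xc <- sweep(G$X[, qtl], 2, colMeans(G$X[, qtl]))
    g <- drop(Xc %*% c(1, -1, 1))
    y <- g + rnorm(1000, sd = sqrt(var(g)))  # three large-effect QTL
    assoc <- scan0(y, G)
    sel <- cojo_select(assoc, G, y, identity_null(1000),
                       selection_config("COJO5"))
    if (setequal(sel$selected, paste0("v", qtl))) hits <- hits + 1L
    # on (near-)orthogonal predictors conditional effects track marginals
    ok <- match(sel$table$id, assoc$SNP)
    expect_true(all(abs(sel$table$b_cond - assoc$b[ok]) <=
                      3 * assoc$se[ok]))
  }
  expect_gte(hits, 9L)
})

test_that("forward selection is near-optimal against all-subsets enumeration", {
  set.seed(76)
  n <- 250
  G <- hw_geno(n, 12, seed = 77)
  Xc <- sweep(G$X, 2, colMeans(G$X))
  y <- drop(Xc[, c(2, 7, 11)] %*% c(0.7, -0.6, 0.5)) + rnorm(n)
  assoc <- scan0(y, G)
  sel <- cojo_select(assoc, G, y, identity_null(n),
                     selection_config("COJO3", prefilter_logp = 0))
  k <- length(sel$selected)
  expect_gte(k, 1)
  rss_fwd <- tail(sel$rss_path, 1)
  # exhaustive oracle: best residual sum of squares over all size-k subsets
  combs <- combn(12, k)
  rss_best <- min(apply(combs, 2, function(ix)
    sum(resid(lm(y ~ G$X[, ix]))^2)))
  expect_lt(rss_fwd, rss_best * 1.05)
})

test_that("selection order is deterministic and variance strictly decreases", {
  G <- hw_geno(300, 40, seed = 78)
  sim <- polygenic_y(G, h2 = 0.6, seed = 79, n_qtl = 5)
  assoc <- scan0(sim$y, G)
  cfg <- selection_config("COJO3", logp_enter = 1, prefilter_logp = 0.5)
  s1 <- cojo_select(assoc, G, sim$y, identity_null(300), cfg)
  s2 <- cojo_select(assoc, G, sim$y, identity_null(300), cfg)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$audit, s2$audit)
  if (length(s1$rss_path) > 1) {
    expect_true(all(diff(s1$rss_path) < 0))
  }
})

test_that("top-N mode stops at N without a significance gate", {
  G <- hw_geno(400, 60, seed = 80)
  sim <- polygenic_y(G, h2 = 0.5, seed = 81, n_qtl = 10)
  assoc <- scan0(sim$y, G)
  sel <- cojo_select(assoc, G, sim$y, identity_null(400),
                     selection_config("COJO_TOPN", top_n = 5))
  expect_equal(length(sel$selected), 5)
  # ranking by |conditional effect| is available and also capped at N
  sel_b <- cojo_select(assoc, G, sim$y, identity_null(400),
                       selection_config("COJO_TOPN", top_n = 5,
                                        rank_by = "effect"))
  expect_equal(length(sel_b$selected), 5)
})

test_that("distant pairs are treated as independent under the distance cap", {
  set.seed(82)
  n <- 300
  x <- rbinom(n, 2, 0.4)
  # same dosages placed 150 Mb apart: r2 = 1 but outside the 100-Mb cap
  X <- cbind(x, x)
  G <- geno_matrix(X, data.frame(chrom = 1, id = c("far1", "far2"),
                                 bp = c(1e6, 151e6), a1 = "A", a2 = "B"))
  y <- (x - mean(x)) + rnorm(n, sd = 0.4)
  assoc <- scan0(y, G)
  sel <- cojo_select(assoc, G, y, identity_null(n),
                     selection_config("COJO5LD", logp_enter = 2))
  # far2 is perfectly collinear once far1 is in the model, so it can only
  # be rejected for collinearity, never for LD (assumed independent)
  expect_equal(sel$selected, "far1")
  rej <- sel$audit[sel$audit$action == "rejected", ]
  expect_equal(rej$reason[rej$id == "far2"], "collinearity")
})

test_that("complementary-set exclusion follows the selection mode", {
  # threshold mode: the selected ids only
  expect_equal(exclusion_for_grmc(c("a", "b"), NULL, mode = "PVAL"),
               c("a", "b"))
  # conditional mode: selected variant plus its 50 perfect-LD neighbours
  set.seed(83)
  x <- rbinom(200, 2, 0.4)
  X <- cbind(matrix(x, 200, 51), rbinom(200, 2, 0.4))
  G <- geno_matrix(X, data.frame(chrom = 1, id = paste0("v", 1:52),
                                 bp = c(seq(1e6, 2e6, length.out = 51), 8e6),
                                 a1 = "A", a2 = "B"))
  excl <- exclusion_for_grmc("v1", G, mode = "COJO5")
  expect_equal(length(excl), 51)
  expect_false("v52" %in% excl)
  # a lone selected variant with no window neighbours excludes only itself
  Glone <- geno_matrix(cbind(x, rbinom(200, 2, 0.3)),
                       data.frame(chrom = c(1, 2), id = c("v1", "v2"),
                                  bp = c(1e6, 1e6), a1 = "A", a2 = "B"))
  expect_equal(exclusion_for_grmc("v1", Glone, mode = "COJO5"), "v1")
  expect_error(exclusion_for_grmc(character(0), G), "empty")
})

test_that("selection reports round-trip to TSV", {
  G <- hw_geno(300, 30, seed = 84)
  sim <- polygenic_y(G, h2 = 0.6, seed = 85, n_qtl = 3)
  assoc <- scan0(sim$y, G)
  sel <- cojo_select(assoc, G, sim$y, identity_null(300),
                     selection_config("COJO3", logp_enter = 1,
                                      prefilter_logp = 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection_report(sel, path)
  tab <- read.delim(path)
  expect_equal(tab$id, sel$table$id)
  expect_equal(tab$b_joint, sel$table$b_joint, tolerance = 1e-9)
})
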