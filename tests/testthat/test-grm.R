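simple_geno <- function(X, bp = NULL, chrom = NULL) {
  m <- ncol(X)
  geno_matrix(X, data.frame(chrom = chrom %||% rep(1L, m),
                            id = paste0("v", seq_len(m)),
                            bp = bp %||% (seq_len(m) * 1000L),
                            a1 = "A", a2 = "B"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("MAF filtering recomputes frequencies on the retained sample", {
  X <- cbind(rep(0, 100), c(1, rep(0, 99)), rbinom(100, 2, 0.3))
  G <- simple_geno(X)
  Gf <- filter_maf(G, 0)
  expect_equal(ncol(Gf$X), 2)  # monomorphic removed at any threshold
  Gf <- filter_maf(G, 0.01)
  expect_equal(ncol(Gf$X), 1)  # single heterozygote: p = 1/200 < 0.01
  G2 <- simple_geno(matrix(rbinom(200, 2, 0.4), 100, 2))
  expect_identical(filter_maf(G2, 0), G2)
  expect_error(filter_maf(simple_geno(matrix(0, 10, 1)), 0.01),
               "removed every variant")
})

test_that("single-variant GRM entries match the closed forms", {
  G <- simple_geno(matrix(c(2, 0), 2, 1))
  G$p <- 0.5
  K <- build_grm(G, diag_mode = "yang")
  expect_equal(K$K[1, 2], -2, tolerance = 1e-12)   # (2-1)(0-1)/0.5
  expect_equal(K$K[1, 1], 2, tolerance = 1e-12)    # 1 + (4-4+0.5)/0.5... = 2
  G1 <- simple_geno(matrix(c(1, 1), 2, 1))
  G1$p <- 0.5
  expect_equal(build_grm(G1, "yang")$K[1, 1], 0, tolerance = 1e-12)
  expect_error(build_grm(simple_geno(matrix(c(0, 0), 2, 1))), "monomorphic")
})

test_that("crossprod GRM equals the dense W W'/N oracle", {
  G <- hw_geno(200, 1000, seed = 20)
  K <- build_grm(G, diag_mode = "crossprod")
  # independent dense construction, element by element from the definition
  p <- colMeans(G$X) / 2
  W <- (G$X - matrix(2 * p, 200, 1000, byrow = TRUE)) /
    matrix(sqrt(2 * p * (1 - p)), 200, 1000, byrow = TRUE)
  oracle <- (W %*% t(W)) / 1000
  expect_lt(max(abs(K$K - unname(oracle))), 1e-10)
})

test_that("GRM is invariant to which allele is dosage-counted", {
  G <- hw_geno(80, 300, seed = 21)
  Gflip <- G
  Gflip$X <- 2 - G$X
  Gflip$p <- 1 - G$p
  for (mode in c("yang", "crossprod")) {
    expect_equal(build_grm(G, mode)$K, build_grm(Gflip, mode)$K,
                 tolerance = 1e-10)
  }
})

test_that("Yang GRM on an unrelated HW population is near identity", {
  G <- hw_geno(500, 20000, seed = 22)
  K <- build_grm(G, diag_mode = "yang")
  expect_equal(mean(diag(K$K)), 1, tolerance = 0.02)
  off <- K$K[upper.tri(K$K)]
  expect_lt(mean(abs(off)), 0.01)
})

test_that("dosage LD is a squared correlation with its symmetries", {
  G <- hw_geno(200, 5, seed = 23)
  expect_equal(ld_r2(G, 1, 1), 1)
  Gd <- simple_geno(cbind(rep(0:2, 10), rev(rep(0:2, 10))))
  expect_equal(ld_r2(Gd, 1, 2), 1)  # allele flip leaves r2 unchanged
  Gbig <- hw_geno(10000, 2, seed = 24)
  expect_lt(ld_r2(Gbig, 1, 2), 0.001 + 3 / 10000)
  Gz <- simple_geno(cbind(rbinom(50, 2, 0.4), rep(1, 50)))
  expect_error(ld_r2(Gz, 1, 2), "zero-variance")
})

test_that("LD exclusion windows are closed, chromosome-local and significance-gated", {
  expect_equal(ld_exclusion_set(hw_geno(50, 3, seed = 1), character(0)),
               character(0))
  # perfect-LD neighbour 1 kb away is excluded; independent variant 3 Mb
  # away is retained even if correlated by chance
  set.seed(25)
  x <- rbinom(100, 2, 0.4)
  X <- cbind(x, x, rbinom(100, 2, 0.4))
  G <- simple_geno(X, bp = c(1e6, 1e6 + 1000, 4e6))
  excl <- ld_exclusion_set(G, "v1", window_bp = 2e6, p_thresh = 0.01)
  expect_setequal(excl, c("v1", "v2"))
  # same-chromosome but outside the 2-Mb window: retained regardless of LD
  Gfar <- simple_geno(cbind(x, x), bp = c(1e6, 4.1e6))
  expect_equal(ld_exclusion_set(Gfar, "v1"), "v1")
  # other chromosome: never scanned
  Gchr <- simple_geno(cbind(x, x), bp = c(1e6, 1e6 + 1000), chrom = c(1L, 2L))
  expect_equal(ld_exclusion_set(Gchr, "v1"), "v1")
  expect_error(ld_exclusion_set(G, "nope"), "nope")
})

test_that("complementary sets are plain set arithmetic", {
  G <- hw_geno(30, 10, seed = 26)
  expect_identical(complement_geno(G, character(0)), G)
  Gc <- complement_geno(G, c("v1", "v2", "v3"))
  expect_equal(ncol(Gc$X), 7)
  expect_false(any(c("v1", "v2", "v3") %in% Gc$map$id))
  Gc2 <- complement_geno(G, c("v1", "v2"), extra_excluded = c("v2", "v9"))
  expect_equal(ncol(Gc2$X), 7)
  expect_error(complement_geno(G, G$map$id), "empty")
  expect_error(complement_geno(G, "zz"), "not all present")
})

test_that("positive-definite bending floors eigenvalues and little else", {
  K <- grm_matrix(diag(5), N = 10)
  expect_identical(ensure_pd(K), K)  # already PD: unchanged
  A <- matrix(c(1, 1, 1, 1), 2, 2)  # eigenvalues 2, 0
  expect_message(B <- ensure_pd(grm_matrix(A, N = 1)), "floored")
  ev <- eigen(B$K, symmetric = TRUE)$values
  expect_gte(min(ev), 1e-6 * mean(diag(A)) - 1e-15)
  expect_lt(max(abs(B$K - A)), 1e-5)
  expect_true(B$bent)
  # property: bending any random symmetric matrix yields a Cholesky-factorable
  # matrix with eigenvalues above the floor
  set.seed(27)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    M <- crossprod(matrix(rnorm(n * n), n)) - diag(n) * runif(1, 0, 2)
    M <- (M + t(M)) / 2
    diag(M) <- abs(diag(M)) + 0.1
    Mb <- suppressMessages(ensure_pd(M, eps = 1e-6))
    expect_silent(chol(Mb + diag(n) * 0))
    expect_gte(min(eigen(Mb, symmetric = TRUE)$values),
               1e-6 * mean(diag(M)) - 1e-12)
  }
})

test_that("PLINK bed/bim/fam and GCTA GRM files round-trip", {
  G <- hw_geno(37, 25, seed = 28)  # n deliberately not a multiple of 4
  prefix <- file.path(withr::local_tempdir(), "pop")
  write_plink(G, prefix)
  G2 <- read_plink(prefix)
  expect_equal(unname(G2$X), unname(G$X))
  expect_equal(G2$map$id, G$map$id)
  expect_equal(G2$ids, G$ids)

  K <- build_grm(G, diag_mode = "yang")
  write_gcta_grm(K, prefix)
  K2 <- read_gcta_grm(prefix)
  expect_equal(K2$K, K$K, tolerance = 1e-6)  # float32 precision
  expect_equal(K2$N, K$N)
  expect_equal(K2$ids, K$ids)

  sets <- file.path(withr::local_tempdir(), "set.txt")
  write_variant_set(G$map$id[1:5], sets)
  expect_equal(read_variant_set(sets), G$map$id[1:5])
})

test_that("missing genotypes are mean-imputed on load", {
  X <- matrix(c(0, 1, 2, NA, 2, 2, 0, 0), 4, 2)
  G <- geno_matrix(X, data.frame(chrom = 1, id = c("a", "b"), bp = c(1, 2),
                                 a1 = "A", a2 = "B"))
  expect_equal(G$X[4, 1], 1)  # mean of 0,1,2
  expect_false(anyNA(G$X))
})
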