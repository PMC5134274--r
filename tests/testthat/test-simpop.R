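test_that("pedigree construction gives half-sib families and the cohort split", {
  ped <- make_pedigree(1, 1, 1, seed = 1)
  expect_s3_class(ped, "pedigree")
  sons <- ped[ped$generation == 1 & ped$sex == "M", ]
  expect_equal(nrow(sons), 1)
  expect_equal(ped$cohort[ped$id == sons$sire], "discovery")
  expect_equal(sons$cohort, "validation")

  ped <- make_pedigree(20, 10, 2, seed = 7)
  last <- ped[ped$generation == 2, ]
  expect_equal(nrow(last), 200)
  sire_cohort <- ped$cohort[match(last$sire, ped$id)]
  expect_equal(mean(sire_cohort == "discovery"), 1.0)
  # each sire of the last generation has exactly 10 sons
  expect_true(all(table(last$sire) == 10))

  expect_identical(make_pedigree(20, 10, 2, seed = 7),
                   make_pedigree(20, 10, 2, seed = 7))
  expect_error(make_pedigree(0, 1, 1), "must all be")
})

test_that("founder haplotypes realize the requested LD structure", {
  cm <- chrom_map(1, 5001, 1e8)
  H0 <- sim_founder_haplotypes(cm, maf_low = 0.05, ld_rho = 0,
                               n_haplotypes = 200, seed = 2)
  r2_adj <- function(H, sep) {
    i <- seq_len(ncol(H) - sep)
    vapply(i, function(j) suppressWarnings(cor(H[, j], H[, j + sep]))^2,
           numeric(1))
  }
  m0 <- mean(r2_adj(H0, 1), na.rm = TRUE)
  expect_lt(m0, 3 / 200 + 0.01)  # null expectation of r2 is ~1/n

  H9 <- sim_founder_haplotypes(cm, maf_low = 0.05, ld_rho = 0.95,
                               n_haplotypes = 200, seed = 2)
  expect_gt(mean(r2_adj(H9, 1), na.rm = TRUE),
            mean(r2_adj(H9, 50), na.rm = TRUE))  # monotone LD decay
  expect_true(all(pmin(colMeans(H9), 1 - colMeans(H9)) >= 0.05))

  H2 <- sim_founder_haplotypes(chrom_map(1, 1, 100), maf_low = 0.4,
                               ld_rho = 0, n_haplotypes = 2, seed = 5)
  expect_equal(sum(H2[, 1]), 1)  # only polymorphic two-haplotype configuration

  expect_error(sim_founder_haplotypes(cm, ld_rho = 1), "ld_rho")
  expect_error(sim_founder_haplotypes(cm, n_haplotypes = 3), "even")
})

test_that("gene dropping transmits gametes with map-driven recombination", {
  ped <- make_pedigree(2, 3, 1, seed = 1)
  cm <- chrom_map(1, 200, 1e8)
  nf <- sum(is.na(ped$sire))
  H <- sim_founder_haplotypes(cm, n_haplotypes = 2 * nf, seed = 3)

  G0 <- gene_drop(ped, H, morgans_per_chrom = 0, seed = 4,
                  keep_gametes = TRUE)
  gam <- attr(G0, "gametes")
  off <- which(!is.na(ped$sire))
  for (r in off) {
    ps <- match(ped$sire[r], ped$id)
    expect_true(identical(gam$paternal[r, ], gam$paternal[ps, ]) ||
                  identical(gam$paternal[r, ], gam$maternal[ps, ]))
  }

  # fixation transmission: force dosage 2 in all founders at site 1
  Hfix <- H; Hfix[, 1] <- 1L
  attr(Hfix, "map") <- attr(H, "map")
  Gfix <- gene_drop(ped, Hfix, morgans_per_chrom = 1, seed = 4)
  expect_true(all(Gfix$X[, 1] == 2))

  Hshort <- H[1:3, , drop = FALSE]
  attr(Hshort, "map") <- attr(H, "map")
  expect_error(gene_drop(ped, Hshort), "pool too small")
  expect_equal(gene_drop(ped, H, seed = 9)$X, gene_drop(ped, H, seed = 9)$X)
})

test_that("full sibs share half their genome on average", {
  # many independent couples, one full-sib pair each; centering against the
  # population (not within family) exposes the 0.5 additive relationship
  n_fam <- 50
  ped <- data.frame(
    id = c(paste0("s", 1:n_fam), paste0("d", 1:n_fam),
           paste0("k", 1:n_fam, "_1"), paste0("k", 1:n_fam, "_2")),
    sire = c(rep(NA, 2 * n_fam), rep(paste0("s", 1:n_fam), 2)),
    dam = c(rep(NA, 2 * n_fam), rep(paste0("d", 1:n_fam), 2)),
    generation = rep(c(0, 1), each = 2 * n_fam),
    stringsAsFactors = FALSE)
  cm <- chrom_map(1, 10000, 1e8)
  H <- sim_founder_haplotypes(cm, maf_low = 0.1, ld_rho = 0,
                              n_haplotypes = 4 * n_fam, seed = 11)
  G <- gene_drop(ped, H, morgans_per_chrom = 1, seed = 12)
  Xc <- sweep(G$X, 2, colMeans(G$X))
  k1 <- Xc[2 * n_fam + (1:n_fam), ]
  k2 <- Xc[3 * n_fam + (1:n_fam), ]
  r <- mean(vapply(seq_len(n_fam),
                   function(i) cor(k1[i, ], k2[i, ]), numeric(1)))
  expect_equal(r, 0.5, tolerance = 0.05 / 0.5)
})

test_that("gene dropping conserves allele frequency (drift only)", {
  # wide one-generation design: offspring gametes are Mendelian draws from
  # many founder couples, so the founder frequency is recovered within
  # binomial sampling error and with no directional bias
  n_fam <- 100
  kids_per_fam <- 5
  kid <- paste0("k", rep(1:n_fam, each = kids_per_fam), "_",
                rep(1:kids_per_fam, n_fam))
  ped <- data.frame(
    id = c(paste0("s", 1:n_fam), paste0("d", 1:n_fam), kid),
    sire = c(rep(NA, 2 * n_fam), rep(paste0("s", 1:n_fam),
                                     each = kids_per_fam)),
    dam = c(rep(NA, 2 * n_fam), rep(paste0("d", 1:n_fam),
                                    each = kids_per_fam)),
    generation = c(rep(0, 2 * n_fam), rep(1, n_fam * kids_per_fam)),
    stringsAsFactors = FALSE)
  cm <- chrom_map(1, 500, 1e8)
  H <- sim_founder_haplotypes(cm, ld_rho = 0, n_haplotypes = 4 * n_fam,
                              seed = 6)
  G <- gene_drop(ped, H, seed = 7)
  p_founder <- colMeans(H)
  off <- grepl("^k", ped$id)
  p_off <- colMeans(G$X[off, ]) / 2
  se <- sqrt(p_founder * (1 - p_founder) / (2 * sum(off)))
  expect_gt(mean(abs(p_off - p_founder) <= 3 * se), 0.95)
  # no directional bias across variants
  expect_lt(abs(mean(p_off - p_founder)),
            3 * sd(p_off - p_founder) / sqrt(length(p_founder)))
})

test_that("bull records carry the reliability structure they claim", {
  tbv <- rnorm(5000)
  rec <- sim_bull_records(tbv, h2 = 0.25, edc_range = c(1e9, 1e9), seed = 1)
  expect_true(all(rec$REL_EBV >= 0.999))  # EDC/(EDC+alpha) asymptote

  rec <- sim_bull_records(tbv, h2 = 0.25, edc_range = c(135, 135), seed = 1)
  expect_equal(unique(round(rec$REL_EBV, 10)), 135 / 150)  # alpha = 15

  set.seed(3)
  rec <- sim_bull_records(rnorm(5000), h2 = 0.3, edc_range = c(24, 971),
                          seed = 2)
  expect_equal(cor(rec$EBV, rec$TBV)^2, mean(rec$REL_EBV), tolerance = 0.05)
  expect_error(sim_bull_records(tbv, h2 = 1.2), "h2")
})

test_that("simulated phenotypes realize the target heritability", {
  G <- hw_geno(2500, 400, seed = 8)
  arch <- sim_trait(G, n_qtl = 50, h2 = 0.4, seed = 9)
  y <- sim_phenotypes(arch, seed = 10)
  slope <- coef(lm(y ~ arch$tbv))[2]
  expect_equal(unname(slope), 1, tolerance = 0.05)
  expect_equal(var(arch$tbv) / var(y), 0.4, tolerance = 0.1)
})

test_that("sim_dataset is reproducible and structurally coherent", {
  sim <- shared_sim()
  expect_true(all(sim$panels$K50 %in% sim$panels$ISQ))
  expect_true(all(sim$arch$qtl_ids %in% sim$geno$map$id))
  expect_equal(sort(unique(sim$records$cohort)),
               c("discovery", "validation"))
  sim2 <- sim_dataset(n_sires = 8, sons_per_sire = 15, n_generations = 2,
                      n_chrom = 2, variants_per_chrom = 400, n_qtl = 8,
                      h2 = 0.5, seed = 42)
  expect_identical(sim$geno$X, sim2$geno$X)
  expect_identical(sim$records, sim2$records)
})
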