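#!/usr/bin/env Rscript
# Build the desk-scale study population: a half-sib structured cattle-like
# pedigree with LD-structured dense variants, three polygenic-plus-QTL
# traits on shared genotypes, and progeny-based bull records. Writes
# population summaries under results/ and the PLINK/TSV filesets under
# scratch/ (large, regenerable). Everything downstream re-derives the same
# population from the seed recorded in results/population_config.tsv.

library(gpresel)

seed <- 20260923L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

sim <- sim_dataset(n_sires = 20, sons_per_sire = 25, n_generations = 2,
                   n_chrom = 3, variants_per_chrom = 4000,
                   n_qtl = 50, h2 = 0.6, seed = seed)

cfg <- data.frame(parameter = c("seed", "n_sires", "sons_per_sire",
                                "n_generations", "n_chrom",
                                "variants_per_chrom", "n_qtl", "h2",
                                "qtl_var_frac"),
                  value = c(seed, 20, 25, 2, 3, 4000, 50, 0.6, 0.3))
write.table(cfg, "results/population_config.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ped <- sim$pedigree
message(sprintf("population: %d individuals (%d discovery, %d validation), %d variants",
                nrow(ped), sum(ped$cohort == "discovery"),
                sum(ped$cohort == "validation"), ncol(sim$geno$X)))
val <- ped[ped$cohort == "validation", ]
sire_in_disc <- mean(ped$cohort[match(val$sire, ped$id)] == "discovery")
message(sprintf("validation animals with a discovery sire: %.0f%%",
                100 * sire_in_disc))

# LD decay profile of the realized genotypes (chromosome 1)
G <- sim$geno
on1 <- which(G$map$chrom == 1)
set.seed(1)
pairs <- data.frame(sep = rep(c(1, 5, 10, 25, 50, 100), each = 200))
pairs$r2 <- vapply(seq_len(nrow(pairs)), function(i) {
  a <- sample(on1[seq_len(length(on1) - pairs$sep[i])], 1)
  suppressWarnings(cor(G$X[, a], G$X[, a + pairs$sep[i]])^2)
}, numeric(1))
ld <- aggregate(r2 ~ sep, data = pairs, FUN = mean, na.rm = TRUE)
ld$dist_kb <- ld$sep * diff(G$map$bp[on1])[1] / 1000
write.table(ld, "results/ld_decay.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("mean adjacent-pair r2: ", round(ld$r2[1], 3),
        " (at ", round(ld$dist_kb[1]), " kb)")

# cohort summary
summ <- aggregate(cbind(EDC_EBV, REL_EBV) ~ cohort, data = sim$records,
                  FUN = mean)
write.table(summ, "results/cohort_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# persist the full fileset for inspection (regenerable; kept out of results/)
write_plink(sim$geno, "scratch/population")
write.table(sim$records, "scratch/bull_records.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
truth <- data.frame(id = sim$arch$qtl_ids, effect = sim$arch$qtl_effects)
write.table(truth, "results/qtl_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/population_config.tsv, ld_decay.tsv, cohort_summary.tsv, qtl_truth.tsv")
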