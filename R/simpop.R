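#' Chromosome map for the simulator
#'
#' Describes one simulated chromosome: a strictly increasing vector of
#' 1-based bp positions inside `[1, length_bp]`. Real bovine data span 29
#' autosomes; simulations typically scale this down to a handful of
#' chromosomes with proportionally fewer variants.
#'
#' @param chrom_id integer chromosome id.
#' @param n_variants number of variants to place.
#' @param length_bp chromosome length in bp.
#' @param positions optional integer positions; when `NULL`, positions are
#'   evenly spaced with deterministic jitter-free rounding.
#' @return an object of class `chrom_map`.
#' @export
chrom_map <- function(chrom_id, n_variants, length_bp, positions = NULL) {
  stopifnot(n_variants >= 1, length_bp >= n_variants)
  if (is.null(positions)) {
    positions <- unique(round(seq(1, length_bp, length.out = n_variants)))
    # rounding collisions only at silly densities; enforce the contract
    if (length(positions) < n_variants) {
      positions <- seq_len(n_variants) * (length_bp %/% n_variants)
    }
  }
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  if (positions[1] < 1 || positions[length(positions)] > length_bp) {
    stop("positions must lie in [1, length_bp]")
  }
  structure(list(chrom_id = as.integer(chrom_id),
                 n_variants = length(positions),
                 length_bp = as.integer(length_bp),
                 positions = positions),
            class = "chrom_map")
}

#' Half-sib family pedigree with a discovery/validation cohort split
#'
#' Generates a multi-generation pedigree of the kind found in progeny-tested
#' dairy cattle: a set of elite sires each mated to unrelated dams, producing
#' paternal half-sib families; sons of one generation become the sires of the
#' next. The final generation can be assigned to a validation cohort while
#' all earlier animals form the discovery cohort, emulating a birth-year
#' split in which most validation animals have a discovery-cohort sire.
#'
#' @param n_sires sires used per generation.
#' @param sons_per_sire sons per sire per generation (each from a distinct,
#'   newly introduced unrelated dam).
#' @param n_generations number of son generations to produce.
#' @param validation_last_gen if `TRUE` (default), the last generation is
#'   cohort `"validation"`; all other animals are `"discovery"`.
#' @param seed integer seed (reserved for future stochastic mating designs;
#'   the default design is deterministic).
#' @return data.frame of class `pedigree` with columns `id`, `sire`, `dam`,
#'   `generation`, `cohort`, `sex`.
#' @export
make_pedigree <- function(n_sires, sons_per_sire, n_generations,
                          validation_last_gen = TRUE, seed = 1L) {
  if (n_sires < 1 || sons_per_sire < 1 || n_generations < 1) {
    stop("n_sires, sons_per_sire and n_generations must all be >= 1")
  }
  ped <- data.frame(id = paste0("S0_", seq_len(n_sires)),
                    sire = NA_character_, dam = NA_character_,
                    generation = 0L, sex = "M", stringsAsFactors = FALSE)
  sires <- ped$id
  for (g in seq_len(n_generations)) {
    n_off <- n_sires * sons_per_sire
    dams <- data.frame(id = paste0("D", g, "_", seq_len(n_off)),
                       sire = NA_character_, dam = NA_character_,
                       generation = g - 1L, sex = "F",
                       stringsAsFactors = FALSE)
    sons <- data.frame(id = paste0("S", g, "_", seq_len(n_off)),
                       sire = rep(sires, each = sons_per_sire),
                       dam = dams$id, generation = g, sex = "M",
                       stringsAsFactors = FALSE)
    ped <- rbind(ped, dams, sons)
    sires <- sons$id[seq_len(min(n_sires, nrow(sons)))]
  }
  last <- max(ped$generation)
  ped$cohort <- if (validation_last_gen) {
    ifelse(ped$generation == last, "validation", "discovery")
  } else "discovery"
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Simulate founder haplotypes with first-order Markov linkage disequilibrium
#'
#' Builds a binary haplotype pool in which the allele at each site is, with
#' probability `ld_rho`, copied from the previous site of the same haplotype
#' and otherwise drawn fresh at that site's frequency. Adjacent-site allelic
#' correlation is then approximately `ld_rho` and decays geometrically with
#' distance, giving the long-range LD structure that makes variant selection
#' hard in dense cattle data. Sites whose realized minor allele frequency
#' falls below `maf_low` (including monomorphic sites) are redrawn as
#' independent sites until the pool satisfies the frequency floor.
#'
#' @param chrom_map a [chrom_map] (or list of them; haplotypes are simulated
#'   per chromosome and LD never crosses a chromosome boundary).
#' @param maf_low lower bound on realized MAF, in (0, 0.5).
#' @param ld_rho copying probability in \[0, 1).
#' @param n_haplotypes pool size (even).
#' @param seed integer seed.
#' @return binary matrix, haplotypes in rows, variants in columns; attribute
#'   `"map"` holds the variant table.
#' @export
sim_founder_haplotypes <- function(chrom_map, maf_low = 0.05, ld_rho = 0.9,
                                   n_haplotypes = 200L, seed = 1L) {
  if (inherits(chrom_map, "chrom_map")) chrom_map <- list(chrom_map)
  stopifnot(maf_low > 0, maf_low < 0.5)
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (n_haplotypes %% 2 != 0) stop("n_haplotypes must be even")
  set.seed(seed)
  blocks <- vector("list", length(chrom_map))
  maps <- vector("list", length(chrom_map))
  for (ci in seq_along(chrom_map)) {
    cm <- chrom_map[[ci]]
    m <- cm$n_variants
    f <- stats::runif(m, maf_low, 1 - maf_low)
    H <- matrix(0L, n_haplotypes, m)
    H[, 1] <- stats::rbinom(n_haplotypes, 1L, f[1])
    if (m > 1) {
      for (i in 2:m) {
        copy <- stats::runif(n_haplotypes) < ld_rho
        fresh <- stats::rbinom(n_haplotypes, 1L, f[i])
        H[, i] <- ifelse(copy, H[, i - 1], fresh)
      }
    }
    # frequency floor: redraw rare/monomorphic sites as independent sites
    repeat {
      maf <- pmin(colMeans(H), 1 - colMeans(H))
      bad <- which(maf < maf_low)
      if (length(bad) == 0) break
      for (i in bad) {
        H[, i] <- stats::rbinom(n_haplotypes, 1L,
                                stats::runif(1, 0.5 * (maf_low + 0.5), 0.5))
      }
    }
    blocks[[ci]] <- H
    maps[[ci]] <- data.frame(
      chrom = cm$chrom_id,
      id = paste0("v", cm$chrom_id, "_", seq_len(m)),
      bp = cm$positions,
      a1 = "A", a2 = "B",
      length_bp = cm$length_bp,
      stringsAsFactors = FALSE
    )
  }
  H <- do.call(cbind, blocks)
  attr(H, "map") <- do.call(rbind, maps)
  H
}

# one recombinant gamete per (parent haplotype pair); vectorized over sites
.recombine <- function(h1, h2, rec_prob, u_start, u_cross) {
  cross <- u_cross < rec_prob
  src <- (cumsum(c(u_start < 0.5, cross)) %% 2L)[seq_along(h1)]
  ifelse(src == 0L, h1, h2)
}

#' Drop founder haplotypes through a pedigree with recombination
#'
#' Founders receive consecutive haplotype pairs from the pool; every
#' non-founder inherits one recombinant gamete from each parent. Crossover
#' probability between adjacent variants comes from Haldane's map function
#' `c = (1 - exp(-2d))/2` with `d` the bp gap scaled to `morgans_per_chrom`
#' Morgans over the chromosome length (uniform recombination rate).
#'
#' @param pedigree a [make_pedigree] result (any data.frame with `id`,
#'   `sire`, `dam`, ordered so parents precede offspring).
#' @param founders haplotype pool from [sim_founder_haplotypes].
#' @param morgans_per_chrom genetic length of each chromosome in Morgans
#'   (default 1, roughly a bovine autosome).
#' @param seed integer seed.
#' @param keep_gametes retain the phased gametes in attribute `"gametes"`
#'   (default `FALSE`; they double the memory footprint of dense genomes).
#' @return a [geno_matrix] of dosages (count of allele `"A"`) for every
#'   pedigree member.
#' @export
gene_drop <- function(pedigree, founders, morgans_per_chrom = 1, seed = 1L,
                      keep_gametes = FALSE) {
  map <- attr(founders, "map")
  if (is.null(map)) stop("founders must carry a variant map attribute")
  founder_rows <- which(is.na(pedigree$sire) & is.na(pedigree$dam))
  n_founders <- length(founder_rows)
  if (nrow(founders) < 2 * n_founders) {
    stop("founder haplotype pool too small: need ", 2 * n_founders,
         " haplotypes for ", n_founders, " founders, have ", nrow(founders))
  }
  set.seed(seed)
  m <- nrow(map)
  # per-gap recombination probabilities within chromosomes (0 across)
  gap_bp <- diff(map$bp)
  same_chr <- diff(map$chrom) == 0L
  d <- ifelse(same_chr, morgans_per_chrom * gap_bp / map$length_bp[-1], NA)
  rec_prob <- ifelse(same_chr, 0.5 * (1 - exp(-2 * d)), 0.5)
  n <- nrow(pedigree)
  gam1 <- matrix(0L, n, m)  # paternal
  gam2 <- matrix(0L, n, m)  # maternal
  idx <- stats::setNames(seq_len(n), pedigree$id)
  next_h <- 1L
  for (r in seq_len(n)) {
    s <- pedigree$sire[r]; dd <- pedigree$dam[r]
    if (is.na(s) && is.na(dd)) {
      gam1[r, ] <- founders[next_h, ]
      gam2[r, ] <- founders[next_h + 1L, ]
      next_h <- next_h + 2L
    } else {
      if (is.na(s) || is.na(dd)) stop("half-specified parentage for ",
                                      pedigree$id[r])
      ps <- idx[[s]]; pd <- idx[[dd]]
      if (is.null(ps) || is.null(pd) || ps >= r || pd >= r) {
        stop("parents must precede offspring in the pedigree")
      }
      gam1[r, ] <- .recombine(gam1[ps, ], gam2[ps, ], rec_prob,
                              stats::runif(1), stats::runif(m - 1))
      gam2[r, ] <- .recombine(gam1[pd, ], gam2[pd, ], rec_prob,
                              stats::runif(1), stats::runif(m - 1))
    }
  }
  G <- geno_matrix(gam1 + gam2,
                   map[, c("chrom", "id", "bp", "a1", "a2")],
                   ids = pedigree$id)
  if (keep_gametes) {
    attr(G, "gametes") <- list(paternal = gam1, maternal = gam2)
  }
  G
}

#' Assign a trait architecture and true breeding values
#'
#' Builds the architecture typical of quantitative dairy traits: `n_qtl`
#' named large-effect loci with normal per-allele effects, carrying
#' `qtl_var_frac` of the genetic variance, on top of a polygenic background
#' spread over every other variant (standardized infinitesimal effects)
#' carrying the rest. `qtl_var_frac = 1` gives a pure oligogenic trait.
#' Phenotypes simulated at heritability `h2` are `TBV + e` with
#' `var(e) = var(TBV) (1 - h2)/h2`.
#'
#' @param G a [geno_matrix].
#' @param n_qtl number of large-effect causal variants.
#' @param h2 target heritability in (0, 1).
#' @param qtl_var_frac fraction of the genetic variance carried by the named
#'   QTL (default 0.3; most of the variance of traits like yield, fertility
#'   or somatic cell score is polygenic).
#' @param seed integer seed.
#' @return list of class `trait_architecture` with `qtl_ids`, `qtl_effects`
#'   (per-allele, on the TBV scale), `bg_effects` (per-allele background
#'   effects, named by variant; `NULL` when `qtl_var_frac = 1`), `tbv`
#'   (named by individual), `h2`, `qtl_var_frac`, `var_tbv`.
#' @export
sim_trait <- function(G, n_qtl, h2, qtl_var_frac = 0.3, seed = 1L) {
  stopifnot(inherits(G, "geno_matrix"), n_qtl >= 1, h2 > 0, h2 < 1,
            qtl_var_frac > 0, qtl_var_frac <= 1)
  set.seed(seed)
  m <- ncol(G$X)
  qtl <- sort(sample.int(m, n_qtl))
  a <- stats::rnorm(n_qtl)
  Xc <- sweep(G$X[, qtl, drop = FALSE], 2, 2 * G$p[qtl])
  g_qtl <- drop(Xc %*% a)
  if (qtl_var_frac < 1 && m > n_qtl) {
    bg <- setdiff(seq_len(m), qtl)
    sbg <- sqrt(2 * G$p[bg] * (1 - G$p[bg]))
    Wb <- sweep(sweep(G$X[, bg, drop = FALSE], 2, 2 * G$p[bg]), 2, sbg, "/")
    b <- stats::rnorm(length(bg), sd = sqrt(1 / length(bg)))
    g_bg <- drop(Wb %*% b)
    cq <- sqrt(qtl_var_frac) / stats::sd(g_qtl)
    cb <- sqrt(1 - qtl_var_frac) / stats::sd(g_bg)
    tbv <- cq * g_qtl + cb * g_bg
    qtl_eff <- a * cq
    bg_eff <- stats::setNames(b * cb / sbg, G$map$id[bg])
  } else {
    tbv <- g_qtl
    qtl_eff <- a
    bg_eff <- NULL
  }
  names(tbv) <- G$ids
  structure(list(qtl_ids = G$map$id[qtl], qtl_effects = qtl_eff,
                 bg_effects = bg_eff, tbv = tbv, h2 = h2,
                 qtl_var_frac = qtl_var_frac, var_tbv = stats::var(tbv)),
            class = "trait_architecture")
}

#' Simulate phenotypes at a target heritability
#'
#' @param arch a [sim_trait] result.
#' @param seed integer seed.
#' @return numeric vector of phenotypes, named by individual.
#' @export
sim_phenotypes <- function(arch, seed = 1L) {
  set.seed(seed)
  ve <- arch$var_tbv * (1 - arch$h2) / arch$h2
  arch$tbv + stats::rnorm(length(arch$tbv), sd = sqrt(ve))
}

#' Simulate progeny-tested bull records
#'
#' Emulates national-evaluation output for progeny-tested bulls: each bull
#' gets an effective daughter contribution (EDC) drawn uniformly from
#' `edc_range`, the implied reliability `REL = EDC/(EDC + alpha)` with
#' `alpha = (4 - h2)/h2`, and an EBV regressed toward the mean,
#' `EBV = REL * TBV + e` with `var(e) = REL (1 - REL) var(TBV)` so that
#' `cor(EBV, TBV)^2 = REL`. Parent averages and parent reliabilities are
#' generated consistently (parent-average reliability strictly below the
#' bull's own) so that de-regression is always well defined.
#'
#' @param tbv named numeric vector of true breeding values.
#' @param h2 trait heritability in (0, 1).
#' @param edc_range length-2 numeric, uniform EDC range (e.g. `c(24, 971)`).
#' @param seed integer seed.
#' @return data.frame with columns `id`, `TBV`, `EDC_EBV`, `REL_EBV`, `EBV`,
#'   `PA`, `REL_sire`, `REL_dam`, `h2`.
#' @export
sim_bull_records <- function(tbv, h2, edc_range = c(24, 971), seed = 1L) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  if (edc_range[1] <= 0 || edc_range[1] > edc_range[2]) {
    stop("edc_range must satisfy 0 < low <= high")
  }
  set.seed(seed)
  n <- length(tbv)
  al <- alpha_of(h2)
  edc <- stats::runif(n, edc_range[1], edc_range[2])
  rel <- edc / (edc + al)
  vt <- stats::var(tbv)
  if (is.na(vt) || vt == 0) vt <- 1
  ebv <- rel * tbv + stats::rnorm(n, sd = sqrt(rel * (1 - rel) * vt))
  # parent reliabilities: REL_PA = (REL_s + REL_d)/4 kept below 0.8 * REL_EBV
  rel_s <- stats::runif(n, 0.2, 0.9)
  rel_d <- stats::runif(n, 0.05, 0.5)
  cap <- 0.8 * rel
  over <- (rel_s + rel_d) / 4 > cap
  scl <- ifelse(over, cap / ((rel_s + rel_d) / 4), 1)
  rel_s <- rel_s * scl
  rel_d <- rel_d * scl
  rel_pa <- (rel_s + rel_d) / 4
  pa <- rel_pa * tbv + stats::rnorm(n, sd = sqrt(pmax(rel_pa * (1 - rel_pa), 0) * vt))
  data.frame(id = if (is.null(names(tbv))) paste0("ind_", seq_len(n)) else names(tbv),
             TBV = as.numeric(tbv), EDC_EBV = edc, REL_EBV = rel, EBV = ebv,
             PA = pa, REL_sire = rel_s, REL_dam = rel_d, h2 = h2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a complete study population
#'
#' One-call convenience wrapper: pedigree, LD-structured founder haplotypes,
#' gene dropping, trait architecture, bull records and panel subsets
#' (a dense "sequence" set plus thinned "HD" and "50k"-like arrays). Defaults
#' give a desk-scale population; all sizes are arguments.
#'
#' @param n_sires,sons_per_sire,n_generations pedigree design
#'   (see [make_pedigree]).
#' @param n_chrom,variants_per_chrom,chrom_length_bp genome design.
#' @param ld_rho,maf_low founder LD and frequency floor.
#' @param n_qtl,h2,qtl_var_frac trait architecture (see [sim_trait]).
#' @param edc_range EDC range for bull records.
#' @param panel_fracs named fractions of variants for the thinned panels.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `sim_dataset`: `geno`, `pedigree`, `arch`,
#'   `records`, `panels` (list of variant id vectors incl. `ISQ` = all).
#' @export
sim_dataset <- function(n_sires = 20, sons_per_sire = 25, n_generations = 2,
                        n_chrom = 3, variants_per_chrom = 2000,
                        chrom_length_bp = 1e8, ld_rho = 0.9, maf_low = 0.03,
                        n_qtl = 30, h2 = 0.5, qtl_var_frac = 0.3,
                        edc_range = c(24, 971),
                        panel_fracs = c(HD = 0.25, K50 = 0.05), seed = 1L) {
  ped <- make_pedigree(n_sires, sons_per_sire, n_generations, seed = seed)
  cms <- lapply(seq_len(n_chrom), function(ci)
    chrom_map(ci, variants_per_chrom, chrom_length_bp))
  n_founders <- sum(is.na(ped$sire) & is.na(ped$dam))
  H <- sim_founder_haplotypes(cms, maf_low = maf_low, ld_rho = ld_rho,
                              n_haplotypes = 2 * n_founders, seed = seed + 1L)
  G <- gene_drop(ped, H, morgans_per_chrom = 1, seed = seed + 2L)
  G <- filter_maf(G, 0.01)
  arch <- sim_trait(G, n_qtl = n_qtl, h2 = h2, qtl_var_frac = qtl_var_frac,
                    seed = seed + 3L)
  rec <- sim_bull_records(arch$tbv, h2 = h2, edc_range = edc_range,
                          seed = seed + 4L)
  rec$cohort <- ped$cohort[match(rec$id, ped$id)]
  m <- ncol(G$X)
  set.seed(seed + 5L)
  panels <- list(ISQ = G$map$id)
  for (nm in names(panel_fracs)) {
    k <- max(2L, round(panel_fracs[[nm]] * m))
    panels[[nm]] <- G$map$id[sort(sample.int(m, k))]
  }
  structure(list(geno = G, pedigree = ped, arch = arch, records = rec,
                 panels = panels, seed = seed),
            class = "sim_dataset")
}
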