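#' Variant-selection configuration
#'
#' Encodes the selection rules for the five supported modes, with each
#' mode's conventional defaults:
#' * `PVAL`: plain marginal `-log10(p) > logp_enter` thresholding.
#' * `COJO3` / `COJO5`: forward conditional selection among variants
#'   prefiltered at marginal `-log10(p) > 3`; candidates in LD `r^2 > 0.8`
#'   with an already-selected variant are never added; entry requires
#'   conditional `-log10(p) >= 3` (resp. 5).
#' * `COJO5LD`: no prefilter; pairs more than 100 Mb apart (or on different
#'   chromosomes) are treated as independent (`r^2 = 0`); LD cap `r^2 > 0.5`;
#'   entry at conditional `-log10(p) >= 5`.
#' * `COJO_TOPN`: as `COJO5LD` but with no significance gate; the `top_n`
#'   most conditionally significant variants (or largest conditional
#'   effects, see `rank_by`) are taken.
#'
#' @param mode one of `"PVAL"`, `"COJO3"`, `"COJO5"`, `"COJO5LD"`,
#'   `"COJO_TOPN"`.
#' @param logp_enter,r2_cap,max_ld_dist_bp,prefilter_logp,top_n overrides of
#'   the mode defaults.
#' @param rank_by for `COJO_TOPN`: rank candidates by conditional
#'   significance (`"p"`, default) or absolute conditional effect
#'   (`"effect"`).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(mode = c("PVAL", "COJO3", "COJO5", "COJO5LD",
                                      "COJO_TOPN"),
                             logp_enter = NULL, r2_cap = NULL,
                             max_ld_dist_bp = NULL, prefilter_logp = NULL,
                             top_n = NULL, rank_by = c("p", "effect")) {
  mode <- match.arg(mode)
  rank_by <- match.arg(rank_by)
  def <- switch(mode,
    PVAL      = list(logp_enter = 5, r2_cap = 1, max_ld_dist_bp = Inf,
                     prefilter_logp = NULL, top_n = NULL),
    COJO3     = list(logp_enter = 3, r2_cap = 0.8, max_ld_dist_bp = Inf,
                     prefilter_logp = 3, top_n = NULL),
    COJO5     = list(logp_enter = 5, r2_cap = 0.8, max_ld_dist_bp = Inf,
                     prefilter_logp = 3, top_n = NULL),
    COJO5LD   = list(logp_enter = 5, r2_cap = 0.5, max_ld_dist_bp = 100e6,
                     prefilter_logp = NULL, top_n = NULL),
    COJO_TOPN = list(logp_enter = 0, r2_cap = 0.5, max_ld_dist_bp = 100e6,
                     prefilter_logp = NULL, top_n = 100)
  )
  ovr <- list(logp_enter = logp_enter, r2_cap = r2_cap,
              max_ld_dist_bp = max_ld_dist_bp,
              prefilter_logp = prefilter_logp, top_n = top_n)
  for (nm in names(ovr)) if (!is.null(ovr[[nm]])) def[[nm]] <- ovr[[nm]]
  if (def$r2_cap <= 0 || def$r2_cap > 1) stop("r2_cap must be in (0, 1]")
  structure(c(list(mode = mode, rank_by = rank_by), def),
            class = "selection_config")
}

#' Threshold-based variant selection
#'
#' @param assoc an [mlma_scan] table.
#' @param logp select variants with `-log10(p) > logp`.
#' @return character vector of selected variant ids.
#' @export
select_pval <- function(assoc, logp) {
  stopifnot(inherits(assoc, "assoc_table") || is.data.frame(assoc))
  if (nrow(assoc) == 0) stop("empty association table")
  sel <- assoc$SNP[-log10(assoc$p) > logp]
  if (length(sel) == 0) warning("no variant passes -log10(p) > ", logp)
  sel
}

#' Conditional-and-joint forward variant selection
#'
#' Greedy forward selection on individual-level data under the fixed null
#' covariance: at each step every remaining candidate's conditional Wald
#' statistic (given the variants already in the model) is computed by
#' residualizing the whitened dosages against the current model, and the
#' most significant eligible candidate is added. Eligibility rules:
#'
#' * LD cap: a candidate whose dosage `r^2` with any selected variant
#'   exceeds `cfg$r2_cap` is rejected permanently (reason `"LD cap"`);
#'   pairs farther apart than `cfg$max_ld_dist_bp` (or on different
#'   chromosomes when that cap is finite) are treated as independent.
#' * Collinearity: candidates whose residual norm after projection on the
#'   model falls below `1e-8` of their original norm are rejected (reason
#'   `"collinearity"`) — the individual-level analogue of a condition-number
#'   cap, and the guard against the grossly overestimated conditional
#'   effects that collinear adds produce.
#' * Entry: conditional `-log10(p) >= cfg$logp_enter` and a strict decrease
#'   (tolerance `1e-12`) in the joint-model residual variance. `COJO_TOPN`
#'   drops the significance gate and stops after `top_n` accepts.
#'
#' Ties in conditional significance are broken by ascending
#' (chromosome, bp, id), making the selection order deterministic.
#'
#' @param assoc an [mlma_scan] table for the same variants as `G`.
#' @param G a [geno_matrix] holding the candidate dosages.
#' @param y response vector (de-regressed proofs).
#' @param null a [fit_null] result (fixed variance components).
#' @param cfg a [selection_config].
#' @return object of class `selection_result`: `selected` (ids in selection
#'   order), `table` (per selected variant: marginal and joint effects,
#'   conditional p, entry step), `audit` (accept/reject trail with reasons),
#'   `rss_path` (joint residual variance after each accept), `cfg`.
#' @export
cojo_select <- function(assoc, G, y, null, cfg) {
  stopifnot(inherits(G, "geno_matrix"), inherits(null, "null_model"),
            inherits(cfg, "selection_config"))
  a <- as.data.frame(assoc)
  ai <- match(G$map$id, a$SNP)
  if (anyNA(ai)) stop("association table does not cover all variants in G")
  a <- a[ai, ]
  n <- length(y)
  cand <- seq_len(ncol(G$X))
  if (!is.null(cfg$prefilter_logp)) {
    cand <- cand[-log10(a$p) > cfg$prefilter_logp]
  }
  cand <- cand[!vapply(cand, function(j) stats::var(G$X[, j]) == 0, logical(1))]
  empty <- function() {
    structure(list(selected = character(0),
                   table = data.frame(), audit = data.frame(),
                   rss_path = numeric(0), cfg = cfg),
              class = "selection_result")
  }
  if (length(cand) == 0) return(empty())

  yw <- drop(null$Wh %*% y)
  ow <- drop(null$Wh %*% rep(1, n))
  Gw <- null$Wh %*% G$X[, cand, drop = FALSE]
  q0 <- ow / sqrt(sum(ow^2))
  yp <- yw - q0 * sum(q0 * yw)
  Gp <- Gw - outer(q0, colSums(q0 * Gw))
  norm0 <- colSums(Gp^2)  # reference norms for the collinearity guard
  rss <- sum(yp^2)
  rss_path <- numeric(0)
  sel <- integer(0)       # indices into cand
  alive <- rep(TRUE, length(cand))
  audit <- list()
  tab <- list()
  step <- 0L
  chrom <- G$map$chrom[cand]
  bp <- G$map$bp[cand]
  ids <- G$map$id[cand]

  reject <- function(j, reason, logp = NA_real_) {
    alive[j] <<- FALSE
    audit[[length(audit) + 1L]] <<- data.frame(
      step = step + 1L, id = ids[j], action = "rejected", reason = reason,
      cond_logp = logp, stringsAsFactors = FALSE)
  }

  repeat {
    live <- which(alive)
    if (length(live) == 0) break
    xx <- colSums(Gp[, live, drop = FALSE]^2)
    xy <- colSums(Gp[, live, drop = FALSE] * yp)
    collin <- xx < 1e-8 * norm0[live]
    if (any(collin)) {
      for (j in live[collin]) reject(j, "collinearity")
      live <- live[!collin]
      xx <- xx[!collin]
      xy <- xy[!collin]
      if (length(live) == 0) break
    }
    chi <- xy^2 / xx
    bcond <- xy / xx
    keyval <- if (cfg$mode == "COJO_TOPN" && cfg$rank_by == "effect") {
      abs(bcond)
    } else chi
    bl <- order(-keyval, chrom[live], bp[live], ids[live])[1]
    j <- live[bl]
    logp_cond <- -stats::pchisq(chi[bl], 1, lower.tail = FALSE,
                                log.p = TRUE) / log(10)
    if (cfg$mode != "COJO_TOPN" && logp_cond < cfg$logp_enter) {
      break  # candidates are ranked: nothing remaining qualifies
    }
    if (chi[bl] <= 1e-12) {
      reject(j, "no variance gain", logp_cond)
      break  # the best candidate explains nothing; neither will the rest
    }
    step <- step + 1L
    qv <- Gp[, j] / sqrt(sum(Gp[, j]^2))
    yp <- yp - qv * sum(qv * yp)
    Gp <- Gp - outer(qv, colSums(qv * Gp))
    rss <- rss - chi[bl]
    rss_path <- c(rss_path, rss)
    sel <- c(sel, j)
    alive[j] <- FALSE
    audit[[length(audit) + 1L]] <- data.frame(
      step = step, id = ids[j], action = "selected", reason = "",
      cond_logp = logp_cond, stringsAsFactors = FALSE)
    tab[[length(tab) + 1L]] <- data.frame(
      step = step, id = ids[j], chrom = chrom[j], bp = bp[j],
      b_marginal = a$b[cand[j]], p_marginal = a$p[cand[j]],
      b_cond = bcond[bl],
      p_cond = stats::pchisq(chi[bl], 1, lower.tail = FALSE),
      stringsAsFactors = FALSE)
    if (!is.null(cfg$top_n) && length(sel) >= cfg$top_n) break
    # permanently retire candidates in disqualifying LD with the new variant
    live <- which(alive)
    if (length(live) > 0) {
      linked <- if (is.finite(cfg$max_ld_dist_bp)) {
        chrom[live] == chrom[j] & abs(bp[live] - bp[j]) <= cfg$max_ld_dist_bp
      } else rep(TRUE, length(live))
      if (any(linked)) {
        r <- suppressWarnings(
          stats::cor(G$X[, cand[j]], G$X[, cand[live[linked]], drop = FALSE]))
        r[is.na(r)] <- 0
        for (jj in live[linked][r[1, ]^2 > cfg$r2_cap]) reject(jj, "LD cap")
      }
    }
  }

  if (length(sel) == 0) return(empty())
  tab <- do.call(rbind, tab)
  # joint effects: one GLS fit of all selected variants together
  Xj <- cbind(ow, Gw[, sel, drop = FALSE])
  bj <- qr.coef(qr(Xj), yw)
  tab$b_joint <- unname(bj[-1])
  audit <- do.call(rbind, audit)
  structure(list(selected = tab$id, table = tab, audit = audit,
                 rss_path = rss_path, cfg = cfg),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d variant(s) selected, %d rejected\n",
              x$cfg$mode, length(x$selected),
              sum(x$audit$action == "rejected")))
  invisible(x)
}

#' Exclusion list feeding the complementary GRM
#'
#' For threshold (`PVAL`) selections the complementary set simply drops the
#' selected variants. For conditional selections, many unselected variants
#' remain in strong LD with the selected ones, so the selected variants plus
#' every variant in significant LD with them (chi-square test at
#' `p < p_thresh`, searched within `window_bp` on either side) are excluded
#' via [ld_exclusion_set].
#'
#' @param selected character vector of selected variant ids, or a
#'   `selection_result`.
#' @param G a [geno_matrix].
#' @param mode `"PVAL"` or any conditional mode.
#' @param window_bp,p_thresh see [ld_exclusion_set].
#' @return character vector of variant ids to exclude from the complement.
#' @export
exclusion_for_grmc <- function(selected, G, mode = "COJO",
                               window_bp = 2e6, p_thresh = 0.01) {
  if (inherits(selected, "selection_result")) {
    mode <- selected$cfg$mode
    selected <- selected$selected
  }
  if (length(selected) == 0) stop("empty selection")
  if (mode == "PVAL") return(as.character(selected))
  ld_exclusion_set(G, selected, window_bp = window_bp, p_thresh = p_thresh)
}

#' Write a selection report TSV
#'
#' @param sel a [cojo_select] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  utils::write.table(sel$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
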