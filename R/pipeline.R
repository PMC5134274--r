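#' Enumerate the default scenario grid of variant sets
#'
#' The study design crosses three variant sources — the full imputed
#' sequence set (`ISQ`) and two nested genotyping-array subsets (`HD`,
#' `K50`) — with selection rules. Three all-variant sets (one per source)
#' are trait-independent; per trait there are the two threshold selections
#' for each source plus the four conditional-selection modes on the full
#' sequence set, i.e. `3 + n_traits * (3 * 2 + 4)` variant sets — 33 for the
#' default three traits.
#'
#' @param traits character vector of trait labels (default three).
#' @param sources variant sources (default `ISQ`, `HD`, `K50`).
#' @return data.frame with columns `set_id`, `trait` (`NA` for all-variant
#'   sets), `source`, `selection`.
#' @export
scenario_grid <- function(traits = c("trait1", "trait2", "trait3"),
                          sources = c("ISQ", "HD", "K50")) {
  rows <- list()
  for (s in sources) {
    rows[[length(rows) + 1L]] <- data.frame(
      trait = NA_character_, source = s, selection = "NONE",
      stringsAsFactors = FALSE)
  }
  for (tr in traits) {
    for (s in sources) {
      for (sel in c("PVAL3", "PVAL5")) {
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, source = s, selection = sel, stringsAsFactors = FALSE)
      }
    }
    for (sel in c("COJO3", "COJO5", "COJO5LD", "COJO_TOP100")) {
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, source = sources[1], selection = sel,
        stringsAsFactors = FALSE)
    }
  }
  g <- do.call(rbind, rows)
  g$set_id <- paste0(ifelse(is.na(g$trait), "all", g$trait),
                     "_", g$source, "_", g$selection)
  g[, c("set_id", "trait", "source", "selection")]
}

.selection_cfg <- function(selection, top_n = 100) {
  switch(selection,
         COJO3 = selection_config("COJO3"),
         COJO5 = selection_config("COJO5"),
         COJO5LD = selection_config("COJO5LD"),
         COJO_TOP100 = selection_config("COJO_TOPN", top_n = top_n),
         stop("unknown conditional selection: ", selection))
}

#' Run one variant-selection / variance / prediction scenario
#'
#' Executes the full chain on a simulated dataset: de-regression of the bull
#' records, a discovery-only association scan against a structure GRM built
#' from the `structure_panel` subset, variant selection per `selection`,
#' construction of the selected-set GRM and (optionally) its complementary
#' GRM under the LD exclusion rule, validation-only variance estimation, and
#' discovery-trained GBLUP prediction scored on the validation animals via
#' back-solved variant effects.
#'
#' @param sim a [sim_dataset].
#' @param source variant source: a name of `sim$panels`.
#' @param selection `"NONE"`, `"PVAL3"`, `"PVAL5"`, `"COJO3"`, `"COJO5"`,
#'   `"COJO5LD"` or `"COJO_TOP100"`.
#' @param model `"GRM_ONLY"`, `"GRMC_ONLY"` or `"GRM_PLUS_GRMC"`. The
#'   complement is always taken within the full sequence set; an all-variant
#'   `ISQ` scenario therefore supports only `GRM_ONLY`.
#' @param structure_panel panel used for the association-scan structure GRM
#'   (default `"HD"`).
#' @param ld_window_bp,ld_p_thresh complementary-set LD exclusion rule
#'   (defaults 2 Mb, 0.01; applied for conditional selections only).
#' @param top_n size of the `COJO_TOP100` selection (default 100).
#' @param weight_by_edc weight REML residuals by progeny information
#'   (`EDC_prog`, scaled to mean 1) in the variance and training fits
#'   (default `FALSE`, the conventional unweighted analysis; the
#'   association scan is always unweighted).
#' @param verbose log stage progress via `message()`.
#' @return list of class `scenario_report`: `counts` (variant bookkeeping),
#'   `variance` (validation [genomic_h2] table), `metrics`
#'   ([validate_predictions] on the validation animals), `selection` (the
#'   `selection_result`, or `NULL`), `config`.
#' @export
run_scenario <- function(sim, source = "ISQ", selection = "NONE",
                         model = c("GRM_ONLY", "GRMC_ONLY", "GRM_PLUS_GRMC"),
                         structure_panel = "HD", ld_window_bp = 2e6,
                         ld_p_thresh = 0.01, top_n = 100,
                         weight_by_edc = FALSE, verbose = FALSE) {
  stopifnot(inherits(sim, "sim_dataset"))
  model <- match.arg(model)
  if (!source %in% names(sim$panels)) stop("unknown source: ", source)
  say <- function(...) if (verbose) message(sprintf(...))

  drp_tab <- deregress(sim$records)
  keep <- !drp_tab$excluded
  drp_tab <- drp_tab[keep, ]
  disc <- drp_tab$id[drp_tab$cohort == "discovery"]
  val <- drp_tab$id[drp_tab$cohort == "validation"]
  if (length(val) < 30) stop("validation cohort too small")
  drp <- stats::setNames(drp_tab$DRP, drp_tab$id)
  w <- if (weight_by_edc) {
    stats::setNames(drp_tab$EDC_prog / mean(drp_tab$EDC_prog), drp_tab$id)
  } else NULL
  say("deregress: %d records (%d discovery / %d validation), %d excluded",
      nrow(drp_tab), length(disc), length(val), sum(!keep))

  G <- sim$geno
  G_disc <- subset_geno(G, individuals = disc)
  src_ids <- sim$panels[[source]]

  sel_res <- NULL
  if (selection == "NONE") {
    selected <- src_ids
    exclusion <- src_ids
  } else {
    K_struct <- ensure_pd(build_grm(
      subset_geno(G_disc, variants = sim$panels[[structure_panel]])))
    null <- fit_null(drp[disc], K_struct)
    say("null model: h2 = %.3f (%d iterations)", null$fit$h2_total,
        null$fit$n_iter)
    G_src_disc <- subset_geno(G_disc, variants = src_ids)
    assoc <- mlma_scan(drp[disc], G_src_disc, null)
    if (selection %in% c("PVAL3", "PVAL5")) {
      selected <- select_pval(assoc, logp = if (selection == "PVAL3") 3 else 5)
      exclusion <- selected
    } else {
      cfg <- .selection_cfg(selection, top_n = top_n)
      sel_res <- cojo_select(assoc, G_src_disc, drp[disc], null, cfg)
      selected <- sel_res$selected
      exclusion <- if (length(selected) > 0) {
        exclusion_for_grmc(selected, G_disc, mode = cfg$mode,
                           window_bp = ld_window_bp, p_thresh = ld_p_thresh)
      } else character(0)
    }
    say("selection %s: %d variant(s) selected, %d excluded for the complement",
        selection, length(selected), length(exclusion))
  }
  if (length(selected) == 0) stop("selection produced an empty variant set")

  comp_ids <- setdiff(G$map$id, exclusion)
  if (model != "GRM_ONLY" && length(comp_ids) == 0) {
    stop("complementary set is empty; use model = \"GRM_ONLY\"")
  }

  # GRMs over all animals (combined-sample frequencies); cohort sub-blocks
  # are taken for validation-only variance estimation
  take_block <- function(K, ids) {
    i <- match(ids, K$ids)
    grm_matrix(K$K[i, i], N = K$N, diag_mode = K$diag_mode,
               source = K$source, ids = ids)
  }
  K_sel <- ensure_pd(build_grm(subset_geno(G, variants = selected),
                               source = "selected"))
  gc(FALSE)
  K_comp <- if (model != "GRM_ONLY") {
    ensure_pd(build_grm(subset_geno(G, variants = comp_ids),
                        source = "complementary"))
  } else NULL
  gc(FALSE)
  K_list_val <- switch(model,
                       GRM_ONLY = list(take_block(K_sel, val)),
                       GRMC_ONLY = list(take_block(K_comp, val)),
                       GRM_PLUS_GRMC = list(take_block(K_sel, val),
                                            take_block(K_comp, val)))
  est_val <- reml(drp[val], lapply(K_list_val, ensure_pd), weights = w[val])
  variance <- genomic_h2(est_val, force = TRUE)
  say("validation variance: total h2 = %.3f", est_val$h2_total)

  # training on discovery with crossprod GRMs for exact back-solving
  G_sel_disc <- subset_geno(G_disc, variants = selected)
  G_comp_disc <- if (model != "GRM_ONLY") {
    subset_geno(G_disc, variants = comp_ids)
  } else NULL
  G_train_list <- switch(model,
                         GRM_ONLY = list(G_sel_disc),
                         GRMC_ONLY = list(G_comp_disc),
                         GRM_PLUS_GRMC = list(G_sel_disc, G_comp_disc))
  K_train_list <- lapply(G_train_list, function(g) {
    k <- ensure_pd(build_grm(g, diag_mode = "crossprod"))
    gc(FALSE)
    k
  })
  est_train <- reml(drp[disc], K_train_list, weights = w[disc])
  pred <- gblup_train(drp[disc], K_train_list, est_train)
  eff <- backsolve_effects(pred, G_train_list)
  G_val <- subset_geno(G, individuals = val, recompute_freq = FALSE)
  gebv_val <- score_gebv(G_val, eff)
  metrics <- validate_predictions(drp[val], gebv_val)
  say("prediction: accuracy = %.3f, slope = %.3f", metrics$accuracy,
      metrics$slope)

  counts <- data.frame(
    source = source, selection = selection, model = model,
    n_source = length(src_ids), n_selected = length(selected),
    n_excluded_ld = length(exclusion) - length(selected),
    n_complement = length(comp_ids),
    n_discovery = length(disc), n_validation = length(val),
    stringsAsFactors = FALSE)
  structure(list(counts = counts, variance = variance, metrics = metrics,
                 selection = sel_res,
                 config = list(source = source, selection = selection,
                               model = model,
                               structure_panel = structure_panel,
                               ld_window_bp = ld_window_bp,
                               ld_p_thresh = ld_p_thresh, top_n = top_n)),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("scenario:", x$counts$source, "/", x$counts$selection, "/",
      x$counts$model, "\n")
  cat(sprintf("  %d selected of %d source variants; complement %d\n",
              x$counts$n_selected, x$counts$n_source, x$counts$n_complement))
  cat(sprintf("  validation h2 total = %.3f; accuracy = %.3f, slope = %.3f\n",
              x$variance$h2[x$variance$component == "total"],
              x$metrics$accuracy, x$metrics$slope))
  invisible(x)
}
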