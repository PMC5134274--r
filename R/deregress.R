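#' Daughter-equivalent scaling constant
#'
#' `alpha = (4 - h2)/h2` converts between reliability and effective daughter
#' contributions for a trait with heritability `h2`.
#'
#' @param h2 heritability in (0, 1].
#' @return numeric.
#' @export
alpha_of <- function(h2) {
  if (any(h2 <= 0 | h2 > 1)) stop("h2 must be in (0, 1]")
  (4 - h2) / h2
}

#' Effective daughter contribution from a reliability
#'
#' `EDC = alpha * rel / (1 - rel)`: the effective number of daughter
#' phenotypes behind an EBV of reliability `rel`.
#'
#' @param rel reliability in \[0, 1).
#' @param alpha scaling constant from [alpha_of].
#' @return numeric, monotone increasing in `rel`.
#' @export
edc_from_rel <- function(rel, alpha) {
  if (any(rel < 0 | rel >= 1)) stop("rel must be in [0, 1): rel = 1 implies infinite EDC")
  if (any(alpha <= 0)) stop("alpha must be positive")
  alpha * rel / (1 - rel)
}

#' De-regress estimated breeding values into pseudo-phenotypes
#'
#' Removes the parent-average contribution from each EBV and re-expands the
#' remaining deviation by the ratio of total to progeny-only information:
#' `DRP = PA + (EBV - PA) * EDC_EBV / EDC_prog`, where
#' `EDC_prog = EDC_EBV - EDC_PA`, `EDC_PA` comes from the parent-average
#' reliability `REL_PA = (REL_sire + REL_dam)/4`, and EDCs follow
#' [edc_from_rel] with `alpha = (4 - h2)/h2`. Records whose progeny
#' information content is non-positive (`EDC_prog <= 0`) cannot be
#' de-regressed; they are flagged `excluded` with a reason and their DRP is
#' `NA`. Missing parent reliabilities are treated as 0 (no parent
#' information), in which case `DRP = EBV`.
#'
#' @param records data.frame with columns `EBV`, `PA`, `REL_EBV`,
#'   `REL_sire`, `REL_dam`, `h2` (per-record heritability permitted), and
#'   optionally `id`.
#' @return the input with added columns `alpha`, `REL_PA`, `EDC_EBV`,
#'   `EDC_PA`, `EDC_prog`, `DRP`, `excluded` (logical), `exclude_reason`.
#'   The number of exclusions is reported via `message()`.
#' @export
deregress <- function(records) {
  req <- c("EBV", "PA", "REL_EBV", "REL_sire", "REL_dam", "h2")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  rec <- records
  rec$REL_sire[is.na(rec$REL_sire)] <- 0
  rec$REL_dam[is.na(rec$REL_dam)] <- 0
  if (any(rec$REL_EBV < 0 | rec$REL_EBV >= 1)) {
    stop("REL_EBV must be in [0, 1)")
  }
  al <- alpha_of(rec$h2)
  rel_pa <- (rec$REL_sire + rec$REL_dam) / 4
  edc_ebv <- edc_from_rel(rec$REL_EBV, al)
  edc_pa <- edc_from_rel(rel_pa, al)
  edc_prog <- edc_ebv - edc_pa
  ok <- edc_prog > 0
  drp <- ifelse(ok, rec$PA + (rec$EBV - rec$PA) * edc_ebv / edc_prog, NA_real_)
  rec$alpha <- al
  rec$REL_PA <- rel_pa
  rec$EDC_EBV <- edc_ebv
  rec$EDC_PA <- edc_pa
  rec$EDC_prog <- edc_prog
  rec$DRP <- drp
  rec$excluded <- !ok
  rec$exclude_reason <- ifelse(ok, "",
                               "non-positive progeny information (EDC_prog <= 0)")
  if (any(!ok)) {
    message(sum(!ok), " record(s) excluded from de-regression: EDC_prog <= 0")
  }
  rec
}

#' Read or write bull-record / de-regression TSVs
#'
#' `read_bull_records` expects at least (`id`, `EBV`, `PA`, `REL_EBV`,
#' `REL_sire`, `REL_dam`) plus either an `h2` column or the `h2` argument;
#' `write_drp` writes the full de-regression output.
#'
#' @param path TSV path.
#' @param h2 trait heritability used when the file has no `h2` column.
#' @param records de-regression output from [deregress].
#' @return a data.frame / `path` invisibly.
#' @export
read_bull_records <- function(path, h2 = NULL) {
  rec <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"h2" %in% names(rec)) {
    if (is.null(h2)) stop("file has no h2 column and no h2 was given")
    rec$h2 <- h2
  }
  rec
}

#' @rdname read_bull_records
#' @export
write_drp <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
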