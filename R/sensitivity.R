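#' Rerun the MR analysis after excluding named instruments
#'
#' Hypothesis-driven exclusions (e.g. a SNP suspected of population
#' stratification or of acting on the outcome through a pathway other
#' than the biomarker) are re-analysed simply by dropping the instrument
#' and repeating the full estimator on the remainder.
#'
#' @param records An `mr_instruments` data frame.
#' @param excluded_rsids Character vector of rsids to drop. Must be a
#'   subset of the available instruments. Empty means no exclusion.
#' @param config An [analysis_config].
#' @param name Optional plan label recorded on the result.
#' @return An `mr_analysis` (see [run_mr]) with attribute `plan`.
#' @export
exclude_and_rerun <- function(records, excluded_rsids,
                              config = analysis_config(), name = NULL) {
  unknown <- setdiff(excluded_rsids, records$rsid)
  if (length(unknown) > 0) {
    stop("excluded rsid(s) not among the instruments: ",
         paste(unknown, collapse = ", "))
  }
  keep <- !(records$rsid %in% excluded_rsids)
  if (!any(keep)) stop("exclusion removes every instrument")
  out <- run_mr(records[keep, , drop = FALSE], config)
  attr(out, "plan") <- if (is.null(name)) {
    if (length(excluded_rsids) == 0) "full" else
      paste0("minus_", paste(excluded_rsids, collapse = "+"))
  } else {
    name
  }
  out
}

#' Stratified MR by biological pathway
#'
#' Splits the instruments by their pathway label (synthesis versus
#' metabolism of the biomarker) and runs an independent analysis per
#' stratum. Heterogeneity confidence intervals are flagged unreliable
#' for two-SNP strata (see [cochran_q]).
#'
#' @param records An `mr_instruments` data frame; every row must carry a
#'   pathway label other than `"unknown"`.
#' @param config An [analysis_config].
#' @return A named list of `mr_analysis` objects, one per pathway.
#' @export
stratify_by_pathway <- function(records, config = analysis_config()) {
  if (any(is.na(records$pathway) | records$pathway == "unknown")) {
    stop("unlabeled instrument(s): ",
         paste(records$rsid[is.na(records$pathway) |
                              records$pathway == "unknown"],
               collapse = ", "))
  }
  strata <- split(seq_len(nrow(records)), records$pathway)
  lapply(strata, function(idx) {
    out <- run_mr(records[idx, , drop = FALSE], config)
    attr(out, "plan") <- records$pathway[idx[1]]
    out
  })
}

#' Leave-one-out sensitivity table
#'
#' Repeats the fixed-effects analysis omitting each instrument in turn.
#' An instrument whose omission moves the pooled estimate far more than
#' any other is a candidate outlier (directional pleiotropy).
#'
#' @param records An `mr_instruments` data frame with at least two rows.
#' @param config An [analysis_config].
#' @return A data frame with one row per omitted rsid: fixed-effects
#'   `alpha`, `se`, `p`, `i2`, and the per-SD odds ratio with CI.
#' @export
leave_one_out <- function(records, config = analysis_config()) {
  if (nrow(records) < 2) stop("leave-one-out needs at least two instruments")
  rows <- lapply(seq_len(nrow(records)), function(i) {
    fit <- run_mr(records[-i, , drop = FALSE], config)
    fx <- fit$fixed
    data.frame(omitted = records$rsid[i],
               n_snps = nrow(fit$wald),
               alpha = fx$pooled$alpha,
               se = fx$pooled$se,
               p = fx$pooled$p,
               i2 = fx$pooled$het$i2,
               or_per_sd = fx$or_per_sd,
               or_ci_low = fx$or_ci_low,
               or_ci_high = fx$or_ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
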