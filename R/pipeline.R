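#' Aligned text forest table of per-SNP and pooled odds ratios
#'
#' Per-SNP odds ratios per 1-SD decrease of log 25OHD (Wald ratio scaled
#' by sigma) with 95% confidence intervals, followed by the pooled row.
#' Display rounding is two decimals; full precision lives in the
#' results TSV.
#'
#' @param analysis An `mr_analysis` from [run_mr].
#' @param model `"fixed"` or `"random"` pooled row.
#' @return Character vector of table lines (also printed with `cat`
#'   when interactive via `print`); class `mr_forest`.
#' @export
forest_table <- function(analysis, model = c("fixed", "random")) {
  model <- match.arg(model)
  res <- analysis[[model]]
  if (is.null(res)) stop("no ", model, "-effects result available")
  wald <- analysis$wald
  sigma <- analysis$sigma_logx
  zq <- stats::qnorm(0.975)
  fmt <- function(label, or, lo, hi, wt) {
    sprintf("%-12s %8.2f  (%.2f-%.2f) %10s", label, or, lo, hi, wt)
  }
  lines <- c(
    sprintf("%-12s %8s  %11s %10s", "snp", "OR/SD", "95% CI", "weight%"),
    vapply(seq_len(nrow(wald)), function(i) {
      a <- wald$alpha[i]; s <- sqrt(wald$variance[i])
      fmt(wald$rsid[i], exp(a * sigma), exp((a - zq * s) * sigma),
          exp((a + zq * s) * sigma),
          sprintf("%.1f", 100 * wald$weight[i] / sum(wald$weight)))
    }, ""),
    fmt(paste0("pooled(", substr(model, 1, 1), ")"),
        res$or_per_sd, res$or_ci_low, res$or_ci_high, "100.0")
  )
  structure(lines, class = "mr_forest")
}

#' @export
print.mr_forest <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

.result_row <- function(analysis_name, res, model) {
  pool <- res$pooled
  het <- pool$het
  data.frame(
    analysis = analysis_name, model = model,
    n_snps = nrow(res$instruments),
    alpha = pool$alpha, se = pool$se, z = pool$z, p = pool$p,
    q = het$q, df = het$df, i2 = het$i2,
    i2_lo = het$i2_ci_low, i2_hi = het$i2_ci_high, tau2 = het$tau2,
    sigma = res$sigma_logx, or_per_sd = res$or_per_sd,
    or_lo = res$or_ci_low, or_hi = res$or_ci_high,
    stringsAsFactors = FALSE
  )
}

.analysis_rows <- function(name, fit) {
  rows <- .result_row(name, fit$fixed, "fixed")
  if (!is.null(fit$random)) {
    rows <- rbind(rows, .result_row(name, fit$random, "random"))
  }
  rows
}

#' Run the full analysis pipeline and write its report files
#'
#' Executes, from an instrument table: the Bonferroni outcome screen,
#' the full fixed- and random-effects MR, every configured exclusion
#' plan, the pathway-stratified analyses, and the clinical-threshold
#' equivalence table. Writes `results.tsv` (one row per analysis and
#' model, full precision), `forest.txt` (per-SNP text forest table),
#' `equivalence.tsv` and `run.log` into the output directory.
#' Re-running with the same configuration reproduces the result files
#' byte for byte (only the log carries a timestamp).
#'
#' @param config An [analysis_config]; `instrument_path` defaults to
#'   the packaged fixture and `output_dir` to a temporary directory.
#' @return Invisibly, a list: `results` (the combined table),
#'   `analyses` (named `mr_analysis` objects), `screen`, `equivalence`,
#'   `paths`.
#' @export
#' @examples
#' bundle <- run_pipeline(analysis_config(output_dir = tempfile()))
#' bundle$results[bundle$results$model == "fixed", c("analysis", "or_per_sd")]
run_pipeline <- function(config = analysis_config()) {
  path <- if (is.null(config$instrument_path)) {
    instrument_fixture_path()
  } else {
    config$instrument_path
  }
  out_dir <- if (is.null(config$output_dir)) {
    tempfile("vitdmr_run_")
  } else {
    config$output_dir
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  records <- read_instrument_table(path)
  screen <- bonferroni_screen(records, fwer = config$fwer)

  analyses <- list(full = run_mr(records, config))
  for (plan in names(config$plans)) {
    analyses[[plan]] <- exclude_and_rerun(records, config$plans[[plan]],
                                          config, name = plan)
  }
  if (isTRUE(config$stratify_pathways) &&
      all(records$pathway %in% c("synthesis", "metabolism"))) {
    strata <- stratify_by_pathway(records, config)
    for (nm in names(strata)) analyses[[nm]] <- strata[[nm]]
  }

  results <- do.call(rbind, lapply(names(analyses), function(nm) {
    .analysis_rows(nm, analyses[[nm]])
  }))

  thr <- config$thresholds
  equivalence <- data.frame(
    label = if (is.null(names(thr))) as.character(thr) else names(thr),
    level_nmol_l = as.numeric(thr),
    equivalent_nmol_l = sd_equivalent_level(as.numeric(thr),
                                            config$sigma_thresh),
    sigma = config$sigma_thresh, stringsAsFactors = FALSE
  )

  paths <- list(results = file.path(out_dir, "results.tsv"),
                forest = file.path(out_dir, "forest.txt"),
                equivalence = file.path(out_dir, "equivalence.tsv"),
                log = file.path(out_dir, "run.log"))
  utils::write.table(results, paths$results, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(as.character(forest_table(analyses$full, "fixed")),
             paths$forest)
  utils::write.table(equivalence, paths$equivalence, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(
    paste0("vitdmr ", as.character(utils::packageVersion("vitdmr"))),
    paste0("time: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("instruments: ", path),
    paste0("sigma_logx: ", config$sigma_logx),
    paste0("sigma_thresh: ", config$sigma_thresh),
    paste0("fwer: ", config$fwer, " (threshold ", screen$threshold, ")"),
    paste0("bonferroni passing: ", paste(screen$passing, collapse = ", ")),
    paste0("analyses: ", paste(names(analyses), collapse = ", "))
  ), paths$log)

  invisible(list(results = results, analyses = analyses, screen = screen,
                 equivalence = equivalence, paths = paths))
}
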