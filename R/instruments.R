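#' Summary-statistic instruments for two-sample Mendelian randomization
#'
#' An instrument table carries, per SNP, the association with the exposure
#' (effect per allele on natural-log 25OHD, estimated in a population
#' cohort) and with the outcome (odds ratio for multiple sclerosis with a
#' 95% confidence interval, from a case-control consortium). The packaged
#' fixture `camos_imsgc_table1.tsv` ships the four genome-wide-significant
#' vitamin D SNPs (near *CYP2R1*, *DHCR7*, *GC* and *CYP24A1*) used as
#' instrumental variables, with the outcome associations drawn from the
#' IMSGC Immunochip and IMSGC/WTCCC2 studies (two via perfect-LD proxies).
#'
#' @section File dialect:
#' UTF-8 tab-separated text with a header row. Required columns (exact
#' names): `rsid`, `locus`, `chromosome`, `decreasing_allele`,
#' `allele_freq`, `gamma`, `gamma_se`, `p_exposure`, `f_statistic`,
#' `or_outcome`, `ci_low`, `ci_high`, `p_outcome`, `source_study`,
#' `proxy_rsid`, `proxy_r2`, `pathway`. Missing optional values are
#' encoded as `"."`; p-values may use scientific notation.
#'
#' @name instruments
NULL

.instrument_columns <- c(
  "rsid", "locus", "chromosome", "decreasing_allele", "allele_freq",
  "gamma", "gamma_se", "p_exposure", "f_statistic", "or_outcome",
  "ci_low", "ci_high", "p_outcome", "source_study", "proxy_rsid",
  "proxy_r2", "pathway"
)

#' Path to the packaged instrument fixture
#'
#' Returns the installed path of `camos_imsgc_table1.tsv`, the
#' four-SNP vitamin D instrument table (CaMos exposure effects, IMSGC
#' outcome odds ratios).
#'
#' @return A file path.
#' @export
#' @examples
#' read_instrument_table(instrument_fixture_path())
instrument_fixture_path <- function() {
  path <- system.file("extdata", "camos_imsgc_table1.tsv",
                      package = "vitdmr", mustWork = TRUE)
  path
}

#' Read a summary-statistic instrument table
#'
#' Parses a tab-separated instrument file (see [instruments] for the
#' column dialect) and validates each row: odds ratio and CI ordering,
#' allele frequency strictly inside (0, 1), probabilities in (0, 1],
#' known pathway labels, and proxy bookkeeping (a proxy rsid requires a
#' proxy r-squared). Validation failures name the offending row and
#' column.
#'
#' @param path Path to a TSV file.
#' @return A data frame of class `mr_instruments`, one row per SNP.
#'   Missing optional fields are `NA`.
#' @export
read_instrument_table <- function(path) {
  if (!file.exists(path)) stop("instrument file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = ".", colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.instrument_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("instrument file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, .instrument_columns]
  if (nrow(raw) == 0) {
    out <- raw
    numeric_cols <- c("chromosome", "allele_freq", "gamma", "gamma_se",
                      "p_exposure", "f_statistic", "or_outcome", "ci_low",
                      "ci_high", "p_outcome", "proxy_r2")
    for (col in numeric_cols) out[[col]] <- numeric(0)
    class(out) <- c("mr_instruments", "data.frame")
    return(out)
  }

  parse_num <- function(col, required = TRUE) {
    txt <- raw[[col]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(val))
    if (length(bad) > 0) {
      stop("row ", bad[1], ", column '", col, "': not a number ('",
           txt[bad[1]], "')")
    }
    if (required && anyNA(val)) {
      stop("row ", which(is.na(val))[1], ", column '", col,
           "': required value is missing")
    }
    val
  }

  out <- data.frame(
    rsid = raw$rsid,
    locus = raw$locus,
    chromosome = parse_num("chromosome"),
    decreasing_allele = raw$decreasing_allele,
    allele_freq = parse_num("allele_freq"),
    gamma = parse_num("gamma"),
    gamma_se = parse_num("gamma_se", required = FALSE),
    p_exposure = parse_num("p_exposure"),
    f_statistic = parse_num("f_statistic", required = FALSE),
    or_outcome = parse_num("or_outcome"),
    ci_low = parse_num("ci_low"),
    ci_high = parse_num("ci_high"),
    p_outcome = parse_num("p_outcome"),
    source_study = raw$source_study,
    proxy_rsid = raw$proxy_rsid,
    proxy_r2 = parse_num("proxy_r2", required = FALSE),
    pathway = raw$pathway,
    stringsAsFactors = FALSE
  )

  if (anyDuplicated(out$rsid)) {
    stop("duplicate rsid: ", out$rsid[duplicated(out$rsid)][1])
  }
  for (i in seq_len(nrow(out))) {
    row <- out[i, ]
    if (!(row$allele_freq > 0 && row$allele_freq < 1)) {
      stop("row ", i, ", column 'allele_freq': frequency out of (0,1)")
    }
    if (!(row$decreasing_allele %in% c("A", "C", "G", "T"))) {
      stop("row ", i, ", column 'decreasing_allele': must be one of A,C,G,T")
    }
    if (!(row$chromosome %in% 1:22)) {
      stop("row ", i, ", column 'chromosome': must be an autosome 1-22")
    }
    if (row$ci_low > row$or_outcome || row$or_outcome > row$ci_high) {
      stop("row ", i, ": CI must bracket the odds ratio (ci_low <= OR <= ci_high)")
    }
    if (row$ci_low <= 0) stop("row ", i, ", column 'ci_low': must be positive")
    for (col in c("p_exposure", "p_outcome")) {
      p <- row[[col]]
      if (!(p > 0 && p <= 1)) {
        stop("row ", i, ", column '", col, "': p-value out of (0,1]")
      }
    }
    if (!is.na(row$gamma_se) && row$gamma_se <= 0) {
      stop("row ", i, ", column 'gamma_se': must be positive when present")
    }
    if (!is.na(row$proxy_rsid) && is.na(row$proxy_r2)) {
      stop("row ", i, ": proxy_rsid given without proxy_r2")
    }
    if (!is.na(row$proxy_r2) && (row$proxy_r2 < 0 || row$proxy_r2 > 1)) {
      stop("row ", i, ", column 'proxy_r2': must lie in [0,1]")
    }
    if (!(row$pathway %in% c("synthesis", "metabolism", "unknown"))) {
      stop("row ", i, ", column 'pathway': must be synthesis, metabolism or unknown")
    }
  }
  class(out) <- c("mr_instruments", "data.frame")
  out
}

#' Log odds and standard error from an odds ratio and its CI
#'
#' Converts a reported odds ratio with a symmetric-on-the-log-scale
#' confidence interval into the log-odds `beta` and its standard error,
#' `se = (ln hi - ln lo) / (2 z)`, with `z` the standard-normal quantile
#' at `(1 + level)/2` (1.959964 for a 95% interval).
#'
#' @param or Odds ratio (positive).
#' @param lo,hi Confidence-interval bounds (positive, `lo <= or <= hi`).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A list with components `log_odds` and `se`. Vectorised over
#'   `or`, `lo`, `hi`.
#' @export
#' @examples
#' beta_from_or_ci(1.11, 1.07, 1.15)
beta_from_or_ci <- function(or, lo, hi, level = 0.95) {
  stopifnot(length(level) == 1, level > 0, level < 1)
  if (any(or <= 0 | lo <= 0 | hi <= 0)) {
    stop("odds ratio and CI bounds must be positive")
  }
  if (any(lo > hi)) stop("ci_low exceeds ci_high")
  if (any(lo > or | or > hi)) stop("CI must bracket the odds ratio")
  if (any(lo == hi)) stop("zero-width confidence interval: se would be 0")
  z <- stats::qnorm((1 + level) / 2)
  list(log_odds = log(or), se = (log(hi) - log(lo)) / (2 * z))
}

#' Standard error of a log odds ratio from its p-value
#'
#' Inverts the two-sided normal test: `se = |log_odds| / z(p)` with
#' `z(p)` the upper `p/2` standard-normal quantile. Useful when a
#' reported CI is more coarsely rounded than the p-value.
#'
#' @param log_odds Log odds ratio (non-zero).
#' @param p Two-sided p-value in (0, 1).
#' @return Standard error(s), positive. Vectorised.
#' @export
se_from_p <- function(log_odds, p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0,1)")
  if (any(log_odds == 0)) {
    stop("log_odds = 0 is inconsistent with a p-value below 1")
  }
  abs(log_odds) / stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Orient instruments to the 25OHD-decreasing allele
#'
#' Expresses every instrument per copy of the exposure-*decreasing*
#' allele, the convention under which all pooled estimates read as
#' log-odds of disease per unit *decrease* in log 25OHD. A record whose
#' stated allele lowers the biomarker (negative `gamma`) is kept as is,
#' with `gamma_decrease = |gamma|`; a record stated for the increasing
#' allele (positive `gamma`) has its outcome log-odds sign-flipped in
#' lockstep. Outcome log-odds and standard errors are derived from the
#' reported OR and CI by default ([beta_from_or_ci]); set
#' `se_method = "p"` to derive the SE from the reported p-value instead
#' ([se_from_p]).
#'
#' @param records An `mr_instruments` data frame ([read_instrument_table]).
#' @param se_method `"ci"` (default) or `"p"`.
#' @param ci_level Confidence level of the reported intervals.
#' @return A data frame of class `mr_harmonized` with columns `rsid`,
#'   `locus`, `gamma_decrease`, `beta`, `se_beta`, `pathway` and
#'   `flipped` (whether the orientation was reversed).
#' @export
harmonize <- function(records, se_method = c("ci", "p"), ci_level = 0.95) {
  se_method <- match.arg(se_method)
  if (nrow(records) == 0) stop("no instruments to harmonize")
  if (any(records$gamma == 0)) {
    stop("null instrument (gamma = 0): ",
         records$rsid[records$gamma == 0][1])
  }
  conv <- beta_from_or_ci(records$or_outcome, records$ci_low,
                          records$ci_high, level = ci_level)
  se_beta <- if (se_method == "ci") {
    conv$se
  } else {
    se_from_p(conv$log_odds, records$p_outcome)
  }
  flipped <- records$gamma > 0
  beta <- ifelse(flipped, -conv$log_odds, conv$log_odds)
  out <- data.frame(
    rsid = records$rsid,
    locus = records$locus,
    gamma_decrease = abs(records$gamma),
    beta = beta,
    se_beta = se_beta,
    pathway = records$pathway,
    flipped = flipped,
    stringsAsFactors = FALSE
  )
  attr(out, "se_method") <- se_method
  attr(out, "orientation") <- "per 25OHD-decreasing allele"
  class(out) <- c("mr_harmonized", "data.frame")
  out
}

#' Bonferroni screen of instrument-outcome associations
#'
#' Declares an instrument associated with the outcome when its reported
#' p-value is at most `fwer / n`, the Bonferroni threshold for the
#' number of instruments screened.
#'
#' @param records An `mr_instruments` data frame.
#' @param fwer Family-wise error rate in (0, 1); default 0.05.
#' @return A list with `threshold` (the corrected p-value cut-off) and
#'   `passing` (rsids meeting it, input order preserved).
#' @export
bonferroni_screen <- function(records, fwer = 0.05) {
  stopifnot(fwer > 0, fwer < 1)
  if (nrow(records) == 0) stop("no instruments to screen")
  threshold <- fwer / nrow(records)
  list(threshold = threshold,
       passing = records$rsid[records$p_outcome <= threshold])
}
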