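#' Individual-level cohorts
#'
#' A cohort table holds one row per participant: genotype dosage columns
#' `g_<rsid>` counting copies of the 25OHD-*decreasing* allele (0/1/2),
#' covariates `sex` (0/1), `age` (years), `bmi` (kg/m2), `season`
#' (categorical with levels summer, autumn, winter, spring),
#' `log25ohd` (natural-log 25OHD), and optional `disease` (0/1) and
#' `non_european` (0/1) columns. The attribute
#' `oriented_to_decreasing` records that dosages count decreasing
#' alleles; score construction refuses tables without it.
#'
#' @name cohort
NULL

.season_levels <- c("summer", "autumn", "winter", "spring")

.cohort_snps <- function(cohort) {
  snps <- attr(cohort, "snps")
  if (is.null(snps)) {
    snps <- sub("^g_", "", grep("^g_", names(cohort), value = TRUE))
  }
  snps
}

#' Read an individual-level cohort table
#'
#' @param path Tab-separated file with the [cohort] column schema.
#' @return A data frame of class `mr_cohort` with orientation metadata.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  out <- utils::read.delim(path, header = TRUE, sep = "\t", na.strings = ".",
                           fileEncoding = "UTF-8")
  gcols <- grep("^g_", names(out), value = TRUE)
  if (length(gcols) == 0) stop("no genotype columns (g_<rsid>) found")
  for (col in gcols) {
    if (anyNA(out[[col]]) || !all(out[[col]] %in% 0:2)) {
      stop("column '", col, "': dosages must be complete and in {0,1,2}")
    }
  }
  if (!all(out$season %in% .season_levels)) {
    stop("season must be one of: ", paste(.season_levels, collapse = ", "))
  }
  out$season <- factor(out$season, levels = .season_levels)
  attr(out, "snps") <- sub("^g_", "", gcols)
  attr(out, "oriented_to_decreasing") <- TRUE
  class(out) <- c("mr_cohort", "data.frame")
  out
}

#' Per-individual count of 25OHD-decreasing alleles
#'
#' The unweighted allele score: the sum of dosages across instruments,
#' ranging from 0 (homozygous for the increasing allele everywhere) to
#' twice the number of SNPs.
#'
#' @param cohort An `mr_cohort` table whose dosages are oriented to the
#'   decreasing allele.
#' @return Integer vector of length `nrow(cohort)`.
#' @export
allele_count_score <- function(cohort) {
  if (!isTRUE(attr(cohort, "oriented_to_decreasing"))) {
    stop("cohort lacks orientation metadata: dosages must be counts of ",
         "the 25OHD-decreasing allele")
  }
  gcols <- paste0("g_", .cohort_snps(cohort))
  as.integer(rowSums(cohort[, gcols, drop = FALSE]))
}

#' Residualize log 25OHD for the measurement covariates
#'
#' Ordinary least-squares adjustment of natural-log 25OHD for sex, age,
#' age squared, BMI and season of measurement. Rows with missing
#' covariates are dropped listwise (a message reports the count) and
#' their residuals returned as `NA`, so the vector stays aligned with
#' the cohort.
#'
#' @param cohort An `mr_cohort` table.
#' @return Numeric vector of residuals (mean zero over complete cases).
#' @export
residualize_exposure <- function(cohort) {
  dat <- data.frame(y = cohort$log25ohd, sex = cohort$sex, age = cohort$age,
                    bmi = cohort$bmi,
                    season = factor(cohort$season, levels = .season_levels))
  n_miss <- sum(!stats::complete.cases(dat))
  if (n_miss > 0) message(n_miss, " row(s) dropped for missing covariates")
  fit <- stats::lm(y ~ sex + age + I(age^2) + bmi + season, data = dat,
                   na.action = stats::na.exclude)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient covariate design (collinear covariates)")
  }
  as.numeric(stats::residuals(fit))
}

# closed-form simple linear regression; hot path for simulation studies
.simple_lm <- function(y, x) {
  ok <- stats::complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("predictor is constant")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  rss <- syy - slope * sxy
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  tstat <- slope / se
  list(slope = slope, se = se, t = tstat, f_statistic = tstat^2,
       r2 = if (syy > 0) sxy^2 / (sxx * syy) else NA_real_,
       p = 2 * stats::pt(-abs(tstat), df), n = n, df = df)
}

#' Instrument strength of the allele score
#'
#' Regresses covariate-residualized log 25OHD on the allele score
#' (single-predictor least squares, two-stage convention: the residual
#' degrees of freedom are `n - 2`, not adjusted for the first-stage
#' covariates). Reports the slope, the F-statistic (the squared slope
#' t-statistic), the variance explained and the p-value. For a joint
#' one-stage convention see [score_strength_joint].
#'
#' @param residuals Residualized log-biomarker ([residualize_exposure]).
#' @param score Allele-count score ([allele_count_score]), same length.
#' @return A list: `slope`, `se`, `f_statistic`, `r2`, `p`, `n`, `df`.
#' @export
instrument_strength <- function(residuals, score) {
  if (length(residuals) != length(score)) {
    stop("residuals and score differ in length")
  }
  .simple_lm(residuals, score)
}

#' Single-SNP instrument strength
#'
#' As [instrument_strength] with one SNP's dosage as the predictor.
#'
#' @param residuals Residualized log-biomarker.
#' @param dosage Dosage vector (0/1/2) for one SNP.
#' @return As [instrument_strength].
#' @export
per_snp_strength <- function(residuals, dosage) {
  if (length(unique(dosage[!is.na(dosage)])) < 2) {
    stop("monomorphic SNP: dosage is constant")
  }
  instrument_strength(residuals, dosage)
}

#' Allele-score strength from the joint covariate model
#'
#' One-stage alternative convention: fits log 25OHD on the covariates
#' *and* the score in a single multiple regression and reports the
#' partial F (squared t) for the score with the correctly reduced
#' residual degrees of freedom. The two conventions differ slightly in
#' df accounting; both are reported by the package.
#'
#' @param cohort An `mr_cohort` table.
#' @param score Allele score vector.
#' @return A list: `slope`, `se`, `f_statistic`, `p`, `n`, `df`.
#' @export
score_strength_joint <- function(cohort, score) {
  dat <- data.frame(y = cohort$log25ohd, sex = cohort$sex, age = cohort$age,
                    bmi = cohort$bmi,
                    season = factor(cohort$season, levels = .season_levels),
                    score = score)
  fit <- stats::lm(y ~ sex + age + I(age^2) + bmi + season + score,
                   data = dat)
  cf <- summary(fit)$coefficients["score", ]
  list(slope = unname(cf[1]), se = unname(cf[2]),
       f_statistic = unname(cf[3])^2, p = unname(cf[4]),
       n = sum(stats::complete.cases(dat)), df = fit$df.residual)
}

#' Non-parametric trend test across allele-count groups
#'
#' Cuzick's rank-based test for trend across ordered groups, with group
#' scores equal to the allele counts. The statistic is
#' `T = sum(l_i R_i)` over individuals with group score `l` and midrank
#' `R`; under the null of no trend, `z = (T - E[T]) / sqrt(Var[T])` is
#' standard normal (tie-corrected variance). With exactly two groups it
#' reduces to the normal approximation of the Wilcoxon rank-sum test.
#'
#' @param residuals Residualized log-biomarker values.
#' @param score Ordered group scores (allele counts), same length.
#' @return A list: `z`, `p` (two-sided), `group_means` (mean residual
#'   per allele count, ascending), `group_n`.
#' @export
trend_test <- function(residuals, score) {
  ok <- stats::complete.cases(residuals, score)
  y <- residuals[ok]; l <- score[ok]
  if (length(unique(l)) < 2) stop("trend test needs at least two groups")
  n <- length(y)
  r <- rank(y)
  t_obs <- sum(l * r)
  e_t <- (n + 1) / 2 * sum(l)
  ties <- table(y)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  var_rank <- (n^2 - 1) / 12 * tie_corr
  var_t <- var_rank * n / (n - 1) * (sum(l^2) - sum(l)^2 / n)
  z <- (t_obs - e_t) / sqrt(var_t)
  groups <- sort(unique(l))
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       group_means = vapply(groups, function(g) mean(y[l == g]), 0),
       group_n = vapply(groups, function(g) sum(l == g), 0L))
}

#' Pairwise linkage disequilibrium between instrument dosages
#'
#' Composite LD: the squared sample correlation of dosage columns.
#' Instruments for MR must be (near) independent; the analysis expects
#' all off-diagonal entries at or below about 0.01.
#'
#' @param dosages Numeric matrix or data frame, individuals by SNPs,
#'   at least two columns, none monomorphic.
#' @return Symmetric m-by-m matrix with unit diagonal.
#' @export
pairwise_r2 <- function(dosages) {
  d <- as.matrix(dosages)
  if (ncol(d) < 2) stop("need at least two SNPs")
  v <- apply(d, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(d)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("monomorphic SNP column: ", paste(bad, collapse = ", "))
  }
  r2 <- stats::cor(d)^2
  diag(r2) <- 1
  r2
}

#' Association of a SNP with ancestry group
#'
#' Cochran-Armitage trend test of genotype dosage against a binary
#' ancestry indicator (non-European status), the screen for population
#' stratification. A 2-by-3 genotype chi-square is available as an
#' option.
#'
#' @param dosage Dosage vector (0/1/2).
#' @param non_european Binary vector (0/1), same length.
#' @param method `"trend"` (default, Cochran-Armitage) or `"chisq"`.
#' @return A list: `statistic` (chi-squared, 1 df for the trend test),
#'   `p` (two-sided).
#' @export
ancestry_association <- function(dosage, non_european,
                                 method = c("trend", "chisq")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(dosage, non_european)
  g <- dosage[ok]; grp <- non_european[ok]
  if (length(unique(grp)) < 2) stop("both ancestry groups must be non-empty")
  if (method == "chisq") {
    tst <- suppressWarnings(stats::chisq.test(table(grp, g)))
    return(list(statistic = unname(tst$statistic), p = tst$p.value))
  }
  lev <- sort(unique(g))
  events <- vapply(lev, function(l) sum(grp[g == l]), 0)
  totals <- vapply(lev, function(l) sum(g == l), 0)
  tst <- suppressWarnings(stats::prop.trend.test(events, totals, score = lev))
  list(statistic = unname(tst$statistic), p = tst$p.value)
}

#' Hardy-Weinberg goodness-of-fit check
#'
#' One-degree-of-freedom chi-square comparison of observed genotype
#' counts with the proportions expected from the estimated allele
#' frequency. Monomorphic input returns `p = 1` with a warning.
#'
#' @param dosage Dosage vector (0/1/2), at least 30 individuals.
#' @return P-value of the goodness-of-fit test.
#' @export
hwe_check <- function(dosage) {
  g <- dosage[!is.na(dosage)]
  n <- length(g)
  if (n < 30) warning("fewer than 30 genotypes: HWE check is unreliable")
  counts <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  f <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (f == 0 || f == 1) {
    warning("monomorphic SNP: HWE check is vacuous")
    return(1)
  }
  expected <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  stat <- sum((counts - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}
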