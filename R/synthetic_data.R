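#' Simulation parameters for genotype-biomarker-disease cohorts
#'
#' Defines the full generative model used for parameter-recovery and
#' calibration studies. Defaults emulate the study conditions of the
#' vitamin D / multiple sclerosis analysis: an exposure cohort of 2,347
#' individuals genotyped at four biallelic SNPs (frequencies and
#' per-allele log-25OHD effects of the four instruments), and a
#' case-control outcome study sampled to 14,498 cases and 24,091
#' controls.
#'
#' The biomarker model is
#' `log 25OHD = mu + sum(-gamma_j (g_j - 2 f_j)) + covariate terms +
#'  lambda_x U + eps`,
#' with genotypes drawn in Hardy-Weinberg proportions, `U` a latent
#' standard-normal confounder, and the residual SD solved so that the
#' marginal variance equals `sigma_logx^2` exactly (an error reports the
#' variance budget if that is impossible). Disease status follows a
#' logistic model on the standardized log-biomarker,
#' `logit P(y=1) = kappa - alpha_true z_x + sum(delta_j g_j) + lambda_y U`,
#' so `alpha_true` is directly the log-odds per 1-SD decrease of log
#' 25OHD, the MR estimand; `delta_j` injects directional pleiotropy.
#'
#' Covariate effects default to zero so that `sigma_logx` describes both
#' the marginal and the covariate-adjusted scale; the covariate
#' distributions (age, BMI, sex, season) are configurable and are not
#' sourced from any study.
#'
#' @param n_exposure Exposure-cohort size.
#' @param n_cases,n_controls Outcome-study case and control counts.
#' @param snps Data frame with columns `rsid`, `freq` (decreasing-allele
#'   frequency), `gamma_decrease` (log-25OHD decrease per allele) and
#'   `pathway`.
#' @param sigma_logx Marginal SD of natural-log 25OHD.
#' @param mu_logx Mean of natural-log 25OHD.
#' @param covariate_effects List with scalars `sex`, `age`, `age2`,
#'   `bmi` and a length-4 `season` vector of additive shifts.
#' @param alpha_true Log-odds of disease per 1-SD decrease of log 25OHD.
#' @param kappa Baseline log-odds of disease in the simulated source
#'   population (case-control sampling is outcome-dependent, which
#'   leaves logistic slopes unbiased).
#' @param pleiotropy_delta Per-SNP direct log-odds per allele.
#' @param confounder_lambda_x,confounder_lambda_y Loadings of the latent
#'   confounder on the biomarker and the liability.
#' @param strat Optional list `(subpop_fraction, freq_offsets,
#'   kappa_offset)` describing a second subpopulation with shifted
#'   allele frequencies and baseline risk.
#' @param seed Master seed; exposure and outcome cohorts use disjoint
#'   derived streams.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_exposure = 2347L,
                       n_cases = 14498L,
                       n_controls = 24091L,
                       snps = default_snps(),
                       sigma_logx = 0.38829,
                       mu_logx = log(60),
                       covariate_effects = list(sex = 0, age = 0, age2 = 0,
                                                bmi = 0,
                                                season = c(0, 0, 0, 0)),
                       alpha_true = 0.70,
                       kappa = stats::qlogis(0.35),
                       pleiotropy_delta = rep(0, nrow(snps)),
                       confounder_lambda_x = 0,
                       confounder_lambda_y = 0,
                       strat = NULL,
                       seed = 1L) {
  stopifnot(n_exposure > 0, n_cases > 0, n_controls > 0, sigma_logx > 0,
            all(snps$freq > 0 & snps$freq < 1),
            length(pleiotropy_delta) == nrow(snps),
            length(covariate_effects$season) == 4)
  if (!is.null(strat)) {
    stopifnot(strat$subpop_fraction > 0, strat$subpop_fraction < 1,
              length(strat$freq_offsets) == nrow(snps))
    f2 <- snps$freq + strat$freq_offsets
    if (any(f2 <= 0 | f2 >= 1)) {
      stop("stratified allele frequencies fall outside (0,1)")
    }
  }
  params <- structure(
    list(n_exposure = as.integer(n_exposure), n_cases = as.integer(n_cases),
         n_controls = as.integer(n_controls), snps = snps,
         sigma_logx = sigma_logx, mu_logx = mu_logx,
         covariate_effects = covariate_effects, alpha_true = alpha_true,
         kappa = kappa, pleiotropy_delta = pleiotropy_delta,
         confounder_lambda_x = confounder_lambda_x,
         confounder_lambda_y = confounder_lambda_y,
         strat = strat, seed = as.integer(seed),
         covariate_dists = list(sex_p = 0.69, age_mean = 62, age_sd = 13,
                                age_lim = c(25, 95), bmi_mean = 27,
                                bmi_sd = 4.5, bmi_lim = c(12, 60))),
    class = "sim_params")
  budget <- variance_budget(params)  # errors early if infeasible
  params$residual_sd <- sqrt(budget$residual)
  params
}

#' The four default instrument SNPs
#'
#' Decreasing-allele frequencies and per-allele effects of the four
#' vitamin D instruments (near *CYP2R1*, *DHCR7*, *GC*, *CYP24A1*).
#'
#' @return A data frame with columns `rsid`, `freq`, `gamma_decrease`,
#'   `pathway`.
#' @export
default_snps <- function() {
  data.frame(
    rsid = c("rs10741657", "rs12785878", "rs2282679", "rs6013897"),
    freq = c(0.62, 0.27, 0.30, 0.19),
    gamma_decrease = c(0.052, 0.056, 0.047, 0.027),
    pathway = c("synthesis", "synthesis", "metabolism", "metabolism"),
    stringsAsFactors = FALSE
  )
}

# raw moments E[X^k], k = 1..4, of a truncated normal via quadrature
.trunc_moments <- function(mean, sd, lim) {
  z_mass <- stats::pnorm(lim[2], mean, sd) - stats::pnorm(lim[1], mean, sd)
  vapply(1:4, function(k) {
    stats::integrate(function(x) x^k * stats::dnorm(x, mean, sd) / z_mass,
                     lim[1], lim[2], rel.tol = 1e-12)$value
  }, 0)
}

#' Analytic variance budget of the simulated log-biomarker
#'
#' Decomposes `sigma_logx^2` into the genetic contribution
#' `sum 2 f (1-f) gamma^2`, the covariate contribution (exact moments of
#' the configured covariate distributions), the confounder loading
#' `lambda_x^2`, and the residual. The residual is solved by
#' subtraction; a negative value is an error reporting the breakdown.
#'
#' @param params A [sim_params] list.
#' @return A list: `genetic`, `covariate`, `confounder`, `residual`,
#'   `total`.
#' @export
variance_budget <- function(params) {
  f <- params$snps$freq
  genetic <- sum(2 * f * (1 - f) * params$snps$gamma_decrease^2)
  ce <- params$covariate_effects
  cd <- params$covariate_dists
  var_cov <- ce$sex^2 * cd$sex_p * (1 - cd$sex_p)
  if (ce$age != 0 || ce$age2 != 0) {
    m <- .trunc_moments(cd$age_mean, cd$age_sd, cd$age_lim)
    var_age <- m[2] - m[1]^2
    var_age2 <- m[4] - m[2]^2
    cov_age_age2 <- m[3] - m[1] * m[2]
    var_cov <- var_cov + ce$age^2 * var_age + ce$age2^2 * var_age2 +
      2 * ce$age * ce$age2 * cov_age_age2
  }
  if (ce$bmi != 0) {
    m <- .trunc_moments(cd$bmi_mean, cd$bmi_sd, cd$bmi_lim)
    var_cov <- var_cov + ce$bmi^2 * (m[2] - m[1]^2)
  }
  var_cov <- var_cov + mean(ce$season^2) - mean(ce$season)^2
  confounder <- params$confounder_lambda_x^2
  residual <- params$sigma_logx^2 - genetic - var_cov - confounder
  if (residual < 0) {
    stop(sprintf(paste0(
      "infeasible variance budget: sigma^2 = %.5f < genetic %.5f + ",
      "covariate %.5f + confounder %.5f"),
      params$sigma_logx^2, genetic, var_cov, confounder))
  }
  list(genetic = genetic, covariate = var_cov, confounder = confounder,
       residual = residual, total = params$sigma_logx^2)
}

.rtrunc_norm <- function(n, mean, sd, lim) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lim[1] | x > lim[2])
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lim[1] | x[bad] > lim[2]]
  }
  x
}

# one batch of individuals from the generative model
.draw_individuals <- function(params, n, with_disease) {
  m <- nrow(params$snps)
  cd <- params$covariate_dists
  ce <- params$covariate_effects
  strat <- params$strat
  subpop <- if (is.null(strat)) {
    integer(n)
  } else {
    stats::rbinom(n, 1, strat$subpop_fraction)
  }
  g <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    fj <- rep(params$snps$freq[j], n)
    if (!is.null(strat)) fj <- fj + subpop * strat$freq_offsets[j]
    g[, j] <- stats::rbinom(n, 2, fj)
  }
  colnames(g) <- paste0("g_", params$snps$rsid)
  sex <- stats::rbinom(n, 1, cd$sex_p)
  age <- .rtrunc_norm(n, cd$age_mean, cd$age_sd, cd$age_lim)
  bmi <- .rtrunc_norm(n, cd$bmi_mean, cd$bmi_sd, cd$bmi_lim)
  season <- sample(.season_levels, n, replace = TRUE)
  u <- stats::rnorm(n)

  # centered contributions keep mu_logx the marginal mean
  gene_term <- as.numeric(g %*% (-params$snps$gamma_decrease)) +
    sum(2 * params$snps$freq * params$snps$gamma_decrease)
  cov_term <- ce$sex * (sex - cd$sex_p)
  if (ce$age != 0 || ce$age2 != 0) {
    mo <- .trunc_moments(cd$age_mean, cd$age_sd, cd$age_lim)
    cov_term <- cov_term + ce$age * (age - mo[1]) + ce$age2 * (age^2 - mo[2])
  }
  if (ce$bmi != 0) {
    mo <- .trunc_moments(cd$bmi_mean, cd$bmi_sd, cd$bmi_lim)
    cov_term <- cov_term + ce$bmi * (bmi - mo[1])
  }
  se <- ce$season - mean(ce$season)
  cov_term <- cov_term + se[match(season, .season_levels)]
  logx <- params$mu_logx + gene_term + cov_term +
    params$confounder_lambda_x * u +
    stats::rnorm(n, 0, params$residual_sd)

  out <- data.frame(g, sex = sex, age = age, bmi = bmi,
                    season = factor(season, levels = .season_levels),
                    log25ohd = logx,
                    non_european = subpop, stringsAsFactors = FALSE)
  if (with_disease) {
    zx <- (logx - params$mu_logx) / params$sigma_logx
    lp <- params$kappa - params$alpha_true * zx +
      as.numeric(g %*% params$pleiotropy_delta) +
      params$confounder_lambda_y * u
    if (!is.null(strat)) lp <- lp + subpop * strat$kappa_offset
    out$disease <- stats::rbinom(n, 1, stats::plogis(lp))
  } else {
    out$disease <- NA_integer_
  }
  out
}

.finish_cohort <- function(df, params, role) {
  df$id <- paste0(substr(role, 1, 3), "_", seq_len(nrow(df)))
  df <- df[, c("id", setdiff(names(df), "id"))]
  attr(df, "snps") <- params$snps$rsid
  attr(df, "oriented_to_decreasing") <- TRUE
  attr(df, "role") <- role
  class(df) <- c("mr_cohort", "data.frame")
  df
}

#' Simulate an individual-level cohort
#'
#' Draws a cohort from the generative model in [sim_params]. The
#' `"exposure"` role yields `n_exposure` individuals without disease
#' status; the `"outcome"` role draws source-population batches and
#' retains the first `n_cases` cases and `n_controls` controls
#' (outcome-dependent sampling). The two roles consume disjoint
#' pseudo-random streams derived from the master seed, so exposure and
#' outcome cohorts never share individuals.
#'
#' @param params A [sim_params] list.
#' @param role `"exposure"` or `"outcome"`.
#' @param seed Master seed; defaults to `params$seed`.
#' @return An `mr_cohort` data frame ([cohort]).
#' @export
simulate_cohort <- function(params, role = c("exposure", "outcome"),
                            seed = params$seed) {
  role <- match.arg(role)
  set.seed(seed)
  streams <- sample.int(2147483646L, 2)
  if (role == "exposure") {
    set.seed(streams[1])
    df <- .draw_individuals(params, params$n_exposure, with_disease = FALSE)
    return(.finish_cohort(df, params, role))
  }
  set.seed(streams[2])
  need_cases <- params$n_cases
  need_controls <- params$n_controls
  batch <- ceiling(1.25 * (need_cases + need_controls))
  cases <- list(); controls <- list()
  n_cases_got <- 0L; n_controls_got <- 0L
  for (iter in 1:50) {
    df <- .draw_individuals(params, batch, with_disease = TRUE)
    if (n_cases_got < need_cases) {
      take <- df[df$disease == 1, , drop = FALSE]
      cases[[length(cases) + 1]] <- utils::head(take, need_cases - n_cases_got)
      n_cases_got <- n_cases_got + nrow(cases[[length(cases)]])
    }
    if (n_controls_got < need_controls) {
      take <- df[df$disease == 0, , drop = FALSE]
      controls[[length(controls) + 1]] <-
        utils::head(take, need_controls - n_controls_got)
      n_controls_got <- n_controls_got + nrow(controls[[length(controls)]])
    }
    if (n_cases_got >= need_cases && n_controls_got >= need_controls) break
  }
  if (n_cases_got < need_cases || n_controls_got < need_controls) {
    stop("could not reach the requested case/control counts; ",
         "baseline log-odds kappa may be too extreme")
  }
  .finish_cohort(do.call(rbind, c(cases, controls)), params, role)
}

# logistic fit of y on one dosage column; returns beta, se, convergence
.fast_logit <- function(y, x) {
  xm <- cbind(1, x)
  fit <- suppressWarnings(
    stats::glm.fit(xm, y, family = stats::binomial())
  )
  r <- fit$qr$qr[1:2, 1:2, drop = FALSE]
  r[lower.tri(r)] <- 0
  covm <- chol2inv(r)
  list(beta = unname(fit$coefficients[2]),
       se = sqrt(covm[2, 2]),
       converged = fit$converged && all(is.finite(fit$coefficients)))
}

#' Per-SNP exposure associations from a simulated cohort
#'
#' Single-SNP regressions of the covariate-residualized log-biomarker on
#' each dosage column, mirroring how per-allele effects on log 25OHD are
#' estimated in a population cohort. Returned effects are per copy of
#' the decreasing allele and therefore negative in expectation.
#'
#' @param cohort An exposure-role `mr_cohort`.
#' @return A data frame: `rsid`, `gamma_hat`, `se`, `p`, `freq_hat`.
#'   Monomorphic SNPs are dropped with a warning.
#' @export
summarize_exposure_gwas <- function(cohort) {
  snps <- .cohort_snps(cohort)
  resid <- residualize_exposure(cohort)
  rows <- lapply(snps, function(s) {
    g <- cohort[[paste0("g_", s)]]
    if (length(unique(g)) < 2) {
      warning("monomorphic SNP dropped: ", s)
      return(NULL)
    }
    fit <- .simple_lm(resid, g)
    data.frame(rsid = s, gamma_hat = fit$slope, se = fit$se, p = fit$p,
               freq_hat = mean(g) / 2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-SNP case-control associations from a simulated cohort
#'
#' Single-SNP logistic regressions of disease status on dosage with
#' Wald 95% confidence intervals, mirroring the consortium summary
#' statistics the MR analysis consumes.
#'
#' @param cohort An outcome-role `mr_cohort` with both cases and
#'   controls.
#' @return A data frame: `rsid`, `or`, `ci_low`, `ci_high`, `p`,
#'   `beta`, `se`. SNPs with separation are dropped with a warning.
#' @export
summarize_outcome_gwas <- function(cohort) {
  if (!all(c(0, 1) %in% cohort$disease)) {
    stop("outcome cohort must contain both cases and controls")
  }
  snps <- .cohort_snps(cohort)
  zq <- stats::qnorm(0.975)
  rows <- lapply(snps, function(s) {
    g <- cohort[[paste0("g_", s)]]
    if (length(unique(g)) < 2) {
      warning("monomorphic SNP dropped: ", s)
      return(NULL)
    }
    fit <- .fast_logit(cohort$disease, g)
    if (!fit$converged || abs(fit$beta) > 8 || fit$se > 8) {
      warning("separation detected, SNP dropped: ", s)
      return(NULL)
    }
    z <- fit$beta / fit$se
    data.frame(rsid = s, or = exp(fit$beta),
               ci_low = exp(fit$beta - zq * fit$se),
               ci_high = exp(fit$beta + zq * fit$se),
               p = 2 * stats::pnorm(-abs(z)),
               beta = fit$beta, se = fit$se, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a complete two-sample summary dataset
#'
#' Draws independent exposure and outcome cohorts (disjoint seed
#' streams), summarizes each with the module's GWAS operations, and
#' assembles the per-SNP summary statistics into an instrument table
#' ready for [run_mr]. The generating parameters are retained for
#' parameter-recovery tests.
#'
#' @param params A [sim_params] list.
#' @param seed Master seed; defaults to `params$seed`.
#' @return A list of class `two_sample_dataset`: `instruments` (an
#'   `mr_instruments` data frame), `truth` (the params), and the two
#'   summary tables.
#' @export
make_two_sample_dataset <- function(params, seed = params$seed) {
  exp_cohort <- simulate_cohort(params, "exposure", seed = seed)
  out_cohort <- simulate_cohort(params, "outcome", seed = seed)
  es <- summarize_exposure_gwas(exp_cohort)
  os <- summarize_outcome_gwas(out_cohort)
  common <- intersect(es$rsid, os$rsid)
  if (length(common) == 0) stop("no SNP summarized in both cohorts")
  es <- es[match(common, es$rsid), ]
  os <- os[match(common, os$rsid), ]
  pw <- params$snps$pathway[match(common, params$snps$rsid)]
  inst <- data.frame(
    rsid = common, locus = common,
    chromosome = rep(1, length(common)),
    decreasing_allele = rep("A", length(common)),
    allele_freq = pmin(pmax(es$freq_hat, 1e-6), 1 - 1e-6),
    gamma = es$gamma_hat, gamma_se = es$se,
    p_exposure = pmax(es$p, 1e-300),
    f_statistic = NA_real_,
    or_outcome = os$or, ci_low = os$ci_low, ci_high = os$ci_high,
    p_outcome = pmin(pmax(os$p, 1e-300), 1),
    source_study = "synthetic", proxy_rsid = NA_character_,
    proxy_r2 = NA_real_, pathway = pw, stringsAsFactors = FALSE
  )
  class(inst) <- c("mr_instruments", "data.frame")
  structure(list(instruments = inst, truth = params,
                 exposure_summary = es, outcome_summary = os),
            class = "two_sample_dataset")
}
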