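fixture_wald <- function() wald_ratio(harmonize(fixture_instruments()))

test_that("Wald ratios match extended-precision arithmetic", {
  w <- fixture_wald()
  expect_equal(w$alpha, frozen$alpha, tolerance = 1e-7)
  expect_equal(w$weight, frozen$weight, tolerance = 1e-6)
  expect_equal(w$weight * w$variance, rep(1, 4), tolerance = 1e-12)

  # a null outcome effect passes through as alpha = 0
  h <- data.frame(rsid = "rs0", locus = "L", gamma_decrease = 0.05,
                  beta = 0, se_beta = 0.02, pathway = "unknown",
                  flipped = FALSE)
  class(h) <- c("mr_harmonized", "data.frame")
  w0 <- wald_ratio(h)
  expect_equal(w0$alpha, 0)
  expect_equal(w0$variance, (0.02 / 0.05)^2)
})

test_that("fixed-effects IVW equals the zero-intercept weighted regression", {
  w <- fixture_wald()
  pooled <- pool_fixed(w)
  expect_equal(pooled$alpha, frozen$alpha_fixed, tolerance = 1e-7)
  expect_equal(pooled$se, frozen$se_fixed, tolerance = 1e-7)
  expect_equal(pooled$z, pooled$alpha / pooled$se)

  # oracle: regression of beta on gamma through the origin, weights 1/se^2
  fit <- lm(beta ~ 0 + gamma_decrease, data = w, weights = 1 / w$se_beta^2)
  expect_equal(pooled$alpha, unname(coef(fit)), tolerance = 1e-12)

  # and on 200 random instrument sets
  for (i in 1:200) {
    wr <- random_wald(n = sample(2:10, 1), seed = 3000 + i)
    p <- pool_fixed(wr)
    ora <- sum(wr$beta * wr$gamma_decrease / wr$se_beta^2) /
      sum(wr$gamma_decrease^2 / wr$se_beta^2)
    expect_equal(p$alpha, ora, tolerance = 1e-12)
  }

  # n = 1 identity and two-estimate symmetry
  p1 <- pool_fixed(fixture_wald()[1, ])
  expect_equal(p1$alpha, frozen$alpha[1], tolerance = 1e-7)
  expect_equal(p1$se, sqrt(1 / frozen$weight[1]), tolerance = 1e-7)
  twin <- random_wald(2, seed = 9)
  twin$alpha <- c(1.2, 1.2); twin$variance <- c(0.5, 0.5)
  twin$weight <- c(2, 2)
  p2 <- pool_fixed(twin)
  expect_equal(p2$alpha, 1.2)
  expect_equal(p2$se, sqrt(0.5 / 2))

  expect_error(pool_fixed(fixture_wald()[0, ]), "empty")
})

test_that("Cochran's Q, I-squared, its CI and tau-squared are reproduced", {
  w <- fixture_wald()
  het <- cochran_q(w, pool_fixed(w)$alpha)
  expect_equal(het$q, frozen$q, tolerance = 1e-6)
  expect_equal(het$df, 3L)
  expect_equal(het$i2, frozen$i2, tolerance = 1e-4)
  expect_equal(het$i2_ci_low, 0)
  expect_equal(het$i2_ci_high, frozen$i2_hi, tolerance = 1e-4)
  expect_equal(het$tau2, frozen$tau2, tolerance = 1e-6)
  expect_false(het$ci_unstable)

  # excluding the GC instrument
  w3 <- w[w$rsid != "rs2282679", ]
  het3 <- cochran_q(w3, pool_fixed(w3)$alpha)
  expect_equal(het3$i2, frozen$i2_minus_gc, tolerance = 1e-4)

  # homogeneity: identical estimates give Q = 0, I2 = 0, tau2 = 0
  twin <- random_wald(2, seed = 4)
  twin$alpha <- c(0.8, 0.8)
  h0 <- cochran_q(twin, 0.8)
  expect_equal(h0$q, 0)
  expect_equal(h0$i2, 0)
  expect_equal(h0$tau2, 0)
  expect_true(h0$ci_unstable)               # flagged for 2 instruments

  # single estimate: heterogeneity undefined
  h1 <- cochran_q(w[1, ], w$alpha[1])
  expect_equal(h1$df, 0L)
  expect_true(is.na(h1$i2))

  # Q <= df truncates both the point estimate and the lower bound to 0
  set.seed(11)
  for (i in 1:20) {
    wr <- random_wald(5, seed = 600 + i)
    wr$alpha <- rep(1, 5) + rnorm(5, 0, 1e-4)
    hh <- cochran_q(wr, pool_fixed(wr)$alpha)
    if (hh$q <= hh$df) {
      expect_equal(hh$i2, 0)
      expect_equal(hh$i2_ci_low, 0)
    }
  }
})

test_that("DerSimonian-Laird pooling matches the independent reference fit", {
  w <- fixture_wald()
  rnd <- pool_random(w)
  expect_equal(rnd$alpha, frozen$alpha_random, tolerance = 1e-7)
  expect_equal(rnd$se, frozen$se_random, tolerance = 1e-7)

  ref <- metafor::rma(yi = w$alpha, vi = w$variance, method = "DL")
  expect_equal(rnd$alpha, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(rnd$se, ref$se, tolerance = 1e-10)
  expect_equal(rnd$het$tau2, ref$tau2, tolerance = 1e-10)

  # tau2 = 0 reduces random effects to the fixed-effects answer exactly
  hom <- random_wald(4, seed = 21)
  hom$alpha <- rep(1.1, 4)
  expect_identical(pool_random(hom)$alpha, pool_fixed(hom)$alpha)
  expect_identical(pool_random(hom)$se, pool_fixed(hom)$se)

  # equal variances: the pooled alpha is the plain mean whatever tau2 is
  pair <- random_wald(2, seed = 22)
  pair$alpha <- c(0.4, 1.9); pair$variance <- c(0.3, 0.3)
  pair$weight <- 1 / pair$variance
  expect_equal(pool_random(pair)$alpha, mean(pair$alpha), tolerance = 1e-12)

  expect_error(pool_random(w[1, ]), "at least two")
})

test_that("per-SD scaling yields the published odds ratios and is invariant", {
  w <- fixture_wald()
  fx <- pool_fixed(w)
  res <- express_per_sd(fx, frozen$sigma_or)
  expect_equal(res$or_per_sd, 2.02, tolerance = 1e-3)
  res2 <- express_per_sd(fx, frozen$sigma_thresh)
  expect_equal(res2$or_per_sd, 1.69498, tolerance = 1e-4)

  # z, p, Q, I2 do not depend on the scaling
  expect_identical(res$pooled$z, res2$pooled$z)
  expect_identical(res$pooled$p, res2$pooled$p)
  expect_identical(res$pooled$het$i2, res2$pooled$het$i2)

  # identity scaling
  expect_equal(express_per_sd(fx, 1)$or_per_sd, exp(fx$alpha))
  expect_error(express_per_sd(fx, 0), "positive")
})

test_that("clinical thresholds back-transform to the equivalent levels", {
  lv <- sd_equivalent_level(c(25, 50, 75), 0.38829)
  expect_equal(lv, c(36.8614, 73.7229, 110.5843), tolerance = 1e-5)
  expect_equal(sd_equivalent_level(40, 0), 40)
  expect_error(sd_equivalent_level(-1, 0.4), "positive")
})

test_that("run_mr composes the full stack deterministically", {
  tab <- fixture_instruments()
  fit <- run_mr(tab, analysis_config())
  expect_equal(fit$fixed$pooled$het$i2, frozen$i2, tolerance = 1e-4)
  expect_equal(fit$fixed$pooled$het$i2_ci_high, frozen$i2_hi,
               tolerance = 1e-4)
  expect_equal(fit$fixed$or_per_sd, 2.02, tolerance = 1e-3)
  expect_identical(run_mr(tab, analysis_config()), fit)

  single <- tab[2, , drop = FALSE]
  fit1 <- run_mr(single, analysis_config())
  expect_null(fit1$random)
  expect_equal(fit1$fixed$pooled$het$df, 0L)
})

test_that("a concordant extra instrument tightens the SE, not the estimate", {
  for (i in 1:20) {
    wr <- random_wald(sample(2:8, 1), seed = 700 + i)
    p0 <- pool_fixed(wr)
    extra <- wr[1, ]
    extra$rsid <- "rs_extra"
    extra$alpha <- p0$alpha
    extra$beta <- p0$alpha * extra$gamma_decrease
    aug <- rbind(wr, extra)
    class(aug) <- class(wr)
    p1 <- pool_fixed(aug)
    expect_equal(p1$alpha, p0$alpha, tolerance = 1e-12)
    expect_lt(p1$se, p0$se)
  }
})
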