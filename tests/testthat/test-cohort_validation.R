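test_that("cohort tables round-trip through the TSV dialect", {
  co <- simulate_cohort(small_params(seed = 314), "exposure")
  tmp <- tempfile(fileext = ".tsv")
  df <- as.data.frame(co)
  df$disease <- NULL
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_cohort_table(tmp)
  expect_s3_class(back, "mr_cohort")
  expect_identical(attr(back, "snps"), attr(co, "snps"))
  expect_true(isTRUE(attr(back, "oriented_to_decreasing")))
  expect_equal(back$log25ohd, co$log25ohd, tolerance = 1e-10)
  expect_identical(as.integer(back$g_rs2282679), co$g_rs2282679)
  expect_identical(levels(back$season), levels(co$season))

  bad <- df
  bad$g_rs2282679[1] <- 3L
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort_table(tmp), "0,1,2")
})

test_that("the allele score counts decreasing alleles and needs orientation", {
  co <- simulate_cohort(small_params(seed = 101), "exposure")
  sc <- allele_count_score(co)
  expect_true(all(sc >= 0 & sc <= 2 * length(attr(co, "snps"))))
  g <- as.matrix(co[, paste0("g_", attr(co, "snps"))])
  expect_identical(sc, as.integer(rowSums(g)))

  # hand-built rows: (2,2,1,1) -> 6; all increasing-homozygous -> 0
  toy <- data.frame(g_a = c(2L, 0L), g_b = c(2L, 0L),
                    g_c = c(1L, 0L), g_d = c(1L, 0L))
  attr(toy, "oriented_to_decreasing") <- TRUE
  expect_identical(allele_count_score(toy), c(6L, 0L))

  attr(toy, "oriented_to_decreasing") <- NULL
  expect_error(allele_count_score(toy), "orientation")
})

test_that("residualization removes covariate-attributable variation", {
  # constant biomarker: residuals all zero
  co <- simulate_cohort(small_params(seed = 5), "exposure")
  co$log25ohd <- rep(4, nrow(co))
  expect_equal(residualize_exposure(co), rep(0, nrow(co)),
               tolerance = 1e-10)

  # collinear covariates are a hard error
  co2 <- simulate_cohort(small_params(seed = 6), "exposure")
  co2$bmi <- 2 * co2$age
  expect_error(residualize_exposure(co2), "rank-deficient|collinear")

  # a true summer shift is almost entirely removed
  eff <- list(sex = 0, age = 0, age2 = 0, bmi = 0,
              season = c(0.2, 0, 0, 0))
  set.seed(31)
  removed <- replicate(100, {
    p <- small_params(covariate_effects = eff,
                      seed = sample.int(1e6, 1))
    coh <- simulate_cohort(p, "exposure")
    r <- residualize_exposure(coh)
    between <- function(y) {
      m <- tapply(y, coh$season, mean)
      n <- tapply(y, coh$season, length)
      sum(n * (m - mean(y))^2) / length(y)
    }
    1 - between(r) / between(coh$log25ohd)
  })
  expect_gte(mean(removed), 0.95)
})

test_that("instrument strength equals the regression t-squared and lm", {
  co <- simulate_cohort(small_params(seed = 77), "exposure")
  r <- residualize_exposure(co)
  sc <- allele_count_score(co)
  st <- instrument_strength(r, sc)
  expect_equal(st$f_statistic, st$t^2, tolerance = 1e-12)

  fit <- summary(lm(r ~ sc))
  expect_equal(st$slope, fit$coefficients[2, 1], tolerance = 1e-10)
  expect_equal(st$se, fit$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(st$p, fit$coefficients[2, 4], tolerance = 1e-10)
  expect_equal(st$r2, fit$r.squared, tolerance = 1e-10)

  # perfectly linear residuals explain everything
  expect_equal(instrument_strength(0.3 * sc, sc)$r2, 1, tolerance = 1e-12)
  expect_error(instrument_strength(r, rep(2, length(r))), "constant")
  expect_error(per_snp_strength(r, rep(1L, length(r))), "monomorphic")

  # joint one-stage convention reports the covariate-adjusted df
  js <- score_strength_joint(co, sc)
  expect_equal(js$df, nrow(co) - 9)  # intercept + 7 covariate cols + score
  expect_equal(sign(js$slope), sign(st$slope))
})

test_that("the F-statistic is calibrated under the null", {
  set.seed(202)
  n <- 400
  rej <- replicate(5000, {
    instrument_strength(rnorm(n), rbinom(n, 2, 0.3))$p < 0.05
  })
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("the rank trend test reduces to the two-group rank-sum test", {
  set.seed(55)
  y <- rnorm(60)
  grp <- rbinom(60, 1, 0.5)
  tt <- trend_test(y, grp)
  ref <- wilcox.test(y[grp == 1], y[grp == 0], exact = FALSE,
                     correct = FALSE)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-10)

  # a strong monotone decrease gives a large negative z
  n <- 2000
  score <- rbinom(n, 8, 0.35)
  yy <- -0.1 * score + rnorm(n, 0, 0.4)
  td <- trend_test(yy, score)
  expect_lt(td$z, -5)
  expect_lt(td$p, 1e-6)
  expect_true(all(diff(td$group_means) < 0.2))  # decreasing up to noise

  expect_error(trend_test(y, rep(3, 60)), "two groups")
})

test_that("the rank trend test is calibrated under permutation", {
  set.seed(303)
  n <- 300
  score <- rbinom(n, 8, 0.35)
  rej <- replicate(5000, trend_test(rnorm(n), score)$p < 0.05)
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("pairwise r2 behaves as a composite-LD matrix", {
  co <- simulate_cohort(small_params(seed = 88), "exposure")
  g <- as.matrix(co[, paste0("g_", attr(co, "snps"))])
  r2 <- pairwise_r2(g)
  expect_equal(r2, t(r2))
  expect_equal(diag(r2), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(r2 >= 0 & r2 <= 1))

  # duplicated column: off-diagonal exactly 1
  dup <- cbind(g[, 1], g[, 1], g[, 2])
  expect_equal(pairwise_r2(dup)[1, 2], 1)

  # reflection invariance: relabeling the counted allele leaves r2 alone
  flip <- g; flip[, 2] <- 2 - flip[, 2]
  expect_equal(pairwise_r2(flip), pairwise_r2(g), tolerance = 1e-12)

  # complete positive association at matched frequency 0.5
  set.seed(9)
  hap <- rbinom(500, 1, 0.5) + rbinom(500, 1, 0.5)
  expect_equal(pairwise_r2(cbind(hap, hap))[1, 2], 1)

  mono <- g; mono[, 3] <- 1L
  expect_error(pairwise_r2(mono), "monomorphic.*rs2282679")
})

test_that("the ancestry trend test matches the closed-form statistic", {
  set.seed(14)
  g <- rbinom(800, 2, 0.3)
  grp <- rbinom(800, 1, 0.1 + 0.15 * (g / 2))
  res <- ancestry_association(g, grp)

  # independent oracle: Cochran-Armitage chi-square from first principles
  lev <- sort(unique(g))
  e <- sapply(lev, function(l) sum(grp[g == l]))
  n <- sapply(lev, function(l) sum(g == l))
  pbar <- sum(e) / sum(n)
  num <- sum(lev * (e - n * pbar))^2
  den <- pbar * (1 - pbar) * (sum(n * lev^2) - sum(n * lev)^2 / sum(n))
  expect_equal(unname(res$statistic), num / den, tolerance = 1e-10)
  expect_equal(res$p, pchisq(num / den, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # perfect separation drives p toward zero
  sep <- ancestry_association(c(rep(0, 500), rep(2, 500)),
                              c(rep(0, 500), rep(1, 500)))
  expect_lt(sep$p, 1e-100)

  expect_error(ancestry_association(g, rep(0, 800)), "non-empty")
  # genotype-table chi-square option runs and agrees on direction
  expect_lt(ancestry_association(g, grp, method = "chisq")$p, 0.05)
})

test_that("the ancestry trend test is calibrated with no frequency gap", {
  set.seed(404)
  rej <- replicate(5000, {
    g <- rbinom(1000, 2, 0.3)
    grp <- rbinom(1000, 1, 0.1)
    ancestry_association(g, grp)$p < 0.05
  })
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("Hardy-Weinberg checks accept HWE counts and reject disequilibrium", {
  # counts exactly at HWE proportions for f = 0.3
  g <- c(rep(0L, 49), rep(1L, 42), rep(2L, 9))
  expect_equal(hwe_check(g), 1)
  expect_gt(hwe_check(c(rep(0L, 52), rep(1L, 40), rep(2L, 8))), 0.05)

  # maximal disequilibrium: no heterozygotes at f = 0.5
  expect_lt(hwe_check(c(rep(0L, 50), rep(2L, 50))), 1e-10)

  expect_warning(p1 <- hwe_check(rep(0L, 100)), "monomorphic")
  expect_equal(p1, 1)
  expect_warning(hwe_check(rep(c(0L, 1L), 5)), "fewer than 30")
})

test_that("simulated genotypes produce uniform HWE p-values", {
  ps <- unlist(lapply(1:400, function(i) {
    co <- simulate_cohort(sim_params(seed = 50000 + i), "exposure")
    sapply(paste0("g_", attr(co, "snps")),
           function(cn) hwe_check(co[[cn]]))
  }))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
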