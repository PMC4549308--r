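# Shared fixtures and frozen oracle values.
#
# The "frozen" numbers below were computed in extended precision from the
# packaged instrument table by direct evaluation of the defining formulas
# (log/qnorm arithmetic, weighted sums), independently of the package
# code paths they are used to check.

fixture_instruments <- function() {
  read_instrument_table(instrument_fixture_path())
}

# per-SNP quantities in fixture row order:
# rs10741657, rs12785878, rs2282679, rs6013897
frozen <- list(
  beta   = c(0.0487901641694, 0.104360015324, 0.0392207131533,
             0.0676586484738),
  se_ci  = c(0.01693272669, 0.0183940354185, 0.0196332794233,
             0.0190822927545),
  alpha  = c(0.938272387874, 1.86357170222, 0.83448325858, 2.5058758694),
  weight = c(9.43089457937, 9.26876811591, 5.73073096775, 2.00201081653),
  alpha_fixed = 1.3589664772,
  se_fixed    = 0.19450540056,
  q  = 8.23905823377,
  i2 = 63.5880714169,
  i2_hi = 87.7089347278,
  tau2 = 0.284372067062,
  alpha_random = 1.4207205895,
  se_random    = 0.341678370152,
  alpha_minus_gc = 1.50415629585,
  i2_minus_gc    = 67.8778875952,
  sigma_or = 0.51738,
  sigma_thresh = 0.38829
)

# a tiny instrument table built in code (not the fixture) for edge cases
toy_instruments <- function(n = 2, gamma = rep(-0.05, n),
                            or = rep(1.10, n),
                            half_width = rep(1.04, n),
                            p_outcome = rep(0.01, n)) {
  df <- data.frame(
    rsid = paste0("rs", seq_len(n)), locus = paste0("L", seq_len(n)),
    chromosome = rep(1, n), decreasing_allele = rep("A", n),
    allele_freq = rep(0.3, n), gamma = gamma, gamma_se = NA_real_,
    p_exposure = rep(1e-10, n), f_statistic = NA_real_,
    or_outcome = or, ci_low = or / half_width, ci_high = or * half_width,
    p_outcome = p_outcome, source_study = "toy",
    proxy_rsid = NA_character_, proxy_r2 = NA_real_,
    pathway = rep("unknown", n), stringsAsFactors = FALSE
  )
  class(df) <- c("mr_instruments", "data.frame")
  df
}

# random valid wald-estimate sets for property tests
random_wald <- function(n, seed) {
  set.seed(seed)
  harm <- data.frame(
    rsid = paste0("rs", seq_len(n)),
    locus = paste0("L", seq_len(n)),
    gamma_decrease = runif(n, 0.01, 0.1),
    beta = rnorm(n, 0.08, 0.04),
    se_beta = runif(n, 0.005, 0.05),
    pathway = "unknown", flipped = FALSE, stringsAsFactors = FALSE
  )
  class(harm) <- c("mr_harmonized", "data.frame")
  wald_ratio(harm)
}

small_params <- function(...) {
  sim_params(n_exposure = 500L, n_cases = 600L, n_controls = 900L, ...)
}
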