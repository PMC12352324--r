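ref_moments <- function() moment_summary(reference_correlations(), 282)

test_that("ratio-tied reparameterization reproduces the saturated fit and ratios", {
  m <- ref_moments()
  sat <- fit_apim(m)
  est <- setNames(sat$estimates$estimate, sat$estimates$term)
  tied <- fit_apim(m, apim_spec(ratio_k = "two"))
  expect_equal(tied$F_ml, 0, tolerance = 1e-10)
  tk <- setNames(tied$estimates$estimate, tied$estimates$term)
  expect_equal(tk[["k1"]], est[["p12"]] / est[["a1"]], tolerance = 1e-8)
  expect_equal(tk[["k2"]], est[["p21"]] / est[["a2"]], tolerance = 1e-8)
  # fixing the ratios at the unconstrained p/a preserves the saturated fit
  fixed <- fit_apim(m, apim_spec(ratio_k = "two",
                                 k1 = est[["p12"]] / est[["a1"]],
                                 k2 = est[["p21"]] / est[["a2"]]))
  expect_equal(fixed$F_ml, 0, tolerance = 1e-10)
  expect_equal(max(abs(implied_moments(fixed) - m$S)), 0, tolerance = 1e-6)
})

test_that("k point estimates and guards follow the ratio definition", {
  # construction: a = 0.5, p = 0.25 on both sides -> k = 0.5 exactly
  pp <- sim_params(a1 = 0.5, a2 = 0.5, p12 = 0.25, p21 = 0.25, rho_x = 0.2)
  kc <- estimate_k(implied_population_moments(pp), distinguishable = TRUE, B = 0)
  expect_equal(kc$k, c(0.5, 0.5), tolerance = 1e-8)
  # small actor effect triggers the 0.10 guard
  weak <- sim_params(a1 = 0.05, a2 = 0.5, p12 = 0.02, p21 = 0.1)
  expect_error(estimate_k(implied_population_moments(weak), B = 0), "guard")
  # the reference moments give the published pair of ratios
  kk <- estimate_k(ref_moments(), B = 0)
  expect_equal(sort(kk$k), c(0.0584, 0.0657), tolerance = 5e-4)
  # outgoing convention divides the emanating path instead
  ko <- estimate_k(ref_moments(), B = 0, convention = "outgoing")
  sat <- setNames(fit_apim(ref_moments())$estimates$estimate,
                  fit_apim(ref_moments())$estimates$term)
  expect_equal(ko$k[1], sat[["p21"]] / sat[["a1"]], tolerance = 1e-8)
})

test_that("bootstrap CIs are seed-reproducible and stable in B", {
  m <- ref_moments()
  k1 <- estimate_k(m, B = 800, seed = 99)
  k2 <- estimate_k(m, B = 800, seed = 99)
  expect_identical(k1$ci_low, k2$ci_low)
  expect_identical(k1$ci_high, k2$ci_high)
  k4 <- estimate_k(m, B = 3200, seed = 100)
  expect_lt(max(abs(k4$ci_low - k1$ci_low)), 0.06)
  expect_lt(max(abs(k4$ci_high - k1$ci_high)), 0.06)
  expect_true(all(k1$ci_low <= k1$k & k1$k <= k1$ci_high))
  expect_error(estimate_k(m, B = 100), "seed")
})

test_that("k equality test accepts symmetric and rejects opposed ratios", {
  # swap-symmetric moments: statistic 0, p = 1
  pp <- sim_params(a1 = 0.5, a2 = 0.5, p12 = 0.2, p21 = 0.2)
  eq <- test_k_equality(implied_population_moments(pp))
  expect_lt(eq$statistic, 1e-5)
  expect_gt(eq$p_value, 0.999)
  # population with k1 = 0.5, k2 = -0.5 at large N: decisive rejection
  opp <- sim_params(a1 = 0.5, a2 = 0.5, p12 = 0.25, p21 = -0.25, n = 5000)
  ne <- test_k_equality(implied_population_moments(opp))
  expect_lt(ne$p_value, 1e-6)
  # the reference moments do not reject (printed ratios nearly equal)
  expect_gt(test_k_equality(ref_moments())$p_value, 0.2)
})

test_that("pattern classifier takes the rule-forced branches", {
  m <- ref_moments()
  k <- estimate_k(m, B = 1000, seed = 12)
  # forge CI sets to exercise each branch deterministically
  forge <- function(lo, hi) {
    kk <- k
    kk$ci_low <- lo
    kk$ci_high <- hi
    kk
  }
  couple <- classify_pattern(forge(c(0.8, 0.8), c(1.2, 1.2)), collapse_equal = FALSE)
  expect_true(couple$pattern %in% c("couple", "none"))
  expect_match(paste(couple$trace$question, collapse = " "), "k = 1")
  contrast <- classify_pattern(forge(c(-1.3, -1.3), c(-0.7, -0.7)), collapse_equal = FALSE)
  expect_match(paste(contrast$trace$question, collapse = " "), "k = -1")
  wide <- classify_pattern(forge(c(-0.2, -0.2), c(1.1, 1.1)), collapse_equal = FALSE)
  expect_equal(wide$pattern, "ambiguous")
  expect_true(length(wide$refits) >= 2)
  nothing <- classify_pattern(forge(c(0.3, 0.3), c(0.6, 0.6)), collapse_equal = FALSE)
  expect_equal(nothing$pattern, "none")
  disagree <- classify_pattern(forge(c(-0.1, 0.7), c(0.2, 1.2)), collapse_equal = FALSE)
  expect_equal(disagree$pattern, "ambiguous")
  expect_gt(nrow(couple$trace), 0)
})

test_that("reference moments classify as actor-only with an audited trace", {
  k <- estimate_k(ref_moments(), B = 1500, seed = 2024)
  pd <- classify_pattern(k)
  expect_equal(pd$pattern, "actor_only")
  expect_gt(pd$k_equality_p, 0.05)  # collapsed to a common k
  expect_equal(pd$k_active$which, "common")
  expect_true(pd$refits$k0$adequate)
  expect_false(anyNA(pd$trace$answer))
  # without the collapse the two separate CIs reach the same conclusion here
  pd2 <- classify_pattern(k, collapse_equal = FALSE)
  expect_equal(pd2$pattern, "actor_only")
})

test_that("classifier input validation and expert partner-only flag", {
  k0 <- estimate_k(ref_moments(), B = 0)
  expect_error(classify_pattern(k0), "no confidence intervals")
  k <- estimate_k(ref_moments(), B = 500, seed = 5)
  pd <- classify_pattern(k, allow_partner_only = TRUE)
  expect_true("partner_only_candidate" %in% names(pd$refits))
})
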