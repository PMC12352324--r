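ref_moments <- function() moment_summary(reference_correlations(), 282)

test_that("saturated fit matches the closed-form two-predictor regression", {
  m <- ref_moments()
  fit <- fit_apim(m)
  expect_equal(fit$F_ml, 0)
  expect_equal(fit$chi2, 0)
  expect_equal(fit$df, 0L)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  # standardized a1 by hand: (r13 - r12 r23) / (1 - r12^2)
  expect_equal(est[["a1"]], (0.629 - 0.212 * 0.168) / (1 - 0.212^2), tolerance = 1e-12)
  # implied moments of the saturated fit reproduce the input exactly
  expect_equal(max(abs(implied_moments(fit) - m$S)), 0, tolerance = 1e-12)
})

test_that("saturated fit agrees with an independent least-squares oracle on raw dyads", {
  for (seed in c(2, 3)) {
    d <- generate_dyads(sim_scenario("paper_like"), seed = seed)
    fit <- fit_apim(d)
    est <- setNames(fit$estimates$estimate, fit$estimates$term)
    ora <- lm_saturated_paths(d)
    expect_equal(est[c("a1", "p12", "p21", "a2")], ora[c("a1", "p12", "p21", "a2")],
                 tolerance = 1e-8)
    expect_equal(fit$F_ml, 0, tolerance = 1e-12)
  }
})

test_that("orthogonal or null moment structures give the expected degenerate paths", {
  S0 <- diag(4)
  f0 <- fit_apim(moment_summary(S0, 100))
  expect_equal(max(abs(f0$estimates$estimate[1:4])), 0)
  # r_x1x2 = 0 makes a1 equal r_x1y1 exactly
  S <- diag(4)
  S[1, 3] <- S[3, 1] <- 0.5
  f <- fit_apim(moment_summary(S, 100))
  expect_equal(f$estimates$estimate[f$estimates$term == "a1"], 0.5)
})

test_that("constrained ML fits minimize the discrepancy and respect F >= 0", {
  m <- ref_moments()
  fit0 <- fit_apim(m, apim_spec(p12 = 0, p21 = 0))
  expect_true(fit0$converged)
  expect_gt(fit0$F_ml, 0)
  expect_equal(fit0$df, 2L)
  # discrepancy recomputed directly from the implied matrix agrees
  expect_equal(fit0$F_ml, fml_direct(implied_moments(fit0), m$S), tolerance = 1e-10)
  # perturbing the solution never lowers the discrepancy (local optimality)
  est <- setNames(fit0$estimates$estimate, fit0$estimates$term)
  for (i in 1:5) {
    th <- est
    th[c("a1", "a2")] <- th[c("a1", "a2")] + rnorm(2, sd = 0.01)
    Sig <- with(as.list(th), {
      B <- rbind(c(a1, p12), c(p21, a2))
      Sxx <- matrix(c(var_x1, cov_x, cov_x, var_x2), 2)
      Psi <- matrix(c(var_e1, cov_e, cov_e, var_e2), 2)
      rbind(cbind(Sxx, Sxx %*% t(B)), cbind(B %*% Sxx, B %*% Sxx %*% t(B) + Psi))
    })
    expect_gte(fml_direct(Sig, m$S) + 1e-12, fit0$F_ml)
  }
  # chi-square scaling conventions
  expect_equal(fit_apim(m, apim_spec(p12 = 0, p21 = 0), scaling = "N")$chi2,
               282 / 281 * fit0$chi2, tolerance = 1e-8)
})

test_that("partner relabeling maps estimates symmetrically and keeps fit statistics", {
  m <- ref_moments()
  perm <- c(2, 1, 4, 3)  # swap partners: x1<->x2, y1<->y2
  m_swap <- moment_summary(m$S[perm, perm], m$n)
  f <- fit_apim(m, apim_spec(p12 = 0, p21 = 0))
  f_swap <- fit_apim(m_swap, apim_spec(p12 = 0, p21 = 0))
  e <- setNames(f$estimates$estimate, f$estimates$term)
  es <- setNames(f_swap$estimates$estimate, f_swap$estimates$term)
  expect_equal(es[["a1"]], e[["a2"]], tolerance = 1e-7)
  expect_equal(es[["a2"]], e[["a1"]], tolerance = 1e-7)
  expect_equal(f_swap$F_ml, f$F_ml, tolerance = 1e-9)
})

test_that("likelihood-ratio tests are monotone, nested and calibrated at the population limit", {
  m <- ref_moments()
  full <- fit_apim(m)
  restricted <- fit_apim(m, apim_spec(p12 = 0, p21 = 0))
  lr <- lr_test(restricted, full)
  expect_equal(lr$statistic, restricted$chi2)  # full is saturated
  expect_equal(lr$df, 2L)
  expect_identical(lr_test(full, full)$p_value, 1)
  expect_error(lr_test(full, restricted), "df")
  # population moments generated with a1 = a2 -> equality restriction costless
  pp <- sim_params(a1 = 0.4, a2 = 0.4, p12 = 0.1, p21 = 0.1)
  mp <- implied_population_moments(pp)
  req <- fit_apim(mp, apim_spec(equal = list(c("a1", "a2"), c("p12", "p21"))))
  expect_lt(lr_test(req, fit_apim(mp))$statistic, 1e-6)
})

test_that("distinguishability is decided by the LR p-value against 0.2", {
  # swap-symmetric moments: indistinguishable with p = 1
  S <- diag(4)
  S[1, 2] <- S[2, 1] <- 0.3
  S[1, 3] <- S[3, 1] <- S[2, 4] <- S[4, 2] <- 0.5
  S[2, 3] <- S[3, 2] <- S[1, 4] <- S[4, 1] <- 0.2
  S[3, 4] <- S[4, 3] <- 0.25
  d_sym <- test_distinguishability(moment_summary(S, 200))
  expect_false(d_sym$distinguishable)
  expect_gt(d_sym$overall$p_value, 0.999)
  # reference moments: distinguishable
  d_ref <- test_distinguishability(ref_moments())
  expect_true(d_ref$distinguishable)
  expect_lt(d_ref$overall$p_value, 0.2)
  # strongly asymmetric population at large N
  pp <- sim_params(a1 = 0.6, a2 = 0.3, n = 5000)
  d_pop <- test_distinguishability(implied_population_moments(pp))
  expect_true(d_pop$distinguishable)
  expect_equal(nrow(tidy(d_ref)), 3L)
})

test_that("moment containers validate their inputs", {
  expect_error(moment_summary(diag(3), 50), "4x4")
  bad <- diag(4)
  bad[1, 2] <- 2  # asymmetric
  expect_error(moment_summary(bad, 50), "symmetric")
  npd <- matrix(0.99, 4, 4)
  diag(npd) <- c(1, 1, 1, 0.5)
  expect_error(moment_summary(npd, 50), "positive definite")
  # CSV round trip preserves values and sample size
  m <- ref_moments()
  path <- withr::local_tempfile(fileext = ".csv")
  write_moments_csv(m, path)
  m2 <- read_moments_csv(path)
  expect_equal(m2$S, m$S)
  expect_equal(m2$n, m$n)
})
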