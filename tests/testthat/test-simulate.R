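test_that("implied population moments follow the path-tracing rules", {
  # all paths and correlations zero: identity
  p0 <- sim_params(a1 = 0, a2 = 0, rho_x = 0, rho_e = 0)
  expect_equal(implied_population_moments(p0)$S, diag(4), ignore_attr = TRUE)
  # no partner paths: r(x2, y1) = a1 * rho_x
  p1 <- sim_params(a1 = 0.5, a2 = 0.3, rho_x = 0.4, rho_e = 0)
  S1 <- implied_population_moments(p1)$S
  expect_equal(S1["x2", "y1"], 0.5 * 0.4)
  expect_equal(S1["x1", "y1"], 0.5)
  expect_equal(unname(diag(S1)), rep(1, 4))  # unit-variance defaults
  # round trip: parameters fitted from the reference correlations reproduce them
  pp <- sim_scenario("paper_like")
  expect_lt(max(abs(implied_population_moments(pp)$S - reference_correlations())), 1e-6)
})

test_that("the generator is seed-deterministic and matches its own moments at large n", {
  pp <- sim_scenario("paper_like", n = 100000)
  d1 <- generate_dyads(pp, seed = 123)
  d2 <- generate_dyads(pp, seed = 123)
  expect_identical(d1, d2)
  emp <- cor(as.matrix(d1[, -1]))
  expect_lt(max(abs(emp - reference_correlations())), 0.015)
})

test_that("fitting recovers the generating paths without bias at n = 282", {
  pp <- sim_scenario("paper_like")
  truth <- c(a1 = pp$a1, a2 = pp$a2, p12 = pp$p12, p21 = pp$p21)
  R <- 200
  est <- matrix(NA_real_, R, 4, dimnames = list(NULL, names(truth)))
  for (r in seq_len(R)) {
    f <- fit_apim(generate_dyads(pp, seed = 5000 + r))
    e <- setNames(f$estimates$estimate, f$estimates$term)
    est[r, ] <- e[names(truth)]
  }
  bias <- colMeans(est) - truth
  mc_se <- apply(est, 2, sd) / sqrt(R)
  expect_true(all(abs(bias) < 3 * mc_se))
})

test_that("degenerate residual limit makes outcomes deterministic in the stresses", {
  p <- sim_params(a1 = 0.6, a2 = 0.6, sd_y_resid1 = 1e-8, sd_y_resid2 = 1e-8)
  d <- generate_dyads(p, seed = 4)
  resid <- d$woman_depression - 0.6 * d$woman_stress
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("invalid generator parameters are refused", {
  expect_error(sim_params(a1 = 0.9, p12 = 0.9), "explained variance")
  expect_error(sim_params(rho_x = 1), "rho_x")
  expect_error(sim_params(n = 2), "at least 4")
  expect_error(generate_dyads(sim_params()), "seed")
})

test_that("item generation is uniform over compositions and inverts scoring", {
  # round trip across the whole EPDS range
  totals <- 0:30
  items <- generate_item_responses(totals, "EPDS", seed = 31)
  rescored <- vapply(seq_along(totals),
                     function(i) score_epds(as.integer(items[i, -1]))$total, integer(1))
  expect_equal(rescored, totals)
  # boundary totals admit a single composition
  expect_true(all(items[1, -1] == 0))
  expect_true(all(items[nrow(items), -1] == 3))
  # PSS-14 round trip honours reverse keying
  t_pss <- c(0L, 13L, 28L, 41L, 56L)
  it_pss <- generate_item_responses(t_pss, "PSS14", seed = 32)
  re_pss <- vapply(seq_along(t_pss),
                   function(i) score_pss14(as.integer(it_pss[i, -1]))$total, integer(1))
  expect_equal(re_pss, t_pss)
  # uniformity over compositions: EPDS total 1 has exactly 10 item vectors
  draws <- generate_item_responses(rep(1L, 4000), "EPDS", seed = 33)
  which_item <- apply(as.matrix(draws[, -1]), 1, which.max)
  counts <- tabulate(which_item, 10)
  expect_gt(chisq.test(counts)$p.value, 0.001)
  expect_error(generate_item_responses(31, "EPDS", seed = 1), "0\\.\\.30")
})
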