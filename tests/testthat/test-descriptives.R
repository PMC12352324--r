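test_that("signed-rank test matches the enumeration oracle at small n and behaves antisymmetrically", {
  x <- c(3, 5, 9, 2, 8)
  y <- c(2, 3, 6, 3, 4)  # differences 1, 2, 3, -1, 4 with a tie on |d| = 1
  res <- wilcoxon_signed_rank(x, y)
  exact <- wilcoxon_exact_p(x, y)
  expect_lt(abs(res$p_value - exact), 0.12)  # crude at n = 5
  # swapping the vectors flips Z, keeps p
  flipped <- wilcoxon_signed_rank(y, x)
  expect_equal(flipped$z, -res$z)
  expect_equal(flipped$p_value, res$p_value)
  # agreement with stats::wilcox.test's normal approximation (no continuity
  # correction), which uses the same tie-corrected variance
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(30)
    b <- rnorm(30)
    ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE))
    got <- wilcoxon_signed_rank(a, b)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("normal-approximation signed-rank p converges to the exact enumeration p", {
  set.seed(7)
  errs <- sapply(c(6, 9, 12), function(n) {
    max(sapply(1:12, function(i) {
      x <- sample(0:30, n, replace = TRUE)
      y <- sample(0:30, n, replace = TRUE)
      if (all(x == y)) x[1] <- x[1] + 1
      abs(wilcoxon_signed_rank(x, y)$p_value - wilcoxon_exact_p(x, y))
    }))
  })
  expect_true(all(errs < 0.15))
  expect_lt(errs[3], errs[2])
  expect_lt(errs[2], errs[1])  # approximation improves with n
  expect_lt(errs[3], 0.05)
})

test_that("signed-rank test drops zero differences and refuses degenerate input", {
  v <- c(1, 2, 3, 4, 5, 6)
  expect_error(wilcoxon_signed_rank(v, v), "all within-pair differences are zero")
  w <- c(2, 3, 3, 4, 5, 7)  # three zero differences dropped
  expect_equal(wilcoxon_signed_rank(v, w)$n_used, 3L)
})

test_that("uncorrected 2x2 chi-square matches closed form and its invariances", {
  # closed form chi2 = N (ad - bc)^2 / (r1 r2 c1 c2)
  m <- matrix(c(20, 30, 15, 35), 2, 2)
  byhand <- sum(m) * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    (prod(rowSums(m)) * prod(colSums(m)))
  expect_equal(chi2_2x2(m)$statistic, byhand)
  # invariant to transpose and row swap
  expect_equal(chi2_2x2(t(m))$statistic, chi2_2x2(m)$statistic)
  expect_equal(chi2_2x2(m[2:1, ])$statistic, chi2_2x2(m)$statistic)
  # proportional rows give zero
  expect_equal(chi2_2x2(matrix(c(10, 10, 20, 20), 2, 2))$statistic, 0)
  # zero margin refused
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 7), 2, 2, byrow = TRUE)), "margin")
  # Yates option is more conservative
  expect_lt(chi2_2x2(m, correct = TRUE)$statistic, chi2_2x2(m)$statistic)
})

test_that("correlation matrix reproduces hand computation and refuses constants", {
  df <- data.frame(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4), z = c(2, 4, 6, 8))
  cs <- correlation_matrix(df)
  # hand product-moment value for x vs y
  r_hand <- sum((df$x - 2.5) * (df$y - 2.5)) /
    sqrt(sum((df$x - 2.5)^2) * sum((df$y - 2.5)^2))
  expect_equal(cs$r["x", "y"], r_hand)
  expect_equal(unname(diag(cs$r)), rep(1, 3))
  expect_equal(cs$r["x", "z"], 1)  # exact linear relation
  expect_true(max(abs(cs$r - t(cs$r))) == 0)
  expect_true(min(eigen(cs$r, symmetric = TRUE, only.values = TRUE)$values) > -1e-12)
  # affine rescaling leaves r unchanged
  df2 <- transform(df, y = 10 * y - 3)
  expect_equal(correlation_matrix(df2)$r, cs$r)
  expect_error(correlation_matrix(data.frame(x = 1:5, c = rep(2, 5))), "constant.*c")
  expect_equal(nrow(tidy(cs)), 3L)
})

test_that("stress-gender interaction model recovers built-in slopes with clustered SEs", {
  # noiseless construction: slope 0.5 for women, 0.3 for men
  n <- 60
  long <- data.frame(
    dyad_id = rep(1:n, each = 2),
    gender = rep(c(0, 1), n),
    stress = rep(seq(0, 10, length.out = n), each = 2) + rep(c(0, 0.5), n)
  )
  long$depression <- with(long, ifelse(gender == 0, 0.5 * stress, 0.3 * stress))
  ct <- suppressWarnings(stress_gender_interaction(long))  # noiseless fit
  inter <- ct[grepl(":", ct$term), ]
  expect_equal(unname(abs(inter$estimate)), 0.2, tolerance = 1e-10)
  # identical slopes: interaction exactly zero
  long$depression <- 0.4 * long$stress + 1
  ct0 <- suppressWarnings(stress_gender_interaction(long))
  expect_equal(unname(ct0$estimate[grepl(":", ct0$term)]), 0, tolerance = 1e-10)
  expect_error(
    stress_gender_interaction(transform(long, stress = 1)),
    "singular")
})

test_that("describe_dyads builds the role-comparison block on synthetic couples", {
  d <- generate_dyads(sim_params(n = 120, mu = c(24, 22, 5, 4),
                                 sd_x1 = 7, sd_x2 = 7), seed = 9)
  # spread the depression totals so the cutoff splits both roles
  d$woman_depression <- round((d$woman_depression - 5) * 4 + 9)
  d$husband_depression <- round((d$husband_depression - 4) * 4 + 7)
  tab <- describe_dyads(d)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_match(tab$variable[3], "EPDS")
  # cutoff never reached: the chi-square row degrades to NA, no error
  d0 <- d
  d0$woman_depression <- pmin(d0$woman_depression, 8)
  d0$husband_depression <- pmin(d0$husband_depression, 8)
  tab0 <- describe_dyads(d0)
  expect_true(is.na(tab0$statistic[3]))
  expect_match(tab0$method[3], "not computable")
})
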