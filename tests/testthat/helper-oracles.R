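# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact two-sided signed-rank p by full enumeration of the 2^n sign
# assignments (zero differences dropped, mid-ranks for ties).
wilcoxon_exact_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Saturated APIM oracle: two least-squares regressions on raw dyads.
lm_saturated_paths <- function(dyads) {
  f1 <- lm(woman_depression ~ woman_stress + husband_stress, data = dyads)
  f2 <- lm(husband_depression ~ woman_stress + husband_stress, data = dyads)
  c(a1 = unname(coef(f1)["woman_stress"]),
    p12 = unname(coef(f1)["husband_stress"]),
    p21 = unname(coef(f2)["woman_stress"]),
    a2 = unname(coef(f2)["husband_stress"]))
}

# ML discrepancy evaluated directly (no package internals).
fml_direct <- function(Sigma, S) {
  as.numeric(determinant(Sigma)$modulus - determinant(S)$modulus) +
    sum(diag(S %*% solve(Sigma))) - 4
}

# The published couple correlation matrix, re-entered by hand so tests do
# not depend on the packaged fixture file.
reference_correlations <- function() {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.212
  R[1, 3] <- R[3, 1] <- 0.629
  R[2, 3] <- R[3, 2] <- 0.168
  R[1, 4] <- R[4, 1] <- 0.132
  R[2, 4] <- R[4, 2] <- 0.482
  R[3, 4] <- R[4, 3] <- 0.208
  R
}
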