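#' Fit-adequacy thresholds
#'
#' The conventional cutoffs used to call a path model's fit adequate:
#' chi-square/df below 3, CFI and TLI at or above 0.90, RMSEA and SRMR at
#' or below 0.08. All five must hold simultaneously for a fit to count as
#' adequate in the pattern classifier.
#'
#' @param chi2_df,cfi,tli,rmsea,srmr Numeric cutoffs.
#' @return Named list of thresholds.
#' @export
fit_thresholds <- function(chi2_df = 3, cfi = 0.90, tli = 0.90,
                           rmsea = 0.08, srmr = 0.08) {
  list(chi2_df = chi2_df, cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr)
}

# independence baseline: implied covariance diagonal, variances free.
# Closed form: F_b = -log det of the sample correlation matrix, df = 6.
independence_baseline <- function(S, scale_n) {
  R <- cov2cor(S)
  f <- -as.numeric(determinant(R, logarithm = TRUE)$modulus)
  list(F_ml = f, chi2 = scale_n * f, df = 6L)
}

#' SEM fit indices for an APIM fit
#'
#' Computes chi-square/df, CFI, TLI, RMSEA and SRMR for a fitted APIM
#' against the independence baseline (all covariances zero, variances
#' free), plus the verdicts against [fit_thresholds]. Conventions:
#' \itemize{
#'   \item CFI truncates excess chi-square at zero, so `chi2 <= df` forces
#'     CFI = 1; TLI is not truncated and may exceed 1.
#'   \item RMSEA = sqrt(max(chi2 - df, 0) / (df * scale_n)) with the same
#'     scaling constant as the fit's chi-square; `chi2 <= df` forces 0.
#'   \item SRMR is the root mean square of the residual correlations over
#'     the 10 unique entries of the 4x4 matrix (diagonal included; its
#'     residuals are zero whenever variances are free).
#'   \item A saturated target (df = 0) reports the exact constants
#'     chi2/df = 0, CFI = TLI = 1, RMSEA = SRMR = 0 with `saturated = TRUE`.
#' }
#'
#' @param fit An [fit_apim] result (the target model).
#' @param baseline Optional [fit_apim] of the baseline on the same moments;
#'   by default the independence model is computed in closed form.
#' @param thresholds A [fit_thresholds] list.
#' @return A `fit_indices` object: one-row tibble of indices plus verdicts.
#' @export
compute_fit_indices <- function(fit, baseline = NULL, thresholds = fit_thresholds()) {
  stopifnot(inherits(fit, "apim_fit"))
  if (is.null(baseline)) {
    b <- independence_baseline(fit$S, fit$scale_n)
  } else {
    stopifnot(inherits(baseline, "apim_fit"))
    if (max(abs(baseline$S - fit$S)) > 1e-10) abort("baseline is not on the same moments")
    b <- list(chi2 = baseline$chi2, df = baseline$df)
  }
  if (b$df <= 0 || b$chi2 <= 0) abort("degenerate baseline model (no df or zero chi-square)")
  chi2_t <- fit$chi2
  df_t <- fit$df
  saturated <- df_t == 0L
  # SRMR on the correlation-scale residuals, 10 unique entries
  rs <- cov2cor(fit$S) - cov2cor(fit$Sigma)
  srmr <- sqrt(mean(rs[lower.tri(rs, diag = TRUE)]^2))
  if (saturated) {
    chi2_over_df <- 0
    cfi <- 1
    tli <- 1
    rmsea <- 0
  } else {
    chi2_over_df <- chi2_t / df_t
    num <- max(chi2_t - df_t, 0)
    cfi <- 1 - num / max(chi2_t - df_t, b$chi2 - b$df, .Machine$double.eps)
    tli <- (b$chi2 / b$df - chi2_t / df_t) / (b$chi2 / b$df - 1)
    rmsea <- sqrt(num / (df_t * fit$scale_n))
  }
  idx <- tibble::tibble(
    chi2 = chi2_t, df = df_t, chi2_over_df = chi2_over_df,
    srmr = srmr, rmsea = rmsea, tli = tli, cfi = cfi
  )
  verdicts <- c(
    chi2_df = chi2_over_df < thresholds$chi2_df,
    cfi = cfi >= thresholds$cfi,
    tli = tli >= thresholds$tli,
    rmsea = rmsea <= thresholds$rmsea,
    srmr = srmr <= thresholds$srmr
  )
  structure(list(indices = idx, verdicts = verdicts,
                 adequate = all(verdicts), saturated = saturated,
                 thresholds = thresholds,
                 baseline = tibble::tibble(chi2 = b$chi2, df = b$df)),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  i <- x$indices
  cat(sprintf("chi2 = %.3f (df = %d, chi2/df = %.3f)  SRMR = %.3f  RMSEA = %.3f  TLI = %.3f  CFI = %.3f\n",
              i$chi2, i$df, i$chi2_over_df, i$srmr, i$rmsea, i$tli, i$cfi))
  if (x$saturated) cat("  (saturated model: indices are exact constants)\n")
  cat(sprintf("  fit %s (thresholds: chi2/df < %g, CFI >= %g, TLI >= %g, RMSEA <= %g, SRMR <= %g)\n",
              if (x$adequate) "adequate" else "NOT adequate",
              x$thresholds$chi2_df, x$thresholds$cfi, x$thresholds$tli,
              x$thresholds$rmsea, x$thresholds$srmr))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.fit_indices <- function(x, ...) {
  dplyr::mutate(x$indices, adequate = x$adequate, saturated = x$saturated)
}

#' @exportS3Method generics::tidy
tidy.fit_indices <- function(x, ...) glance.fit_indices(x)

#' Tabulate fit indices for several models
#'
#' Builds a model-comparison block (one row per model, columns df,
#' chi-square, chi-square/df, SRMR, RMSEA, TLI, CFI).
#'
#' @param fits Named list of [fit_apim] results on the same moments.
#' @param thresholds A [fit_thresholds] list.
#' @return Tibble with one row per model.
#' @export
fit_table <- function(fits, thresholds = fit_thresholds()) {
  purrr::imap_dfr(fits, function(f, nm) {
    g <- glance(compute_fit_indices(f, thresholds = thresholds))
    dplyr::mutate(g, model = nm, .before = 1)
  })
}
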