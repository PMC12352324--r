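#' Wilcoxon signed-rank test for paired samples
#'
#' Tie-corrected normal-approximation signed-rank test on within-pair
#' differences `x - y`. Zero differences are dropped before ranking (the
#' classical Wilcoxon convention); tied absolute differences receive
#' mid-ranks and the variance is tie-corrected. Z is signed so that a
#' positive value means `x` tends to exceed `y`.
#'
#' @param x,y Equal-length numeric vectors, paired by position (dyad).
#' @return One-row tibble: `statistic` (signed-rank sum W+), `z`, `p_value`,
#'   `n_used` (pairs after dropping zero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length (paired by dyad)")
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort("all within-pair differences are zero (or missing): the signed-rank test is undefined")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / 48
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_corr
  if (sigma2 <= 0) abort("zero variance after tie correction: all absolute differences are tied at one value")
  z <- (w_pos - mu) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(statistic = w_pos, z = z, p_value = p, n_used = n,
                 method = "Wilcoxon signed rank (normal approximation, ties corrected)")
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Uncorrected (no Yates continuity correction) by default, df = 1.
#'
#' @param counts 2x2 matrix of non-negative counts (rows = category,
#'   columns = group/role), or a length-4 vector filled column-wise.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
chi2_2x2 <- function(counts, correct = FALSE) {
  m <- as_2x2(counts)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("a row or column margin is zero: the chi-square test is undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  tibble::tibble(statistic = unname(ht$statistic), df = 1L,
                 p_value = unname(ht$p.value),
                 method = if (correct) "Pearson chi-square (Yates-corrected)" else "Pearson chi-square (uncorrected)")
}

#' McNemar test on a paired 2x2 table
#'
#' Companion to [chi2_2x2] for genuinely paired binary classifications
#' (rows/columns = the two partners' statuses on the same dyads). Not used
#' on the default descriptive path, which mirrors the common unpaired
#' chi-square presentation of role differences.
#'
#' @param counts 2x2 cross-classification of the two partners' statuses.
#' @param correct Continuity correction (default `TRUE`, the usual McNemar form).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
mcnemar_2x2 <- function(counts, correct = TRUE) {
  m <- as_2x2(counts)
  ht <- stats::mcnemar.test(m, correct = correct)
  tibble::tibble(statistic = unname(ht$statistic), df = 1L,
                 p_value = unname(ht$p.value), method = "McNemar")
}

as_2x2 <- function(counts) {
  m <- if (is.matrix(counts)) counts else matrix(as.numeric(counts), 2, 2)
  if (!all(dim(m) == c(2L, 2L))) abort("counts must form a 2x2 table")
  if (any(m < 0) || anyNA(m)) abort("counts must be non-negative and complete")
  m
}

#' Pairwise Pearson correlation matrix with significance
#'
#' @param data Data frame of numeric variables (rows = dyads).
#' @param vars Character vector of columns to correlate; defaults to all
#'   numeric columns.
#' @return A `correlation_summary`: list with `r` (correlation matrix),
#'   `p` (two-sided t-test p-values), `n`, `vars`. `tidy()` gives the
#'   long-format lower triangle.
#' @export
correlation_matrix <- function(data, vars = NULL) {
  data <- as.data.frame(data)
  if (is.null(vars)) vars <- names(data)[vapply(data, is.numeric, logical(1))]
  x <- data[vars]
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3L) abort("need at least 3 complete dyads for a correlation matrix")
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0)) {
    abort(sprintf("constant variable(s): %s", paste(vars[sds == 0], collapse = ", ")))
  }
  r <- stats::cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  out <- list(r = r, p = p, n = n, vars = vars)
  class(out) <- "correlation_summary"
  out
}

#' @export
print.correlation_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlations (N = %d)\n", x$n))
  print(round(x$r, digits))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.correlation_summary <- function(x, ...) {
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = x$vars[idx[, 2]], var2 = x$vars[idx[, 1]],
    r = x$r[idx], p_value = x$p[idx], n = x$n
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.correlation_summary <- function(object, ...) {
  df <- tidyr::expand_grid(var1 = object$vars, var2 = object$vars)
  df$r <- as.vector(t(object$r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Pooled stress-by-gender interaction model
#'
#' Least-squares fit of `depression ~ stress * gender` on the stacked
#' individual-level table (two rows per dyad, one per partner), with
#' cluster-robust (CR0 sandwich) standard errors clustered on dyad to
#' respect within-couple dependence. The interaction row tests whether the
#' stress-depression slope differs by gender.
#'
#' @param data Long-format data frame with one row per individual.
#' @param outcome,stress,gender,cluster Column names (strings) for the
#'   depression outcome, stress predictor, gender code, and dyad identifier.
#' @return Tibble of coefficients: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, with the interaction as the last row.
#' @export
stress_gender_interaction <- function(data, outcome = "depression",
                                      stress = "stress", gender = "gender",
                                      cluster = "dyad_id") {
  data <- as.data.frame(data)
  for (col in c(outcome, stress, gender, cluster)) {
    if (!col %in% names(data)) abort(sprintf("column '%s' not found", col))
  }
  f <- stats::reformulate(sprintf("%s * %s", stress, gender), response = outcome)
  fit <- lm(f, data = data)
  if (any(is.na(coef(fit)))) abort("singular design: interaction model is not estimable")
  vc <- sandwich::vcovCL(fit, cluster = data[[cluster]])
  ct <- lmtest::coeftest(fit, vcov. = vc)
  tibble::tibble(
    term = rownames(ct), estimate = ct[, 1], std_error = ct[, 2],
    statistic = ct[, 3], p_value = ct[, 4]
  )
}

#' Role-comparison descriptive table for a wide dyad table
#'
#' Builds the descriptive layer for a wide couple table: per-role medians
#' and interquartile ranges with a paired signed-rank test for the stress
#' and depression totals, and the depressed/not-depressed 2x2 chi-square
#' at the EPDS cutoff.
#'
#' @param data Wide dyad table with columns `woman_stress`, `woman_depression`,
#'   `husband_stress`, `husband_depression` (and optionally `dyad_id`).
#' @param cutoff EPDS depression cutoff (default 10).
#' @return Tibble, one row per comparison: `variable`, per-role summaries,
#'   `statistic`, `p_value`, `method`.
#' @export
describe_dyads <- function(data, cutoff = 10L) {
  data <- tibble::as_tibble(data)
  need <- c("woman_stress", "woman_depression", "husband_stress", "husband_depression")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  med_iqr <- function(v) sprintf("%.0f (%.0f, %.0f)", median(v), quantile(v, .25), quantile(v, .75))
  rows <- purrr::map(c(stress = "stress", depression = "depression"), function(what) {
    w <- data[[paste0("woman_", what)]]
    h <- data[[paste0("husband_", what)]]
    tst <- wilcoxon_signed_rank(w, h)
    tibble::tibble(variable = paste("prenatal", what), woman = med_iqr(w),
                   husband = med_iqr(h), statistic = tst$z,
                   p_value = tst$p_value, method = "Wilcoxon signed rank (Z)")
  })
  dep_tab <- rbind(
    c(sum(data$woman_depression >= cutoff), sum(data$husband_depression >= cutoff)),
    c(sum(data$woman_depression < cutoff), sum(data$husband_depression < cutoff))
  )
  chi <- tryCatch(chi2_2x2(dep_tab), error = function(e) {
    tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                   method = "Pearson chi-square (not computable: zero margin)")
  })
  pct <- function(k) sprintf("%d (%.1f%%)", k, 100 * k / nrow(data))
  rows$depressed <- tibble::tibble(
    variable = sprintf("depressed (EPDS >= %d)", cutoff),
    woman = pct(dep_tab[1, 1]), husband = pct(dep_tab[1, 2]),
    statistic = chi$statistic, p_value = chi$p_value,
    method = chi$method
  )
  dplyr::bind_rows(rows)
}
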