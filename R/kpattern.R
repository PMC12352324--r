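# fast closed-form saturated solution used inside bootstrap loops:
# returns paths, standardized actor effects, and the two ratio conventions
sat_paths <- function(S) {
  v1 <- S[1, 1]; v2 <- S[2, 2]; cx <- S[1, 2]
  det <- v1 * v2 - cx * cx
  b11 <- (v2 * S[1, 3] - cx * S[2, 3]) / det   # a1:  x1 -> y1
  b21 <- (v1 * S[2, 3] - cx * S[1, 3]) / det   # p12: x2 -> y1
  b12 <- (v2 * S[1, 4] - cx * S[2, 4]) / det   # p21: x1 -> y2
  b22 <- (v1 * S[2, 4] - cx * S[1, 4]) / det   # a2:  x2 -> y2
  sdx1 <- sqrt(v1); sdx2 <- sqrt(v2)
  sdy1 <- sqrt(S[3, 3]); sdy2 <- sqrt(S[4, 4])
  c(a1 = b11, a2 = b22, p12 = b21, p21 = b12,
    a1_std = b11 * sdx1 / sdy1, a2_std = b22 * sdx2 / sdy2)
}

ratio_pair <- function(paths, convention) {
  if (convention == "incoming") {
    c(k1 = unname(paths[["p12"]] / paths[["a1"]]),
      k2 = unname(paths[["p21"]] / paths[["a2"]]))
  } else {
    c(k1 = unname(paths[["p21"]] / paths[["a1"]]),
      k2 = unname(paths[["p12"]] / paths[["a2"]]))
  }
}

#' Estimate the partner/actor ratio k with bootstrap confidence intervals
#'
#' The ratio k = p/a (partner effect over actor effect) indexes the dyadic
#' pattern: 0 marks actor-only, 1 couple-oriented, -1 contrast. For
#' distinguishable dyads two ratios are estimated (k1 for partner 1, k2 for
#' partner 2) via the ratio-tied (phantom-variable) reparameterization of
#' the unrestricted APIM, which reproduces the saturated fit exactly; for
#' indistinguishable dyads a single common k is estimated under the
#' equal-effects model. Confidence intervals are 95% percentile bootstrap:
#' dyads are resampled with replacement when raw data are supplied, and a
#' parametric bootstrap from the multivariate normal implied by the moments
#' is used when only summary moments are available (an approximation, since
#' no raw rows exist to resample). Ratios are formed on the fitted
#' (unstandardized) scale; with correlation input the two coincide.
#'
#' Following the small-actor-effect guard, k is refused whenever a required
#' standardized actor effect is below 0.10 in absolute value, and bootstrap
#' replicates violating the guard (or failing to converge) are dropped and
#' counted; more than 5% dropped raises a warning.
#'
#' @param x A [moment_summary] or wide dyad table.
#' @param distinguishable Estimate two ratios (`TRUE`, default) or a single
#'   common ratio under the equal-effects model (`FALSE`). Usually taken
#'   from [test_distinguishability].
#' @param B Bootstrap replicates (default 5000); `B = 0` skips the CI.
#' @param seed Integer seed, required whenever `B > 0`.
#' @param convention Ratio pairing. `"incoming"` (default): k_i divides the
#'   partner path arriving at partner i's outcome by partner i's actor
#'   effect (k1 = p12/a1, k2 = p21/a2). `"outgoing"`: k_i uses the partner
#'   path emanating from partner i's predictor (k1 = p21/a1, k2 = p12/a2).
#' @param guard Standardized actor-effect magnitude below which k is not
#'   computed (default 0.10).
#' @param conf Confidence level (default 0.95).
#' @param scaling Chi-square scaling, see [fit_apim].
#' @return A `k_estimate` tibble (one row per ratio): `which`, `k`,
#'   `ci_low`, `ci_high`, `actor_std`, `actor_guard_ok`, `B`, `B_used`,
#'   `seed`, `convention`. The bootstrap replicate paths are attached as
#'   `attr(, "replicates")` and the saturated fit as `attr(, "fit")`.
#' @export
estimate_k <- function(x, distinguishable = TRUE, B = 5000, seed = NULL,
                       convention = c("incoming", "outgoing"), guard = 0.10,
                       conf = 0.95, scaling = c("N-1", "N")) {
  convention <- match.arg(convention)
  scaling <- match.arg(scaling)
  if (B > 0 && (is.null(seed) || is.na(seed))) {
    abort("a seed is required for the bootstrap (pass seed=, or B = 0 for point estimates only)")
  }
  X <- NULL
  if (is.data.frame(x)) {
    X <- dyad_matrix(x)
    moments <- moment_summary(cov(X), nrow(X))
  } else {
    stopifnot(inherits(x, "moment_summary"))
    moments <- x
  }
  if (!is.null(X) && B > 0 && B < 1000) {
    warn("fewer than 1000 bootstrap replicates gives unstable percentile bounds")
  }
  n <- moments$n
  fit <- fit_apim(moments, apim_spec(ratio_k = "two"), scaling = scaling)
  paths <- sat_paths(moments$S)

  if (distinguishable) {
    a_std <- c(k1 = unname(paths[["a1_std"]]), k2 = unname(paths[["a2_std"]]))
    guard_ok <- abs(a_std) >= guard
    if (!all(guard_ok)) {
      abort(sprintf(
        "standardized actor effect(s) %s below the %.2f guard (%s): the ratio k is not computed for small actor effects",
        paste(names(a_std)[!guard_ok], collapse = ", "), guard,
        paste(sprintf("%.3f", a_std[!guard_ok]), collapse = ", ")))
    }
    k_hat <- ratio_pair(paths, convention)
  } else {
    cfit <- fit_apim(moments, apim_spec(equal = list(c("a1", "a2")), ratio_k = "common"),
                     scaling = scaling)
    a_common <- cfit$estimates$std_estimate[cfit$estimates$term == "a1"]
    guard_ok <- abs(a_common) >= guard
    if (!guard_ok) {
      abort(sprintf("common standardized actor effect %.3f is below the %.2f guard", a_common, guard))
    }
    a_std <- c(common = a_common)
    k_hat <- c(common = cfit$estimates$estimate[cfit$estimates$term == "k"])
    fit <- cfit
  }

  reps <- NULL
  ci <- matrix(NA_real_, length(k_hat), 2,
               dimnames = list(names(k_hat), c("lo", "hi")))
  n_dropped <- 0L
  B_used <- 0L
  if (B > 0) {
    set.seed(seed)
    reps <- bootstrap_k(X, moments, B, distinguishable, convention, guard, scaling)
    kcols <- if (distinguishable) c("k1", "k2") else "k"
    keep <- stats::complete.cases(reps[, kcols, drop = FALSE])
    n_dropped <- sum(!keep)
    B_used <- sum(keep)
    if (n_dropped > 0.05 * B) {
      warn(sprintf("%d of %d bootstrap replicates dropped (guard or convergence failures)",
                   n_dropped, B))
    }
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    for (i in seq_along(k_hat)) {
      ci[i, ] <- quantile(reps[keep, kcols[i]], probs, names = FALSE)
    }
  }

  seed_val <- if (B > 0) as.integer(seed) else NA_integer_
  out <- tibble::tibble(
    which = names(k_hat), k = unname(k_hat),
    ci_low = ci[, 1], ci_high = ci[, 2],
    actor_std = unname(a_std), actor_guard_ok = TRUE,
    B = .env$B, B_used = .env$B_used, seed = seed_val,
    convention = .env$convention
  )
  class(out) <- c("k_estimate", class(out))
  attr(out, "replicates") <- reps
  attr(out, "fit") <- fit
  attr(out, "moments") <- moments
  attr(out, "data") <- X
  attr(out, "scaling") <- scaling
  attr(out, "guard") <- guard
  attr(out, "conf") <- conf
  attr(out, "n_dropped") <- n_dropped
  out
}

# lean common-ratio replicate fit via the concentrated discrepancy:
# minimize log det Psi_hat over (a1, a2, k), or over (a, k) when the actor
# effects are equated (indistinguishable dyads). Returns the parameter
# vector with k last, or NULL on failure.
common_k_rep <- function(Sb, start, equal_actors = FALSE) {
  Sxx <- Sb[1:2, 1:2]
  Sxy <- Sb[1:2, 3:4]
  Syy <- Sb[3:4, 3:4]
  Syx <- t(Sxy)
  obj <- function(par) {
    k <- par[length(par)]
    a1 <- par[1]
    a2 <- if (equal_actors) par[1] else par[2]
    B <- matrix(c(a1, k * a1, k * a2, a2), 2, 2, byrow = TRUE)
    Psi <- Syy - Syx %*% t(B) - B %*% Sxy + B %*% Sxx %*% t(B)
    d <- Psi[1, 1] * Psi[2, 2] - Psi[1, 2]^2
    if (Psi[1, 1] <= 0 || Psi[2, 2] <= 0 || d <= 0) return(1e4)
    log(d)
  }
  op <- tryCatch(optim(start, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12)),
                 error = function(e) NULL)
  if (is.null(op) || !is.finite(op$value) || op$value >= 1e3) return(NULL)
  op$par
}

# common ratio (k1 = k2 = k, actor effects free) with bootstrap CI;
# used when the flowchart collapses two equal ratios to a single k
estimate_common_ratio <- function(X, moments, B, seed, guard, conf, scaling) {
  fitc <- fit_apim(moments, apim_spec(ratio_k = "common"), scaling = scaling)
  est <- fitc$estimates
  k_hat <- est$estimate[est$term == "k"]
  a_std <- sat_paths(moments$S)[c("a1_std", "a2_std")]
  n <- moments$n
  ci <- c(NA_real_, NA_real_)
  B_used <- 0L
  if (B > 0) {
    set.seed(seed)
    parametric <- is.null(X)
    if (parametric) R_chol <- chol(moments$S)
    k_reps <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      Xb <- if (parametric) {
        matrix(stats::rnorm(n * 4), n, 4) %*% R_chol
      } else {
        X[sample.int(n, n, replace = TRUE), , drop = FALSE]
      }
      Sb <- cov(Xb)
      sp <- sat_paths(Sb)
      if (abs(sp[["a1_std"]]) < guard || abs(sp[["a2_std"]]) < guard) next
      par <- common_k_rep(Sb, c(sp[["a1"]], sp[["a2"]],
                                mean(ratio_pair(sp, "incoming"))))
      if (!is.null(par)) k_reps[b] <- par[3]
    }
    keep <- is.finite(k_reps)
    B_used <- sum(keep)
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    ci <- quantile(k_reps[keep], probs, names = FALSE)
  }
  tibble::tibble(which = "common", k = k_hat, ci_low = ci[1], ci_high = ci[2],
                 actor_std = mean(abs(a_std)), actor_guard_ok = TRUE,
                 B = .env$B, B_used = .env$B_used,
                 seed = as.integer(seed), convention = "incoming")
}

# bootstrap replicate matrix of paths and ratios; NA rows = dropped
bootstrap_k <- function(X, moments, B, distinguishable, convention, guard, scaling) {
  n <- moments$n
  parametric <- is.null(X)
  if (parametric) R_chol <- chol(moments$S)
  cols <- if (distinguishable) c("a1", "a2", "p12", "p21", "k1", "k2") else c("a", "p", "k")
  out <- matrix(NA_real_, B, length(cols), dimnames = list(NULL, cols))
  for (b in seq_len(B)) {
    Xb <- if (parametric) {
      matrix(stats::rnorm(n * 4), n, 4) %*% R_chol
    } else {
      X[sample.int(n, n, replace = TRUE), , drop = FALSE]
    }
    Sb <- cov(Xb)
    if (distinguishable) {
      pb <- sat_paths(Sb)
      if (abs(pb[["a1_std"]]) < guard || abs(pb[["a2_std"]]) < guard) next
      out[b, 1:4] <- pb[c("a1", "a2", "p12", "p21")]
      out[b, 5:6] <- ratio_pair(pb, convention)
    } else {
      pb <- sat_paths(Sb)
      if (mean(abs(pb[c("a1_std", "a2_std")])) < guard) next
      par <- common_k_rep(Sb, c(mean(pb[c("a1", "a2")]),
                                mean(ratio_pair(pb, "incoming"))),
                          equal_actors = TRUE)
      if (is.null(par)) next
      out[b, ] <- c(par[1], par[2] * par[1], par[2])
    }
  }
  out
}

#' @export
print.k_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("Partner/actor ratio k (%s convention, %d/%d bootstrap replicates)\n",
              x$convention[1], x$B_used[1], x$B[1]))
  df <- as.data.frame(x[, c("which", "k", "ci_low", "ci_high", "actor_std")])
  print(cbind(df[1], round(df[-1], digits)), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.k_estimate <- function(object, ...) {
  reps <- attr(object, "replicates")
  if (is.null(reps)) abort("no bootstrap replicates stored (B = 0)")
  kcols <- intersect(c("k1", "k2", "k"), colnames(reps))
  df <- tidyr::pivot_longer(tibble::as_tibble(reps[, kcols, drop = FALSE]),
                            dplyr::all_of(kcols), names_to = "which", values_to = "k")
  df <- dplyr::filter(df, is.finite(.data$k))
  ci <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey60") +
    ggplot2::geom_vline(data = ci, ggplot2::aes(xintercept = .data$k), linewidth = 0.8) +
    ggplot2::geom_vline(data = ci, ggplot2::aes(xintercept = .data$ci_low), linetype = 2) +
    ggplot2::geom_vline(data = ci, ggplot2::aes(xintercept = .data$ci_high), linetype = 2) +
    ggplot2::facet_wrap(~which, scales = "free") +
    ggplot2::labs(x = "bootstrap k", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Test equality of the two partner/actor ratios
#'
#' Likelihood-ratio test of the model constraining k1 = k2 (single common
#' ratio, actor effects still free) against the two-free-ratio model
#' (which is saturated). A non-significant difference supports describing
#' the dyad with a single k.
#'
#' @param x A [moment_summary] or wide dyad table.
#' @param scaling Chi-square scaling, see [fit_apim].
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
test_k_equality <- function(x, scaling = c("N-1", "N")) {
  scaling <- match.arg(scaling)
  if (is.data.frame(x)) x <- dyad_moments(x)
  full <- fit_apim(x, apim_spec(ratio_k = "two"), scaling = scaling)
  restricted <- fit_apim(x, apim_spec(ratio_k = "common"), scaling = scaling)
  out <- lr_test(restricted, full)
  out$method <- "LR test of k1 = k2 (common-ratio vs two-ratio model)"
  out
}

#' Classify the dyadic pattern from k confidence intervals
#'
#' Implements the sequential pattern flowchart. For distinguishable dyads
#' with two estimated ratios, equality of k1 and k2 is tested first
#' (LR test); when the difference is non-significant (p >=
#' `equality_alpha`) the ratios are collapsed to a single common k (actor
#' effects still free) whose bootstrap CI drives the decision, mirroring
#' the four-step procedure. Each critical value of k (0 = actor-only,
#' 1 = couple-oriented, -1 = contrast) is a candidate only if every active
#' confidence interval covers it; the model is then re-estimated with the
#' ratios fixed at that value and the pattern is accepted only when the
#' constrained fit meets all adequacy thresholds. A CI set covering both 0
#' and a unit value is ambiguous and both candidate refits are reported; a
#' CI set covering none of the critical values yields `none`. Every branch
#' taken is recorded in the decision trace. The partner-only pattern is
#' excluded from the flowchart (it is empirically rare); setting
#' `allow_partner_only = TRUE` additionally reports an
#' actor-paths-fixed-to-zero candidate refit for expert review.
#'
#' @param k_est A [estimate_k] result (with CIs, i.e. `B > 0`).
#' @param thresholds A [fit_thresholds] list defining adequate fit.
#' @param collapse_equal Collapse two non-significantly different ratios to
#'   a common k before applying the CI rules (default `TRUE`).
#' @param equality_alpha Significance level of the k1 = k2 test
#'   (default 0.05).
#' @param allow_partner_only Expert flag, see above (default `FALSE`).
#' @return A `pattern_decision`: `pattern` (one of `actor_only`, `couple`,
#'   `contrast`, `none`, `ambiguous`), the constrained refit indices,
#'   `k_equality_p` when tested, and the decision trace.
#' @export
classify_pattern <- function(k_est, thresholds = fit_thresholds(),
                             collapse_equal = TRUE, equality_alpha = 0.05,
                             allow_partner_only = FALSE) {
  stopifnot(inherits(k_est, "k_estimate"))
  if (anyNA(k_est$ci_low)) abort("k estimates carry no confidence intervals (bootstrap with B > 0 first)")
  moments <- attr(k_est, "moments")
  scaling <- attr(k_est, "scaling")
  common <- identical(k_est$which, "common")
  refit_k <- function(v) {
    f <- if (common) {
      fit_apim(moments, apim_spec(equal = list(c("a1", "a2")), ratio_k = "common", k = v),
               scaling = scaling)
    } else {
      fit_apim(moments, apim_spec(ratio_k = "two", k1 = v, k2 = v), scaling = scaling)
    }
    compute_fit_indices(f, thresholds = thresholds)
  }
  trace <- list()
  note <- function(q, a) trace[[length(trace) + 1L]] <<- tibble::tibble(question = q, answer = a)
  active <- k_est
  k_equality_p <- NA_real_
  if (!common && collapse_equal && nrow(k_est) == 2L) {
    keq <- test_k_equality(moments, scaling = scaling)
    k_equality_p <- keq$p_value
    collapse <- k_equality_p >= equality_alpha
    note(sprintf("k1 = k2 not rejected (LR p = %.3f >= %.2f): use a single common k",
                 k_equality_p, equality_alpha), collapse)
    if (collapse) {
      active <- estimate_common_ratio(attr(k_est, "data"), moments,
                                      B = k_est$B[1],
                                      seed = k_est$seed[1] + 1L,
                                      guard = attr(k_est, "guard") %||% 0.10,
                                      conf = attr(k_est, "conf") %||% 0.95,
                                      scaling = scaling)
    }
  }
  covers <- function(v) active$ci_low <= v & active$ci_high >= v
  all0 <- all(covers(0))
  all1 <- all(covers(1))
  allm1 <- all(covers(-1))
  note("every k CI includes 0", all0)
  note("every k CI includes +1", all1)
  note("every k CI includes -1", allm1)
  refits <- list()
  pattern <- NULL
  if (all0 && !all1 && !allm1) {
    note("candidate: fix k = 0 and re-estimate", TRUE)
    refits$k0 <- refit_k(0)
    note("k = 0 refit meets all fit thresholds", refits$k0$adequate)
    pattern <- if (refits$k0$adequate) "actor_only" else "none"
  } else if (all1 && !all0 && !allm1) {
    note("candidate: fix k = 1 and re-estimate", TRUE)
    refits$k1 <- refit_k(1)
    note("k = 1 refit meets all fit thresholds", refits$k1$adequate)
    pattern <- if (refits$k1$adequate) "couple" else "none"
  } else if (allm1 && !all0 && !all1) {
    note("candidate: fix k = -1 and re-estimate", TRUE)
    refits$km1 <- refit_k(-1)
    note("k = -1 refit meets all fit thresholds", refits$km1$adequate)
    pattern <- if (refits$km1$adequate) "contrast" else "none"
  } else if (all0 && (all1 || allm1)) {
    note("CIs cover 0 and a unit value: ambiguous, reporting both candidate refits", TRUE)
    refits$k0 <- refit_k(0)
    if (all1) refits$k1 <- refit_k(1)
    if (allm1) refits$km1 <- refit_k(-1)
    pattern <- "ambiguous"
  } else if (!all0 && !all1 && !allm1 && any(covers(0) | covers(1) | covers(-1))) {
    note("the ratios' CIs disagree on the critical values: ambiguous", TRUE)
    pattern <- "ambiguous"
  } else {
    note("no critical value (0, +1, -1) is covered by every k CI", TRUE)
    pattern <- "none"
  }
  if (allow_partner_only) {
    f <- fit_apim(moments, apim_spec(a1 = 0, a2 = 0), scaling = scaling)
    refits$partner_only_candidate <- compute_fit_indices(f, thresholds = thresholds)
    note("expert flag: actor-paths-fixed-to-zero candidate reported", TRUE)
  }
  structure(list(pattern = pattern, k = tibble::as_tibble(k_est),
                 k_active = tibble::as_tibble(active),
                 k_equality_p = k_equality_p,
                 refits = refits, trace = dplyr::bind_rows(trace),
                 thresholds = thresholds),
            class = "pattern_decision")
}

#' @export
print.pattern_decision <- function(x, ...) {
  cat(sprintf("Dyadic pattern: %s\n", x$pattern))
  k <- x$k
  for (i in seq_len(nrow(k))) {
    cat(sprintf("  %s = %.3f, 95%% CI (%.3f, %.3f)\n",
                k$which[i], k$k[i], k$ci_low[i], k$ci_high[i]))
  }
  if (!identical(x$k_active$which, x$k$which)) {
    a <- x$k_active
    cat(sprintf("  collapsed: common k = %.3f, 95%% CI (%.3f, %.3f) (k1 = k2 LR p = %.3f)\n",
                a$k, a$ci_low, a$ci_high, x$k_equality_p))
  }
  cat("decision trace:\n")
  tr <- x$trace
  for (i in seq_len(nrow(tr))) {
    cat(sprintf("  - %s: %s\n", tr$question[i], tr$answer[i]))
  }
  for (nm in names(x$refits)) {
    cat(sprintf("refit [%s]: ", nm))
    print(x$refits[[nm]])
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pattern_decision <- function(x, ...) {
  dplyr::mutate(x$k, pattern = x$pattern)
}
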