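# Moment-structure parameters of the four-variable APIM. Path system:
#   y1 = a1*x1 + p12*x2 + e1,   y2 = p21*x1 + a2*x2 + e2
# with cov(x1,x2) = cov_x and residual covariance cov_e. Ten parameters
# saturate the ten unique moments of (x1, x2, y1, y2).
apim_variance_params <- c("var_x1", "var_x2", "cov_x", "var_e1", "var_e2", "cov_e")
apim_path_params <- c("a1", "a2", "p12", "p21")

#' Specify an APIM parameterization
#'
#' Declares the status of every parameter of the four-variable APIM:
#' `"free"` or a number (fixed at that value). Cross-parameter equality
#' constraints are listed in `equal`. The ratio-tied (phantom-variable)
#' parameterization replaces the partner paths by `p12 = k1 * a1` and
#' `p21 = k2 * a2` (`ratio_k = "two"`), or by a single common ratio `k`
#' (`ratio_k = "common"`), making the partner/actor ratio a directly
#' estimated parameter without changing the fit of the unrestricted model.
#'
#' @param a1,a2 Actor paths (x1 to y1, x2 to y2).
#' @param p12,p21 Partner paths (x2 to y1, x1 to y2); must stay `"free"`
#'   when a ratio parameterization is used (they become derived).
#' @param var_x1,var_x2,cov_x Exogenous (co)variances.
#' @param var_e1,var_e2,cov_e Residual (co)variances.
#' @param equal List of character vectors of parameter names constrained
#'   equal, e.g. `list(c("a1", "a2"), c("p12", "p21"))`.
#' @param ratio_k `"none"` (direct paths), `"two"` (k1, k2), or `"common"`
#'   (single k).
#' @param k1,k2,k Ratio parameters, `"free"` or fixed numbers; used only in
#'   the matching `ratio_k` mode.
#' @return An `apim_spec` object.
#' @export
apim_spec <- function(a1 = "free", a2 = "free", p12 = "free", p21 = "free",
                      var_x1 = "free", var_x2 = "free", cov_x = "free",
                      var_e1 = "free", var_e2 = "free", cov_e = "free",
                      equal = NULL,
                      ratio_k = c("none", "two", "common"),
                      k1 = "free", k2 = "free", k = "free") {
  ratio_k <- match.arg(ratio_k)
  base <- list(a1 = a1, a2 = a2, p12 = p12, p21 = p21,
               var_x1 = var_x1, var_x2 = var_x2, cov_x = cov_x,
               var_e1 = var_e1, var_e2 = var_e2, cov_e = cov_e)
  if (ratio_k != "none") {
    if (!identical(p12, "free") || !identical(p21, "free")) {
      abort("with a ratio parameterization p12 and p21 are derived (k * a); leave them \"free\"")
    }
    base$p12 <- NULL
    base$p21 <- NULL
    base <- c(base, if (ratio_k == "two") list(k1 = k1, k2 = k2) else list(k = k))
  }
  for (nm in names(base)) {
    v <- base[[nm]]
    ok <- identical(v, "free") || (is.numeric(v) && length(v) == 1L && is.finite(v))
    if (!ok) abort(sprintf("parameter '%s' must be \"free\" or a finite number", nm))
  }
  equal <- equal %||% list()
  for (grp in equal) {
    if (length(grp) < 2L) abort("each equality group needs at least 2 parameters")
    unknown <- setdiff(grp, names(base))
    if (length(unknown)) {
      abort(sprintf("equality group names unknown in this parameterization: %s",
                    paste(unknown, collapse = ", ")))
    }
    if (!all(vapply(base[grp], identical, logical(1), "free"))) {
      abort("equality groups may only contain free parameters")
    }
  }
  if (length(unique(unlist(equal))) != length(unlist(equal))) {
    abort("a parameter appears in more than one equality group")
  }
  structure(list(params = base, equal = equal, ratio = ratio_k), class = "apim_spec")
}

#' @export
print.apim_spec <- function(x, ...) {
  st <- vapply(x$params, function(v) if (identical(v, "free")) "free" else sprintf("= %g", v),
               character(1))
  cat(sprintf("APIM specification (ratio mode: %s)\n", x$ratio))
  cat(paste(sprintf("  %-7s %s", names(st), st), collapse = "\n"), "\n")
  for (grp in x$equal) cat("  equal:", paste(grp, collapse = " = "), "\n")
  invisible(x)
}

# free-parameter bookkeeping: each free slot gets an index into phi;
# equality-group members share one index
spec_map <- function(spec) {
  nms <- names(spec$params)
  idx <- setNames(rep(NA_integer_, length(nms)), nms)
  fixed <- setNames(rep(NA_real_, length(nms)), nms)
  grp_of <- setNames(rep(NA_integer_, length(nms)), nms)
  for (g in seq_along(spec$equal)) grp_of[spec$equal[[g]]] <- g
  nxt <- 0L
  grp_idx <- integer(length(spec$equal))
  for (nm in nms) {
    v <- spec$params[[nm]]
    if (identical(v, "free")) {
      g <- grp_of[[nm]]
      if (!is.na(g)) {
        if (grp_idx[g] == 0L) { nxt <- nxt + 1L; grp_idx[g] <- nxt }
        idx[[nm]] <- grp_idx[g]
      } else {
        nxt <- nxt + 1L
        idx[[nm]] <- nxt
      }
    } else {
      fixed[[nm]] <- v
    }
  }
  list(idx = idx, fixed = fixed, n_free = nxt, names = nms)
}

# phi (free vector) -> full structural parameter vector theta
# (a1, a2, p12, p21, var_x1, var_x2, cov_x, var_e1, var_e2, cov_e)
phi_to_theta <- function(phi, map, ratio) {
  raw <- ifelse(is.na(map$idx), map$fixed, phi[pmax(map$idx, 1L)])
  names(raw) <- map$names
  th <- raw[c("a1", "a2")]
  if (ratio == "none") {
    th <- c(th, raw[c("p12", "p21")])
  } else if (ratio == "two") {
    th <- c(th, p12 = unname(raw[["k1"]] * raw[["a1"]]),
            p21 = unname(raw[["k2"]] * raw[["a2"]]))
  } else {
    th <- c(th, p12 = unname(raw[["k"]] * raw[["a1"]]),
            p21 = unname(raw[["k"]] * raw[["a2"]]))
  }
  c(th, raw[apim_variance_params])
}

# model-implied covariance of (x1, x2, y1, y2) under the path system
implied_sigma <- function(theta) {
  Sxx <- matrix(c(theta[["var_x1"]], theta[["cov_x"]],
                  theta[["cov_x"]], theta[["var_x2"]]), 2, 2)
  L <- matrix(c(theta[["a1"]], theta[["p12"]],
                theta[["p21"]], theta[["a2"]]), 2, 2, byrow = TRUE)
  Psi <- matrix(c(theta[["var_e1"]], theta[["cov_e"]],
                  theta[["cov_e"]], theta[["var_e2"]]), 2, 2)
  Sxy <- Sxx %*% t(L)
  Syy <- L %*% Sxx %*% t(L) + Psi
  Sig <- rbind(cbind(Sxx, Sxy), cbind(t(Sxy), Syy))
  dimnames(Sig) <- list(apim_vars, apim_vars)
  Sig
}

#' Model-implied moments of an APIM fit
#'
#' @param fit An [fit_apim] result.
#' @return The 4x4 model-implied covariance matrix over (x1, x2, y1, y2).
#' @export
implied_moments <- function(fit) {
  stopifnot(inherits(fit, "apim_fit"))
  fit$Sigma
}

# ML discrepancy F = log|Sigma| - log|S| + tr(S Sigma^-1) - 4
fml_discrepancy <- function(Sigma, S, logdet_S) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  2 * sum(log(diag(ch))) - logdet_S + sum(S * chol2inv(ch)) - 4
}

# exact ML solution of the unrestricted model: two two-predictor
# regressions on the sample moments plus the residual (co)variances
saturated_theta <- function(S) {
  Sxx <- S[1:2, 1:2]
  Sxy <- S[1:2, 3:4]
  B <- solve(Sxx, Sxy)                     # columns: (y1, y2) on rows (x1, x2)
  Psi <- S[3:4, 3:4] - t(Sxy) %*% B
  c(a1 = B[1, 1], a2 = B[2, 2], p12 = B[2, 1], p21 = B[1, 2],
    var_x1 = Sxx[1, 1], var_x2 = Sxx[2, 2], cov_x = Sxx[1, 2],
    var_e1 = Psi[1, 1], var_e2 = Psi[2, 2], cov_e = Psi[1, 2])
}

# standardized solution from theta and the implied covariance
standardize_theta <- function(theta, Sigma) {
  s <- sqrt(diag(Sigma))
  c(a1 = theta[["a1"]] * s[["x1"]] / s[["y1"]],
    a2 = theta[["a2"]] * s[["x2"]] / s[["y2"]],
    p12 = theta[["p12"]] * s[["x2"]] / s[["y1"]],
    p21 = theta[["p21"]] * s[["x1"]] / s[["y2"]],
    var_x1 = 1, var_x2 = 1,
    cov_x = theta[["cov_x"]] / (s[["x1"]] * s[["x2"]]),
    var_e1 = theta[["var_e1"]] / Sigma[["y1", "y1"]],
    var_e2 = theta[["var_e2"]] / Sigma[["y2", "y2"]],
    cov_e = theta[["cov_e"]] / (s[["y1"]] * s[["y2"]]))
}

#' Fit the four-variable APIM by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' \eqn{F = \log|\Sigma(\theta)| - \log|S| + tr(S\Sigma(\theta)^{-1}) - 4}
#' over the free parameters of `spec`, where `S` is the sample covariance
#' (or correlation) matrix. The unrestricted (saturated) model has the
#' closed-form solution of two two-predictor regressions and is not
#' iterated. `chi2 = (n-1) * F` by default (`scaling = "N-1"`); the
#' alternative `"N"` convention is available.
#'
#' @param moments A [moment_summary], or a wide dyad table (from which
#'   covariance moments are computed).
#' @param spec An [apim_spec]; default saturated.
#' @param scaling Chi-square scaling constant, `"N-1"` (default) or `"N"`.
#' @param standardized_input Treat `moments` as standardized even if it is a
#'   covariance matrix (rarely needed; correlation input is detected).
#' @return An `apim_fit` object: tidy `estimates` (unstandardized and
#'   standardized), `F_ml`, `chi2`, `df`, `converged`, implied moments, and
#'   provenance. Use [tidy()] / [glance()] to extract.
#' @export
fit_apim <- function(moments, spec = apim_spec(), scaling = c("N-1", "N"),
                     standardized_input = FALSE) {
  scaling <- match.arg(scaling)
  prov <- "moments"
  X <- NULL
  if (is.data.frame(moments)) {
    X <- dyad_matrix(moments)
    moments <- moment_summary(cov(X), nrow(X))
    prov <- "raw data"
  }
  stopifnot(inherits(moments, "moment_summary"))
  S <- moments$S
  n <- moments$n
  map <- spec_map(spec)
  if (n < map$n_free) abort("sample size smaller than the number of free parameters")
  logdet_S <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  th_sat <- saturated_theta(S)

  saturated_free <- map$n_free == 10L
  if (saturated_free && spec$ratio != "none" &&
      (abs(th_sat[["a1"]]) < 1e-12 || abs(th_sat[["a2"]]) < 1e-12)) {
    saturated_free <- FALSE  # ratio undefined at a = 0; fall through to optim
  }
  # concentration: when every (co)variance parameter is free and uncoupled,
  # the ML solution sets the exogenous block to the sample block and the
  # residual block to the empirical residual covariance of the fitted paths,
  # so the discrepancy reduces to log det Psi_hat(B) over path parameters only
  conc_ok <- !saturated_free &&
    all(vapply(spec$params[apim_variance_params], identical, logical(1), "free")) &&
    !any(apim_variance_params %in% unlist(spec$equal))
  if (saturated_free) {
    theta <- th_sat
    f <- 0
    converged <- TRUE
  } else if (conc_ok) {
    cf <- fit_concentrated(S, spec, map, th_sat, logdet_S)
    theta <- cf$theta
    f <- cf$F_ml
    converged <- cf$converged
    phi_hat <- cf$phi
  } else {
    phi0 <- start_values(spec, map, th_sat)
    obj <- function(phi) {
      theta <- phi_to_theta(phi, map, spec$ratio)
      if (theta[["var_x1"]] <= 0 || theta[["var_x2"]] <= 0 ||
          theta[["var_e1"]] <= 0 || theta[["var_e2"]] <= 0) {
        return(1e4 * (1 + sum(pmax(-theta[apim_variance_params[c(1, 2, 4, 5)]], 0))))
      }
      f <- fml_discrepancy(implied_sigma(theta), S, logdet_S)
      if (!is.finite(f)) 1e4 else f
    }
    op <- optim(phi0, obj, method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
    op2 <- optim(op$par, obj, method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
    theta <- phi_to_theta(op2$par, map, spec$ratio)
    f <- op2$value
    converged <- is.finite(f) && f < 1e3 && abs(op$value - op2$value) < 1e-8
    phi_hat <- op2$par
  }
  if (f < 0) f <- max(f, 0)  # clamp numerical noise; F_ML >= 0 analytically
  Sigma <- implied_sigma(theta)
  scale_n <- if (scaling == "N-1") n - 1 else n
  std <- standardize_theta(theta, Sigma)
  est <- tibble::tibble(
    term = names(theta),
    estimate = unname(theta),
    std_estimate = unname(std[names(theta)])
  )
  if (spec$ratio != "none") {
    rk <- if (spec$ratio == "two") c("k1", "k2") else "k"
    raw <- ifelse(is.na(map$idx), map$fixed,
                  (if (saturated_free) {
                    # ratio parameters implied by the closed form
                    sat_phi <- start_values(spec, map, th_sat)
                    sat_phi[pmax(map$idx, 1L)]
                  } else phi_hat[pmax(map$idx, 1L)]))
    names(raw) <- map$names
    est <- dplyr::bind_rows(est, tibble::tibble(
      term = rk, estimate = unname(raw[rk]), std_estimate = NA_real_))
  }
  structure(list(
    estimates = est, theta = theta, std_theta = std,
    F_ml = f, chi2 = scale_n * f, df = 10L - map$n_free, n_free = map$n_free,
    n = n, scaling = scaling, scale_n = scale_n, converged = converged,
    S = S, moment_type = moments$type, Sigma = Sigma, spec = spec,
    provenance = prov, data = X
  ), class = "apim_fit")
}

# start the optimizer at the saturated closed form (ratios at p/a)
start_values <- function(spec, map, th_sat) {
  ratio_start <- function(p, a) if (abs(a) < 1e-8) 0 else p / a
  full <- c(th_sat,
            k1 = ratio_start(th_sat[["p12"]], th_sat[["a1"]]),
            k2 = ratio_start(th_sat[["p21"]], th_sat[["a2"]]),
            k = ratio_start(mean(th_sat[c("p12", "p21")]), mean(th_sat[c("a1", "a2")])))
  phi <- numeric(map$n_free)
  for (nm in map$names) {
    i <- map$idx[[nm]]
    if (!is.na(i)) phi[i] <- full[[nm]]
  }
  # equality groups: average the members' saturated values
  for (grp in spec$equal) {
    i <- map$idx[[grp[1]]]
    phi[i] <- mean(vapply(grp, function(nm) full[[nm]], numeric(1)))
  }
  phi
}

# concentrated ML: optimize path/ratio parameters against
# log det Psi_hat(B), Psi_hat = Syy - Syx B' - B Sxy + B Sxx B'
# (exogenous block at the sample block, residual block at the empirical
# residual covariance; tr(S Sigma^-1) is then exactly 4)
fit_concentrated <- function(S, spec, map, th_sat, logdet_S) {
  Sxx <- S[1:2, 1:2]
  Sxy <- S[1:2, 3:4]
  Syy <- S[3:4, 3:4]
  Syx <- t(Sxy)
  logdet_Sxx <- log(Sxx[1, 1] * Sxx[2, 2] - Sxx[1, 2]^2)
  phi0 <- start_values(spec, map, th_sat)
  path_idx <- sort(unique(map$idx[setdiff(map$names, apim_variance_params)]))
  path_idx <- path_idx[!is.na(path_idx)]
  psi_of <- function(theta) {
    B <- matrix(c(theta[["a1"]], theta[["p12"]],
                  theta[["p21"]], theta[["a2"]]), 2, 2, byrow = TRUE)
    Syy - Syx %*% t(B) - B %*% Sxy + B %*% Sxx %*% t(B)
  }
  obj <- function(pp) {
    phi <- phi0
    phi[path_idx] <- pp
    Psi <- psi_of(phi_to_theta(phi, map, spec$ratio))
    d <- Psi[1, 1] * Psi[2, 2] - Psi[1, 2]^2
    if (Psi[1, 1] <= 0 || Psi[2, 2] <= 0 || d <= 0) return(1e4)
    log(d)
  }
  phi <- phi0
  if (length(path_idx) == 0L) {
    converged <- TRUE
  } else {
    op <- optim(phi0[path_idx], obj, method = "BFGS",
                control = list(maxit = 1000, reltol = 1e-14))
    op2 <- optim(op$par, obj, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    phi[path_idx] <- op2$par
    converged <- is.finite(op2$value) && op2$value < 1e3 &&
      abs(op$value - op2$value) < 1e-8
  }
  theta <- phi_to_theta(phi, map, spec$ratio)
  Psi <- psi_of(theta)
  theta[["var_x1"]] <- Sxx[1, 1]
  theta[["var_x2"]] <- Sxx[2, 2]
  theta[["cov_x"]] <- Sxx[1, 2]
  theta[["var_e1"]] <- Psi[1, 1]
  theta[["var_e2"]] <- Psi[2, 2]
  theta[["cov_e"]] <- Psi[1, 2]
  f <- logdet_Sxx + log(Psi[1, 1] * Psi[2, 2] - Psi[1, 2]^2) - logdet_S
  list(theta = theta, F_ml = f, converged = converged, phi = phi)
}

#' @export
print.apim_fit <- function(x, digits = 3, ...) {
  cat(sprintf("APIM fit (%s, %s input, N = %d)\n", x$provenance, x$moment_type, x$n))
  cat(sprintf("  F_ML = %.6f   chi2(%s) = %.3f   df = %d   converged: %s\n",
              x$F_ml, x$scaling, x$chi2, x$df, x$converged))
  df <- as.data.frame(x$estimates)
  df$estimate <- round(df$estimate, digits)
  df$std_estimate <- round(df$std_estimate, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.apim_fit <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.apim_fit <- function(x, ...) {
  tibble::tibble(F_ml = x$F_ml, chi2 = x$chi2, df = x$df, n = x$n,
                 n_free = x$n_free, converged = x$converged,
                 scaling = x$scaling, provenance = x$provenance)
}

#' @exportS3Method ggplot2::autoplot
autoplot.apim_fit <- function(object, standardized = TRUE, ...) {
  df <- dplyr::filter(object$estimates, .data$term %in% apim_path_params)
  df$value <- if (standardized) df$std_estimate else df$estimate
  df$kind <- ifelse(df$term %in% c("a1", "a2"), "actor", "partner")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$value, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = if (standardized) "standardized path" else "path",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Likelihood-ratio test of nested APIM fits
#'
#' @param restricted,full Two [fit_apim] results on the same moments, the
#'   restricted model nested in the full one.
#' @return One-row tibble: `statistic` (chi-square difference), `df`,
#'   `p_value`, `method`.
#' @export
lr_test <- function(restricted, full) {
  stopifnot(inherits(restricted, "apim_fit"), inherits(full, "apim_fit"))
  if (max(abs(restricted$S - full$S)) > 1e-10 * max(1, max(abs(full$S))) ||
      restricted$n != full$n) {
    abort("the two fits are not on the same moments")
  }
  if (restricted$df < full$df) abort("'restricted' must have at least as many df as 'full'")
  stat <- restricted$chi2 - full$chi2
  if (stat < -1e-6 * max(1, full$chi2)) {
    abort("restricted model fits better than the full model beyond tolerance: models are not nested (or a fit failed)")
  }
  stat <- max(stat, 0)
  df <- restricted$df - full$df
  p <- if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p_value = p,
                 method = "likelihood-ratio chi-square difference")
}

#' Test dyadic distinguishability
#'
#' Fits the unrestricted APIM and the model equating the two actor effects
#' and the two partner effects, and compares them by likelihood-ratio test.
#' Following the conventional liberal criterion, partners are treated as
#' indistinguishable when p >= `alpha` (default 0.2) and distinguishable
#' otherwise. The two single-pair tests (actor equality alone, partner
#' equality alone) are reported as well.
#'
#' @param moments A [moment_summary] or wide dyad table.
#' @param alpha Decision threshold on the LR p-value (default 0.2).
#' @param scaling Chi-square scaling, see [fit_apim].
#' @param include_variances Also equate exogenous and residual variances
#'   across partners (a stricter variant, off the default path).
#' @return A `distinguishability_test`: overall and single-pair LR rows and
#'   the `distinguishable` verdict.
#' @export
test_distinguishability <- function(moments, alpha = 0.2, scaling = c("N-1", "N"),
                                    include_variances = FALSE) {
  scaling <- match.arg(scaling)
  if (is.data.frame(moments)) moments <- dyad_moments(moments)
  full <- fit_apim(moments, apim_spec(), scaling = scaling)
  eq <- list(c("a1", "a2"), c("p12", "p21"))
  if (include_variances) eq <- c(eq, list(c("var_x1", "var_x2"), c("var_e1", "var_e2")))
  restricted <- fit_apim(moments, apim_spec(equal = eq), scaling = scaling)
  overall <- lr_test(restricted, full)
  actor <- lr_test(fit_apim(moments, apim_spec(equal = list(c("a1", "a2"))), scaling = scaling), full)
  partner <- lr_test(fit_apim(moments, apim_spec(equal = list(c("p12", "p21"))), scaling = scaling), full)
  structure(list(
    overall = overall, actor = actor, partner = partner,
    distinguishable = overall$p_value < alpha, alpha = alpha,
    fit_full = full, fit_restricted = restricted
  ), class = "distinguishability_test")
}

#' @export
print.distinguishability_test <- function(x, ...) {
  cat("Dyadic distinguishability (LR test of equal actor and partner effects)\n")
  cat(sprintf("  overall: chi2 = %.3f, df = %d, p = %.4f\n",
              x$overall$statistic, x$overall$df, x$overall$p_value))
  cat(sprintf("  actor equality:   chi2 = %.3f, p = %.4f\n", x$actor$statistic, x$actor$p_value))
  cat(sprintf("  partner equality: chi2 = %.3f, p = %.4f\n", x$partner$statistic, x$partner$p_value))
  cat(sprintf("  verdict: %s (p %s %.2f)\n",
              if (x$distinguishable) "distinguishable" else "indistinguishable",
              if (x$distinguishable) "<" else ">=", x$alpha))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.distinguishability_test <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$overall, test = "overall", .before = 1),
    dplyr::mutate(x$actor, test = "actor_equality", .before = 1),
    dplyr::mutate(x$partner, test = "partner_equality", .before = 1)
  )
}
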