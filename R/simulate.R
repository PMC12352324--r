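#' Parameters of the synthetic couple generator
#'
#' Defines the population from which synthetic dyads are drawn: a linear
#' path system on z-scaled predictors,
#' \deqn{y_1^* = a_1 z_1 + p_{12} z_2 + s_1 e_1, \qquad
#'       y_2^* = p_{21} z_1 + a_2 z_2 + s_2 e_2,}
#' where (z1, z2) are standard normal stress scores with correlation
#' `rho_x` and (e1, e2) standard normal residuals with correlation `rho_e`.
#' By default the residual scale factors are chosen so that the outcomes
#' have unit variance, making the paths standardized coefficients. Raw
#' variables are then `mu + sd * z-scale value`.
#'
#' @param a1,a2 Actor paths (standardized when the default residual scales
#'   are used).
#' @param p12,p21 Partner paths.
#' @param rho_x Stress cross-correlation between partners.
#' @param rho_e Residual correlation between the two outcomes.
#' @param sd_x1,sd_x2 Predictor scale factors (default 1).
#' @param sd_y_resid1,sd_y_resid2 Residual scale factors; `NULL` (default)
#'   solves for unit outcome variance.
#' @param mu Length-4 means of (x1, x2, y1, y2); default zeros.
#' @param n Number of dyads (default 282, the reference sample size).
#' @return A `sim_params` list.
#' @export
sim_params <- function(a1 = 0.5, a2 = 0.5, p12 = 0, p21 = 0,
                       rho_x = 0.212, rho_e = 0.16,
                       sd_x1 = 1, sd_x2 = 1,
                       sd_y_resid1 = NULL, sd_y_resid2 = NULL,
                       mu = c(0, 0, 0, 0), n = 282L) {
  if (abs(rho_x) >= 1 || abs(rho_e) >= 1) abort("rho_x and rho_e must lie in (-1, 1)")
  if (sd_x1 <= 0 || sd_x2 <= 0) abort("predictor scale factors must be positive")
  if (length(mu) != 4L) abort("mu must have length 4 (x1, x2, y1, y2)")
  if (n < 4) abort("n must be at least 4")
  resid_sd <- function(a, p, given) {
    if (!is.null(given)) {
      if (given <= 0) abort("residual scale factors must be positive")
      return(given)
    }
    v <- 1 - (a^2 + p^2 + 2 * a * p * rho_x)
    if (v <= 0) {
      abort(sprintf("paths imply explained variance >= 1 (a = %g, p = %g, rho_x = %g): supply sd_y_resid explicitly",
                    a, p, rho_x))
    }
    sqrt(v)
  }
  out <- list(a1 = a1, a2 = a2, p12 = p12, p21 = p21,
              rho_x = rho_x, rho_e = rho_e,
              sd_x1 = sd_x1, sd_x2 = sd_x2,
              sd_y_resid1 = resid_sd(a1, p12, sd_y_resid1),
              sd_y_resid2 = resid_sd(a2, p21, sd_y_resid2),
              mu = mu, n = as.integer(n))
  class(out) <- "sim_params"
  out
}

#' Population moments implied by generator parameters
#'
#' Closed-form covariance of (x1, x2, y1, y2) under the generator's linear
#' path system; e.g. on the z scale `cov(x2, y1) = p12 + a1 * rho_x`.
#'
#' @param params A [sim_params].
#' @return A [moment_summary] with the exact population moments
#'   (n is carried over from `params`).
#' @export
implied_population_moments <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  # z-scale covariance, then rescale predictors
  vy1 <- p$a1^2 + p$p12^2 + 2 * p$a1 * p$p12 * p$rho_x + p$sd_y_resid1^2
  vy2 <- p$a2^2 + p$p21^2 + 2 * p$a2 * p$p21 * p$rho_x + p$sd_y_resid2^2
  cx1y1 <- p$a1 + p$p12 * p$rho_x
  cx2y1 <- p$p12 + p$a1 * p$rho_x
  cx1y2 <- p$p21 + p$a2 * p$rho_x
  cx2y2 <- p$a2 + p$p21 * p$rho_x
  cy1y2 <- p$a1 * p$p21 + p$p12 * p$a2 + (p$a1 * p$a2 + p$p12 * p$p21) * p$rho_x +
    p$rho_e * p$sd_y_resid1 * p$sd_y_resid2
  Sz <- matrix(c(1, p$rho_x, cx1y1, cx1y2,
                 p$rho_x, 1, cx2y1, cx2y2,
                 cx1y1, cx2y1, vy1, cy1y2,
                 cx1y2, cx2y2, cy1y2, vy2), 4, 4)
  d <- diag(c(p$sd_x1, p$sd_x2, 1, 1))
  S <- d %*% Sz %*% d
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev)) {
    abort(sprintf("implied moment matrix is not positive definite (smallest eigenvalue %.3g)", min(ev)))
  }
  moment_summary(S, p$n)
}

#' Generate synthetic couples
#'
#' Draws `params$n` dyads from the generator's multivariate-normal path
#' system and returns a wide dyad table. An optional discretization step
#' rounds and clips the totals to the instruments' integer ranges (PSS-14
#' stress 0-56, EPDS depression 0-30) for robustness stress-testing; it is
#' off by default because the analysis treats totals as continuous.
#'
#' @param params A [sim_params].
#' @param seed Integer seed (required; the generator is deterministic given
#'   the seed).
#' @param discretize Round and clip to instrument ranges (default `FALSE`).
#' @return Tibble with columns `dyad_id`, `woman_stress`, `husband_stress`,
#'   `woman_depression`, `husband_depression`.
#' @export
generate_dyads <- function(params, seed, discretize = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  if (missing(seed) || is.null(seed) || is.na(seed)) abort("seed is required")
  set.seed(seed)
  p <- params
  n <- p$n
  Z <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, p$rho_x, p$rho_x, 1), 2, 2))
  E <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, p$rho_e, p$rho_e, 1), 2, 2))
  y1 <- p$a1 * Z[, 1] + p$p12 * Z[, 2] + p$sd_y_resid1 * E[, 1]
  y2 <- p$p21 * Z[, 1] + p$a2 * Z[, 2] + p$sd_y_resid2 * E[, 2]
  out <- tibble::tibble(
    dyad_id = seq_len(n),
    woman_stress = p$mu[1] + p$sd_x1 * Z[, 1],
    husband_stress = p$mu[2] + p$sd_x2 * Z[, 2],
    woman_depression = p$mu[3] + y1,
    husband_depression = p$mu[4] + y2
  )
  if (discretize) {
    clip <- function(v, hi) pmin(pmax(round(v), 0), hi)
    out$woman_stress <- clip(out$woman_stress, 56)
    out$husband_stress <- clip(out$husband_stress, 56)
    out$woman_depression <- clip(out$woman_depression, 30)
    out$husband_depression <- clip(out$husband_depression, 30)
  }
  out
}

#' Preset generator scenarios
#'
#' Named parameter presets used throughout the validation suite:
#' \describe{
#'   \item{`paper_like`}{paths obtained by fitting the saturated APIM to
#'     the packaged couple correlation matrix ([couple_moments]), so the
#'     implied population moments reproduce it exactly; n = 282.}
#'   \item{`actor_only`}{a1 = a2 = 0.5, partner paths 0 (k = 0).}
#'   \item{`couple`}{a = p = 0.4 for both partners (k = 1).}
#'   \item{`contrast`}{a = 0.4, p = -0.4 for both partners (k = -1).}
#' }
#' All presets share the reference stress cross-correlation (0.212),
#' residual correlation (0.16) and sample size (282).
#'
#' @param scenario Preset name.
#' @param n Number of dyads (default 282).
#' @return A [sim_params].
#' @export
sim_scenario <- function(scenario = c("paper_like", "actor_only", "couple", "contrast"),
                         n = 282L) {
  scenario <- match.arg(scenario)
  if (scenario == "paper_like") {
    m <- couple_moments()
    th <- saturated_theta(m$S)
    rho_e <- th[["cov_e"]] / sqrt(th[["var_e1"]] * th[["var_e2"]])
    return(sim_params(a1 = th[["a1"]], a2 = th[["a2"]],
                      p12 = th[["p12"]], p21 = th[["p21"]],
                      rho_x = th[["cov_x"]], rho_e = rho_e,
                      sd_y_resid1 = sqrt(th[["var_e1"]]),
                      sd_y_resid2 = sqrt(th[["var_e2"]]), n = n))
  }
  paths <- switch(scenario,
    actor_only = c(a = 0.5, p = 0),
    couple = c(a = 0.4, p = 0.4),
    contrast = c(a = 0.4, p = -0.4))
  sim_params(a1 = paths[["a"]], a2 = paths[["a"]],
             p12 = paths[["p"]], p21 = paths[["p"]], n = n)
}

# count compositions: ways[t+1, j] = number of item vectors of length j
# with entries 0..m summing to t
composition_counts <- function(n_items, max_item, total_max) {
  ways <- matrix(0, total_max + 1L, n_items + 1L)
  ways[1, 1] <- 1
  for (j in seq_len(n_items)) {
    for (t in 0:total_max) {
      lo <- max(0L, t - max_item)
      ways[t + 1L, j + 1L] <- sum(ways[(lo:t) + 1L, j])
    }
  }
  ways
}

#' Generate item responses consistent with given totals
#'
#' For each total, draws an item vector uniformly at random among all
#' vectors with entries in the instrument's item range whose scored sum
#' equals the total (exact dynamic-programming sampling, no rejection).
#' For the PSS-14, reverse-keyed items are then mapped back to raw
#' responses (`raw = 4 - scored`) so that [score_pss14] recovers the
#' totals; EPDS responses are already oriented.
#'
#' @param totals Integer vector of target totals, each within the
#'   instrument's range (PSS-14 0-56, EPDS 0-30).
#' @param instrument `"PSS14"` or `"EPDS"`.
#' @param seed Integer seed (required).
#' @param reverse_items Reverse-keyed positions (defaults to the
#'   instrument's standard keying for PSS-14, none for EPDS).
#' @return Tibble, one row per respondent: `respondent` plus the item
#'   columns (`pss_01..pss_14` or `epds_01..epds_10`).
#' @export
generate_item_responses <- function(totals, instrument = c("PSS14", "EPDS"), seed,
                                    reverse_items = NULL) {
  instrument <- match.arg(instrument)
  if (missing(seed) || is.null(seed) || is.na(seed)) abort("seed is required")
  info <- instrument_info(instrument)
  if (is.null(reverse_items)) {
    reverse_items <- if (instrument == "PSS14") pss14_reverse_items else integer(0)
  }
  if (any(totals != floor(totals)) || any(totals < 0) || any(totals > info$max_total)) {
    abort(sprintf("totals must be integers in 0..%d for %s", info$max_total, instrument))
  }
  set.seed(seed)
  ways <- composition_counts(info$n_items, info$max_item, info$max_total)
  draw_one <- function(total) {
    scored <- integer(info$n_items)
    t <- as.integer(total)
    for (j in info$n_items:1) {
      vals <- max(0L, t - (j - 1L) * info$max_item):min(info$max_item, t)
      w <- ways[t - vals + 1L, j]
      v <- vals[sample.int(length(vals), 1L, prob = w)]
      scored[info$n_items - j + 1L] <- v
      t <- t - v
    }
    scored
  }
  scored <- t(vapply(totals, draw_one, integer(info$n_items)))
  raw <- scored
  if (length(reverse_items)) raw[, reverse_items] <- info$max_item - raw[, reverse_items]
  colnames(raw) <- sprintf("%s_%02d", tolower(instrument_prefix(instrument)), seq_len(info$n_items))
  dplyr::bind_cols(tibble::tibble(respondent = seq_along(totals)), tibble::as_tibble(raw))
}

instrument_prefix <- function(instrument) if (instrument == "PSS14") "pss" else "epds"
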