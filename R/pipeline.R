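#' Run the full dyadic replication pipeline
#'
#' One-call path from input to pattern: scoring (items mode), descriptive
#' blocks, saturated APIM, distinguishability, ratio estimation with
#' bootstrap CIs, ratio-equality test, pattern classification, and the
#' model-fit and effect tables. Every random step is driven by `seed`, so
#' re-running with the same configuration reproduces the report exactly.
#'
#' @param input The data: a wide dyad table (`mode = "totals"`), an
#'   item-level respondent table with `dyad_id` and `role` columns
#'   (`mode = "items"`), a [moment_summary] (`mode = "moments"`), or a file
#'   path to the corresponding CSV.
#' @param mode Input mode; `"totals"`, `"items"`, or `"moments"`.
#' @param B Bootstrap replicates for the k confidence intervals
#'   (default 5000).
#' @param seed Integer seed (required, no default).
#' @param scaling Chi-square scaling convention, see [fit_apim].
#' @param convention Ratio pairing convention, see [estimate_k].
#' @param thresholds A [fit_thresholds] list.
#' @param alpha_distinguishable LR p-value threshold below which dyads are
#'   treated as distinguishable (default 0.2).
#' @param epds_cutoff Depression flag cutoff (default 10).
#' @param output_dir Optional directory; when given, every block is written
#'   as CSV and JSON (`table1`, `table2`, `table3`, `table4`,
#'   `pattern.json`).
#' @return A `dyadic_report` list: `descriptives`, `correlations`,
#'   `distinguishability`, `k`, `k_equality`, `pattern`, `fit_table`,
#'   `effects`, `config`.
#' @export
run_dyadic_analysis <- function(input, mode = c("totals", "items", "moments"),
                                B = 5000, seed, scaling = c("N-1", "N"),
                                convention = c("incoming", "outgoing"),
                                thresholds = fit_thresholds(),
                                alpha_distinguishable = 0.2,
                                epds_cutoff = 10L, output_dir = NULL) {
  mode <- match.arg(mode)
  scaling <- match.arg(scaling)
  convention <- match.arg(convention)
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("seed is required (every bootstrap draw must be reproducible)")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage:%s] %s", name, conditionMessage(e)))
    })
  }

  dyads <- NULL
  descriptives <- NULL
  correlations <- NULL
  if (mode == "items") {
    items <- stage("read", if (is.character(input)) tibble::as_tibble(read.csv(input)) else tibble::as_tibble(input))
    scored <- stage("score", score_items(items))
    if (!all(c("dyad_id", "role") %in% names(scored))) {
      abort("[stage:score] items input needs dyad_id and role columns")
    }
    dyads <- stage("score", items_to_wide(scored))
  } else if (mode == "totals") {
    dyads <- stage("read", if (is.character(input)) tibble::as_tibble(read.csv(input)) else tibble::as_tibble(input))
  }

  if (!is.null(dyads)) {
    descriptives <- stage("describe", describe_dyads(dyads, cutoff = epds_cutoff))
    correlations <- stage("describe", correlation_matrix(
      dyads, vars = c("woman_stress", "husband_stress", "woman_depression", "husband_depression")))
    moments <- stage("moments", dyad_moments(dyads))
    k_input <- dyads
  } else {
    moments <- stage("read", if (is.character(input)) read_moments_csv(input) else input)
    if (!inherits(moments, "moment_summary")) abort("[stage:read] moments input must be a moment_summary or CSV path")
    correlations <- moments
    k_input <- moments
  }

  saturated <- stage("apim", fit_apim(moments, apim_spec(), scaling = scaling))
  phantom <- stage("apim", fit_apim(moments, apim_spec(ratio_k = "two"), scaling = scaling))
  disting <- stage("distinguishability",
                   test_distinguishability(moments, alpha = alpha_distinguishable, scaling = scaling))
  k_est <- stage("k", estimate_k(k_input, distinguishable = disting$distinguishable,
                                 B = B, seed = seed, convention = convention,
                                 scaling = scaling))
  k_eq <- if (disting$distinguishable) stage("k", test_k_equality(moments, scaling = scaling)) else NULL
  pattern <- stage("pattern", classify_pattern(k_est, thresholds = thresholds))

  ft <- stage("fit_table", {
    tab <- fit_table(list(saturated = saturated, phantom_two_k = phantom), thresholds = thresholds)
    refit_rows <- purrr::imap_dfr(pattern$refits, function(fi, nm) {
      dplyr::mutate(glance(fi), model = paste0("constrained_", nm), .before = 1)
    })
    dplyr::bind_rows(tab, refit_rows)
  })
  effects <- stage("effects", effects_table(k_est))

  report <- structure(list(
    descriptives = descriptives, correlations = correlations,
    saturated = saturated, distinguishability = disting,
    k = k_est, k_equality = k_eq, pattern = pattern,
    fit_table = ft, effects = effects,
    config = list(mode = mode, B = B, seed = seed, scaling = scaling,
                  convention = convention, thresholds = thresholds,
                  alpha_distinguishable = alpha_distinguishable,
                  epds_cutoff = epds_cutoff)
  ), class = "dyadic_report")
  if (!is.null(output_dir)) write_dyadic_report(report, output_dir)
  report
}

# item-level scored rows (dyad_id, role, stress, depression) -> wide dyads
items_to_wide <- function(scored) {
  if (!all(c("stress", "depression") %in% names(scored))) {
    abort("items input must contain both PSS-14 and EPDS blocks")
  }
  bad <- setdiff(unique(scored$role), c("woman", "husband"))
  if (length(bad)) abort(sprintf("unknown role value(s): %s", paste(bad, collapse = ", ")))
  wide <- tidyr::pivot_wider(
    dplyr::select(scored, "dyad_id", "role", "stress", "depression"),
    names_from = "role", values_from = c("stress", "depression"),
    names_glue = "{role}_{.value}")
  dplyr::select(wide, "dyad_id", "woman_stress", "husband_stress",
                "woman_depression", "husband_depression")
}

# Table-4-like block: per-partner actor and partner effects with bootstrap
# normal-approximation p-values, the ratio k and its percentile CI
effects_table <- function(k_est) {
  fit <- attr(k_est, "fit")
  reps <- attr(k_est, "replicates")
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  boot_p <- function(term, value) {
    if (is.null(reps) || !term %in% colnames(reps)) return(NA_real_)
    s <- sd(reps[, term], na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(NA_real_)
    2 * pnorm(-abs(value) / s)
  }
  if (identical(k_est$which, "common")) {
    return(tibble::tibble(
      partner = "common (indistinguishable)",
      actor_effect = est[["a1"]], actor_p = boot_p("a", est[["a1"]]),
      partner_effect = est[["p12"]], partner_p = boot_p("p", est[["p12"]]),
      k = k_est$k, ci_low = k_est$ci_low, ci_high = k_est$ci_high))
  }
  # incoming convention: row i carries partner i's actor effect and the
  # partner path arriving at partner i's outcome; outgoing: the path leaving i
  inc <- k_est$convention[1] == "incoming"
  tibble::tibble(
    partner = c("woman", "husband"),
    actor_effect = c(est[["a1"]], est[["a2"]]),
    actor_p = c(boot_p("a1", est[["a1"]]), boot_p("a2", est[["a2"]])),
    partner_effect = if (inc) c(est[["p12"]], est[["p21"]]) else c(est[["p21"]], est[["p12"]]),
    partner_p = if (inc) {
      c(boot_p("p12", est[["p12"]]), boot_p("p21", est[["p21"]]))
    } else {
      c(boot_p("p21", est[["p21"]]), boot_p("p12", est[["p12"]]))
    },
    k = k_est$k, ci_low = k_est$ci_low, ci_high = k_est$ci_high
  )
}

#' @export
print.dyadic_report <- function(x, ...) {
  cat("== Dyadic analysis report ==\n")
  if (!is.null(x$descriptives)) {
    cat("\n-- descriptives --\n")
    print(as.data.frame(x$descriptives), row.names = FALSE)
  }
  cat("\n-- distinguishability --\n")
  print(x$distinguishability)
  cat("\n-- effects and k --\n")
  print(as.data.frame(dplyr::mutate(x$effects, dplyr::across(dplyr::where(is.numeric), ~round(.x, 3)))),
        row.names = FALSE)
  cat("\n-- model fit --\n")
  print(as.data.frame(dplyr::mutate(x$fit_table, dplyr::across(dplyr::where(is.numeric), ~round(.x, 3)))),
        row.names = FALSE)
  cat("\n-- pattern --\n")
  cat(sprintf("classified dyadic pattern: %s\n", x$pattern$pattern))
  invisible(x)
}

#' Write a dyadic report to disk
#'
#' Emits the report blocks as CSV and JSON: `table1` (descriptives, when
#' available), `table2` (correlations/moments), `table3` (model fit),
#' `table4` (effects and k), and `pattern.json` (pattern, CIs, decision
#' trace, configuration).
#'
#' @param report A [run_dyadic_analysis] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dyadic_report <- function(report, dir) {
  stopifnot(inherits(report, "dyadic_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
    jsonlite::write_json(df, file.path(dir, paste0(name, ".json")),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(report$descriptives)) emit(report$descriptives, "table1")
  corr <- report$correlations
  corr_df <- if (inherits(corr, "correlation_summary")) {
    tidy(corr)
  } else {
    m <- as.data.frame(corr$S)
    names(m) <- corr$labels
    cbind(variable = corr$labels, m)
  }
  emit(corr_df, "table2")
  emit(report$fit_table, "table3")
  emit(report$effects, "table4")
  pat <- list(
    pattern = report$pattern$pattern,
    k = as.data.frame(tibble::as_tibble(report$k)),
    k_equality = if (!is.null(report$k_equality)) as.list(report$k_equality) else NULL,
    distinguishable = report$distinguishability$distinguishable,
    distinguishability_p = report$distinguishability$overall$p_value,
    decision_trace = as.data.frame(report$pattern$trace),
    config = report$config[c("mode", "B", "seed", "scaling", "convention",
                             "alpha_distinguishable", "epds_cutoff")]
  )
  jsonlite::write_json(pat, file.path(dir, "pattern.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
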