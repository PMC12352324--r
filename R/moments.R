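# Canonical variable order for the four-variable APIM:
#   x1 = partner 1 predictor (woman stress),  x2 = partner 2 predictor,
#   y1 = partner 1 outcome (woman depression), y2 = partner 2 outcome.
apim_vars <- c("x1", "x2", "y1", "y2")

#' Summary moments of a couple sample
#'
#' The sufficient statistics all APIM fitting consumes: a 4x4 covariance (or
#' correlation) matrix over (x1, x2, y1, y2) = (woman stress, husband
#' stress, woman depression, husband depression), plus the number of dyads.
#' A correlation matrix is treated as the covariance matrix of standardized
#' variables, so estimates fitted to it are standardized estimates.
#'
#' @param S Symmetric positive-definite 4x4 matrix.
#' @param n Number of dyads.
#' @param labels Optional display labels for the four variables, in the
#'   order woman stress, husband stress, woman depression, husband depression.
#' @return A `moment_summary` object.
#' @export
moment_summary <- function(S, n, labels = NULL) {
  S <- as.matrix(S)
  if (!all(dim(S) == c(4L, 4L))) abort("S must be a 4x4 matrix over (x1, x2, y1, y2)")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) abort("S must be symmetric")
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev)) {
    abort(sprintf("moment matrix is not positive definite (smallest eigenvalue %.3g)", min(ev)))
  }
  if (!is.numeric(n) || length(n) != 1L || n < 4) abort("n must be a single sample size >= 4")
  dimnames(S) <- list(apim_vars, apim_vars)
  structure(list(S = S, n = as.integer(n),
                 type = if (max(abs(diag(S) - 1)) < 1e-8) "correlation" else "covariance",
                 labels = labels %||% c("stress_w", "stress_h", "dep_w", "dep_h")),
            class = "moment_summary")
}

#' @export
print.moment_summary <- function(x, digits = 3, ...) {
  cat(sprintf("APIM moment summary (%s matrix, N = %d dyads)\n", x$type, x$n))
  m <- x$S
  dimnames(m) <- list(x$labels, x$labels)
  print(round(m, digits))
  invisible(x)
}

#' Compute summary moments from a wide dyad table
#'
#' @param data Wide dyad table with columns `woman_stress`, `husband_stress`,
#'   `woman_depression`, `husband_depression`.
#' @param standardize Return the correlation matrix instead of the
#'   covariance matrix (default `FALSE`).
#' @return A [moment_summary].
#' @export
dyad_moments <- function(data, standardize = FALSE) {
  X <- dyad_matrix(data)
  S <- cov(X)
  if (standardize) S <- cov2cor(S)
  moment_summary(S, nrow(X))
}

# wide dyad table -> n x 4 matrix in canonical order
dyad_matrix <- function(data) {
  data <- as.data.frame(data)
  need <- c("woman_stress", "husband_stress", "woman_depression", "husband_depression")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(sprintf("missing dyad columns: %s", paste(miss, collapse = ", ")))
  X <- as.matrix(data[need])
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < 4L) abort("need at least 4 complete dyads")
  colnames(X) <- apim_vars
  X
}

#' Read a labeled 4x4 moment matrix from CSV
#'
#' Expects a CSV with a `variable` column plus the four variable columns,
#' rows in the order woman stress, husband stress, woman depression,
#' husband depression. The sample size may be embedded as a leading comment
#' line `# n: 282` or passed via `n`.
#'
#' @param path CSV file path.
#' @param n Sample size; overrides any `# n:` header line.
#' @return A [moment_summary].
#' @export
read_moments_csv <- function(path, n = NULL) {
  header <- readLines(path, n = 5L)
  if (is.null(n)) {
    nl <- grep("^#\\s*n\\s*:", header, value = TRUE)
    if (length(nl)) n <- as.integer(sub("^#\\s*n\\s*:\\s*", "", nl[1]))
  }
  if (is.null(n) || is.na(n)) abort("sample size not found: pass n= or add a '# n: <N>' header line")
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  labels <- as.character(df[[1]])
  S <- as.matrix(df[, -1, drop = FALSE])
  moment_summary(S, n, labels = labels)
}

#' Write a moment summary to CSV
#'
#' Inverse of [read_moments_csv]; the sample size is stored as a
#' `# n:` header line.
#'
#' @param x A [moment_summary].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_moments_csv <- function(x, path) {
  stopifnot(inherits(x, "moment_summary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n: %d", x$n), con)
  m <- as.data.frame(x$S)
  names(m) <- x$labels
  df <- cbind(variable = x$labels, m)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged couple correlation moments
#'
#' The published correlation matrix of prenatal stress and depression for
#' 282 couples that the worked examples and the replication path use:
#' pairwise Pearson correlations among woman/husband stress and depression
#' totals.
#'
#' @return A [moment_summary] (correlation type, N = 282).
#' @export
couple_moments <- function() {
  read_moments_csv(system.file("extdata", "couple_moments.csv",
                               package = "dyadik", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
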