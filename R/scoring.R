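#' Standard reverse-keyed items of the PSS-14
#'
#' The positively worded items of the 14-item Perceived Stress Scale, which
#' are reverse-scored before summation (1-based positions).
#'
#' @format Integer vector of item positions.
#' @export
pss14_reverse_items <- c(4L, 5L, 6L, 7L, 9L, 10L, 13L)

instrument_info <- function(instrument) {
  switch(instrument,
    PSS14 = list(n_items = 14L, max_item = 4L, max_total = 56L),
    EPDS  = list(n_items = 10L, max_item = 3L, max_total = 30L),
    abort(sprintf("unknown instrument '%s' (use \"PSS14\" or \"EPDS\")", instrument))
  )
}

check_item_responses <- function(responses, instrument) {
  info <- instrument_info(instrument)
  if (length(responses) != info$n_items) {
    abort(sprintf("%s requires exactly %d item responses, got %d",
                  instrument, info$n_items, length(responses)))
  }
  miss <- which(is.na(responses))
  if (length(miss) > 0L) {
    abort(sprintf(
      "missing %s item(s) at position(s) %s: totals are not imputed, complete responses are required",
      instrument, paste(miss, collapse = ", ")))
  }
  if (any(responses != floor(responses)) ||
      any(responses < 0) || any(responses > info$max_item)) {
    abort(sprintf("%s responses must be integers in 0..%d", instrument, info$max_item))
  }
  invisible(info)
}

#' Score the 14-item Perceived Stress Scale
#'
#' Sums the 14 item responses after reverse-scoring the positively worded
#' items (`4 - raw`). Totals range 0-56; higher totals mean greater
#' perceived stress. Missing items are refused, never imputed.
#'
#' @param responses Integer vector of 14 raw item responses, each in 0-4
#'   (0 = never, 4 = very often).
#' @param reverse_items 1-based positions of the reverse-scored (positively
#'   worded) items. Defaults to the instrument's standard keying,
#'   [pss14_reverse_items].
#' @return One-row tibble with columns `instrument`, `total`, `n_missing`.
#' @examples
#' score_pss14(rep(0, 14))$total  # 28: the seven reverse items contribute 4 each
#' @export
score_pss14 <- function(responses, reverse_items = pss14_reverse_items) {
  check_item_responses(responses, "PSS14")
  if (length(reverse_items) > 0 &&
      (any(reverse_items < 1) || any(reverse_items > 14)))
    abort("reverse_items must be positions in 1..14")
  scored <- responses
  scored[reverse_items] <- 4L - scored[reverse_items]
  tibble::tibble(instrument = "PSS14", total = sum(scored), n_missing = 0L)
}

#' Score the Edinburgh Postnatal Depression Scale
#'
#' Sums the 10 item responses (totals 0-30) and flags probable depression at
#' the clinical cutoff of 10 or more. By default the caller supplies
#' already-oriented severity codes (0-3, higher = more severe); a reverse-item
#' set can be given for raw forms whose keying differs.
#'
#' @param responses Integer vector of 10 item responses, each in 0-3.
#' @param reverse_items Optional 1-based positions to reverse (`3 - raw`)
#'   before summation; empty by default.
#' @param cutoff Total at or above which the depression flag is set (default 10).
#' @return One-row tibble with columns `instrument`, `total`, `depressed`,
#'   `n_missing`.
#' @export
score_epds <- function(responses, reverse_items = integer(0), cutoff = 10L) {
  check_item_responses(responses, "EPDS")
  if (length(reverse_items) > 0 &&
      (any(reverse_items < 1) || any(reverse_items > 10)))
    abort("reverse_items must be positions in 1..10")
  scored <- responses
  scored[reverse_items] <- 3L - scored[reverse_items]
  total <- sum(scored)
  tibble::tibble(instrument = "EPDS", total = total,
                 depressed = total >= cutoff, n_missing = 0L)
}

#' Score an item-level table of PSS-14 and EPDS responses
#'
#' Takes one row per respondent with item columns `pss_01..pss_14` and/or
#' `epds_01..epds_10` (plus any identifier columns, typically `dyad_id` and
#' `role`) and returns the scored totals. Rows with missing items are
#' refused.
#'
#' @param data Data frame, one row per respondent.
#' @param pss_reverse_items Reverse-keyed PSS-14 positions
#'   (default [pss14_reverse_items]).
#' @param epds_reverse_items Reverse-keyed EPDS positions (default none).
#' @return Tibble with the identifier columns plus `stress` (PSS-14 total),
#'   `depression` (EPDS total) and `depressed` for whichever instruments are
#'   present.
#' @export
score_items <- function(data, pss_reverse_items = pss14_reverse_items,
                        epds_reverse_items = integer(0)) {
  data <- tibble::as_tibble(data)
  pss_cols <- sprintf("pss_%02d", 1:14)
  epds_cols <- sprintf("epds_%02d", 1:10)
  has_pss <- all(pss_cols %in% names(data))
  has_epds <- all(epds_cols %in% names(data))
  if (!has_pss && !has_epds) {
    abort("no complete item block found: expected columns pss_01..pss_14 and/or epds_01..epds_10")
  }
  id_cols <- setdiff(names(data), c(pss_cols, epds_cols))
  out <- data[id_cols]
  if (has_pss) {
    out$stress <- vapply(seq_len(nrow(data)), function(i) {
      score_pss14(as.integer(data[i, pss_cols]), reverse_items = pss_reverse_items)$total
    }, integer(1))
  }
  if (has_epds) {
    sc <- lapply(seq_len(nrow(data)), function(i) {
      score_epds(as.integer(data[i, epds_cols]), reverse_items = epds_reverse_items)
    })
    out$depression <- vapply(sc, function(s) s$total, integer(1))
    out$depressed <- vapply(sc, function(s) s$depressed, logical(1))
  }
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = J/(J-1) \, (1 - \sum_j s_j^2 / s_T^2)} where \eqn{s_j^2} are
#' the item variances and \eqn{s_T^2} the variance of the respondent totals.
#'
#' @param items Numeric matrix or data frame, respondents in rows, items in
#'   columns; at least 2 items, 3 respondents, and no missing cells.
#' @return A single numeric value.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (!is.numeric(items)) abort("items must be numeric")
  if (ncol(items) < 2L) abort("Cronbach's alpha needs at least 2 items")
  if (nrow(items) < 3L) abort("Cronbach's alpha needs at least 3 respondents")
  if (anyNA(items)) abort("items contains missing cells; alpha is computed on complete data only")
  totals <- rowSums(items)
  vt <- var(totals)
  if (vt <= .Machine$double.eps * max(1, mean(abs(totals))^2)) {
    abort("total-score variance is zero: alpha is undefined (all respondents have the same total)")
  }
  J <- ncol(items)
  (J / (J - 1)) * (1 - sum(apply(items, 2, var)) / vt)
}
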