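# Core network scale-up estimators. The known-population method rests on the
# proportionality e0/t = m0/c: the share of a respondent's network falling in
# subpopulations of known total size e0 matches those subpopulations' share of
# the region, so the mean personal network size is c = m0 * t / e0. The same
# proportionality applied to the hidden population gives e1 = (m1 / c) * t.

#' Mean reported known-population alter count (m0)
#'
#' Mean, over answered respondents, of the row-sum of known-population counts.
#' Blank answer sheets (`answered = FALSE`) are excluded listwise; the
#' exclusion count is reported via `message()`.
#'
#' @param table a [general_survey()] (or any table with `name_` columns and an
#'   `answered` flag; tables without the flag are treated as fully answered).
#' @return The mean row-sum (numeric scalar), with attribute `"n_excluded"`.
#' @export
mean_known_count <- function(table) {
  answered <- if ("answered" %in% names(table)) as.logical(table$answered) else
    rep(TRUE, nrow(table))
  n_excl <- sum(!answered)
  tab <- table[answered, , drop = FALSE]
  if (nrow(tab) == 0L) abort_stage("mean_known_count", "no answered rows")
  if (n_excl > 0) {
    message(sprintf("mean_known_count: excluded %d unanswered row(s) of %d",
                    n_excl, nrow(table)))
  }
  m <- mean(rowSums(known_matrix(tab)))
  attr(m, "n_excluded") <- n_excl
  m
}

#' Personal network size from known populations (c = m t / e0)
#'
#' @param m mean known-population alter count (m0), non-negative.
#' @param frame a [study_frame()].
#' @return Estimated mean personal network size `c`.
#' @examples
#' fr <- taiyuan_frame()
#' network_size_from_known(8.3, fr)  # 124.4 (the study printed 123.9 from
#'                                   # the unrounded mean)
#' @export
network_size_from_known <- function(m, frame) {
  stopifnot(inherits(frame, "study_frame"))
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0) {
    abort_stage("network_size_from_known", "m must be a single non-negative number")
  }
  m * frame$t / frame$e0
}

#' Basic network scale-up estimate (e1 = m1 t / c)
#'
#' Unadjusted hidden-population size: the mean number of hidden-population
#' alters per respondent, scaled by the population-to-network ratio `t / c`.
#' Barrier effects and transmission error make this an underestimate by the
#' factor `delta * tau`; see [adjusted_estimate()].
#'
#' @param m1 mean number of hidden-population alters per respondent.
#' @param c mean personal network size (must be positive).
#' @param t total population.
#' @return The basic scale-up estimate `e1`.
#' @export
basic_nsum_estimate <- function(m1, c, t) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0) {
    abort_stage("basic_nsum_estimate", "c must be a single positive number")
  }
  if (!is.numeric(m1) || length(m1) != 1L || is.na(m1)) {
    abort_stage("basic_nsum_estimate", "m1 must be a single number")
  }
  (m1 / c) * t
}

#' Per-respondent network-size estimates (diagnostic)
#'
#' The pooled estimator in this package is ratio-of-means (one `c` from the
#' grand mean m0). The per-respondent mean-of-ratios variant is exposed for
#' diagnostics only — inspecting its spread, not feeding the pipeline.
#'
#' @inheritParams mean_known_count
#' @param frame a [study_frame()].
#' @return Numeric vector of `rowSum * t / e0` over answered rows.
#' @export
respondent_network_sizes <- function(table, frame) {
  stopifnot(inherits(frame, "study_frame"))
  answered <- if ("answered" %in% names(table)) as.logical(table$answered) else
    rep(TRUE, nrow(table))
  rowSums(known_matrix(table[answered, , drop = FALSE])) * frame$t / frame$e0
}

#' Name-proportion diagnostic: reported vs actual subpopulation shares
#'
#' Sanity check of the known-population method: across name groups, the share
#' of all reported alters falling in group j should track the group's actual
#' population share N_j / e0. Returns the Pearson correlation and its
#' two-sided p-value, plus the per-name table for plotting.
#'
#' @param table any survey table with `name_<label>` columns (general or RDS);
#'   unanswered rows are excluded.
#' @param frame a [study_frame()] whose labels match the table.
#' @return List with `r`, `p_value`, `n_names`, and `by_name` (data.frame of
#'   reported and actual shares).
#' @export
name_proportion_diagnostic <- function(table, frame) {
  stopifnot(inherits(frame, "study_frame"))
  answered <- if ("answered" %in% names(table)) as.logical(table$answered) else
    rep(TRUE, nrow(table))
  km <- known_matrix(table[answered, , drop = FALSE])
  if (ncol(km) < 3L) {
    abort_stage("name_proportion_diagnostic", "need >= 3 known subpopulations")
  }
  idx <- match(colnames(km), frame$known$label)
  if (anyNA(idx)) {
    abort_stage("name_proportion_diagnostic", "table name groups not in the frame")
  }
  totals <- colSums(km)
  if (sum(totals) == 0) {
    abort_stage("name_proportion_diagnostic", "all reported counts are zero")
  }
  reported <- totals / sum(totals)
  actual <- frame$known$size[idx] / frame$e0
  if (stats::sd(reported) == 0 || stats::sd(actual) == 0) {
    abort_stage("name_proportion_diagnostic",
                "constant shares: correlation undefined")
  }
  ct <- stats::cor.test(reported, actual, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_names = ncol(km),
       by_name = data.frame(label = colnames(km), reported = reported,
                            actual = actual, row.names = NULL))
}
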