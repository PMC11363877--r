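# Barrier-effect and transmission-error adjustment. Hidden-population members
# tend to have smaller personal networks (barrier effect, popularity ratio
# delta = c_H / c_G < 1) and their alters are not always aware of their
# membership (transmission error, information transmission rate
# tau = aware / c_H <= 1). Both deflate the basic scale-up estimate by the
# same multiplicative mechanism, so the correction divides e1 by delta * tau.

#' Mean personal network size of the hidden population (c_H)
#'
#' Same known-population formula as [network_size_from_known()], applied to
#' the RDS sample of the hidden population: mean row-sum of known-population
#' counts scaled by `t / e0`.
#'
#' @param rds an [rds_table()].
#' @param frame a [study_frame()].
#' @param weighted if `TRUE`, use an RDS-II style inverse-degree weighted mean
#'   (degree proxied by the respondent's known-population row-sum) instead of
#'   the unweighted mean. Off by default: the reference analysis reports
#'   unweighted means.
#' @return Estimated mean network size of hidden-population members.
#' @export
hidden_network_size <- function(rds, frame, weighted = FALSE) {
  stopifnot(inherits(frame, "study_frame"))
  if (nrow(rds) == 0L) abort_stage("hidden_network_size", "empty RDS table")
  rs <- rowSums(known_matrix(rds))
  scaled_mean(rs, rs, frame, weighted, "hidden_network_size")
}

#' Mean number of alters aware of the respondent's hidden-group membership
#'
#' As [hidden_network_size()] but on the `aware_` counts: the network-size
#' scale-up of the alters who know about the respondent's membership.
#'
#' @inheritParams hidden_network_size
#' @return Estimated mean number of aware alters per hidden-population member.
#' @export
aware_network_size <- function(rds, frame, weighted = FALSE) {
  stopifnot(inherits(frame, "study_frame"))
  if (nrow(rds) == 0L) abort_stage("aware_network_size", "empty RDS table")
  scaled_mean(rowSums(aware_matrix(rds)), rowSums(known_matrix(rds)),
              frame, weighted, "aware_network_size")
}

scaled_mean <- function(x, degree_rs, frame, weighted, stage) {
  if (weighted) {
    keep <- degree_rs > 0
    if (!any(keep)) abort_stage(stage, "all degree proxies are zero")
    if (any(!keep)) {
      warning(sprintf("%s: dropped %d zero-degree row(s) from the weighted mean",
                      stage, sum(!keep)), call. = FALSE)
    }
    w <- 1 / degree_rs[keep]
    sum(w * x[keep]) / sum(w) * frame$t / frame$e0
  } else {
    mean(x) * frame$t / frame$e0
  }
}

#' Popularity ratio (delta = c_H / c_G)
#'
#' Ratio of the hidden population's mean personal network size to the general
#' population's. Values below 1 quantify the barrier effect. Estimation noise
#' can push the ratio above 1; that triggers a warning, not an error.
#'
#' @param c_H hidden-population mean network size.
#' @param c_G general-population mean network size (positive).
#' @return The popularity ratio.
#' @export
popularity_ratio <- function(c_H, c_G) {
  if (!is.numeric(c_G) || length(c_G) != 1L || is.na(c_G) || c_G <= 0) {
    abort_stage("popularity_ratio", "c_G must be a single positive number")
  }
  if (!is.numeric(c_H) || length(c_H) != 1L || is.na(c_H) || c_H < 0) {
    abort_stage("popularity_ratio", "c_H must be a single non-negative number")
  }
  delta <- c_H / c_G
  if (delta > 1) {
    warning(sprintf("popularity ratio %.3f > 1: hidden population appears *more* popular than average (estimation noise?)",
                    delta), call. = FALSE)
  }
  delta
}

#' Information transmission rate (tau = aware / c_H)
#'
#' Fraction of a hidden-population member's network that is aware of their
#' membership. On any valid RDS table tau <= 1 because awareness counts are
#' bounded by tie counts cell-wise.
#'
#' @param aware mean number of aware alters.
#' @param c_H hidden-population mean network size (positive).
#' @return The transmission rate.
#' @export
transmission_rate <- function(aware, c_H) {
  if (!is.numeric(c_H) || length(c_H) != 1L || is.na(c_H) || c_H <= 0) {
    abort_stage("transmission_rate", "c_H must be a single positive number")
  }
  if (!is.numeric(aware) || length(aware) != 1L || is.na(aware) || aware < 0) {
    abort_stage("transmission_rate", "aware must be a single non-negative number")
  }
  tau <- aware / c_H
  if (tau > 1) {
    warning("transmission rate > 1: aware mean exceeds network size (invalid inputs?)",
            call. = FALSE)
  }
  tau
}

#' Bundle of adjustment factors
#'
#' @param delta popularity ratio (> 0; > 1 warned by [popularity_ratio()]).
#' @param tau information transmission rate in (0, 1].
#' @return An object of class `adjustment_factors`.
#' @export
adjustment_factors <- function(delta, tau) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0) {
    abort_stage("adjustment_factors", "delta must be a single positive number")
  }
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0 || tau > 1) {
    abort_stage("adjustment_factors", "tau must lie in (0, 1]")
  }
  structure(list(delta = delta, tau = tau), class = "adjustment_factors")
}

#' Estimate the adjustment factors from an RDS survey
#'
#' Convenience wrapper: computes c_H and the aware network size from the RDS
#' table, then delta against the supplied general-population network size and
#' tau as their ratio.
#'
#' @inheritParams hidden_network_size
#' @param c_G general-population mean network size.
#' @return An `adjustment_factors` object with attributes `c_H` and `aware`.
#' @export
estimate_adjustment_factors <- function(rds, frame, c_G, weighted = FALSE) {
  c_H <- hidden_network_size(rds, frame, weighted = weighted)
  aware <- aware_network_size(rds, frame, weighted = weighted)
  out <- adjustment_factors(popularity_ratio(c_H, c_G),
                            transmission_rate(aware, c_H))
  attr(out, "c_H") <- c_H
  attr(out, "aware") <- aware
  out
}

#' Adjusted scale-up estimate (e1 / (delta tau))
#'
#' Divides the basic estimate by the popularity ratio and the transmission
#' rate, undoing the two multiplicative sources of underestimation.
#'
#' @param e1 basic scale-up estimate.
#' @param factors an [adjustment_factors()] (or list with `delta`, `tau`).
#' @return The adjusted hidden-population size.
#' @examples
#' adjusted_estimate(585.1, adjustment_factors(0.536, 0.879))  # 1241.9
#' @export
adjusted_estimate <- function(e1, factors) {
  delta <- factors$delta; tau <- factors$tau
  if (is.null(delta) || is.null(tau) || !is.finite(delta * tau) || delta * tau <= 0) {
    abort_stage("adjusted_estimate", "delta * tau must be positive")
  }
  e1 / (delta * tau)
}

#' Prevalence among the adult population, in percent
#'
#' @param adjusted adjusted hidden-population size.
#' @param frame a [study_frame()] with a positive `adult_pop`.
#' @return Prevalence as a percentage of the 15-64 population.
#' @export
prevalence <- function(adjusted, frame) {
  stopifnot(inherits(frame, "study_frame"))
  if (frame$adult_pop <= 0) abort_stage("prevalence", "adult_pop must be positive")
  100 * adjusted / frame$adult_pop
}
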