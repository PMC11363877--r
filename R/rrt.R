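#' Two-group unrelated-question randomized response design
#'
#' In the quantitative unrelated-question randomized response technique (RRT),
#' each respondent is shown either the sensitive question or an innocuous
#' unrelated one, with a group-specific probability; only the respondent knows
#' which was answered. `p1` and `p2` are the probabilities of receiving the
#' *sensitive* question in groups 1 and 2 (the study design here used 0.8 and
#' 0.2). They must differ, otherwise the unmasking system is singular.
#'
#' @param p1,p2 sensitive-question probabilities for the two groups, in
#'   `[0, 1]`, `p1 != p2`.
#' @return An object of class `rrt_design`.
#' @export
rrt_design <- function(p1 = 0.8, p2 = 0.2) {
  if (!is.numeric(p1) || !is.numeric(p2) || length(p1) != 1L || length(p2) != 1L ||
      is.na(p1) || is.na(p2) || p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) {
    abort_stage("rrt_design", "p1 and p2 must be single probabilities in [0, 1]")
  }
  if (p1 == p2) {
    abort_stage("rrt_design",
                "degenerate design: p1 must differ from p2 (p1 - p2 divides the unmasked mean)")
  }
  structure(list(p1 = p1, p2 = p2), class = "rrt_design")
}

#' Unmask the sensitive mean from two-group RRT answers
#'
#' Let mu1, mu2 be the group mean answers. Because each group's answers are a
#' mixture of the sensitive variable S and the unrelated variable U with known
#' weights, the sensitive mean is recovered algebraically:
#'
#'   mu_S = \[(1 - p2) mu1 - (1 - p1) mu2\] / (p1 - p2)
#'
#' The variance of `mu_s` follows by the delta rule on the two independent
#' group means:
#' `var = [(1-p2)^2 var(mu1) + (1-p1)^2 var(mu2)] / (p1-p2)^2`,
#' with `var(mu_g) = var(answers_g)/n_g`. At small samples the unmasked mean
#' can be negative; the raw value is reported alongside a zero-floored
#' convenience field (`mu_s_floor`), and is never silently truncated.
#'
#' @param answers_g1,answers_g2 numeric answer vectors for the two groups
#'   (each of length >= 2 so the variance is estimable).
#' @param design an [rrt_design()].
#' @return An object of class `rrt_result`: list with `mu_s`, `mu_s_floor`,
#'   `var_mu_s`, `se`, `mu1`, `mu2`, `n1`, `n2`.
#' @examples
#' d <- rrt_design(0.8, 0.2)
#' # Exactly invertible mixture: S has mean 2, U has mean 10.
#' unmask_mean(c(3.6, 3.6), c(8.4, 8.4), d)$mu_s  # 2
#' @export
unmask_mean <- function(answers_g1, answers_g2, design) {
  stopifnot(inherits(design, "rrt_design"))
  g1 <- answers_g1[!is.na(answers_g1)]
  g2 <- answers_g2[!is.na(answers_g2)]
  if (length(g1) < 2L || length(g2) < 2L) {
    abort_stage("unmask_mean",
                "each RRT group needs >= 2 answers for the variance to be estimable")
  }
  p1 <- design$p1; p2 <- design$p2
  mu1 <- mean(g1); mu2 <- mean(g2)
  mu_s <- ((1 - p2) * mu1 - (1 - p1) * mu2) / (p1 - p2)
  var_mu_s <- ((1 - p2)^2 * stats::var(g1) / length(g1) +
               (1 - p1)^2 * stats::var(g2) / length(g2)) / (p1 - p2)^2
  structure(
    list(mu_s = mu_s, mu_s_floor = max(0, mu_s), var_mu_s = var_mu_s,
         se = sqrt(var_mu_s), mu1 = mu1, mu2 = mu2,
         n1 = length(g1), n2 = length(g2)),
    class = "rrt_result"
  )
}

#' @export
print.rrt_result <- function(x, ...) {
  cat(sprintf("RRT unmasked mean: %.5g (SE %.3g; group means %.4g / %.4g; n = %d + %d)\n",
              x$mu_s, x$se, x$mu1, x$mu2, x$n1, x$n2))
  if (x$mu_s < 0) cat("  note: raw mean is negative; mu_s_floor = 0\n")
  invisible(x)
}

#' Mask per-respondent answers under an RRT design (simulation)
#'
#' For each respondent, returns their sensitive value with the sensitive-
#' question probability of their group, else their unrelated value. Which
#' question was answered is deliberately *not* returned — only the group label
#' is observable, mirroring the privacy guarantee of the field design.
#'
#' @param sensitive,unrelated aligned numeric vectors, one entry per
#'   respondent.
#' @param group_assignment vector of group labels, values `1`/`2` (numeric or
#'   character).
#' @param design an [rrt_design()].
#' @param seed optional integer; when given, masking is run in an isolated,
#'   reproducible RNG stream.
#' @return Numeric vector of masked answers, one per respondent.
#' @export
mask_responses <- function(sensitive, unrelated, group_assignment, design,
                           seed = NULL) {
  stopifnot(inherits(design, "rrt_design"))
  n <- length(sensitive)
  if (length(unrelated) != n || length(group_assignment) != n) {
    abort_stage("mask_responses",
                "sensitive, unrelated and group_assignment must have equal length")
  }
  grp <- as.character(group_assignment)
  if (!all(grp %in% c("1", "2"))) {
    abort_stage("mask_responses", "group_assignment values must be 1 or 2")
  }
  p <- ifelse(grp == "1", design$p1, design$p2)
  with_seed(seed, {
    take_sensitive <- stats::runif(n) < p
    ifelse(take_sensitive, sensitive, unrelated)
  })
}
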