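# Synthetic survey generator. Every estimator in the package is validated
# against surveys drawn from a fully specified ground truth: a general
# population with mean personal network size c_true, a hidden population of
# size N_H whose members have networks smaller by the factor delta_true
# (barrier effect) and whose alters know about their membership with
# probability tau_true (transmission error). Ties to hidden members visible
# to a general respondent are therefore thinned by delta_true * tau_true at
# the tie level — exactly the multiplicative model the adjusted estimator
# inverts, which makes parameter recovery a sharp end-to-end test. No explicit
# social graph over t individuals is simulated; counts are drawn from the
# implied marginal binomials, which is sufficient for every estimator here.

#' Ground truth for the synthetic surveys
#'
#' Defaults describe the reference study's world: the Taiyuan frame, a hidden
#' population of 1242 people who inject drugs, general network size 123.9,
#' popularity ratio 0.536, transmission rate 0.879, an unrelated RRT question
#' with mean 20 (weekly web hours), and a 6.3% blank-sheet rate.
#'
#' @param frame a [study_frame()]; default [taiyuan_frame()].
#' @param N_H true hidden-population size (< `frame$t`).
#' @param c_true mean personal network size of the general population.
#' @param delta_true popularity ratio in (0, 1].
#' @param tau_true information transmission rate in (0, 1].
#' @param degree_dispersion negative-binomial size parameter of the degree
#'   distribution (smaller = more overdispersed; `Inf` gives Poisson degrees).
#' @param mu_unrelated mean of the unrelated-question answers.
#' @param nonresponse_rate fraction of blank answer sheets in `[0, 1)`.
#' @param cluster_sd standard deviation of an optional log-normal department-
#'   level random effect on network size (0 = exchangeable clusters).
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(frame = taiyuan_frame(), N_H = 1242,
                            c_true = 123.9, delta_true = 0.536,
                            tau_true = 0.879, degree_dispersion = 2,
                            mu_unrelated = 20, nonresponse_rate = 0.063,
                            cluster_sd = 0) {
  stopifnot(inherits(frame, "study_frame"))
  if (!is.numeric(N_H) || N_H < 0 || N_H >= frame$t) {
    abort_stage("synthetic_truth", "N_H must satisfy 0 <= N_H < frame$t")
  }
  if (c_true <= 0) abort_stage("synthetic_truth", "c_true must be positive")
  if (delta_true <= 0 || delta_true > 1) {
    abort_stage("synthetic_truth", "delta_true must lie in (0, 1]")
  }
  if (tau_true <= 0 || tau_true > 1) {
    abort_stage("synthetic_truth", "tau_true must lie in (0, 1]")
  }
  if (degree_dispersion <= 0) {
    abort_stage("synthetic_truth", "degree_dispersion must be positive")
  }
  if (mu_unrelated < 0) abort_stage("synthetic_truth", "mu_unrelated must be >= 0")
  if (nonresponse_rate < 0 || nonresponse_rate >= 1) {
    abort_stage("synthetic_truth", "nonresponse_rate must lie in [0, 1)")
  }
  if (cluster_sd < 0) abort_stage("synthetic_truth", "cluster_sd must be >= 0")
  structure(
    list(frame = frame, N_H = round(N_H), c_true = c_true,
         delta_true = delta_true, tau_true = tau_true,
         degree_dispersion = degree_dispersion, mu_unrelated = mu_unrelated,
         nonresponse_rate = nonresponse_rate, cluster_sd = cluster_sd),
    class = "synthetic_truth"
  )
}

draw_degrees <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, size = size, mu = mu)
}

# Deterministic nesting: 83 departments in 36 units in 20 industries, mirroring
# the field survey's sampling stages (exchangeable labels by default).
cluster_map <- function() {
  unit_of_dept <- ((seq_len(83) - 1L) %% 36L) + 1L
  industry_of_unit <- ((seq_len(36) - 1L) %% 20L) + 1L
  list(unit_of_dept = unit_of_dept, industry_of_unit = industry_of_unit)
}

#' Generate a synthetic general-population survey
#'
#' Per respondent: a personal network size d_i (overdispersed count with mean
#' `c_true`), known-population counts `Binomial(d_i, N_j / t)` per name group,
#' a *visible* hidden-alter count `Binomial(d_i, (N_H/t) delta tau)` (barrier
#' effect and transmission error applied at the tie level), RRT masking of
#' that count against an unrelated Poisson(`mu_unrelated`) answer, blank
#' sheets at `nonresponse_rate`, and nested synthetic cluster labels
#' (industry/unit/department).
#'
#' @param truth a [synthetic_truth()].
#' @param n number of respondents.
#' @param design an [rrt_design()].
#' @param seed integer seed; same seed, same table.
#' @return A [general_survey()] with attribute `"hidden_true"` (the unmasked
#'   sensitive counts, for oracle tests only — a real survey never sees them).
#' @export
generate_general_survey <- function(truth, n = 1747, design = rrt_design(),
                                    seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(design, "rrt_design"))
  if (n < 1) abort_stage("generate_general_survey", "n must be >= 1")
  fr <- truth$frame
  J <- nrow(fr$known)
  p_known <- fr$known$size / fr$t
  p_hidden <- (truth$N_H / fr$t) * truth$delta_true * truth$tau_true
  stopifnot(p_hidden >= 0, p_hidden <= 1)
  cm <- cluster_map()
  with_seed(seed, {
    dept <- sample.int(83, n, replace = TRUE)
    unit <- cm$unit_of_dept[dept]
    industry <- cm$industry_of_unit[unit]
    mu_i <- if (truth$cluster_sd > 0) {
      eff <- exp(stats::rnorm(83, 0, truth$cluster_sd) - truth$cluster_sd^2 / 2)
      truth$c_true * eff[dept]
    } else rep(truth$c_true, n)
    d <- draw_degrees(n, mu_i, truth$degree_dispersion)
    known <- matrix(
      stats::rbinom(n * J, size = rep(d, times = J), prob = rep(p_known, each = n)),
      nrow = n, ncol = J)
    hidden_true <- stats::rbinom(n, size = d, prob = p_hidden)
    unrelated <- stats::rpois(n, truth$mu_unrelated)
    grp <- sample(c(1L, 2L), n, replace = TRUE)
    masked <- mask_responses(hidden_true, unrelated, grp, design)
    answered <- stats::runif(n) >= truth$nonresponse_rate
    df <- data.frame(
      id = sprintf("G%05d", seq_len(n)),
      industry = sprintf("I%02d", industry),
      unit = sprintf("U%02d", unit),
      department = sprintf("D%02d", dept),
      stringsAsFactors = FALSE)
    df[paste0("name_", fr$known$label)] <- as.data.frame(known)
    df$rrt_group <- grp
    df$rrt_answer <- masked
    df$answered <- answered
    out <- general_survey(df, frame = fr)
    attr(out, "hidden_true") <- ifelse(answered, hidden_true, NA_integer_)
    out
  })
}

# Draw one unrecruited member, uniformly or degree-proportionally, by
# rejection (O(1) when the recruited fraction is small).
draw_unrecruited <- function(recruited, degrees, degree_proportional, max_d) {
  N <- length(recruited)
  for (tries in seq_len(1000L)) {
    cand <- sample.int(N, 1L)
    if (recruited[cand]) next
    if (!degree_proportional || stats::runif(1) < degrees[cand] / max_d) {
      return(cand)
    }
  }
  pool <- which(!recruited)
  if (length(pool) == 0L) return(NA_integer_)
  if (degree_proportional) {
    pool[sample.int(length(pool), 1L, prob = degrees[pool] + 1e-12)]
  } else pool[sample.int(length(pool), 1L)]
}

#' Generate a synthetic RDS survey of the hidden population
#'
#' Simulates a hidden population of `truth$N_H` members with network sizes of
#' mean `c_true * delta_true`, then grows a recruitment forest: `n_seeds`
#' wave-0 seeds, each enrolled respondent recruiting
#' `Binomial(coupons, recruit_prob)` distinct not-yet-recruited members, wave
#' by wave, until `n_target` respondents are enrolled or `max_wave` is
#' exceeded. Should every chain die out before the target (rare at the
#' defaults), a fresh wave-0 seed is drawn so fieldwork continues — as a field
#' team would. Per respondent, name-group counts are
#' `Binomial(d, N_j / t)` and awareness counts `Binomial(known, tau_true)`,
#' so `aware <= known` holds cell-wise by construction.
#'
#' @param truth a [synthetic_truth()].
#' @param n_target target sample size (default 302).
#' @param n_seeds number of initial seeds (default 2).
#' @param coupons recruitment coupons per respondent (default 3).
#' @param max_wave maximum recruitment wave (default 8).
#' @param seed integer seed.
#' @param recruit_prob per-coupon redemption probability (default 0.75, which
#'   gives effective branching 2.25 — enough to reach 302 from 2 seeds within
#'   8 waves).
#' @param degree_proportional recruit proportionally to degree instead of
#'   uniformly (stress test for the unweighted RDS means).
#' @return An [rds_table()] with `n_target` rows (fewer, with a warning, only
#'   if `max_wave` truncates growth first).
#' @export
generate_rds_survey <- function(truth, n_target = 302, n_seeds = 2,
                                coupons = 3, max_wave = 8, seed = NULL,
                                recruit_prob = 0.75,
                                degree_proportional = FALSE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_seeds < 1 || n_target < n_seeds) {
    abort_stage("generate_rds_survey", "need n_target >= n_seeds >= 1")
  }
  N <- truth$N_H
  if (n_target > N) {
    abort_stage("generate_rds_survey",
                "recruitment exhausts the population: n_target > N_H")
  }
  fr <- truth$frame
  J <- nrow(fr$known)
  p_known <- fr$known$size / fr$t
  with_seed(seed, {
    degrees <- draw_degrees(N, truth$c_true * truth$delta_true,
                            truth$degree_dispersion)
    max_d <- max(degrees, 1)
    recruited <- logical(N)
    member <- integer(n_target)   # population index of enrollee k
    rec_of <- integer(n_target)   # enrollee index of recruiter (0 = seed)
    wave_of <- integer(n_target)
    total <- 0L
    new_seed <- function() {
      cand <- draw_unrecruited(recruited, degrees, degree_proportional, max_d)
      if (is.na(cand)) return(FALSE)
      recruited[cand] <<- TRUE
      total <<- total + 1L
      member[total] <<- cand; rec_of[total] <<- 0L; wave_of[total] <<- 0L
      TRUE
    }
    for (s in seq_len(n_seeds)) {
      if (total >= n_target) break
      if (!new_seed()) {
        abort_stage("generate_rds_survey",
                    "recruitment exhausts the population before the seeds are placed")
      }
    }
    frontier <- seq_len(total)
    wave <- 0L
    while (total < n_target) {
      if (length(frontier) == 0L) {
        # all chains extinct: replenish with a fresh seed (documented choice)
        if (!new_seed()) break
        frontier <- total
        wave <- 0L
        next
      }
      if (wave >= max_wave) break
      nxt <- integer(0)
      for (k in frontier) {
        if (total >= n_target) break
        n_rec <- stats::rbinom(1L, coupons, recruit_prob)
        n_rec <- min(n_rec, n_target - total)
        if (n_rec <= 0L) next
        for (r in seq_len(n_rec)) {
          cand <- draw_unrecruited(recruited, degrees, degree_proportional, max_d)
          if (is.na(cand)) break
          recruited[cand] <- TRUE
          total <- total + 1L
          member[total] <- cand; rec_of[total] <- k
          wave_of[total] <- wave_of[k] + 1L
          nxt <- c(nxt, total)
        }
      }
      frontier <- nxt
      wave <- wave + 1L
    }
    if (total < n_target) {
      warning(sprintf(
        "generate_rds_survey: reached %d of %d respondents before max_wave/extinction",
        total, n_target), call. = FALSE)
      member <- member[seq_len(total)]
      rec_of <- rec_of[seq_len(total)]
      wave_of <- wave_of[seq_len(total)]
    }
    n <- length(member)
    d_s <- degrees[member]
    known <- matrix(
      stats::rbinom(n * J, size = rep(d_s, times = J), prob = rep(p_known, each = n)),
      nrow = n, ncol = J)
    aware <- matrix(stats::rbinom(n * J, size = as.vector(known),
                                  prob = truth$tau_true), nrow = n, ncol = J)
    ids <- sprintf("R%04d", seq_len(n))
    df <- data.frame(
      id = ids,
      recruiter_id = ifelse(rec_of == 0L, NA_character_, ids[pmax(rec_of, 1L)]),
      wave = wave_of,
      stringsAsFactors = FALSE)
    df[paste0("name_", fr$known$label)] <- as.data.frame(known)
    df[paste0("aware_", fr$known$label)] <- as.data.frame(aware)
    rds_table(df, frame = fr)
  })
}

#' Implied target quantities of a synthetic truth
#'
#' Pure function of the truth: the quantities each pipeline stage should
#' recover, used by the recovery tests.
#'
#' @param truth a [synthetic_truth()].
#' @return List with `N_H`, `c_general`, `c_hidden`, `aware_network`,
#'   `delta`, `tau`, `m0_expected`, `m1_expected`, `e1_expected` (the basic
#'   estimator's target `N_H * delta * tau`), and `prevalence_pct`.
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  fr <- truth$frame
  dt <- truth$delta_true * truth$tau_true
  list(
    N_H = truth$N_H,
    c_general = truth$c_true,
    c_hidden = truth$c_true * truth$delta_true,
    aware_network = truth$c_true * truth$delta_true * truth$tau_true,
    delta = truth$delta_true,
    tau = truth$tau_true,
    m0_expected = truth$c_true * fr$e0 / fr$t,
    m1_expected = truth$c_true * (truth$N_H / fr$t) * dt,
    e1_expected = truth$N_H * dt,
    prevalence_pct = 100 * truth$N_H / fr$adult_pop
  )
}

#' Write a complete synthetic study to disk
#'
#' Emits `general_survey.csv`, `rds_survey.csv`, `frame.yaml` and
#' `truth.json` into `dir` — the file set [run_estimate()] consumes.
#'
#' @param truth a [synthetic_truth()].
#' @param dir output directory (created if needed).
#' @param n_general general-survey sample size.
#' @param design an [rrt_design()].
#' @param seed master seed; the two surveys use derived substreams.
#' @param ... further arguments passed to [generate_rds_survey()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, dir, n_general = 1747,
                             design = rrt_design(), seed = 1, ...) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(seed, 2)
  gen <- generate_general_survey(truth, n = n_general, design = design,
                                 seed = seeds[1])
  rds <- generate_rds_survey(truth, seed = seeds[2], ...)
  utils::write.csv(as.data.frame(gen), file.path(dir, "general_survey.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(rds), file.path(dir, "rds_survey.csv"),
                   row.names = FALSE)
  write_frame(truth$frame, file.path(dir, "frame.yaml"))
  tr <- truth[setdiff(names(truth), "frame")]
  jsonlite::write_json(c(tr, truth_report(truth)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
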