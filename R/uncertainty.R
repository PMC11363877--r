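# Percentile bootstrap machinery. Three flavors: plain respondent (or whole-
# cluster) resampling for the general survey; a recruitment-chain bootstrap
# for the RDS survey that regrows the observed recruitment forest (resample
# seeds with replacement, then recursively resample each node's observed
# recruits with replacement, truncating at the observed maximum wave and the
# observed sample size); and a joint bootstrap that resamples both surveys
# independently and recomputes the whole estimation chain per resample, so
# RRT unmasking noise and RDS dependence both propagate into the final CIs.

#' Bootstrap settings
#'
#' @param B resample count (default 10,000 as in the reference analysis).
#' @param level nominal CI coverage in (0, 1); default 0.95.
#' @param seed master seed; each resample gets its own substream so results
#'   are reproducible and order-independent.
#' @param cluster_level resampling unit for the general survey: `"none"`
#'   (respondents), `"department"`, `"unit"` or `"industry"`.
#' @param rds_flavor `"chain"` (recruitment-forest bootstrap) or
#'   `"respondent"` (plain row resampling fallback).
#' @return An object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(B = 10000, level = 0.95, seed = NULL,
                           cluster_level = c("none", "department", "unit", "industry"),
                           rds_flavor = c("chain", "respondent")) {
  if (!is.numeric(B) || length(B) != 1L || is.na(B) || B < 1) {
    abort_stage("bootstrap_spec", "B must be a positive integer")
  }
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    abort_stage("bootstrap_spec", "level must lie in (0, 1)")
  }
  structure(list(B = as.integer(B), level = level, seed = seed,
                 cluster_level = match.arg(cluster_level),
                 rds_flavor = match.arg(rds_flavor)),
            class = "bootstrap_spec")
}

#' Percentile bootstrap for a general-survey statistic
#'
#' Resamples respondents (or whole clusters when `cluster_level` is set in the
#' spec) with replacement and recomputes `statistic` per resample. Aborts if
#' the statistic fails on more than 1% of resamples.
#'
#' @param table a [general_survey()] (any data.frame works; cluster resampling
#'   requires the named cluster column).
#' @param statistic function mapping a table to a numeric scalar.
#' @param spec a [bootstrap_spec()].
#' @return A [scaleup_estimate()] with percentile CI and the replicate vector.
#' @export
bootstrap_general <- function(table, statistic, spec = bootstrap_spec()) {
  stopifnot(is.function(statistic), inherits(spec, "bootstrap_spec"))
  point <- statistic(table)
  n <- nrow(table)
  seeds <- spawn_seeds(spec$seed, spec$B)
  cl <- spec$cluster_level
  if (cl != "none") {
    if (!cl %in% names(table)) {
      abort_stage("bootstrap_general", paste("no cluster column:", cl))
    }
    groups <- split(seq_len(n), table[[cl]])
  }
  reps <- vapply(seq_len(spec$B), function(b) {
    with_seed(seeds[b], {
      idx <- if (cl == "none") {
        sample.int(n, n, replace = TRUE)
      } else {
        unlist(groups[sample.int(length(groups), length(groups), replace = TRUE)],
               use.names = FALSE)
      }
      tryCatch(suppressMessages(statistic(table[idx, , drop = FALSE])),
               error = function(e) NA_real_)
    })
  }, numeric(1))
  fail <- mean(is.na(reps))
  if (fail > 0.01) {
    abort_stage("bootstrap_general", sprintf(
      "statistic failed on %.1f%% of resamples (> 1%% tolerated)", 100 * fail))
  }
  ci <- percentile_ci(reps, spec$level)
  scaleup_estimate(point, ci[1], ci[2], n = n, level = spec$level, B = spec$B,
                   replicates = reps)
}

# Build the recruitment forest of an rds_table: list of child row-indices per
# row, plus the seed row-indices and observed max wave.
build_forest <- function(rds) {
  id <- as.character(rds$id)
  recruiter <- as.character(rds$recruiter_id)
  recruiter[recruiter %in% c("", "NA")] <- NA_character_
  parent <- match(recruiter, id)
  if (any(is.na(parent) & !is.na(recruiter))) {
    abort_stage("rds_chain_bootstrap", "dangling recruiter_id")
  }
  n <- nrow(rds)
  children <- vector("list", n)
  kids <- which(!is.na(parent))
  for (k in kids) children[[parent[k]]] <- c(children[[parent[k]]], k)
  list(children = children, seeds = which(is.na(parent)),
       max_wave = max(rds$wave), n = n)
}

# One regrowth of the forest: seed chains are drawn with replacement and
# regrown (each node's observed recruits resampled with replacement,
# recursively, truncated at the observed max wave) until the observed sample
# size is reached, then truncated to exactly n rows. Drawing chains until n
# keeps every resample at the observed size even when an observed seed
# recruited nobody (otherwise a dead seed would yield degenerate two-row
# resamples a quarter of the time with two seeds).
regrow_forest <- function(forest) {
  out <- integer(0)
  ns <- length(forest$seeds)
  while (length(out) < forest$n) {
    frontier <- forest$seeds[sample.int(ns, 1L)]
    wave <- 0L
    while (length(frontier) && wave <= forest$max_wave &&
           length(out) < forest$n) {
      out <- c(out, frontier)
      nxt <- lapply(frontier, function(v) {
        kids <- forest$children[[v]]
        k <- length(kids)
        if (k) kids[sample.int(k, k, replace = TRUE)] else integer(0)
      })
      frontier <- unlist(nxt, use.names = FALSE)
      wave <- wave + 1L
    }
  }
  out[seq_len(forest$n)]
}

#' Recruitment-chain bootstrap for an RDS-survey statistic
#'
#' Respects the dependence induced by chain referral: each resample regrows
#' the recruitment forest — seed chains drawn with replacement, each selected
#' respondent's recruits resampled with replacement recursively, each chain
#' truncated at the observed maximum wave — until the observed sample size is
#' reached, then truncated to exactly that size. With
#' `spec$rds_flavor = "respondent"` a plain row bootstrap is used instead.
#'
#' @param rds an [rds_table()] (validated: the links form a forest).
#' @param statistic function mapping an RDS table to a numeric scalar.
#' @param spec a [bootstrap_spec()].
#' @return A [scaleup_estimate()].
#' @export
rds_chain_bootstrap <- function(rds, statistic, spec = bootstrap_spec()) {
  stopifnot(is.function(statistic), inherits(spec, "bootstrap_spec"))
  rds <- rds_table(as.data.frame(rds))  # re-validate links before resampling
  point <- statistic(rds)
  seeds <- spawn_seeds(spec$seed, spec$B)
  forest <- build_forest(rds)
  reps <- vapply(seq_len(spec$B), function(b) {
    with_seed(seeds[b], {
      idx <- if (spec$rds_flavor == "chain") regrow_forest(forest) else
        sample.int(forest$n, forest$n, replace = TRUE)
      tryCatch(statistic(rds[idx, , drop = FALSE]), error = function(e) NA_real_)
    })
  }, numeric(1))
  fail <- mean(is.na(reps))
  if (fail > 0.01) {
    abort_stage("rds_chain_bootstrap", sprintf(
      "statistic failed on %.1f%% of resamples (> 1%% tolerated)", 100 * fail))
  }
  ci <- percentile_ci(reps, spec$level)
  scaleup_estimate(point, ci[1], ci[2], n = forest$n, level = spec$level,
                   B = spec$B, replicates = reps)
}

#' Joint bootstrap of the full estimation chain
#'
#' Per resample: the general survey is resampled at respondent (or cluster)
#' level and the RDS survey via the chain bootstrap, independently; the whole
#' chain (m0 -> c, RRT unmasking -> m1 -> e1, c_H, aware, delta, tau, adjusted
#' size, prevalence) is recomputed from scratch, so every downstream CI
#' carries all upstream noise including RRT unmasking.
#'
#' @param general a [general_survey()].
#' @param rds an [rds_table()].
#' @param frame a [study_frame()].
#' @param design an [rrt_design()].
#' @param spec a [bootstrap_spec()].
#' @return List of [scaleup_estimate()]s, one per chain quantity
#'   (`m0`, `c`, `m1`, `e1`, `c_H`, `aware`, `delta`, `tau`, `adjusted`,
#'   `prevalence`), plus `replicates`, the B x 10 matrix of resampled chains.
#' @export
joint_pipeline_ci <- function(general, rds, frame, design = rrt_design(),
                              spec = bootstrap_spec()) {
  stopifnot(inherits(frame, "study_frame"), inherits(design, "rrt_design"),
            inherits(spec, "bootstrap_spec"))
  rds <- rds_table(as.data.frame(rds))
  general <- general_survey(as.data.frame(general))

  # Precompute per-row quantities once; resamples only index into them.
  ans_rows <- which(general$answered)
  if (length(ans_rows) == 0L) abort_stage("joint_pipeline_ci", "no answered rows")
  g_rs <- rowSums(known_matrix(general[ans_rows, , drop = FALSE]))
  g_answer <- general$rrt_answer[ans_rows]
  g_group <- as.character(general$rrt_group[ans_rows])
  r_known <- rowSums(known_matrix(rds))
  r_aware <- rowSums(aware_matrix(rds))
  scale <- frame$t / frame$e0
  n_g <- length(g_rs)

  cl <- spec$cluster_level
  if (cl != "none") {
    if (!cl %in% names(general)) {
      abort_stage("joint_pipeline_ci", paste("no cluster column:", cl))
    }
    groups <- split(seq_len(n_g), general[[cl]][ans_rows])
  }
  forest <- build_forest(rds)

  chain <- function(gi, ri) {
    m0 <- mean(g_rs[gi])
    cg <- m0 * scale
    a1 <- g_answer[gi][g_group[gi] == "1"]
    a2 <- g_answer[gi][g_group[gi] == "2"]
    if (length(a1) < 2L || length(a2) < 2L || cg <= 0) return(rep(NA_real_, 10))
    m1 <- unmask_mean(a1, a2, design)$mu_s
    e1 <- (m1 / cg) * frame$t
    c_H <- mean(r_known[ri]) * scale
    aware <- mean(r_aware[ri]) * scale
    if (c_H <= 0) return(rep(NA_real_, 10))
    delta <- c_H / cg
    tau <- aware / c_H
    adj <- if (delta * tau > 0) e1 / (delta * tau) else NA_real_
    c(m0, cg, m1, e1, c_H, aware, delta, tau, adj,
      100 * adj / frame$adult_pop)
  }

  point <- chain(seq_len(n_g), seq_len(forest$n))
  seeds <- spawn_seeds(spec$seed, spec$B)
  reps <- matrix(NA_real_, spec$B, 10)
  for (b in seq_len(spec$B)) {
    reps[b, ] <- with_seed(seeds[b], {
      gi <- if (cl == "none") sample.int(n_g, n_g, replace = TRUE) else
        unlist(groups[sample.int(length(groups), length(groups), replace = TRUE)],
               use.names = FALSE)
      ri <- if (spec$rds_flavor == "chain") regrow_forest(forest) else
        sample.int(forest$n, forest$n, replace = TRUE)
      chain(gi, ri)
    })
  }
  nm <- c("m0", "c", "m1", "e1", "c_H", "aware", "delta", "tau",
          "adjusted", "prevalence")
  colnames(reps) <- nm
  fail <- mean(is.na(reps[, "adjusted"]))
  if (fail > 0.01) {
    abort_stage("joint_pipeline_ci", sprintf(
      "chain failed on %.1f%% of resamples (> 1%% tolerated)", 100 * fail))
  }
  out <- lapply(seq_along(nm), function(j) {
    ci <- percentile_ci(reps[, j], spec$level)
    scaleup_estimate(point[j], ci[1], ci[2],
                     n = n_g, level = spec$level, B = spec$B)
  })
  names(out) <- nm
  out$replicates <- reps
  out
}
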