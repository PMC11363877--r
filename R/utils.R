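# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
abort_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. With seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# One master seed -> B reproducible substream seeds, so serial and chunked
# execution of a bootstrap agree resample-by-resample.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n, replace = TRUE))
}

percentile_ci <- function(x, level) {
  a <- (1 - level) / 2
  stats::quantile(x, probs = c(a, 1 - a), na.rm = TRUE, names = FALSE, type = 7)
}

is_count <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

#' Point estimate with a percentile bootstrap confidence interval
#'
#' Light container returned by the bootstrap routines: the statistic on the
#' full data plus the percentile interval over resamples.
#'
#' @param point numeric point estimate.
#' @param ci_low,ci_high interval endpoints (may be `NA` when no CI was
#'   requested).
#' @param n number of sampling units behind the point estimate.
#' @param level nominal coverage of the interval.
#' @param B number of bootstrap resamples.
#' @param replicates optional numeric vector of bootstrap replicates.
#' @return An object of class `scaleup_estimate`.
#' @export
scaleup_estimate <- function(point, ci_low = NA_real_, ci_high = NA_real_,
                             n = NA_integer_, level = NA_real_, B = NA_integer_,
                             replicates = NULL) {
  if (!is.na(ci_low) && !is.na(ci_high)) {
    if (!(ci_low <= ci_high)) stop("ci_low must be <= ci_high", call. = FALSE)
  }
  structure(
    list(point = point, ci_low = ci_low, ci_high = ci_high,
         n = n, level = level, B = B, replicates = replicates),
    class = "scaleup_estimate"
  )
}

#' @export
print.scaleup_estimate <- function(x, ...) {
  if (is.na(x$ci_low)) {
    cat(sprintf("%.4g (n = %s)\n", x$point, format(x$n)))
  } else {
    cat(sprintf("%.4g (%.0f%% CI %.4g-%.4g; B = %s, n = %s)\n",
                x$point, 100 * x$level, x$ci_low, x$ci_high,
                format(x$B), format(x$n)))
  }
  invisible(x)
}
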