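# Small in-code fixtures shared across test files.

# 10-name frame on a town of 100,000 (all names inside the 0.1-0.2% band).
tiny_frame <- function() {
  study_frame(
    t = 100000, adult_pop = 65000,
    known = data.frame(label = paste0("N", 1:10),
                       size = seq(105L, 195L, by = 10L))
  )
}

tiny_truth <- function(...) {
  args <- utils::modifyList(
    list(frame = tiny_frame(), N_H = 500, c_true = 80, delta_true = 0.6,
         tau_true = 0.8, degree_dispersion = 2, mu_unrelated = 5,
         nonresponse_rate = 0.05),
    list(...))
  do.call(synthetic_truth, args)
}

# Hand-built general survey: known row-sums and RRT columns fully controlled.
manual_general <- function(rowsums, frame = tiny_frame(), rrt_answer = NULL,
                           rrt_group = NULL, answered = NULL) {
  n <- length(rowsums)
  km <- matrix(0L, n, nrow(frame$known))
  km[, 1] <- rowsums  # put the whole row-sum in the first name group
  df <- data.frame(id = paste0("G", seq_len(n)), stringsAsFactors = FALSE)
  df[paste0("name_", frame$known$label)] <- as.data.frame(km)
  df$rrt_group <- rrt_group %||% rep(c(1L, 2L), length.out = n)
  df$rrt_answer <- rrt_answer %||% rep(0, n)
  df$answered <- answered %||% rep(TRUE, n)
  general_survey(df, frame)
}

# Hand-built RDS table: a single seed recruiting a chain, counts controlled.
manual_rds <- function(known_rows, aware_rows = known_rows,
                       frame = tiny_frame(),
                       recruiter = NULL, wave = NULL) {
  n <- nrow(known_rows)
  ids <- paste0("R", seq_len(n))
  df <- data.frame(
    id = ids,
    recruiter_id = recruiter %||% c(NA, ids[-n]),  # one chain by default
    wave = wave %||% (seq_len(n) - 1L),
    stringsAsFactors = FALSE)
  df[paste0("name_", frame$known$label)] <- as.data.frame(known_rows)
  df[paste0("aware_", frame$known$label)] <- as.data.frame(aware_rows)
  rds_table(df, frame)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
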