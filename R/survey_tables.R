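# Survey containers: validated data.frames for the general-population survey
# and the RDS survey of the hidden population. Both carry per-name-group alter
# counts in columns `name_<label>`; the RDS table additionally carries
# `aware_<label>` columns (alters aware of the respondent's hidden-group
# membership, necessarily <= the name count cell-wise).

name_cols <- function(df) grep("^name_", names(df), value = TRUE)
aware_cols <- function(df) grep("^aware_", names(df), value = TRUE)

#' Extract the known-population count matrix from a survey table
#'
#' @param table a `general_survey` or `rds_table` (any data.frame with
#'   `name_<label>` columns).
#' @return Integer matrix, one row per respondent, one column per name group.
#' @export
known_matrix <- function(table) {
  cols <- name_cols(table)
  if (length(cols) == 0L) abort_stage("known_matrix", "no name_<label> columns")
  m <- as.matrix(table[, cols, drop = FALSE])
  storage.mode(m) <- "numeric"
  colnames(m) <- sub("^name_", "", cols)
  m
}

#' Extract the awareness count matrix from an RDS table
#'
#' @param table an `rds_table`.
#' @return Numeric matrix aligned with [known_matrix()].
#' @export
aware_matrix <- function(table) {
  cols <- aware_cols(table)
  if (length(cols) == 0L) abort_stage("aware_matrix", "no aware_<label> columns")
  m <- as.matrix(table[, cols, drop = FALSE])
  storage.mode(m) <- "numeric"
  colnames(m) <- sub("^aware_", "", cols)
  m
}

#' Validate a general-population survey table
#'
#' Required columns: `id`, `rrt_group` (1/2), `rrt_answer`, `answered`
#' (logical; `FALSE` marks a blank answer sheet), plus one `name_<label>`
#' count column per known subpopulation. Optional cluster labels `industry`,
#' `unit`, `department` are kept for the cluster bootstrap. Rows with
#' `answered = FALSE` carry no counts (their count and answer cells are forced
#' to `NA`).
#'
#' @param df a data.frame with the columns above.
#' @param frame optional `study_frame`; when given, the `name_` columns must
#'   match its labels and are reordered to the ledger order.
#' @return The validated table, classed `general_survey`.
#' @export
general_survey <- function(df, frame = NULL) {
  if (!is.data.frame(df)) abort_stage("general_survey", "df must be a data.frame")
  need <- c("id", "rrt_group", "rrt_answer", "answered")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_stage("general_survey", paste("missing columns:", paste(miss, collapse = ", ")))
  }
  nm <- name_cols(df)
  if (length(nm) == 0L) abort_stage("general_survey", "no name_<label> count columns")
  if (!is.null(frame)) {
    want <- paste0("name_", frame$known$label)
    miss <- setdiff(want, nm)
    if (length(miss)) {
      abort_stage("general_survey", paste(
        "name columns do not match the study frame; missing:",
        paste(utils::head(miss, 5), collapse = ", ")))
    }
    other <- setdiff(names(df), want)
    df <- df[, c(other, want)]
    nm <- want
  }
  df$answered <- as.logical(df$answered)
  if (anyNA(df$answered)) abort_stage("general_survey", "answered must be TRUE/FALSE")
  # Missing counts read as unanswered.
  all_na <- rowSums(!is.na(as.matrix(df[, nm]))) == 0L
  df$answered[all_na] <- FALSE
  df[!df$answered, nm] <- NA
  df[!df$answered, "rrt_answer"] <- NA
  km <- as.matrix(df[df$answered, nm, drop = FALSE])
  if (nrow(km) > 0 && !all(is_count(km))) {
    abort_stage("general_survey", "name_<label> counts must be non-negative integers")
  }
  grp <- as.character(df$rrt_group)
  if (!all(grp %in% c("1", "2"))) {
    abort_stage("general_survey", "rrt_group values must be 1 or 2")
  }
  ans <- df$rrt_answer[df$answered]
  if (length(ans) && any(!is.na(ans) & ans < 0)) {
    abort_stage("general_survey", "rrt_answer must be non-negative")
  }
  class(df) <- unique(c("general_survey", class(df)))
  df
}

#' Validate an RDS survey table of the hidden population
#'
#' Required columns: `id`, `recruiter_id` (`NA`/empty for seeds), `wave`
#' (0 for seeds), `name_<label>` counts and matching `aware_<label>` counts.
#' Enforced invariants: `0 <= aware <= name` cell-wise; every `recruiter_id`
#' refers to an existing row of a strictly earlier wave (so the recruitment
#' graph is a forest rooted at the seeds); seeds are exactly the wave-0 rows.
#'
#' @param df a data.frame with the columns above.
#' @param frame optional `study_frame` used to check and order name columns.
#' @return The validated table, classed `rds_table`.
#' @export
rds_table <- function(df, frame = NULL) {
  if (!is.data.frame(df)) abort_stage("rds_table", "df must be a data.frame")
  need <- c("id", "recruiter_id", "wave")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_stage("rds_table", paste("missing columns:", paste(miss, collapse = ", ")))
  }
  nm <- name_cols(df); aw <- aware_cols(df)
  if (length(nm) == 0L) abort_stage("rds_table", "no name_<label> count columns")
  if (length(aw) == 0L) abort_stage("rds_table", "no aware_<label> count columns")
  labs_nm <- sub("^name_", "", nm); labs_aw <- sub("^aware_", "", aw)
  if (!setequal(labs_nm, labs_aw)) {
    abort_stage("rds_table", "name_ and aware_ columns must cover the same labels")
  }
  if (!is.null(frame)) {
    if (!setequal(labs_nm, frame$known$label)) {
      abort_stage("rds_table", "name columns do not match the study frame labels")
    }
    labs_nm <- frame$known$label
  }
  nm <- paste0("name_", labs_nm); aw <- paste0("aware_", labs_nm)
  other <- setdiff(names(df), c(nm, aw))
  df <- df[, c(other, nm, aw)]
  km <- as.matrix(df[, nm]); am <- as.matrix(df[, aw])
  storage.mode(km) <- "numeric"; storage.mode(am) <- "numeric"
  if (!all(is_count(km)) || !all(is_count(am))) {
    abort_stage("rds_table", "name_/aware_ counts must be non-negative integers")
  }
  if (any(am > km)) {
    bad <- which(am > km, arr.ind = TRUE)[1, ]
    abort_stage("rds_table", sprintf(
      "aware count exceeds name count (row %d, group %s): awareness is a subset of ties",
      bad[1], labs_nm[bad[2]]))
  }
  df$recruiter_id <- as.character(df$recruiter_id)
  df$recruiter_id[df$recruiter_id %in% c("", "NA")] <- NA_character_
  id <- as.character(df$id)
  if (anyDuplicated(id)) abort_stage("rds_table", "duplicate respondent ids")
  wave <- df$wave
  if (!all(is_count(wave))) abort_stage("rds_table", "wave must be a non-negative integer")
  is_seed <- is.na(df$recruiter_id)
  if (!any(is_seed)) abort_stage("rds_table", "no seeds (rows with empty recruiter_id)")
  if (any(wave[is_seed] != 0)) abort_stage("rds_table", "seeds must have wave 0")
  if (any(wave[!is_seed] == 0)) abort_stage("rds_table", "wave-0 rows must be seeds")
  ridx <- match(df$recruiter_id[!is_seed], id)
  if (anyNA(ridx)) {
    abort_stage("rds_table", "dangling recruiter_id: recruiter not present in the table")
  }
  if (any(wave[ridx] >= wave[!is_seed])) {
    abort_stage("rds_table",
                "recruiter must belong to a strictly earlier wave (no cycles)")
  }
  class(df) <- unique(c("rds_table", class(df)))
  df
}

#' Read a general survey from CSV
#'
#' @param path CSV file with the [general_survey()] columns.
#' @param frame optional `study_frame` for column validation.
#' @return A `general_survey`.
#' @export
read_general_survey <- function(path, frame = NULL) {
  if (!file.exists(path)) abort_stage("read_general_survey", paste("no such file:", path))
  general_survey(utils::read.csv(path, stringsAsFactors = FALSE), frame = frame)
}

#' Read an RDS survey from CSV
#'
#' @param path CSV file with the [rds_table()] columns.
#' @param frame optional `study_frame` for column validation.
#' @return An `rds_table`.
#' @export
read_rds_survey <- function(path, frame = NULL) {
  if (!file.exists(path)) abort_stage("read_rds_survey", paste("no such file:", path))
  rds_table(utils::read.csv(path, stringsAsFactors = FALSE), frame = frame)
}
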