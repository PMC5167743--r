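#' Write and read multi-subject two-step trial tables as CSV
#'
#' One row per trial with a `subject_id` column; columns are validated on
#' read with an informative error naming anything missing.
#'
#' @param sessions Named list of per-subject trial data frames.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); named list of per-subject trial data
#'   frames (reader).
#' @export
write_trials_csv <- function(sessions, path) {
  rows <- lapply(names(sessions), function(id)
    cbind(data.frame(subject_id = id, stringsAsFactors = FALSE),
          sessions[[id]]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "t", "a1", "state2", "transition", "a2", "r",
            "valid", "practice")
  check_columns(df, need, "trial table")
  split_subjects(df)
}

#' Write and read instrumental-task phase records as CSV
#'
#' All four phases of all subjects in one long table, with `subject_id` and
#' `phase` columns.
#'
#' @param slips Named list (one element per subject) of named lists of phase
#'   record data frames, as produced by [simulate_slips_subject()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); the nested list (reader).
#' @export
write_slips_csv <- function(slips, path) {
  rows <- list()
  for (id in names(slips)) {
    for (ph in names(slips[[id]])) {
      rec <- slips[[id]][[ph]]
      common <- c("phase", "block", "trial", "response", "correct")
      extra <- setdiff(names(rec), common)
      rec <- cbind(data.frame(subject_id = id, stringsAsFactors = FALSE),
                   rec[c("phase", "block", "trial", extra,
                         "response", "correct")])
      rows[[length(rows) + 1L]] <- rec
    }
  }
  # phases have different columns; take the union
  cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (c in setdiff(cols, names(r))) r[[c]] <- NA
    r[cols]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_slips_csv
#' @export
read_slips_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "phase", "block", "trial", "response",
                      "correct"), "phase records")
  out <- lapply(split_subjects(df), function(sub) {
    phases <- split(sub, sub$phase)
    lapply(phases, function(p) {
      p$subject_id <- NULL
      p <- p[, colSums(is.na(p)) < nrow(p), drop = FALSE]  # drop unused cols
      rownames(p) <- NULL
      p
    })
  })
  out
}

#' Write and read a fitted parameter table as CSV
#'
#' @param params Data frame from [em_params_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); the data frame (reader).
#' @export
write_params_csv <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params_csv
#' @export
read_params_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", param_names(), "beta_mb", "beta_mf",
                      "nll"), "parameter table")
  df
}

#' Serialize a group prior (or any parameter set) to JSON
#'
#' The scale is tagged explicitly so natural- and transformed-scale vectors
#' cannot be confused on re-import.
#'
#' @param prior A [group_prior()].
#' @param path Output JSON path.
#' @return `path`, invisibly (writer); a [group_prior()] (reader).
#' @export
write_prior_json <- function(prior, path) {
  stopifnot(inherits(prior, "group_prior"))
  jsonlite::write_json(list(scale = "transformed",
                            mean = as.list(prior$mean),
                            var = as.list(prior$var)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prior_json
#' @export
read_prior_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$scale, "transformed"))
    stop("prior JSON must be tagged scale = \"transformed\"", call. = FALSE)
  group_prior(unlist(x$mean)[param_names()], unlist(x$var)[param_names()])
}

check_columns <- function(df, need, what) {
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

split_subjects <- function(df) {
  ids <- unique(df$subject_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$subject_id == id, , drop = FALSE]
    sub$subject_id <- NULL
    rownames(sub) <- NULL
    sub
  })
  names(out) <- ids
  out
}
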