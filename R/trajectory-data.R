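#' Construct a trajectory dataset
#'
#' A trajectory dataset is a long-format table of repeated measures: one row
#' per subject-visit, with a subject identifier, an observation time (for
#' example age in years) and an outcome value (for example BMI in kg/m2).
#' Subjects may contribute different numbers of observations at different
#' times; the only structural requirements are that every `(id, time)` pair is
#' unique and that all times and outcomes are finite.
#'
#' An optional plausibility window drops rows whose outcome falls outside
#' `[window[1], window[2]]`; the number of rows removed is recorded in the
#' `"n_dropped"` attribute so exclusions are always reported, never silent.
#'
#' @param df data.frame containing at least the mapped columns.
#' @param columns named character vector mapping the roles `id`, `time`, `y`
#'   to column names in `df`. Default `c(id = "id", time = "time", y = "y")`.
#' @param window optional numeric length-2 vector `c(y_min, y_max)`; rows with
#'   `y` outside the closed interval are dropped and counted. Default `NULL`
#'   (no filtering).
#' @return An object of class `trajectory_data`: a data.frame with columns
#'   `id` (character), `time` (numeric), `y` (numeric), rows sorted by subject
#'   (order of first appearance) then time, with attributes `n_subjects` and
#'   `n_dropped`.
#' @examples
#' df <- data.frame(id = 1, time = c(18, 35, 50), y = c(21, 24, 26))
#' td <- trajectory_data(df)
#' attr(td, "n_subjects")
#' @export
trajectory_data <- function(df, columns = c(id = "id", time = "time", y = "y"),
                            window = NULL) {
  need <- c("id", "time", "y")
  if (!all(need %in% names(columns))) {
    stop("`columns` must map the roles: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(unname(columns[need]), names(df))
  if (length(missing_cols)) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    id   = as.character(df[[columns[["id"]]]]),
    time = as.numeric(df[[columns[["time"]]]]),
    y    = as.numeric(df[[columns[["y"]]]]),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) stop("dataset contains no observations", call. = FALSE)
  if (anyNA(out$id)) stop("missing subject identifiers", call. = FALSE)
  if (!all(is.finite(out$time))) stop("non-finite time values", call. = FALSE)
  if (!all(is.finite(out$y))) stop("non-finite outcome values", call. = FALSE)

  n_dropped <- 0L
  if (!is.null(window)) {
    stopifnot(is.numeric(window), length(window) == 2L, window[1] < window[2])
    keep <- out$y >= window[1] & out$y <= window[2]
    n_dropped <- sum(!keep)
    out <- out[keep, , drop = FALSE]
    if (nrow(out) == 0L) {
      stop("all observations fall outside the plausibility window",
           call. = FALSE)
    }
  }

  dup <- duplicated(out[c("id", "time")])
  if (any(dup)) {
    bad <- unique(out$id[dup])
    stop("duplicate (subject, time) pairs for subject(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }

  # stable subject order: first appearance; observations sorted by time within
  subj <- unique(out$id)
  out <- out[order(match(out$id, subj), out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("trajectory_data", "data.frame"),
            n_subjects = length(subj),
            n_dropped = n_dropped)
}

#' Read a long-format trajectory CSV
#'
#' Reads a delimited text file with one row per subject-visit and returns a
#' [trajectory_data] object. Column names are configurable; the default
#' convention is `id,time,y`.
#'
#' @param path path to a CSV file.
#' @inheritParams trajectory_data
#' @param sep field separator, default `","`.
#' @return A [trajectory_data] object; `attr(x, "n_dropped")` reports rows
#'   removed by the plausibility window.
#' @seealso [write_trajectories()]
#' @export
read_trajectories <- function(path, columns = c(id = "id", time = "time", y = "y"),
                              window = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty input file: ", path, call. = FALSE)
  trajectory_data(df, columns = columns, window = window)
}

#' Write a trajectory dataset as long-format CSV
#'
#' @param x a [trajectory_data] object (or data.frame with `id,time,y`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("id", "time", "y")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.trajectory_data <- function(x, ...) {
  cat(sprintf("Trajectory data: %d subjects, %d observations\n",
              attr(x, "n_subjects"), nrow(x)))
  obs <- table(x$id)
  cat(sprintf("  observations per subject: %d-%d (median %g)\n",
              min(obs), max(obs), stats::median(obs)))
  cat(sprintf("  time range: [%g, %g]   outcome range: [%g, %g]\n",
              min(x$time), max(x$time), min(x$y), max(x$y)))
  if (attr(x, "n_dropped") > 0L)
    cat(sprintf("  rows dropped by plausibility window: %d\n",
                attr(x, "n_dropped")))
  invisible(x)
}

#' Subject identifiers in canonical order
#' @param x a [trajectory_data] object.
#' @return character vector of subject ids, in the dataset's stable order.
#' @export
subjects <- function(x) unique(x$id)
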