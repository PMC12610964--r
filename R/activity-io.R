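#' Read an aggregated activity table
#'
#' Reads a CSV (or TSV) table of per-interval activity durations in the
#' standard sensor-export layout: one row per aggregation interval with
#' columns `No`, `T`, `H`, `THI`, the six behavioural duration columns
#' (`F`, `M`, `L`, `S`, `RS`, `RL`, minutes) and `TOTAL_MIN`, the interval
#' length in minutes. Header matching is case-insensitive; row order is
#' preserved. Row indices are 1-based in files and kept as-is in the
#' returned table.
#'
#' @param path path to the CSV/TSV file.
#' @param state_space a [state_space()]; its labels name the nine variable
#'   columns expected in the header.
#' @param sep field separator, `","` by default; pass `"\t"` for TSV.
#' @param interval_minutes nominal aggregation interval (1440 for daily
#'   rows; 15 and 1 are the other supported resolutions). Stored as an
#'   attribute; per-row lengths come from `TOTAL_MIN`.
#' @param cow_id optional animal identifier stored with the table.
#' @return A data frame of class `activity_table` with the columns above,
#'   attributes `state_space`, `interval_minutes` and `cow_id`.
#' @seealso [validate_activity_table()], [write_activity_table()]
#' @examples
#' path <- system.file("extdata", "activity_daily_30d.csv", package = "cattlemc")
#' tab <- read_activity_table(path)
#' tab$L[1]  # minutes spent lying on day 1
#' @export
read_activity_table <- function(path, state_space = cattlemc::state_space(),
                                sep = ",", interval_minutes = 1440,
                                cow_id = NA_character_) {
  if (!file.exists(path)) {
    stop("activity table file not found: ", path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           colClasses = "character", fileEncoding = "UTF-8")
  wanted <- c("No", state_space$labels, "TOTAL_MIN")
  pos <- match(toupper(wanted), toupper(names(raw)))
  if (anyNA(pos)) {
    stop("activity table is missing required column(s): ",
         paste(wanted[is.na(pos)], collapse = ", "))
  }
  raw <- raw[, pos, drop = FALSE]
  names(raw) <- wanted
  if (nrow(raw) == 0L) {
    stop("activity table contains no records")
  }
  for (col in wanted) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           ": '", raw[[col]][bad[1]], "'")
    }
    raw[[col]] <- vals
  }
  structure(raw,
            class = c("activity_table", "data.frame"),
            state_space = state_space,
            interval_minutes = interval_minutes,
            cow_id = cow_id)
}

#' Write an activity table to CSV
#'
#' Inverse of [read_activity_table()]; numeric cells are written with full
#' precision so a read-write-read round trip reproduces every value.
#'
#' @param table an `activity_table`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(table, path, sep = ",") {
  utils::write.table(as.data.frame(table), path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate internal consistency of an activity table
#'
#' A row passes when its six behavioural durations are non-negative and sum
#' exactly to its own `TOTAL_MIN`, temperature and humidity are finite, and
#' humidity lies in [0, 100]. The check is against each row's own recorded
#' interval length, not a fixed constant, so tables with heterogeneous
#' interval lengths (e.g. one short day) validate cleanly. The input is
#' never modified.
#'
#' @param table an `activity_table` (or data frame with the same columns).
#' @param tol numeric tolerance on the duration sum, default 1e-8.
#' @return A data frame with one row per record: `row`, `pass` (logical)
#'   and `message` (empty when the row passes).
#' @examples
#' tab <- read_activity_table(system.file("extdata", "activity_daily_30d.csv",
#'                                        package = "cattlemc"))
#' report <- validate_activity_table(tab)
#' all(report$pass)
#' @export
validate_activity_table <- function(table, tol = 1e-8) {
  ss <- attr(table, "state_space")
  if (is.null(ss)) ss <- state_space()
  beh <- ss$behavioral
  msgs <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    problems <- character(0)
    durs <- as.numeric(table[i, beh])
    if (anyNA(durs) || any(!is.finite(durs))) {
      problems <- c(problems, "non-finite duration")
    } else {
      if (any(durs < 0)) problems <- c(problems, "negative duration")
      s <- sum(durs)
      if (abs(s - table$TOTAL_MIN[i]) > tol) {
        problems <- c(problems,
                      sprintf("duration sum %s != total %s",
                              format(s), format(table$TOTAL_MIN[i])))
      }
    }
    # NA environment = not recorded (sequence-only aggregates); only
    # recorded values must be finite and in range
    if ((!is.na(table$T[i]) && !is.finite(table$T[i])) ||
        (!is.na(table$H[i]) && !is.finite(table$H[i]))) {
      problems <- c(problems, "non-finite T or H")
    } else if (!is.na(table$H[i]) &&
               (table$H[i] < 0 || table$H[i] > 100)) {
      problems <- c(problems, "humidity outside [0, 100]")
    }
    msgs[i] <- paste(problems, collapse = "; ")
  }
  data.frame(row = seq_len(nrow(table)), pass = msgs == "", message = msgs,
             stringsAsFactors = FALSE)
}

#' Read a state sequence file
#'
#' One state label per line, plain text.
#'
#' @param path input file.
#' @param state_space a [state_space()]; every label in the file must be a
#'   member.
#' @param step_seconds sampling step of the sequence, in seconds.
#' @return A character vector of class `state_sequence` with attributes
#'   `state_space` and `step_seconds`.
#' @export
read_state_sequence <- function(path, state_space = cattlemc::state_space(),
                                step_seconds = 60) {
  if (!file.exists(path)) stop("state sequence file not found: ", path)
  labels <- readLines(path, encoding = "UTF-8")
  labels <- labels[nzchar(labels)]
  state_sequence(labels, state_space, step_seconds)
}

#' Construct a state sequence
#'
#' @param labels character vector of state labels, in time order.
#' @inheritParams read_state_sequence
#' @return A `state_sequence` object.
#' @export
state_sequence <- function(labels, state_space = cattlemc::state_space(),
                           step_seconds = 60) {
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), state_space$labels)
  if (length(unknown)) {
    stop("sequence contains labels outside the state space: ",
         paste(unknown, collapse = ", "))
  }
  structure(labels, class = "state_sequence", state_space = state_space,
            step_seconds = step_seconds)
}

#' @export
print.state_sequence <- function(x, ...) {
  cat("State sequence of length", length(x), "(step",
      attr(x, "step_seconds"), "s)\n")
  n <- min(20L, length(x))
  cat("  ", paste(unclass(x)[seq_len(n)], collapse = " "),
      if (length(x) > n) "...\n" else "\n")
  invisible(x)
}

#' Write a state sequence file
#'
#' @param seq a `state_sequence` (or character vector of labels).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_state_sequence <- function(seq, path) {
  writeLines(as.character(seq), path, useBytes = FALSE)
  invisible(path)
}

#' Load a labelled transition matrix from CSV
#'
#' Expects a square numeric matrix with a header row and a leading label
#' column, both matching the state-space order. Entries must be
#' non-negative and no row may sum to zero. Rows are renormalised to sum
#' exactly to one (printed matrices rounded to three decimals typically
#' have row sums slightly off 1); the original row sums are kept in the
#' `row_sums_original` attribute for diagnostics.
#'
#' @param path path to the matrix CSV.
#' @param state_space a [state_space()] fixing label order.
#' @return A [transition_matrix()] with `source = "printed"`.
#' @examples
#' P <- load_transition_matrix(system.file("extdata",
#'        "transition_matrix_9state.csv", package = "cattlemc"))
#' attr(P, "row_sums_original")[1]  # 0.996 before renormalisation
#' @export
load_transition_matrix <- function(path, state_space = cattlemc::state_space()) {
  if (!file.exists(path)) stop("transition matrix file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    stop("transition matrix must be square; got ", nrow(m), "x", ncol(m))
  }
  if (!identical(lab, colnames(m))) {
    stop("row labels and column labels disagree")
  }
  rownames(m) <- lab
  if (!setequal(lab, state_space$labels)) {
    stop("matrix labels do not match the state space: expected ",
         paste(state_space$labels, collapse = ", "))
  }
  m <- m[state_space$labels, state_space$labels, drop = FALSE]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("transition matrix contains non-numeric cells")
  if (any(m < 0)) stop("transition matrix contains negative entries")
  renormalize_rows(m, state_space = state_space, source = "printed")
}

#' Write a transition matrix to CSV
#'
#' @param matrix a `transition_matrix` (or labelled square matrix).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(matrix, path) {
  df <- data.frame(state = rownames(matrix), as.data.frame(unclass(matrix)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Paths to the bundled example data
#'
#' The package ships small plain-text reference datasets from a
#' sensor-monitored dairy herd (five Holstein cows observed over one summer
#' month): a 30-day daily activity table for one cow, the nine-state
#' transition matrix derived from it, its stationary distribution rounded
#' to three decimals, and the simulation error table (AAE/AES/RMSE per cow
#' at 3000/4000/5000 iterations).
#'
#' @param which one of `"activity"`, `"matrix"`, `"stationary"`, `"errors"`.
#' @return The file path of the requested dataset.
#' @export
cattlemc_example <- function(which = c("activity", "matrix", "stationary",
                                       "errors")) {
  which <- match.arg(which)
  file <- switch(which,
                 activity = "activity_daily_30d.csv",
                 matrix = "transition_matrix_9state.csv",
                 stationary = "stationary_9state.csv",
                 errors = "simulation_errors_5cows.csv")
  system.file("extdata", file, package = "cattlemc", mustWork = TRUE)
}
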