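#' Validate a subject-level cohort table
#'
#' A cohort table has one row per subject with the columns `subject_id`,
#' `entry_age` (delayed-entry age in years), `exit_age` (event or censoring
#' age), `event` (0/1), `positive_at_first_visit` (0/1, left-censored case),
#' plus any number of numeric covariate columns.  Enforced invariants:
#' `exit_age > entry_age`, `positive_at_first_visit` implies `event`, no
#' missing values in required columns, unique subject ids.
#'
#' @param records data frame in the cohort schema.
#' @return The validated data frame, with `event` and
#'   `positive_at_first_visit` coerced to integer 0/1, invisibly usable
#'   downstream.
#' @export
validate_cohort <- function(records) {
  req <- c("subject_id", "entry_age", "exit_age", "event",
           "positive_at_first_visit")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("cohort table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  records <- as.data.frame(records)
  for (cl in setdiff(req, "subject_id")) {
    if (anyNA(records[[cl]])) {
      stop("missing values forbidden in required column '", cl, "' (rows ",
           paste(utils::head(which(is.na(records[[cl]]))), collapse = ", "),
           ")")
    }
  }
  if (anyDuplicated(records$subject_id)) {
    stop("duplicate subject_id in cohort table")
  }
  records$event <- as.integer(records$event != 0)
  records$positive_at_first_visit <-
    as.integer(records$positive_at_first_visit != 0)
  bad <- which(!(records$exit_age > records$entry_age))
  if (length(bad)) {
    stop("exit_age must exceed entry_age (violated at row ",
         bad[1L], ")")
  }
  bad <- which(records$positive_at_first_visit == 1L & records$event == 0L)
  if (length(bad)) {
    stop("positive_at_first_visit implies event (violated at row ",
         bad[1L], ")")
  }
  if (any(records$entry_age < 0)) stop("entry_age must be >= 0")
  records
}

#' Read / write cohort and measurement tables
#'
#' Plain CSV with a header row, UTF-8.  The measurement table is long format
#' with columns `subject_id`, `age`, `value` and strictly increasing ages
#' within subject; it carries a time-varying covariate such as an exposure
#' re-measured at study visits.
#'
#' @param path file path.
#' @return `read_cohort`: validated cohort data frame.
#' @export
read_cohort <- function(path) {
  validate_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @export
read_measurements <- function(path) {
  validate_measurements(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @param x data frame to write.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
validate_measurements <- function(x) {
  req <- c("subject_id", "age", "value")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("measurement table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  x <- as.data.frame(x)
  if (anyNA(x$age) || anyNA(x$value)) {
    stop("missing values forbidden in measurement table")
  }
  ord <- order(x$subject_id, x$age)
  x <- x[ord, , drop = FALSE]
  dup <- stats::ave(x$age, x$subject_id,
                    FUN = function(a) c(1, diff(a)))
  if (any(dup <= 0)) {
    stop("measurement ages must be strictly increasing within subject")
  }
  rownames(x) <- NULL
  x
}

#' Exclude left-censored cases
#'
#' Removes subjects who were already event-positive at their first study
#' visit: their onset age is unknown (only an upper bound is observed), so
#' they cannot contribute to an analysis that treats the event age as the
#' first positive visit.  Order of the retained records is preserved.
#'
#' @param records validated cohort table.
#' @return list with `retained` (cohort table) and `n_removed` (count).
#' @export
exclude_left_censored <- function(records) {
  if (nrow(records) == 0L) {
    return(list(retained = records, n_removed = 0L))
  }
  records <- validate_cohort(records)
  drop <- records$positive_at_first_visit == 1L
  list(retained = records[!drop, , drop = FALSE],
       n_removed = sum(drop))
}

#' Expand a cohort to counting-process episodes
#'
#' Converts subject-level records (and optionally a long-format measurement
#' table for one time-varying covariate) to episodes: half-open intervals
#' `(start, stop]` on which every covariate is constant, with an event flag
#' at `stop` of the final episode.  With measurements, each subject's
#' follow-up is split at its own measurement ages and the covariate value is
#' carried forward from the most recent measurement at or before the episode
#' start (LOCF).  Time before a subject's first measurement contributes no
#' risk: the subject enters the expanded data at the first measurement age
#' (values for unmeasured exposure are never fabricated).
#'
#' @param records validated cohort table.
#' @param measurements optional measurement table (see
#'   [read_measurements()]); subjects present in `records` but absent from
#'   the measurement table are dropped with a message (they carry no
#'   exposure information).
#' @param tv_name column name for the time-varying covariate in the episode
#'   table.
#' @param carry carry rule for measurement values; only
#'   `"locf"` (last observation carried forward) is supported.
#' @param on_unusable what to do with a subject whose measurement series
#'   has no observation before `exit_age` (so the subject contributes no
#'   risk time): `"error"` (default) or `"drop"` with a message — the
#'   assessment pipeline uses `"drop"`, since a single sample taken at the
#'   exit visit is a normal occurrence in visit-based cohorts.
#' @return Episode data frame with columns `subject_id`, `start`, `stop`,
#'   `event`, fixed covariate columns, and (if measurements were given) the
#'   `tv_name` column.  Attribute `n_dropped_no_series` counts subjects
#'   dropped for lack of measurements.
#' @export
expand_counting_process <- function(records, measurements = NULL,
                                    tv_name = "exposure", carry = "locf",
                                    on_unusable = c("error", "drop")) {
  carry <- match.arg(carry, "locf")
  on_unusable <- match.arg(on_unusable)
  records <- validate_cohort(records)
  fixed <- setdiff(names(records),
                   c("subject_id", "entry_age", "exit_age", "event",
                     "positive_at_first_visit"))
  if (is.null(measurements)) {
    ep <- data.frame(subject_id = records$subject_id,
                     start = records$entry_age,
                     stop = records$exit_age,
                     event = records$event,
                     records[fixed],
                     check.names = FALSE)
    rownames(ep) <- NULL
    return(ep)
  }
  measurements <- validate_measurements(measurements)
  unknown <- setdiff(unique(measurements$subject_id), records$subject_id)
  if (length(unknown)) {
    stop("measurement series for unknown subject(s): ",
         paste(utils::head(unknown), collapse = ", "))
  }
  meas_by <- split(measurements[c("age", "value")],
                   measurements$subject_id)
  has_series <- records$subject_id %in% names(meas_by)
  n_dropped <- sum(!has_series)
  if (n_dropped > 0L) {
    message(n_dropped,
            " subject(s) without a measurement series dropped from the ",
            "counting-process expansion")
  }
  kept <- records[has_series, , drop = FALSE]
  pieces <- vector("list", nrow(kept))
  n_unusable <- 0L
  for (i in seq_len(nrow(kept))) {
    rec <- kept[i, , drop = FALSE]
    m <- meas_by[[as.character(rec$subject_id)]]
    usable <- m$age < rec$exit_age
    if (!any(usable)) {
      if (on_unusable == "error") {
        stop("no usable measurement for subject '", rec$subject_id,
             "': all measurement ages are at or after exit_age")
      }
      n_unusable <- n_unusable + 1L
      next
    }
    m <- m[usable, , drop = FALSE]
    risk_start <- max(rec$entry_age, m$age[1L])
    cuts <- m$age[m$age > risk_start & m$age < rec$exit_age]
    bounds <- c(risk_start, cuts, rec$exit_age)
    ns <- length(bounds) - 1L
    starts <- bounds[-length(bounds)]
    # LOCF: value of the latest measurement at or before each episode start
    vals <- m$value[findInterval(starts, m$age)]
    piece <- data.frame(subject_id = rep(rec$subject_id, ns),
                        start = starts,
                        stop = bounds[-1L],
                        event = c(rep(0L, ns - 1L), rec$event),
                        check.names = FALSE)
    for (cl in fixed) piece[[cl]] <- rec[[cl]]
    piece[[tv_name]] <- vals
    pieces[[i]] <- piece
  }
  if (n_unusable > 0L) {
    message(n_unusable,
            " subject(s) with no measurement before exit_age dropped")
  }
  ep <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  rownames(ep) <- NULL
  attr(ep, "n_dropped_no_series") <- n_dropped
  attr(ep, "n_dropped_no_usable") <- n_unusable
  ep
}

# Validate an episode table for model fitting: required columns, finite
# half-open intervals with start < stop, named covariates present and
# numeric, per-subject episodes non-overlapping with events only on a
# subject's final episode.
validate_episodes <- function(episodes, covariates = character()) {
  req <- c("subject_id", "start", "stop", "event")
  miss <- setdiff(req, names(episodes))
  if (length(miss)) {
    stop("episode table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  miss <- setdiff(covariates, names(episodes))
  if (length(miss)) {
    stop("covariate(s) not found in episode table: ",
         paste(miss, collapse = ", "))
  }
  ep <- as.data.frame(episodes)
  if (!all(is.finite(ep$start)) || !all(is.finite(ep$stop))) {
    stop("episode start/stop must be finite")
  }
  if (any(ep$stop <= ep$start)) {
    stop("episodes must satisfy start < stop")
  }
  for (cl in covariates) {
    if (!is.numeric(ep[[cl]]) || anyNA(ep[[cl]])) {
      stop("covariate '", cl, "' must be numeric with no missing values")
    }
  }
  ep$event <- as.integer(ep$event != 0)
  sid <- as.character(ep$subject_id)
  ord <- order(sid, ep$start)
  s <- ep[ord, , drop = FALSE]
  same <- sid[ord][-1L] == sid[ord][-length(ord)]
  if (length(same) && any(same & s$start[-1L] < s$stop[-nrow(s)] - 1e-12)) {
    stop("episodes of one subject must not overlap")
  }
  ev <- s$event[-nrow(s)] == 1L
  if (length(same) && any(same & ev)) {
    stop("only the final episode of a subject may carry the event")
  }
  ep
}

# Split episodes at the given interior times (used to evaluate
# time-interaction terms at event times).  Fully vectorised; covariate
# columns are carried onto the sub-intervals unchanged, the event flag moves
# to the last sub-interval.
split_episodes_at <- function(episodes, times) {
  tt <- sort(unique(times))
  if (!length(tt)) return(episodes)
  a <- findInterval(episodes$start, tt)              # tt <= start
  b <- findInterval(episodes$stop, tt, left.open = TRUE)  # tt <  stop
  reps <- pmax(b - a, 0L) + 1L
  idx <- rep(seq_len(nrow(episodes)), reps)
  s <- sequence(reps)
  last <- s == reps[idx]
  first <- s == 1L
  new_start <- numeric(length(idx))
  new_start[first] <- episodes$start[idx[first]]
  new_start[!first] <- tt[(a[idx] + s - 1L)[!first]]
  new_stop <- numeric(length(idx))
  new_stop[last] <- episodes$stop[idx[last]]
  new_stop[!last] <- tt[(a[idx] + s)[!last]]
  out <- episodes[idx, , drop = FALSE]
  out$start <- new_start
  out$stop <- new_stop
  out$event <- ifelse(last, episodes$event[idx], 0L)
  rownames(out) <- NULL
  out
}
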