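#' Replicate concentration-vs-time data for one treatment
#'
#' A `timecourse` is the package's container for the raw observations of one
#' degradation experiment: typically triplicate flasks sampled over 28 days.
#' It is a data frame with columns `time_days`, `replicate` and
#' `concentration_mg_L`, plus attributes carrying the treatment label, the
#' nominal starting concentration and whether the series is a non-inoculated
#' abiotic control.
#'
#' Validation enforces the design the analysis assumes: at least four
#' distinct time points, at least one observation at time zero, finite
#' concentrations, and times sorted increasing (unsorted input is sorted
#' with a message).
#'
#' @param time_days sampling times (days, non-negative).
#' @param replicate replicate identifier (coerced to character).
#' @param concentration_mg_L measured concentrations (mg/L; may be slightly
#'   negative from instrument noise — clipping happens at fit time).
#' @param treatment free-text treatment label.
#' @param nominal_M0 nominal initial concentration (mg/L); defaults to the
#'   mean of the observations at time zero.
#' @param is_control logical; `TRUE` for non-inoculated sterile controls.
#' @return A data frame of class `"timecourse"`.
#' @examples
#' tc <- timecourse(time_days = rep(c(0, 1, 3, 7, 14), each = 2),
#'                  replicate = rep(1:2, 5),
#'                  concentration_mg_L = c(10, 10.2, 6, 6.1, 3, 2.9, 1, 1.2, 0.2, 0.1))
#' summary_times(tc)
#' @export
timecourse <- function(time_days, replicate, concentration_mg_L,
                       treatment = "", nominal_M0 = NULL,
                       is_control = FALSE) {
  if (!is.numeric(time_days) || anyNA(time_days) || any(time_days < 0))
    stop("'time_days' must be non-negative numbers", call. = FALSE)
  if (!is.numeric(concentration_mg_L) || any(!is.finite(concentration_mg_L)))
    stop("'concentration_mg_L' must be finite numbers", call. = FALSE)
  n <- length(time_days)
  if (length(replicate) != n || length(concentration_mg_L) != n)
    stop("'time_days', 'replicate' and 'concentration_mg_L' must have equal length",
         call. = FALSE)
  if (length(unique(time_days)) < 4L)
    stop("a timecourse needs at least 4 distinct time points", call. = FALSE)
  if (!any(time_days == 0))
    stop("a timecourse needs at least one observation at time 0", call. = FALSE)

  df <- data.frame(time_days = as.numeric(time_days),
                   replicate = as.character(replicate),
                   concentration_mg_L = as.numeric(concentration_mg_L),
                   stringsAsFactors = FALSE)
  if (is.unsorted(df$time_days)) {
    message("timecourse observations were not sorted by time; sorting")
    df <- df[order(df$time_days, df$replicate), , drop = FALSE]
    rownames(df) <- NULL
  }
  if (is.null(nominal_M0))
    nominal_M0 <- mean(df$concentration_mg_L[df$time_days == 0])
  structure(df,
            treatment = as.character(treatment)[1],
            nominal_M0 = as.numeric(nominal_M0),
            is_control = isTRUE(is_control),
            class = c("timecourse", "data.frame"))
}

#' Replicate-mean concentrations per time point
#'
#' @param tc a [timecourse()].
#' @return Data frame with `time_days` and the replicate-mean
#'   `concentration_mg_L` at each distinct time, sorted by time.
#' @export
summary_times <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  agg <- stats::aggregate(concentration_mg_L ~ time_days, data = tc, FUN = mean)
  agg[order(agg$time_days), , drop = FALSE]
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("timecourse: %s%s\n  %d observations, %d time points (%g-%g d), nominal M0 = %g mg/L\n",
              if (nzchar(attr(x, "treatment"))) attr(x, "treatment") else "<unlabelled>",
              if (attr(x, "is_control")) " [abiotic control]" else "",
              nrow(x), length(unique(x$time_days)),
              min(x$time_days), max(x$time_days), attr(x, "nominal_M0")))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Read and write time-course CSV files
#'
#' The CSV dialect is RFC-4180, UTF-8, `.` decimal, with header columns
#' `time_days`, `replicate`, `concentration_mg_L` and optional `treatment`
#' and `is_control`.  Malformed rows are reported with their line numbers;
#' missing required columns produce a schema error naming the column.
#' Negative concentrations load as-is with a notice that they will be
#' clipped to zero at fit time.
#'
#' @param path file path.
#' @param tc a [timecourse()] to write.
#' @return `read_timecourse_csv()` returns a validated [timecourse()];
#'   `write_timecourse_csv()` returns `path` invisibly.  The pair round-trips:
#'   reading a written file reproduces the original object.
#' @export
read_timecourse_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_days", "replicate", "concentration_mg_L")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("time_days", "concentration_mg_L")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' at data line(s) %s", col,
                   paste(bad + 1L, collapse = ", ")), call. = FALSE)
    raw[[col]] <- v
  }
  bad <- which(is.na(raw$time_days) | is.na(raw$concentration_mg_L))
  if (length(bad))
    stop("missing values at data line(s) ", paste(bad + 1L, collapse = ", "),
         call. = FALSE)
  if (any(raw$concentration_mg_L < 0))
    message(sum(raw$concentration_mg_L < 0),
            " negative concentration(s) loaded; they are clipped to 0 when fitting")
  timecourse(raw$time_days, raw$replicate, raw$concentration_mg_L,
             treatment = if ("treatment" %in% names(raw)) raw$treatment[1] else "",
             is_control = if ("is_control" %in% names(raw))
               isTRUE(as.logical(raw$is_control[1])) else FALSE)
}

#' @rdname read_timecourse_csv
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  out <- as.data.frame(tc)
  out$treatment <- attr(tc, "treatment")
  out$is_control <- attr(tc, "is_control")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
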