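#' ROI time series
#'
#' Container for one run's regional time series: a numeric matrix with one
#' row per acquired frame (TR) and one column per region of interest (ROI),
#' together with the metadata needed to keep track of whose run it is.
#'
#' @param data Numeric matrix, `T` frames x `R` ROIs, no missing values,
#'   `T >= 2` and `R >= 2`.
#' @param participant_id Participant identifier (coerced to character).
#' @param condition Condition identifier, e.g. `"rest"` (coerced to
#'   character).
#' @param run Run index, integer `>= 1`.
#' @param tr_seconds Optional repetition time in seconds (sampling interval
#'   of the frames); required only by operations that convert seconds to
#'   frames, such as [trim_task_blocks()].
#'
#' @return An object of class `roi_timeseries`.
#' @seealso [correlation_from_timeseries()], [trim_task_blocks()],
#'   [equate_length()], [sample_segments()]
#' @export
roi_timeseries <- function(data, participant_id = "p1", condition = "rest",
                           run = 1L, tr_seconds = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) {
    stop("a time series needs at least 2 frames, got ", nrow(data))
  }
  if (ncol(data) < 2L) {
    stop("a time series needs at least 2 ROIs, got ", ncol(data))
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("time series contains missing or non-finite values")
  }
  run <- as.integer(run)
  if (is.na(run) || run < 1L) stop("'run' must be an integer >= 1")
  if (!is.null(tr_seconds)) {
    tr_seconds <- as.numeric(tr_seconds)
    if (!is.finite(tr_seconds) || tr_seconds <= 0) {
      stop("'tr_seconds' must be a positive number")
    }
  }
  structure(
    list(
      data = data,
      participant_id = as.character(participant_id),
      condition = as.character(condition),
      run = run,
      tr_seconds = tr_seconds
    ),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf(
    "<roi_timeseries> participant %s, condition %s, run %d: %d frames x %d ROIs\n",
    x$participant_id, x$condition, x$run, nrow(x$data), ncol(x$data)
  ))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$data)

# number of frames / ROIs, used throughout
n_frames <- function(ts) nrow(ts$data)
n_rois <- function(ts) ncol(ts$data)

# carry metadata onto a new data matrix (pure-function helper)
replace_ts_data <- function(ts, data) {
  out <- ts
  out$data <- data
  out
}
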