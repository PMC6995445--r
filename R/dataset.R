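#' Parcellation: ROI to subnetwork mapping
#'
#' Maps every ROI index (0-based) to exactly one named subnetwork.
#'
#' @param roi_labels Character vector of subnetwork names, one per ROI in
#'   original ROI order.
#' @param network_names Optional ordered vector of network names; defaults
#'   to the order of first appearance in `roi_labels`.
#' @return An object of class `parcellation` with fields `roi_labels` and
#'   `network_names`.
#' @seealso [select_subnetworks()], [cortical_parcellation_300()]
#' @export
parcellation <- function(roi_labels, network_names = NULL) {
  roi_labels <- as.character(roi_labels)
  if (!length(roi_labels)) stop("empty parcellation")
  if (anyNA(roi_labels)) stop("every ROI must be mapped to a subnetwork")
  if (is.null(network_names)) network_names <- unique(roi_labels)
  if (!all(roi_labels %in% network_names)) {
    stop("labels not covered by 'network_names': ",
         paste(setdiff(roi_labels, network_names), collapse = ", "))
  }
  structure(
    list(roi_labels = roi_labels, network_names = as.character(network_names)),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d ROIs, %d subnetworks\n",
              length(x$roi_labels), length(x$network_names)))
  print(table(factor(x$roi_labels, levels = x$network_names)))
  invisible(x)
}

#' Seven-subnetwork 300-ROI cortical parcellation
#'
#' The 300-ROI local-global cortical parcellation grouped into the seven
#' canonical subnetworks, with the published subnetwork sizes: visual 47,
#' somatomotor 57, dorsal attention 34, ventral attention 34, limbic 20,
#' frontoparietal 40, default 68 (totalling 300).  ROIs of each subnetwork
#' are contiguous in index order.
#'
#' @return A [parcellation()] of 300 ROIs.
#' @export
cortical_parcellation_300 <- function() {
  sizes <- c(
    visual = 47L, somatomotor = 57L, dorsal_attention = 34L,
    ventral_attention = 34L, limbic = 20L, frontoparietal = 40L,
    default = 68L
  )
  parcellation(rep(names(sizes), times = sizes), names(sizes))
}

#' Task block schedule
#'
#' Timing of the stimulus blocks of a task run, in seconds.  Blocks must be
#' ordered and non-overlapping; `has_cue` marks blocks that open with a cue
#' of `cue_seconds` duration.
#'
#' @param onsets,offsets Numeric vectors of block start/end times (seconds).
#' @param has_cue Logical vector, one entry per block.
#' @param tr_seconds Repetition time (sampling interval), seconds.
#' @param cue_seconds Cue duration, seconds (default 3).
#' @return An object of class `block_schedule`.
#' @export
block_schedule <- function(onsets, offsets, has_cue = rep(FALSE, length(onsets)),
                           tr_seconds, cue_seconds = 3) {
  onsets <- as.numeric(onsets)
  offsets <- as.numeric(offsets)
  has_cue <- as.logical(has_cue)
  if (length(offsets) != length(onsets) || length(has_cue) != length(onsets)) {
    stop("'onsets', 'offsets' and 'has_cue' must have equal length")
  }
  if (any(offsets <= onsets)) stop("every block must end after it starts")
  if (length(onsets) > 1L && any(diff(onsets) <= 0)) {
    stop("blocks must be ordered by onset")
  }
  if (length(onsets) > 1L && any(onsets[-1L] < offsets[-length(offsets)])) {
    stop("blocks must not overlap")
  }
  if (tr_seconds <= 0) stop("'tr_seconds' must be positive")
  if (cue_seconds < 0) stop("'cue_seconds' must be >= 0")
  structure(
    list(onsets = onsets, offsets = offsets, has_cue = has_cue,
         tr_seconds = as.numeric(tr_seconds), cue_seconds = as.numeric(cue_seconds)),
    class = "block_schedule"
  )
}

#' Trim a task run to its task-related frames
#'
#' Removes fixation periods and accounts for hemodynamic lag.  For a block
#' without a cue, the first `lag_drop_trs` frames of the block are dropped
#' and the first `lag_keep_trs` frames after the block's end are kept:
#' frames `[onset_TR + lag_drop_trs, offset_TR + lag_keep_trs)`.  For a
#' cued block, frames from `cue_shift_seconds` after the cue onset to 3
#' seconds after the block's end are kept:
#' `[ceil((onset + cue_shift_seconds)/tr), offset_TR + round(3/tr))`.
#' Frame indices are 0-based with half-open ranges; seconds-to-TR
#' conversion uses `ceiling` for onsets and `round` for the 3-second tail.
#' Tail frames beyond the end of the run are clipped; a block whose own
#' extent runs past the end of the run is an error.  The trimmed segments
#' are concatenated in temporal order.
#'
#' @param ts An [roi_timeseries()] (its `tr_seconds` is used unless the
#'   schedule provides one).
#' @param sched A [block_schedule()].
#' @param lag_drop_trs,lag_keep_trs Hemodynamic-lag frames dropped at block
#'   onset / kept after block offset (defaults 4 and 4).
#' @param cue_shift_seconds Seconds after cue onset from which cued-block
#'   data are used (default 12).
#' @return A new, shorter [roi_timeseries()]; the input is not modified.
#' @export
trim_task_blocks <- function(ts, sched, lag_drop_trs = 4L, lag_keep_trs = 4L,
                             cue_shift_seconds = 12) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(sched, "block_schedule"))
  tr <- sched$tr_seconds %||% ts$tr_seconds
  if (is.null(tr)) stop("no 'tr_seconds' available")
  t_total <- n_frames(ts)
  if (!length(sched$onsets)) stop("no task frames: empty block schedule")
  keep <- integer(0)
  for (b in seq_along(sched$onsets)) {
    onset_tr <- ceiling(sched$onsets[b] / tr)
    offset_tr <- ceiling(sched$offsets[b] / tr)
    if (offset_tr > t_total) {
      stop("block ", b, " extends past the end of the run (",
           offset_tr, " > ", t_total, " frames)")
    }
    if (sched$has_cue[b]) {
      from <- ceiling((sched$onsets[b] + cue_shift_seconds) / tr)
      to <- offset_tr + round(3 / tr)
    } else {
      from <- onset_tr + lag_drop_trs
      to <- offset_tr + lag_keep_trs
    }
    to <- min(to, t_total)
    if (from < to) keep <- c(keep, seq.int(from, to - 1L))
  }
  keep <- unique(keep)
  if (!length(keep)) stop("no task frames left after trimming")
  replace_ts_data(ts, ts$data[keep + 1L, , drop = FALSE])
}

#' Trim a run to a common length, keeping the middle
#'
#' Equates time-course length across conditions by deleting frames at the
#' beginning and end of the run, retaining the centered window.  When the
#' number of frames to remove is odd, the extra frame is removed from the
#' end.  The default of 138 frames corresponds to equating every condition
#' to the shortest task run.
#'
#' @param ts An [roi_timeseries()] with at least `target_len` frames.
#' @param target_len Target number of frames.
#' @return A new [roi_timeseries()] of exactly `target_len` frames.
#' @export
equate_length <- function(ts, target_len = 138L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  target_len <- as.integer(target_len)
  t_total <- n_frames(ts)
  if (t_total < target_len) {
    stop("run has ", t_total, " frames, fewer than target ", target_len)
  }
  start <- (t_total - target_len) %/% 2L
  replace_ts_data(ts, ts$data[start + seq_len(target_len), , drop = FALSE])
}

#' Random contiguous segments of a run
#'
#' Draws `n_segments` contiguous windows of `seg_len` frames whose start
#' frames are sampled uniformly *without replacement* from all valid starts
#' `{0, ..., T - seg_len}`, so several segments of the same length are
#' obtained without favouring the beginning of the scan.  If fewer than
#' `n_segments` distinct starts exist, all of them are returned with a
#' warning.
#'
#' @param ts An [roi_timeseries()].
#' @param seg_len Segment length in frames, `<= T`.
#' @param n_segments Number of segments requested (default 50).
#' @param seed Integer seed; the draw is reproducible and does not disturb
#'   the caller's RNG state.
#' @return A list of [roi_timeseries()] segments, each carrying the start
#'   frame as attribute `"start_frame"` (0-based).
#' @export
sample_segments <- function(ts, seg_len, n_segments = 50L, seed = 1L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  seg_len <- as.integer(seg_len)
  t_total <- n_frames(ts)
  if (seg_len > t_total) {
    stop("segment length ", seg_len, " exceeds run length ", t_total)
  }
  if (seg_len < 2L) stop("segments need at least 2 frames")
  n_starts <- t_total - seg_len + 1L
  k <- as.integer(n_segments)
  if (n_starts < k) {
    warning("only ", n_starts, " distinct start frames exist; returning all ",
            "of them instead of the requested ", k, " segments")
    k <- n_starts
  }
  starts <- withr::with_seed(seed, sort(sample.int(n_starts, k) - 1L))
  lapply(starts, function(s) {
    seg <- replace_ts_data(ts, ts$data[s + seq_len(seg_len), , drop = FALSE])
    attr(seg, "start_frame") <- s
    seg
  })
}

#' Restrict to a set of subnetworks
#'
#' Keeps only the ROIs belonging to the requested subnetworks, preserving
#' the original ROI order.  For a time series this selects columns; for an
#' FC matrix it takes the principal submatrix, i.e. all within- *and*
#' between-network connections among the selected ROIs.  A principal
#' submatrix of a positive-semidefinite matrix is positive semidefinite, so
#' the FC-matrix invariants are preserved.
#'
#' @param obj An [roi_timeseries()], [fc_matrix()] or [fc_database()].
#' @param parc A [parcellation()] whose length matches the object's ROI
#'   dimension.
#' @param networks Character vector of subnetwork names to keep.
#' @return The same kind of object as `obj`, restricted to the selected
#'   ROIs.
#' @export
select_subnetworks <- function(obj, parc, networks) {
  stopifnot(inherits(parc, "parcellation"))
  unknown <- setdiff(networks, parc$network_names)
  if (length(unknown)) {
    stop("unknown subnetwork(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(parc$network_names, collapse = ", "))
  }
  idx <- which(parc$roi_labels %in% networks)
  if (inherits(obj, "roi_timeseries")) {
    if (length(parc$roi_labels) != n_rois(obj)) {
      stop("parcellation length does not match the number of ROIs")
    }
    return(replace_ts_data(obj, obj$data[, idx, drop = FALSE]))
  }
  if (inherits(obj, "fc_matrix")) {
    if (length(parc$roi_labels) != nrow(obj$values)) {
      stop("parcellation length does not match the FC dimension")
    }
    out <- obj
    out$values <- obj$values[idx, idx, drop = FALSE]
    return(out)
  }
  if (inherits(obj, "fc_database")) {
    out <- obj
    out$matrices <- lapply(obj$matrices, select_subnetworks,
                           parc = parc, networks = networks)
    return(out)
  }
  stop("cannot select subnetworks from an object of class ",
       paste(class(obj), collapse = "/"))
}
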