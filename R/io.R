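#' Read and write package objects as TSV
#'
#' All tabular interchange uses plain TSV.  Matrices (FC, distance,
#' dissimilarity) are written with row/column identifier headers; object
#' metadata (participant, condition, run, measure, regularization, seeds)
#' goes to a JSON sidecar named `<file>.json`.
#'
#' @param q An [fc_matrix()].
#' @param file Path of the TSV file to write/read.
#' @param sidecar Write/read the JSON metadata sidecar (default `TRUE`)?
#' @return `write_*` return `file` invisibly; `read_*` return the object.
#' @name fc_io
NULL

write_matrix_tsv <- function(m, file) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, file,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(file)
}

read_matrix_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

sidecar_path <- function(file) paste0(file, ".json")

write_sidecar <- function(meta, file) {
  meta <- Filter(Negate(is.null), meta)
  jsonlite::write_json(meta, sidecar_path(file), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(file) {
  p <- sidecar_path(file)
  if (!file.exists(p)) return(NULL)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

#' @rdname fc_io
#' @export
write_fc_tsv <- function(q, file, sidecar = TRUE) {
  stopifnot(inherits(q, "fc_matrix"))
  m <- q$values
  ids <- paste0("roi", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  write_matrix_tsv(m, file)
  if (sidecar) {
    write_sidecar(list(
      participant_id = q$participant_id, condition = q$condition,
      run = q$run, regularization_tau = q$regularization_tau
    ), file)
  }
  invisible(file)
}

#' @rdname fc_io
#' @export
read_fc_tsv <- function(file) {
  m <- read_matrix_tsv(file)
  meta <- read_sidecar(file) %||% list()
  fc_matrix(unname(m),
    participant_id = meta$participant_id %||% "p1",
    condition = meta$condition %||% "rest",
    run = meta$run %||% 1L,
    regularization_tau = meta$regularization_tau %||% 0
  )
}

#' Distance-matrix TSV round trip
#'
#' @param d A [distance_matrix()].
#' @param file TSV path; a `<file>.json` sidecar stores the measure and
#'   identifiers.
#' @return `write_distance_tsv` returns `file` invisibly;
#'   `read_distance_tsv` the [distance_matrix()].
#' @export
write_distance_tsv <- function(d, file) {
  stopifnot(inherits(d, "distance_matrix"))
  write_matrix_tsv(d$values, file)
  write_sidecar(list(
    measure = d$measure, row_ids = d$row_ids, col_ids = d$col_ids
  ), file)
  invisible(file)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(file) {
  m <- read_matrix_tsv(file)
  meta <- read_sidecar(file)
  if (is.null(meta)) stop("missing sidecar ", sidecar_path(file))
  distance_matrix(unname(m),
    measure = meta$measure,
    row_ids = meta$row_ids, col_ids = meta$col_ids
  )
}

#' Time-series TSV round trip
#'
#' Frames are rows, ROIs columns (`roi1...roiR` header).  Metadata goes to
#' the JSON sidecar.
#'
#' @param ts An [roi_timeseries()].
#' @param file TSV path.
#' @return `write_timeseries_tsv` returns `file` invisibly;
#'   `read_timeseries_tsv` the [roi_timeseries()].
#' @export
write_timeseries_tsv <- function(ts, file) {
  stopifnot(inherits(ts, "roi_timeseries"))
  m <- ts$data
  colnames(m) <- paste0("roi", seq_len(ncol(m)))
  utils::write.table(m, file,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  write_sidecar(list(
    participant_id = ts$participant_id, condition = ts$condition,
    run = ts$run, tr_seconds = ts$tr_seconds
  ), file)
  invisible(file)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(file) {
  m <- as.matrix(utils::read.delim(file, check.names = FALSE))
  meta <- read_sidecar(file) %||% list()
  tr <- meta$tr_seconds
  if (!length(tr) || !is.numeric(tr)) tr <- NULL
  roi_timeseries(unname(m),
    participant_id = meta$participant_id %||% "p1",
    condition = meta$condition %||% "rest",
    run = meta$run %||% 1L,
    tr_seconds = tr
  )
}

#' Parcellation TSV round trip
#'
#' Two columns: `roi_index` (0-based) and `network_name`.
#'
#' @param parc A [parcellation()].
#' @param file TSV path.
#' @return `write_parcellation_tsv` returns `file` invisibly;
#'   `read_parcellation_tsv` the [parcellation()].
#' @export
write_parcellation_tsv <- function(parc, file) {
  stopifnot(inherits(parc, "parcellation"))
  utils::write.table(
    data.frame(
      roi_index = seq_along(parc$roi_labels) - 1L,
      network_name = parc$roi_labels
    ),
    file, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(file)
}

#' @rdname write_parcellation_tsv
#' @export
read_parcellation_tsv <- function(file) {
  df <- utils::read.delim(file)
  if (!all(c("roi_index", "network_name") %in% names(df))) {
    stop("parcellation file ", file,
         " must have columns 'roi_index' and 'network_name'")
  }
  df <- df[order(df$roi_index), ]
  if (!identical(as.integer(df$roi_index), seq_len(nrow(df)) - 1L)) {
    stop("parcellation file ", file,
         " must map every 0-based ROI index exactly once")
  }
  parcellation(df$network_name)
}

#' Block-schedule TSV reader
#'
#' Three columns: `onset_s`, `offset_s`, `has_cue` (0/1 or logical); the
#' repetition time and cue duration are supplied as arguments (config
#' keys).
#'
#' @param file TSV path.
#' @param tr_seconds,cue_seconds Passed to [block_schedule()].
#' @return A [block_schedule()].
#' @export
read_block_schedule_tsv <- function(file, tr_seconds, cue_seconds = 3) {
  df <- utils::read.delim(file)
  need <- c("onset_s", "offset_s", "has_cue")
  if (!all(need %in% names(df))) {
    stop("schedule file ", file, " must have columns ",
         paste(need, collapse = ", "))
  }
  block_schedule(df$onset_s, df$offset_s, as.logical(df$has_cue),
                 tr_seconds = tr_seconds, cue_seconds = cue_seconds)
}

#' Serialize an identification result to JSON
#'
#' @param res An `identification_result` from [symmetric_accuracy()].
#' @param file JSON path.
#' @param seed Optional seed to record.
#' @return `file`, invisibly.
#' @export
write_identification_json <- function(res, file, seed = NULL) {
  stopifnot(inherits(res, "identification_result"))
  jsonlite::write_json(
    list(
      measure = res$measure,
      accuracy_dir1 = res$accuracy_dir1,
      accuracy_dir2 = res$accuracy_dir2,
      mean_accuracy = res$mean_accuracy,
      predicted_dir1 = as.list(stats::setNames(res$predicted_dir1, res$dist$row_ids)),
      predicted_dir2 = as.list(stats::setNames(res$predicted_dir2, res$dist$col_ids)),
      seed = seed
    ),
    file, auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}
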