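#' Read a spike-list CSV
#'
#' Reads the plain spike-list dialect used throughout this package: a CSV
#' with header columns `time_s`, `electrode` (codes `"R<row>C<col>"`,
#' 1-based) and optionally `amplitude_uV`. One recording per file. Rows are
#' grouped per electrode into [spike_train] objects; electrodes of the grid
#' that never appear get empty trains.
#'
#' @param path CSV file path.
#' @param grid an [electrode_grid] resolving electrode codes.
#' @param t_start,t_stop recording window in seconds; if `NULL`, taken as
#'   `0` and the maximum observed spike time respectively.
#' @param metadata passed to [mea_recording].
#' @return An [mea_recording].
#' @export
read_spike_list <- function(path, grid, t_start = NULL, t_stop = NULL,
                            metadata = list()) {
  stopifnot(inherits(grid, "electrode_grid"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "electrode")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("spike list is missing required column(s): ",
         paste(miss, collapse = ", "))
  unknown <- setdiff(unique(df$electrode), grid$electrodes)
  if (length(unknown))
    stop("spike list contains electrode code(s) not on the grid: ",
         paste(unknown, collapse = ", "))
  if (is.null(t_start)) t_start <- 0
  if (is.null(t_stop))
    t_stop <- if (nrow(df)) max(df$time_s) else t_start + 1
  trains <- list()
  if (nrow(df)) {
    by_e <- split(df$time_s, df$electrode)
    trains <- lapply(names(by_e), function(e)
      spike_train(by_e[[e]], t_start, t_stop, e))
    names(trains) <- names(by_e)
  }
  mea_recording(trains, grid, metadata)
}

#' Write a recording as a spike-list CSV
#'
#' Inverse of [read_spike_list]; spike times are written with enough digits
#' to round-trip to better than 1e-9 s.
#'
#' @param recording an [mea_recording].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_list <- function(recording, path) {
  stopifnot(inherits(recording, "mea_recording"))
  rows <- lapply(recording$trains, function(tr) {
    if (!length(tr$times)) return(NULL)
    data.frame(time_s = tr$times, electrode = tr$electrode_id,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(time_s = numeric(0), electrode = character(0))
  df <- df[order(df$time_s, df$electrode), , drop = FALSE]
  df$time_s <- sprintf("%.9f", df$time_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pairwise and directionality results
#'
#' Writes the pairwise table as CSV (columns `e1, e2, sttc, significant,
#' delay_s, distance_pitch, distance_m, speed_mps`) and the directionality
#' field as JSON. Both round-trip losslessly through [read_pairwise_csv] and
#' [read_directionality_json].
#'
#' @param pairwise data.frame from [pairwise_table].
#' @param field `directionality_field` from [assembloid_directionality], or
#'   `NULL` to skip.
#' @param csv_path,json_path output paths (`NULL` skips that output).
#' @return named list of written paths, invisibly.
#' @export
write_results <- function(pairwise, field = NULL, csv_path = NULL,
                          json_path = NULL) {
  out <- list()
  if (!is.null(csv_path)) {
    df <- pairwise
    num <- vapply(df, is.numeric, logical(1))
    for (j in which(num)) df[[j]] <- sprintf("%.12g", df[[j]])
    df[df == "NA"] <- NA
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
    out$csv <- csv_path
  }
  if (!is.null(json_path)) {
    stopifnot(inherits(field, "directionality_field"))
    jsonlite::write_json(unclass(field), json_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    out$json <- json_path
  }
  invisible(out)
}

#' @rdname write_results
#' @param path file to read back.
#' @export
read_pairwise_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df)) df$significant <- as.logical(df$significant)
  df
}

#' @rdname write_results
#' @export
read_directionality_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$established <- isTRUE(x$established)
  structure(x, class = "directionality_field")
}

#' Read a raw voltage-trace CSV matrix
#'
#' One column per electrode (header = electrode code), one row per sample,
#' values in microvolts, with a declared sample rate.
#'
#' @param path CSV path.
#' @param sample_rate sampling rate in Hz (12500 for the target hardware).
#' @return named list of `voltage_trace` objects (fields `samples`,
#'   `sample_rate`, `electrode_id`).
#' @export
read_trace_csv <- function(path, sample_rate = 12500) {
  stopifnot(sample_rate > 0)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(stats::setNames(names(df), names(df)), function(e)
    voltage_trace(df[[e]], sample_rate, e))
}

#' Construct a voltage trace
#' @param samples numeric vector, microvolts, regularly sampled.
#' @param sample_rate Hz.
#' @param electrode_id label.
#' @export
voltage_trace <- function(samples, sample_rate, electrode_id = "e") {
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("voltage samples must be finite")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive")
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate),
                 electrode_id = as.character(electrode_id)),
            class = "voltage_trace")
}
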