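#' Construct a spike train
#'
#' A spike train is the ordered sequence of spike times (in seconds) detected
#' on one electrode within a recording window. Times must lie inside
#' `[t_start, t_stop]` and be strictly increasing; exact duplicate times are
#' collapsed to a single event with a warning, since true duplicates are
#' impossible at the 12.5 kHz acquisition rate of the hardware this pipeline
#' targets (the refractory period spans many samples).
#'
#' @param times numeric vector of spike times in seconds (any order; sorted
#'   internally).
#' @param t_start,t_stop recording window in seconds, `t_stop > t_start`.
#' @param electrode_id electrode label, e.g. `"R3C5"`.
#' @return An object of class `spike_train` with fields `electrode_id`,
#'   `times`, `t_start`, `t_stop`.
#' @examples
#' st <- spike_train(c(0.5, 1.2, 2.0), 0, 180, "R1C1")
#' n_spikes(st)
#' @export
spike_train <- function(times, t_start, t_stop, electrode_id = "e") {
  stopifnot(is.numeric(t_start), is.numeric(t_stop), length(t_start) == 1L,
            length(t_stop) == 1L)
  if (!is.finite(t_start) || !is.finite(t_stop) || t_stop <= t_start)
    stop("t_stop must be strictly greater than t_start")
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times)))
    stop("spike times must be finite")
  if (any(times < t_start) || any(times > t_stop))
    stop("spike times outside the recording window [t_start, t_stop]")
  times <- sort(times)
  if (anyDuplicated(times)) {
    n0 <- length(times)
    times <- unique(times)
    warning(sprintf("electrode %s: collapsed %d duplicate spike time(s)",
                    electrode_id, n0 - length(times)))
  }
  structure(
    list(electrode_id = as.character(electrode_id), times = times,
         t_start = as.numeric(t_start), t_stop = as.numeric(t_stop)),
    class = "spike_train")
}

#' @rdname spike_train
#' @param x a `spike_train`.
#' @export
n_spikes <- function(x) {
  stopifnot(inherits(x, "spike_train"))
  length(x$times)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s: %d spikes in [%g, %g] s>\n",
              x$electrode_id, length(x$times), x$t_start, x$t_stop))
  invisible(x)
}

#' Assemble a recording
#'
#' A recording bundles one spike train per grid electrode with the electrode
#' grid geometry and free-form metadata (assembloid id, batch, day in vitro).
#' All trains must share the same recording window. Electrodes of the grid
#' with no train are filled with empty trains so that downstream stages can
#' iterate over the full grid.
#'
#' @param trains named list of [spike_train] objects; names are electrode ids
#'   present on `grid`.
#' @param grid an [electrode_grid].
#' @param metadata named list; recognised keys: `assembloid_id`, `batch_id`,
#'   `div` (day in vitro, >= 0), `sample_rate` (Hz).
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(trains, grid, metadata = list()) {
  stopifnot(inherits(grid, "electrode_grid"), is.list(trains))
  if (length(trains)) {
    stopifnot(!is.null(names(trains)))
    ok <- vapply(trains, inherits, logical(1), "spike_train")
    if (!all(ok)) stop("all elements of trains must be spike_train objects")
    unknown <- setdiff(names(trains), grid$electrodes)
    if (length(unknown))
      stop("trains for electrodes not on the grid: ",
           paste(unknown, collapse = ", "))
    ts <- vapply(trains, `[[`, numeric(1), "t_start")
    te <- vapply(trains, `[[`, numeric(1), "t_stop")
    if (max(ts) - min(ts) > 1e-9 || max(te) - min(te) > 1e-9)
      stop("all trains must share the same recording window")
    t_start <- ts[[1L]]; t_stop <- te[[1L]]
  } else {
    t_start <- 0; t_stop <- 1
  }
  if (!is.null(metadata$div) && metadata$div < 0)
    stop("day in vitro must be >= 0")
  # fill missing electrodes with empty trains
  missing <- setdiff(grid$electrodes, names(trains))
  for (e in missing)
    trains[[e]] <- spike_train(numeric(0), t_start, t_stop, e)
  trains <- trains[grid$electrodes]
  structure(list(trains = trains, grid = grid, metadata = metadata,
                 t_start = t_start, t_stop = t_stop),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  n <- vapply(x$trains, function(t) length(t$times), integer(1))
  cat(sprintf("<mea_recording: %d electrodes, %d spikes, window [%g, %g] s>\n",
              length(x$trains), sum(n), x$t_start, x$t_stop))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an [mea_recording].
#' @export
recording_duration <- function(recording) {
  stopifnot(inherits(recording, "mea_recording"))
  recording$t_stop - recording$t_start
}
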