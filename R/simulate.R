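#' Simulation configuration
#'
#' Describes the generative model of a synthetic two-compartment MEA
#' recording: homogeneous Poisson background activity on every electrode,
#' optional renewal bursts, and a set of directed connections along which
#' each source spike is copied to the target electrode with a transmission
#' probability, delayed by distance / conduction speed plus Gaussian jitter
#' (truncated at 3 SD so the planted delay stays within one-to-two
#' correlogram bins).
#'
#' Defaults describe a 3-minute recording on a 300-um-pitch 8x8 grid with
#' 1 Hz background per electrode and a conduction speed of 0.3 m/s, inside
#' the 0.2-0.5 m/s band reported for signals propagating between cortical
#' electrodes in comparable preparations. Background firing rates of
#' biological assembloids are not published; the 1 Hz default is an
#' engineering choice in the plausible 0.5-5 Hz range.
#'
#' @param duration recording length, seconds (default 180).
#' @param background_rate Hz per electrode (default 1).
#' @param connections data.frame with columns `source`, `target`
#'   (electrode ids), `transmission_prob` in `[0, 1]`; or `NULL` for none.
#' @param conduction_speed m/s (default 0.3).
#' @param jitter_sd propagation jitter SD, seconds (default 2e-4).
#' @param pitch_um electrode pitch, micrometres (default 300).
#' @param boundary_row first StrO row (default 5).
#' @param burst_rate bursts per second per electrode (default 0: bursts
#'   off).
#' @param burst_spikes spikes per burst (default 5).
#' @param burst_isi intra-burst inter-spike interval, seconds
#'   (default 0.010).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(duration = 180, background_rate = 1,
                              connections = NULL, conduction_speed = 0.3,
                              jitter_sd = 2e-4, pitch_um = 300,
                              boundary_row = 5, burst_rate = 0,
                              burst_spikes = 5, burst_isi = 0.010) {
  stopifnot(duration > 0, background_rate >= 0, conduction_speed > 0,
            jitter_sd >= 0, pitch_um > 0, burst_rate >= 0,
            burst_spikes >= 2, burst_isi > 0)
  if (!is.null(connections)) {
    stopifnot(is.data.frame(connections),
              all(c("source", "target", "transmission_prob") %in%
                    names(connections)))
    if (any(connections$transmission_prob < 0 |
              connections$transmission_prob > 1))
      stop("transmission_prob must lie in [0, 1]")
  }
  structure(list(duration = duration, background_rate = background_rate,
                 connections = connections,
                 conduction_speed = conduction_speed,
                 jitter_sd = jitter_sd, pitch_um = pitch_um,
                 boundary_row = boundary_row, burst_rate = burst_rate,
                 burst_spikes = burst_spikes, burst_isi = burst_isi),
            class = "simulation_config")
}

#' Homogeneous Poisson background spike train
#'
#' @param rate firing rate in Hz, >= 0.
#' @param duration window length, seconds.
#' @param seed optional integer seed (omit to use the current RNG state).
#' @param electrode_id label for the resulting train.
#' @return a [spike_train] on `[0, duration]`.
#' @export
simulate_background <- function(rate, duration, seed = NULL,
                                electrode_id = "e") {
  if (!is.numeric(rate) || rate < 0) stop("rate must be >= 0")
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1L, rate * duration)
  times <- sort(stats::runif(n, 0, duration))
  # guard against astronomically unlikely exact duplicates from runif
  times <- unique(times)
  spike_train(times, 0, duration, electrode_id)
}

#' Default inter-compartment connection topology
#'
#' One vertical connection per column crossing the compartment boundary
#' (row 2 to row `n_rows - 1`), in both directions, with separate forward
#' (MO to StrO) and backward transmission probabilities. A `forward_prob`
#' larger than `backward_prob` plants a net MO-to-StrO directionality.
#'
#' @param grid an [electrode_grid].
#' @param forward_prob MO-to-StrO transmission probability.
#' @param backward_prob StrO-to-MO transmission probability.
#' @return connections data.frame for [simulation_config].
#' @export
default_connections <- function(grid, forward_prob = 0.8,
                                backward_prob = 0.2) {
  stopifnot(inherits(grid, "electrode_grid"))
  cols <- seq_len(grid$n_cols)
  mo_row <- 2L
  stro_row <- grid$n_rows - 1L
  fwd <- data.frame(source = sprintf("R%dC%d", mo_row, cols),
                    target = sprintf("R%dC%d", stro_row, cols),
                    transmission_prob = forward_prob,
                    stringsAsFactors = FALSE)
  bwd <- data.frame(source = fwd$target, target = fwd$source,
                    transmission_prob = backward_prob,
                    stringsAsFactors = FALSE)
  rbind(fwd, bwd)
}

# Gaussian jitter truncated at +/- 3 sd (inverse-CDF sampling keeps a
# single draw per spike, preserving stream reproducibility)
truncated_jitter <- function(n, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  lo <- stats::pnorm(-3); hi <- stats::pnorm(3)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

#' Simulate a two-compartment assembloid recording
#'
#' Generates background Poisson activity (plus optional renewal bursts) on
#' every electrode of the grid, then propagates spikes along the configured
#' connections: each source spike is copied to the target with probability
#' `transmission_prob` at `time + distance / conduction_speed + jitter`;
#' copies falling outside the recording window are dropped. Returns the
#' recording together with the planted ground truth (per-connection delay,
#' direction sign, and the net directionality sign).
#'
#' @param config a [simulation_config].
#' @param seed integer seed driving all randomness (background, bursts,
#'   transmission, jitter) reproducibly.
#' @return list with `recording` ([mea_recording]) and `ground_truth`
#'   (list: `connections` data.frame with planted `delay_s`,
#'   `direction` (+1 toward StrO, -1 toward MO, 0 lateral),
#'   `transmission_prob`; `net_direction_sign`; `conduction_speed_mps`;
#'   `seed`).
#' @export
simulate_assembloid <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed))
  grid <- build_grid(pitch_um = config$pitch_um,
                     boundary_row = config$boundary_row)
  dur <- config$duration
  # background (electrode order fixed: row-major grid order => reproducible)
  trains <- list()
  for (e in grid$electrodes) {
    n <- stats::rpois(1L, config$background_rate * dur)
    times <- stats::runif(n, 0, dur)
    if (config$burst_rate > 0) {
      nb <- stats::rpois(1L, config$burst_rate * dur)
      starts <- stats::runif(nb, 0, dur)
      offs <- (seq_len(config$burst_spikes) - 1L) * config$burst_isi
      times <- c(times, rep(starts, each = config$burst_spikes) +
                   rep(offs, times = nb))
    }
    trains[[e]] <- sort(unique(times[times >= 0 & times <= dur]))
  }
  gt_rows <- NULL
  if (!is.null(config$connections) && nrow(config$connections)) {
    cn <- config$connections
    bad <- setdiff(unique(c(cn$source, cn$target)), grid$electrodes)
    if (length(bad))
      stop("connection references electrode(s) not on the grid: ",
           paste(bad, collapse = ", "))
    d_m <- grid_distance(grid, cn$source, cn$target, units = "m")
    delay <- d_m / config$conduction_speed
    src_comp <- grid_compartment(grid, cn$source)
    tgt_comp <- grid_compartment(grid, cn$target)
    dir_sign <- ifelse(src_comp == tgt_comp, 0L,
                       ifelse(src_comp == "MO", 1L, -1L))
    extra <- vector("list", nrow(cn))
    for (i in seq_len(nrow(cn))) {
      src <- trains[[cn$source[i]]]
      if (!length(src)) next
      pass <- stats::runif(length(src)) < cn$transmission_prob[i]
      t_new <- src[pass] + delay[i] +
        truncated_jitter(sum(pass), config$jitter_sd)
      t_new <- t_new[t_new >= 0 & t_new <= dur]
      extra[[i]] <- list(target = cn$target[i], times = t_new)
    }
    for (x in extra) {
      if (is.null(x)) next
      trains[[x$target]] <- sort(unique(c(trains[[x$target]], x$times)))
    }
    gt_rows <- data.frame(source = cn$source, target = cn$target,
                          transmission_prob = cn$transmission_prob,
                          delay_s = delay, direction = dir_sign,
                          stringsAsFactors = FALSE)
  }
  st <- lapply(grid$electrodes, function(e)
    spike_train(trains[[e]], 0, dur, e))
  names(st) <- grid$electrodes
  rec <- mea_recording(st, grid, metadata = list(simulated = TRUE,
                                                 seed = as.integer(seed)))
  net <- if (is.null(gt_rows)) 0 else
    sign(sum(gt_rows$direction * gt_rows$transmission_prob))
  list(recording = rec,
       ground_truth = list(connections = gt_rows,
                           net_direction_sign = net,
                           conduction_speed_mps = config$conduction_speed,
                           seed = as.integer(seed)))
}

#' Write the canonical fixture suite
#'
#' Generates four named fixtures and writes each as a spike-list CSV plus a
#' ground-truth JSON: `null` (no connections), `forward` (MO-to-StrO bias,
#' transmission 0.8 vs 0.2), `backward` (the mirror-image bias), and
#' `shifted_pair` (a two-electrode deterministic copy with a planted 5-pitch
#' delay). Regeneration with the same seed is byte-identical.
#'
#' @param out_dir writable directory (created if missing).
#' @param seed integer seed.
#' @param duration recording length, seconds (default 180).
#' @return named list: for each fixture, `csv` and `json` paths.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L, duration = 180) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  grid <- build_grid(pitch_um = 300, boundary_row = 5)
  specs <- list(
    null = simulation_config(duration = duration, connections = NULL),
    forward = simulation_config(duration = duration,
      connections = default_connections(grid, 0.8, 0.2)),
    backward = simulation_config(duration = duration,
      connections = default_connections(grid, 0.2, 0.8)),
    shifted_pair = simulation_config(duration = duration,
      connections = data.frame(source = "R2C4", target = "R7C4",
                               transmission_prob = 1,
                               stringsAsFactors = FALSE),
      jitter_sd = 0))
  out <- list()
  for (nm in names(specs)) {
    sim <- simulate_assembloid(specs[[nm]],
                               seed = as.integer(seed) + match(nm, names(specs)))
    csv <- file.path(out_dir, paste0(nm, ".csv"))
    json <- file.path(out_dir, paste0(nm, "_truth.json"))
    write_spike_list(sim$recording, csv)
    jsonlite::write_json(sim$ground_truth, json, auto_unbox = TRUE,
                         digits = NA, null = "null")
    out[[nm]] <- list(csv = csv, json = json)
  }
  out
}
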