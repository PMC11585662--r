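#' Pairwise connectivity table
#'
#' Runs the full pairwise stage over a recording: for every unordered pair
#' of active electrodes (those with at least `min_spikes_per_electrode`
#' spikes) computes the STTC, the probability cross-correlogram, the
#' significance-gated conduction delay (signed: positive means `e1` leads
#' `e2`), the physical distance and, where defined, the propagation speed.
#'
#' @param recording an [mea_recording].
#' @param config an [analysis_config].
#' @return data.frame with columns `e1, e2, sttc, significant, delay_s,
#'   distance_pitch, distance_m, speed_mps`; zero rows (with a warning)
#'   when fewer than two electrodes are active. Excluded electrodes are
#'   recorded in the `"excluded"` attribute.
#' @export
pairwise_table <- function(recording, config = analysis_config()) {
  stopifnot(inherits(recording, "mea_recording"),
            inherits(config, "analysis_config"))
  counts <- vapply(recording$trains, function(t) length(t$times), integer(1))
  active <- names(counts)[counts >= config$min_spikes_per_electrode]
  excluded <- setdiff(names(counts), active)
  empty <- data.frame(e1 = character(0), e2 = character(0),
                      sttc = numeric(0), significant = logical(0),
                      delay_s = numeric(0), distance_pitch = numeric(0),
                      distance_m = numeric(0), speed_mps = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(active) < 2L) {
    warning("fewer than 2 active electrodes; returning an empty table")
    attr(empty, "excluded") <- excluded
    return(empty)
  }
  grid <- recording$grid
  # per-electrode quantities shared across pairs
  tf <- vapply(recording$trains[active], tiling_fraction, numeric(1),
               dt = config$dt_sttc)
  pairs <- utils::combn(active, 2L)
  n <- ncol(pairs)
  s_v <- delay_v <- numeric(n)
  sig_v <- logical(n)
  term <- function(p, t) { den <- 1 - p * t; if (den == 0) 1 else (p - t) / den }
  for (i in seq_len(n)) {
    e1 <- pairs[1L, i]; e2 <- pairs[2L, i]
    a <- recording$trains[[e1]]; b <- recording$trains[[e2]]
    pa <- tiled_proportion(a, b, config$dt_sttc)
    pb <- tiled_proportion(b, a, config$dt_sttc)
    s_v[i] <- 0.5 * (term(pa, tf[[e2]]) + term(pb, tf[[e1]]))
    cg <- cross_correlogram(a, b, bin = config$cc_bin,
                            half_window = config$cc_window)
    sig <- significant_delay(cg, sig_sd = config$sig_sd,
                             min_count = config$sig_min_count)
    sig_v[i] <- sig$significant
    delay_v[i] <- sig$delay_s
  }
  d_pitch <- grid_distance(grid, pairs[1L, ], pairs[2L, ], units = "pitch")
  d_m <- d_pitch * grid$pitch_um * 1e-6
  speed <- ifelse(sig_v, propagation_speed(d_m, delay_v), NA_real_)
  out <- data.frame(e1 = pairs[1L, ], e2 = pairs[2L, ], sttc = s_v,
                    significant = sig_v, delay_s = delay_v,
                    distance_pitch = d_pitch, distance_m = d_m,
                    speed_mps = speed, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
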