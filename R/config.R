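#' Analysis configuration
#'
#' Collects every tunable parameter of the pairwise-connectivity and
#' directionality stages. Defaults follow the published analysis protocol
#' this pipeline mirrors: a 10 ms STTC window chosen to privilege
#' mono-synaptic coupling, 0.5 ms correlogram bins, a mean + 5 SD
#' significance gate on the correlogram maximum, an STTC cut-off of 0.3 to
#' accept a connection, and an establishment threshold of 2 pitch units on
#' the vertical component of the assembloid vector.
#'
#' @param dt_sttc STTC half-window \eqn{\Delta t} in seconds (default 0.010).
#' @param cc_bin correlogram bin width in seconds (default 5e-4).
#' @param cc_window correlogram half-window in seconds (default 0.050).
#' @param sig_sd significance gate: maximum must exceed mean + `sig_sd` *
#'   SD of per-bin probabilities (default 5).
#' @param sig_min_count minimum coincidence count in the maximal bin for a
#'   delay to count as significant (default 5; guards the SD gate against
#'   sparsely populated correlograms, see [significant_delay]).
#' @param sttc_cutoff minimum STTC to accept a connection (default 0.3).
#' @param establishment_threshold vertical-component threshold, pitch units
#'   (default 2).
#' @param min_spikes_per_electrode electrodes with fewer spikes are excluded
#'   from pairwise analysis (default 10; STTC and correlograms are unstable
#'   below this).
#' @param detection_k spike-detection threshold in noise SDs (default 6).
#' @param burst_max_isi maximum in-burst inter-spike interval, seconds
#'   (default 0.1).
#' @param burst_min_spikes minimum spikes per burst (default 5).
#' @param attachment pair-vector attachment rule, `"both"` (each accepted
#'   pair contributes its displacement to both member electrodes; the
#'   assembloid sum is normalised by the resulting multiplicity of 2 before
#'   thresholding) or `"lead"` (lead electrode only, multiplicity 1).
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(dt_sttc = 0.010, cc_bin = 0.0005,
                            cc_window = 0.050, sig_sd = 5,
                            sig_min_count = 5,
                            sttc_cutoff = 0.3,
                            establishment_threshold = 2,
                            min_spikes_per_electrode = 10,
                            detection_k = 6,
                            burst_max_isi = 0.1, burst_min_spikes = 5,
                            attachment = c("both", "lead")) {
  attachment <- match.arg(attachment)
  num <- list(dt_sttc = dt_sttc, cc_bin = cc_bin, cc_window = cc_window,
              sig_sd = sig_sd, sig_min_count = sig_min_count,
              sttc_cutoff = sttc_cutoff,
              establishment_threshold = establishment_threshold,
              min_spikes_per_electrode = min_spikes_per_electrode,
              detection_k = detection_k, burst_max_isi = burst_max_isi,
              burst_min_spikes = burst_min_spikes)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(nm, " must be a single positive number")
  }
  if (cc_bin >= cc_window)
    stop("cc_bin must be smaller than cc_window")
  structure(c(num, list(attachment = attachment)),
            class = "analysis_config")
}

#' Read a flat key-value configuration file
#'
#' Parses a minimal YAML-like dialect: one `key: value` pair per line,
#' `#` comments and blank lines ignored. Values are converted to numeric
#' where possible. Keys matching [analysis_config] arguments override its
#' defaults; unknown keys are kept alongside (e.g. `pitch_um`,
#' `boundary_row`, which are geometry, not analysis, parameters).
#'
#' @param path file path.
#' @return list with elements `config` ([analysis_config]) and `extra`
#'   (named list of non-analysis keys).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[[`, character(1), 2L)
  vals <- vapply(kv, `[[`, character(1), 3L)
  parse1 <- function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else if (v %in% c("true", "TRUE")) TRUE
    else if (v %in% c("false", "FALSE")) FALSE else v
  }
  parsed <- stats::setNames(lapply(vals, parse1), keys)
  known <- intersect(names(parsed), names(formals(analysis_config)))
  cfg <- do.call(analysis_config, parsed[known])
  list(config = cfg, extra = parsed[setdiff(names(parsed), known)])
}
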