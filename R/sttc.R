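#' Tiling fraction of a spike train
#'
#' Fraction of the recording window covered by the union of tiles
#' `[s - dt, s + dt]` around the spikes `s`, clipped to
#' `[t_start, t_stop]`. This is the `T` ingredient of the spike time tiling
#' coefficient: the probability that a uniformly random time falls within
#' `dt` of some spike.
#'
#' @param train a [spike_train] (or a sorted numeric vector when `t_start`
#'   and `t_stop` are given).
#' @param dt tile half-width in seconds, > 0.
#' @param t_start,t_stop window override (defaults to the train's window).
#' @return fraction in `[0, 1]`.
#' @export
tiling_fraction <- function(train, dt, t_start = NULL, t_stop = NULL) {
  if (inherits(train, "spike_train")) {
    times <- train$times
    if (is.null(t_start)) t_start <- train$t_start
    if (is.null(t_stop)) t_stop <- train$t_stop
  } else {
    times <- as.numeric(train)
    stopifnot(!is.null(t_start), !is.null(t_stop))
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number")
  n <- length(times)
  if (n == 0L) return(0)
  starts <- pmax(times - dt, t_start)
  ends <- pmin(times + dt, t_stop)
  # times sorted and tiles have equal pre-clip width, so starts are sorted;
  # union length = total length minus pairwise overlaps of neighbours
  covered <- sum(ends - starts)
  if (n > 1L) {
    overlap <- pmax(0, ends[-n] - starts[-1L])
    covered <- covered - sum(overlap)
  }
  covered / (t_stop - t_start)
}

#' Proportion of spikes tiled by the partner train
#'
#' `P` ingredient of the STTC: the proportion of spikes of `a` that fall
#' within `dt` of at least one spike of `b`.
#'
#' @param a,b [spike_train] objects (sorted times).
#' @param dt half-window in seconds.
#' @return proportion in `[0, 1]`.
#' @export
tiled_proportion <- function(a, b, dt) {
  ta <- if (inherits(a, "spike_train")) a$times else as.numeric(a)
  tb <- if (inherits(b, "spike_train")) b$times else as.numeric(b)
  if (!length(ta)) stop("train a is empty")
  if (!length(tb)) return(0)
  idx <- findInterval(ta, tb)            # last tb <= each ta (0 if none)
  d_prev <- ifelse(idx >= 1L, ta - tb[pmax(idx, 1L)], Inf)
  d_next <- ifelse(idx < length(tb), tb[pmin(idx + 1L, length(tb))] - ta, Inf)
  mean(pmin(d_prev, d_next) <= dt)
}

#' Spike time tiling coefficient
#'
#' Firing-rate-insensitive pairwise synchrony measure:
#' \deqn{STTC = \frac{1}{2}\left(\frac{P_A - T_B}{1 - P_A T_B} +
#'   \frac{P_B - T_A}{1 - P_B T_A}\right)}
#' where \eqn{P_X} is the proportion of spikes of train X falling within
#' \eqn{\pm\Delta t} of any spike of the other train ([tiled_proportion])
#' and \eqn{T_X} is the tiling fraction of X ([tiling_fraction]). Values lie
#' in `[-1, 1]`; identical trains give exactly 1. If a term's denominator
#' vanishes (possible only when `P = T = 1`) it contributes 1, the
#' continuous limit of the formula.
#'
#' @param a,b non-empty [spike_train] objects sharing a window.
#' @param dt coincidence half-window \eqn{\Delta t} in seconds
#'   (default 0.010, chosen to privilege mono-synaptic coupling).
#' @return STTC value in `[-1, 1]`.
#' @export
sttc <- function(a, b, dt = 0.010) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"))
  if (!length(a$times) || !length(b$times))
    stop("sttc is undefined for empty spike trains")
  if (abs(a$t_start - b$t_start) > 1e-9 || abs(a$t_stop - b$t_stop) > 1e-9)
    stop("trains must share the same recording window")
  pa <- tiled_proportion(a, b, dt)
  pb <- tiled_proportion(b, a, dt)
  ta <- tiling_fraction(a, dt)
  tb <- tiling_fraction(b, dt)
  term <- function(p, t) {
    den <- 1 - p * t
    if (den == 0) 1 else (p - t) / den
  }
  0.5 * (term(pa, tb) + term(pb, ta))
}
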