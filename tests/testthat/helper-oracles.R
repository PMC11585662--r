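# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: proportions by dense outer() distance matrices,
# tile coverage by explicit interval merging, correlograms by enumerating
# every spike pair.

poisson_train <- function(rate, duration, id = "e") {
  n <- rpois(1L, rate * duration)
  spike_train(sort(runif(n, 0, duration)), 0, duration, id)
}

# tiling fraction by sequential interval merge (scalar loop)
tiling_brute <- function(times, dt, t0, t1) {
  if (!length(times)) return(0)
  iv <- cbind(pmax(times - dt, t0), pmin(times + dt, t1))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  total <- 0
  cur_s <- iv[1L, 1L]; cur_e <- iv[1L, 2L]
  if (nrow(iv) > 1L) for (i in 2L:nrow(iv)) {
    if (iv[i, 1L] <= cur_e) {
      cur_e <- max(cur_e, iv[i, 2L])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- iv[i, 1L]; cur_e <- iv[i, 2L]
    }
  }
  total <- total + (cur_e - cur_s)
  total / (t1 - t0)
}

# STTC by the published formula, all ingredients brute force
sttc_brute <- function(a, b, dt) {
  ta <- a$times; tb <- b$times
  d <- abs(outer(ta, tb, "-"))
  pa <- mean(apply(d, 1L, min) <= dt)
  pb <- mean(apply(d, 2L, min) <= dt)
  Ta <- tiling_brute(ta, dt, a$t_start, a$t_stop)
  Tb <- tiling_brute(tb, dt, b$t_start, b$t_stop)
  term <- function(p, t) if (1 - p * t == 0) 1 else (p - t) / (1 - p * t)
  0.5 * (term(pa, Tb) + term(pb, Ta))
}

# correlogram counts by full pair enumeration
correlogram_brute <- function(a, b, bin = 5e-4, hw = 0.05) {
  d <- as.vector(outer(b$times, a$times, "-"))
  d <- d[abs(d) <= hw]
  k_max <- as.integer(round(hw / bin))
  k <- as.integer(round(d / bin))
  k <- k[abs(k) <= k_max]
  counts <- tabulate(k + k_max + 1L, nbins = 2L * k_max + 1L)
  list(centers = seq.int(-k_max, k_max) * bin, counts = counts)
}

# a small recording on an 8x8 grid from a list of electrode -> times
quick_recording <- function(times_by_electrode, duration = 10,
                            pitch_um = 300, boundary_row = 5) {
  grid <- build_grid(pitch_um, boundary_row)
  trains <- lapply(names(times_by_electrode), function(e)
    spike_train(times_by_electrode[[e]], 0, duration, e))
  names(trains) <- names(times_by_electrode)
  mea_recording(trains, grid)
}
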