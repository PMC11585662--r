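#' Basal activity metrics for one spike train
#'
#' Number of spikes, mean inter-spike interval (ISI), and burst frequency.
#' Bursts are detected with the max-interval method: a burst is a maximal
#' run of at least `burst_min_spikes` spikes whose successive ISIs are all
#' at most `burst_max_isi`. Burst frequency is bursts per second of
#' recording. The mean ISI is defined only for trains with at least two
#' spikes (`NA` otherwise).
#'
#' @param train a [spike_train].
#' @param burst_max_isi maximum in-burst ISI, seconds (default 0.1).
#' @param burst_min_spikes minimum spikes per burst (default 5).
#' @return list with `electrode_id`, `n_spikes`, `mean_isi_s`,
#'   `n_bursts`, `burst_frequency_hz`, `duration_s`.
#' @export
basal_metrics <- function(train, burst_max_isi = 0.1, burst_min_spikes = 5) {
  stopifnot(inherits(train, "spike_train"),
            burst_max_isi > 0, burst_min_spikes >= 2)
  dur <- train$t_stop - train$t_start
  n <- length(train$times)
  mean_isi <- if (n >= 2L) mean(diff(train$times)) else NA_real_
  n_bursts <- 0L
  if (n >= burst_min_spikes) {
    short <- diff(train$times) <= burst_max_isi
    r <- rle(short)
    # a run of k short ISIs spans k + 1 spikes
    n_bursts <- sum(r$values & r$lengths >= burst_min_spikes - 1L)
  }
  list(electrode_id = train$electrode_id, n_spikes = n,
       mean_isi_s = mean_isi, n_bursts = n_bursts,
       burst_frequency_hz = n_bursts / dur, duration_s = dur)
}

#' Mean firing rate of a whole recording
#'
#' Total spikes across all electrodes divided by the number of electrodes
#' times the recording duration, in Hz.
#'
#' @param recording an [mea_recording].
#' @return firing rate in Hz.
#' @export
mean_firing_rate <- function(recording) {
  stopifnot(inherits(recording, "mea_recording"))
  dur <- recording$t_stop - recording$t_start
  if (dur <= 0) stop("recording duration must be positive")
  total <- sum(vapply(recording$trains, function(t) length(t$times),
                      integer(1)))
  total / (length(recording$trains) * dur)
}

#' Batch normalisation
#'
#' Divides each value by the mean of its batch, so every batch has output
#' mean 1. Idempotent: applying it twice equals applying it once.
#'
#' @param values numeric vector.
#' @param batch batch labels, same length as `values`.
#' @return numeric vector of normalised values.
#' @export
batch_normalize <- function(values, batch) {
  stopifnot(length(values) == length(batch))
  if (anyNA(values)) stop("values must not contain NA")
  means <- tapply(values, batch, mean)
  if (any(means == 0))
    stop("batch(es) with zero mean cannot be normalised: ",
         paste(names(means)[means == 0], collapse = ", "))
  as.numeric(values / means[as.character(batch)])
}

#' IQR proximity outlier filter
#'
#' Removes values outside the fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.
#' Quartiles use linear interpolation (R's default type 7 convention); the
#' fences depend on this choice, which is therefore fixed and documented.
#' Fewer than 4 values pass through unchanged with a warning. The filter is
#' single-pass: fences are computed once on the input (re-filtering the
#' kept set can, on rare configurations, remove further points).
#'
#' @param values numeric vector.
#' @return list with `kept`, `removed`, `fences` (`c(lower, upper)`).
#' @export
iqr_outlier_filter <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 4L) {
    warning("fewer than 4 values: outlier filter passes data through")
    return(list(kept = values, removed = numeric(0),
                fences = c(-Inf, Inf)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  fences <- c(q[1L] - 1.5 * iqr, q[2L] + 1.5 * iqr)
  in_f <- values >= fences[1L] & values <= fences[2L]
  list(kept = values[in_f], removed = values[!in_f], fences = fences)
}

#' Significance stars
#'
#' Standard star convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Dunn's post-hoc test
#'
#' All pairwise comparisons after a Kruskal-Wallis test: z statistics on
#' rank means with tie correction, two-sided normal p-values, and
#' Benjamini-Hochberg adjustment.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of group labels.
#' @return data.frame with columns `group1, group2, z, p, p_adj`.
#' @export
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- tabulate(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_corr
  lev <- levels(groups)
  cmb <- utils::combn(seq_along(lev), 2L)
  z <- p <- numeric(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1L, k]; j <- cmb[2L, k]
    se2 <- v0 * (1 / ni[i] + 1 / ni[j])
    if (se2 <= 0) {            # fully tied data: no detectable difference
      z[k] <- 0; p[k] <- 1
    } else {
      z[k] <- (rbar[[i]] - rbar[[j]]) / sqrt(se2)
      p[k] <- 2 * stats::pnorm(-abs(z[k]))
    }
  }
  data.frame(group1 = lev[cmb[1L, ]], group2 = lev[cmb[2L, ]],
             z = z, p = p, p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Routed hypothesis tests
#'
#' Implements the statistics routing used throughout this pipeline's
#' protocol. Normality of each group is assessed with the Shapiro-Wilk
#' test (alpha 0.05); groups smaller than 3 cannot be tested and force the
#' nonparametric route with a warning. If all groups pass, the parametric
#' route is used: Welch's t-test for 2 groups, one-way ANOVA with Tukey's
#' HSD for more. Otherwise the nonparametric route: two-sided Wilcoxon
#' rank-sum for 2 groups (exact when the combined n is at most 20 and
#' there are no ties, normal approximation with continuity correction
#' above), Kruskal-Wallis with Dunn's post-hoc and Benjamini-Hochberg
#' adjustment for more.
#'
#' @param groups named list of numeric vectors (>= 2 non-empty groups).
#' @param shapiro_alpha normality alpha (default 0.05).
#' @param route `"auto"` (default: route on Shapiro-Wilk normality) or an
#'   explicit `"parametric"` / `"nonparametric"` override for analyses
#'   where the scale of measurement, not a small-sample normality test,
#'   dictates the method.
#' @return list with `route` (`"parametric"`/`"nonparametric"`),
#'   `normality` (data.frame: group, n, shapiro_p), `omnibus` (method,
#'   statistic, p), `pairwise` (data.frame: group1, group2, statistic, p,
#'   p_adj, stars; `NULL` for 2 groups where the omnibus is the pairwise
#'   test), and `stars` for the omnibus p.
#' @export
hypothesis_tests <- function(groups, shapiro_alpha = 0.05,
                             route = c("auto", "parametric",
                                       "nonparametric")) {
  route <- match.arg(route)
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) == 0L)) stop("all groups must be non-empty")
  ns <- lengths(groups)
  sh_p <- rep(NA_real_, length(groups))
  can_test <- ns >= 3L & vapply(groups, function(g) length(unique(g)) > 1L,
                                logical(1))
  for (i in which(can_test))
    sh_p[i] <- stats::shapiro.test(groups[[i]])$p.value
  if (route == "auto") {
    if (any(!can_test))
      warning("group(s) too small or constant for Shapiro-Wilk; ",
              "routing to nonparametric tests")
    normal <- all(can_test) && all(sh_p > shapiro_alpha)
    route <- if (normal) "parametric" else "nonparametric"
  }
  normal <- route == "parametric"
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  pairwise <- NULL
  if (length(groups) == 2L) {
    if (normal) {
      ht <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = FALSE)
      omnibus <- list(method = "Welch two-sample t-test",
                      statistic = unname(ht$statistic), p = ht$p.value)
    } else {
      exact <- sum(ns) <= 20 && !anyDuplicated(v)
      ht <- stats::wilcox.test(groups[[1L]], groups[[2L]],
                               alternative = "two.sided", exact = exact,
                               correct = TRUE)
      omnibus <- list(method = "Wilcoxon rank-sum test (two-sided)",
                      statistic = unname(ht$statistic), p = ht$p.value)
    }
  } else if (normal) {
    fit <- stats::aov(v ~ g)
    an <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$g
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(
      group1 = vapply(nm, `[`, character(1), 2L),
      group2 = vapply(nm, `[`, character(1), 1L),
      statistic = tk[, "diff"], p = tk[, "p adj"], p_adj = tk[, "p adj"],
      stringsAsFactors = FALSE, row.names = NULL)
    omnibus <- list(method = "One-way ANOVA",
                    statistic = an[["F value"]][1L],
                    p = an[["Pr(>F)"]][1L])
  } else {
    kw <- stats::kruskal.test(v, g)
    dn <- dunn_test(v, g)
    pairwise <- data.frame(group1 = dn$group1, group2 = dn$group2,
                           statistic = dn$z, p = dn$p, p_adj = dn$p_adj,
                           stringsAsFactors = FALSE)
    omnibus <- list(method = "Kruskal-Wallis rank sum test",
                    statistic = unname(kw$statistic), p = kw$p.value)
  }
  if (!is.null(pairwise)) pairwise$stars <- p_stars(pairwise$p_adj)
  list(route = route,
       normality = data.frame(group = names(groups), n = ns,
                              shapiro_p = sh_p, stringsAsFactors = FALSE,
                              row.names = NULL),
       omnibus = omnibus, pairwise = pairwise,
       stars = p_stars(omnibus$p))
}
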