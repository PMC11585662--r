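#' Accept or reject a pairwise connection
#'
#' A connection between two electrodes is accepted when the correlogram
#' maximum passed the significance gate AND the STTC reaches the cut-off
#' (default 0.3). Both gates are required.
#'
#' @param significant logical, correlogram significance.
#' @param sttc STTC value of the pair.
#' @param sttc_cutoff acceptance threshold (default 0.3).
#' @return logical vector.
#' @export
accept_pair <- function(significant, sttc, sttc_cutoff = 0.3) {
  as.logical(significant) & !is.na(sttc) & sttc >= sttc_cutoff
}

#' Displacement vector of an accepted pair
#'
#' The displacement from the leading electrode (the one the signal leaves
#' first) to the lagging electrode, in pitch units. Its magnitude equals the
#' grid distance between the pair; it is not normalised to unit length.
#'
#' @param grid an [electrode_grid].
#' @param e_lead,e_lag electrode ids; must differ.
#' @return numeric vector `c(x, y)` in pitch units.
#' @export
pair_vector <- function(grid, e_lead, e_lag) {
  if (identical(e_lead, e_lag)) stop("lead and lag electrodes must differ")
  p <- grid_position(grid, c(e_lead, e_lag))
  c(x = unname(p[2L, "x"] - p[1L, "x"]),
    y = unname(p[2L, "y"] - p[1L, "y"]))
}

#' Per-electrode directionality vector
#'
#' Componentwise sum of the pair vectors attached to one electrode; the
#' zero vector when no accepted pair involves it.
#'
#' @param vectors numeric matrix with columns `x`, `y` (one row per
#'   attached pair vector), or `NULL`/zero rows.
#' @return numeric `c(x, y)`.
#' @export
electrode_vector <- function(vectors) {
  if (is.null(vectors) || NROW(vectors) == 0L) return(c(x = 0, y = 0))
  c(x = sum(vectors[, "x"]), y = sum(vectors[, "y"]))
}

#' Assembloid directionality field
#'
#' Builds the per-electrode directionality vectors from the accepted pairs
#' of a pairwise table, sums them into the assembloid mean vector, and
#' decides whether an inter-compartment connection is established.
#'
#' For each accepted pair the lead electrode is determined by the sign of
#' the delay (positive: `e1` leads). Pairs with an exactly zero delay carry
#' no direction and are skipped. Under the default `"both"` attachment rule
#' the pair's displacement (lead to lag) is attached to both member
#' electrodes, so the raw assembloid sum counts every pair twice; the
#' vertical (`y`) and lateral (`|x|`) components reported for thresholding
#' are therefore normalised by the attachment multiplicity (2 for
#' `"both"`, 1 for `"lead"`), making the verdict independent of the
#' attachment convention.
#'
#' The y axis points from the MO compartment towards the StrO compartment,
#' so `y > 0` means the signal travels net MO to StrO. Establishment
#' requires `|y| >= establishment_threshold` (default 2 pitch units);
#' either net direction establishes a connection.
#'
#' @param recording an [mea_recording].
#' @param pairwise data.frame from [pairwise_table].
#' @param config an [analysis_config].
#' @return A `directionality_field`: list with `electrode_vectors`
#'   (data.frame electrode, x, y), `assembloid_vector` (raw componentwise
#'   sum of the electrode vectors), `y` (signed, normalised by attachment
#'   multiplicity), `abs_x`, `established`, `threshold`, `attachment`,
#'   `n_accepted_pairs`, `mean_firing_rate_hz`, and a `conventions` block.
#' @export
assembloid_directionality <- function(recording, pairwise,
                                      config = analysis_config()) {
  stopifnot(inherits(recording, "mea_recording"),
            inherits(config, "analysis_config"))
  grid <- recording$grid
  electrodes <- grid$electrodes
  vx <- stats::setNames(numeric(length(electrodes)), electrodes)
  vy <- vx
  mult <- if (config$attachment == "both") 2 else 1
  n_acc <- 0L
  if (nrow(pairwise)) {
    acc <- accept_pair(pairwise$significant, pairwise$sttc,
                       config$sttc_cutoff)
    acc <- acc & !is.na(pairwise$delay_s) & pairwise$delay_s != 0
    for (i in which(acc)) {
      lead <- if (pairwise$delay_s[i] > 0) pairwise$e1[i] else pairwise$e2[i]
      lag <- if (pairwise$delay_s[i] > 0) pairwise$e2[i] else pairwise$e1[i]
      v <- pair_vector(grid, lead, lag)
      vx[lead] <- vx[lead] + v[["x"]]
      vy[lead] <- vy[lead] + v[["y"]]
      if (config$attachment == "both") {
        vx[lag] <- vx[lag] + v[["x"]]
        vy[lag] <- vy[lag] + v[["y"]]
      }
      n_acc <- n_acc + 1L
    }
  }
  asm <- c(x = sum(vx), y = sum(vy))
  y_norm <- asm[["y"]] / mult
  x_norm <- asm[["x"]] / mult
  established <- abs(y_norm) >= config$establishment_threshold
  structure(list(
    electrode_vectors = data.frame(electrode = electrodes,
                                   x = unname(vx), y = unname(vy),
                                   stringsAsFactors = FALSE),
    assembloid_vector = list(x = asm[["x"]], y = asm[["y"]]),
    y = y_norm, abs_x = abs(x_norm),
    established = established,
    threshold = config$establishment_threshold,
    attachment = config$attachment,
    n_accepted_pairs = n_acc,
    mean_firing_rate_hz = mean_firing_rate(recording),
    conventions = list(
      units = "pitch",
      y_axis = "positive from MO towards StrO (increasing row)",
      delay_sign = "positive delay: e1 leads e2",
      normalisation = "y and abs_x divided by attachment multiplicity")),
    class = "directionality_field")
}

#' @export
print.directionality_field <- function(x, ...) {
  cat(sprintf(
    "<directionality_field: y = %.3f, |x| = %.3f pitch units, %s (threshold %g)>\n",
    x$y, x$abs_x, if (x$established) "ESTABLISHED" else "not established",
    x$threshold))
  invisible(x)
}

#' Connection establishment verdict
#'
#' TRUE when the absolute vertical component of the assembloid vector
#' reaches the threshold (in pitch units, i.e. inter-electrode distances).
#'
#' @param field a `directionality_field`.
#' @param threshold pitch units (default: the field's stored threshold).
#' @return logical.
#' @export
connection_established <- function(field, threshold = NULL) {
  stopifnot(inherits(field, "directionality_field"))
  if (is.null(threshold)) threshold <- field$threshold
  abs(field$y) >= threshold
}

#' Directionality across maturation stages
#'
#' Summarises the vertical and lateral components per maturation stage
#' (mean and SD) and tests for a stage effect with the Kruskal-Wallis
#' omnibus test, followed by Dunn's pairwise post-hoc comparisons with
#' Benjamini-Hochberg adjustment (via [dunn_test]).
#'
#' @param fields_by_stage named list: stage label to list of
#'   `directionality_field` objects (at least 2 per stage; smaller stages
#'   are dropped with a warning).
#' @return list with `summary` (data.frame: stage, n, mean_y, sd_y,
#'   mean_abs_x, sd_abs_x), `test_y` and `test_abs_x` (each: `kruskal`
#'   htest result plus `dunn` data.frame).
#' @export
maturation_trajectory <- function(fields_by_stage) {
  stopifnot(is.list(fields_by_stage), !is.null(names(fields_by_stage)))
  sizes <- lengths(fields_by_stage)
  if (any(sizes < 2L)) {
    warning("dropping stage(s) with fewer than 2 assembloids: ",
            paste(names(fields_by_stage)[sizes < 2L], collapse = ", "))
    fields_by_stage <- fields_by_stage[sizes >= 2L]
  }
  if (length(fields_by_stage) < 2L)
    stop("need at least 2 stages with >= 2 assembloids each")
  y_vals <- lapply(fields_by_stage, function(fs)
    vapply(fs, function(f) f$y, numeric(1)))
  x_vals <- lapply(fields_by_stage, function(fs)
    vapply(fs, function(f) f$abs_x, numeric(1)))
  summ <- data.frame(
    stage = names(fields_by_stage),
    n = lengths(fields_by_stage),
    mean_y = vapply(y_vals, mean, numeric(1)),
    sd_y = vapply(y_vals, stats::sd, numeric(1)),
    mean_abs_x = vapply(x_vals, mean, numeric(1)),
    sd_abs_x = vapply(x_vals, stats::sd, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  run_tests <- function(vals) {
    g <- factor(rep(names(vals), lengths(vals)), levels = names(vals))
    v <- unlist(vals, use.names = FALSE)
    if (length(unique(v)) == 1L) {
      # all observations tied: no evidence of any stage effect
      kw <- structure(list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
                           parameter = c(df = nlevels(g) - 1),
                           p.value = 1, method = "Kruskal-Wallis rank sum test",
                           data.name = "v by g"), class = "htest")
      return(list(kruskal = kw, dunn = dunn_test(v, g)))
    }
    list(kruskal = stats::kruskal.test(v, g), dunn = dunn_test(v, g))
  }
  list(summary = summ, test_y = run_tests(y_vals),
       test_abs_x = run_tests(x_vals))
}
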