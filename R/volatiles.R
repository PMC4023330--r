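# GC/MS volatile phenotyping: internal-standard normalization, producer calls,
# five-class seasonal trend labels, and standard-curve concentration estimates.

#' Normalize a gamma-decalactone peak area to the internal standard
#'
#' GC/MS runs vary in extraction and injection efficiency; dividing the
#' analyte peak area by the area of a co-extracted internal standard
#' (3-hexanone spiked at a known concentration) yields a unitless response
#' comparable across samples and harvests.
#'
#' @param gd_area Analyte (gamma-decalactone) peak area, `>= 0`. Vectorized.
#' @param is_area Internal-standard peak area, strictly positive. Vectorized.
#' @return Numeric vector of normalized responses `gd_area / is_area`.
#' @examples
#' normalize_to_internal_standard(25000, 50000)
#' @export
normalize_to_internal_standard <- function(gd_area, is_area) {
  if (any(!is.finite(is_area)) || any(is_area <= 0)) {
    stop("internal-standard peak area must be > 0 (failed spike?)", call. = FALSE)
  }
  if (any(!is.finite(gd_area)) || any(gd_area < 0)) {
    stop("analyte peak area must be >= 0", call. = FALSE)
  }
  gd_area / is_area
}

#' Summarize a peak table into per-genotype, per-harvest volatile series
#'
#' Technical replicates are averaged (their SD retained); harvests are
#' ordered by their `harvest_id`.
#'
#' @param peaks Data frame with columns `genotype_id`, `harvest_id`,
#'   `environment`, `replicate`, `gd_area`, `is_area`.
#' @return Data frame with one row per genotype x harvest: `genotype_id`,
#'   `harvest_id`, `environment`, `mean_response`, `sd_response`,
#'   `n_replicates`.
#' @export
volatile_series <- function(peaks) {
  assert_columns(peaks, c("genotype_id", "harvest_id", "replicate",
                          "gd_area", "is_area"), "peak table")
  if (nrow(peaks) == 0L) stop("peak table is empty", call. = FALSE)
  peaks$response <- normalize_to_internal_standard(peaks$gd_area, peaks$is_area)
  key <- interaction(peaks$genotype_id, peaks$harvest_id, drop = TRUE)
  agg <- do.call(rbind, lapply(split(peaks, key), function(d) {
    data.frame(genotype_id = d$genotype_id[1L],
               harvest_id = d$harvest_id[1L],
               environment = if ("environment" %in% names(d)) d$environment[1L] else NA_character_,
               mean_response = mean(d$response),
               sd_response = stats::sd(d$response),
               n_replicates = nrow(d),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$genotype_id, agg$harvest_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Call producer / non-producer status from a volatile series
#'
#' A genotype is a PRODUCER if the volatile was detected above the noise
#' floor in any harvest. Because the trait is strongly environment- and
#' season-dependent, a NONPRODUCER call requires at least three harvests
#' all at or below the floor; with fewer harvests and no detection the call
#' is INSUFFICIENT_DATA.
#'
#' @param responses Per-harvest mean normalized responses for one genotype.
#' @param noise_floor Detection floor on the normalized response scale
#'   (`>= 0`); see [estimate_noise_floor()].
#' @param min_harvests Harvest count required to declare a non-producer
#'   (default 3).
#' @return One of `"PRODUCER"`, `"NONPRODUCER"`, `"INSUFFICIENT_DATA"`.
#' @export
call_producer_status <- function(responses, noise_floor, min_harvests = 3L) {
  if (length(responses) == 0L) stop("empty volatile series", call. = FALSE)
  assert_scalar_number(noise_floor, "noise_floor", min = 0)
  if (any(responses > noise_floor)) return("PRODUCER")
  if (length(responses) >= min_harvests) return("NONPRODUCER")
  "INSUFFICIENT_DATA"
}

#' Default noise floor from blank / non-producer responses
#'
#' The detection limit is not an instrument constant here; it is estimated
#' as mean + 3 SD of responses from blanks or from the non-producing parent,
#' and can be overridden wherever a floor is taken.
#'
#' @param blank_responses Normalized responses of blank or known-negative
#'   samples.
#' @return Scalar noise floor.
#' @export
estimate_noise_floor <- function(blank_responses) {
  if (length(blank_responses) < 2L) {
    stop("need >= 2 blank responses to estimate a noise floor", call. = FALSE)
  }
  mean(blank_responses) + 3 * stats::sd(blank_responses)
}

#' Classify the seasonal trend of a three-harvest volatile series
#'
#' Producers fall into four seasonal shapes over three harvests -- a
#' mid-season PEAK, the reciprocal VALLEY, an early-season DECREASE, and a
#' monotone INCREASE -- with NONPRODUCER as the fifth class. Comparisons are
#' relative: `a` exceeds `b` when `a > b * (1 + rel_tol)`.
#'
#' Rules (v1, v2, v3 the harvest means):
#' * NONPRODUCER: all three at or below `noise_floor`;
#' * PEAK: v2 exceeds both neighbours;
#' * VALLEY: both neighbours exceed v2;
#' * DECREASE: v1 exceeds v2 and v3, and v2 ~ v3 (within tolerance);
#' * INCREASE: v3 exceeds v2 and v2 exceeds v1.
#'
#' A flat producer profile fires none of these; ties are then broken by a
#' fixed priority (PEAK if v2 is a weak maximum, else DECREASE if v1 is,
#' else INCREASE), so the classifier is total and single-valued.
#'
#' @param responses Exactly three per-harvest mean responses, in season order.
#' @param noise_floor Detection floor (normalized response scale).
#' @param rel_tol Relative tolerance in `[0, 1)` used for "exceeds";
#'   default 0.2.
#' @return One of `"NONPRODUCER"`, `"PEAK"`, `"VALLEY"`, `"DECREASE"`,
#'   `"INCREASE"`.
#' @export
classify_seasonal_trend <- function(responses, noise_floor, rel_tol = 0.2) {
  if (length(responses) != 3L) {
    stop("seasonal trend classification requires exactly 3 harvest means",
         call. = FALSE)
  }
  assert_scalar_number(noise_floor, "noise_floor", min = 0)
  if (!is.numeric(rel_tol) || rel_tol < 0 || rel_tol >= 1) {
    stop("`rel_tol` must lie in [0, 1)", call. = FALSE)
  }
  if (any(responses < 0)) stop("responses must be >= 0", call. = FALSE)
  v1 <- responses[1L]; v2 <- responses[2L]; v3 <- responses[3L]
  if (all(responses <= noise_floor)) return("NONPRODUCER")
  exceeds <- function(a, b) a > b * (1 + rel_tol)
  if (exceeds(v2, v1) && exceeds(v2, v3)) return("PEAK")
  if (exceeds(v1, v2) && exceeds(v3, v2)) return("VALLEY")
  if (exceeds(v1, v2) && exceeds(v1, v3) &&
      abs(v2 - v3) <= rel_tol * max(v2, v3)) return("DECREASE")
  if (exceeds(v3, v2) && exceeds(v2, v1)) return("INCREASE")
  # flat or near-flat producer profile: fixed priority tie-break
  if (v2 >= v1 && v2 >= v3) return("PEAK")
  if (v1 >= v2 && v1 >= v3) return("DECREASE")
  "INCREASE"
}

#' Phenotype a whole peak table
#'
#' Convenience wrapper: builds volatile series, then per genotype calls
#' producer status and (when exactly three harvests are present) the
#' seasonal trend class.
#'
#' @inheritParams volatile_series
#' @inheritParams classify_seasonal_trend
#' @param min_harvests Harvests required for a NONPRODUCER call.
#' @return Data frame: `genotype_id`, `status`, `trend_class`, `n_harvests`.
#' @export
phenotype_volatiles <- function(peaks, noise_floor, rel_tol = 0.2,
                                min_harvests = 3L) {
  series <- volatile_series(peaks)
  out <- do.call(rbind, lapply(split(series, series$genotype_id), function(d) {
    d <- d[order(d$harvest_id), , drop = FALSE]
    status <- call_producer_status(d$mean_response, noise_floor, min_harvests)
    trend <- if (nrow(d) == 3L && status != "INSUFFICIENT_DATA") {
      classify_seasonal_trend(d$mean_response, noise_floor, rel_tol)
    } else NA_character_
    data.frame(genotype_id = d$genotype_id[1L], status = status,
               trend_class = trend, n_harvests = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fit a standard curve from spiked-puree responses
#'
#' Known amounts of the pure volatile are spiked into fruit puree and the
#' internal-standard-normalized response is regressed on concentration by
#' ordinary least squares, after subtracting the response of unspiked puree
#' (the matrix baseline).
#'
#' @param spike_mM Spike concentrations in mM (at least 3 distinct values).
#' @param responses Normalized responses at those spikes.
#' @param baseline_response Response of unspiked puree (matrix background).
#' @return An object of class `standard_curve`: `slope` (response per mM),
#'   `intercept`, `baseline`, `r_squared`, `range_mM` (calibrated range).
#' @export
fit_standard_curve <- function(spike_mM, responses, baseline_response = 0) {
  if (length(spike_mM) != length(responses)) {
    stop("spike concentrations and responses differ in length", call. = FALSE)
  }
  if (length(unique(spike_mM)) < 3L) {
    stop("standard curve requires >= 3 distinct spike concentrations",
         call. = FALSE)
  }
  if (any(spike_mM < 0)) stop("spike concentrations must be >= 0", call. = FALSE)
  assert_scalar_number(baseline_response, "baseline_response", min = 0)
  y <- responses - baseline_response
  fit <- stats::lm(y ~ spike_mM)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    baseline = baseline_response,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    range_mM = range(spike_mM[spike_mM > 0])
  ), class = "standard_curve")
}

#' Estimate a concentration from a fitted standard curve
#'
#' Inverts the calibration line; negative inversions are truncated to 0.
#' Estimates outside the calibrated spike range are returned but flagged as
#' extrapolated; estimates below the lowest spike are additionally flagged
#' as below calibration.
#'
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @param response Normalized response(s) to invert.
#' @return Data frame: `est_mM`, `extrapolated`, `below_calibration`.
#' @export
estimate_concentration <- function(curve, response) {
  if (!inherits(curve, "standard_curve")) {
    stop("`curve` must be a standard_curve object", call. = FALSE)
  }
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stop("standard curve slope must be > 0", call. = FALSE)
  }
  est <- pmax(0, (response - curve$baseline - curve$intercept) / curve$slope)
  data.frame(
    est_mM = est,
    extrapolated = est < curve$range_mM[1L] | est > curve$range_mM[2L],
    below_calibration = est < curve$range_mM[1L]
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: response = %.4g * mM + %.4g (baseline %.4g)\n",
              x$slope, x$intercept, x$baseline))
  cat(sprintf("  R^2 = %.4f; calibrated range %.3g-%.3g mM\n",
              x$r_squared, x$range_mM[1L], x$range_mM[2L]))
  invisible(x)
}
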