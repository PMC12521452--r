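# Tumor growth kinetics: volumes from masks and the log volume change rate
# (LVCR), a weighted least-squares slope of ln(volume) on time.

#' Tumor volume from a segmentation mask
#'
#' Foreground voxel count times the voxel volume, converted to cm^3.
#'
#' @param mask A [seg_mask()].
#' @return Volume in cm^3. An empty mask returns 0 with a warning and an
#'   `empty` attribute (volume 0 is invalid for LVCR).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  n <- sum(mask$voxels)
  v <- n * prod(mask$spacing) / 1000
  if (n == 0L) {
    warning("empty mask: volume 0 cm^3 is not usable for LVCR")
    attr(v, "empty") <- TRUE
  }
  v
}

#' Construct a longitudinal volume series
#'
#' Time-ordered (time, volume) observations for one patient, the substrate of
#' LVCR. Times are days from baseline (first observation at 0, strictly
#' increasing); volumes are positive, in cm^3.
#'
#' @param patient_id Identifier.
#' @param times Numeric vector of scan times in days; `times[1]` must be 0.
#' @param volumes Positive tumor volumes in cm^3, one per time.
#' @param sigma Optional positive measurement uncertainties (cm^3), required
#'   for inverse-variance weighting.
#' @return An object of class `longitudinal_series`.
#' @export
longitudinal_series <- function(patient_id, times, volumes, sigma = NULL) {
  times <- as.numeric(times); volumes <- as.numeric(volumes)
  if (length(times) != length(volumes))
    stop_mk("times and volumes must have equal length", class = "mkunet_validation_error")
  if (length(times) < 1L)
    stop_mk("series needs at least one observation", class = "mkunet_validation_error")
  if (times[1] != 0)
    stop_mk("baseline scan must be at time 0 (got ", times[1], ")",
            class = "mkunet_validation_error")
  if (any(diff(times) <= 0))
    stop_mk("times must be strictly increasing", class = "mkunet_validation_error")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop_mk("all volumes must be finite and > 0", class = "mkunet_validation_error")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(times) || any(!is.finite(sigma)) || any(sigma <= 0))
      stop_mk("sigma must be positive, one per observation",
              class = "mkunet_validation_error")
  }
  structure(list(patient_id = as.character(patient_id), times = times,
                 volumes = volumes, sigma = sigma),
            class = "longitudinal_series")
}

#' Log volume change rate (LVCR)
#'
#' The weighted least-squares slope of ln(volume) against time:
#' \deqn{\mathrm{LVCR} = \frac{\sum_i w_i (\ln V_i - \overline{\ln V}_w)(t_i - \bar t_w)}
#'                            {\sum_i w_i (t_i - \bar t_w)^2}}
#' in 1/day, where the centering means are weighted (uniform weighting then
#' reduces exactly to the ordinary least-squares slope). Weighting schemes:
#' `"uniform"` (default), `"time-interval"` (\eqn{w_i = t_i - t_{i-1}}, with
#' the undefined first weight set to the mean of the remaining interval
#' weights), and `"inverse-variance"` (\eqn{w_i = 1/\sigma_i^2}, requiring
#' `sigma`). The estimate is invariant to rescaling all weights by a positive
#' constant and to multiplying all volumes by a positive constant.
#'
#' @param series A [longitudinal_series()] with >= 2 observations.
#' @param weighting Weighting scheme (see Details).
#' @return Slope in 1/day.
#' @export
lvcr <- function(series, weighting = c("uniform", "time-interval", "inverse-variance")) {
  stopifnot(inherits(series, "longitudinal_series"))
  weighting <- match.arg(weighting)
  t <- series$times
  n <- length(t)
  if (n < 2L)
    stop_mk("LVCR needs at least 2 observations", class = "mkunet_validation_error")
  if (max(t) - min(t) <= 0)
    stop_mk("degenerate design: all scan times equal", class = "mkunet_validation_error")
  w <- switch(weighting,
    "uniform" = rep(1, n),
    "time-interval" = {
      wi <- c(NA, diff(t))
      wi[1] <- mean(wi[-1])
      wi
    },
    "inverse-variance" = {
      if (is.null(series$sigma))
        stop_mk("inverse-variance weighting requires sigma in the series",
                class = "mkunet_validation_error")
      1 / series$sigma^2
    })
  y <- log(series$volumes)
  w <- w / sum(w)
  tb <- sum(w * t); yb <- sum(w * y)
  sum(w * (y - yb) * (t - tb)) / sum(w * (t - tb)^2)
}

#' Stratify LVCR values into high/low growth
#'
#' A tumor is labeled `"high"` iff its LVCR strictly exceeds the threshold
#' (default 0.15/day).
#'
#' @param values Numeric LVCR values (1/day).
#' @param threshold Strict threshold in 1/day (default 0.15).
#' @return Factor with levels `c("low", "high")`, same length as `values`.
#' @export
stratify_lvcr <- function(values, threshold = 0.15) {
  factor(ifelse(values > threshold, "high", "low"), levels = c("low", "high"))
}
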