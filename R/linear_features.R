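# Magnitude-based sway metrics from a filtered trial and its velocity series.

#' Mean planar CoP velocity
#'
#' Mean over samples of the planar speed sqrt(vel_ap^2 + vel_ml^2), in cm/s.
#'
#' @param vel a [cop_velocity()] result.
#' @return scalar, cm/s.
#' @export
mean_planar_velocity <- function(vel) {
  stopifnot(inherits(vel, "velocity_series"))
  if (!length(vel$vel_ap)) stop("empty velocity series", call. = FALSE)
  mean(sqrt(vel$vel_ap^2 + vel$vel_ml^2))
}

#' Area of the 95% confidence ellipse of the CoP trajectory
#'
#' `pi * q95 * sqrt(lambda1 * lambda2)` where lambda are the eigenvalues of the
#' 2x2 sample covariance of (AP, ML) and q95 is the 0.95 chi-square quantile
#' with 2 df (about 5.991). A rank-deficient trajectory returns 0 with a
#' warning.
#'
#' @param trial a [cop_trial()].
#' @return scalar, cm^2.
#' @export
ellipse_area_95 <- function(trial) {
  stopifnot(inherits(trial, "cop_trial"))
  if (n_samples(trial) < 3) stop("need at least 3 samples", call. = FALSE)
  S <- stats::cov(cbind(trial$cop_ap, trial$cop_ml))
  detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(detS) || detS <= 0) {
    warning("degenerate (rank-deficient) CoP trajectory; area set to 0",
            call. = FALSE)
    return(0)
  }
  pi * qchisq(0.95, df = 2) * sqrt(detS)
}

#' Direction-specific velocity statistics
#'
#' Per axis: the mean rectified velocity (mean of |v|, cm/s) and the sample
#' standard deviation of the signed velocity (n - 1 denominator, cm/s).
#'
#' @param vel a [cop_velocity()] result.
#' @return named vector `velo_ap`, `velo_ml`, `velo_sd_ap`, `velo_sd_ml`.
#' @export
directional_velocity_stats <- function(vel) {
  stopifnot(inherits(vel, "velocity_series"))
  if (!length(vel$vel_ap)) stop("empty velocity series", call. = FALSE)
  c(velo_ap = mean(abs(vel$vel_ap)), velo_ml = mean(abs(vel$vel_ml)),
    velo_sd_ap = sd(vel$vel_ap), velo_sd_ml = sd(vel$vel_ml))
}

#' Mean frequency of sway (velocity / mean distance from center)
#'
#' Per axis: mean rectified velocity divided by the mean absolute distance from
#' the trial's spatial center (the per-axis mean position). The plain ratio is
#' used, without the 2*pi normalization some frequency variants apply; set
#' `constant` for cross-study comparability if required. Units 1/s.
#'
#' @param trial a [cop_trial()] (positions).
#' @param vel the matching [cop_velocity()] result.
#' @param constant optional multiplicative constant (default 1).
#' @return named vector `mfreq_ap`, `mfreq_ml`; `NA` with a warning where the
#'   mean distance from center is zero.
#' @export
mfreq <- function(trial, vel, constant = 1) {
  stopifnot(inherits(trial, "cop_trial"), inherits(vel, "velocity_series"))
  out <- c(mfreq_ap = NA_real_, mfreq_ml = NA_real_)
  pos <- list(trial$cop_ap, trial$cop_ml)
  v <- list(vel$vel_ap, vel$vel_ml)
  for (k in 1:2) {
    md <- mean(abs(pos[[k]] - mean(pos[[k]])))
    if (md <= 0) {
      warning("zero mean distance from center; mfreq undefined", call. = FALSE)
      next
    }
    out[k] <- constant * mean(abs(v[[k]])) / md
  }
  out
}

#' All linear sway features of a trial
#'
#' @param trial a filtered [cop_trial()].
#' @return named numeric vector: `velo`, `area`, `velo_ap`, `velo_ml`,
#'   `velo_sd_ap`, `velo_sd_ml`, `mfreq_ap`, `mfreq_ml`.
#' @export
linear_features <- function(trial) {
  vel <- cop_velocity(trial)
  c(velo = mean_planar_velocity(vel),
    area = ellipse_area_95(trial),
    directional_velocity_stats(vel),
    mfreq(trial, vel))
}
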