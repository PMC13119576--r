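#' Construct a CoP trial object
#'
#' A `cop_trial` holds one quiet-standing center-of-pressure recording: the
#' anteroposterior (AP) and mediolateral (ML) coordinate series in cm, the
#' sampling rate, and identifying labels (participant, condition, trial index).
#'
#' @param cop_ap,cop_ml numeric vectors of equal length, CoP coordinates in cm.
#' @param fs sampling frequency in Hz.
#' @param participant_id character scalar.
#' @param condition `"EO_firm"` (eyes open) or `"EC_firm"` (eyes closed).
#' @param trial_index 1-based trial number within the condition.
#' @return An object of class `cop_trial`.
#' @export
cop_trial <- function(cop_ap, cop_ml, fs = 100,
                      participant_id = "P1", condition = c("EO_firm", "EC_firm"),
                      trial_index = 1L) {
  condition <- match.arg(condition)
  cop_ap <- as.numeric(cop_ap)
  cop_ml <- as.numeric(cop_ml)
  if (length(cop_ap) != length(cop_ml))
    stop("AP and ML series must have equal length", call. = FALSE)
  if (anyNA(cop_ap) || anyNA(cop_ml))
    stop("CoP series must not contain missing values", call. = FALSE)
  stopifnot_scalar(fs, "fs", lower = 1e-12)
  stopifnot_scalar(trial_index, "trial_index", lower = 1, integer = TRUE)
  structure(list(participant_id = as.character(participant_id),
                 condition = condition,
                 trial_index = as.integer(trial_index),
                 fs = fs, cop_ap = cop_ap, cop_ml = cop_ml),
            class = "cop_trial")
}

#' @export
print.cop_trial <- function(x, ...) {
  cat(sprintf("<cop_trial> %s / %s / trial %d: %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, x$condition, x$trial_index,
              length(x$cop_ap), x$fs, length(x$cop_ap) / x$fs))
  invisible(x)
}

n_samples <- function(trial) length(trial$cop_ap)
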