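# Cohort selection, zero-phase low-pass filtering, and velocity derivation.

#' Select the older-adult analysis cohort
#'
#' Keeps participants aged >= 60 with a recorded 12-month fall count and at
#' least one firm-surface trial in each of the eyes-open and eyes-closed
#' conditions, labels them faller (falls12m >= 1) or non-faller (falls12m = 0),
#' and restricts the trial set to the selected participants.
#'
#' @param records participant metadata data.frame (see [read_metadata()]).
#' @param trials list of [cop_trial()] objects.
#' @param min_age eligibility age threshold (years).
#' @return list of class `cohort_selection`: `records` (with a `group` column),
#'   `trials`, `counts` (fallers, non-fallers, recurrent fallers with
#'   falls12m >= 2) and `excluded` (ids with reasons).
#' @export
select_cohort <- function(records, trials, min_age = 60) {
  ids_trials <- vapply(trials, function(t) t$participant_id, character(1))
  conds <- vapply(trials, function(t) t$condition, character(1))
  has_eo <- unique(ids_trials[conds == "EO_firm"])
  has_ec <- unique(ids_trials[conds == "EC_firm"])
  reasons <- character(nrow(records))
  ok_age <- !is.na(records$age) & records$age >= min_age
  ok_falls <- !is.na(records$falls12m)
  ok_trials <- records$participant_id %in% intersect(has_eo, has_ec)
  reasons[!ok_age] <- paste0("age < ", min_age)
  reasons[ok_age & !ok_falls] <- "missing falls12m"
  reasons[ok_age & ok_falls & !ok_trials] <- "missing EO or EC firm-surface trial"
  keep <- ok_age & ok_falls & ok_trials
  excluded <- data.frame(participant_id = records$participant_id[!keep],
                         reason = reasons[!keep], stringsAsFactors = FALSE)
  sel <- records[keep, , drop = FALSE]
  rownames(sel) <- NULL
  if (nrow(sel) == 0) {
    warning("empty cohort: no participant met the selection criteria",
            call. = FALSE)
    sel$group <- character(0)
    return(structure(list(records = sel, trials = list(),
                          counts = c(fallers = 0L, nonfallers = 0L,
                                     recurrent = 0L),
                          excluded = excluded),
                     class = "cohort_selection"))
  }
  sel$group <- ifelse(sel$falls12m >= 1, "faller", "nonfaller")
  keep_tr <- trials[ids_trials %in% sel$participant_id]
  structure(list(records = sel, trials = keep_tr,
                 counts = c(fallers = sum(sel$group == "faller"),
                            nonfallers = sum(sel$group == "nonfaller"),
                            recurrent = sum(sel$falls12m >= 2)),
                 excluded = excluded),
            class = "cohort_selection")
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat(sprintf("<cohort_selection> %d fallers, %d non-fallers (%d recurrent); %d trials; %d excluded\n",
              x$counts["fallers"], x$counts["nonfallers"], x$counts["recurrent"],
              length(x$trials), nrow(x$excluded)))
  invisible(x)
}

# Zero-phase filtering with reflective padding of 3*(order+1) samples per end,
# then forward and backward passes of the same filter. Each pass starts from
# steady state at its first sample (the analogue of scipy's lfilter_zi), so
# the short pad fully absorbs the edge transient.
.filtfilt_refl <- function(x, flt, order) {
  pad <- 3L * (order + 1L)
  n <- length(x)
  if (n <= pad + 1L)
    stop(sprintf("series too short to filter: %d samples, need > %d", n, pad + 1L),
         call. = FALSE)
  nstate <- max(length(flt$b), length(flt$a)) - 1L
  g <- sum(flt$b) / sum(flt$a) # DC gain
  run <- function(v) {
    as.numeric(signal::filter(flt, v, init.x = rep(v[1], nstate),
                              init.y = rep(v[1] * g, nstate)))
  }
  # odd (point-reflected) extension anchors the signal value at the edges
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Low-pass filter a CoP trial (zero phase)
#'
#' Applies a second-order Butterworth low-pass, forward and backward (zero
#' phase, effective fourth order), to both CoP channels. Edges are handled by
#' odd reflective padding of 3*(order+1) samples.
#'
#' @param trial a [cop_trial()].
#' @param cutoff cutoff frequency in Hz (default 20).
#' @param order filter order for each pass (default 2).
#' @return the filtered [cop_trial()], length preserved.
#' @export
filter_cop <- function(trial, cutoff = 20, order = 2) {
  stopifnot(inherits(trial, "cop_trial"))
  if (cutoff <= 0 || cutoff >= trial$fs / 2)
    stop("'cutoff' must lie in (0, fs/2)", call. = FALSE)
  flt <- signal::butter(order, cutoff / (trial$fs / 2), type = "low")
  trial$cop_ap <- .filtfilt_refl(trial$cop_ap, flt, order)
  trial$cop_ml <- .filtfilt_refl(trial$cop_ml, flt, order)
  trial
}

#' Instantaneous CoP velocity
#'
#' First difference of each (filtered) CoP channel multiplied by the sampling
#' frequency; the velocity series is one sample shorter than the input.
#'
#' @param trial a (filtered) [cop_trial()].
#' @return list of class `velocity_series` with `vel_ap`, `vel_ml` (cm/s), `fs`.
#' @export
cop_velocity <- function(trial) {
  stopifnot(inherits(trial, "cop_trial"))
  structure(list(vel_ap = diff(trial$cop_ap) * trial$fs,
                 vel_ml = diff(trial$cop_ml) * trial$fs,
                 fs = trial$fs),
            class = "velocity_series")
}
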