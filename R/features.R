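# Trial-level feature extraction and within-participant trial averaging.

#' Canonical CoP feature names
#'
#' The full metric set, in table order: magnitude-based metrics first, then
#' temporal-structure metrics.
#' @return character vector of 28 metric names.
#' @export
cop_feature_names <- function() {
  c("velo", "area", "velo_ap", "velo_ml", "velo_sd_ap", "velo_sd_ml",
    "mfreq_ap", "mfreq_ml",
    "mp3", "mt3", "md3", "fd", "alpha_ap", "alpha_ml",
    "sda_ds", "sda_dl", "sda_crit", "sda_crid",
    "mse1_ap", "mse10_ap", "mse40_ap", "mse1_ml", "mse10_ml", "mse40_ml",
    "det_ap", "det_ml", "lam_ap", "lam_ml")
}

# metric name -> estimator group, used to skip estimators nobody asked for
.metric_groups <- function(metrics) {
  g <- character(0)
  if (any(metrics %in% c("velo", "area", "velo_ap", "velo_ml", "velo_sd_ap",
                         "velo_sd_ml", "mfreq_ap", "mfreq_ml"))) g <- c(g, "linear")
  if (any(metrics %in% c("mp3", "mt3", "md3"))) g <- c(g, "sdc")
  if ("fd" %in% metrics) g <- c(g, "fd")
  if (any(metrics %in% c("alpha_ap", "alpha_ml"))) g <- c(g, "dfa")
  if (any(metrics %in% c("sda_ds", "sda_dl", "sda_crit", "sda_crid"))) g <- c(g, "sda")
  if (any(grepl("^mse", metrics))) g <- c(g, "mse")
  if (any(grepl("^(det|lam)_", metrics))) g <- c(g, "rqa")
  g
}

.trial_features <- function(trial, control, groups) {
  out <- setNames(rep(NA_real_, length(cop_feature_names())),
                  cop_feature_names())
  if ("linear" %in% groups) {
    lf <- suppressWarnings(linear_features(trial))
    out[names(lf)] <- lf
  }
  if ("sdc" %in% groups) {
    s <- sway_density(trial, control$sdc_radius, control$sdc_smooth_cutoff)
    out["mp3"] <- s$mp3; out["mt3"] <- s$mt3; out["md3"] <- s$md3
  }
  if ("fd" %in% groups)
    out["fd"] <- tryCatch(katz_fd(trial), error = function(e) NA_real_)
  nl_groups <- intersect(groups, c("dfa", "sda", "mse", "rqa"))
  if (length(nl_groups)) {
    chans <- list(ap = trial$cop_ap, ml = trial$cop_ml)
    if ("dfa" %in% groups) {
      for (ch in names(chans))
        out[paste0("alpha_", ch)] <- tryCatch(
          as.numeric(dfa(chans[[ch]], order = control$dfa_order)),
          error = function(e) NA_real_)
    }
    if ("sda" %in% groups) {
      sda_max <- min(control$sda_max_lag,
                     floor((n_samples(trial) - 1) / trial$fs / 1.5))
      sr <- tryCatch(sda(trial, sda_max, control$sda_short_window,
                         pmin(control$sda_long_window, sda_max)),
                     error = function(e) NULL)
      if (!is.null(sr)) {
        out["sda_ds"] <- sr$ds; out["sda_dl"] <- sr$dl
        out["sda_crit"] <- sr$crit_t; out["sda_crid"] <- sr$crit_d
      }
    }
    if ("mse" %in% groups) {
      for (ch in names(chans)) {
        for (s in control$mse_scales) {
          nm <- paste0("mse", s, "_", ch)
          if (!nm %in% names(out)) next
          out[nm] <- tryCatch(
            unname(mse(chans[[ch]], control$mse_m, control$mse_r_factor, s)),
            error = function(e) NA_real_)
        }
      }
    }
    if ("rqa" %in% groups) {
      for (ch in names(chans)) {
        rq <- tryCatch({
          x <- chans[[ch]]
          tau <- select_delay_ami(x, control$ami_max_lag, control$ami_bins)
          m <- select_dim_fnn(x, tau, control$fnn_max_dim, control$fnn_rtol,
                              control$fnn_atol, control$fnn_n_ref)
          rqa(x, embedding_spec(tau, as.integer(m)), lmin = control$rqa_lmin,
              target_rr = control$rqa_target_rr)
        }, error = function(e) NULL)
        if (!is.null(rq)) {
          out[paste0("det_", ch)] <- rq$det
          out[paste0("lam_", ch)] <- rq$lam
        }
      }
    }
  }
  out
}

#' Extract trial-averaged CoP features
#'
#' Filters each trial (zero-phase 20 Hz low-pass by default), computes the
#' requested metrics per trial, then averages within participant x condition.
#' A metric undefined on some trials is averaged over the trials where it is
#' defined, and is `NA` only if undefined on all of them. Participants with no
#' valid trial in a condition are absent from that condition's rows.
#'
#' @param trials list of [cop_trial()] objects.
#' @param metrics metric names to compute (default: all of
#'   [cop_feature_names()]). Estimators not needed for the requested metrics
#'   are skipped.
#' @param control an [nl_control()].
#' @param filter logical; low-pass filter trials first (default `TRUE`).
#' @param filter_cutoff cutoff in Hz for the trial filter.
#' @return data.frame with `participant_id`, `condition` and one column per
#'   requested metric; one row per participant x condition.
#' @export
extract_features <- function(trials, metrics = cop_feature_names(),
                             control = nl_control(), filter = TRUE,
                             filter_cutoff = 20) {
  metrics <- match.arg(metrics, cop_feature_names(), several.ok = TRUE)
  if (!length(trials)) {
    warning("no trials supplied; returning empty feature table", call. = FALSE)
    out <- data.frame(participant_id = character(0), condition = character(0))
    for (m in metrics) out[[m]] <- numeric(0)
    return(out)
  }
  groups <- .metric_groups(metrics)
  rows <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (filter) tr <- filter_cop(tr, cutoff = filter_cutoff)
    f <- .trial_features(tr, control, groups)[metrics]
    rows[[i]] <- data.frame(participant_id = tr$participant_id,
                            condition = tr$condition, t(f),
                            stringsAsFactors = FALSE)
  }
  per_trial <- do.call(rbind, rows)
  key <- interaction(per_trial$participant_id, per_trial$condition, drop = TRUE)
  agg <- lapply(split(per_trial, key), function(d) {
    vals <- vapply(metrics, function(m) {
      v <- d[[m]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    data.frame(participant_id = d$participant_id[1], condition = d$condition[1],
               t(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$condition, out$participant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
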