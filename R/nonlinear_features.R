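# Temporal-structure sway metrics: sway density, Katz fractal dimension, DFA,
# stabilogram diffusion analysis, multiscale sample entropy, and RQA with
# AMI/FNN embedding selection and recurrence-rate calibration.

#' Sway density curve and its summary indices
#'
#' For each sample t the sway density SDC(t) is the time (count / fs, in s)
#' the CoP spends within `radius` cm of CoP(t) during the trial. The curve is
#' smoothed with a zero-phase low-pass (two passes of a second-order
#' Butterworth at `smooth_cutoff` Hz) before peak picking; peaks are strict
#' local maxima. MP3 is the mean peak value (s), MT3 the mean time between
#' successive peaks (s), MD3 the mean planar distance (cm) between the CoP
#' positions at successive peaks. With fewer than 2 peaks MT3/MD3 are `NA`
#' and the result is flagged.
#'
#' @param trial a filtered [cop_trial()].
#' @param radius neighbourhood radius in cm (default 0.3).
#' @param smooth_cutoff smoothing cutoff in Hz (default 2.5).
#' @return list of class `sdc_result`: `mp3`, `mt3`, `md3`, `n_peaks`,
#'   `undefined` flag.
#' @export
sway_density <- function(trial, radius = 0.3, smooth_cutoff = 2.5) {
  stopifnot(inherits(trial, "cop_trial"))
  stopifnot_scalar(radius, "radius", lower = 1e-12)
  sdc <- cpp_sway_density_counts(trial$cop_ap, trial$cop_ml, radius) / trial$fs
  flt <- signal::butter(2, smooth_cutoff / (trial$fs / 2), type = "low")
  s <- .filtfilt_refl(sdc, flt, 2)
  n <- length(s)
  # a numerically flat curve (e.g. stationary CoP) has no real peaks; guard
  # against filter-induced machine-precision ripple
  pk <- if (diff(range(s)) <= 1e-8 * max(1, abs(mean(s)))) integer(0)
        else which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] > s[3:n]) + 1L
  if (length(pk) < 2) {
    return(structure(list(mp3 = if (length(pk)) s[pk] else NA_real_,
                          mt3 = NA_real_, md3 = NA_real_,
                          n_peaks = length(pk), undefined = TRUE),
                     class = "sdc_result"))
  }
  dpos <- sqrt(diff(trial$cop_ap[pk])^2 + diff(trial$cop_ml[pk])^2)
  structure(list(mp3 = mean(s[pk]), mt3 = mean(diff(pk)) / trial$fs,
                 md3 = mean(dpos), n_peaks = length(pk), undefined = FALSE),
            class = "sdc_result")
}

#' Katz fractal dimension of the planar CoP trajectory
#'
#' FD = log10(n) / (log10(n) + log10(d/L)) with n the number of steps
#' (samples - 1), L the total planar path length and d the maximum planar
#' distance from the first point. A straight-line trajectory gives exactly 1;
#' a degenerate (zero-length) trajectory returns 1 with a warning.
#'
#' @param trial a [cop_trial()].
#' @return scalar >= 1.
#' @export
katz_fd <- function(trial) {
  stopifnot(inherits(trial, "cop_trial"))
  n <- n_samples(trial)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  steps <- sqrt(diff(trial$cop_ap)^2 + diff(trial$cop_ml)^2)
  L <- sum(steps)
  if (L <= 0) {
    warning("degenerate trajectory (zero path length); FD set to 1", call. = FALSE)
    return(1)
  }
  d <- max(sqrt((trial$cop_ap - trial$cop_ap[1])^2 +
                (trial$cop_ml - trial$cop_ml[1])^2))
  log10(n - 1) / (log10(n - 1) + log10(d / L))
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Integrates the demeaned series, partitions the profile into non-overlapping
#' boxes of each size (forward and reversed so all data are used), removes a
#' least-squares polynomial trend of the given order per box, and computes the
#' RMS fluctuation F(n). The exponent alpha is the slope of log F(n) on log n.
#' 0.5 indicates uncorrelated noise, 1.0 1/f-like correlation, 1.5 Brownian
#' motion.
#'
#' @param series numeric vector.
#' @param box_sizes integer vector of box sizes; default about 20 log-spaced
#'   sizes from 10 to length/8.
#' @param order detrending polynomial order (default 1).
#' @return scalar alpha, with attribute `fn` (data.frame of n and F(n)).
#' @export
dfa <- function(series, box_sizes = NULL, order = 1) {
  x <- as.numeric(series)
  n <- length(x)
  if (is.null(box_sizes)) {
    box_sizes <- unique(round(exp(seq(log(10), log(max(n %/% 8, 11)),
                                      length.out = 20))))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  box_sizes <- box_sizes[box_sizes >= order + 2 & box_sizes <= n %/% 2]
  if (length(box_sizes) < 4)
    stop("fewer than 4 usable box sizes", call. = FALSE)
  if (n < 4 * max(box_sizes))
    stop("series shorter than 4 x max box size", call. = FALSE)
  y <- cumsum(x - mean(x))
  fn <- numeric(length(box_sizes))
  for (k in seq_along(box_sizes)) {
    bs <- box_sizes[k]
    nb <- n %/% bs
    X <- outer(seq_len(bs), 0:order, `^`)
    P <- X %*% solve(crossprod(X), t(X)) # hat matrix, shared by all boxes
    f2 <- 0
    for (dir in 1:2) {
      yd <- if (dir == 1) y[seq_len(nb * bs)] else rev(y)[seq_len(nb * bs)]
      Y <- matrix(yd, nrow = bs)
      R <- Y - P %*% Y
      f2 <- f2 + sum(R^2)
    }
    fn[k] <- sqrt(f2 / (2 * nb * bs))
  }
  fit <- lm(log(fn) ~ log(box_sizes))
  alpha <- unname(coef(fit)[2])
  attr(alpha, "fn") <- data.frame(n = box_sizes, fn = fn)
  alpha
}

#' Stabilogram diffusion analysis
#'
#' Computes the planar mean-square displacement MSD(dt) of the CoP trajectory
#' for lags up to `max_lag` s, fits least-squares lines (linear coordinates)
#' over a short-lag and a long-lag window, and reports the short- and long-term
#' diffusion coefficients Ds and Dl (slopes divided by 4, per-axis-equivalent,
#' cm^2/s) and the critical point (crit_t in s, crit_d in cm^2) where the two
#' fitted lines intersect.
#'
#' @param trial a filtered [cop_trial()].
#' @param max_lag maximum lag analyzed, s.
#' @param short_window,long_window lag windows (s) for the two line fits.
#' @return list of class `sda_result`: `ds`, `dl`, `crit_t`, `crit_d`, `flag`
#'   (`"ok"`, `"degenerate"` or `"no-intersection"`), `msd` (data.frame).
#' @export
sda <- function(trial, max_lag = 10, short_window = c(0.1, 0.8),
                long_window = c(2, 10)) {
  stopifnot(inherits(trial, "cop_trial"))
  fs <- trial$fs
  max_samp <- as.integer(round(max_lag * fs))
  if (n_samples(trial) <= max_samp)
    stop("trial shorter than max_lag", call. = FALSE)
  msd <- cpp_planar_msd(trial$cop_ap, trial$cop_ml, max_samp)
  lag_s <- seq_len(max_samp) / fs
  out <- list(ds = NA_real_, dl = NA_real_, crit_t = NA_real_,
              crit_d = NA_real_, flag = "ok",
              msd = data.frame(lag = lag_s, msd = msd))
  if (all(msd <= 0)) {
    out$flag <- "degenerate"
    return(structure(out, class = "sda_result"))
  }
  fit_win <- function(w) {
    i <- which(lag_s >= w[1] & lag_s <= w[2])
    coef(lm(msd[i] ~ lag_s[i]))
  }
  cs <- fit_win(short_window)
  cl <- fit_win(long_window)
  out$ds <- unname(cs[2]) / 4
  out$dl <- unname(cl[2]) / 4
  if (!is.finite(cs[2] - cl[2]) || cs[2] == cl[2]) {
    out$flag <- "no-intersection"
  } else {
    ct <- unname((cl[1] - cs[1]) / (cs[2] - cl[2]))
    if (ct <= 0 || ct > max_lag) {
      out$flag <- "no-intersection"
    } else {
      out$crit_t <- ct
      out$crit_d <- unname(cs[1] + cs[2] * ct)
    }
  }
  if (out$ds <= 0) out$flag <- "degenerate"
  structure(out, class = "sda_result")
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B) where B counts pairs of m-length templates within
#' Chebyshev distance r and A counts pairs of (m+1)-length templates,
#' self-matches excluded. Returns `NA` (saturation) when A or B is zero.
#'
#' @param series numeric vector.
#' @param m embedding dimension (default 2).
#' @param r tolerance, absolute units.
#' @return scalar, nats.
#' @export
sampen <- function(series, m = 2, r) {
  stopifnot_scalar(m, "m", lower = 1, integer = TRUE)
  stopifnot_scalar(r, "r", lower = 0)
  cnt <- cpp_sampen_counts(as.numeric(series), as.integer(m), r)
  if (cnt$A <= 0 || cnt$B <= 0) return(NA_real_)
  -log(cnt$A / cnt$B)
}

#' Multiscale entropy
#'
#' Coarse-grains the series by non-overlapping means of length `scale` and
#' computes SampEn(m, r) per scale. The tolerance r = `r_factor` times the SD
#' of the original (scale-1) series is held fixed across scales. Scales whose
#' match counts are zero return `NA` rather than 0.
#'
#' @param series numeric vector.
#' @param m embedding dimension (default 2).
#' @param r_factor tolerance as a fraction of the series SD (default 0.2).
#' @param scales integer vector of scales (default 1, 10, 40).
#' @return named numeric vector, one entropy (nats) per scale.
#' @export
mse <- function(series, m = 2, r_factor = 0.2, scales = c(1, 10, 40)) {
  x <- as.numeric(series)
  scales <- as.integer(scales)
  if (any(scales < 1)) stop("scales must be >= 1", call. = FALSE)
  if (length(x) / max(scales) < 100)
    stop("series too short for the largest scale (need length/scale >= 100)",
         call. = FALSE)
  r <- r_factor * sd(x)
  out <- setNames(numeric(length(scales)), paste0("scale_", scales))
  for (k in seq_along(scales)) {
    s <- scales[k]
    xc <- if (s == 1) x else {
      nb <- length(x) %/% s
      colMeans(matrix(x[seq_len(nb * s)], nrow = s))
    }
    out[k] <- sampen(xc, m, r)
  }
  out
}

#' Embedding delay by auto mutual information
#'
#' Histogram-based mutual information I(x_t; x_(t+tau)) for tau = 1..max_lag;
#' returns the first local minimum of the (lightly smoothed) AMI curve, falling
#' back to the first lag where I drops below I(1)/e when no local minimum
#' exists. The histogram MI estimator has a positive bias floor of about
#' (occupied bins - 1)^2 / (2n); a series whose lag-1 AMI is already at that
#' floor carries no detectable lag dependence and returns delay 1.
#'
#' @param series numeric vector (non-constant).
#' @param max_lag largest lag examined, samples.
#' @param n_bins histogram bins per axis (default 32).
#' @return integer delay in samples.
#' @export
select_delay_ami <- function(series, max_lag = 200, n_bins = 32) {
  x <- as.numeric(series)
  if (sd(x) == 0) stop("constant series: AMI undefined", call. = FALSE)
  n <- length(x)
  max_lag <- min(max_lag, n - 10L)
  bins <- cut(x, breaks = n_bins, labels = FALSE)
  nocc <- length(unique(bins))
  ami <- numeric(max_lag)
  for (tau in seq_len(max_lag)) {
    a <- bins[1:(n - tau)]
    b <- bins[(1 + tau):n]
    joint <- table(a, b) / (n - tau)
    px <- rowSums(joint); py <- colSums(joint)
    nz <- joint > 0
    ami[tau] <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  }
  bias <- (nocc - 1)^2 / (2 * n)
  if (ami[1] < 3 * bias) return(1L) # flat/independent: no structure at any lag
  # smooth against binning wiggles, then first local minimum over a +/-3 window
  sw <- 7L; w <- 3L
  if (max_lag > sw + 2 * w) {
    s <- stats::filter(ami, rep(1 / sw, sw), sides = 2)
    for (i in (sw + w):(max_lag - w)) {
      win <- s[(i - w):(i + w)]
      if (anyNA(win)) next
      if (s[i] < min(s[(i - w):(i - 1)]) && s[i] <= min(s[(i + 1):(i + w)]) &&
          s[i] < s[sw])
        return(i)
    }
  }
  below <- which(ami < ami[1] / exp(1))
  if (length(below)) below[1] else max_lag
}

#' Embedding dimension by false nearest neighbours
#'
#' For m = 1..max_dim, computes the fraction of nearest neighbours in the
#' m-dimensional delay embedding that are false by the distance-ratio (`rtol`)
#' or attractor-size (`atol`) criterion, and returns the smallest m whose FNN
#' fraction is below 1% (else `max_dim`). Reference points are subsampled with
#' a fixed stride (about `n_ref` points) for speed; results are deterministic.
#'
#' @param series numeric vector.
#' @param delay embedding delay, samples.
#' @param max_dim largest dimension tried (default 10).
#' @param rtol,atol Kennel false-neighbour thresholds (defaults 10 and 2).
#' @param n_ref approximate number of reference points (default 1000).
#' @return integer dimension, with attribute `fnn` (fractions per dimension).
#' @export
select_dim_fnn <- function(series, delay, max_dim = 10, rtol = 10, atol = 2,
                           n_ref = 1000) {
  x <- as.numeric(series)
  stopifnot_scalar(delay, "delay", lower = 1, integer = TRUE)
  if (length(x) - max_dim * delay < 10)
    stop("series too short for max_dim at this delay", call. = FALSE)
  asize <- sd(x)
  frac <- numeric(max_dim)
  chosen <- max_dim
  for (m in seq_len(max_dim)) {
    frac[m] <- cpp_fnn_fraction(x, m, as.integer(delay), as.integer(delay),
                                rtol, atol, asize, as.integer(n_ref))
    if (frac[m] < 0.01) { chosen <- m; frac <- frac[seq_len(m)]; break }
  }
  structure(as.integer(chosen), fnn = frac)
}

#' Embedding specification for RQA
#'
#' @param delay embedding delay (samples), >= 1.
#' @param dim embedding dimension, >= 1.
#' @param threshold recurrence threshold (cm), or `NULL` to calibrate.
#' @param achieved_rr recurrence rate achieved at `threshold`, if known.
#' @return list of class `embedding_spec`.
#' @export
embedding_spec <- function(delay, dim, threshold = NULL, achieved_rr = NULL) {
  stopifnot_scalar(delay, "delay", lower = 1, integer = TRUE)
  stopifnot_scalar(dim, "dim", lower = 1, integer = TRUE)
  structure(list(delay = as.integer(delay), dim = as.integer(dim),
                 threshold = threshold, achieved_rr = achieved_rr),
            class = "embedding_spec")
}

#' Recurrence quantification analysis
#'
#' Embeds the series with the given delay/dimension, calibrates the recurrence
#' threshold by bisection so the recurrence point density hits `target_rr`
#' (must land within `rr_band`), and computes determinism (DET: fraction of
#' recurrent points on diagonal lines of length >= `lmin`) and laminarity
#' (LAM: same for vertical lines). Pairs within the Theiler window of the main
#' diagonal are excluded. Euclidean norm throughout.
#'
#' @param series numeric vector (one CoP channel).
#' @param spec an [embedding_spec()]; if `NULL`, delay is selected by
#'   [select_delay_ami()] and dimension by [select_dim_fnn()].
#' @param lmin minimal line length (default 2).
#' @param theiler Theiler window in samples; default = the embedding delay.
#' @param target_rr target recurrence rate (default 0.05).
#' @param rr_band admissible achieved-RR interval (default 0.045-0.055).
#' @return list of class `rqa_result`: `det`, `lam`, `rr`, `threshold`,
#'   `delay`, `dim`, `theiler`, `n_embedded`.
#' @export
rqa <- function(series, spec = NULL, lmin = 2, theiler = NULL,
                target_rr = 0.05, rr_band = c(0.045, 0.055)) {
  x <- as.numeric(series)
  if (is.null(spec)) {
    tau <- select_delay_ami(x)
    m <- select_dim_fnn(x, tau)
    spec <- embedding_spec(tau, as.integer(m))
  }
  stopifnot(inherits(spec, "embedding_spec"))
  if (is.null(theiler)) theiler <- spec$delay
  ne <- length(x) - (spec$dim - 1) * spec$delay
  if (ne < 10) stop("embedded series shorter than 10 points", call. = FALSE)
  if (is.null(spec$threshold)) {
    cal <- cpp_rqa_calibrate(x, spec$dim, spec$delay, as.integer(theiler),
                             target_rr, 1e-4, 60L)
    if (cal$rr < rr_band[1] || cal$rr > rr_band[2]) {
      tr <- paste(sprintf("eps=%.4g rr=%.4f", cal$trace_eps, cal$trace_rr),
                  collapse = "; ")
      stop(sprintf("recurrence-rate calibration failed (achieved %.4f): %s",
                   cal$rr, tr), call. = FALSE)
    }
    spec$threshold <- cal$eps
  }
  mres <- cpp_rqa_measures(x, spec$dim, spec$delay, as.integer(theiler),
                           spec$threshold, as.integer(lmin))
  structure(list(det = mres$det, lam = mres$lam, rr = mres$rr,
                 threshold = spec$threshold, delay = spec$delay,
                 dim = spec$dim, theiler = as.integer(theiler),
                 n_embedded = ne),
            class = "rqa_result")
}

#' @export
print.rqa_result <- function(x, ...) {
  cat(sprintf("<rqa> dim=%d delay=%d theiler=%d eps=%.4g: RR=%.2f%% DET=%.3f LAM=%.3f\n",
              x$dim, x$delay, x$theiler, x$threshold, 100 * x$rr, x$det, x$lam))
  invisible(x)
}

#' Control settings for nonlinear feature extraction
#'
#' Collects the tunable constants of the temporal-structure estimators: sway
#' density radius (cm) and smoothing cutoff (Hz), DFA detrend order, SDA lag
#' windows (s), MSE parameters, AMI/FNN embedding-selection settings and RQA
#' calibration settings.
#'
#' @param sdc_radius,sdc_smooth_cutoff sway density radius (cm) and smoothing (Hz).
#' @param dfa_order DFA detrending order.
#' @param sda_max_lag,sda_short_window,sda_long_window SDA lag settings (s).
#' @param mse_m,mse_r_factor,mse_scales multiscale entropy settings.
#' @param ami_max_lag,ami_bins delay selection settings.
#' @param fnn_max_dim,fnn_rtol,fnn_atol,fnn_n_ref dimension selection settings.
#' @param rqa_lmin,rqa_target_rr RQA line length and target recurrence rate.
#' @return list of class `nl_control`.
#' @export
nl_control <- function(sdc_radius = 0.3, sdc_smooth_cutoff = 2.5,
                       dfa_order = 1,
                       sda_max_lag = 10, sda_short_window = c(0.1, 0.8),
                       sda_long_window = c(2, 10),
                       mse_m = 2, mse_r_factor = 0.2, mse_scales = c(1, 10, 40),
                       ami_max_lag = 200, ami_bins = 32,
                       fnn_max_dim = 10, fnn_rtol = 10, fnn_atol = 2,
                       fnn_n_ref = 1000,
                       rqa_lmin = 2, rqa_target_rr = 0.05) {
  structure(as.list(environment()), class = "nl_control")
}

#' All nonlinear sway features of a trial
#'
#' Computes the sway density indices, Katz FD, per-channel DFA exponents, SDA
#' diffusion parameters, multiscale entropy at the configured scales, and
#' per-channel RQA determinism/laminarity with AMI/FNN-selected embedding.
#' Estimators that are undefined on the trial (degenerate trajectory, entropy
#' saturation, failed RR calibration) yield `NA` for their features.
#'
#' @param trial a filtered [cop_trial()].
#' @param control an [nl_control()].
#' @return named numeric vector: `mp3`, `mt3`, `md3`, `fd`, `alpha_ap`,
#'   `alpha_ml`, `sda_ds`, `sda_dl`, `sda_crit`, `sda_crid`, `mse1_ap`,
#'   `mse10_ap`, `mse40_ap`, `mse1_ml`, `mse10_ml`, `mse40_ml`, `det_ap`,
#'   `det_ml`, `lam_ap`, `lam_ml`.
#' @export
nonlinear_features <- function(trial, control = nl_control()) {
  stopifnot(inherits(trial, "cop_trial"), inherits(control, "nl_control"))
  sdc <- sway_density(trial, control$sdc_radius, control$sdc_smooth_cutoff)
  sda_max <- min(control$sda_max_lag,
                 floor((n_samples(trial) - 1) / trial$fs / 1.5))
  sd_res <- tryCatch(sda(trial, sda_max, control$sda_short_window,
                         pmin(control$sda_long_window, sda_max)),
                     error = function(e) NULL)
  chans <- list(ap = trial$cop_ap, ml = trial$cop_ml)
  alpha <- mse_tab <- det <- lam <- list()
  for (ch in names(chans)) {
    x <- chans[[ch]]
    alpha[[ch]] <- tryCatch(as.numeric(dfa(x, order = control$dfa_order)),
                            error = function(e) NA_real_)
    mse_tab[[ch]] <- setNames(vapply(control$mse_scales, function(s)
      tryCatch(unname(mse(x, control$mse_m, control$mse_r_factor, s)),
               error = function(e) NA_real_), numeric(1)),
      paste0("scale_", control$mse_scales))
    rq <- tryCatch({
      tau <- select_delay_ami(x, control$ami_max_lag, control$ami_bins)
      m <- select_dim_fnn(x, tau, control$fnn_max_dim, control$fnn_rtol,
                          control$fnn_atol, control$fnn_n_ref)
      rqa(x, embedding_spec(tau, as.integer(m)), lmin = control$rqa_lmin,
          target_rr = control$rqa_target_rr)
    }, error = function(e) NULL)
    det[[ch]] <- if (is.null(rq)) NA_real_ else rq$det
    lam[[ch]] <- if (is.null(rq)) NA_real_ else rq$lam
  }
  ms <- function(ch, s) {
    v <- mse_tab[[ch]][paste0("scale_", s)]
    if (length(v)) unname(v) else NA_real_
  }
  c(mp3 = sdc$mp3, mt3 = sdc$mt3, md3 = sdc$md3,
    fd = tryCatch(katz_fd(trial), error = function(e) NA_real_),
    alpha_ap = alpha$ap, alpha_ml = alpha$ml,
    sda_ds = if (is.null(sd_res)) NA_real_ else sd_res$ds,
    sda_dl = if (is.null(sd_res)) NA_real_ else sd_res$dl,
    sda_crit = if (is.null(sd_res)) NA_real_ else sd_res$crit_t,
    sda_crid = if (is.null(sd_res)) NA_real_ else sd_res$crit_d,
    mse1_ap = ms("ap", 1), mse10_ap = ms("ap", 10), mse40_ap = ms("ap", 40),
    mse1_ml = ms("ml", 1), mse10_ml = ms("ml", 10), mse40_ml = ms("ml", 40),
    det_ap = det$ap, det_ml = det$ml, lam_ap = lam$ap, lam_ml = lam$ml)
}
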