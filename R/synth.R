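# Synthetic CoP-like signals with analytically known dynamics, and synthetic
# cohorts with known confounding / group-effect structure. These stand in for
# the public stabilometry dataset in all tests.

#' Generate power-law (colored) noise by spectral synthesis
#'
#' Builds a zero-mean, unit-SD series whose power spectrum is proportional to
#' f^-beta with beta = 2*alpha_target - 1, so its expected DFA scaling exponent
#' equals `alpha_target` (0.5 = white noise, 1.0 = 1/f noise, 1.5 = Brownian-like).
#' Synthesis uses random phases on the target amplitude spectrum followed by an
#' inverse FFT, which fixes the spectrum exactly.
#'
#' @param alpha_target target DFA exponent, in \[0.2, 1.8\].
#' @param n_samples series length (>= 100).
#' @param seed integer seed; identical seeds give identical output.
#' @return numeric vector of length `n_samples`, zero mean, unit SD.
#' @export
gen_colored_noise <- function(alpha_target, n_samples = 6000, seed = 1) {
  stopifnot_scalar(alpha_target, "alpha_target", lower = 0.2, upper = 1.8)
  stopifnot_scalar(n_samples, "n_samples", lower = 100, integer = TRUE)
  beta <- 2 * alpha_target - 1
  n <- as.integer(n_samples)
  nf <- n %/% 2
  with_seed(seed, {
    freq <- seq_len(nf) / n
    amp <- freq^(-beta / 2)
    phases <- runif(nf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = phases)
    # hermitian-symmetric spectrum, zero DC
    full <- complex(real = numeric(n))
    full[2:(nf + 1)] <- spec
    if (n %% 2 == 0) {
      full[nf + 1] <- complex(real = amp[nf] * cos(phases[nf]))
      full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
    } else {
      full[(nf + 2):n] <- Conj(spec[nf:1])
    }
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    x <- x - mean(x)
    x / sd(x)
  })
}

#' Generate a planar Ornstein-Uhlenbeck walk
#'
#' Two independent OU channels with stationary standard deviation `ou_sigma`
#' (cm) and relaxation time `ou_tau` (s), simulated by the exact discrete-time
#' update and started from the stationary distribution. The planar mean-square
#' displacement follows MSD(dt) = 4 * ou_sigma^2 * (1 - exp(-dt/ou_tau)):
#' short-lag slope 4 * ou_sigma^2 / ou_tau, long-lag plateau 4 * ou_sigma^2.
#' This bounded-random-walk structure gives the two-regime diffusion shape that
#' stabilogram diffusion analysis assumes.
#'
#' @param ou_sigma stationary SD in cm (0 gives a constant-zero series).
#' @param ou_tau relaxation time in s; must be >= 5/fs.
#' @param n_samples,fs series length and sampling rate.
#' @param seed integer seed.
#' @return matrix with `n_samples` rows and columns `ap`, `ml` (cm).
#' @export
gen_ou_walk <- function(ou_sigma, ou_tau, n_samples = 6000, fs = 100, seed = 1) {
  if (!is.numeric(ou_sigma) || length(ou_sigma) != 1 || ou_sigma < 0)
    stop("'ou_sigma' must be a single non-negative number", call. = FALSE)
  stopifnot_scalar(fs, "fs", lower = 1e-12)
  stopifnot_scalar(ou_tau, "ou_tau", lower = 5 / fs)
  stopifnot_scalar(n_samples, "n_samples", lower = 2, integer = TRUE)
  n <- as.integer(n_samples)
  if (ou_sigma == 0)
    return(matrix(0, n, 2, dimnames = list(NULL, c("ap", "ml"))))
  dt <- 1 / fs
  a <- exp(-dt / ou_tau)
  innov_sd <- ou_sigma * sqrt(1 - a^2)
  with_seed(seed, {
    out <- matrix(0, n, 2, dimnames = list(NULL, c("ap", "ml")))
    for (ch in 1:2) {
      z <- rnorm(n)
      x <- numeric(n)
      x[1] <- ou_sigma * z[1]
      for (i in 2:n) x[i] <- a * x[i - 1] + innov_sd * z[i]
      out[, ch] <- x
    }
    out
  })
}

#' Parameters for one synthetic CoP trial
#'
#' The generated signal per channel is an Ornstein-Uhlenbeck walk (the bounded
#' sway component) plus spectrally synthesized colored noise scaled to
#' `noise_sd`, with an optional sinusoidal component carrying a fraction
#' `periodic_fraction` of the total variance (used to dial regularity for the
#' entropy/recurrence estimators). `alpha_target`, `noise_sd` and
#' `periodic_fraction` may be length 2 (AP, ML) for channel-specific control.
#'
#' @param n_samples samples per trial (default 6000 = 60 s at 100 Hz).
#' @param fs sampling rate in Hz (default 100).
#' @param alpha_target DFA exponent of the colored-noise component.
#' @param periodic_fraction fraction of channel variance from a sinusoid, in \[0,1\].
#' @param ou_sigma,ou_tau OU stationary SD (cm) and relaxation time (s).
#' @param noise_sd SD (cm) of the colored-noise component.
#' @param seed integer seed.
#' @return list of class `synth_signal_params`.
#' @export
synth_signal_params <- function(n_samples = 6000, fs = 100, alpha_target = 1.0,
                                periodic_fraction = 0.1, ou_sigma = 0.35,
                                ou_tau = 1.5, noise_sd = 0.12, seed = 1) {
  stopifnot_scalar(n_samples, "n_samples", lower = 100, integer = TRUE)
  stopifnot_scalar(fs, "fs", lower = 1e-12)
  stopifnot_scalar(ou_tau, "ou_tau", lower = 1e-12)
  if (any(periodic_fraction < 0) || any(periodic_fraction > 1))
    stop("'periodic_fraction' must lie in [0, 1]", call. = FALSE)
  if (any(alpha_target < 0.2) || any(alpha_target > 1.8))
    stop("'alpha_target' must lie in [0.2, 1.8]", call. = FALSE)
  if (any(noise_sd < 0) || ou_sigma < 0)
    stop("'noise_sd' and 'ou_sigma' must be non-negative", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), fs = fs,
                 alpha_target = rep_len(alpha_target, 2),
                 periodic_fraction = rep_len(periodic_fraction, 2),
                 ou_sigma = ou_sigma, ou_tau = ou_tau,
                 noise_sd = rep_len(noise_sd, 2), seed = as.integer(seed)),
            class = "synth_signal_params")
}

# Sinusoid frequencies used for the periodic component (Hz), one per channel.
.periodic_freq <- c(ap = 0.3, ml = 0.4)

#' Generate one synthetic CoP trial
#'
#' Mixes the OU walk, colored noise and optional sinusoid described in
#' [synth_signal_params()]. With `periodic_fraction = 1` the channel is a pure
#' sinusoid whose variance equals the variance the stochastic mixture would
#' have had. Deterministic given `params$seed`.
#'
#' @param params a [synth_signal_params()] object.
#' @param participant_id,condition,trial_index labels passed to [cop_trial()].
#' @return a [cop_trial()].
#' @export
gen_cop_trial <- function(params = synth_signal_params(),
                          participant_id = "S1",
                          condition = c("EO_firm", "EC_firm"),
                          trial_index = 1L) {
  stopifnot(inherits(params, "synth_signal_params"))
  condition <- match.arg(condition)
  n <- params$n_samples
  ou <- gen_ou_walk(params$ou_sigma, params$ou_tau, n, params$fs,
                    seed = derive_seed(params$seed, "ou"))
  tt <- seq_len(n) / params$fs
  ch <- matrix(0, n, 2)
  for (k in 1:2) {
    pf <- params$periodic_fraction[k]
    nsd <- params$noise_sd[k]
    cn <- if (nsd > 0)
      nsd * gen_colored_noise(params$alpha_target[k], n,
                              seed = derive_seed(params$seed, "cn", k))
    else numeric(n)
    base <- ou[, k] + cn
    v <- params$ou_sigma^2 + nsd^2
    phase <- with_seed(derive_seed(params$seed, "ph", k), runif(1, 0, 2 * pi))
    sine <- sin(2 * pi * .periodic_freq[k] * tt + phase)
    if (pf >= 1) {
      ch[, k] <- sqrt(2 * v) * sine
    } else if (pf > 0) {
      amp <- sqrt(2 * v * pf / (1 - pf))
      ch[, k] <- base + amp * sine
    } else {
      ch[, k] <- base
    }
  }
  cop_trial(ch[, 1], ch[, 2], fs = params$fs, participant_id = participant_id,
            condition = condition, trial_index = trial_index)
}
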