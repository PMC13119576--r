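# Synthetic cohorts: participant covariate tables with controllable
# confounding between age and fall status, plus per-subject CoP trials whose
# generator parameters can be perturbed so chosen extracted features differ
# between groups by a requested standardized effect.

# Nominal covariate distribution parameters for the simulated older-adult
# cohort (means near the source population the package targets).
.cohort_age_mean <- 71
.cohort_age_sd <- 6.5

# Feature-effect injection: parameter shifted per +1 SD of the target feature.
# Gains calibrated once by simulation over the null cohort parameter
# distribution (see the methods vignette); kind says which generator knob moves.
.effect_gains <- list(
  mse1_ap    = list(kind = "pf",    channel = 1, gain = -0.43),
  mse1_ml    = list(kind = "pf",    channel = 2, gain = -0.43),
  mse10_ap   = list(kind = "pf",    channel = 1, gain = -0.23),
  mse10_ml   = list(kind = "pf",    channel = 2, gain = -0.23),
  det_ap     = list(kind = "pf",    channel = 1, gain = 0.65),
  det_ml     = list(kind = "pf",    channel = 2, gain = 0.65),
  lam_ap     = list(kind = "pf",    channel = 1, gain = 0.65),
  lam_ml     = list(kind = "pf",    channel = 2, gain = 0.65),
  alpha_ap   = list(kind = "alpha", channel = 1, gain = 0.21),
  alpha_ml   = list(kind = "alpha", channel = 2, gain = 0.21),
  velo       = list(kind = "noise", channel = 0, gain = 0.40),
  velo_ap    = list(kind = "noise", channel = 1, gain = 0.40),
  velo_ml    = list(kind = "noise", channel = 2, gain = 0.40),
  velo_sd_ap = list(kind = "noise", channel = 1, gain = 0.40),
  velo_sd_ml = list(kind = "noise", channel = 2, gain = 0.40),
  area       = list(kind = "sigma", channel = 0, gain = 0.16)
)

#' Parameters for a synthetic cohort
#'
#' @param n_fallers,n_nonfallers group sizes (>= 1).
#' @param confound_strength standardized mean shift of age in fallers (age-SD
#'   units); engineers measured confounding between age and fall status.
#' @param effect_features named numeric vector (or named list) of standardized
#'   group effects to inject into chosen extracted features, e.g.
#'   `c(mse1_ml = -0.8)`. Valid names: `r paste(names(.effect_gains), collapse=", ")`.
#' @param trials_per_condition trials per participant per condition (default 3).
#' @param n_samples,fs trial length and sampling rate.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return list of class `synth_cohort_params`.
#' @export
synth_cohort_params <- function(n_fallers, n_nonfallers, confound_strength = 0,
                                effect_features = NULL,
                                trials_per_condition = 3,
                                n_samples = 6000, fs = 100, seed = 1) {
  stopifnot_scalar(n_fallers, "n_fallers", lower = 1, integer = TRUE)
  stopifnot_scalar(n_nonfallers, "n_nonfallers", lower = 1, integer = TRUE)
  stopifnot_scalar(confound_strength, "confound_strength")
  stopifnot_scalar(trials_per_condition, "trials_per_condition", lower = 1,
                   integer = TRUE)
  eff <- unlist(effect_features)
  if (length(eff)) {
    if (is.null(names(eff)) || any(!nzchar(names(eff))))
      stop("'effect_features' must be named", call. = FALSE)
    bad <- setdiff(names(eff), names(.effect_gains))
    if (length(bad))
      stop(sprintf("unknown feature(s) in 'effect_features': %s. Valid names: %s",
                   paste(bad, collapse = ", "),
                   paste(names(.effect_gains), collapse = ", ")), call. = FALSE)
    if (any(!is.finite(eff)))
      stop("effect sizes must be finite", call. = FALSE)
  }
  structure(list(n_fallers = as.integer(n_fallers),
                 n_nonfallers = as.integer(n_nonfallers),
                 confound_strength = confound_strength,
                 effect_features = eff,
                 trials_per_condition = as.integer(trials_per_condition),
                 n_samples = as.integer(n_samples), fs = fs,
                 seed = as.integer(seed)),
            class = "synth_cohort_params")
}

# Draw per-subject signal-generator parameters (channel-specific where the
# trial generator supports it).
.draw_subject_params <- function(seed) {
  with_seed(seed, list(
    ou_sigma = 0.35 * exp(rnorm(1, 0, 0.20)),
    ou_tau   = 1.5 * exp(rnorm(1, 0, 0.15)),
    noise_sd = 0.12 * exp(rnorm(2, 0, 0.25)),
    alpha    = pmin(pmax(rnorm(2, 1.0, 0.12), 0.3), 1.7),
    pf       = stats::rbeta(2, 2, 18)
  ))
}

.apply_effects <- function(sp, effects) {
  for (nm in names(effects)) {
    g <- .effect_gains[[nm]]
    e <- effects[[nm]]
    ch <- if (g$channel == 0) 1:2 else g$channel
    if (g$kind == "pf") {
      sp$pf[ch] <- pmin(pmax(sp$pf[ch] + e * g$gain, 0), 0.95)
    } else if (g$kind == "alpha") {
      sp$alpha[ch] <- pmin(pmax(sp$alpha[ch] + e * g$gain, 0.2), 1.8)
    } else if (g$kind == "noise") {
      sp$noise_sd[ch] <- sp$noise_sd[ch] * exp(e * g$gain)
    } else if (g$kind == "sigma") {
      sp$ou_sigma <- sp$ou_sigma * exp(e * g$gain)
    }
  }
  sp
}

#' Generate a synthetic cohort of participants and CoP trials
#'
#' Participant records carry the eight propensity-model covariates (age, sex,
#' BMI, ADL, illness, number of medications, disability, orthosis/prosthesis
#' use) plus the 12-month fall count. Fallers' age is shifted by
#' `confound_strength` age-SDs to engineer confounding; fall counts for fallers
#' are drawn from \{1, 2, 3\} with probabilities \{0.8, 0.15, 0.05\} so recurrent
#' fallers are scarce. Group effects named in `effect_features` are injected by
#' shifting the corresponding per-subject generator parameters for fallers
#' (calibrated gains; realized effects are approximate). Eyes-closed trials use
#' a larger sway amplitude than eyes-open, emulating visual-condition contrast.
#'
#' @param params a [synth_cohort_params()] object.
#' @return list with `records` (data.frame, one row per participant), `trials`
#'   (list of [cop_trial()], `trials_per_condition` per condition per subject)
#'   and `subject_params` (the generator truth, for verification).
#' @export
gen_cohort <- function(params) {
  stopifnot(inherits(params, "synth_cohort_params"))
  n <- params$n_fallers + params$n_nonfallers
  is_faller <- c(rep(TRUE, params$n_fallers), rep(FALSE, params$n_nonfallers))
  ids <- sprintf("S%03d", seq_len(n))
  records <- with_seed(derive_seed(params$seed, "records"), {
    age <- rnorm(n, .cohort_age_mean, .cohort_age_sd) +
      ifelse(is_faller, params$confound_strength * .cohort_age_sd, 0)
    falls <- ifelse(is_faller,
                    sample(c(1L, 2L, 3L), n, replace = TRUE,
                           prob = c(0.8, 0.15, 0.05)),
                    0L)
    data.frame(participant_id = ids,
               age = round(age, 1),
               sex = rbinom(n, 1, 0.7),
               bmi = round(rnorm(n, 25.5, 2.9), 1),
               adl = rbinom(n, 1, 0.8),
               illness = rbinom(n, 1, 0.5),
               n_medications = stats::rpois(n, 2),
               disability = rbinom(n, 1, 0.2),
               orthosis = rbinom(n, 1, 0.1),
               falls12m = falls,
               stringsAsFactors = FALSE)
  })
  subject_params <- vector("list", n)
  trials <- vector("list", n * 2L * params$trials_per_condition)
  it <- 0L
  for (i in seq_len(n)) {
    sp <- .draw_subject_params(derive_seed(params$seed, "subj", i))
    if (is_faller[i] && length(params$effect_features))
      sp <- .apply_effects(sp, as.list(params$effect_features))
    subject_params[[i]] <- sp
    for (cond in c("EO_firm", "EC_firm")) {
      amp <- if (cond == "EC_firm") 1.3 else 1.0
      for (tr in seq_len(params$trials_per_condition)) {
        psig <- synth_signal_params(
          n_samples = params$n_samples, fs = params$fs,
          alpha_target = sp$alpha, periodic_fraction = sp$pf,
          ou_sigma = sp$ou_sigma * amp, ou_tau = sp$ou_tau,
          noise_sd = sp$noise_sd * amp,
          seed = derive_seed(params$seed, "trial", i, cond, tr))
        it <- it + 1L
        trials[[it]] <- gen_cop_trial(psig, participant_id = ids[i],
                                      condition = cond, trial_index = tr)
      }
    }
  }
  list(records = records, trials = trials, subject_params = subject_params,
       params = params)
}
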