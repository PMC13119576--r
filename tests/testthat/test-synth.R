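# Synthetic-signal and cohort generators: determinism, analytically known
# dynamical properties, and engineered cohort structure.

test_that("generators are deterministic given the seed", {
  expect_identical(gen_colored_noise(1.0, 500, seed = 7),
                   gen_colored_noise(1.0, 500, seed = 7))
  expect_identical(gen_ou_walk(0.4, 1.2, 500, 100, seed = 7),
                   gen_ou_walk(0.4, 1.2, 500, 100, seed = 7))
  p <- synth_signal_params(n_samples = 500, seed = 11)
  expect_identical(gen_cop_trial(p)$cop_ap, gen_cop_trial(p)$cop_ap)
  cp <- synth_cohort_params(3, 4, trials_per_condition = 1, n_samples = 120,
                            seed = 5)
  a <- gen_cohort(cp); b <- gen_cohort(cp)
  expect_identical(a$records, b$records)
  expect_identical(a$trials[[5]]$cop_ml, b$trials[[5]]$cop_ml)
})

test_that("colored noise hits its target DFA exponent", {
  for (target in c(0.5, 1.0, 1.5)) {
    est <- vapply(1:20, function(s)
      as.numeric(dfa(gen_colored_noise(target, 6000, seed = s))), numeric(1))
    expect_lt(abs(mean(est) - target), 0.08)
  }
})

test_that("colored noise rejects unsupported exponents and is zero-mean", {
  expect_error(gen_colored_noise(0.1, 1000), "alpha_target")
  expect_error(gen_colored_noise(2.0, 1000), "alpha_target")
  x <- gen_colored_noise(0.8, 4096, seed = 3)
  expect_lt(abs(mean(x)), 1e-10)
  expect_equal(sd(x), 1)
})

test_that("OU walk matches its closed-form planar MSD", {
  # MSD(dt) = 4 sigma^2 (1 - exp(-dt/tau)); at sigma=0.5, tau=1, dt=0.1 s
  theory <- 4 * 0.25 * (1 - exp(-0.1))
  est <- vapply(1:20, function(s) {
    w <- gen_ou_walk(0.5, 1, 6000, 100, seed = s)
    k <- 10
    mean((w[-(1:k), 1] - w[1:(6000 - k), 1])^2 +
         (w[-(1:k), 2] - w[1:(6000 - k), 2])^2)
  }, numeric(1))
  expect_lt(abs(mean(est) - theory) / theory, 0.10)
})

test_that("OU degenerate and Brownian-limit cases behave", {
  expect_true(all(gen_ou_walk(0, 1, 200, 100, seed = 1) == 0))
  # very large tau: MSD grows linearly in lag over the analysis window
  w <- gen_ou_walk(1, 500, 6000, 100, seed = 2)
  msd <- function(k) mean((w[-(1:k), 1] - w[1:(6000 - k), 1])^2 +
                          (w[-(1:k), 2] - w[1:(6000 - k), 2])^2)
  expect_lt(abs(msd(40) / msd(20) - 2), 0.35)
  expect_error(gen_ou_walk(0.5, 0.01, 200, 100), "ou_tau")
})

test_that("pure-sinusoid trials are deterministic signals with DET near 1", {
  tr <- gen_cop_trial(synth_signal_params(n_samples = 3000,
                                          periodic_fraction = 1, seed = 4))
  # exactly sinusoidal: residual of a fitted sinusoid is numerically zero
  tt <- seq_len(3000) / 100
  fit <- lm(tr$cop_ap ~ sin(2 * pi * 0.3 * tt) + cos(2 * pi * 0.3 * tt))
  expect_lt(sd(residuals(fit)), 1e-8)
  r <- rqa(tr$cop_ap, embedding_spec(83L, 2L))
  expect_gte(r$det, 0.95)
})

test_that("periodic_fraction = 0 reproduces the manual OU + noise composition", {
  p <- synth_signal_params(n_samples = 600, periodic_fraction = 0,
                           alpha_target = 0.5, seed = 21)
  tr <- gen_cop_trial(p)
  ou <- gen_ou_walk(p$ou_sigma, p$ou_tau, 600, 100,
                    seed = copsway:::derive_seed(21L, "ou"))
  cn <- p$noise_sd[1] * gen_colored_noise(0.5, 600,
                                          seed = copsway:::derive_seed(21L, "cn", 1))
  expect_equal(tr$cop_ap, ou[, "ap"] + cn)
})

test_that("cohort confounding shifts faller age by the requested amount", {
  coh <- gen_cohort(synth_cohort_params(200, 200, confound_strength = 1.0,
                                        trials_per_condition = 1,
                                        n_samples = 120, seed = 3))
  g <- coh$records$falls12m >= 1
  shift <- (mean(coh$records$age[g]) - mean(coh$records$age[!g])) / 6.5
  expect_lt(abs(shift - 1.0), 0.2)
  expect_true(all(coh$records$falls12m[g] %in% 1:3))
  expect_true(all(coh$records$falls12m[!g] == 0))
})

test_that("unknown effect feature names are rejected with the valid list", {
  expect_error(synth_cohort_params(2, 2, effect_features = c(bogus = 1)),
               "bogus.*Valid names", perl = TRUE)
  expect_error(synth_cohort_params(2, 2, effect_features = c(mse1_ml = Inf)),
               "finite")
})

test_that("null cohorts show nominal Welch type-I error on an extracted metric", {
  rej <- vapply(1:500, function(i) {
    coh <- gen_cohort(synth_cohort_params(10, 10, trials_per_condition = 1,
                                          n_samples = 150, seed = 5000 + i))
    eo <- Filter(function(t) t$condition == "EO_firm", coh$trials)
    v <- vapply(eo, function(t)
      mean_planar_velocity(cop_velocity(filter_cop(t))), numeric(1))
    ids <- vapply(eo, function(t) t$participant_id, character(1))
    g <- (coh$records$falls12m >= 1)[match(ids, coh$records$participant_id)]
    t.test(v[g], v[!g], var.equal = FALSE)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("an injected entropy deficit is recovered at roughly its nominal size", {
  # -0.8 SD on mse1_ml; realized effect must land in a band covering
  # calibration and estimator noise
  coh <- gen_cohort(synth_cohort_params(80, 80,
                                        effect_features = c(mse1_ml = -0.8),
                                        trials_per_condition = 2,
                                        n_samples = 6000, seed = 9))
  eo <- Filter(function(t) t$condition == "EO_firm", coh$trials)
  feats <- extract_features(eo, metrics = "mse1_ml",
                            control = nl_control(mse_scales = 1))
  g <- coh$records$falls12m[match(feats$participant_id,
                                  coh$records$participant_id)] >= 1
  sp <- sqrt((var(feats$mse1_ml[g]) + var(feats$mse1_ml[!g])) / 2)
  d <- (mean(feats$mse1_ml[g]) - mean(feats$mse1_ml[!g])) / sp
  expect_lt(d, -0.5)
  expect_gt(d, -1.1)
})
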