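# Propensity model, caliper matching, balance diagnostics, comparisons.

make_records <- function(n1, n0, confound = 0, seed = 1) {
  gen_cohort(synth_cohort_params(n1, n0, confound_strength = confound,
                                 trials_per_condition = 1, n_samples = 100,
                                 seed = seed))$records
}

test_that("propensity model recovers null and confounded structure", {
  rec <- make_records(150, 150, confound = 0, seed = 2)
  fit <- fit_propensity(rec)
  expect_true(all(fit$ps > 0 & fit$ps < 1))
  expect_lt(max(abs(fit$ps - 0.5)), 0.35)        # near the base rate under the null
  expect_lt(abs(fit$coefficients[["age"]]), 0.05)
  rec2 <- make_records(150, 150, confound = 1.0, seed = 3)
  fit2 <- fit_propensity(rec2)
  expect_gt(fit2$coefficients[["age"]], 0.05)    # engineered age confounding
})

test_that("single binary covariate coefficient equals the 2x2 log odds ratio", {
  # toy table: exposure x outcome counts 20/10 (treated) vs 10/25 (control)
  rec <- data.frame(
    participant_id = sprintf("P%02d", 1:65),
    age = 70, sex = 0, bmi = 25, adl = 1, illness = 0, n_medications = 0,
    disability = 0,
    orthosis = rep(c(1, 0, 1, 0), c(20, 10, 10, 25)),
    falls12m = rep(c(1, 0), c(30, 35)))
  fit <- suppressWarnings(fit_propensity(rec))
  or <- (20 / 10) / (10 / 25)
  expect_equal(unname(fit$coefficients["orthosis"]), log(or), tolerance = 1e-4)
})

test_that("separation triggers the penalized fallback with a warning", {
  rec <- make_records(20, 20, seed = 4)
  rec$illness <- as.integer(rec$falls12m >= 1)   # perfect separator
  expect_warning(fit <- fit_propensity(rec), "separation")
  expect_identical(fit$method, "ridge")
  expect_true(all(is.finite(fit$logit_ps)))
})

test_that("matching respects the caliper, never reuses controls, honors order", {
  for (s in 1:10) {
    rec <- make_records(15, 30, confound = 0.8, seed = s)
    fit <- fit_propensity(rec)
    m <- nn_caliper_match(fit)
    expect_lte(m$n_pairs, 15)
    expect_false(any(duplicated(m$pairs$nonfaller_id)))
    expect_false(any(duplicated(m$pairs$faller_id)))
    expect_true(all(m$pairs$distance <= m$caliper))
    expect_equal(m$n_pairs + length(m$unmatched), 15)
  }
})

test_that("matching equals a hand-traced greedy assignment on a toy set", {
  fit <- structure(list(
    ps = plogis(c(2.0, 0.0, -1.0, 1.8, 0.1, -0.9)),
    logit_ps = c(2.0, 0.0, -1.0, 1.8, 0.1, -0.9),
    participant_id = c("T1", "T2", "T3", "C1", "C2", "C3"),
    treated = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    coefficients = NULL, method = "ml"), class = "propensity_fit")
  # caliper = 0.2 * sd(logit) = 0.2 * 1.3784 = 0.2757
  # order: T1 (2.0) -> C1 (|0.2|); T2 (0.0) -> C2 (|0.1|); T3 (-1.0) -> C3 (|0.1|)
  m <- nn_caliper_match(fit)
  expect_equal(m$pairs$faller_id, c("T1", "T2", "T3"))
  expect_equal(m$pairs$nonfaller_id, c("C1", "C2", "C3"))
  # tighten the caliper: only the 0.1-distance matches survive
  m2 <- nn_caliper_match(fit, caliper_mult = 0.15 / sd(fit$logit_ps))
  expect_equal(m2$n_pairs, 2L)
  expect_equal(m2$unmatched, "T1")
  # all controls out of caliper: nothing matched
  m3 <- nn_caliper_match(fit, caliper_mult = 1e-6)
  expect_equal(m3$n_pairs, 0L)
  expect_setequal(m3$unmatched, c("T1", "T2", "T3"))
})

test_that("SMD table follows its definition and label symmetry", {
  rec <- make_records(40, 40, seed = 5)
  rec$age <- rep(c(70, 70), each = 40)           # identical -> SMD 0
  tab <- smd_table(rec)
  expect_equal(tab$smd_before[tab$covariate == "age"], 0)
  # means exactly 1 pooled SD apart
  rec$age <- c(rnorm(40, 80, 5), rnorm(40, 80, 5))
  g <- rec$falls12m >= 1
  rec$age[g] <- rec$age[g] - mean(rec$age[g]) + mean(rec$age[!g]) +
    sqrt((var(rec$age[g]) + var(rec$age[!g])) / 2)
  tab2 <- smd_table(rec)
  expect_equal(tab2$smd_before[tab2$covariate == "age"], 1, tolerance = 1e-10)
  # binary covariate formula
  p1 <- mean(rec$illness[g]); p0 <- mean(rec$illness[!g])
  expect_equal(tab2$smd_before[tab2$covariate == "illness"],
               abs(p1 - p0) / sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2))
  # swapping group labels leaves the absolute SMDs unchanged
  rec_sw <- rec; rec_sw$falls12m <- ifelse(rec$falls12m >= 1, 0L, 1L)
  expect_equal(smd_table(rec_sw)$smd_before, tab2$smd_before)
})

test_that("Welch comparisons reproduce the textbook formulas", {
  x1 <- c(5.1, 4.8, 6.2, 5.5, 5.9); x0 <- c(4.2, 4.9, 3.8, 4.4, 4.1)
  feats <- data.frame(
    participant_id = c(sprintf("F%d", 1:5), sprintf("N%d", 1:5)),
    condition = "EO_firm", velo = c(x1, x0))
  match <- structure(list(pairs = data.frame(faller_id = sprintf("F%d", 1:5),
                                             nonfaller_id = sprintf("N%d", 1:5),
                                             distance = 0),
                          caliper = 1, n_pairs = 5L, unmatched = character(0)),
                     class = "cop_match")
  tab <- welch_compare(feats, NULL, match)
  o <- oracle_welch(x1, x0)
  expect_equal(tab$t, o$t, tolerance = 1e-12)
  expect_equal(tab$df, o$df, tolerance = 1e-12)
  expect_equal(tab$p, o$p, tolerance = 1e-12)
  expect_lte(tab$df, 8)
  # equal group means give t exactly 0
  feats2 <- feats; feats2$velo <- rep(c(1, 2, 3, 4, 5), 2)
  expect_equal(welch_compare(feats2, NULL, match)$t, 0)
})

test_that("adjusted analysis removes a purely age-driven difference", {
  rec <- make_records(60, 60, confound = 1.2, seed = 6)
  fit <- fit_propensity(rec)
  # feature driven only by age: raw difference large, adjusted ~ 0
  feats <- data.frame(participant_id = rec$participant_id,
                      condition = "EO_firm",
                      velo = 0.5 * rec$age + rnorm(120, 0, 0.1))
  g <- rec$falls12m >= 1
  raw_diff <- mean(feats$velo[g]) - mean(feats$velo[!g])
  expect_gt(abs(raw_diff), 1)
  sens <- sensitivity_analyses(feats, rec, fit)
  expect_lt(abs(sens$adj_estimate), 0.15)
  expect_lt(abs(sens$strat_estimate), abs(raw_diff))
})

test_that("adjusted analysis recovers an injected group effect", {
  set.seed(7)
  rec <- make_records(100, 100, confound = 0.5, seed = 7)
  g <- rec$falls12m >= 1
  feats <- data.frame(participant_id = rec$participant_id,
                      condition = "EO_firm",
                      velo = rnorm(200) + 1.0 * g + 0.05 * rec$age)
  fit <- fit_propensity(rec)
  sens <- sensitivity_analyses(feats, rec, fit)
  expect_lt(abs(sens$adj_estimate - 1.0), 0.3)
  # null: no effect, no confounding
  rec0 <- make_records(100, 100, seed = 8)
  feats0 <- data.frame(participant_id = rec0$participant_id,
                       condition = "EO_firm", velo = rnorm(200))
  sens0 <- sensitivity_analyses(feats0, rec0, fit_propensity(rec0))
  expect_lt(abs(sens0$adj_estimate), 0.3)
})
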