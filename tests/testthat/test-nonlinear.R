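# Temporal-structure estimators against independent oracles and known limits.

test_that("Katz FD is exactly 1 on a line and matches the naive formula", {
  line <- cop_trial(seq(0, 1, length.out = 100), seq(0, 2, length.out = 100))
  expect_equal(katz_fd(line), 1)
  for (s in 1:5) {
    tr <- make_test_trial(seed = s, n = 500)
    fd <- katz_fd(tr)
    expect_gte(fd, 1)
    expect_equal(fd, oracle_katz(tr$cop_ap, tr$cop_ml), tolerance = 1e-12)
  }
  expect_warning(fd0 <- katz_fd(cop_trial(rep(0, 10), rep(0, 10))), "degenerate")
  expect_equal(fd0, 1)
})

test_that("DFA recovers the exponents of white and Brownian noise", {
  w <- vapply(1:10, function(s) { set.seed(s)
    as.numeric(dfa(rnorm(6000))) }, numeric(1))
  expect_lt(abs(mean(w) - 0.5), 0.05)
  b <- vapply(1:10, function(s) { set.seed(s)
    as.numeric(dfa(cumsum(rnorm(6000)))) }, numeric(1))
  expect_lt(abs(mean(b) - 1.5), 0.08)
  expect_error(dfa(rnorm(30)), "box sizes")
  # sign-flip invariance
  set.seed(3); x <- rnorm(2000)
  expect_equal(as.numeric(dfa(x)), as.numeric(dfa(-x)))
})

test_that("sample entropy agrees exactly with the brute-force oracle", {
  for (s in 1:4) {
    set.seed(s)
    x <- rnorm(300)
    r <- 0.2 * sd(x)
    expect_equal(sampen(x, 2, r), oracle_sampen(x, 2, r), tolerance = 1e-12)
    expect_equal(sampen(x, 3, r), oracle_sampen(x, 3, r), tolerance = 1e-12)
  }
  # exactly periodic signal: perfect regularity, entropy near 0 (the only
  # mismatches sit at the sawtooth discontinuities)
  saw <- rep(seq(0, 1, length.out = 25), 20)
  expect_lt(sampen(saw, 2, 0.2 * sd(saw)), 0.05)
  # saturation returns NA, never 0
  expect_true(is.na(sampen(c(1e3, -1e3, 5e2, -7e2, 0, 1e3, -1e3, 2e2, 900, -40),
                           2, 1e-6)))
})

test_that("multiscale entropy uses a fixed tolerance and declines with scale", {
  set.seed(11); x <- rnorm(6000)
  v <- mse(x, scales = c(1, 10, 40))
  expect_true(all(diff(v) < 0))          # coarse-graining shrinks variance vs fixed r
  expect_true(all(v > 0))
  # fixed r from the scale-1 SD: entropy at scale s of white noise is close to
  # the analytic pairwise-match value with sigma_s = sigma/sqrt(s)
  p10 <- 2 * pnorm(0.2 / sqrt(2 / 10)) - 1
  expect_lt(abs(v[["scale_10"]] - (-log(p10))), 0.12)
  expect_error(mse(rnorm(500), scales = 40), "too short")
  expect_equal(mse(x, scales = 1), mse(-x, scales = 1))
})

test_that("SDA recovers the diffusion coefficient of planar Brownian motion", {
  D <- 0.005; fs <- 100
  est <- sapply(1:10, function(s) { set.seed(s)
    tr <- cop_trial(cumsum(rnorm(6000, 0, sqrt(2 * D / fs))),
                    cumsum(rnorm(6000, 0, sqrt(2 * D / fs))), fs = fs)
    r <- sda(tr)
    c(r$ds, r$dl)
  })
  expect_lt(abs(mean(est[1, ]) - D) / D, 0.15)
  expect_lt(abs(mean(est[2, ]) - D) / D, 0.15)
})

test_that("SDA shows the two-regime structure of a bounded (OU) walk", {
  w <- gen_ou_walk(0.5, 1, 6000, 100, seed = 3)
  r <- sda(cop_trial(w[, 1], w[, 2]))
  expect_equal(r$flag, "ok")
  expect_gt(r$ds, 0.25 / 4)              # short-term slope, attenuated by the window
  expect_lt(r$ds, 0.25)                  # but below the instantaneous sigma^2/tau
  expect_lt(abs(r$dl), 0.02)             # long-term plateau
  expect_gt(r$crit_t, 0.3); expect_lt(r$crit_t, 4)  # on the order of tau
  rc <- sda(cop_trial(rep(1, 2000), rep(1, 2000)))
  expect_equal(rc$flag, "degenerate")
})

test_that("sway density matches constructed dwell geometries", {
  # constant CoP: every sample within radius -> SDC = 60 s, at most 1 peak
  const <- cop_trial(rep(0.2, 6000), rep(-0.1, 6000))
  s <- sway_density(const)
  expect_true(s$undefined)
  expect_true(is.na(s$mt3) && is.na(s$md3))
  # two dwell clusters 3 cm apart, visited alternately: MD3 ~ 3 cm
  fs <- 100; dwell <- 60; hop <- 10; ncyc <- 14
  set.seed(1)
  ap <- numeric(0)
  for (k in seq_len(ncyc)) {
    cen <- if (k %% 2 == 1) 0 else 3
    ap <- c(ap, cen + 0.02 * rnorm(dwell), seq(cen, 3 - cen, length.out = hop))
  }
  tr <- cop_trial(ap, rep(0, length(ap)), fs = fs)
  s2 <- sway_density(tr)
  expect_false(s2$undefined)
  expect_lt(abs(s2$md3 - 3), 0.5)
  # trajectory moving far faster than the radius: tiny sway density peaks
  fast <- cop_trial(seq(0, 60, length.out = 3000),
                    seq(0, 60, length.out = 3000), fs = fs)
  s3 <- sway_density(fast)
  expect_lt(max(s3$mp3, 0, na.rm = TRUE), 0.3)
})

test_that("AMI delay selection: quarter-period for rhythms, 1 for white noise", {
  set.seed(5)
  x <- sin(2 * pi * 0.3 * (1:6000) / 100) + 0.05 * rnorm(6000) # period 333
  tau <- select_delay_ami(x)
  expect_gte(tau, 333 / 8); expect_lte(tau, 333 / 2)
  set.seed(6)
  expect_equal(select_delay_ami(rnorm(6000)), 1L)
  w <- rnorm(3000)
  expect_identical(select_delay_ami(w), select_delay_ami(w))
  expect_error(select_delay_ami(rep(1, 1000)), "constant")
})

test_that("FNN dimension: 2 for a limit cycle, saturating for noise", {
  x <- sin(2 * pi * 0.3 * (1:6000) / 100)
  expect_equal(as.integer(select_dim_fnn(x, 83L)), 2L)
  set.seed(8)
  expect_equal(as.integer(select_dim_fnn(rnorm(4000), 1L, max_dim = 8)), 8L)
  y <- rnorm(2000)
  expect_identical(as.integer(select_dim_fnn(y, 2L)),
                   as.integer(select_dim_fnn(y, 2L)))
  expect_error(select_dim_fnn(rnorm(50), 10L), "too short")
})

test_that("RQA agrees exactly with naive line counting on small series", {
  for (s in 1:3) {
    set.seed(s)
    x <- as.numeric(arima.sim(list(ar = 0.9), 100))
    spec0 <- embedding_spec(2L, 3L)
    r <- rqa(x, spec0, lmin = 2, theiler = 2, rr_band = c(0.03, 0.08))
    o <- oracle_rqa(x, 3, 2, r$threshold, 2, 2)
    expect_equal(r$rr, o$rr, tolerance = 1e-12)
    expect_equal(r$det, o$det, tolerance = 1e-12)
    expect_equal(r$lam, o$lam, tolerance = 1e-12)
  }
})

test_that("RQA separates periodic from stochastic dynamics and stays in range", {
  sine <- sin(2 * pi * 0.3 * (1:3000) / 100)
  rs <- rqa(sine, embedding_spec(83L, 2L))
  expect_gte(rs$det, 0.95)
  # delay >= 2 so embedded vectors share no samples (the overlap artifact of
  # delay-1 embeddings inflates DET even for noise)
  set.seed(9); w <- rnorm(3000)
  rw <- rqa(w, embedding_spec(5L, 3L))
  expect_lt(rw$det, 0.5 * rs$det)
  for (r in list(rs, rw)) {
    expect_true(r$det >= 0 && r$det <= 1)
    expect_true(r$lam >= 0 && r$lam <= 1)
    expect_true(r$rr >= 0.045 && r$rr <= 0.055)
  }
  # channel-offset invariance
  r2 <- rqa(sine + 7, embedding_spec(83L, 2L))
  expect_equal(r2$det, rs$det, tolerance = 1e-10)
})
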