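# Independent brute-force reference implementations used as oracles. These are
# written directly from the definitions and share no code with the package
# internals.

# Sample entropy by explicit template enumeration (Chebyshev distance,
# self-matches excluded, templates limited to the first N - m start points).
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Recurrence measures by explicit construction of the full recurrence matrix
# and naive line counting. Conventions: symmetric matrix, pairs with
# |i - j| <= theiler excluded, diagonal/vertical lines of length >= lmin,
# runs broken by the Theiler band.
oracle_rqa <- function(x, dim, delay, eps, theiler, lmin) {
  ne <- length(x) - (dim - 1) * delay
  emb <- sapply(0:(dim - 1), function(k) x[(1 + k * delay):(ne + k * delay)])
  emb <- matrix(emb, nrow = ne)
  D <- as.matrix(dist(emb))
  R <- D <= eps
  excl <- abs(row(R) - col(R)) <= theiler
  R[excl] <- FALSE
  n_rec <- sum(R)
  if (n_rec == 0) return(list(rr = 0, det = NA, lam = NA))
  count_runs <- function(v) {
    tot <- 0; run <- 0
    for (z in c(v, FALSE)) {
      if (z) run <- run + 1
      else { if (run >= lmin) tot <- tot + run; run <- 0 }
    }
    tot
  }
  n_diag <- 0
  for (d in setdiff(-(ne - 1):(ne - 1), 0)) {
    idx <- which(row(R) - col(R) == d, arr.ind = FALSE)
    v <- R[idx][order(row(R)[idx])]
    n_diag <- n_diag + count_runs(v)
  }
  n_vert <- sum(apply(R, 2, count_runs))
  denom <- sum(!excl) / 2
  list(rr = (n_rec / 2) / denom, det = n_diag / n_rec, lam = n_vert / n_rec)
}

# Katz fractal dimension evaluated directly from the published formula.
oracle_katz <- function(ap, ml) {
  L <- sum(sqrt(diff(ap)^2 + diff(ml)^2))
  d <- max(sqrt((ap - ap[1])^2 + (ml - ml[1])^2))
  n <- length(ap) - 1
  log10(n) / (log10(n) + log10(d / L))
}

# Welch's t-test from the textbook formulas.
oracle_welch <- function(x1, x0) {
  v1 <- var(x1) / length(x1); v0 <- var(x0) / length(x0)
  t <- (mean(x1) - mean(x0)) / sqrt(v1 + v0)
  df <- (v1 + v0)^2 / (v1^2 / (length(x1) - 1) + v0^2 / (length(x0) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Quick synthetic trial for tests.
make_test_trial <- function(seed = 1, n = 3000, pf = 0.1, ...) {
  gen_cop_trial(synth_signal_params(n_samples = n, periodic_fraction = pf,
                                    seed = seed, ...))
}

# Feature table with an exactly planted standardized group-mean shift in one
# feature (pooled-SD units), all other features null.
make_planted_features <- function(n1, n0, p = 28, effect = 1.5, feature = 5,
                                  seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n1 + n0) * p), n1 + n0, p,
              dimnames = list(NULL, cop_feature_names()[seq_len(p)]))
  y <- rep(c(1L, 0L), c(n1, n0))
  x1 <- X[y == 1, feature]; x0 <- X[y == 0, feature]
  sp <- sqrt(((n1 - 1) * var(x1) + (n0 - 1) * var(x0)) / (n1 + n0 - 2))
  X[y == 1, feature] <- x1 - mean(x1) + mean(x0) + effect * sp
  list(X = X, y = y)
}
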