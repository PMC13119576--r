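# Propensity-score estimation, 1:1 nearest-neighbor caliper matching, balance
# diagnostics, matched Welch comparisons, and covariate-adjusted / PS-stratified
# sensitivity analyses.

.ps_covariates <- c("age", "sex", "bmi", "adl", "illness", "n_medications",
                    "disability", "orthosis")

#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of fall status (falls12m >= 1) on the
#' eight covariates: age, sex, BMI, ADL level, illness, number of medications,
#' disability, orthosis/prosthesis use. If the fit separates (fitted
#' probabilities pinned at 0/1 or non-convergence), a weakly ridge-penalized
#' fit (lambda = 1e-4 on standardized covariates) is used instead, with a
#' warning.
#'
#' @param records participant data.frame with the covariates and `falls12m`.
#' @return object of class `propensity_fit`: `coefficients`, `ps`, `logit_ps`,
#'   `participant_id`, `treated` (logical), `method`.
#' @export
fit_propensity <- function(records) {
  miss <- setdiff(c(.ps_covariates, "falls12m", "participant_id"),
                  names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(complete.cases(records[, .ps_covariates])))
    stop("covariates must be complete", call. = FALSE)
  y <- as.integer(records$falls12m >= 1)
  if (length(unique(y)) < 2)
    stop("need at least one participant in each group", call. = FALSE)
  X <- as.matrix(records[, .ps_covariates])
  storage.mode(X) <- "double"
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ X, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  eps <- 1e-8
  if (!sep) sep <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  if (!sep) {
    ps <- unname(fit$fitted.values)
    cf <- setNames(coef(fit), c("(Intercept)", .ps_covariates))
    method <- "ml"
  } else {
    warning("separation detected in the propensity model; using a weakly ridge-penalized fit",
            call. = FALSE)
    mu <- colMeans(X); sdev <- apply(X, 2, sd); sdev[sdev == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
    rfit <- .ridge_logistic(Xs, y, lambda = 1e-4, max_iter = 200)
    ps <- plogis(rfit$a0 + as.numeric(Xs %*% rfit$beta))
    b <- rfit$beta / sdev
    cf <- setNames(c(rfit$a0 - sum(rfit$beta * mu / sdev), b),
                   c("(Intercept)", .ps_covariates))
    method <- "ridge"
  }
  ps <- pmin(pmax(ps, 1e-12), 1 - 1e-12)
  structure(list(coefficients = cf, ps = ps, logit_ps = qlogis(ps),
                 participant_id = records$participant_id,
                 treated = y == 1L, method = method),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("<propensity_fit> (%s) %d treated / %d control; PS range [%.3f, %.3f]\n",
              x$method, sum(x$treated), sum(!x$treated), min(x$ps), max(x$ps)))
  invisible(x)
}

#' 1:1 nearest-neighbor caliper matching on the propensity score
#'
#' Matches each faller (treatment group; ATT estimand) to the nearest unmatched
#' non-faller by absolute distance on the logit propensity score, without
#' replacement, within a caliper of `caliper_mult` times the SD of the logit
#' propensity scores. Treated units are processed in descending PS order; ties
#' (in processing order and in distance) are broken by record order.
#'
#' @param fit a [fit_propensity()] result.
#' @param caliper_mult caliper width as a multiple of SD(logit PS), default 0.2.
#' @return object of class `cop_match`: `pairs` (data.frame `faller_id`,
#'   `nonfaller_id`, `distance`), `caliper`, `n_pairs`, `unmatched` (treated ids
#'   left unmatched).
#' @export
nn_caliper_match <- function(fit, caliper_mult = 0.2) {
  stopifnot(inherits(fit, "propensity_fit"))
  caliper <- caliper_mult * sd(fit$logit_ps)
  tr_idx <- which(fit$treated)
  co_idx <- which(!fit$treated)
  # descending PS; ties by record order (stable sort on -ps)
  tr_idx <- tr_idx[order(-fit$ps[tr_idx])]
  used <- logical(length(fit$ps))
  pairs <- list()
  unmatched <- character(0)
  for (i in tr_idx) {
    avail <- co_idx[!used[co_idx]]
    if (!length(avail)) { unmatched <- c(unmatched, fit$participant_id[i]); next }
    d <- abs(fit$logit_ps[avail] - fit$logit_ps[i])
    j <- avail[which.min(d)] # which.min returns the first minimum: record order
    if (min(d) <= caliper) {
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(faller_id = fit$participant_id[i],
                   nonfaller_id = fit$participant_id[j],
                   distance = min(d), stringsAsFactors = FALSE)
    } else {
      unmatched <- c(unmatched, fit$participant_id[i])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(faller_id = character(0), nonfaller_id = character(0),
               distance = numeric(0))
  structure(list(pairs = pairs, caliper = caliper, n_pairs = nrow(pairs),
                 unmatched = unmatched),
            class = "cop_match")
}

#' @export
print.cop_match <- function(x, ...) {
  cat(sprintf("<cop_match> %d pairs (caliper %.4f logit units), %d treated unmatched\n",
              x$n_pairs, x$caliper, length(x$unmatched)))
  invisible(x)
}

.smd_one <- function(x1, x0) {
  vals <- unique(c(x1, x0))
  if (all(vals %in% c(0, 1))) {
    p1 <- mean(x1); p0 <- mean(x0)
    den <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
  } else {
    den <- sqrt((var(x1) + var(x0)) / 2)
    p1 <- mean(x1); p0 <- mean(x0)
  }
  if (!is.finite(den) || den == 0) {
    # identical constants differ by 0; a real difference with zero pooled SD
    # is undefined
    return(if (isTRUE(all.equal(p1, p0))) 0 else NA_real_)
  }
  abs(p1 - p0) / den
}

#' Standardized mean differences before and after matching
#'
#' Absolute SMDs per covariate: continuous covariates use the pooled-SD
#' denominator sqrt((s1^2 + s0^2)/2); binary covariates use
#' sqrt((p1(1-p1) + p0(1-p0))/2). "Before" uses the full sample, "after" the
#' matched sample. This is the Love-plot table.
#'
#' @param records participant data.frame.
#' @param match a [nn_caliper_match()] result, or `NULL` for before-only.
#' @return data.frame `covariate`, `smd_before`, `smd_after`.
#' @export
smd_table <- function(records, match = NULL) {
  g <- records$falls12m >= 1
  out <- data.frame(covariate = .ps_covariates,
                    smd_before = NA_real_, smd_after = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(.ps_covariates)) {
    v <- records[[.ps_covariates[k]]]
    out$smd_before[k] <- .smd_one(v[g], v[!g])
  }
  if (!is.null(match) && match$n_pairs > 0) {
    r1 <- records[match(match$pairs$faller_id, records$participant_id), ]
    r0 <- records[match(match$pairs$nonfaller_id, records$participant_id), ]
    for (k in seq_along(.ps_covariates)) {
      out$smd_after[k] <- .smd_one(r1[[.ps_covariates[k]]],
                                   r0[[.ps_covariates[k]]])
    }
  }
  out
}

#' Welch comparisons of matched groups
#'
#' For each condition x metric in the trial-averaged feature table, compares
#' matched fallers and non-fallers with Welch's t-test (Satterthwaite df,
#' two-tailed). No multiplicity correction is applied (the comparisons are
#' interpreted descriptively); a Benjamini-Hochberg column `p_bh` is appended
#' as clearly-optional extra output.
#'
#' @param features feature table from [extract_features()].
#' @param records participant data.frame.
#' @param match a [nn_caliper_match()] result.
#' @return data.frame `condition`, `metric`, `mean_faller`, `mean_nonfaller`,
#'   `t`, `df`, `p`, `p_bh`, `flag`.
#' @export
welch_compare <- function(features, records, match) {
  stopifnot(inherits(match, "cop_match"))
  ids1 <- match$pairs$faller_id
  ids0 <- match$pairs$nonfaller_id
  metrics <- setdiff(names(features), c("participant_id", "condition"))
  rows <- list()
  for (cond in unique(features$condition)) {
    fc <- features[features$condition == cond, , drop = FALSE]
    for (m in metrics) {
      x1 <- fc[[m]][fc$participant_id %in% ids1]
      x0 <- fc[[m]][fc$participant_id %in% ids0]
      x1 <- x1[is.finite(x1)]; x0 <- x0[is.finite(x0)]
      row <- data.frame(condition = cond, metric = m,
                        mean_faller = if (length(x1)) mean(x1) else NA_real_,
                        mean_nonfaller = if (length(x0)) mean(x0) else NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        flag = "", stringsAsFactors = FALSE)
      if (length(x1) < 2 || length(x0) < 2) {
        row$flag <- "group n < 2"
      } else if (var(x1) == 0 && var(x0) == 0) {
        row$flag <- if (mean(x1) == mean(x0)) "degenerate: zero variance" else "zero variance"
        if (mean(x1) == mean(x0)) { row$t <- 0 }
      } else {
        tt <- t.test(x1, x0, var.equal = FALSE)
        row$t <- unname(tt$statistic); row$df <- unname(tt$parameter)
        row$p <- tt$p.value
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  for (cond in unique(out$condition)) {
    i <- out$condition == cond
    out$p_bh[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted and PS-stratified sensitivity analyses
#'
#' On the full (unmatched) cohort, per condition x metric: (a) the group
#' coefficient and p-value from a least-squares fit of the metric on the group
#' indicator plus the eight propensity covariates; (b) a propensity-score
#' quintile-stratified estimate: within-stratum faller-minus-non-faller mean
#' differences combined with stratum-size weights (strata containing a single
#' group are dropped with a warning).
#'
#' @param features feature table from [extract_features()].
#' @param records participant data.frame.
#' @param fit a [fit_propensity()] result.
#' @param n_strata number of PS strata (default 5 = quintiles).
#' @return data.frame `condition`, `metric`, `adj_estimate`, `adj_p`,
#'   `strat_estimate`, `n_strata_used`.
#' @export
sensitivity_analyses <- function(features, records, fit, n_strata = 5) {
  stopifnot(inherits(fit, "propensity_fit"))
  ord <- match(records$participant_id, fit$participant_id)
  ps <- fit$ps[ord]
  qs <- quantile(ps, probs = seq(0, 1, length.out = n_strata + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  stratum <- cut(ps, breaks = unique(qs), labels = FALSE)
  grp <- as.integer(records$falls12m >= 1)
  metrics <- setdiff(names(features), c("participant_id", "condition"))
  rows <- list()
  dropped_any <- FALSE
  for (cond in unique(features$condition)) {
    fc <- features[features$condition == cond, , drop = FALSE]
    idx <- match(records$participant_id, fc$participant_id)
    for (m in metrics) {
      yv <- fc[[m]][idx]
      ok <- is.finite(yv)
      row <- data.frame(condition = cond, metric = m, adj_estimate = NA_real_,
                        adj_p = NA_real_, strat_estimate = NA_real_,
                        n_strata_used = 0L, stringsAsFactors = FALSE)
      if (sum(ok) > length(.ps_covariates) + 3) {
        dat <- data.frame(y = yv[ok], group = grp[ok],
                          records[ok, .ps_covariates])
        lmfit <- lm(y ~ ., data = dat)
        sm <- summary(lmfit)$coefficients
        if ("group" %in% rownames(sm)) {
          row$adj_estimate <- sm["group", "Estimate"]
          row$adj_p <- sm["group", "Pr(>|t|)"]
        }
        est <- w <- numeric(0)
        for (s in sort(unique(stratum[ok]))) {
          i <- ok & stratum == s
          if (length(unique(grp[i])) < 2) { dropped_any <- TRUE; next }
          est <- c(est, mean(yv[i & grp == 1]) - mean(yv[i & grp == 0]))
          w <- c(w, sum(i))
        }
        if (length(est)) {
          row$strat_estimate <- sum(est * w) / sum(w)
          row$n_strata_used <- length(est)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (dropped_any)
    warning("one or more PS strata contained a single group and were dropped",
            call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
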