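# Standardized ridge-logistic classification of fall history, Monte-Carlo
# Shapley feature attribution computed on training folds only, and top-5
# ranking stability over repeated stratified cross-validation.

#' Repeated stratified k-fold cross-validation plan
#'
#' Builds `k * repeats` train/test splits. Within each repeat every class is
#' shuffled (deterministically from `base_seed`) and dealt round-robin into k
#' folds, so each test fold's class proportion is within one subject of the
#' global proportion and the test folds of a repeat partition all subjects.
#'
#' @param labels logical or 0/1 vector (TRUE/1 = faller).
#' @param k number of folds (default 5).
#' @param repeats number of repetitions (default 30).
#' @param base_seed integer seed; identical seeds give identical plans.
#' @return object of class `cv_plan`: `splits` (list of `train`/`test` index
#'   vectors with `repeat_id`/`fold`), `k`, `repeats`, `base_seed`.
#' @export
make_cv_plan <- function(labels, k = 5, repeats = 30, base_seed = 1) {
  y <- as.integer(as.logical(labels))
  stopifnot_scalar(k, "k", lower = 2, integer = TRUE)
  stopifnot_scalar(repeats, "repeats", lower = 1, integer = TRUE)
  if (min(table(y)) < k)
    stop(sprintf("smallest class has %d members, fewer than k = %d folds",
                 min(table(y)), k), call. = FALSE)
  n <- length(y)
  splits <- vector("list", k * repeats)
  s <- 0L
  for (r in seq_len(repeats)) {
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- with_seed(derive_seed(base_seed, "cv", r, cls),
                       sample(idx, length(idx)))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    for (f in seq_len(k)) {
      s <- s + 1L
      splits[[s]] <- list(train = which(fold != f), test = which(fold == f),
                          repeat_id = r, fold = f)
    }
  }
  structure(list(splits = splits, k = as.integer(k),
                 repeats = as.integer(repeats), base_seed = as.integer(base_seed),
                 labels = y),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d splits (%d-fold x %d repeats), %d subjects (%d/%d)\n",
              length(x$splits), x$k, x$repeats, length(x$labels),
              sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

# Exact Newton-IRLS fit of the penalized logistic objective
# -loglik + lambda/2 * ||beta||^2 (intercept unpenalized).
.ridge_logistic <- function(x, y, lambda, max_iter = 100, tol = 1e-10) {
  X <- cbind(1, x)
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    grad <- as.numeric(crossprod(X, y - mu)) - pen * beta
    W <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * W, X) + diag(pen, p)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(a0 = beta[1], beta = beta[-1])
}

#' Ridge-penalized logistic regression with training-fold standardization
#'
#' Centers and scales each predictor using the supplied (training) data only,
#' mean-imputes missing values with the training means, drops constant columns
#' with a warning, and fits a logistic regression with an L2 penalty of
#' `lambda/2 * ||beta||^2` added to the negative log-likelihood (intercept
#' unpenalized) by Newton iteration, solved to numerical convergence. The
#' standardization parameters travel with the model so test-fold data are
#' transformed with training statistics only.
#'
#' @param x numeric matrix or data.frame of predictors (rows = subjects).
#' @param y logical or 0/1 outcome.
#' @param lambda ridge penalty on the standardized scale (default 1).
#' @return object of class `std_logistic`.
#' @export
fit_standardized_logistic <- function(x, y, lambda = 1) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2)
    stop("training fold contains a single class", call. = FALSE)
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  sdev <- apply(x, 2, sd)
  keep <- which(is.finite(sdev) & sdev > 0)
  if (length(keep) < ncol(x))
    warning(sprintf("dropping %d constant feature(s): %s",
                    ncol(x) - length(keep),
                    paste(colnames(x)[-keep], collapse = ", ")), call. = FALSE)
  if (!length(keep)) stop("no non-constant features", call. = FALSE)
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  fit <- .ridge_logistic(xs, y, lambda)
  structure(list(a0 = fit$a0, beta = fit$beta,
                 center = mu, scale = sdev, keep = keep,
                 feature_names = colnames(x), lambda = lambda),
            class = "std_logistic")
}

#' Standardize new data with a model's training statistics
#' @param object a [fit_standardized_logistic()] model.
#' @param newx matrix/data.frame on the original feature scale.
#' @return standardized matrix restricted to the model's retained columns.
#' @export
std_transform <- function(object, newx) {
  stopifnot(inherits(object, "std_logistic"))
  x <- as.matrix(newx); storage.mode(x) <- "double"
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- object$center[j]
  sweep(sweep(x[, object$keep, drop = FALSE], 2, object$center[object$keep]),
        2, object$scale[object$keep], "/")
}

#' @export
predict.std_logistic <- function(object, newx, type = c("response", "link"),
                                 standardized = FALSE, ...) {
  type <- match.arg(type)
  xs <- if (standardized) as.matrix(newx)[, object$keep, drop = FALSE]
        else std_transform(object, newx)
  eta <- object$a0 + as.numeric(xs %*% object$beta)
  if (type == "link") eta else plogis(eta)
}

#' Monte-Carlo (permutation) Shapley feature attribution
#'
#' Estimates per-subject, per-feature Shapley values of the model output by
#' coalition sampling: for each of `n_sim` draws a random feature permutation
#' and a background row (sampled from the training background) are taken;
#' features up to and including the target feature in permutation order come
#' from the explained subject and the rest from the background row, and the
#' attribution is the model-output difference when the target feature switches
#' from the subject's value to the background value. Output scale is the
#' predicted probability by default; `scale = "link"` gives the log-odds scale
#' on which a linear model's exact Shapley value is
#' `beta_j * (x_j - mean(background x_j))`.
#'
#' @param model a [fit_standardized_logistic()] model (or any object with a
#'   `predict(model, newx, type)` method on the original feature scale).
#' @param x matrix/data.frame of subjects to explain (the training fold).
#' @param background background data; defaults to `x` itself.
#' @param n_sim Monte-Carlo draws per feature (default 64).
#' @param seed integer seed.
#' @param scale `"response"` (probability) or `"link"` (log-odds).
#' @return object of class `shap_run`: `shap` (n x p matrix), `se` (Monte-Carlo
#'   standard errors), `ranking` (features by decreasing mean |SHAP|).
#' @export
mc_shapley <- function(model, x, background = x, n_sim = 64, seed = 1,
                       scale = c("response", "link")) {
  scale <- match.arg(scale)
  stopifnot_scalar(n_sim, "n_sim", lower = 1, integer = TRUE)
  x <- as.matrix(x); storage.mode(x) <- "double"
  bg <- as.matrix(background); storage.mode(bg) <- "double"
  n <- nrow(x); p <- ncol(x); nb <- nrow(bg)
  phi <- se <- matrix(0, n, p, dimnames = list(rownames(x), colnames(x)))
  with_seed(derive_seed(seed, "shap"), {
    B1 <- matrix(0, n * n_sim, p)
    B2 <- matrix(0, n * n_sim, p)
    colnames(B1) <- colnames(B2) <- colnames(x)
    for (j in seq_len(p)) {
      for (s in seq_len(n_sim)) {
        rows <- (s - 1L) * n + seq_len(n)
        perm <- sample.int(p)
        upto <- perm[seq_len(which(perm == j))] # features taken from the subject
        b1 <- bg[sample.int(nb, n, replace = TRUE), , drop = FALSE]
        b1[, upto] <- x[, upto, drop = FALSE]
        B1[rows, ] <- b1
        b1[, j] <- bg[sample.int(nb, n, replace = TRUE), j]
        B2[rows, ] <- b1
      }
      d <- predict(model, B1, type = scale) - predict(model, B2, type = scale)
      sims <- matrix(d, n, n_sim)
      phi[, j] <- rowMeans(sims)
      se[, j] <- apply(sims, 1, sd) / sqrt(n_sim)
    }
  })
  ranking <- colnames(x)[order(-colMeans(abs(phi)))]
  structure(list(shap = phi, se = se, ranking = ranking, scale = scale,
                 n_sim = as.integer(n_sim)),
            class = "shap_run")
}

#' SHAP-based feature-contribution analysis for one condition
#'
#' For each cross-validation split: fits the standardized ridge-logistic model
#' on the training fold, computes Monte-Carlo Shapley values using the training
#' data only, records the 5 features with the largest mean |SHAP|, and predicts
#' the held-out test fold. Aggregates the per-split top-5 sets into a stability
#' table (proportion of splits each feature ranked top 5), pools out-of-fold
#' predictions into exploratory AUROC/accuracy estimates, and emits a
#' beeswarm-ready table (per-subject SHAP value and standardized feature value,
#' averaged over the splits in which the subject was in training). Split
#' failures are recorded and the analysis continues.
#'
#' @param features feature table for one condition: a data.frame (metric
#'   columns; `participant_id`/`condition` columns are dropped) or matrix.
#' @param labels logical or 0/1 fall-status vector aligned with rows.
#' @param plan a [make_cv_plan()]; defaults to 5-fold x 30 repeats.
#' @param n_sim Monte-Carlo draws per feature for [mc_shapley()] (default 64).
#' @param lambda ridge penalty (default 1).
#' @param shap_scale `"response"` or `"link"`.
#' @param top_k size of the recorded top set (default 5).
#' @return object of class `shap_cv_result`: `stability` (data.frame with
#'   `feature`, `top5_prop`, `mean_abs_shap`), `oof` (`auroc`, `accuracy`),
#'   `beeswarm`, `n_splits`, `failures`.
#' @export
run_condition_analysis <- function(features, labels, plan = NULL, n_sim = 64,
                                   lambda = 1, shap_scale = "response",
                                   top_k = 5) {
  if (is.data.frame(features)) {
    drop <- intersect(c("participant_id", "condition"), names(features))
    features <- as.matrix(features[, setdiff(names(features), drop),
                                   drop = FALSE])
  }
  storage.mode(features) <- "double"
  y <- as.integer(as.logical(labels))
  if (is.null(plan)) plan <- make_cv_plan(y)
  stopifnot(inherits(plan, "cv_plan"))
  p <- ncol(features)
  top_k <- min(top_k, p)
  feat <- colnames(features)
  top_counts <- setNames(numeric(p), feat)
  abs_shap_sum <- setNames(numeric(p), feat)
  shap_sum <- matrix(0, nrow(features), p, dimnames = list(NULL, feat))
  shap_n <- numeric(nrow(features))
  oof_pred <- oof_lab <- numeric(0)
  failures <- character(0)
  n_ok <- 0L
  for (s in seq_along(plan$splits)) {
    sp <- plan$splits[[s]]
    res <- tryCatch({
      fit <- suppressWarnings(
        fit_standardized_logistic(features[sp$train, , drop = FALSE],
                                  y[sp$train], lambda = lambda))
      sh <- mc_shapley(fit, features[sp$train, , drop = FALSE],
                       n_sim = n_sim,
                       seed = derive_seed(plan$base_seed, "shapsplit", s),
                       scale = shap_scale)
      list(fit = fit, sh = sh)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("split %d: %s", s, res))
      next
    }
    n_ok <- n_ok + 1L
    mean_abs <- setNames(numeric(p), feat)
    mean_abs[colnames(res$sh$shap)] <- colMeans(abs(res$sh$shap))
    top <- names(sort(mean_abs, decreasing = TRUE))[seq_len(top_k)]
    top_counts[top] <- top_counts[top] + 1
    abs_shap_sum <- abs_shap_sum + mean_abs
    shap_sum[sp$train, colnames(res$sh$shap)] <-
      shap_sum[sp$train, colnames(res$sh$shap)] + res$sh$shap
    shap_n[sp$train] <- shap_n[sp$train] + 1
    oof_pred <- c(oof_pred, predict(res$fit, features[sp$test, , drop = FALSE]))
    oof_lab <- c(oof_lab, y[sp$test])
  }
  if (n_ok == 0) stop("every cross-validation split failed", call. = FALSE)
  stability <- data.frame(feature = feat,
                          top5_prop = unname(top_counts) / n_ok,
                          mean_abs_shap = unname(abs_shap_sum) / n_ok,
                          stringsAsFactors = FALSE)
  stability <- stability[order(-stability$top5_prop, -stability$mean_abs_shap), ]
  rownames(stability) <- NULL
  auroc <- if (length(unique(oof_lab)) == 2) {
    as.numeric(pROC::auc(oof_lab, oof_pred, quiet = TRUE,
                         direction = "<", levels = c(0, 1)))
  } else NA_real_
  acc <- mean((oof_pred >= 0.5) == (oof_lab == 1))
  # beeswarm: per-subject mean SHAP over its training appearances + globally
  # standardized feature value
  mu <- colMeans(features, na.rm = TRUE)
  sdev <- apply(features, 2, sd, na.rm = TRUE); sdev[sdev == 0 | !is.finite(sdev)] <- 1
  sw <- list()
  for (j in seq_len(p)) {
    sw[[j]] <- data.frame(subject = seq_len(nrow(features)), feature = feat[j],
                          shap = ifelse(shap_n > 0, shap_sum[, j] / pmax(shap_n, 1),
                                        NA_real_),
                          scaled_value = (features[, j] - mu[j]) / sdev[j],
                          stringsAsFactors = FALSE)
  }
  structure(list(stability = stability,
                 oof = c(auroc = auroc, accuracy = acc),
                 beeswarm = do.call(rbind, sw),
                 n_splits = n_ok, top_k = top_k,
                 failures = failures),
            class = "shap_cv_result")
}

#' @export
print.shap_cv_result <- function(x, ...) {
  cat(sprintf("<shap_cv_result> %d splits; exploratory out-of-fold AUROC %.3f, accuracy %.3f\n",
              x$n_splits, x$oof["auroc"], x$oof["accuracy"]))
  cat("top features by top-5 stability:\n")
  print(head(x$stability, x$top_k), row.names = FALSE)
  if (length(x$failures)) cat(length(x$failures), "split failure(s)\n")
  invisible(x)
}
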