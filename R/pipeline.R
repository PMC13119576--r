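# End-to-end orchestration: simulate/load -> select -> extract -> match ->
# SHAP-CV -> report tables, with a run manifest and reproducible seeding.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline. Input is either a directory of trial
#' files plus a metadata table, or (default) a synthetic cohort generated at run
#' time. The defaults are sized for a demonstration run that exercises every
#' stage.
#'
#' @param input_dir,metadata_path paths to trial files and the metadata table;
#'   both `NULL` (default) simulates a cohort instead.
#' @param dialect a [cop_dialect()] for reading/writing trials.
#' @param synth a [synth_cohort_params()] describing the simulated cohort (used
#'   when no input paths are given). Its seed is re-derived from `seed`.
#' @param metrics metric names to extract (default all).
#' @param filter_cutoff trial low-pass cutoff, Hz.
#' @param nl an [nl_control()].
#' @param caliper_mult matching caliper in SDs of logit PS.
#' @param cv_k,cv_repeats cross-validation folds and repeats (5 x 30 = 150
#'   splits per condition).
#' @param n_sim Monte-Carlo draws per feature for SHAP.
#' @param lambda ridge penalty of the classification model.
#' @param seed global seed; all stage seeds derive from it.
#' @param out_dir if non-`NULL`, report tables are written there as
#'   tab-separated text plus a `manifest.txt`.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, metadata_path = NULL,
                       dialect = cop_dialect(),
                       synth = synth_cohort_params(n_fallers = 15,
                                                   n_nonfallers = 30,
                                                   confound_strength = 0.5,
                                                   trials_per_condition = 1),
                       metrics = cop_feature_names(),
                       filter_cutoff = 20,
                       nl = nl_control(),
                       caliper_mult = 0.2,
                       cv_k = 5, cv_repeats = 30,
                       n_sim = 64, lambda = 1,
                       seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

.write_report_table <- function(x, out_dir, name) {
  write.table(x, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
              row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, cohort selection, feature extraction, propensity
#' matching with balance diagnostics and matched/adjusted/stratified
#' comparisons, and per-condition SHAP cross-validation. Any stage failure is
#' recorded in the manifest and downstream stages are skipped with explicit
#' status. All randomness derives from `config$seed`.
#'
#' @param config a [run_config()].
#' @return object of class `cop_run` with elements `features`, `propensity`,
#'   `match`, `smd`, `welch`, `sensitivity`, `shap` (one [run_condition_analysis()]
#'   result per condition), `selection` and `manifest`.
#' @export
run_full <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("copsway")),
    r_version = R.version.string,
    seed = config$seed,
    started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    stages = list())
  out <- list(manifest = manifest)
  status <- function(stage, ok, detail) {
    out$manifest$stages[[stage]] <<- list(ok = ok, detail = detail)
  }
  fail <- function(stage, e) {
    status(stage, FALSE, conditionMessage(e))
    out$manifest$stages$aborted_at <<- stage
  }

  # --- input stage ---------------------------------------------------------
  dat <- tryCatch({
    if (!is.null(config$input_dir)) {
      files <- list.files(config$input_dir, full.names = TRUE,
                          pattern = "\\.(txt|csv|tsv|dat)$")
      trials <- lapply(files, read_trial, dialect = config$dialect)
      records <- read_metadata(config$metadata_path)
      list(records = records, trials = trials,
           detail = sprintf("%d trial files, %d metadata records (%d excluded on read)",
                            length(trials), nrow(records),
                            nrow(attr(records, "exclusions"))))
    } else {
      sp <- config$synth
      sp$seed <- derive_seed(config$seed, "cohort")
      coh <- gen_cohort(sp)
      list(records = coh$records, trials = coh$trials,
           detail = sprintf("simulated %d participants, %d trials",
                            nrow(coh$records), length(coh$trials)))
    }
  }, error = function(e) e)
  if (inherits(dat, "error")) { fail("input", dat); return(structure(out, class = "cop_run")) }
  status("input", TRUE, dat$detail)

  # --- cohort selection ----------------------------------------------------
  sel <- tryCatch(select_cohort(dat$records, dat$trials), error = function(e) e)
  if (inherits(sel, "error")) { fail("select", sel); return(structure(out, class = "cop_run")) }
  out$selection <- sel
  status("select", TRUE,
         sprintf("%d fallers, %d non-fallers, %d recurrent (falls12m >= 2); %d excluded",
                 sel$counts["fallers"], sel$counts["nonfallers"],
                 sel$counts["recurrent"], nrow(sel$excluded)))
  if (nrow(sel$records) == 0) {
    out$manifest$stages$aborted_at <- "select"
    return(structure(out, class = "cop_run"))
  }

  # --- feature extraction --------------------------------------------------
  feats <- tryCatch(
    extract_features(sel$trials, metrics = config$metrics, control = config$nl,
                     filter_cutoff = config$filter_cutoff),
    error = function(e) e)
  if (inherits(feats, "error")) { fail("extract", feats); return(structure(out, class = "cop_run")) }
  out$features <- feats
  n_missing <- sum(is.na(feats[, config$metrics, drop = FALSE]))
  status("extract", TRUE,
         sprintf("%d participant x condition rows, %d metrics, %d missing values",
                 nrow(feats), length(config$metrics), n_missing))

  # --- matching + comparisons ---------------------------------------------
  mt <- tryCatch({
    fit <- fit_propensity(sel$records)
    match <- nn_caliper_match(fit, caliper_mult = config$caliper_mult)
    list(fit = fit, match = match,
         smd = smd_table(sel$records, match),
         welch = welch_compare(feats, sel$records, match),
         sens = sensitivity_analyses(feats, sel$records, fit))
  }, error = function(e) e)
  if (inherits(mt, "error")) { fail("match", mt); return(structure(out, class = "cop_run")) }
  out$propensity <- mt$fit; out$match <- mt$match; out$smd <- mt$smd
  out$welch <- mt$welch; out$sensitivity <- mt$sens
  status("match", TRUE,
         sprintf("%d matched pairs (caliper %.4f), %d treated unmatched; propensity fit: %s",
                 mt$match$n_pairs, mt$match$caliper, length(mt$match$unmatched),
                 mt$fit$method))

  # --- SHAP cross-validation per condition --------------------------------
  out$shap <- list()
  for (cond in c("EO_firm", "EC_firm")) {
    fc <- feats[feats$condition == cond, , drop = FALSE]
    res <- tryCatch({
      ids <- fc$participant_id
      y <- sel$records$falls12m[match(ids, sel$records$participant_id)] >= 1
      plan <- make_cv_plan(y, k = config$cv_k, repeats = config$cv_repeats,
                           base_seed = derive_seed(config$seed, "cv", cond))
      run_condition_analysis(fc, y, plan, n_sim = config$n_sim,
                             lambda = config$lambda)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status(paste0("shap_", cond), FALSE, conditionMessage(res))
    } else {
      out$shap[[cond]] <- res
      status(paste0("shap_", cond), TRUE,
             sprintf("%d CV splits (%d-fold x %d repeats), oof AUROC %.3f; %d split failure(s)",
                     res$n_splits, config$cv_k, config$cv_repeats,
                     res$oof["auroc"], length(res$failures)))
    }
  }
  out$manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")

  # --- report tables -------------------------------------------------------
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    .write_report_table(out$features, config$out_dir, "features")
    .write_report_table(out$smd, config$out_dir, "smd_love")
    .write_report_table(out$welch, config$out_dir, "welch_comparisons")
    .write_report_table(out$sensitivity, config$out_dir, "sensitivity")
    .write_report_table(out$match$pairs, config$out_dir, "matched_pairs")
    for (cond in names(out$shap)) {
      .write_report_table(out$shap[[cond]]$stability, config$out_dir,
                          paste0("shap_stability_", cond))
      .write_report_table(out$shap[[cond]]$beeswarm, config$out_dir,
                          paste0("shap_beeswarm_", cond))
    }
    mf <- file.path(config$out_dir, "manifest.txt")
    lines <- c(sprintf("copsway %s / %s", out$manifest$package_version,
                       out$manifest$r_version),
               sprintf("seed: %d", config$seed),
               sprintf("started: %s", out$manifest$started),
               vapply(names(out$manifest$stages), function(s) {
                 st <- out$manifest$stages[[s]]
                 if (is.list(st))
                   sprintf("%s: %s | %s", s, if (st$ok) "ok" else "FAILED", st$detail)
                 else sprintf("aborted_at: %s", st)
               }, character(1)))
    writeLines(lines, mf)
  }
  structure(out, class = "cop_run")
}

#' @export
print.cop_run <- function(x, ...) {
  cat("<cop_run>\n")
  for (s in names(x$manifest$stages)) {
    st <- x$manifest$stages[[s]]
    if (is.list(st))
      cat(sprintf("  %-12s %s  %s\n", s, if (st$ok) "ok " else "FAIL", st$detail))
    else cat(sprintf("  aborted at: %s\n", st))
  }
  invisible(x)
}
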