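# Delimited-text readers/writers for stabilometry trials and participant
# metadata. Column labels in public releases vary, so both readers take a
# configurable dialect/column mapping.

#' Trial-file dialect
#'
#' Describes how a delimited stabilometry trial file is laid out: the CoP
#' column names, the delimiter (`NULL` = auto-detect whitespace vs comma), a
#' unit scale applied on read (values multiplied to get cm), and the nominal
#' trial duration used to validate the sample count (`NULL` disables the check).
#'
#' @param col_ap,col_ml header names of the AP and ML CoP columns
#'   (matched case-insensitively).
#' @param delim field delimiter, or `NULL` to auto-detect.
#' @param unit_scale multiplicative factor to convert stored units to cm.
#' @param duration_s nominal trial duration in seconds; files whose sample
#'   count differs from `fs * duration_s` by more than 1 sample are rejected.
#' @return list of class `cop_dialect`.
#' @export
cop_dialect <- function(col_ap = "COP_AP", col_ml = "COP_ML", delim = NULL,
                        unit_scale = 1, duration_s = 60) {
  structure(list(col_ap = col_ap, col_ml = col_ml, delim = delim,
                 unit_scale = unit_scale, duration_s = duration_s),
            class = "cop_dialect")
}

.detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) "," else ""
}

#' Read one stabilometry trial file
#'
#' Reads a delimited text file (one row per sample) holding CoP AP and ML
#' coordinates, mapping channels by header name so column order is irrelevant.
#' Rows with missing or non-numeric CoP values are a read error naming the file
#' and row; a sample count inconsistent with `fs * duration_s` (beyond 1
#' sample) is rejected rather than truncated.
#'
#' @param path file to read.
#' @param dialect a [cop_dialect()].
#' @param fs sampling rate in Hz.
#' @param participant_id,condition,trial_index trial labels; if `NULL` they are
#'   parsed from a filename of the form `<id>_<EO|EC>_<k>.*` (as written by
#'   [write_trial()]).
#' @return a [cop_trial()].
#' @export
read_trial <- function(path, dialect = cop_dialect(), fs = 100,
                       participant_id = NULL, condition = NULL,
                       trial_index = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  delim <- if (is.null(dialect$delim)) .detect_delim(path) else dialect$delim
  tab <- read.table(path, header = TRUE, sep = delim, stringsAsFactors = FALSE)
  hdr <- tolower(names(tab))
  i_ap <- match(tolower(dialect$col_ap), hdr)
  i_ml <- match(tolower(dialect$col_ml), hdr)
  if (is.na(i_ap) || is.na(i_ml))
    stop(sprintf("%s: missing CoP column(s) '%s'/'%s' (found: %s)",
                 path, dialect$col_ap, dialect$col_ml,
                 paste(names(tab), collapse = ", ")), call. = FALSE)
  ap <- suppressWarnings(as.numeric(tab[[i_ap]]))
  ml <- suppressWarnings(as.numeric(tab[[i_ml]]))
  bad <- which(!is.finite(ap) | !is.finite(ml))
  if (length(bad))
    stop(sprintf("%s: missing/non-numeric CoP value at data row %d", path,
                 bad[1]), call. = FALSE)
  if (!is.null(dialect$duration_s)) {
    expected <- fs * dialect$duration_s
    if (abs(length(ap) - expected) > 1)
      stop(sprintf("%s: %d samples, expected %g (= %g Hz x %g s); trial rejected",
                   path, length(ap), expected, fs, dialect$duration_s),
           call. = FALSE)
  }
  base <- sub("\\.[^.]*$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (is.null(participant_id))
    participant_id <- if (length(parts) >= 3) parts[1] else base
  if (is.null(condition)) {
    condition <- if (length(parts) >= 3 && parts[2] %in% c("EO", "EC"))
      paste0(parts[2], "_firm") else "EO_firm"
  }
  if (is.null(trial_index)) {
    trial_index <- if (length(parts) >= 3 &&
                       !is.na(suppressWarnings(as.integer(parts[3]))))
      as.integer(parts[3]) else 1L
  }
  cop_trial(ap * dialect$unit_scale, ml * dialect$unit_scale, fs = fs,
            participant_id = participant_id, condition = condition,
            trial_index = trial_index)
}

#' Write a trial in the dialect the reader consumes
#'
#' @param trial a [cop_trial()].
#' @param dir output directory (created if needed).
#' @param dialect a [cop_dialect()]; values are divided by `unit_scale` before
#'   writing so a read round-trip restores cm.
#' @param digits decimal places written.
#' @return the path written, invisibly.
#' @export
write_trial <- function(trial, dir, dialect = cop_dialect(), digits = 6) {
  stopifnot(inherits(trial, "cop_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cond <- if (trial$condition == "EO_firm") "EO" else "EC"
  path <- file.path(dir, sprintf("%s_%s_%d.txt", trial$participant_id, cond,
                                 trial$trial_index))
  delim <- if (is.null(dialect$delim) || dialect$delim == "") " " else dialect$delim
  tab <- data.frame(a = round(trial$cop_ap / dialect$unit_scale, digits),
                    b = round(trial$cop_ml / dialect$unit_scale, digits))
  names(tab) <- c(dialect$col_ap, dialect$col_ml)
  write.table(tab, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Canonical metadata columns and the default file-to-record mapping.
.meta_cols <- c("participant_id", "age", "sex", "bmi", "adl", "illness",
                "n_medications", "disability", "orthosis", "falls12m")

.norm_binary <- function(x, field) {
  if (is.numeric(x)) return(as.integer(x != 0))
  s <- tolower(trimws(as.character(x)))
  out <- ifelse(s %in% c("1", "true", "yes", "y", "f", "female"), 1L,
         ifelse(s %in% c("0", "false", "no", "n", "m", "male"), 0L, NA_integer_))
  out
}

#' Read a participant metadata table
#'
#' Reads a delimited table of participant covariates and the 12-month fall
#' count. Categorical fields are normalized: sex to 1 = female / 0 = male
#' (accepting `M/F`, `male/female` in any case, or 0/1), the binary status
#' fields (`adl` when two-level, `illness`, `disability`, `orthosis`) to 0/1.
#' Records whose fall count is blank or unparseable are excluded and listed in
#' the `exclusions` attribute rather than failing the read.
#'
#' @param path file to read.
#' @param col_map named character vector mapping canonical names
#'   (`participant_id`, `age`, `sex`, `bmi`, `adl`, `illness`,
#'   `n_medications`, `disability`, `orthosis`, `falls12m`) to the file's
#'   column names; defaults to identity.
#' @param delim field delimiter, `NULL` to auto-detect.
#' @return data.frame of typed participant records with attribute `exclusions`.
#' @export
read_metadata <- function(path, col_map = NULL, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(delim)) delim <- .detect_delim(path)
  tab <- read.table(path, header = TRUE, sep = delim, stringsAsFactors = FALSE)
  map <- setNames(.meta_cols, .meta_cols)
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  hdr <- tolower(names(tab))
  idx <- match(tolower(map), hdr)
  if (anyNA(idx))
    stop(sprintf("%s: missing metadata column(s): %s", path,
                 paste(map[is.na(idx)], collapse = ", ")), call. = FALSE)
  out <- data.frame(
    participant_id = as.character(tab[[idx[1]]]),
    age = as.numeric(tab[[idx[2]]]),
    sex = .norm_binary(tab[[idx[3]]], "sex"),
    bmi = as.numeric(tab[[idx[4]]]),
    adl = tab[[idx[5]]],
    illness = .norm_binary(tab[[idx[6]]], "illness"),
    n_medications = as.integer(tab[[idx[7]]]),
    disability = .norm_binary(tab[[idx[8]]], "disability"),
    orthosis = .norm_binary(tab[[idx[9]]], "orthosis"),
    falls12m = suppressWarnings(as.integer(as.character(tab[[idx[10]]]))),
    stringsAsFactors = FALSE)
  # ADL: ordered numeric if multi-level, else normalized binary
  adl_num <- suppressWarnings(as.numeric(as.character(out$adl)))
  out$adl <- if (!anyNA(adl_num) && length(unique(adl_num)) > 2) adl_num
             else .norm_binary(out$adl, "adl")
  keep <- !is.na(out$falls12m)
  exclusions <- data.frame(participant_id = out$participant_id[!keep],
                           reason = rep_len("missing or unparseable falls12m",
                                            sum(!keep)),
                           stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  out
}

#' Write a participant metadata table
#'
#' @param records data.frame with the canonical metadata columns.
#' @param path output file.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path, delim = ",") {
  write.table(records[, .meta_cols], path, sep = delim, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
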