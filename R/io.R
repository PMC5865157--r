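# Delimited-text I/O: compound libraries, peak tables and annotation
# reports. All tables are comma-separated UTF-8 with one header line;
# unit-resolution integer m/z and small libraries make binary formats
# unnecessary.

# Read a CSV while rejecting silently-truncated files (a file whose last
# line is incomplete is refused rather than partially parsed).
.read_csv_checked <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  truncated <- FALSE
  lines <- withCallingHandlers(
    readLines(path),
    warning = function(w) {
      if (grepl("incomplete final line", conditionMessage(w))) {
        truncated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (truncated) {
    stop(sprintf("%s appears truncated (incomplete final line)", path),
         call. = FALSE)
  }
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1L) {
    stop(sprintf("%s is empty", path), call. = FALSE)
  }
  utils::read.csv(text = lines, stringsAsFactors = FALSE)
}

#' Read a compound library from delimited text
#'
#' Expected columns: `name`, `formula`, `chem_class`, and optionally
#' `carbon_count`, `reference_ri`, `proton_affinity`,
#' `aromatic_substituted`. Formulas are parsed and validated; duplicate
#' names and malformed rows are rejected with the offending line.
#'
#' @param path CSV path.
#' @return List of [compound_record()]s, named by compound, of class
#'   `"compound_library"`.
#' @export
read_compound_library <- function(path) {
  df <- .read_csv_checked(path)
  needed <- c("name", "formula", "chem_class")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("compound library %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dup <- df$name[duplicated(df$name)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate compound name(s) in %s: %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  opt <- function(col, i, default) {
    if (col %in% names(df) && !is.na(df[[col]][i])) df[[col]][i] else default
  }
  recs <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(
      compound_record(
        name = df$name[i], formula = df$formula[i],
        chem_class = df$chem_class[i],
        carbon_count = opt("carbon_count", i, NULL),
        reference_ri = opt("reference_ri", i, NA_real_),
        proton_affinity = opt("proton_affinity", i, NA_real_),
        aromatic_substituted = isTRUE(as.logical(
          opt("aromatic_substituted", i, FALSE)))),
      error = function(e) {
        stop(sprintf("%s line %d (%s): %s", path, i + 1L, df$name[i],
                     conditionMessage(e)), call. = FALSE)
      })
  })
  names(recs) <- df$name
  structure(recs, class = "compound_library")
}

#' Read an observed peak table from delimited text
#'
#' Expected columns: `platform`, `mz`, `intensity`, optionally `sample`,
#' `rt`, `ri`. Negative intensities are rejected. SIFT platforms have no
#' chromatography: a retention column on a SIFT table triggers a warning
#' and is ignored.
#'
#' @param path CSV path.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path) {
  df <- .read_csv_checked(path)
  needed <- c("platform", "mz", "intensity")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("peak table %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  platform <- unique(df$platform)
  if (length(platform) != 1L) {
    stop(sprintf("%s mixes platforms (%s): one platform per peak table",
                 path, paste(platform, collapse = ", ")), call. = FALSE)
  }
  if (any(df$intensity < 0)) {
    stop(sprintf("%s contains negative intensities", path), call. = FALSE)
  }
  ri <- if ("ri" %in% names(df)) df$ri else NA_real_
  if (startsWith(platform, "SIFT") &&
      any(c("rt", "ri") %in% names(df)) &&
      any(!is.na(unlist(df[intersect(c("rt", "ri"), names(df))])))) {
    warning(sprintf(
      "%s: SIFT-MS has no chromatography; retention column(s) ignored",
      path))
    ri <- NA_real_
  }
  peak_table(df$mz, df$intensity, ri = ri, platform = platform,
             sample = if ("sample" %in% names(df)) df$sample[1L] else "S1")
}

#' Write a peak table to delimited text
#'
#' @param pt A [peak_table()].
#' @param path Output path.
#' @export
write_peak_table <- function(pt, path) {
  stopifnot(inherits(pt, "peak_table"))
  out <- data.frame(platform = attr(pt, "platform"),
                    sample = attr(pt, "sample"),
                    ri = pt$ri, mz = pt$mz, intensity = pt$intensity)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read an annotation report
#'
#' The report is the [screen_candidates()] table (optionally with a
#' `feature` column when several features were screened), written as CSV
#' under comment lines carrying the configuration fingerprint so any
#' annotation run can be reproduced. `read_annotation_report()` restores
#' the table and exposes the fingerprint as attribute
#' `config_fingerprint`; write-then-read is the identity on all fields.
#'
#' @param results An `annotation_screen` data.frame (or several rbind-ed
#'   ones with a `feature` column).
#' @param path Report path.
#' @export
write_annotation_report <- function(results, path) {
  stopifnot(is.data.frame(results))
  fp <- attr(results, "config_fingerprint")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# breathvoc annotation report",
               sprintf("# config: %s",
                       if (is.null(fp)) "unspecified" else fp)), con)
  utils::write.csv(as.data.frame(results), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_report
#' @return `read_annotation_report()`: the report data.frame.
#' @export
read_annotation_report <- function(path) {
  lines <- readLines(path)
  cfg <- sub("^# config: ", "", grep("^# config: ", lines, value = TRUE))
  df <- .read_csv_checked(path)
  # all-empty string columns come back as logical NA; restore them
  for (col in intersect(c("platforms_matched", "ambiguity_set"), names(df))) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  }
  attr(df, "config_fingerprint") <- if (length(cfg) > 0L) cfg[1L] else NULL
  df
}

#' Screen many feature groups and build one report table
#'
#' Driver over [screen_candidates()]: one row per (feature, candidate)
#' with the feature identifier and rank prepended, ready for
#' [write_annotation_report()].
#'
#' @param feature_groups Named list; each element
#'   `list(peaks = <named list of peak_table>, observed_ri = <numeric>)`
#'   (the structure [group_simulated_peaks()] produces).
#' @param candidates Compound library.
#' @param config An [annotation_config()].
#' @return data.frame with columns `feature`, `rank`, then the
#'   [screen_candidates()] columns; attribute `config_fingerprint`.
#' @export
annotate_features <- function(feature_groups, candidates,
                              config = annotation_config()) {
  stopifnot(is.list(feature_groups), length(feature_groups) >= 1L)
  out <- do.call(rbind, lapply(names(feature_groups), function(fid) {
    g <- feature_groups[[fid]]
    screen <- screen_candidates(g$peaks, candidates, config,
                                observed_ri = g$observed_ri)
    cbind(data.frame(feature = fid, rank = seq_len(nrow(screen))),
          as.data.frame(screen))
  }))
  rownames(out) <- NULL
  attr(out, "config_fingerprint") <- config_fingerprint(config)
  out
}
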