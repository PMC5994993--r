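#' Read a CGM record from CSV
#'
#' Expects columns `timestamp` and `glucose_mg_dl` (a `glucose` column in
#' mmol/l is accepted only with `mmol = TRUE`, converted by the factor
#' 18.016). Timestamps may be ISO-8601 date-times or plain minutes; either
#' way the returned series uses minutes from the first sample, the internal
#' time convention of the whole package. Rows with a non-numeric or missing
#' glucose value are dropped with a warning counting them; unsorted or
#' duplicated timestamps are a hard error listing the offenders.
#'
#' @param path Path to a CSV file.
#' @param source One of `"cgm"`, `"laboratory"`, `"synthetic"`; recorded as
#'   metadata.
#' @param mmol Set `TRUE` if glucose is in mmol/l; it is converted to mg/dl.
#' @return A tibble of class `cgm_series` with columns `time_min` and
#'   `glucose`, plus attributes `source`, `cadence_min` (median sampling
#'   interval) and `t0` (the first raw timestamp).
#' @export
read_cgm <- function(path, source = c("cgm", "laboratory", "synthetic"),
                     mmol = FALSE) {
  source <- match.arg(source)
  raw <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  gcol <- intersect(c("glucose_mg_dl", "glucose"), names(raw))[1]
  if (!("timestamp" %in% names(raw)) || is.na(gcol)) {
    abort(sprintf(
      "'%s' must have columns `timestamp` and `glucose_mg_dl`.", path
    ))
  }
  glucose <- suppressWarnings(as.numeric(raw[[gcol]]))
  bad <- !is.finite(glucose)
  if (any(bad)) {
    warn(sprintf(
      "Dropped %d row(s) with non-numeric glucose from '%s'.",
      sum(bad), path
    ))
  }
  ts_raw <- raw$timestamp[!bad]
  glucose <- glucose[!bad]
  t_num <- suppressWarnings(as.numeric(ts_raw))
  if (all(is.finite(t_num))) {
    t0 <- t_num[1]
    time_min <- t_num - t0
  } else {
    dt <- as.POSIXct(ts_raw, tz = "UTC", tryFormats = c(
      "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"
    ))
    if (anyNA(dt)) {
      abort(sprintf(
        "Unparseable timestamp(s) in '%s': %s", path,
        paste(head(ts_raw[is.na(dt)], 3), collapse = ", ")
      ))
    }
    t0 <- dt[1]
    time_min <- as.numeric(difftime(dt, t0, units = "mins"))
  }
  if (is.unsorted(time_min, strictly = TRUE)) {
    off <- which(diff(time_min) <= 0)
    abort(sprintf(
      "Timestamps must be strictly increasing; offending row(s) in '%s': %s",
      path, paste(head(off + 1, 5), collapse = ", ")
    ))
  }
  if (mmol) glucose <- glucose * 18.016
  cgm_series(time_min, glucose, source = source, t0 = t0)
}

#' Construct a CGM glucose series
#'
#' The in-memory form of a CGM record: strictly increasing times in minutes
#' from the first sample and positive glucose in mg/dl.
#'
#' @param time_min Sample times, minutes from the first sample.
#' @param glucose Glucose, mg/dl.
#' @param source Provenance tag: `"cgm"`, `"laboratory"` or `"synthetic"`.
#' @param t0 Optional wall-clock anchor of the first sample.
#' @return A tibble of class `cgm_series`.
#' @export
cgm_series <- function(time_min, glucose,
                       source = c("cgm", "laboratory", "synthetic"),
                       t0 = NULL) {
  source <- match.arg(source)
  if (length(time_min) != length(glucose)) {
    abort("`time_min` and `glucose` must have equal length.")
  }
  if (is.unsorted(time_min, strictly = TRUE)) {
    abort("`time_min` must be strictly increasing.")
  }
  if (any(!is.finite(glucose)) || any(glucose <= 0)) {
    abort("`glucose` must be finite and > 0 (mg/dl).")
  }
  cadence <- if (length(time_min) > 1) median(diff(time_min)) else NA_real_
  structure(
    tibble(time_min = as.numeric(time_min), glucose = as.numeric(glucose)),
    class = c("cgm_series", class(tibble())),
    source = source, cadence_min = cadence, t0 = t0
  )
}

#' @export
print.cgm_series <- function(x, ...) {
  cat(sprintf(
    "<cgm_series> %d samples, cadence %s min, source \"%s\"\n",
    nrow(x), format(attr(x, "cadence_min")), attr(x, "source")
  ))
  NextMethod()
}

#' Write a CGM series, trajectory or observer output as tidy CSV
#'
#' All writes are atomic: content goes to a temporary file in the target
#' directory which is then renamed, so an interrupted run never leaves a
#' half-written file.
#'
#' @param x A data frame (e.g. `cgm_series`, `cgm_trajectory`, observer
#'   output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cgm <- function(x, path) {
  df <- as_tibble(x)
  if ("time_min" %in% names(df) && "glucose" %in% names(df) &&
    !("timestamp" %in% names(df))) {
    df <- dplyr::rename(df, timestamp = "time_min",
      glucose_mg_dl = "glucose")
  }
  write_atomic(path, function(tmp) {
    readr::write_csv(df, tmp)
  })
}

#' Read / write a food diary
#'
#' A diary CSV has columns `timestamp` (minutes or ISO-8601),
#' `meal_class` (`liquid` or `mixed`) and an optional free-text `label`.
#'
#' @param path Path to a CSV file.
#' @param t0 Wall-clock anchor used to convert ISO timestamps to minutes;
#'   taken from the matching CGM series. Ignored for numeric timestamps.
#' @return A tibble with columns `time_min`, `meal_class`, `label`.
#' @export
read_diary <- function(path, t0 = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!all(c("timestamp", "meal_class") %in% names(raw))) {
    abort(sprintf(
      "'%s' must have columns `timestamp` and `meal_class`.", path
    ))
  }
  t_num <- suppressWarnings(as.numeric(raw$timestamp))
  if (all(is.finite(t_num))) {
    time_min <- t_num
  } else {
    if (is.null(t0)) {
      abort("ISO timestamps in the diary need `t0` from the CGM series.")
    }
    dt <- as.POSIXct(raw$timestamp, tz = "UTC", tryFormats = c(
      "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"
    ))
    time_min <- as.numeric(difftime(dt, t0, units = "mins"))
  }
  if (!all(raw$meal_class %in% c("liquid", "mixed"))) {
    abort("Diary `meal_class` must be \"liquid\" or \"mixed\".")
  }
  tibble(
    time_min = time_min, meal_class = raw$meal_class,
    label = raw$label %||% NA_character_
  )
}

#' @rdname read_diary
#' @param diary A tibble with columns `time_min`, `meal_class` and
#'   optionally `label`.
#' @export
write_diary <- function(diary, path) {
  out <- tibble(
    timestamp = diary$time_min, meal_class = diary$meal_class,
    label = diary$label %||% NA_character_
  )
  write_atomic(path, function(tmp) readr::write_csv(out, tmp))
}

# Atomic file write: write to a sibling temp file, then rename.
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = basename(path), tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(sprintf("Could not move temporary file into place at '%s'.", path))
  }
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the inputs' MD5 hashes, the seed and the package version so a run
#' can be reproduced exactly from its manifest.
#'
#' @param path Output path for the manifest JSON.
#' @param inputs Character vector of input file paths (hashed).
#' @param seed The seed used, or `NULL`.
#' @param extra Named list of additional fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = character(), seed = NULL,
                           extra = list()) {
  manifest <- c(
    list(
      package = "cgmpulse",
      version = as.character(utils::packageVersion("cgmpulse")),
      created = format(Sys.time(), tz = "UTC", usetz = TRUE),
      seed = seed,
      inputs = lapply(
        setNames(inputs, basename(inputs)),
        function(f) list(path = f, md5 = unname(tools::md5sum(f)))
      )
    ),
    extra
  )
  write_atomic(path, function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
      null = "null")
  })
}
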