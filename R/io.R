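#' Read haul-out telemetry or sensor CSV
#'
#' Two dialects are supported: an event dialect with columns `seal_id`,
#' `start`, `end` (ISO-8601, UTC), `lon`, `lat`; and a sensor dialect with
#' columns `seal_id`, `timestamp`, `state` (`wet`/`dry`), optionally
#' `lon`, `lat`. Timestamps are parsed as UTC.
#'
#' @param path CSV path.
#' @return data.frame; attribute `"dialect"` is `"events"` or `"sensor"`.
#' @export
read_telemetry <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("seal_id", "start", "end", "lon", "lat") %in% names(d))) {
    d$start <- parse_utc(d$start)
    d$end <- parse_utc(d$end)
    if (is.null(d$duration_h)) d$duration_h <- as.numeric(d$end - d$start, units = "hours")
    attr(d, "dialect") <- "events"
  } else if (all(c("seal_id", "timestamp", "state") %in% names(d))) {
    d$timestamp <- parse_utc(d$timestamp)
    attr(d, "dialect") <- "sensor"
  } else {
    stop("unrecognised telemetry schema; expected columns ",
         "seal_id,start,end,lon,lat or seal_id,timestamp,state")
  }
  d
}

#' Write a haul-out event table as CSV
#'
#' @param events event data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  e <- events
  for (cn in c("start", "end")) {
    if (!is.null(e[[cn]])) e[[cn]] <- format(e[[cn]], "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  }
  utils::write.csv(e, path, row.names = FALSE)
  invisible(path)
}

#' Validate pipeline inputs
#'
#' Schema and sanity checks on a telemetry CSV and, optionally, a
#' boundary GeoJSON: expected columns, coordinate ranges (a fatal issue
#' reports offending row numbers — swapped lon/lat is the classic cause
#' of |lat| > 90), per-seal timestamp monotonicity, and duplicate
#' seal-timestamp rows (non-fatal, counted).
#'
#' @param telemetry path to a telemetry CSV.
#' @param boundaries optional path to a GeoJSON unit map.
#' @return object of class `input_diagnostics`: list with `issues`
#'   (data.frame: severity, message) and `ok` (no fatal issues).
#' @export
validate_inputs <- function(telemetry, boundaries = NULL) {
  issues <- data.frame(severity = character(), message = character())
  note <- function(sev, msg) {
    issues <<- rbind(issues, data.frame(severity = sev, message = msg))
  }
  d <- tryCatch(read_telemetry(telemetry), error = function(e) {
    note("fatal", conditionMessage(e)); NULL
  })
  if (!is.null(d)) {
    if (!is.null(d$lat)) {
      bad <- which(abs(d$lat) > 90 | abs(d$lon) > 180)
      if (length(bad)) {
        note("fatal", sprintf(
          "coordinates out of range (lon/lat swapped?) at row(s): %s",
          paste(utils::head(bad, 10), collapse = ", ")))
      }
    }
    tcol <- if (attr(d, "dialect") == "sensor") "timestamp" else "start"
    for (id in unique(d$seal_id)) {
      ts <- as.numeric(d[[tcol]][d$seal_id == id])
      ndup <- sum(duplicated(ts))
      if (ndup) note("warning", sprintf("seal %s: %d duplicate timestamp row(s)", id, ndup))
      if (is.unsorted(ts)) note("fatal", sprintf("seal %s: timestamps not sorted", id))
    }
  }
  if (!is.null(boundaries)) {
    m <- tryCatch(read_unit_map(boundaries), error = function(e) {
      note("fatal", paste("boundary file:", conditionMessage(e))); NULL
    })
    if (!is.null(m) && !length(m$features)) note("fatal", "boundary file has no features")
  }
  structure(list(issues = issues, ok = !any(issues$severity == "fatal")),
            class = "input_diagnostics")
}

#' @export
print.input_diagnostics <- function(x, ...) {
  if (!nrow(x$issues)) {
    cat("inputs OK: no issues found\n")
  } else {
    for (i in seq_len(nrow(x$issues))) {
      cat(sprintf("[%s] %s\n", x$issues$severity[i], x$issues$message[i]))
    }
  }
  invisible(x)
}

# ISO-8601 UTC parser tolerating "T" separators, fractional seconds and
# bare dates
parse_utc <- function(x) {
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    out <- as.POSIXct(x, tz = "UTC", format = fmt)
    if (!anyNA(out[!is.na(x) & nzchar(x)])) return(out)
  }
  stop("unparseable timestamp(s); expected ISO-8601 UTC, e.g. 2020-09-01T12:00:00Z")
}
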