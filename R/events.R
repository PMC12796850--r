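#' Detect haul-out events from a wet/dry sensor stream
#'
#' Reconstructs haul-out events from a time-stamped binary wet/dry sensor
#' record using the standard tag firmware rules: a haul-out begins with a
#' period in which the sensor is continuously dry for at least `min_dry`
#' seconds, and ends at the first instant a wet period of at least
#' `end_wet` seconds begins. Wet interruptions shorter than `end_wet` do
#' not terminate an event; they (and any dry time that follows) are
#' absorbed into it.
#'
#' @param records data.frame with columns `timestamp` (POSIXct, UTC),
#'   `state` (`"wet"` or `"dry"`), optionally `seal_id` (processed per
#'   seal) and `lon`/`lat` (an event inherits the coordinates of its first
#'   record).
#' @param min_dry minimum continuous dry time opening an event, seconds.
#' @param end_wet minimum wet time terminating an event, seconds.
#' @return data.frame of haul-out events: `seal_id`, `start`, `end`
#'   (POSIXct UTC), `lon`, `lat`, `duration_h`.
#' @details Each record's state is taken to hold on the half-open interval
#'   from its timestamp to the next record's timestamp; the final record
#'   marks the end of the stream. If the stream ends while an event is
#'   open the event is closed at the last record (or at the start of a
#'   trailing short wet run: the dry period is over either way).
#'   Duplicate timestamps within a seal keep the first record; the rest
#'   are dropped with a warning (tags can emit retries). Timestamps
#'   otherwise decreasing is an error.
#' @examples
#' t0 <- as.POSIXct("2020-09-01 00:00:00", tz = "UTC")
#' rec <- data.frame(
#'   timestamp = t0 + c(0, 900, 920, 1820, 1880),
#'   state = c("dry", "wet", "dry", "wet", "dry")
#' )
#' detect_haulouts(rec)  # one event spanning 30 min 20 s
#' @export
detect_haulouts <- function(records, min_dry = 600, end_wet = 40) {
  stopifnot(is.data.frame(records), min_dry > 0, end_wet > 0)
  if (!all(c("timestamp", "state") %in% names(records))) {
    stop("sensor records need columns 'timestamp' and 'state'")
  }
  bad <- setdiff(unique(as.character(records$state)), c("wet", "dry"))
  if (length(bad)) {
    stop("unknown sensor state value(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(records$seal_id)) records$seal_id <- "seal"
  out <- lapply(split(records, records$seal_id, drop = TRUE), function(r) {
    detect_haulouts_one(r, min_dry, end_wet)
  })
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev[order(ev$seal_id, ev$start), , drop = FALSE]
}

detect_haulouts_one <- function(r, min_dry, end_wet) {
  ts <- as.numeric(r$timestamp)
  dup <- duplicated(ts)
  if (any(dup)) {
    warning(sprintf("seal %s: dropping %d duplicate timestamp(s), keeping first",
                    r$seal_id[1], sum(dup)))
    r <- r[!dup, , drop = FALSE]
    ts <- ts[!dup]
  }
  if (is.unsorted(ts, strictly = TRUE)) {
    stop(sprintf("seal %s: sensor records not in increasing time order", r$seal_id[1]))
  }
  n <- nrow(r)
  empty <- data.frame(seal_id = character(), start = r$timestamp[0],
                      end = r$timestamp[0], lon = numeric(), lat = numeric(),
                      duration_h = numeric())
  if (n < 2) return(empty)
  st <- as.character(r$state)
  # run-length encode; run i occupies [t_start_i, t_start_{i+1})
  runs <- rle(st)
  k <- length(runs$lengths)
  first_idx <- cumsum(c(1L, runs$lengths[-k]))
  run_t0 <- ts[first_idx]
  run_t1 <- c(run_t0[-1], ts[n])   # final record closes the stream
  run_dur <- run_t1 - run_t0
  run_state <- runs$values

  has_lon <- !is.null(r$lon)
  starts <- ends <- numeric(0)
  lons <- lats <- numeric(0)
  i <- 1L
  while (i <= k) {
    if (run_state[i] == "dry" && run_dur[i] >= min_dry) {
      ev_start <- run_t0[i]
      j <- i + 1L
      ev_end <- run_t1[i]
      while (j <= k) {
        if (run_state[j] == "wet") {
          if (run_dur[j] >= end_wet || j == k) {
            # qualifying wet (or trailing wet at stream end): dry period over
            ev_end <- run_t0[j]
            break
          }
          # short wet blip: absorbed, event continues
        } else {
          ev_end <- run_t1[j]
        }
        j <- j + 1L
      }
      if (j > k) ev_end <- run_t1[k]
      starts <- c(starts, ev_start)
      ends <- c(ends, ev_end)
      if (has_lon) {
        lons <- c(lons, r$lon[first_idx[i]])
        lats <- c(lats, r$lat[first_idx[i]])
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(starts)) return(empty)
  data.frame(
    seal_id = r$seal_id[1],
    start = .POSIXct(starts, tz = "UTC"),
    end = .POSIXct(ends, tz = "UTC"),
    lon = if (has_lon) lons else NA_real_,
    lat = if (has_lon) lats else NA_real_,
    duration_h = (ends - starts) / 3600
  )
}

#' Merge haul-out events separated by short wet gaps
#'
#' Consecutive haul-out events of one seal whose inter-event gap (end of
#' one to start of the next) is shorter than `gap` seconds are merged and
#' treated as a single haul-out. A merged event keeps the first start, the
#' last end, and the coordinates of its longest constituent event. The
#' operation is idempotent.
#'
#' @param events data.frame of haul-out events as returned by
#'   [detect_haulouts()] (columns `seal_id`, `start`, `end`, `lon`, `lat`).
#' @param gap merge threshold in seconds; gaps strictly shorter than this
#'   are absorbed. Default 600 s (10 min).
#' @return data.frame of merged events with recomputed `duration_h`
#'   (end minus start, i.e. absorbed gaps count towards the duration).
#' @export
merge_events <- function(events, gap = 600) {
  stopifnot(is.data.frame(events), gap >= 0)
  if (!nrow(events)) return(events)
  out <- lapply(split(events, events$seal_id, drop = TRUE), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    s <- as.numeric(e$start); en <- as.numeric(e$end)
    if (any(en <= s)) stop("event with end <= start")
    if (nrow(e) > 1 && any(s[-1] < en[-nrow(e)])) {
      stop(sprintf("seal %s: overlapping haul-out events", e$seal_id[1]))
    }
    grp <- cumsum(c(1, as.integer(s[-1] - en[-length(en)] >= gap)))
    idx <- split(seq_len(nrow(e)), grp)
    merged <- lapply(idx, function(ii) {
      dur <- en[ii] - s[ii]
      best <- ii[which.max(dur)]      # longest constituent keeps the site
      data.frame(seal_id = e$seal_id[1],
                 start = e$start[ii[1]], end = e$end[ii[length(ii)]],
                 lon = e$lon[best], lat = e$lat[best],
                 duration_h = (en[ii[length(ii)]] - s[ii[1]]) / 3600)
    })
    do.call(rbind, merged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bundle events and per-seal metadata into a track set
#'
#' @param events data.frame of haul-out events (`seal_id`, `start`, `end`,
#'   `lon`, `lat`, ...).
#' @param seals data.frame of per-seal metadata: `seal_id`, `tagging_unit`,
#'   `tagging_lon`, `tagging_lat`, `weight_kg`, optionally `sex`,
#'   `track_start`, `track_end` (POSIXct; default to the first event start
#'   and last event end).
#' @return object of class `seal_tracks`: a list with `$events` and
#'   `$seals`, events sorted by seal and start time.
#' @export
seal_tracks <- function(events, seals) {
  stopifnot(is.data.frame(events), is.data.frame(seals))
  if (anyDuplicated(seals$seal_id)) stop("duplicated seal_id in metadata")
  missing_meta <- setdiff(unique(events$seal_id), seals$seal_id)
  if (length(missing_meta)) {
    stop("events for seals with no metadata: ", paste(missing_meta, collapse = ", "))
  }
  events <- events[order(events$seal_id, events$start), , drop = FALSE]
  if (is.null(seals$track_start) || is.null(seals$track_end)) {
    rng <- do.call(rbind, lapply(split(events, events$seal_id), function(e) {
      data.frame(seal_id = e$seal_id[1], s = min(e$start), e = max(e$end))
    }))
    m <- match(seals$seal_id, rng$seal_id)
    if (is.null(seals$track_start)) seals$track_start <- rng$s[m]
    if (is.null(seals$track_end)) seals$track_end <- rng$e[m]
  }
  structure(list(events = events, seals = seals), class = "seal_tracks")
}

#' @export
print.seal_tracks <- function(x, ...) {
  cat(sprintf("<seal_tracks> %d seals, %d haul-out events\n",
              nrow(x$seals), nrow(x$events)))
  invisible(x)
}

#' Drop seals with short deployments
#'
#' Removes seals whose elapsed time between first and last record is below
#' `min_days` (boundary inclusive: a track of exactly `min_days` days is
#' retained). The number of removed individuals is reported as a message.
#'
#' @param tracks a [seal_tracks] object.
#' @param min_days minimum deployment span in days (default 10).
#' @return filtered `seal_tracks`.
#' @export
filter_tracks <- function(tracks, min_days = 10) {
  stopifnot(inherits(tracks, "seal_tracks"), min_days >= 0)
  span <- as.numeric(tracks$seals$track_end) - as.numeric(tracks$seals$track_start)
  keep <- span / 86400 >= min_days
  dropped <- sum(!keep)
  if (dropped) {
    message(sprintf("filter_tracks: removed %d individual(s) with < %g days of data",
                    dropped, min_days))
  }
  ids <- tracks$seals$seal_id[keep]
  seal_tracks(tracks$events[tracks$events$seal_id %in% ids, , drop = FALSE],
              tracks$seals[keep, , drop = FALSE])
}

#' Per-seal haul-out summary with cohort-level means
#'
#' Computes, per seal: deployment duration (days), number of haul-out
#' events, mean haul-out duration (hours), and the great-circle distance
#' from the tagging location to the most distant haul-out site (km). The
#' cohort-level block reports range and mean with a normal-approximation
#' 95% confidence interval (mean +/- 1.96 SE across seals).
#'
#' @param tracks a [seal_tracks] object.
#' @return object of class `track_summary`: list with `$per_seal` and
#'   `$overall` data.frames.
#' @export
summarize_tracks <- function(tracks) {
  stopifnot(inherits(tracks, "seal_tracks"))
  if (!nrow(tracks$events)) stop("no haul-out events to summarise")
  per <- do.call(rbind, lapply(seq_len(nrow(tracks$seals)), function(i) {
    sl <- tracks$seals[i, ]
    e <- tracks$events[tracks$events$seal_id == sl$seal_id, , drop = FALSE]
    disp <- if (nrow(e) && !all(is.na(e$lon))) {
      max(haversine_km(e$lon, e$lat, sl$tagging_lon, sl$tagging_lat), na.rm = TRUE)
    } else NA_real_
    data.frame(
      seal_id = sl$seal_id,
      deployment_days = (as.numeric(sl$track_end) - as.numeric(sl$track_start)) / 86400,
      n_events = nrow(e),
      mean_duration_h = if (nrow(e)) mean(e$duration_h) else NA_real_,
      max_displacement_km = disp
    )
  }))
  rownames(per) <- NULL
  ci <- function(x) {
    x <- x[is.finite(x)]
    se <- stats::sd(x) / sqrt(length(x))
    c(mean = mean(x), lo = mean(x) - 1.96 * se, hi = mean(x) + 1.96 * se,
      min = min(x), max = max(x))
  }
  vars <- c("deployment_days", "n_events", "mean_duration_h", "max_displacement_km")
  overall <- do.call(rbind, lapply(vars, function(v) {
    s <- ci(per[[v]])
    data.frame(variable = v, min = s["min"], max = s["max"],
               mean = s["mean"], ci_lo = s["lo"], ci_hi = s["hi"])
  }))
  rownames(overall) <- NULL
  structure(list(per_seal = per, overall = overall), class = "track_summary")
}

#' @export
print.track_summary <- function(x, digits = 3, ...) {
  cat("Haul-out summary (", nrow(x$per_seal), " seals)\n\n", sep = "")
  print(x$overall, digits = digits, row.names = FALSE)
  invisible(x)
}
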