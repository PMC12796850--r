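#' Build a management-unit map from labelled polygons
#'
#' A management-unit map is an ordered set of labelled polygons in WGS84
#' lon/lat. Feature order matters: a point lying on a boundary shared by
#' two units is assigned to the first feature in file order.
#'
#' @param units character vector of unit labels (must be unique).
#' @param polygons list, one element per unit. Each element is either a
#'   single ring (two-column lon/lat matrix), a polygon (list of rings:
#'   outer first, then holes), or a multipolygon (list of such lists of
#'   rings).
#' @return object of class `unit_map`.
#' @export
unit_map <- function(units, polygons) {
  stopifnot(length(units) == length(polygons))
  units <- as.character(units)
  if (anyDuplicated(units)) stop("unit labels must be unique")
  feats <- Map(function(u, p) {
    list(unit = u, polys = normalize_polys(p))
  }, units, polygons)
  structure(list(features = unname(feats)), class = "unit_map")
}

normalize_polys <- function(p) {
  as_ring <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2 || nrow(m) < 3) stop("invalid geometry: ring needs >= 3 lon/lat points")
    if (any(!is.finite(m))) stop("invalid geometry: non-finite coordinate")
    # close the ring if open
    if (m[1, 1] != m[nrow(m), 1] || m[1, 2] != m[nrow(m), 2]) m <- rbind(m, m[1, ])
    if (nrow(m) < 4) stop("invalid geometry: degenerate ring")
    m
  }
  if (is.matrix(p) || is.data.frame(p)) return(list(list(as_ring(p))))
  if (is.list(p) && (is.matrix(p[[1]]) || is.data.frame(p[[1]]))) {
    return(list(lapply(p, as_ring)))                     # one polygon + holes
  }
  lapply(p, function(rings) lapply(rings, as_ring))      # multipolygon
}

#' Read a management-unit map from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features; the
#' unit label is taken from the feature property named by `label`. CRS is
#' assumed to be WGS84 (EPSG:4326), GeoJSON's default.
#'
#' @param path path to a GeoJSON file.
#' @param label name of the feature property carrying the unit label.
#' @return object of class `unit_map` with features in file order.
#' @export
read_unit_map <- function(path, label = "unit") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  units <- character(0); polys <- list()
  for (f in gj$features) {
    u <- f$properties[[label]]
    if (is.null(u)) stop("feature without property '", label, "'")
    g <- f$geometry
    coords_to_ring <- function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    }
    p <- switch(g$type,
      Polygon = list(lapply(g$coordinates, coords_to_ring)),
      MultiPolygon = lapply(g$coordinates, function(poly) lapply(poly, coords_to_ring)),
      stop("unsupported geometry type: ", g$type)
    )
    units <- c(units, u)
    polys <- c(polys, list(p))
  }
  # unit_map() wants one geometry spec per unit; pass pre-normalized
  m <- unit_map(units, polys)
  m
}

#' @export
print.unit_map <- function(x, ...) {
  cat(sprintf("<unit_map> %d management units: %s\n", length(x$features),
              paste(vapply(x$features, `[[`, "", "unit"), collapse = ", ")))
  invisible(x)
}

# Even-odd ray-casting point-in-polygon with an explicit on-edge rule:
# a point lying on any ring edge counts as inside, so boundary points are
# resolved deterministically by feature order in assign_unit().
point_in_rings <- function(lon, lat, rings) {
  on_edge <- FALSE
  crossings <- 0L
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    for (i in seq_len(n - 1)) {
      x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1]; y2 <- y[i + 1]
      # on-segment test (collinear + within bounding box)
      cr <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
      if (abs(cr) < 1e-12 &&
          lon >= min(x1, x2) - 1e-12 && lon <= max(x1, x2) + 1e-12 &&
          lat >= min(y1, y2) - 1e-12 && lat <= max(y1, y2) + 1e-12) {
        on_edge <- TRUE
      }
      if ((y1 > lat) != (y2 > lat)) {
        xint <- x1 + (lat - y1) / (y2 - y1) * (x2 - x1)
        if (lon < xint) crossings <- crossings + 1L
      }
    }
  }
  on_edge || (crossings %% 2L == 1L)
}

#' Assign haul-out locations to management units
#'
#' Point-in-polygon containment against the unit map, in feature file
#' order: the first containing feature wins (this also resolves points on
#' shared boundaries deterministically). Points inside no feature get
#' `"unassigned"`.
#'
#' @param lon,lat numeric vectors of WGS84 coordinates.
#' @param map a [unit_map].
#' @return character vector of unit labels.
#' @export
assign_unit <- function(lon, lat, map) {
  stopifnot(inherits(map, "unit_map"), length(lon) == length(lat))
  if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(lon) > 180, na.rm = TRUE)) {
    stop("coordinates out of WGS84 range")
  }
  vapply(seq_along(lon), function(i) {
    if (is.na(lon[i]) || is.na(lat[i])) return("unassigned")
    for (f in map$features) {
      for (poly in f$polys) {
        if (point_in_rings(lon[i], lat[i], poly)) return(f$unit)
      }
    }
    "unassigned"
  }, character(1))
}

#' Label events with management units
#'
#' Adds a `unit` column to an event table via [assign_unit()].
#'
#' @param events haul-out event data.frame with `lon`, `lat`.
#' @param map a [unit_map].
#' @param drop_unassigned drop events falling in no unit (with a warning);
#'   the cross-boundary analysis requires this.
#' @return events with a `unit` column.
#' @export
assign_units <- function(events, map, drop_unassigned = FALSE) {
  events$unit <- assign_unit(events$lon, events$lat, map)
  if (drop_unassigned && any(events$unit == "unassigned")) {
    n <- sum(events$unit == "unassigned")
    warning(sprintf("dropping %d event(s) outside all management units", n))
    events <- events[events$unit != "unassigned", , drop = FALSE]
  }
  events
}

#' Flag cross-boundary haul-outs
#'
#' For each seal's time-ordered events, sets `cross_boundary` to 1 when
#' the event's management unit differs from that of the immediately
#' preceding haul-out, 0 when it does not, and NA for the first event
#' (which has no predecessor).
#'
#' @param events event data.frame with `seal_id`, `start`, `unit`
#'   (`"unassigned"` events must be excluded beforehand).
#' @return events with a `cross_boundary` column.
#' @export
flag_cross_boundary <- function(events) {
  stopifnot(!is.null(events$unit))
  if (any(events$unit == "unassigned")) {
    stop("exclude 'unassigned' events before flagging crossings")
  }
  events <- events[order(events$seal_id, events$start), , drop = FALSE]
  events$cross_boundary <- unlist(lapply(split(events$unit, events$seal_id), function(u) {
    if (!length(u)) return(integer(0))
    c(NA_integer_, as.integer(u[-1] != u[-length(u)]))
  }), use.names = FALSE)
  events
}

#' Build counting-process risk intervals for boundary crossings
#'
#' Converts each seal's labelled event sequence into jurisdiction spells
#' in gap-time form. Spell 1 opens at the seal's first haul-out start; a
#' spell ends with `event = 1` at the start of the next cross-boundary
#' haul-out (which opens the following spell, with the clock reset to 0);
#' the final spell is censored (`event = 0`) at the end of the tracking
#' period. Times are days since spell origin.
#'
#' @param tracks a [seal_tracks] object whose events carry `unit`
#'   (unassigned events excluded).
#' @return data.frame of risk intervals: `seal_id`, `spell_index`, `unit`
#'   (departure jurisdiction), `t_start` (0), `t_stop` (days), `event`,
#'   `weight_kg`.
#' @export
build_risk_intervals <- function(tracks) {
  stopifnot(inherits(tracks, "seal_tracks"))
  ev <- tracks$events
  if (is.null(ev$unit)) stop("events must carry assigned units")
  ev <- flag_cross_boundary(ev)
  out <- lapply(split(ev, ev$seal_id, drop = TRUE), function(e) {
    if (!nrow(e)) stop("track with zero assigned events")
    sl <- tracks$seals[match(e$seal_id[1], tracks$seals$seal_id), ]
    tend <- as.numeric(sl$track_end)
    cross_idx <- which(e$cross_boundary %in% 1L)
    origins <- as.numeric(e$start[c(1L, cross_idx)])
    stops <- c(as.numeric(e$start[cross_idx]), tend)
    units <- e$unit[c(1L, cross_idx)]
    data.frame(
      seal_id = e$seal_id[1],
      spell_index = seq_along(origins),
      unit = units,
      t_start = 0,
      t_stop = (stops - origins) / 86400,
      event = c(rep(1L, length(cross_idx)), 0L),
      weight_kg = if (!is.null(sl$weight_kg)) sl$weight_kg else NA_real_
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$t_stop <= res$t_start)) {
    # a censored spell of zero length carries no information; drop it
    res <- res[res$t_stop > res$t_start, , drop = FALSE]
  }
  res
}

#' Percentage of haul-outs outside the tagging unit
#'
#' @param tracks a [seal_tracks] object with unit-labelled events.
#' @return data.frame: `seal_id`, `n_events`, `n_away`,
#'   `displacement_pct` = 100 * n_away / n_events.
#' @export
displacement_fraction <- function(tracks) {
  stopifnot(inherits(tracks, "seal_tracks"))
  ev <- tracks$events
  if (is.null(ev$unit)) stop("events must carry assigned units")
  out <- lapply(split(ev, ev$seal_id, drop = TRUE), function(e) {
    if (!nrow(e)) stop("seal with zero events")
    tu <- tracks$seals$tagging_unit[match(e$seal_id[1], tracks$seals$seal_id)]
    data.frame(seal_id = e$seal_id[1], n_events = nrow(e),
               n_away = sum(e$unit != tu),
               displacement_pct = 100 * mean(e$unit != tu))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Proportion of seals hauled out cross-boundary around a date
#'
#' Among seals recording around `date` (track interval overlapping the
#' window `date` +/- `window` days), the proportion with at least one
#' haul-out inside the window in a unit different from their tagging unit.
#' Used to ask, e.g., how many seals have left their tagging jurisdiction
#' by the opening of the hunting season (1 January +/- 1 week).
#'
#' @param tracks a [seal_tracks] object with unit-labelled events.
#' @param date a Date or POSIXct.
#' @param window half-width of the window in days (default 7).
#' @return list with `numerator`, `denominator`, `proportion`.
#' @export
status_at_date <- function(tracks, date, window = 7) {
  stopifnot(inherits(tracks, "seal_tracks"))
  ev <- tracks$events
  if (is.null(ev$unit)) stop("events must carry assigned units")
  t0 <- as.numeric(as.POSIXct(date, tz = "UTC")) - window * 86400
  t1 <- as.numeric(as.POSIXct(date, tz = "UTC")) + window * 86400
  active <- as.numeric(tracks$seals$track_start) <= t1 &
            as.numeric(tracks$seals$track_end) >= t0
  if (!any(active)) stop("no seal recording within the window")
  ids <- tracks$seals$seal_id[active]
  away <- vapply(ids, function(id) {
    tu <- tracks$seals$tagging_unit[match(id, tracks$seals$seal_id)]
    e <- ev[ev$seal_id == id & as.numeric(ev$start) <= t1 & as.numeric(ev$end) >= t0, ]
    nrow(e) > 0 && any(e$unit != tu)
  }, logical(1))
  list(numerator = sum(away), denominator = length(ids),
       proportion = sum(away) / length(ids))
}
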