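#' Default haul-out site geometry for simulations
#'
#' Eight haul-out sites along a schematic Skagerrak-like coastline,
#' spanning seven management units (five county-scale units plus two
#' national-scale neighbours). Longitudes increase eastward over ~5
#' degrees so inter-site distances range from ~15 to ~250 km.
#'
#' @return data.frame: `site_id`, `lon`, `lat`, `unit`.
#' @export
default_sites <- function() {
  data.frame(
    site_id = paste0("S", 1:8),
    lon = c(7.0, 8.0, 9.2, 10.0, 10.3, 10.6, 11.1, 11.8),
    lat = c(58.0, 58.2, 58.8, 59.1, 59.4, 59.1, 58.9, 57.1),
    unit = c("VestAgder", "AustAgder", "Telemark", "Vestfold", "Buskerud",
             "Ostfold", "Sweden", "Denmark"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic seal-movement generator
#'
#' Parameterizes a semi-Markov renewal model of haul-out behaviour:
#' seals alternate at-sea gaps and haul-outs at a current site; on each
#' haul-out completion a cross-boundary move fires once an exponential
#' waiting time with per-unit hazard `lambda[unit] * exp(b_i)` (clock
#' reset at each crossing) has elapsed, thinned to haul-out boundaries.
#' Destinations are sites in a different unit, weighted by
#' `exp(-distance / dest_scale_km)`.
#'
#' Defaults emulate the scales of post-moult harbour-seal GPS-tag
#' deployments in the Skagerrak: 26 seals, deployments 10-178 days,
#' haul-out durations lognormal with mean ~5.8 h, inter-haul-out gaps
#' averaging ~28 h (so ~0.7 events/day), body mass ~65 +/- 25 kg, and
#' per-unit daily leave hazards spanning two orders of magnitude with the
#' national-scale neighbour unit the leakiest.
#'
#' @param n_seals number of animals.
#' @param sites site table as in [default_sites()].
#' @param lambda named per-day leave hazard per unit (names must cover
#'   all units in `sites`).
#' @param beta_weight log-hazard effect of body weight (kg); 0 by default.
#' @param sigma_b standard deviation of the Gaussian per-seal frailty on
#'   the log hazard.
#' @param p_switch probability of moving to another site within the same
#'   unit at each haul-out.
#' @param dur_meanlog,dur_sdlog lognormal haul-out duration (hours).
#' @param gap_rate rate of the exponential inter-haul-out gap (per hour).
#' @param weight_mean,weight_sd body-mass distribution (kg), truncated at
#'   20 kg.
#' @param track_days_range deployment length range (days), drawn uniform
#'   per seal.
#' @param start_date,start_spread_days tagging date window (UTC).
#' @param jitter_sd_m Gaussian location jitter around the site (metres).
#' @param dest_scale_km distance-decay scale of the destination kernel.
#' @param tagging_sites site ids where seals may be tagged (default: all
#'   sites outside the national-scale units, mirroring a single-country
#'   tagging program).
#' @param seed integer seed; fixes the full output stream. Each seal uses
#'   a counter-based substream derived from it, so enlarging the cohort
#'   does not reshuffle existing animals.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_seals = 26,
                       sites = default_sites(),
                       lambda = c(Sweden = 0.05, VestAgder = 0.048,
                                  Buskerud = 0.025, Ostfold = 0.03,
                                  AustAgder = 0.023, Vestfold = 0.015,
                                  Telemark = 0.004, Denmark = 0.04),
                       beta_weight = 0,
                       sigma_b = 0.85,
                       p_switch = 0.2,
                       dur_meanlog = log(5), dur_sdlog = 0.6,
                       gap_rate = 1 / 28,
                       weight_mean = 65, weight_sd = 25,
                       track_days_range = c(10, 178),
                       start_date = "2020-09-01",
                       start_spread_days = 45,
                       jitter_sd_m = 500,
                       dest_scale_km = 20,
                       tagging_sites = NULL,
                       seed = 1L) {
  stopifnot(n_seals >= 1, all(lambda >= 0), sigma_b >= 0,
            p_switch >= 0, p_switch <= 1, gap_rate > 0,
            length(track_days_range) == 2, track_days_range[1] > 0)
  miss <- setdiff(unique(sites$unit), names(lambda))
  if (length(miss)) stop("no leave hazard for unit(s): ", paste(miss, collapse = ", "))
  if (length(unique(sites$unit)) < 2 && any(lambda[unique(sites$unit)] > 0)) {
    stop("a single-unit site set with positive leave hazard has no destination")
  }
  if (is.null(tagging_sites)) {
    nat <- c("Sweden", "Denmark")
    tagging_sites <- sites$site_id[!(sites$unit %in% nat)]
    if (!length(tagging_sites)) tagging_sites <- sites$site_id
  }
  structure(list(n_seals = n_seals, sites = sites, lambda = lambda,
                 beta_weight = beta_weight, sigma_b = sigma_b,
                 p_switch = p_switch, dur_meanlog = dur_meanlog,
                 dur_sdlog = dur_sdlog, gap_rate = gap_rate,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 track_days_range = track_days_range,
                 start_date = start_date,
                 start_spread_days = start_spread_days,
                 jitter_sd_m = jitter_sd_m, dest_scale_km = dest_scale_km,
                 tagging_sites = tagging_sites,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d seals, %d sites in %d units, sigma_b = %g, seed %d\n",
              x$n_seals, nrow(x$sites), length(unique(x$sites$unit)),
              x$sigma_b, x$seed))
  invisible(x)
}

#' Simulate a multi-seal haul-out cohort with known ground truth
#'
#' Runs the semi-Markov generator described in [sim_config()] and returns
#' both the observable event table (what a telemetry pipeline would see)
#' and the generator's bookkeeping (true frailties, crossing times, trip
#' counts) for parameter-recovery and round-trip testing.
#'
#' @param config a [sim_config()].
#' @return object of class `seal_cohort`: list with
#'   \describe{
#'     \item{events}{`seal_id`, `start`, `end` (POSIXct UTC), `lon`,
#'       `lat`, `site_id`, `unit_true`, `duration_h`.}
#'     \item{seals}{`seal_id`, `tagging_unit`, `tagging_lon`,
#'       `tagging_lat`, `weight_kg`, `sex`, `b` (true frailty),
#'       `track_start`, `track_end`.}
#'     \item{truth}{list: `crossings` (per-seal spell table with true
#'       exponential crossing draws), `site_trips` (true per-site-pair
#'       trip and seal counts), `n_cross` per seal.}
#'     \item{config}{the configuration.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sites <- config$sites
  if (length(unique(sites$unit)) < 2 && any(config$lambda[unique(sites$unit)] > 0)) {
    stop("a single-unit site set with positive leave hazard has no destination")
  }
  dmat <- outer(seq_len(nrow(sites)), seq_len(nrow(sites)), function(i, j) {
    haversine_km(sites$lon[i], sites$lat[i], sites$lon[j], sites$lat[j])
  })
  t0 <- as.POSIXct(config$start_date, tz = "UTC")
  seals <- list(); events <- list(); spells <- list()
  for (i in seq_len(config$n_seals)) {
    # counter-based per-seal substream off the single global seed
    set.seed((config$seed %% 100000L) * 20011L + i)
    sim <- simulate_seal(i, config, sites, dmat, t0)
    seals[[i]] <- sim$seal
    events[[i]] <- sim$events
    spells[[i]] <- sim$spells
  }
  ev <- do.call(rbind, events)
  sl <- do.call(rbind, seals)
  sp <- do.call(rbind, spells)
  rownames(ev) <- rownames(sl) <- rownames(sp) <- NULL
  trips <- count_transitions(data.frame(seal_id = ev$seal_id, start = ev$start,
                                        node = ev$site_id))
  names(trips)[names(trips) %in% c("from", "to")] <- c("site_from", "site_to")
  structure(list(events = ev, seals = sl,
                 truth = list(crossings = sp, site_trips = trips,
                              n_cross = tapply(sp$event, sp$seal_id, sum)),
                 config = config),
            class = "seal_cohort")
}

simulate_seal <- function(i, config, sites, dmat, t0) {
  id <- sprintf("seal_%02d", i)
  b <- stats::rnorm(1, 0, config$sigma_b)
  weight <- max(20, stats::rnorm(1, config$weight_mean, config$weight_sd))
  sex <- sample(c("F", "M"), 1)
  tag_site <- sample(config$tagging_sites, 1)
  track_days <- stats::runif(1, config$track_days_range[1], config$track_days_range[2])
  start_off <- stats::runif(1, 0, config$start_spread_days) * 86400
  track_start <- as.numeric(t0) + start_off
  track_end <- track_start + track_days * 86400

  tag_idx <- match(tag_site, sites$site_id)
  cur <- tag_idx
  loghaz_mult <- b + config$beta_weight * weight
  lam <- function(site) config$lambda[[sites$unit[site]]] * exp(loghaz_mult)

  t <- track_start
  st <- en <- numeric(0); site_seq <- integer(0)
  spell_unit <- character(0); spell_t0 <- numeric(0)
  spell_tcross <- numeric(0); spell_event <- integer(0)
  origin <- NA_real_; t_cross <- Inf
  repeat {
    gap_h <- stats::rexp(1, config$gap_rate)
    h_start <- t + gap_h * 3600
    if (h_start > track_end) break
    dur_h <- stats::rlnorm(1, config$dur_meanlog, config$dur_sdlog)
    h_end <- min(h_start + dur_h * 3600, track_end)
    if (is.na(origin)) {
      # spell 1 opens at the first haul-out
      origin <- h_start
      l <- lam(cur)
      t_cross <- if (l > 0) stats::rexp(1, l) else Inf
      spell_unit <- c(spell_unit, sites$unit[cur])
      spell_t0 <- c(spell_t0, origin)
      spell_tcross <- c(spell_tcross, t_cross)
      spell_event <- c(spell_event, 0L)
    } else if ((h_start - origin) / 86400 >= t_cross) {
      # crossing materializes at this haul-out boundary
      dest <- pick_destination(cur, sites, dmat, config$dest_scale_km)
      cur <- dest
      spell_event[length(spell_event)] <- 1L
      origin <- h_start
      l <- lam(cur)
      t_cross <- if (l > 0) stats::rexp(1, l) else Inf
      spell_unit <- c(spell_unit, sites$unit[cur])
      spell_t0 <- c(spell_t0, origin)
      spell_tcross <- c(spell_tcross, t_cross)
      spell_event <- c(spell_event, 0L)
    } else if (stats::runif(1) < config$p_switch) {
      same <- which(sites$unit == sites$unit[cur])
      if (length(same) > 1) cur <- sample(setdiff(same, cur), 1)
    }
    st <- c(st, h_start); en <- c(en, h_end); site_seq <- c(site_seq, cur)
    t <- h_end
    if (t >= track_end) break
  }
  jit <- config$jitter_sd_m / 111195  # metres -> degrees latitude
  n_ev <- length(st)
  events <- if (n_ev) data.frame(
    seal_id = id,
    start = .POSIXct(st, tz = "UTC"), end = .POSIXct(en, tz = "UTC"),
    lon = sites$lon[site_seq] +
      stats::rnorm(n_ev, 0, jit) / cos(sites$lat[site_seq] * pi / 180),
    lat = sites$lat[site_seq] + stats::rnorm(n_ev, 0, jit),
    site_id = sites$site_id[site_seq],
    unit_true = sites$unit[site_seq],
    duration_h = (en - st) / 3600
  ) else NULL
  spells <- if (length(spell_unit)) data.frame(
    seal_id = id, spell_index = seq_along(spell_unit), unit = spell_unit,
    origin = .POSIXct(spell_t0, tz = "UTC"), t_cross_true = spell_tcross,
    event = spell_event
  ) else NULL
  seal <- data.frame(
    seal_id = id,
    tagging_unit = sites$unit[tag_idx],
    tagging_lon = sites$lon[tag_idx], tagging_lat = sites$lat[tag_idx],
    weight_kg = weight, sex = sex, b = b,
    track_start = .POSIXct(track_start, tz = "UTC"),
    track_end = .POSIXct(track_end, tz = "UTC")
  )
  list(seal = seal, events = events, spells = spells)
}

pick_destination <- function(cur, sites, dmat, scale_km) {
  cand <- which(sites$unit != sites$unit[cur])
  if (!length(cand)) stop("no destination site outside the current unit")
  w <- exp(-dmat[cur, cand] / scale_km)
  cand[sample.int(length(cand), 1, prob = w)]
}

#' Emit a wet/dry sensor stream from haul-out events
#'
#' The inverse of [detect_haulouts()]: dry during events, wet between,
#' sampled every `sampling` seconds with records also placed exactly at
#' every state transition. Optional noise injects short wet blips
#' (< 40 s) inside events and short dry blips (< 10 min) between events —
#' both of which the detection rules must absorb, so the round trip
#' recovers the input events exactly.
#'
#' @param events event data.frame (`seal_id`, `start`, `end`, `lon`,
#'   `lat`); events must not overlap within a seal.
#' @param sampling sampling interval in seconds (default 60). A value
#'   coarser than 40 s only affects sample density, not the transition
#'   records; a warning is issued above 40 s only if `exact_transitions`
#'   is disabled.
#' @param wet_blip_prob probability that an event (longer than 12 min)
#'   receives one interior wet blip of 10-35 s.
#' @param dry_blip_prob probability that an inter-event gap (longer than
#'   22 min) receives one interior dry blip of 1-9 min.
#' @param exact_transitions place records exactly at state changes
#'   (default TRUE; required for exact round-tripping).
#' @return data.frame of sensor records: `seal_id`, `timestamp`, `state`,
#'   `lon`, `lat` (coordinates on dry records only).
#' @export
emit_sensor_stream <- function(events, sampling = 60, wet_blip_prob = 0,
                               dry_blip_prob = 0, exact_transitions = TRUE) {
  stopifnot(nrow(events) > 0, sampling > 0)
  if (sampling > 40 && !exact_transitions) {
    warning("sampling coarser than 40 s without exact transition records: ",
            "the 40 s wet end-rule cannot be resolved")
  }
  out <- lapply(split(events, events$seal_id, drop = TRUE), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    s <- as.numeric(e$start); en <- as.numeric(e$end)
    if (nrow(e) > 1 && any(s[-1] < en[-nrow(e)])) stop("overlapping events")
    segs <- list()
    for (k in seq_len(nrow(e))) {
      # dry segment = the event, possibly cut by one interior wet blip
      dry <- cbind(s[k], en[k])
      if (wet_blip_prob > 0 && (en[k] - s[k]) > 720 &&
          stats::runif(1) < wet_blip_prob) {
        bl <- stats::runif(1, 10, 35)
        bs <- stats::runif(1, s[k] + 601, en[k] - bl - 1)
        dry <- rbind(c(s[k], bs), c(bs + bl, en[k]))
      }
      segs[[length(segs) + 1]] <- list(state = "dry", iv = dry,
                                       lon = e$lon[k], lat = e$lat[k])
      # wet gap to next event (or a trailing wet record)
      gap_end <- if (k < nrow(e)) s[k + 1] else en[k] + max(60, sampling)
      wet <- cbind(en[k], gap_end)
      if (dry_blip_prob > 0 && (gap_end - en[k]) > 1320 &&
          stats::runif(1) < dry_blip_prob) {
        bl <- stats::runif(1, 60, 540)
        bs <- stats::runif(1, en[k] + 41, gap_end - bl - 41)
        segs[[length(segs) + 1]] <- list(state = "wet", iv = cbind(en[k], bs))
        segs[[length(segs) + 1]] <- list(state = "dry", iv = cbind(bs, bs + bl),
                                         lon = NA_real_, lat = NA_real_)
        wet <- cbind(bs + bl, gap_end)
      }
      segs[[length(segs) + 1]] <- list(state = "wet", iv = wet)
    }
    rec <- lapply(segs, function(sg) {
      res <- NULL
      for (r in seq_len(nrow(sg$iv))) {
        a <- sg$iv[r, 1]; bnd <- sg$iv[r, 2]
        ts <- if (exact_transitions) {
          unique(c(a, seq(a, bnd, by = sampling)))
        } else seq(a, bnd, by = sampling)
        ts <- ts[ts < bnd]
        if (!length(ts)) ts <- a
        res <- rbind(res, data.frame(timestamp = ts, state = sg$state,
                                     lon = if (!is.null(sg$lon)) sg$lon else NA_real_,
                                     lat = if (!is.null(sg$lat)) sg$lat else NA_real_))
      }
      res
    })
    rec <- do.call(rbind, rec)
    rec <- rec[order(rec$timestamp), , drop = FALSE]
    rec <- rec[!duplicated(rec$timestamp), , drop = FALSE]
    # close the stream with a final wet record
    last <- rec$timestamp[nrow(rec)]
    rec <- rbind(rec, data.frame(timestamp = max(last + sampling, en[nrow(e)] + 60),
                                 state = "wet", lon = NA_real_, lat = NA_real_))
    cbind(seal_id = e$seal_id[1], rec)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$timestamp <- .POSIXct(res$timestamp, tz = "UTC")
  res
}

#' @export
print.seal_cohort <- function(x, ...) {
  cat(sprintf("<seal_cohort> %d seals, %d events, %d true crossings (seed %d)\n",
              nrow(x$seals), nrow(x$events),
              sum(x$truth$crossings$event), x$config$seed))
  invisible(x)
}

#' Convert a simulated cohort to seal tracks
#'
#' @param cohort a `seal_cohort`.
#' @return a [seal_tracks] object carrying the cohort's per-seal metadata.
#' @export
cohort_tracks <- function(cohort) {
  stopifnot(inherits(cohort, "seal_cohort"))
  seal_tracks(cohort$events, cohort$seals)
}

#' Synthetic management-unit map for the default site geometry
#'
#' Builds a rectangular, longitude-banded unit map that is consistent
#' with a site table: each unit gets a rectangle spanning from the
#' midpoint to its westward neighbour to the midpoint to its eastward
#' neighbour (padded at the extremes), over a generous latitude band.
#' This is a synthetic stand-in geometry for testing and simulation, not
#' a representation of any real administrative boundary.
#'
#' @param sites site table as in [default_sites()].
#' @param lat_range latitude extent of every rectangle.
#' @param pad longitudinal padding beyond the extreme sites (degrees).
#' @return a [unit_map] with one rectangle per unit, west to east.
#' @export
sites_unit_map <- function(sites = default_sites(), lat_range = c(55, 61),
                           pad = 1) {
  u_lon <- sort(tapply(sites$lon, sites$unit, mean))
  k <- length(u_lon)
  cuts <- c(u_lon[1] - pad,
            if (k > 1) (u_lon[-k] + u_lon[-1]) / 2,
            u_lon[k] + pad)
  polys <- lapply(seq_len(k), function(i) {
    rbind(c(cuts[i], lat_range[1]), c(cuts[i + 1], lat_range[1]),
          c(cuts[i + 1], lat_range[2]), c(cuts[i], lat_range[2]),
          c(cuts[i], lat_range[1]))
  })
  unit_map(names(u_lon), polys)
}
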