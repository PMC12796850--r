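# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive: each recomputes its quantity straight from the
# definition, sharing no code path with the package implementation.

t_utc <- function(s) as.POSIXct("2020-09-01 00:00:00", tz = "UTC") + s

# build a sensor stream from alternating (state, duration-in-seconds)
# segments; a closing record marks the stream end
sensor_stream <- function(states, durs, seal_id = "s1", t0 = t_utc(0)) {
  stopifnot(length(states) == length(durs))
  starts <- cumsum(c(0, durs[-length(durs)]))
  data.frame(seal_id = seal_id,
             timestamp = t0 + c(starts, sum(durs)),
             state = c(states, if (states[length(states)] == "wet") "dry" else "wet"))
}

# product-limit straight from the definition
km_oracle <- function(time, status, at) {
  ut <- sort(unique(time[status == 1]))
  vapply(at, function(t) {
    s <- 1
    for (ti in ut[ut <= t]) {
      n <- sum(time >= ti)
      d <- sum(time == ti & status == 1)
      s <- s * (1 - d / n)
    }
    s
  }, numeric(1))
}

# even-odd point-in-polygon is implemented in the package; the oracle
# here is mgcv's independent in/out test (strict interior points only)
pip_oracle <- function(lon, lat, ring) {
  mgcv::in.out(ring, cbind(lon, lat))
}

# connected components under a distance threshold by naive label
# propagation on the full adjacency matrix
cluster_oracle <- function(lon, lat, threshold_km) {
  n <- length(lon)
  adj <- vapply(seq_len(n), function(i) {
    hauloutnet::haversine_km(lon[i], lat[i], lon, lat) <= threshold_km
  }, logical(n))
  lab <- seq_len(n)
  repeat {  # min-label propagation to the fixed point
    new <- vapply(seq_len(n), function(i) min(lab[adj[, i]]), numeric(1))
    if (all(new == lab)) break
    lab <- new
  }
  match(lab, unique(lab))
}

# exhaustive weighted betweenness: enumerate every simple path between
# every node pair by DFS, keep minimum-cost paths, accumulate pair
# fractions for interior vertices
betweenness_oracle <- function(nodes, edges, cost) {
  n <- length(nodes)
  cmat <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    cmat[edges$from[k], edges$to[k]] <- cost[k]
    cmat[edges$to[k], edges$from[k]] <- cost[k]
  }
  paths_between <- function(s, t) {
    found <- list()
    dfs <- function(v, visited, c_so_far, path) {
      if (v == t) { found[[length(found) + 1]] <<- list(cost = c_so_far, path = path); return() }
      for (w in seq_len(n)) {
        if (is.finite(cmat[v, w]) && !visited[w]) {
          vv <- visited; vv[w] <- TRUE
          dfs(w, vv, c_so_far + cmat[v, w], c(path, w))
        }
      }
    }
    vis <- rep(FALSE, n); vis[s] <- TRUE
    dfs(s, vis, 0, s)
    found
  }
  score <- stats::setNames(numeric(n), nodes)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (!length(ps)) next
    costs <- vapply(ps, `[[`, numeric(1), "cost")
    best <- abs(costs - min(costs)) < 1e-9
    sp <- ps[best]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      on_v <- sum(vapply(sp, function(p) v %in% p$path, logical(1)))
      score[v] <- score[v] + on_v / length(sp)
    }
  }
  score
}

# two-unit generator configuration used for parameter-recovery work:
# per-day leave hazards 0.06 / 0.03 (true log-HR = log 2), 100-day tracks
recovery_config <- function(n_seals, sigma_b, seed) {
  sites <- data.frame(site_id = c("W", "E"), lon = c(10, 10.7),
                      lat = c(59, 59), unit = c("U1", "U2"))
  hauloutnet::sim_config(
    n_seals = n_seals, sites = sites,
    lambda = c(U1 = 0.06, U2 = 0.03), sigma_b = sigma_b,
    p_switch = 0, track_days_range = c(100, 100),
    tagging_sites = c("W", "E"), seed = seed
  )
}

risk_intervals_from_cohort <- function(cohort) {
  tr <- hauloutnet::cohort_tracks(cohort)
  tr$events$unit <- tr$events$unit_true
  hauloutnet::build_risk_intervals(tr)
}
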