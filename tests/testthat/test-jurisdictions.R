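square <- function(x0, y0, side = 1) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side), c(x0, y0))
}

test_that("unit assignment is containment with a deterministic boundary rule", {
  m <- unit_map(c("Vestfold", "Sweden"), list(square(10, 59), square(11, 59)))
  expect_equal(assign_unit(10.5, 59.5, m), "Vestfold")
  expect_equal(assign_unit(5, 55, m), "unassigned")  # open sea
  # point on the shared edge x = 11: first feature in file order wins
  expect_equal(assign_unit(11, 59.5, m), "Vestfold")
  m_rev <- unit_map(c("Sweden", "Vestfold"), list(square(11, 59), square(10, 59)))
  expect_equal(assign_unit(11, 59.5, m_rev), "Sweden")
  expect_error(assign_unit(200, 10, m), "range")
  expect_error(unit_map("A", list(rbind(c(0, 0), c(1, 1)))), "invalid geometry")
})

test_that("point-in-polygon agrees with an independent oracle on random points", {
  skip_if_not_installed("mgcv")
  set.seed(42)
  ring <- rbind(c(0, 0), c(4, 0), c(4, 3), c(2, 1.5), c(0, 3), c(0, 0))
  m <- unit_map("A", list(ring))
  lon <- runif(300, -1, 5); lat <- runif(300, -1, 4)
  mine <- assign_unit(lon, lat, m) == "A"
  orac <- pip_oracle(lon, lat, ring)
  expect_equal(mine, as.vector(orac))
})

test_that("multipolygons and holes are honoured", {
  outer_ring <- square(0, 0, 4)
  hole <- square(1, 1, 1)
  m <- unit_map("A", list(list(outer_ring, hole)))
  expect_equal(assign_unit(0.5, 0.5, m), "A")
  expect_equal(assign_unit(1.5, 1.5, m), "unassigned")  # inside the hole
  m2 <- unit_map("B", list(list(list(square(0, 0)), list(square(5, 5)))))
  expect_equal(assign_unit(c(0.5, 5.5, 3), c(0.5, 5.5, 3), m2),
               c("B", "B", "unassigned"))
})

test_that("GeoJSON unit maps round-trip through assignment", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(unit = "Vestfold"),
         geometry = list(type = "Polygon",
                         coordinates = list(apply(square(10, 59), 1, as.list)))),
    list(type = "Feature", properties = list(unit = "Sweden"),
         geometry = list(type = "MultiPolygon",
                         coordinates = list(list(apply(square(11, 59), 1, as.list)))))
  ))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  m <- read_unit_map(path)
  expect_equal(length(m$features), 2)
  expect_equal(assign_unit(c(10.5, 11.5), c(59.5, 59.5), m),
               c("Vestfold", "Sweden"))
})

test_that("cross-boundary flags follow the predecessor rule", {
  ev <- data.frame(seal_id = "s1", start = t_utc(c(0, 100, 200) * 3600),
                   unit = c("VF", "VF", "SE"))
  f <- flag_cross_boundary(ev)
  expect_equal(f$cross_boundary, c(NA_integer_, 0L, 1L))

  ev$unit <- c("VF", "SE", "VF")  # back-and-forth: two crossings
  expect_equal(flag_cross_boundary(ev)$cross_boundary, c(NA_integer_, 1L, 1L))

  ev$unit <- "VF"
  expect_equal(flag_cross_boundary(ev)$cross_boundary, c(NA_integer_, 0L, 0L))

  ev$unit <- c("VF", "unassigned", "VF")
  expect_error(flag_cross_boundary(ev), "unassigned")
})

test_that("risk intervals implement gap-time spells with end-of-track censoring", {
  day <- 86400
  ev <- data.frame(seal_id = "s1",
                   start = t_utc(c(0, 5, 12, 20) * day),
                   end = t_utc(c(0, 5, 12, 20) * day + 3600),
                   lon = 10, lat = 59, duration_h = 1,
                   unit = c("VF", "VF", "SE", "SE"))
  seals <- data.frame(seal_id = "s1", tagging_unit = "VF", tagging_lon = 10,
                      tagging_lat = 59, weight_kg = 80,
                      track_start = t_utc(0), track_end = t_utc(30 * day))
  ri <- build_risk_intervals(seal_tracks(ev, seals))
  expect_equal(nrow(ri), 2)
  expect_equal(ri$unit, c("VF", "SE"))
  expect_equal(ri$t_start, c(0, 0))
  expect_equal(ri$t_stop, c(12, 18))
  expect_equal(ri$event, c(1L, 0L))
  expect_equal(ri$weight_kg, c(80, 80))

  # single-unit track: one censored interval
  ev1 <- ev; ev1$unit <- "VF"
  ri1 <- build_risk_intervals(seal_tracks(ev1, seals))
  expect_equal(ri1$event, 0L)
  expect_equal(ri1$t_stop, 30)

  # a seal whose first haul-out is already outside its tagging unit:
  # spell 1 takes the first haul-out's unit, not the tagging unit
  ev2 <- ev; ev2$unit <- c("SE", "SE", "VF", "VF")
  ri2 <- build_risk_intervals(seal_tracks(ev2, seals))
  expect_equal(ri2$unit[1], "SE")
})

test_that("risk intervals conserve crossing counts and elapsed time", {
  co <- simulate_cohort(sim_config(n_seals = 8, seed = 5))
  tr <- cohort_tracks(co)
  tr$events$unit <- tr$events$unit_true
  fl <- flag_cross_boundary(tr$events)
  ri <- build_risk_intervals(tr)
  for (id in unique(ri$seal_id)) {
    expect_equal(sum(ri$event[ri$seal_id == id]),
                 sum(fl$cross_boundary[fl$seal_id == id], na.rm = TRUE))
    e <- tr$events[tr$events$seal_id == id, ]
    elapsed <- as.numeric(tr$seals$track_end[tr$seals$seal_id == id]) -
      as.numeric(min(e$start))
    expect_equal(sum(ri$t_stop[ri$seal_id == id] - ri$t_start[ri$seal_id == id]),
                 elapsed / 86400, tolerance = 1e-9)
  }
})

test_that("displacement fraction is the share of events outside the tagging unit", {
  mk <- function(units) {
    n <- length(units)
    ev <- data.frame(seal_id = "s1", start = t_utc((1:n) * 3600),
                     end = t_utc((1:n) * 3600 + 600), lon = 10, lat = 59,
                     duration_h = 1 / 6, unit = units)
    seals <- data.frame(seal_id = "s1", tagging_unit = "VF", tagging_lon = 10,
                        tagging_lat = 59, weight_kg = 60)
    displacement_fraction(seal_tracks(ev, seals))$displacement_pct
  }
  expect_equal(mk(rep("VF", 5)), 0)
  expect_equal(mk(c("VF", rep("SE", 9))), 90)
  expect_equal(mk(c("VF", "VF", "SE")), 100 / 3)
})

test_that("status at a date counts cross-boundary seals among those recording", {
  day <- 86400
  mk_seal <- function(id, units, day_offsets, tag = "VF") {
    list(ev = data.frame(seal_id = id, start = t_utc(day_offsets * day),
                         end = t_utc(day_offsets * day + 3600),
                         lon = 10, lat = 59, duration_h = 1, unit = units),
         meta = data.frame(seal_id = id, tagging_unit = tag, tagging_lon = 10,
                           tagging_lat = 59, weight_kg = 60))
  }
  a <- mk_seal("a", c("VF", "SE"), c(100, 121))   # away within window
  b <- mk_seal("b", c("VF", "VF"), c(100, 121))   # home within window
  c_ <- mk_seal("c", c("SE", "SE"), c(1, 2))      # stopped recording long before
  tr <- seal_tracks(rbind(a$ev, b$ev, c_$ev), rbind(a$meta, b$meta, c_$meta))
  st <- status_at_date(tr, t_utc(120 * day), window = 7)
  expect_equal(st$denominator, 2)
  expect_equal(st$numerator, 1)
  expect_equal(st$proportion, 0.5)
  expect_error(status_at_date(tr, t_utc(3000 * day)), "no seal")
})
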