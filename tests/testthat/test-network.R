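table3_net <- function(...) {
  network_from_edges(
    read_edge_table(system.file("extdata", "table3_edges.csv",
                                package = "hauloutnet")), ...)
}

test_that("haversine distance behaves at the landmarks", {
  expect_equal(haversine_km(10, 59, 10, 59), 0)
  expect_equal(haversine_km(0, 0, 1, 0), 6371.0088 * pi / 180, tolerance = 1e-6)
  expect_equal(round(haversine_km(0, 0, 1, 0), 2), 111.20)
  expect_equal(haversine_km(0, 0, 180, 0), pi * 6371.0088, tolerance = 1e-6)
  expect_error(haversine_km(0, 100, 0, 0), "range")
})

test_that("proximity grouping chains transitively at the threshold", {
  # three collinear points at ~0, 8.9, 17.8 km: endpoints are > 10 km
  # apart but chain through the middle point into one node
  lat <- c(0, 0.08, 0.16)
  cl <- cluster_sites(c(0, 0, 0), lat, threshold_km = 10)
  expect_equal(length(unique(cl$node)), 1)

  # two points ~12 km apart: separate nodes, labelled west to east
  cl2 <- cluster_sites(c(0, 0.108), c(0, 0), threshold_km = 10)
  expect_equal(cl2$node, c("A", "B"))

  cl3 <- cluster_sites(10, 59)
  expect_equal(cl3$node, "A")
  expect_equal(cl3$centroids$n_events, 1L)
})

test_that("grouping equals brute-force connected components on random instances", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    lon <- runif(n, 9, 11); lat <- runif(n, 58, 59)
    cl <- cluster_sites(lon, lat, threshold_km = 15)
    orac <- cluster_oracle(lon, lat, 15)
    # same partition: node labels must be a bijection of oracle components
    expect_equal(length(unique(cl$node)), length(unique(orac)))
    expect_true(all(tapply(orac, cl$node, function(x) length(unique(x))) == 1))
  }
})

test_that("transition counting follows consecutive-pair semantics", {
  mk <- function(id, nodes) data.frame(seal_id = id, start = t_utc(seq_along(nodes) * 3600),
                                       node = nodes)
  expect_equal(nrow(count_transitions(mk("s1", c("A", "A", "A")))), 0)

  e <- count_transitions(mk("s1", c("A", "B", "A", "B")))
  expect_equal(e$density, 3L)
  expect_equal(e$occupancy, 1L)

  # seven seals shuttling F-E for 34 trips in total
  evs <- do.call(rbind, lapply(1:7, function(i) {
    reps <- c(5, 5, 5, 5, 5, 5, 4)[i]  # 6*5 + 4 = 34 trips
    mk(paste0("s", i), c("F", rep(c("E", "F"), length.out = reps)))
  }))
  e2 <- count_transitions(evs)
  expect_equal(e2$density, 34L)
  expect_equal(e2$occupancy, 7L)
})

test_that("edge weight is trips per individual with validation", {
  expect_equal(round(edge_weight(34, 7), 1), 4.9)
  expect_equal(round(edge_weight(11, 6), 1), 1.8)
  expect_equal(edge_weight(6, 1), 6)
  for (k in c(1, 3, 9)) expect_equal(edge_weight(k, k), 1)
  expect_error(edge_weight(5, 0), "occupancy")
  expect_error(edge_weight(3, 5), "density")
})

test_that("the printed 17-edge network reconstructs with the published structure", {
  net <- table3_net()
  expect_equal(nrow(net$nodes), 13)
  expect_equal(nrow(net$edges), 17)
  deg <- node_degree(net)
  expect_equal(unname(deg["H"]), 6L)
  expect_equal(unname(deg["A"]), 1L)  # Vest-Agder links only to B
  expect_equal(sum(deg), 2 * 17)
})

test_that("betweenness honours both conventions on canonical graphs", {
  path3 <- data.frame(from = c("A", "B"), to = c("B", "C"),
                      distance_km = 1, occupancy = 1, density = 1)
  net <- network_from_edges(path3)
  b <- node_betweenness(net)
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))

  k4 <- data.frame(from = c("A", "A", "A", "B", "B", "C"),
                   to = c("B", "C", "D", "C", "D", "D"),
                   distance_km = 1, occupancy = 1, density = 1)
  expect_true(all(node_betweenness(network_from_edges(k4)) == 0))
})

test_that("betweenness equals exhaustive path enumeration under both conventions", {
  set.seed(83)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    nodes <- LETTERS[1:n]
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.5
    keep[sample(nrow(pairs), n)] <- TRUE  # keep it reasonably connected
    ed <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                     distance_km = round(runif(sum(keep), 10, 200)),
                     occupancy = sample(1:5, sum(keep), replace = TRUE))
    ed$density <- ed$occupancy * sample(1:4, nrow(ed), replace = TRUE)
    net <- network_from_edges(ed)
    for (cost in c("inverse_dc_weight", "dc_weight")) {
      w <- if (cost == "inverse_dc_weight") 1 / net$edges$dc_weight else net$edges$dc_weight
      raw <- betweenness_oracle(net$nodes$node, net$edges, w)
      expect_equal(node_betweenness(net, cost = cost, normalization = "pairs"),
                   raw / ((n - 1) * (n - 2) / 2), tolerance = 1e-9)
      if (max(raw) > 0) {
        expect_equal(node_betweenness(net, cost = cost, normalization = "max"),
                     raw / max(raw), tolerance = 1e-9)
      }
    }
  }
})

test_that("network assembly from events matches generator ground truth", {
  # two-site shuttle: one seal alternating between sites 60 km apart
  ev <- data.frame(seal_id = "s1", start = t_utc((1:6) * 86400),
                   end = t_utc((1:6) * 86400 + 3600),
                   lon = rep(c(10, 11.05), 3), lat = 59, duration_h = 1)
  net <- build_network(ev)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$density, 5L)
  expect_equal(net$edges$occupancy, 1L)
  expect_equal(net$edges$weight, 5)
  expect_equal(net$edges$distance_km,
               haversine_km(10, 59, 11.05, 59), tolerance = 1e-6)

  # a seal that never moves: one node, no edges
  ev1 <- ev; ev1$lon <- 10
  net1 <- build_network(ev1)
  expect_equal(nrow(net1$nodes), 1)
  expect_equal(nrow(net1$edges), 0)
  expect_error(build_network(ev[0, ]), "no haul-out events")

  # simulated cohort: edge densities must reproduce the generator's
  # true site-level trip counts (sites are > 10 km apart, so nodes = sites)
  co <- simulate_cohort(sim_config(n_seals = 10, jitter_sd_m = 100, seed = 9))
  net2 <- build_network(cohort_tracks(co))
  truth <- co$truth$site_trips
  sites <- co$config$sites
  node_of <- cluster_sites(sites$lon, sites$lat, 10)$node
  names(node_of) <- sites$site_id
  expect_equal(sum(net2$edges$density), sum(truth$density))
  for (k in seq_len(nrow(truth))) {
    a <- node_of[truth$site_from[k]]; b <- node_of[truth$site_to[k]]
    hit <- (net2$edges$from == min(a, b)) & (net2$edges$to == max(a, b))
    expect_equal(net2$edges$density[hit], truth$density[k])
    expect_equal(net2$edges$occupancy[hit], truth$occupancy[k])
  }
})

test_that("edge density is conserved against raw consecutive-pair counts", {
  co <- simulate_cohort(sim_config(n_seals = 8, seed = 13))
  tr <- cohort_tracks(co)
  net <- build_network(tr)
  cl <- cluster_sites(tr$events$lon, tr$events$lat, 10)
  moved <- unlist(lapply(split(cl$node, tr$events$seal_id), function(nd) {
    if (length(nd) < 2) return(integer(0))
    nd[-1] != nd[-length(nd)]
  }))
  expect_equal(sum(net$edges$density), sum(moved))
  expect_true(all(net$edges$occupancy <= net$edges$density))
  expect_true(all(net$edges$weight >= 1))
})

test_that("network export writes GraphML and CSV files", {
  net <- table3_net()
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(file.path(dir, "haulout_network.graphml"),
                          format = "graphml")
  expect_equal(igraph::gsize(g), 17)
})
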