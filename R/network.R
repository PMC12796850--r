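#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius), via \pkg{geosphere}.
#'
#' @param lon1,lat1,lon2,lat2 WGS84 coordinates in decimal degrees
#'   (vectorized).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("coordinates out of WGS84 range")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

#' Group haul-out locations into nodes by spatial proximity
#'
#' Chain-rule (single-linkage) grouping: two locations belong to the same
#' node if they are within `threshold_km` of each other, directly or
#' through a chain of intermediate locations (connected components of the
#' within-threshold graph). Nodes are labelled west to east by centroid
#' longitude: A, B, ..., Z, AA, AB, ...
#'
#' @param lon,lat coordinates of all haul-out events, all seals pooled.
#' @param threshold_km grouping distance in km (default 10).
#' @return list with `node` (label per input point), `centroids`
#'   (data.frame `node`, `lon`, `lat`, `n_events`).
#' @export
cluster_sites <- function(lon, lat, threshold_km = 10) {
  n <- length(lon)
  stopifnot(n >= 1, length(lat) == n, threshold_km > 0)
  comp <- integer(n)
  # flood fill over the within-threshold adjacency, one distance row at a
  # time (no n x n matrix held)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      d <- haversine_km(lon[i], lat[i], lon, lat)
      nb <- which(d <= threshold_km & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  cen_lon <- tapply(lon, comp, mean)
  cen_lat <- tapply(lat, comp, mean)
  ord <- order(cen_lon)
  lab <- node_labels(length(ord))
  relabel <- character(length(ord))
  relabel[ord] <- lab
  data_cent <- data.frame(node = relabel[seq_along(cen_lon)],
                          lon = as.numeric(cen_lon),
                          lat = as.numeric(cen_lat),
                          n_events = as.integer(table(comp)))
  data_cent <- data_cent[order(data_cent$node), , drop = FALSE]
  rownames(data_cent) <- NULL
  list(node = relabel[comp], centroids = data_cent)
}

node_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(n)]
}

#' Count trips between haul-out nodes
#'
#' Every consecutive pair of haul-out events of one seal at two different
#' nodes contributes one trip to that unordered node pair. Edge density is
#' the total trip count; edge occupancy the number of distinct seals
#' contributing at least one trip. Consecutive events at the same node add
#' nothing, and passing near a node without hauling out is not a visit.
#'
#' @param events data.frame with `seal_id`, `start`, `node`
#'   (time-ordered within seal, or orderable by `start`).
#' @return data.frame of edges: `from`, `to` (alphabetical within pair),
#'   `density`, `occupancy`.
#' @export
count_transitions <- function(events) {
  stopifnot(all(c("seal_id", "node") %in% names(events)))
  if (!is.null(events$start)) {
    events <- events[order(events$seal_id, events$start), , drop = FALSE]
  }
  trips <- do.call(rbind, lapply(split(events, events$seal_id, drop = TRUE), function(e) {
    nd <- as.character(e$node)
    if (length(nd) < 2) return(NULL)
    a <- nd[-length(nd)]; b <- nd[-1]
    keep <- a != b
    if (!any(keep)) return(NULL)
    data.frame(seal_id = e$seal_id[1],
               from = pmin(a[keep], b[keep]), to = pmax(a[keep], b[keep]))
  }))
  if (is.null(trips) || !nrow(trips)) {
    return(data.frame(from = character(), to = character(),
                      density = integer(), occupancy = integer()))
  }
  key <- paste(trips$from, trips$to, sep = "\r")
  dens <- table(key)
  occ <- tapply(trips$seal_id, key, function(s) length(unique(s)))
  k <- names(dens)
  out <- data.frame(from = sub("\r.*", "", k), to = sub(".*\r", "", k),
                    density = as.integer(dens), occupancy = as.integer(occ[k]))
  out[order(out$from, out$to), , drop = FALSE]
}

#' Edge weight: trips per individual
#'
#' Standardizes edge density for uneven sampling effort by dividing the
#' total trip count by the number of unique individuals making the
#' connection.
#'
#' @param density total trips on the edge (>= occupancy).
#' @param occupancy unique individuals on the edge (>= 1).
#' @return trips per individual (numeric; >= 1).
#' @examples
#' edge_weight(34, 7)  # 4.857... -> reported as 4.9
#' @export
edge_weight <- function(density, occupancy) {
  if (any(occupancy < 1)) stop("edge occupancy must be >= 1")
  if (any(density < occupancy)) stop("edge density cannot be below occupancy")
  density / occupancy
}

#' Build the spatial haul-out network
#'
#' Clusters all haul-out locations into nodes ([cluster_sites()]), counts
#' per-seal trips between nodes ([count_transitions()]), and attaches the
#' edge metrics (density, occupancy, weight, distance, distance-corrected
#' weight) and node metrics (degree, normalized betweenness).
#'
#' @param tracks a [seal_tracks] object, or an event data.frame with
#'   `seal_id`, `start`, `lon`, `lat`.
#' @param threshold_km node grouping threshold (default 10 km).
#' @param cost,normalization betweenness conventions, see
#'   [node_betweenness()].
#' @return object of class `haulout_network`: list with `nodes`
#'   (`node`, `lon`, `lat`, `n_events`, `degree`, `betweenness`), `edges`
#'   (`from`, `to`, `distance_km`, `occupancy`, `density`, `weight`,
#'   `dc_weight`), `meta`.
#' @export
build_network <- function(tracks, threshold_km = 10,
                          cost = c("inverse_dc_weight", "dc_weight"),
                          normalization = c("pairs", "max")) {
  ev <- if (inherits(tracks, "seal_tracks")) tracks$events else tracks
  if (!nrow(ev)) stop("no haul-out events to build a network from")
  cl <- cluster_sites(ev$lon, ev$lat, threshold_km)
  ev$node <- cl$node
  edges <- count_transitions(ev)
  cen <- cl$centroids
  if (nrow(edges)) {
    i <- match(edges$from, cen$node); j <- match(edges$to, cen$node)
    edges$distance_km <- haversine_km(cen$lon[i], cen$lat[i], cen$lon[j], cen$lat[j])
    edges$weight <- edge_weight(edges$density, edges$occupancy)
    edges$dc_weight <- edges$weight / edges$distance_km
  } else {
    edges$distance_km <- edges$weight <- edges$dc_weight <- numeric(0)
  }
  net <- structure(list(nodes = cen, edges = edges,
                        meta = list(threshold_km = threshold_km,
                                    distance_source = "centroid haversine",
                                    cost = match.arg(cost),
                                    normalization = match.arg(normalization))),
                   class = "haulout_network")
  finalize_network(net)
}

#' Build a network from a printed edge table
#'
#' Reconstructs a `haulout_network` from an edge list of the standard
#' reporting layout: node pair, separation distance (km), edge occupancy,
#' edge density and (optionally) edge weight. Printed distances and
#' weights are treated as authoritative inputs; the weight is recomputed
#' as density/occupancy only where absent.
#'
#' @param edges data.frame with columns `from`, `to`, `distance_km`,
#'   `occupancy`, `density`, optionally `weight`.
#' @inheritParams build_network
#' @return a `haulout_network` (node coordinates unknown, `NA`).
#' @export
network_from_edges <- function(edges, cost = c("inverse_dc_weight", "dc_weight"),
                               normalization = c("pairs", "max")) {
  need <- c("from", "to", "distance_km", "occupancy", "density")
  stopifnot(all(need %in% names(edges)))
  if (is.null(edges$weight)) edges$weight <- edge_weight(edges$density, edges$occupancy)
  edges$dc_weight <- edges$weight / edges$distance_km
  labs <- sort(unique(c(edges$from, edges$to)))
  nodes <- data.frame(node = labs, lon = NA_real_, lat = NA_real_,
                      n_events = NA_integer_)
  net <- structure(list(nodes = nodes, edges = edges,
                        meta = list(threshold_km = NA_real_,
                                    distance_source = "edge table",
                                    cost = match.arg(cost),
                                    normalization = match.arg(normalization))),
                   class = "haulout_network")
  finalize_network(net)
}

finalize_network <- function(net) {
  net$nodes$degree <- node_degree(net)
  net$nodes$betweenness <- node_betweenness(net, cost = net$meta$cost,
                                            normalization = net$meta$normalization)
  net
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$nodes$node)
  g
}

#' Node degree
#'
#' Number of distinct nodes each haul-out node is connected to.
#'
#' @param net a `haulout_network`.
#' @return named integer vector, in node order.
#' @export
node_degree <- function(net) {
  stopifnot(inherits(net, "haulout_network"))
  if (!nrow(net$edges)) {
    return(stats::setNames(integer(nrow(net$nodes)), net$nodes$node))
  }
  deg <- igraph::degree(as_igraph(net))
  stats::setNames(as.integer(deg[net$nodes$node]), net$nodes$node)
}

#' Normalized betweenness centrality on distance-corrected weights
#'
#' Shortest-path betweenness (Brandes' algorithm via \pkg{igraph}) on the
#' haul-out network, with explicit, logged conventions because the metric
#' is sensitive to them:
#'
#' * `cost = "inverse_dc_weight"` (default): the traversal cost of an
#'   edge is 1 / dc_weight = distance / weight, so strongly used, nearby
#'   connections are "short". `"dc_weight"` uses dc_weight itself as the
#'   cost.
#' * `normalization = "pairs"` (default): raw scores divided by
#'   (n-1)(n-2)/2, the number of unordered node pairs excluding the focal
#'   node. `"max"` divides by the maximum raw score.
#'
#' @param net a `haulout_network`.
#' @param cost,normalization convention switches, see Details.
#' @return named numeric vector in `[0, 1]`, in node order.
#' @export
node_betweenness <- function(net, cost = c("inverse_dc_weight", "dc_weight"),
                             normalization = c("pairs", "max")) {
  stopifnot(inherits(net, "haulout_network"))
  cost <- match.arg(cost); normalization <- match.arg(normalization)
  n <- nrow(net$nodes)
  if (!nrow(net$edges) || n < 3) {
    return(stats::setNames(numeric(n), net$nodes$node))
  }
  w <- switch(cost, inverse_dc_weight = 1 / net$edges$dc_weight,
              dc_weight = net$edges$dc_weight)
  if (any(!is.finite(w)) || any(w <= 0)) stop("edge costs must be finite and > 0")
  b <- igraph::betweenness(as_igraph(net), weights = w, directed = FALSE)
  b <- b[net$nodes$node]
  bn <- switch(normalization,
               pairs = b / ((n - 1) * (n - 2) / 2),
               max = if (max(b) > 0) b / max(b) else b)
  stats::setNames(as.numeric(bn), net$nodes$node)
}

#' Betweenness under the full convention grid
#'
#' Computes normalized betweenness for every combination of the two cost
#' conventions and the two normalizations — the disambiguation experiment
#' for under-specified reporting conventions.
#'
#' @param net a `haulout_network`.
#' @return data.frame with one row per (cost, normalization) cell and one
#'   column per node.
#' @export
betweenness_grid <- function(net) {
  grid <- expand.grid(cost = c("inverse_dc_weight", "dc_weight"),
                      normalization = c("pairs", "max"),
                      stringsAsFactors = FALSE)
  scores <- t(apply(grid, 1, function(g) {
    node_betweenness(net, cost = g[["cost"]], normalization = g[["normalization"]])
  }))
  cbind(grid, as.data.frame(scores))
}

#' @export
print.haulout_network <- function(x, ...) {
  cat(sprintf("<haulout_network> %d nodes, %d edges (threshold %s km, %s)\n",
              nrow(x$nodes), nrow(x$edges),
              format(x$meta$threshold_km), x$meta$distance_source))
  cat(sprintf("betweenness convention: cost = %s, normalization = %s\n",
              x$meta$cost, x$meta$normalization))
  invisible(x)
}

#' @export
summary.haulout_network <- function(object, ...) {
  list(nodes = object$nodes,
       edges = object$edges[order(-object$edges$weight), , drop = FALSE])
}

#' @export
plot.haulout_network <- function(x, ...) {
  g <- as_igraph(x)
  igraph::V(g)$size <- 8 + 20 * x$nodes$betweenness[match(igraph::V(g)$name, x$nodes$node)]
  igraph::E(g)$width <- x$edges$occupancy
  lay <- if (!all(is.na(x$nodes$lon))) as.matrix(x$nodes[, c("lon", "lat")]) else NULL
  plot(g, layout = lay, ...)
  invisible(x)
}

#' Export a network as GraphML plus node/edge CSVs
#'
#' @param net a `haulout_network`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths of the written files, invisibly.
#' @export
write_network <- function(net, dir, prefix = "haulout_network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- as_igraph(net)
  for (cn in c("distance_km", "occupancy", "density", "weight", "dc_weight")) {
    g <- igraph::set_edge_attr(g, cn, value = net$edges[[cn]])
  }
  g <- igraph::set_vertex_attr(g, "betweenness", value = net$nodes$betweenness)
  g <- igraph::set_vertex_attr(g, "degree", value = net$nodes$degree)
  paths <- file.path(dir, paste0(prefix, c(".graphml", "_nodes.csv", "_edges.csv")))
  igraph::write_graph(g, paths[1], format = "graphml")
  utils::write.csv(net$nodes, paths[2], row.names = FALSE)
  utils::write.csv(net$edges, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read an edge table CSV
#'
#' Reads an edge list in the reporting layout used by
#' [network_from_edges()]. The packaged example
#' (`system.file("extdata", "table3_edges.csv", package = "hauloutnet")`)
#' is the published 13-node, 17-edge harbour-seal haul-out network for the
#' Skagerrak-Kattegat region, with printed separation distances.
#'
#' @param path CSV with columns `from`, `to`, `distance_km`, `occupancy`,
#'   `density`, optionally `weight`.
#' @return data.frame.
#' @export
read_edge_table <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("from", "to", "distance_km", "occupancy", "density")
  if (!all(need %in% names(e))) {
    stop("edge table must have columns: ", paste(need, collapse = ", "))
  }
  e
}
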