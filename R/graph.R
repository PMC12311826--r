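#' Construct a ZIP-level graph
#'
#' A `zip_graph` is a weighted undirected graph over an ordered set of ZIP
#' codes, stored as a dense symmetric weight matrix `W` with a zero
#' diagonal (no self-loops). Three builders produce the variants used in
#' spatial hesitancy modelling: [contact_graph()] (summed activity-weighted
#' person contacts), [adjacency_graph()] (shared boundaries, unit weights)
#' and [distance_graph()] (inverse centroid distance, fully connected).
#'
#' @param W numeric `[N, N]` symmetric nonnegative matrix with zero diagonal.
#' @param zips character vector of N ZIP identifiers.
#' @param kind one of `"aggregated_contact"`, `"adjacency"`, `"distance"`.
#' @param normalized logical; `TRUE` once [normalize_weights()] has run.
#' @param support logical `[N, N]` matrix marking realized edges; defaults
#'   to `W > 0`. Kept separately because min-max normalization maps the
#'   weakest realized edge to weight 0 without deleting it.
#' @return An object of class `zip_graph`.
#' @export
zip_graph <- function(W, zips,
                      kind = c("aggregated_contact", "adjacency", "distance"),
                      normalized = FALSE, support = NULL) {
  kind <- match.arg(kind)
  zips <- as.character(zips)
  N <- length(zips)
  assert_that(all(dim(W) == c(N, N)), "W must be N x N")
  assert_that(max(abs(W - t(W))) < 1e-12, "W must be symmetric")
  assert_that(all(diag(W) == 0), "W must have a zero diagonal (no self-loops)")
  assert_that(all(W >= 0), "W must be nonnegative")
  dimnames(W) <- list(zips, zips)
  if (is.null(support)) support <- W > 0
  structure(list(zips = zips, W = W, kind = kind,
                 normalized = isTRUE(normalized), support = support),
            class = "zip_graph")
}

#' @export
print.zip_graph <- function(x, ...) {
  ne <- sum(x$support[upper.tri(x$support)])
  cat(sprintf("zip_graph (%s): %d ZIPs, %d edges%s\n", x$kind,
              length(x$zips), ne, if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' ZIP geometry container
#'
#' Planar centroids plus the set of unordered boundary-sharing ZIP pairs.
#'
#' @param zips character vector of ZIP identifiers.
#' @param centroids numeric `[N, 2]` matrix of planar coordinates.
#' @param adjacency_pairs 2-column character matrix of unordered ZIP pairs
#'   sharing a boundary.
#' @return An object of class `zip_geometry`.
#' @export
zip_geometry <- function(zips, centroids, adjacency_pairs) {
  zips <- as.character(zips)
  assert_that(nrow(centroids) == length(zips), "one centroid per ZIP")
  assert_that(!anyDuplicated(paste(centroids[, 1], centroids[, 2])),
              "centroids must be distinct")
  rownames(centroids) <- zips
  if (length(adjacency_pairs))
    assert_that(all(adjacency_pairs %in% zips),
                "adjacency pair references unknown ZIP")
  structure(list(zips = zips, centroids = centroids,
                 adjacency_pairs = adjacency_pairs),
            class = "zip_geometry")
}

#' Aggregate person-level contacts into a ZIP contact graph
#'
#' Sums the activity weights of all person-to-person contacts whose
#' endpoints live in two different ZIP codes: `W[i, j]` is the total
#' contact weight between residents of ZIP i and ZIP j. Intra-ZIP contacts
#' are discarded (the graph has no self-loops); edges referencing ZIPs
#' outside `zips` are dropped with a warning.
#'
#' @param edges data frame with columns `person_u`, `person_v`, `zip_u`,
#'   `zip_v`, `weight` (nonnegative activity weight, e.g. contact hours).
#' @param zips ordered character vector of ZIPs for the graph.
#' @return A `zip_graph` of kind `"aggregated_contact"`.
#' @export
contact_graph <- function(edges, zips) {
  zips <- as.character(zips)
  assert_that(all(edges$weight >= 0), "contact weights must be nonnegative")
  known <- edges$zip_u %in% zips & edges$zip_v %in% zips
  if (!all(known)) {
    warning(sprintf("dropping %d contact(s) referencing unknown ZIPs",
                    sum(!known)))
    edges <- edges[known, , drop = FALSE]
  }
  cross <- edges$zip_u != edges$zip_v
  edges <- edges[cross, , drop = FALSE]
  if (!nrow(edges)) stop("no cross-ZIP contacts: aggregated graph is empty")
  N <- length(zips)
  W <- matrix(0, N, N)
  i <- match(edges$zip_u, zips); j <- match(edges$zip_v, zips)
  lo <- pmin(i, j); hi <- pmax(i, j)
  agg <- rowsum(edges$weight, group = (lo - 1L) * N + hi)
  key <- as.integer(rownames(agg))
  W[cbind((key - 1L) %/% N + 1L, (key - 1L) %% N + 1L)] <- agg[, 1]
  W <- W + t(W)
  zip_graph(W, zips, "aggregated_contact")
}

#' Geographic adjacency graph
#'
#' Unit-weight edges between ZIP codes sharing a geographic boundary.
#'
#' @param geometry a [zip_geometry()].
#' @param zips ZIP ordering for the graph; defaults to `geometry$zips`.
#' @return A `zip_graph` of kind `"adjacency"`.
#' @export
adjacency_graph <- function(geometry, zips = geometry$zips) {
  zips <- as.character(zips)
  N <- length(zips)
  W <- matrix(0, N, N)
  pr <- geometry$adjacency_pairs
  if (length(pr)) {
    keep <- pr[, 1] %in% zips & pr[, 2] %in% zips
    pr <- pr[keep, , drop = FALSE]
    i <- match(pr[, 1], zips); j <- match(pr[, 2], zips)
    W[cbind(i, j)] <- 1; W[cbind(j, i)] <- 1
  }
  diag(W) <- 0
  zip_graph(W, zips, "adjacency")
}

#' Inverse-distance graph
#'
#' Fully connected graph with `W[i, j] = 1 / dist(centroid_i, centroid_j)`.
#' Distances are Euclidean in the centroid units; with `great_circle = TRUE`
#' the centroids are treated as (longitude, latitude) degrees and the
#' haversine great-circle distance in kilometres is used instead.
#'
#' @param geometry a [zip_geometry()].
#' @param zips ZIP ordering for the graph; defaults to `geometry$zips`.
#' @param great_circle use haversine distance on lon/lat coordinates.
#' @return A `zip_graph` of kind `"distance"`.
#' @export
distance_graph <- function(geometry, zips = geometry$zips,
                           great_circle = FALSE) {
  zips <- as.character(zips)
  xy <- geometry$centroids[zips, , drop = FALSE]
  if (great_circle) {
    rad <- pi / 180
    lat <- xy[, 2] * rad; lon <- xy[, 1] * rad
    dlat <- outer(lat, lat, "-") / 2; dlon <- outer(lon, lon, "-") / 2
    a <- sin(dlat)^2 + outer(cos(lat), cos(lat)) * sin(dlon)^2
    D <- 2 * 6371 * asin(pmin(1, sqrt(a)))
  } else {
    D <- as.matrix(stats::dist(xy))
  }
  off <- D[upper.tri(D)]
  if (any(off == 0)) stop("coincident centroids give infinite edge weight")
  W <- 1 / D
  diag(W) <- 0
  zip_graph(W, zips, "distance")
}

#' Min-max normalize graph edge weights
#'
#' Maps the realized edge weights to `[0, 1]` by min-max normalization
#' over the multiset of existing edges; structural zeros (absent edges)
#' stay 0, and a graph with constant edge weights maps every edge to 1
#' (connectivity is kept rather than erased). The weakest realized edge
#' gets weight 0 but remains in the graph's edge support, so
#' re-normalizing is idempotent and the edge pattern is preserved.
#'
#' @param g a [zip_graph()].
#' @return The graph with normalized weights and `normalized = TRUE`.
#' @export
normalize_weights <- function(g) {
  W <- g$W
  sup <- g$support
  es <- sup[upper.tri(sup)]
  if (!any(es)) stop("graph has no edges to normalize")
  w <- W[upper.tri(W)][es]
  r <- range(w)
  ut <- upper.tri(W)
  vals <- W[ut]
  if (r[2] - r[1] <= 0) {
    vals[es] <- 1
  } else {
    vals[es] <- (vals[es] - r[1]) / (r[2] - r[1])
  }
  W[ut] <- vals
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  zip_graph(W, g$zips, g$kind, normalized = TRUE, support = sup)
}

#' Subset a graph to selected ZIP codes
#'
#' @param g a [zip_graph()].
#' @param zips ZIPs to keep (order preserved).
#' @return The induced subgraph.
#' @export
subset_graph <- function(g, zips) {
  idx <- match(zips, g$zips)
  assert_that(!anyNA(idx), "unknown ZIP in graph subset")
  zip_graph(g$W[idx, idx, drop = FALSE], g$zips[idx], g$kind, g$normalized,
            support = g$support[idx, idx, drop = FALSE])
}

#' Write / read a graph as an edge-list CSV plus JSON header
#'
#' @param g a [zip_graph()].
#' @param file CSV path; a `.json` sidecar is written next to it.
#' @return `write_graph()` the path invisibly; `read_graph()` the graph.
#' @export
write_graph <- function(g, file) {
  ut <- which(upper.tri(g$W) & g$support, arr.ind = TRUE)
  el <- data.frame(zip_i = g$zips[ut[, 1]], zip_j = g$zips[ut[, 2]],
                   w = g$W[ut])
  utils::write.csv(el, file, row.names = FALSE)
  jsonlite::write_json(list(zips = g$zips, kind = g$kind,
                            normalized = g$normalized),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_graph
#' @export
read_graph <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  el <- utils::read.csv(file, colClasses = c(zip_i = "character",
                                             zip_j = "character"))
  N <- length(meta$zips)
  W <- matrix(0, N, N)
  sup <- matrix(FALSE, N, N)
  i <- match(el$zip_i, meta$zips); j <- match(el$zip_j, meta$zips)
  W[cbind(i, j)] <- el$w; W[cbind(j, i)] <- el$w
  sup[cbind(i, j)] <- TRUE; sup[cbind(j, i)] <- TRUE
  zip_graph(W, meta$zips, meta$kind, meta$normalized, support = sup)
}

## igraph view of a zip_graph; edge attribute "weight" carries W
as_igraph <- function(g, invert_weights = FALSE) {
  W <- g$W
  if (invert_weights) W[W > 0] <- 1 / W[W > 0]
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  ig
}
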