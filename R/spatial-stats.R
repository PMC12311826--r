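#' Weighted Moran's I on a ZIP graph
#'
#' Global spatial autocorrelation of a node field over a weighted graph:
#' \deqn{I = \frac{N \sum_i \sum_j w_{ij} (h_i - \bar h)(h_j - \bar h)}
#'             {\sum_i \sum_j w_{ij} \cdot \sum_i (h_i - \bar h)^2}}
#' with \eqn{\bar h} the unweighted mean and a zero diagonal. Values near
#' 1 mean similar hesitancy clusters together on the graph, near -1 that
#' dissimilar values are adjacent, near 0 no autocorrelation.
#'
#' @param x numeric node field (e.g. one quarter's hesitancy).
#' @param graph a [zip_graph()].
#' @param row_standardize divide each row of `W` by its sum before
#'   computing the statistic. With heavy-tailed edge weights the raw
#'   statistic is dominated by a handful of edges; row standardisation
#'   (the common spatial-statistics convention) gives every node equal
#'   influence and a much more stable null distribution. Default `FALSE`
#'   (use the weights as given).
#' @return Scalar Moran's I in `[-1, 1]` (up to weight scaling).
#' @export
morans_i <- function(x, graph, row_standardize = FALSE) {
  N <- length(x)
  assert_that(N == length(graph$zips), "field length must match graph")
  W <- graph$W
  if (row_standardize) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, ] / rs[rs > 0]
    W <- (W + t(W)) / 2
  }
  sw <- sum(W)
  if (sw <= 0) stop("graph has no edges")
  d <- x - mean(x)
  ss <- sum(d^2)
  if (ss <= 0) stop("constant field: Moran's I undefined")
  as.numeric(N * (d %*% W %*% d) / (sw * ss))
}

#' Isolation index of a hesitant subpopulation
#'
#' The hesitant-population-weighted average exposure of hesitancy to
#' itself: \deqn{\sum_i \frac{h_i p_i}{\sum_j h_j p_j} h_i} where `p` is
#' the child population. Ranges from near 0 (no segregation: the hesitant
#' population is spread thinly everywhere) to the maximum of `h` (fully
#' concentrated). Invariant to rescaling `p`.
#'
#' @param h numeric hesitancy fractions per node.
#' @param p nonnegative populations per node.
#' @return Scalar isolation index.
#' @export
isolation_index <- function(h, p) {
  assert_that(length(h) == length(p), "h and p lengths differ")
  assert_that(all(p >= 0), "p must be nonnegative")
  tot <- sum(h * p)
  if (tot <= 0) stop("no hesitant population: isolation index undefined")
  sum((h * p / tot) * h)
}

## Poisson log-likelihood ratio of an excess-rate zone
scan_llr <- function(c, e, C) {
  ifelse(c > e & e > 0 & C > c,
         c * log(c / e) + (C - c) * log((C - c) / (C - e)),
         ifelse(c > e & C == c & e > 0, c * log(c / e), 0))
}

#' Poisson Kulldorff scan for high-hesitancy clusters on a graph
#'
#' Detects connected ZIP clusters whose refusal counts exceed their
#' population-based expectation. Case counts are `round(h * p)`; candidate
#' zones are grown around every seed node by repeatedly adding the
#' adjacent unvisited node nearest in hop count (ties to the lowest
#' index), up to `max_cluster_frac` of the total population — every
#' prefix of the growth order is a candidate zone. For a zone with `c`
#' cases and expectation `e = C * P_zone / P`, the log-likelihood ratio is
#' `c log(c/e) + (C - c) log((C - c)/(C - e))` when `c > e`, else 0.
#' Significance is by Monte-Carlo: cases are redistributed
#' multinomially with probabilities `p_i / P`, and
#' `p = (1 + #{max LLR_rep >= LLR_obs}) / (1 + n_mc)`.
#'
#' @param h hesitancy fractions per node.
#' @param p child populations per node.
#' @param graph a [zip_graph()] (typically the geographic adjacency
#'   graph).
#' @param max_cluster_frac maximum population share of a zone.
#' @param n_mc number of Monte-Carlo replicates (`>= 9`).
#' @param seed RNG seed for the replicates.
#' @return A list of class `scan_result_list`: non-overlapping clusters
#'   sorted by decreasing LLR, each with members, observed and expected
#'   counts, `llr`, and Monte-Carlo `p_value`.
#' @export
kulldorff_scan <- function(h, p, graph, max_cluster_frac = 0.5,
                           n_mc = 999, seed = 1) {
  N <- length(h)
  assert_that(N == length(graph$zips) && N == length(p),
              "h, p, graph sizes differ")
  if (n_mc < 9) stop("n_mc < 9 gives no p-value resolution")
  cases <- round(h * p)
  C <- sum(cases)
  if (C <= 0) stop("no cases: scan undefined")
  P <- sum(p)
  adj <- graph$W > 0

  ## hop-ordered neighbourhood growth around each seed; prefixes = zones
  zones <- list()
  seen <- new.env(hash = TRUE)
  for (s in seq_len(N)) {
    ord <- integer(0)
    dist <- rep(Inf, N); dist[s] <- 0
    frontier <- s
    popsum <- 0
    repeat {
      cand <- which(is.finite(dist) & !(seq_len(N) %in% ord))
      if (!length(cand)) break
      nxt <- cand[order(dist[cand], cand)][1]
      if (length(ord) && popsum + p[nxt] > max_cluster_frac * P) break
      ord <- c(ord, nxt)
      popsum <- popsum + p[nxt]
      newn <- which(adj[nxt, ] & !is.finite(dist))
      dist[newn] <- dist[nxt] + 1
      if (popsum > max_cluster_frac * P) break
    }
    for (k in seq_along(ord)) {
      key <- paste(sort(ord[seq_len(k)]), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        zones[[length(zones) + 1L]] <- ord[seq_len(k)]
      }
    }
  }
  Z <- matrix(FALSE, length(zones), N)
  for (i in seq_along(zones)) Z[i, zones[[i]]] <- TRUE
  zone_pop <- as.vector(Z %*% p)
  zone_e <- C * zone_pop / P
  zone_c <- as.vector(Z %*% cases)
  llr <- scan_llr(zone_c, zone_e, C)

  ## Monte-Carlo null: multinomial redistribution of C cases
  mc_max <- with_seed(seed, {
    reps <- stats::rmultinom(n_mc, C, p / P)
    cz <- Z %*% reps
    apply(scan_llr(cz, matrix(zone_e, nrow(Z), n_mc), C), 2, max)
  })

  ord <- order(-llr)
  taken <- rep(FALSE, N)
  out <- list()
  for (i in ord) {
    if (llr[i] <= 0) break
    mem <- zones[[i]]
    if (any(taken[mem])) next
    taken[mem] <- TRUE
    out[[length(out) + 1L]] <- structure(
      list(cluster = mem, zips = graph$zips[mem],
           observed = zone_c[i], expected = zone_e[i], llr = llr[i],
           p_value = (1 + sum(mc_max >= llr[i])) / (1 + n_mc)),
      class = "scan_result")
  }
  structure(out, class = "scan_result_list")
}

#' @export
print.scan_result_list <- function(x, ...) {
  cat(sprintf("Kulldorff scan: %d non-overlapping cluster(s) with LLR > 0\n",
              length(x)))
  for (i in seq_along(utils::head(x, 5))) {
    r <- x[[i]]
    cat(sprintf("  #%d: %d ZIPs, obs %g vs exp %.2f, LLR %.3f, p = %.3f\n",
                i, length(r$cluster), r$observed, r$expected, r$llr,
                r$p_value))
  }
  invisible(x)
}
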