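#' Configuration of the synthetic claims study
#'
#' Fixes the data-generating conditions emulated by the synthetic module:
#' a planar ZIP geography, a gravity-style contact network, and a
#' quarterly hesitancy panel with positive spatial autocorrelation over
#' the contact graph, a rising temporal trend, demographic covariate
#' dependence, and sparsity in small-population ZIPs. Defaults are the
#' package's reference study conditions (see the methods vignette for the
#' rationale behind each value).
#'
#' @param N number of ZIP codes (>= 5).
#' @param TS number of quarters (>= 4).
#' @param seed integer master seed; every stage derives from it.
#' @param rho spatial autocorrelation strength in `[0, 1)` of the latent
#'   logit-rate field over the row-normalized contact graph.
#' @param trend per-quarter drift of the latent logit rate (> 0 gives the
#'   rising hesitancy trend seen in claims panels).
#' @param beta named numeric vector of demographic effects on the latent
#'   logit rate, one per normalized feature column; `NULL` uses the
#'   package defaults.
#' @param noise_sd innovation s.d. of the latent field (logit scale).
#' @param base_rate baseline hesitant fraction in `(0, 1)`.
#' @param pop_lognormal `c(meanlog, sdlog)` of ZIP resident populations;
#'   the heavy tail produces the small-ZIP sparsity of real panels.
#' @param child_share share of residents who are children aged 0-6.
#' @param claim_prob probability a child generates any claim in a quarter.
#' @param contact_scale expected summed contact weight of the strongest
#'   ZIP pair (contact-hours).
#' @param cluster_spec optional `list(nodes =, multiplier =)` planting a
#'   contiguous high-rate cluster (rate multiplied by `multiplier`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(N = 100, TS = 12, seed = 1, rho = 0.6,
                       trend = 0.05, beta = NULL, noise_sd = 0.05,
                       base_rate = 0.1,
                       pop_lognormal = c(log(4000), 0.7),
                       child_share = 0.04, claim_prob = 0.5,
                       contact_scale = 200, cluster_spec = NULL) {
  assert_that(N >= 5, "N must be >= 5")
  assert_that(TS >= 4, "TS must be >= 4")
  assert_that(rho >= 0 && rho < 1, "rho must lie in [0, 1)")
  assert_that(base_rate > 0 && base_rate < 1, "base_rate must be in (0, 1)")
  if (is.null(beta)) beta <- default_beta()
  structure(list(N = N, TS = TS, seed = as.integer(seed), rho = rho,
                 trend = trend, beta = beta, noise_sd = noise_sd,
                 base_rate = base_rate, pop_lognormal = pop_lognormal,
                 child_share = child_share, claim_prob = claim_prob,
                 contact_scale = contact_scale,
                 cluster_spec = cluster_spec),
            class = "sim_config")
}

## demographic effects on the latent logit rate, per normalized feature
default_beta <- function() {
  c(gender.F = -2, gender.M = 2, gender.unknown = 0,
    race.black = -3, race.other = 2, race.white = 6,
    race.unknown = 0,
    hispanic.yes = -6, hispanic.no = 3, hispanic.unknown = 0,
    payer_lob.commercial = -5, payer_lob.medicaid = 7,
    payer_lob.medicare = 1, payer_lob.unknown = 0,
    total = -4)
}

sim_schema <- function() {
  feature_schema(gender = c("F", "M", "unknown"),
                 race = c("black", "other", "white", "unknown"),
                 hispanic = c("yes", "no", "unknown"),
                 payer_lob = c("commercial", "medicaid", "medicare",
                               "unknown"))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha, 1)
  g / sum(g)
}

#' Simulate a planar ZIP geography
#'
#' Draws `N` distinct centroids uniformly on the unit square and connects
#' boundary neighbours with the Gabriel rule (i and j are adjacent iff no
#' third centroid lies inside the circle with diameter ij). The Gabriel
#' graph contains the minimum spanning tree, so the adjacency structure is
#' always connected and every node has at least one neighbour.
#'
#' @param N number of ZIP codes.
#' @param seed RNG seed; a fixed seed reproduces the geometry exactly.
#' @return A [zip_geometry()] with zips `Z001..`, centroids, and
#'   adjacency pairs.
#' @export
simulate_geography <- function(N, seed = 1) {
  assert_that(N >= 5, "N must be >= 5")
  with_seed(seed, {
    xy <- cbind(stats::runif(N), stats::runif(N))
    zips <- sprintf("Z%03d", seq_len(N))
    D2 <- as.matrix(stats::dist(xy))^2
    keep_i <- integer(0); keep_j <- integer(0)
    for (i in seq_len(N - 1)) {
      ## Gabriel: (i, j) adjacent iff every other angle ikj is acute,
      ## i.e. min_k (d2[i,k] + d2[j,k]) > d2[i,j]
      sums <- D2[i, ] + D2[, (i + 1):N, drop = FALSE]
      sums[i, ] <- Inf
      for (jj in seq_len(ncol(sums))) sums[i + jj, jj] <- Inf
      ok <- apply(sums, 2, min) > D2[i, (i + 1):N]
      keep_i <- c(keep_i, rep(i, sum(ok)))
      keep_j <- c(keep_j, ((i + 1):N)[ok])
    }
    zip_geometry(zips, xy, cbind(zips[keep_i], zips[keep_j]))
  })
}

#' Simulate an individual-level contact edge list
#'
#' Gravity-style target contact weights between ZIP pairs,
#' `w_ij ~ pop_i * pop_j / dist_ij^2`, boosted within geographic
#' community blocks, are realized as person-level contact events: the
#' number of contacts per pair is Poisson with mean equal to the target
#' weight (scaled so the strongest pair expects `contact_scale` total
#' weight) and each contact carries a Gamma(4, 4) activity weight with
#' unit mean, so aggregation recovers the target weights up to sampling
#' error. Intra-ZIP contacts are also emitted (the aggregation step
#' discards them).
#'
#' @param geometry a [zip_geometry()].
#' @param populations named vector of ZIP resident populations.
#' @param config a [sim_config()].
#' @return List with `edges` (a person-level contact data frame) and
#'   `target_W` (the expected aggregated weight matrix).
#' @export
simulate_contact_network <- function(geometry, populations, config) {
  N <- length(geometry$zips)
  pop <- populations[geometry$zips]
  with_seed(config$seed + 1L, {
    D <- as.matrix(stats::dist(geometry$centroids))
    G <- outer(pop, pop) / pmax(D, 0.02)^2
    diag(G) <- 0
    km <- stats::kmeans(geometry$centroids, centers = min(4, N), nstart = 3)
    same_block <- outer(km$cluster, km$cluster, "==")
    G[same_block] <- G[same_block] * 2
    diag(G) <- 0
    lambda <- config$contact_scale * G / max(G)
    pu <- list(); pv <- list(); zu <- list(); zv <- list(); wt <- list()
    k <- 0L
    emit <- function(i, j, m) {
      k <<- k + 1L
      pu[[k]] <<- sprintf("%s-p%04d", geometry$zips[i],
                          sample.int(max(pop[i], 1), m, replace = TRUE))
      pv[[k]] <<- sprintf("%s-%s%04d", geometry$zips[j],
                          if (i == j) "q" else "p",
                          sample.int(max(pop[j], 1), m, replace = TRUE))
      zu[[k]] <<- rep(geometry$zips[i], m)
      zv[[k]] <<- rep(geometry$zips[j], m)
      wt[[k]] <<- stats::rgamma(m, shape = 4, rate = 4)
    }
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        if (lambda[i, j] < 0.05) next
        m <- stats::rpois(1, lambda[i, j])
        if (m > 0) emit(i, j, m)
      }
    }
    ## intra-ZIP contacts: present in person-level data, dropped on
    ## aggregation (no self-loops)
    for (i in seq_len(N)) {
      m <- stats::rpois(1, 5)
      if (m > 0) emit(i, i, m)
    }
    edges <- data.frame(person_u = unlist(pu), person_v = unlist(pv),
                        zip_u = unlist(zu), zip_v = unlist(zv),
                        weight = unlist(wt))
    list(edges = edges, target_W = lambda)
  })
}

#' Simulate a quarterly hesitancy panel with planted structure
#'
#' Generates the observed panel and the latent truth. The latent logit
#' rate follows a spatial autoregression over the row-normalized contact
#' graph:
#' `s(t) = rho * Wbar s(t-1) + (1 - rho) * u(t) + noise`, where `u` is
#' the centred demographic signal `beta . x~(t)` computed from the same
#' min-max-normalized features the learners consume, and the full rate is
#' `h* = plogis(qlogis(base_rate) + trend * t + s(t))` (times any planted
#' cluster multiplier). Observed refusal counts are Binomial(p, h*), so
#' small-population ZIPs are noisy and zero-claim cells are masked.
#'
#' @param geometry a [zip_geometry()].
#' @param graph the normalized contact [zip_graph()] the field diffuses
#'   over.
#' @param config a [sim_config()].
#' @param populations named resident populations; drawn from
#'   `config$pop_lognormal` when `NULL`.
#' @return List with `panel` (raw counts [node_panel()]) and `truth`
#'   (latent rates `h_latent`, field `s`, refusal counts, shares,
#'   populations, child counts).
#' @export
simulate_panel <- function(geometry, graph, config, populations = NULL) {
  N <- length(geometry$zips); TS <- config$TS
  schema <- sim_schema()
  fnames <- schema_feature_names(schema)
  X <- length(fnames)
  assert_that(length(config$beta) == X,
              sprintf("beta must have %d elements (one per feature)", X))
  with_seed(config$seed + 2L, {
    if (is.null(populations)) {
      populations <- stats::setNames(
        round(stats::rlnorm(N, config$pop_lognormal[1],
                            config$pop_lognormal[2])), geometry$zips)
    }
    pop <- populations[geometry$zips]
    n_child <- pmax(1L, round(config$child_share * pop))

    ## row-normalized diffusion operator of the contact graph
    Wb <- graph$W
    rs <- rowSums(Wb)
    Wb[rs > 0, ] <- Wb[rs > 0, ] / rs[rs > 0]

    ## Demographic composition is spatially autocorrelated, as in real
    ## ZIP panels, and drifts from quarter to quarter (in-migration,
    ## payer churn): each field's Dirichlet concentration is tilted by a
    ## smoothed Gaussian surface over the contact graph that follows an
    ## AR(1) in time. The drift keeps current features informative about
    ## current hesitancy in a way stale histories are not.
    smooth_field <- function() {
      z <- stats::rnorm(N)
      for (k in 1:3) z <- 0.5 * z + 0.5 * as.vector(Wb %*% z)
      as.vector(scale(z))
    }
    phi <- 0.9  # temporal persistence of the demographic surfaces
    alpha <- list(gender = c(30, 30, 1), race = c(4, 3, 12, 1),
                  hispanic = c(2, 16, 2),
                  payer_lob = c(10, 8, 3, 0.2))
    tilt <- list(gender = c(0, 0, 0), race = c(-0.5, 0, 0.65, 0),
                 hispanic = c(0.7, -0.25, 0),
                 payer_lob = c(-0.55, 0.7, 0, 0))
    zfield <- lapply(names(alpha), function(f) {
      z <- matrix(0, N, TS)
      z[, 1] <- smooth_field()
      for (t in 2:TS)
        z[, t] <- phi * z[, t - 1] + sqrt(1 - phi^2) * smooth_field()
      z
    })
    names(zfield) <- names(alpha)
    shares_at <- function(f, t)
      t(vapply(seq_len(N),
               function(i) rdirichlet1(alpha[[f]] *
                                         exp(zfield[[f]][i, t] * tilt[[f]])),
               numeric(length(alpha[[f]]))))
    p <- matrix(0L, N, TS)
    nc <- array(0, c(N, X, TS))
    shares <- vector("list", TS)
    for (t in seq_len(TS)) {
      ## panel participation fluctuates by ZIP and quarter (claims
      ## capture is uneven), so quarterly denominators are heteroscedastic
      q_it <- stats::rbeta(N, 2, 2 * (1 - config$claim_prob) /
                                config$claim_prob)
      p[, t] <- stats::rbinom(N, n_child, q_it)
      col <- 0L
      sh_t <- list()
      for (f in names(schema$fields)) {
        k <- length(schema$fields[[f]])
        sh <- shares_at(f, t)
        sh_t[[f]] <- sh
        for (i in seq_len(N))
          nc[i, col + seq_len(k), t] <- stats::rmultinom(1, p[i, t],
                                                         sh[i, ])
        col <- col + k
      }
      shares[[t]] <- sh_t
      nc[, X, t] <- p[, t]
    }
    quarters <- sprintf("%dQ%d", 2016 + (seq_len(TS) - 1) %/% 4,
                        (seq_len(TS) - 1) %% 4 + 1)
    raw <- node_panel(geometry$zips, quarters, nc,
                      matrix(0, N, TS), p, fnames)
    xt <- normalize_features(raw)$nc

    s <- matrix(0, N, TS)
    z <- matrix(0, N, TS)
    prev <- rep(0, N)
    mult <- rep(1, N)
    if (!is.null(config$cluster_spec))
      mult[config$cluster_spec$nodes] <- config$cluster_spec$multiplier
    ## hesitancy persists locally and spreads partially to contacts:
    ## the autoregressive carry-over keeps share gamma on neighbours and
    ## 1 - gamma on the node itself
    gam <- 0.4
    for (t in seq_len(TS)) {
      u <- as.vector(xt[, , t] %*% config$beta)
      u <- u - mean(u)
      ## cap the per-node demographic effect at +-7 logit: bounds the
      ## stationary field away from the divergence guard for any seed
      ## while leaving all but the most extreme node-quarters untouched
      u <- pmax(pmin(u, 7), -7)
      carry <- (1 - gam) * prev + gam * as.vector(Wb %*% prev)
      prev <- config$rho * carry + (1 - config$rho) * u +
        stats::rnorm(N, 0, config$noise_sd)
      s[, t] <- prev
      z[, t] <- stats::qlogis(config$base_rate) + config$trend * t + prev
    }
    if (any(abs(z) > 10))
      stop("latent field diverged (|logit| > 10): reduce rho or trend")
    h_latent <- pmin(stats::plogis(z) * mult, 0.99)
    refusals <- matrix(stats::rbinom(N * TS, p, h_latent), N, TS)
    h_obs <- ifelse(p > 0, refusals / pmax(p, 1L), 0)

    panel <- node_panel(geometry$zips, quarters, nc, h_obs, p, fnames)
    if (config$rho >= 0.4 && N >= 20) {
      mi <- morans_i(h_latent[, TS], graph)
      if (mi <= 0)
        warning(sprintf("generated field has nonpositive Moran's I (%.3f)",
                        mi))
    }
    list(panel = panel,
         truth = list(h_latent = h_latent, s = s, refusals = refusals,
                      shares = shares, populations = populations,
                      n_child = n_child))
  })
}

#' Emit per-child claim records reproducing a synthetic panel
#'
#' Writes one block of claims per ZIP-quarter cell: `p` unique children,
#' each with 1-4 claims dated inside the quarter, demographic categories
#' assigned to match the panel's per-category counts exactly, and one
#' Z28-family-coded claim for each refusing child — so running the claims
#' pipeline ([filter_child_claims()], [aggregate_quarterly()]) on the
#' output reproduces the panel's `p` and `h` exactly.
#'
#' @param panel the raw counts panel from [simulate_panel()].
#' @param truth the matching truth list (for refusal counts).
#' @param seed RNG seed.
#' @return Claims data frame with the canonical record fields.
#' @export
simulate_claims <- function(panel, truth, seed = 1) {
  schema <- sim_schema()
  N <- length(panel$zips); TS <- length(panel$quarters)
  z28 <- c("Z28.20", "Z28.21", "Z28.82", "Z28.3", "z28.01")
  benign <- c("Z00.129", "J06.9", "R05", "Z23")
  with_seed(seed, {
    blocks <- list()
    for (i in seq_len(N)) for (t in seq_len(TS)) {
      pit <- panel$p[i, t]
      if (pit == 0) next
      q <- panel$quarters[t]
      y <- as.integer(substr(q, 1, 4)); qq <- as.integer(substr(q, 6, 6))
      day0 <- as.Date(sprintf("%d-%02d-01", y, (qq - 1) * 3 + 1))
      day1 <- seq(day0, by = "3 months", length.out = 2)[2] - 1
      kids <- sprintf("%s-%s-c%04d", panel$zips[i], q, seq_len(pit))
      demo <- lapply(names(schema$fields), function(f) {
        lev <- schema$fields[[f]]
        cnt <- panel$nc[i, paste(f, lev, sep = "."), t]
        sample(rep(lev, times = cnt))
      })
      names(demo) <- names(schema$fields)
      refusing <- seq_len(pit) <= truth$refusals[i, t]
      nclaims <- sample(1:4, pit, replace = TRUE)
      idx <- rep(seq_len(pit), times = nclaims)
      dx <- sample(benign, length(idx), replace = TRUE)
      ## exactly one refusal-coded claim per refusing child
      firsts <- match(which(refusing), idx)
      dx[firsts] <- sample(z28, sum(refusing), replace = TRUE)
      blocks[[length(blocks) + 1L]] <- data.frame(
        person_key = kids[idx],
        incurred_date = as.character(
          day0 + sample.int(as.integer(day1 - day0) + 1L, length(idx),
                            replace = TRUE) - 1L),
        zip = panel$zips[i],
        age_years = sample(0:6, length(idx), replace = TRUE),
        gender = demo$gender[idx], race = demo$race[idx],
        hispanic = demo$hispanic[idx],
        payer_lob = demo$payer_lob[idx],
        dx_code = dx)
    }
    do.call(rbind, blocks)
  })
}

#' Run the full synthetic study pipeline
#'
#' Geography, populations, contact network, normalized contact and
#' adjacency graphs, and the quarterly panel, all derived from one seeded
#' configuration.
#'
#' @param config a [sim_config()].
#' @param include_claims also emit the per-child claims records (only
#'   sensible at small N).
#' @return List with `geometry`, `populations`, `edges`, `graph`
#'   (normalized contact graph), `adjacency` (normalized boundary graph),
#'   `distance` (normalized inverse-distance graph), `panel` (raw),
#'   `truth`, and optionally `claims`.
#' @export
simulate_study <- function(config = sim_config(), include_claims = FALSE) {
  geom <- simulate_geography(config$N, seed = config$seed)
  populations <- with_seed(config$seed + 9L, stats::setNames(
    round(stats::rlnorm(config$N, config$pop_lognormal[1],
                        config$pop_lognormal[2])), geom$zips))
  net <- simulate_contact_network(geom, populations, config)
  graph <- normalize_weights(contact_graph(net$edges, geom$zips))
  adjacency <- normalize_weights(adjacency_graph(geom))
  distance <- normalize_weights(distance_graph(geom))
  sim <- simulate_panel(geom, graph, config, populations)
  out <- list(geometry = geom, populations = populations,
              edges = net$edges, target_W = net$target_W, graph = graph,
              adjacency = adjacency, distance = distance,
              panel = sim$panel, truth = sim$truth, config = config)
  if (include_claims)
    out$claims <- simulate_claims(sim$panel, sim$truth,
                                  seed = config$seed + 3L)
  out
}
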