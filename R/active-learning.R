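#' Select an initial labeled node set
#'
#' Three initialization strategies for budgeted label collection:
#' \describe{
#'   \item{`random`}{uniform sample without replacement.}
#'   \item{`scattered`}{greedy max-min spread: starting from `start`
#'     (default a seeded random node), repeatedly add the node whose
#'     minimum weighted-shortest-path distance to the selected set is
#'     largest. Edge lengths are `1 / w`, so strong contacts are "close";
#'     unreachable nodes sit at distance `Inf` and are picked first.}
#'   \item{`closer`}{start from `start` and repeatedly add the unselected
#'     node with the heaviest edge into the current set, growing one
#'     tightly connected patch of the graph.}
#' }
#' Ties are broken by lowest node index for determinism.
#'
#' @param graph a [zip_graph()].
#' @param n number of nodes to select (`<= N`).
#' @param strategy one of `"random"`, `"scattered"`, `"closer"`.
#' @param seed RNG seed (random draw / default start node).
#' @param start optional start node (index or ZIP name) for the
#'   `scattered` and `closer` strategies.
#' @return Sorted integer vector of selected node indices.
#' @export
select_initial <- function(graph, n,
                           strategy = c("random", "scattered", "closer"),
                           seed = 1, start = NULL) {
  strategy <- match.arg(strategy)
  N <- length(graph$zips)
  if (n > N) stopf("cannot select %d of %d nodes", n, N)
  if (is.character(start)) start <- match(start, graph$zips)
  if (strategy == "random")
    return(with_seed(seed, sort(sample.int(N, n))))
  start <- start %||% with_seed(seed, sample.int(N, 1))
  if (strategy == "scattered") {
    ig <- as_igraph(graph, invert_weights = TRUE)
    D <- igraph::distances(ig, weights = igraph::E(ig)$weight)
    sel <- start
    while (length(sel) < n) {
      dmin <- apply(D[, sel, drop = FALSE], 1, min)
      dmin[sel] <- -Inf
      sel <- c(sel, unname(which.max(dmin)))  # first (lowest) index wins ties
    }
    return(as.integer(sort(sel)))
  }
  ## closer: grow by heaviest edge into the selected set
  sel <- start
  while (length(sel) < n) {
    wmax <- apply(graph$W[, sel, drop = FALSE], 1, max)
    wmax[sel] <- -Inf
    sel <- c(sel, unname(which.max(wmax)))
  }
  as.integer(sort(sel))
}

#' Output-space distance score of a candidate node
#'
#' The query score of the active-learning loop: the Euclidean norm of the
#' candidate's predicted hesitancy minus the vector of training-set labels
#' at the target quarter, `D = || (yhat_x - h_k)_{k in K'} ||`. A
#' candidate predicted far from the bulk of observed labels is the most
#' diverse addition to the training set.
#'
#' @param pred scalar predicted hesitancy for the candidate.
#' @param labels numeric vector of current training-set labels.
#' @return Nonnegative scalar distance.
#' @export
al_distance <- function(pred, labels) {
  assert_that(length(pred) == 1, "pred must be a scalar")
  sqrt(sum((pred - labels)^2))
}

#' Score one candidate node with a fitted model
#'
#' Convenience wrapper around [al_distance()]: forecasts the candidate's
#' target-quarter hesitancy with the fitted model and measures its
#' distance from the training labels. Errors if the candidate is already
#' labeled.
#'
#' @param fit a fitted [vaxstl()] model.
#' @param candidate node index or ZIP name.
#' @return Scalar distance score.
#' @export
al_score <- function(fit, candidate) {
  panel <- fit$panel
  if (is.character(candidate)) candidate <- match(candidate, panel$zips)
  if (candidate %in% fit$split$K)
    stop("candidate is already in the labeled set")
  target <- fit$T_train + fit$control$horizon
  pred <- predict(fit, nodes = candidate)[, fit$control$horizon]
  al_distance(pred, panel$h[fit$split$K, target])
}

#' Budgeted active-learning selection of training ZIP codes
#'
#' Starting from an initial labeled set, repeats `budget` times: retrain
#' the spatio-temporal learner on the current set, forecast the target
#' quarter for every unlabeled node, score each candidate by
#' [al_distance()] against the current labels, and add the arg-max
#' (ties to the lowest node index). The panel must carry labels for any
#' node the loop may query (the simulated-oracle setting).
#'
#' @param panel a normalized [node_panel()].
#' @param graph a weight-normalized [zip_graph()].
#' @param initial_size size of the seed labeled set.
#' @param budget number of additional nodes to query (`B >= 0`).
#' @param init_strategy initial-selection strategy, see [select_initial()].
#' @param control a [vaxstl_control()]; use a reduced `epochs` here
#'   (the model is retrained from scratch at every iteration).
#' @param seed RNG seed (initial selection and every retrain).
#' @param initial_K explicit initial set, overriding
#'   `initial_size`/`init_strategy`.
#' @return List with `K` (final sorted labeled set, size
#'   `initial_size + budget`), `initial_K`, and `trace` (one row per
#'   iteration: selected node and its score).
#' @export
active_learn <- function(panel, graph, initial_size, budget,
                         init_strategy = "random",
                         control = vaxstl_control(), seed = 1,
                         initial_K = NULL) {
  N <- length(panel$zips)
  K0 <- initial_K %||% select_initial(graph, initial_size, init_strategy,
                                      seed = seed)
  K0 <- sort(as.integer(K0))
  if (budget > N - length(K0))
    stopf("budget %d exceeds the %d unlabeled nodes", budget,
          N - length(K0))
  Kp <- K0
  target <- (control$T_train %||%
               (length(panel$quarters) - control$horizon)) + control$horizon
  trace <- data.frame(iter = integer(), node = integer(), zip = character(),
                      score = numeric())
  b <- 0L
  while (b < budget) {
    b <- b + 1L
    split <- train_split(panel, K = Kp)
    fit <- vaxstl(panel, graph, split, control, seed = seed)
    cand <- setdiff(seq_len(N), Kp)
    preds <- predict(fit, nodes = cand)[, control$horizon]
    labels <- panel$h[Kp, target]
    scores <- vapply(preds, al_distance, numeric(1), labels = labels)
    assert_that(all(is.finite(scores)), "non-finite active-learning score")
    pick <- cand[which.max(scores)]  # first max = lowest index on ties
    trace <- rbind(trace, data.frame(iter = b, node = pick,
                                     zip = panel$zips[pick],
                                     score = max(scores)))
    Kp <- sort(c(Kp, pick))
  }
  list(K = Kp, initial_K = K0, trace = trace)
}
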