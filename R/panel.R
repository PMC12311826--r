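#' Construct a node panel
#'
#' A `node_panel` holds the per-ZIP, per-quarter data consumed by every
#' learner in the package: a feature array `nc` (N zips x X features x TS
#' quarters), the hesitancy matrix `h` (fraction of unique children in the
#' ZIP-quarter with at least one vaccine-refusal claim), the unique-children
#' count matrix `p`, and a logical `mask` marking cells with observed data
#' (`p > 0`). Cells with `p = 0` carry `h = 0` and `mask = FALSE`; masked-out
#' cells are excluded from all losses and metrics.
#'
#' @param zips character vector of N ZIP identifiers (no duplicates).
#' @param quarters character vector of TS quarter labels, e.g. `"2019Q2"`.
#' @param nc numeric array `[N, X, TS]` of features.
#' @param h numeric matrix `[N, TS]`, hesitant fraction in `[0, 1]`.
#' @param p integer matrix `[N, TS]`, unique children counts.
#' @param feature_names character vector of length X.
#' @param mask logical matrix `[N, TS]`; defaults to `p > 0`.
#' @param normalized logical; `TRUE` once [normalize_features()] has run.
#' @return An object of class `node_panel`.
#' @seealso [aggregate_quarterly()], [normalize_features()], [simulate_panel()]
#' @export
node_panel <- function(zips, quarters, nc, h, p, feature_names,
                       mask = NULL, normalized = FALSE) {
  zips <- as.character(zips)
  assert_that(!anyDuplicated(zips), "duplicated ZIP identifiers")
  N <- length(zips); TS <- length(quarters)
  assert_that(all(dim(nc) == c(N, length(feature_names), TS)),
              "nc dimensions must be [N, X, TS]")
  assert_that(all(dim(h) == c(N, TS)), "h must be [N, TS]")
  assert_that(all(dim(p) == c(N, TS)), "p must be [N, TS]")
  assert_that(all(h >= 0 & h <= 1), "h must lie in [0, 1]")
  assert_that(all(p >= 0), "p must be nonnegative")
  if (is.null(mask)) mask <- p > 0
  dimnames(nc) <- list(zips, feature_names, quarters)
  dimnames(h) <- dimnames(p) <- dimnames(mask) <- list(zips, quarters)
  structure(list(zips = zips, quarters = as.character(quarters),
                 nc = nc, h = h, p = p, mask = mask,
                 feature_names = as.character(feature_names),
                 normalized = isTRUE(normalized)),
            class = "node_panel")
}

#' @export
print.node_panel <- function(x, ...) {
  cat(sprintf("node_panel: %d ZIPs x %d quarters, %d features%s\n",
              length(x$zips), length(x$quarters), length(x$feature_names),
              if (x$normalized) " (normalized)" else ""))
  cat(sprintf("  quarters  %s .. %s\n", x$quarters[1], tail(x$quarters, 1)))
  cat(sprintf("  h in [%.3f, %.3f], mean %.3f over %d observed cells\n",
              min(x$h[x$mask]), max(x$h[x$mask]), mean(x$h[x$mask]),
              sum(x$mask)))
  invisible(x)
}

#' @export
dim.node_panel <- function(x) {
  c(N = length(x$zips), X = length(x$feature_names), TS = length(x$quarters))
}

#' Subset a panel to selected ZIP codes
#'
#' @param panel a [node_panel()].
#' @param zips character vector of ZIPs to keep (order preserved).
#' @return The subset panel.
#' @export
subset_panel <- function(panel, zips) {
  idx <- match(zips, panel$zips)
  assert_that(!anyNA(idx), "unknown ZIP in subset")
  node_panel(panel$zips[idx], panel$quarters,
             panel$nc[idx, , , drop = FALSE],
             panel$h[idx, , drop = FALSE], panel$p[idx, , drop = FALSE],
             panel$feature_names, panel$mask[idx, , drop = FALSE],
             panel$normalized)
}

#' Drop small-population ZIP codes from a panel
#'
#' Retains ZIP codes whose resident population is strictly greater than
#' `min_pop` (default 1000), the usual claims-panel filter that removes
#' ZIPs too small for stable quarterly rates. Graph consumers must subset
#' their graphs to the same ZIP set (see [subset_graph()]).
#'
#' @param panel a [node_panel()].
#' @param populations named numeric vector, ZIP -> resident population.
#'   Every panel ZIP must be present.
#' @param min_pop population threshold; keep ZIPs with population `> min_pop`.
#' @return The filtered panel.
#' @export
filter_zip_population <- function(panel, populations, min_pop = 1000) {
  pop <- populations[panel$zips]
  missing <- panel$zips[is.na(pop)]
  if (length(missing))
    stopf("missing population for ZIP(s): %s",
          paste(utils::head(missing, 5), collapse = ", "))
  keep <- panel$zips[pop > min_pop]
  assert_that(length(keep) > 0, "no ZIP exceeds the population threshold")
  subset_panel(panel, keep)
}

#' Min-max normalize panel features per quarter
#'
#' Each feature column is mapped to `[0, 1]` by min-max normalization
#' computed *across ZIPs within each quarter*; columns that are constant in
#' a quarter map to 0. The hesitancy target `h` is a fraction already in
#' `[0, 1]` and is left untouched by default; `normalize_h = TRUE` applies
#' the same per-quarter min-max to `h` as well.
#'
#' @param panel a raw [node_panel()].
#' @param normalize_h also min-max normalize the target `h` per quarter.
#' @return The normalized panel, with per-quarter constants stored in
#'   `attr(, "norm_constants")`.
#' @export
normalize_features <- function(panel, normalize_h = FALSE) {
  nc <- panel$nc
  d <- dim(nc)
  cons <- array(NA_real_, c(d[2], 2, d[3]),
                dimnames = list(panel$feature_names, c("min", "max"),
                                panel$quarters))
  for (t in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      x <- nc[, j, t]
      cons[j, , t] <- range(x)
      nc[, j, t] <- minmax01(x)
    }
  }
  h <- panel$h
  if (normalize_h) for (t in seq_len(d[3])) h[, t] <- minmax01(h[, t])
  out <- node_panel(panel$zips, panel$quarters, nc, h, panel$p,
                    panel$feature_names, panel$mask, normalized = TRUE)
  attr(out, "norm_constants") <- cons
  out
}

#' Replace panel features by principal-component scores
#'
#' Fits a PCA pooled over all ZIP-quarter rows of the (normalized) feature
#' array and replaces the X feature columns by the first `n_components`
#' scores at every quarter. Off by default in the modelling pipeline; the
#' explained-variance ratios are attached as an attribute and messaged.
#'
#' @param panel a normalized [node_panel()].
#' @param n_components number of components to keep (`<= X`).
#' @return Panel with `n_components` features named `PC1..`; explained
#'   variance ratios in `attr(, "explained_variance")`.
#' @export
pca_features <- function(panel, n_components) {
  X <- length(panel$feature_names)
  if (n_components > X) stopf("n_components (%d) exceeds X (%d)", n_components, X)
  d <- dim(panel$nc)
  flat <- matrix(aperm(panel$nc, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  nc2 <- aperm(array(scores, c(d[1], d[3], n_components)), c(1, 3, 2))
  out <- node_panel(panel$zips, panel$quarters, nc2, panel$h, panel$p,
                    paste0("PC", seq_len(n_components)), panel$mask,
                    panel$normalized)
  attr(out, "explained_variance") <- evr[seq_len(n_components)]
  message(sprintf("PCA: %d components explain %.1f%% of variance",
                  n_components, 100 * sum(evr[seq_len(n_components)])))
  out
}

#' Write / read a node panel as plain-text files
#'
#' `write_panel()` serializes a panel into a directory: long-format
#' `features.csv` (zip, quarter, feature, value), wide `h.csv` / `p.csv` /
#' `mask.csv`, and a `panel.json` sidecar with ordering and normalization
#' state. `read_panel()` inverts it.
#'
#' @param panel a [node_panel()].
#' @param dir directory to create/use.
#' @return `write_panel()` the directory invisibly; `read_panel()` the panel.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(panel$nc)
  long <- data.frame(
    zip = rep(panel$zips, times = d[2] * d[3]),
    quarter = rep(panel$quarters, each = d[1] * d[2]),
    feature = rep(rep(panel$feature_names, each = d[1]), times = d[3]),
    value = as.vector(panel$nc))
  utils::write.csv(long, file.path(dir, "features.csv"), row.names = FALSE)
  wide <- function(m) data.frame(zip = panel$zips, m, check.names = FALSE)
  utils::write.csv(wide(panel$h), file.path(dir, "h.csv"), row.names = FALSE)
  utils::write.csv(wide(panel$p), file.path(dir, "p.csv"), row.names = FALSE)
  utils::write.csv(wide(panel$mask * 1L), file.path(dir, "mask.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(zips = panel$zips, quarters = panel$quarters,
         feature_names = panel$feature_names, normalized = panel$normalized),
    file.path(dir, "panel.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "panel.json"), simplifyVector = TRUE)
  long <- utils::read.csv(file.path(dir, "features.csv"),
                          colClasses = c(zip = "character"))
  N <- length(meta$zips); X <- length(meta$feature_names)
  TS <- length(meta$quarters)
  nc <- array(NA_real_, c(N, X, TS))
  i <- match(long$zip, meta$zips)
  j <- match(long$feature, meta$feature_names)
  t <- match(long$quarter, meta$quarters)
  nc[cbind(i, j, t)] <- long$value
  readw <- function(f) {
    m <- utils::read.csv(file.path(dir, f), check.names = FALSE,
                         colClasses = c(zip = "character"))
    as.matrix(m[match(meta$zips, m$zip), meta$quarters, drop = FALSE])
  }
  node_panel(meta$zips, meta$quarters, nc, readw("h.csv"), readw("p.csv"),
             meta$feature_names, readw("mask.csv") > 0, meta$normalized)
}
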