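#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## min-max map of a vector; constant vectors map to `constant_to`.
minmax01 <- function(x, constant_to = 0) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(constant_to, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

quarter_label <- function(dates) {
  dates <- as.Date(dates)
  sprintf("%dQ%d", as.integer(format(dates, "%Y")),
          (as.integer(format(dates, "%m")) - 1L) %/% 3L + 1L)
}

## all quarter labels from first to last, inclusive
quarter_seq <- function(from, to) {
  yq <- function(s) {
    y <- as.integer(substr(s, 1, 4)); q <- as.integer(substr(s, 6, 6))
    y * 4L + (q - 1L)
  }
  idx <- seq(yq(from), yq(to))
  sprintf("%dQ%d", idx %/% 4L, idx %% 4L + 1L)
}

config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
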