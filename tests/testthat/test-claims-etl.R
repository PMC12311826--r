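test_that("child filter keeps ages at or below the ceiling, inclusively", {
  cl <- make_claims(c("a", "b", "c"), "2019-01-15", "Z001", c(3L, 6L, 7L),
                    dx = "Z00.129")
  expect_equal(filter_child_claims(cl)$person_key, c("a", "b"))
  expect_equal(nrow(filter_child_claims(cl[0, ])), 0)

  ## brute-force per-record oracle on random ages
  set.seed(42)
  cl2 <- make_claims(sprintf("p%03d", 1:100), "2020-05-01", "Z001",
                     sample(0:12, 100, replace = TRUE), dx = "Z00.129")
  keep <- filter_child_claims(cl2, max_age = 6)
  oracle <- cl2[vapply(seq_len(100),
                       function(i) cl2$age_years[i] <= 6, logical(1)), ]
  expect_identical(keep, oracle)
})

test_that("refusal flag fires on any Z28 subcode and on explicit flags", {
  cl <- make_claims(c("a", "b"), "2019-01-15", "Z001", 2L,
                    dx = c("Z28.82", "J45.909"))
  expect_identical(flag_refusal(cl), c(TRUE, FALSE))

  codes <- c("Z28.20", "z28.01", "Z28", "Z28.3", "Z2", "Z29.1", "A00",
             "J06.9", "Z00.129", " Z28.21", "z27.9", "Z280", "B20",
             "Z28.9", "R05", "Z23", "z28.82", "E11.9", "Z28.39", "I10")
  cl2 <- make_claims(sprintf("p%02d", seq_along(codes)), "2019-01-15",
                     "Z001", 2L, dx = codes)
  oracle <- grepl("^Z28", toupper(trimws(codes)))
  expect_identical(flag_refusal(cl2), oracle)

  ## explicit flag column alone also works
  cl3 <- data.frame(person_key = "a", incurred_date = "2019-01-15",
                    zip = "Z001", age_years = 1L, refusal = TRUE)
  expect_true(flag_refusal(cl3))
  cl3$refusal <- NULL
  expect_error(flag_refusal(cl3), "neither")
})

test_that("quarterly aggregation counts unique children, not claims", {
  ## 3 claims for 2 children; one child refuses once
  cl <- make_claims(c("kid1", "kid1", "kid2"),
                    c("2019-02-01", "2019-03-01", "2019-02-10"), "Z001",
                    c(2L, 2L, 4L), dx = c("Z00.129", "Z28.21", "Z00.129"))
  pan <- aggregate_quarterly(cl)
  expect_equal(unname(pan$p[1, 1]), 2L)
  expect_equal(unname(pan$h[1, 1]), 0.5)

  ## a child with two refusal claims is still one refuser
  cl2 <- make_claims(c("kid1", "kid1", "kid2"), "2019-02-01", "Z001", 2L,
                     dx = c("Z28.21", "Z28.82", "Z00.129"))
  expect_equal(unname(aggregate_quarterly(cl2)$h[1, 1]), 0.5)

  expect_error(aggregate_quarterly(cl, zips_keep = "Z999"), "no claims")
})

test_that("aggregation matches an independent group-by oracle", {
  set.seed(7)
  n <- 500
  ids <- sprintf("p%03d", sample(80, n, replace = TRUE))
  ## demographics are a property of the child, not the claim
  gender_of <- stats::setNames(sample(c("f", "m"), 80, replace = TRUE),
                               sprintf("p%03d", 1:80))
  cl <- make_claims(ids,
                    sample(seq(as.Date("2019-01-01"), as.Date("2019-12-31"),
                               by = "day"), n, replace = TRUE),
                    sample(c("Z001", "Z002", "Z003"), n, replace = TRUE),
                    sample(0:6, n, replace = TRUE),
                    dx = sample(c("Z28.21", "Z00.129", "J06.9"), n,
                                replace = TRUE, prob = c(0.15, 0.6, 0.25)),
                    gender = gender_of[ids])
  pan <- aggregate_quarterly(cl)

  ## oracle: nested split by zip/quarter, unique persons
  q <- sprintf("2019Q%d", (as.integer(format(as.Date(cl$incurred_date),
                                             "%m")) - 1) %/% 3 + 1)
  for (z in pan$zips) for (qq in pan$quarters) {
    sub <- cl[cl$zip == z & q == qq, ]
    expect_equal(unname(pan$p[z, qq]), length(unique(sub$person_key)))
    ref <- unique(sub$person_key[grepl("^Z28", sub$dx_code)])
    hexp <- if (nrow(sub)) length(ref) / length(unique(sub$person_key)) else 0
    expect_equal(unname(pan$h[z, qq]), hexp)
    fexp <- length(unique(sub$person_key[sub$gender == "f"]))
    expect_equal(unname(pan$nc[z, "gender.f", qq]), fexp)
  }

  ## permutation invariance of record order
  perm <- sample(n)
  pan2 <- aggregate_quarterly(cl[perm, ])
  expect_equal(pan2$p, pan$p)
  expect_equal(pan2$h, pan$h)
  expect_equal(pan2$nc, pan$nc)
})

test_that("population filter keeps ZIPs strictly above the threshold", {
  pan <- tiny_panel(N = 4)
  pops <- c(Z001 = 5000, Z002 = 900, Z003 = 1000, Z004 = 1001)
  kept <- filter_zip_population(pan, pops)
  expect_identical(kept$zips, c("Z001", "Z004"))  # 1000 is not > 1000

  expect_identical(filter_zip_population(pan, pops, min_pop = 0)$zips,
                   pan$zips)
  expect_error(filter_zip_population(pan, pops[-2]), "missing population")

  set.seed(11)
  rpops <- stats::setNames(sample(500:2000, 4), pan$zips)
  oracle <- pan$zips[vapply(pan$zips, function(z) rpops[z] > 1000,
                            logical(1))]
  expect_identical(filter_zip_population(pan, rpops)$zips, oracle)
})

test_that("per-quarter min-max normalization and its degenerate cases", {
  N <- 3
  nc <- array(0, c(N, 2, 1))
  nc[, 1, 1] <- c(2, 4, 6)
  nc[, 2, 1] <- c(5, 5, 5)
  pan <- node_panel(c("A", "B", "C"), "2019Q1", nc,
                    matrix(0.1, N, 1), matrix(10L, N, 1), c("x", "y"))
  z <- normalize_features(pan)
  expect_equal(unname(z$nc[, 1, 1]), c(0, 0.5, 1))
  expect_equal(unname(z$nc[, 2, 1]), c(0, 0, 0))  # constant column
  expect_true(z$normalized)

  ## idempotent on columns already spanning [0, 1]
  z2 <- normalize_features(z)
  expect_equal(z2$nc, z$nc)
})

test_that("PCA feature replacement agrees with an eigendecomposition oracle", {
  pan <- tiny_panel(N = 8, X = 4, TS = 3)
  ## full basis: reconstruction error 0
  full <- suppressMessages(pca_features(pan, 4))
  expect_equal(sum(attr(full, "explained_variance")), 1)

  ## rank-1 features: first component explains everything
  r1 <- pan
  base <- matrix(seq_len(8), 8, 1) %*% matrix(c(1, 2, 3, 4), 1, 4)
  for (t in 1:3) r1$nc[, , t] <- base * t
  p1 <- suppressMessages(pca_features(r1, 1))
  expect_equal(attr(p1, "explained_variance")[1], 1)

  ## scores match eigendecomposition of the pooled covariance
  d <- dim(pan$nc)
  flat <- matrix(aperm(pan$nc, c(1, 3, 2)), d[1] * d[3], d[2])
  cf <- scale(flat, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(cf))
  sc <- cf %*% eig$vectors[, 1:2]
  got <- suppressMessages(pca_features(pan, 2))
  gf <- matrix(aperm(got$nc, c(1, 3, 2)), d[1] * d[3], 2)
  ## eigenvector signs are arbitrary
  for (j in 1:2)
    expect_equal(abs(gf[, j]), abs(sc[, j]), tolerance = 1e-8)

  expect_error(pca_features(pan, 10), "exceeds")
})

test_that("panels survive a disk round trip", {
  pan <- tiny_panel()
  d <- withr::local_tempdir()
  write_panel(pan, d)
  back <- read_panel(d)
  expect_equal(back$nc, pan$nc)
  expect_equal(back$h, pan$h)
  expect_equal(unname(back$p), unname(pan$p))
  expect_identical(back$zips, pan$zips)
})
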