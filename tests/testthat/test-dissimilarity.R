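test_that("Bray-Curtis matches the hand formula", {
  tab <- make_table(rbind(a = c(6, 4, 0), b = c(0, 4, 6), c = c(6, 4, 0)))
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["a", "b"], (6 + 0 + 6) / 20)
  expect_equal(d["a", "c"], 0)
  s <- as.matrix(bray_curtis(tab, as = "similarity"))
  expect_equal(s["a", "b"], 0.4)
  # disjoint samples
  dj <- make_table(rbind(c(3, 0), c(0, 7)))
  expect_equal(as.matrix(bray_curtis(dj))[1, 2], 1)
  # random tables against direct evaluation of the formula
  set.seed(1)
  x <- matrix(rpois(4 * 6, 5), 4)
  d2 <- as.matrix(bray_curtis(make_table(x)))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d2[i, j], sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ]))
  expect_error(bray_curtis(make_table(rbind(c(1, 1), c(0, 0)))), "zero-sum")
})

test_that("Bray-Curtis on presence/absence equals Sorensen dissimilarity", {
  set.seed(2)
  x <- matrix(rbinom(5 * 10, 1, 0.6), 5)
  x[, 1] <- 1 # no empty samples
  d <- as.matrix(bray_curtis(make_table(x)))
  for (i in 1:4) for (j in (i + 1):5) {
    shared <- sum(x[i, ] & x[j, ])
    expect_equal(d[i, j], 1 - 2 * shared / (sum(x[i, ]) + sum(x[j, ])))
  }
})

test_that("Jaccard is the binary set formula and satisfies the triangle inequality", {
  x <- rbind(a = c(1, 1, 1, 0, 0), b = c(0, 1, 1, 1, 0))
  expect_equal(as.matrix(jaccard(make_table(x)))["a", "b"], 1 - 2 / 4)
  expect_equal(as.matrix(jaccard(make_table(rbind(c(1, 0), c(1, 0)))))[1, 2], 0)
  expect_equal(as.matrix(jaccard(make_table(rbind(c(1, 0), c(0, 1)))))[1, 2], 1)
  set.seed(3)
  y <- matrix(rpois(6 * 12, 1), 6)
  y[, 1] <- 1
  d <- as.matrix(jaccard(make_table(y)))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("geographic distance is haversine with Earth radius 6371 km", {
  m <- make_meta(c("a", "b", "c"), lon = c(0, 1, 0), lat = c(0, 0, 0))
  d <- as.matrix(geographic_distance(m))
  expect_equal(d["a", "b"], 2 * pi * 6371 / 360, tolerance = 1e-4)
  expect_equal(d["a", "c"], 0)
  # the study region's scale: ~0.2 degrees offset near 24.5N is tens of km
  m2 <- make_meta(c("a", "b"), lon = c(118.09, 117.92), lat = c(24.46, 24.59))
  d2 <- as.matrix(geographic_distance(m2))["a", "b"]
  expect_gt(d2, 15)
  expect_lt(d2, 40)
})

test_that("environment distance log-transforms everything except pH", {
  m <- make_meta(c("a", "b"))
  m$pH <- c(5, 7)
  m$TOC <- c(0, exp(1) - 1)
  expect_equal(as.matrix(environment_distance(m, "pH"))["a", "b"], 2)
  expect_equal(as.matrix(environment_distance(m, "TOC"))["a", "b"], 1)
  expect_equal(as.matrix(environment_distance(m, c("pH", "TOC")))["a", "b"],
               sqrt(5))
  m$TOC <- c(-1, 3)
  expect_error(environment_distance(m, "TOC"), "negative")
  expect_error(environment_distance(m, "TK"), "not in metadata")
  same <- make_meta(c("a", "b"))
  same$pH <- c(6, 6)
  expect_equal(as.matrix(environment_distance(same, "pH"))["a", "b"], 0)
})

test_that("mantel statistic, errors and determinism behave", {
  set.seed(4)
  n <- 8
  pts <- matrix(runif(2 * n), n)
  a <- as.matrix(dist(pts))
  dimnames(a) <- list(letters[1:n], letters[1:n])
  da <- dist_matrix(a, "euclid", "distance")
  res <- mantel_test(da, da, method = "pearson", n_permutations = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_gte(res$p_value, 1 / 100)

  r1 <- mantel_test(da, dist_matrix(a + t(a) * 0, "x", "distance"),
                    n_permutations = 199, seed = 7)
  r2 <- mantel_test(da, dist_matrix(a, "x", "distance"),
                    n_permutations = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)

  const <- matrix(1, n, n, dimnames = dimnames(a))
  diag(const) <- 0
  expect_error(mantel_test(da, dist_matrix(const, "c", "distance")),
               "zero variance")
  b <- a
  dimnames(b) <- list(LETTERS[1:n], LETTERS[1:n])
  expect_error(mantel_test(da, dist_matrix(b, "x", "distance")),
               "ids differ")
})

test_that("mantel agrees with the vegan implementation", {
  set.seed(5)
  n <- 12
  a <- as.matrix(dist(matrix(runif(2 * n), n)))
  b <- as.matrix(dist(matrix(runif(2 * n), n)))
  ids <- sprintf("s%02d", 1:n)
  dimnames(a) <- dimnames(b) <- list(ids, ids)
  for (meth in c("pearson", "spearman")) {
    mine <- mantel_test(dist_matrix(a, "a", "distance"),
                        dist_matrix(b, "b", "distance"),
                        method = meth, n_permutations = 999, seed = 1,
                        tail = "one-sided-greater")
    ref <- vegan::mantel(as.dist(a), as.dist(b), method = meth,
                         permutations = 999)
    expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
    expect_lt(abs(mine$p_value - ref$signif), 0.05)
  }
})

test_that("distance decay recovers an exponential decay exactly and flags zeros", {
  set.seed(6)
  n <- 10
  ids <- sprintf("s%02d", 1:n)
  pos <- sort(runif(n, 0, 30))
  d <- abs(outer(pos, pos, "-"))
  dimnames(d) <- list(ids, ids)
  k <- 0.07
  s <- exp(-k * d)
  diag(s) <- 1
  fit <- distance_decay(dist_matrix(s, "sim", "similarity"),
                        dist_matrix(d, "geo", "distance"),
                        n_permutations = 99, seed = 1)
  expect_equal(fit$slope, -k, tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_lt(fit$r, 0)
  expect_identical(fit$n_excluded, 0L)

  s2 <- s
  s2[1, 2] <- s2[2, 1] <- 0
  fit2 <- distance_decay(dist_matrix(s2, "sim", "similarity"),
                         dist_matrix(d, "geo", "distance"),
                         n_permutations = 99, seed = 1)
  expect_identical(fit2$n_excluded, 1L)

  # similarity independent of distance: slope near zero
  flat <- matrix(0.5, n, n, dimnames = dimnames(d))
  flat <- flat + as.matrix(dist(matrix(rnorm(n), n))) * 1e-3
  diag(flat) <- 1
  fit3 <- distance_decay(dist_matrix(pmin(flat, 1), "sim", "similarity"),
                         dist_matrix(d, "geo", "distance"),
                         n_permutations = 99, seed = 2)
  expect_lt(abs(fit3$slope), 0.01)
  expect_error(distance_decay(dist_matrix(d, "x", "distance"),
                              dist_matrix(d, "geo", "distance")),
               "similarity")
})
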