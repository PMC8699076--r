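test_that("z-scoring uses the population convention and is idempotent", {
  t <- data.frame(a = c(1, 2, 3), b = c(10, 10, 40))
  z <- zscore(t, "a")
  expect_equal(z$a, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(z$a[2], 0)
  # idempotence
  expect_equal(zscore(z, "a")$a, z$a, tolerance = 1e-12)
  # constant column
  t$c <- 5
  expect_error(zscore(t, "c"), "zero standard deviation")
})

test_that("VIF matches the closed-form normal-equation oracle", {
  # orthogonal centred columns: all VIFs 1
  t0 <- data.frame(a = c(-1, -1, 1, 1, 0, 0), b = c(-1, 1, -1, 1, 0, 0),
                   c = c(0, 0, 0, 0, -1, 1))
  expect_equal(unname(vif(t0, c("a", "b", "c"))), rep(1, 3), tolerance = 1e-12)

  # exact collinearity
  set.seed(2)
  t1 <- data.frame(a = rnorm(20), b = rnorm(20))
  t1$c <- t1$a + t1$b
  expect_identical(unname(vif(t1, c("a", "b", "c"))["c"]), Inf)

  # random table against an independent least-squares oracle
  set.seed(31)
  t2 <- as.data.frame(matrix(rnorm(20 * 4), 20, 4))
  names(t2) <- c("w", "x", "y", "z")
  t2$x <- t2$x + 0.8 * t2$w
  got <- vif(t2, names(t2))
  for (col in names(t2)) {
    yv <- t2[[col]]
    X <- cbind(1, as.matrix(t2[setdiff(names(t2), col)]))
    beta <- solve(t(X) %*% X, t(X) %*% yv)
    res <- yv - X %*% beta
    r2 <- 1 - sum(res^2) / sum((yv - mean(yv))^2)
    expect_equal(unname(got[col]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("VIF flags the count/rate pair when session lengths vary little", {
  set.seed(17)
  minutes <- rnorm(62, 60, 2)        # near-constant session lengths
  num <- pmax(0, round(rnorm(62, 20, 15)))
  tab <- data.frame(num = num, freq = num / minutes,
                    dur = rnorm(62, 1.7, 0.3), d_mean = rnorm(62, 430, 150))
  v <- vif(tab, c("num", "freq", "dur", "d_mean"))
  expect_gt(v[["num"]], 5)
  expect_gt(v[["freq"]], 5)
  expect_lt(v[["dur"]], 2)
})

test_that("log transforms handle zeros via log1p and reject negatives", {
  t <- data.frame(a = c(1, exp(1), exp(2)), b = c(0, 1, 2), c = c(-1, 1, 2))
  lt <- log_transform(t, "a")
  expect_equal(lt$a, c(0, 1, 2))
  expect_length(attr(lt, "log_shifted"), 0L)
  lt2 <- log_transform(t, c("a", "b"))
  expect_equal(attr(lt2, "log_shifted"), "b")
  expect_equal(lt2$b, log1p(c(0, 1, 2)))
  expect_error(log_transform(t, "c"), "negative")
  # round trip without zeros
  expect_equal(exp(lt$a), t$a, tolerance = 1e-12)
})

test_that("the 2-D embedding is seeded-deterministic and keeps separation", {
  set.seed(1)
  t <- as.data.frame(matrix(rnorm(40 * 3), 40, 3))
  names(t) <- c("a", "b", "c")
  e1 <- embed_2d(t, names(t), seed = 7)
  e2 <- embed_2d(t, names(t), seed = 7)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(40L, 2L))
  expect_error(embed_2d(t[1:4, ], names(t), n_neighbors = 5), "n_neighbors")

  # two groups separated by >= 6 pooled sd stay separated in 2-D
  g <- rbind(matrix(rnorm(25 * 3, 0, 1), 25, 3),
             matrix(rnorm(25 * 3, 8, 1), 25, 3))
  gt <- as.data.frame(g); names(gt) <- c("a", "b", "c")
  e <- embed_2d(gt, names(gt), seed = 3)
  within <- max(dist(e[1:25, ]), dist(e[26:50, ]))
  between <- sqrt(sum((colMeans(e[1:25, ]) - colMeans(e[26:50, ]))^2))
  expect_gt(between, within)
})

test_that("density clustering reports silhouette on non-noise points", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 10, 0.3), 20, 2))
  cl <- cluster_density(x, 10)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(cl$n_noise, 0L)
  expect_gt(cl$silhouette, 0.8)
  # no density structure: silhouette undefined-flagged
  u <- matrix(runif(30), 15, 2)
  cl0 <- cluster_density(u, 10)
  expect_lte(cl0$n_clusters, 1L)
  expect_true(is.na(cl0$silhouette))
})

test_that("MLR matches closed-form normal equations", {
  # exact fit
  t <- data.frame(y = c(1, 2, 3, 4), x = c(1, 2, 3, 4))
  m <- suppressWarnings(mlr(t, "y", "x"))  # summary.lm warns on exact fits
  expect_equal(m$r_squared, 1)
  expect_equal(m$coefficients["x", "Estimate"], 1)

  # hand-computed 5-point bivariate fit
  set.seed(23)
  t2 <- data.frame(x1 = c(0.1, 1.3, 2.2, 3.1, 4.0),
                   x2 = c(1.0, 0.4, 2.5, 1.8, 0.2))
  t2$y <- 0.7 + 1.2 * t2$x1 - 0.5 * t2$x2 + c(0.05, -0.02, 0.03, -0.04, 0.01)
  m2 <- mlr(t2, "y", c("x1", "x2"))
  X <- cbind(1, t2$x1, t2$x2)
  beta <- solve(t(X) %*% X, t(X) %*% t2$y)
  expect_equal(unname(m2$coefficients[, "Estimate"]), as.numeric(beta),
               tolerance = 1e-8)
  res <- t2$y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((t2$y - mean(t2$y))^2)
  expect_equal(m2$r_squared, r2, tolerance = 1e-10)

  # independent noise: R^2 stays small at n = 62
  set.seed(41)
  r2s <- vapply(1:10, function(i) {
    tn <- data.frame(y = rnorm(62), a = rnorm(62), b = rnorm(62),
                     c = rnorm(62))
    mlr(tn, "y", c("a", "b", "c"))$r_squared
  }, 0)
  expect_lt(mean(r2s), 0.15)

  # rank-deficient design
  t3 <- data.frame(y = rnorm(10), a = 1:10)
  t3$b <- t3$a * 2
  expect_error(mlr(t3, "y", c("a", "b")), "rank-deficient")
})

test_that("the stratification pipeline is deterministic end to end", {
  cols <- c("num", "freq", "dur", "d_mean", "age_months")
  run <- function() {
    co <- simulate_cohort(seed = 6)
    z <- zscore(co, cols)
    cluster_density(embed_2d(z, cols, seed = 6), 10)$labels
  }
  expect_identical(run(), run())
})
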