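test_that("k-nearest-neighbour weights recover lattice geometry and match a
           brute-force distance sort", {
  W <- lattice_weights(6, 6, standardize = FALSE)
  # knn on the same coordinates
  xy <- as.matrix(expand.grid(x = 1:6, y = 1:6))
  K <- knn_neighbors(xy, k = 8, standardize = FALSE)
  # interior cell: exactly the 8 surrounding cells
  ctr <- which(xy[, 1] == 3 & xy[, 2] == 3)
  nb <- sort(K$to[K$from == ctr])
  ring <- which(abs(xy[, 1] - 3) <= 1 & abs(xy[, 2] - 3) <= 1)
  expect_equal(nb, sort(setdiff(ring, ctr)))
  # corner cell is forced beyond its adjacent ring
  cor_i <- which(xy[, 1] == 1 & xy[, 2] == 1)
  nbc <- K$to[K$from == cor_i]
  dc <- sqrt(rowSums(sweep(xy, 2, xy[cor_i, ])^2))
  expect_true(any(dc[nbc] > sqrt(2)))
  expect_length(nbc, 8)
  # seeded scatter vs full distance sort
  set.seed(67)
  pts <- matrix(runif(120), 60, 2)
  Ks <- knn_neighbors(pts, k = 5, standardize = FALSE)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  for (i in c(1, 17, 42, 60)) {
    expect_setequal(Ks$to[Ks$from == i], order(d[i, ])[1:5])
  }
  expect_error(knn_neighbors(pts[1:4, ], k = 8), "n > k")
  # row standardization sums rows to one
  Kr <- knn_neighbors(pts, k = 5)
  expect_true(Kr$row_standardized)
  expect_equal(unname(vapply(split(Kr$w, Kr$from), sum, numeric(1))),
               rep(1, 60), tolerance = 1e-12)
})

test_that("the distance band at 157 km captures queen neighbours on a
           110-km lattice", {
  xy <- as.matrix(expand.grid(x = (1:7) * 110, y = (1:7) * 110))
  W <- distance_band_neighbors(xy, d = 157, standardize = FALSE)
  ctr <- which(xy[, 1] == 440 & xy[, 2] == 440)
  expect_length(W$to[W$from == ctr], 8)  # 110 and ~155.6 km both inside
  # default band: median 8th-nearest-neighbour distance = 110*sqrt(2)
  Wd <- distance_band_neighbors(xy)
  expect_equal(Wd$d, 110 * sqrt(2), tolerance = 1e-9)
  # band below minimum spacing isolates everything
  expect_warning(expect_error(distance_band_neighbors(xy, d = 50), "no links"),
                 "without neighbours")
  # band at infinity is the complete graph minus self
  Wi <- distance_band_neighbors(xy[1:10, ], d = Inf, standardize = FALSE)
  expect_equal(length(Wi$from), 10 * 9)
})

test_that("Moran's I matches the dense double-loop formula, an independent
           implementation, and the checkerboard/gradient signs", {
  set.seed(71)
  for (n_side in c(5, 8)) {
    W <- lattice_weights(n_side, n_side)
    x <- rnorm(n_side^2)
    got <- morans_i(x, W)
    Wd <- weights_matrix(W, sparse = FALSE)
    z <- x - mean(x)
    dense <- (length(x) / sum(Wd)) * drop(z %*% Wd %*% z) / sum(z^2)
    expect_equal(got, dense, tolerance = 1e-12)
  }
  # independent oracle
  skip_if_not_installed("ape")
  W8 <- lattice_weights(8, 8)
  x <- rnorm(64)
  expect_equal(morans_i(x, W8),
               ape::Moran.I(x, weights_matrix(W8, sparse = FALSE))$observed,
               tolerance = 1e-10)
  # checkerboard on a rook lattice is negatively autocorrelated
  xy9 <- as.matrix(expand.grid(x = 1:3, y = 1:3))
  rook <- distance_band_neighbors(xy9, d = 1.0, standardize = FALSE)
  chk <- (-1)^(xy9[, 1] + xy9[, 2])
  expect_lt(morans_i(chk, rook), 0)
  # smooth gradient is positively autocorrelated
  grad <- as.vector(expand.grid(x = 1:8, y = 1:8)$x) + rnorm(64, sd = 0.1)
  expect_gt(morans_i(grad, W8), 0)
  expect_error(morans_i(rep(2, 64), W8), "constant")
})

test_that("the permutation test has null mean -1/(n-1) and flags structure", {
  W <- lattice_weights(7, 7)
  set.seed(73)
  x <- rnorm(49)
  z <- x - mean(x)
  perms <- replicate(2000, {
    zb <- z[sample.int(49)]
    (49 / sum(W$w)) * sum(W$w * zb[W$from] * zb[W$to]) / sum(zb^2)
  })
  e <- -1 / 48
  expect_lt(abs(mean(perms) - e), 3 * sd(perms) / sqrt(2000))
  # strong gradient: small p; pure noise: typically not small
  grad <- as.vector(expand.grid(x = 1:7, y = 1:7)$x)
  tg <- morans_i_test(grad + rnorm(49, sd = 0.01), W, n_perm = 999, seed = 5)
  expect_lte(tg$p, 0.01)
  expect_equal(tg$expectation, e)
  # p-value respects the +1 permutation correction lower bound
  expect_gte(tg$p, 1 / 1000)
})

test_that("SAR error fit with lambda fixed at 0 reproduces OLS exactly", {
  W <- lattice_weights(12, 12)
  set.seed(79)
  tab <- data.frame(x1 = rnorm(144), x2 = rnorm(144))
  y <- 2 + tab$x1 - 0.5 * tab$x2 + rnorm(144)
  f0 <- sar_error_fit(as.matrix(tab), y, W, n_perm = 0, fixed_lambda = 0)
  ols <- lm(y ~ x1 + x2, tab)
  expect_equal(unname(f0$coefficients[, "estimate"]), unname(coef(ols)),
               tolerance = 1e-8)
  expect_equal(unname(f0$residuals), unname(residuals(ols)),
               tolerance = 1e-8)
  expect_equal(f0$loglik, as.numeric(logLik(ols)), tolerance = 1e-8)
  # lambda = 0 means the two pseudo-R2s coincide
  expect_equal(f0$r2_pred, f0$r2_full)
  expect_equal(f0$r2_pred, summary(ols)$r.squared, tolerance = 1e-8)
})

test_that("profile likelihood is maximized at the reported lambda", {
  W <- lattice_weights(10, 10)
  set.seed(83)
  tab <- data.frame(x = rnorm(100))
  y <- make_richness_response(tab, response_spec(c(x = 1), "sar",
                                                 lambda = 0.6, seed = 11), W)
  f <- sar_error_fit(as.matrix(tab), y, W, n_perm = 0)
  grid <- seq(f$interval[1] + 0.01, f$interval[2] - 0.01, by = 0.01)
  ll <- vapply(grid, function(l)
    sar_error_fit(as.matrix(tab), y, W, n_perm = 0, fixed_lambda = l)$loglik,
    numeric(1))
  expect_true(all(f$loglik >= ll - 1e-6))
  expect_error(sar_error_fit(cbind(tab$x, tab$x), y, W), "singular")
})

test_that("SAR-correlated errors are detected and absorbed", {
  W <- lattice_weights(20, 20)
  set.seed(2)
  tab <- data.frame(x1 = rnorm(400), x2 = rnorm(400))
  spec <- response_spec(c(x1 = 1, x2 = -0.5), "sar", lambda = 0.8,
                        sigma = 1, intercept = 5, seed = 314)
  y <- make_richness_response(tab, spec, W)
  # the generated u itself is spatially autocorrelated
  u <- y - 5 - drop(scale(as.matrix(tab)) %*% c(1, -0.5))
  ut <- morans_i_test(u, W, n_perm = 199, seed = 1)
  expect_lte(ut$p, 0.05)
  f <- sar_error_fit(as.matrix(tab), y, W, n_perm = 199, seed = 1)
  expect_lt(abs(f$lambda - 0.8), 0.15)
  # innovations after the fit carry no detectable autocorrelation
  expect_gt(f$moran$p, 0.05)
  # full signal explains more than the trend alone
  expect_gt(f$r2_full, f$r2_pred)
  pr <- pseudo_r2(f)
  expect_equal(pr$r2_pred, f$r2_pred)
})

test_that("principal-coordinate filters are orthogonal, zero-mean, ordered,
           and track a linear arrangement", {
  set.seed(89)
  # planar coordinates carry exactly two positive principal-coordinate axes
  pts <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  mf <- mem_filters(pts, 2)
  V <- mf$vectors
  expect_equal(dim(V), c(40, 2))
  expect_lt(max(abs(colMeans(V))), 1e-10)
  G <- crossprod(V)
  expect_equal(G, diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(mem_filters(pts, 3), "positive eigenvalues")
  expect_true(all(diff(mf$values) <= 1e-9))
  # points on a line: first filter follows the along-line coordinate
  line <- cbind(seq(0, 10, length.out = 30), 0.5 * seq(0, 10, length.out = 30))
  m1 <- mem_filters(line, 1)
  expect_gt(abs(cor(m1$vectors[, 1], line[, 1])), 0.99)
  expect_error(mem_filters(line, 31), "positive eigenvalues")
})

test_that("weights survive the triplet-CSV and GAL round trips", {
  set.seed(97)
  pts <- matrix(runif(40), 20, 2)
  W <- knn_neighbors(pts, k = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_weights_csv(W, f)
  back <- read_weights_csv(f)
  expect_equal(back$n, W$n)
  expect_true(back$row_standardized)
  expect_equal(weights_matrix(back), weights_matrix(W), tolerance = 1e-12)
  # GAL: wikipedia-style neighbour list
  gal <- withr::local_tempfile(fileext = ".gal")
  writeLines(c("3", "1 2", "2 3", "2 1", "3", "3 1", "2"), gal)
  Wg <- read_gal(gal)
  expect_equal(Wg$n, 3)
  expect_setequal(Wg$to[Wg$from == 1], c(2, 3))
  expect_equal(Wg$to[Wg$from == 3], 2)
  expect_false(Wg$row_standardized)
})
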