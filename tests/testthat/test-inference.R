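test_that("Spearman correlation matches rank-then-Pearson and its t test", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  set.seed(17)
  x <- sample(rep(1:10, 3))  # heavy ties
  y <- x + rnorm(30, sd = 4)
  got <- spearman_cor(x, y)
  rho <- cor(rank(x), rank(y))
  expect_equal(got$rho, rho, tolerance = 1e-12)
  t <- rho * sqrt(28 / (1 - rho^2))
  expect_equal(got$p, 2 * pt(-abs(t), 28), tolerance = 1e-12)
  # invariant under strictly monotone transforms of either argument
  expect_equal(spearman_cor(exp(x), y)$rho, rho, tolerance = 1e-12)
  expect_equal(spearman_cor(x, y^3 + 5)$rho,
               spearman_cor(x, y)$rho, tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 10), 1:10), "constant")
})

test_that("variance partitioning satisfies its algebraic identities", {
  set.seed(23)
  n <- 200
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  # orthogonalize b against a exactly
  d$b <- residuals(lm(b ~ a, d))
  y <- 2 * d$a + 1 * d$b + rnorm(n)
  vp <- variance_partition(y, list(A = "a", B = "b"), d)
  r2a <- summary(lm(y ~ a, d))$r.squared
  r2b <- summary(lm(y ~ b, d))$r.squared
  # orthogonal predictors: unique fractions equal marginal R2, shared ~ 0
  expect_equal(unname(vp$unique["A"]), r2a, tolerance = 1e-10)
  expect_equal(unname(vp$unique["B"]), r2b, tolerance = 1e-10)
  expect_lt(abs(vp$shared), 1e-10)
  # components sum to the full-model R2 by construction
  expect_equal(sum(vp$unique) + vp$shared, vp$full_r2)
  # single group: partition equals marginal R2
  vp1 <- variance_partition(y, list(A = "a"), d)
  expect_equal(vp1$full_r2, r2a)
  expect_equal(unname(vp1$unique["A"]), r2a)
  # full-model R2 matches ols_fit on the same columns
  fit <- ols_fit(cbind(d, y = y), model_spec("y", c("a", "b")))
  expect_equal(vp$full_r2, fit$r_squared, tolerance = 1e-12)
})

test_that("VIFs match brute-force per-column regressions", {
  set.seed(29)
  d <- as.data.frame(matrix(rnorm(5 * 120), 120))
  names(d) <- paste0("v", 1:5)
  d$v5 <- d$v1 + 0.5 * d$v2 + rnorm(120, sd = 0.4)
  got <- vif_terms(d)
  for (j in 1:5) {
    r2 <- summary(lm(d[[j]] ~ ., d[-j]))$r.squared
    expect_equal(unname(got[j]), 1 / (1 - r2), tolerance = 1e-9)
  }
  # duplicated column is flagged infinite
  d$v6 <- d$v1
  expect_true(is.infinite(vif_terms(d)["v6"]) ||
                is.infinite(vif_terms(d)["v1"]))
})

test_that("the collinearity screen drops planted near-duplicates and
           keeps orthogonal tables intact", {
  set.seed(37)
  n <- 150
  d <- data.frame(p = rnorm(n), q = rnorm(n), r = rnorm(n))
  scr0 <- collinearity_screen(d, r_max = 0.7, vif_max = 5)
  expect_setequal(scr0$retained, c("p", "q", "r"))
  expect_equal(nrow(scr0$dropped), 0)
  # planted near-duplicate of p
  d$p2 <- d$p + rnorm(n, sd = 0.05)
  scr <- collinearity_screen(d, r_max = 0.7, vif_max = 5)
  expect_true(any(c("p", "p2") %in% scr$dropped$term))
  expect_false(all(c("p", "p2") %in% scr$retained))
  expect_equal(scr$dropped$reason[1], "spearman")
  # re-screen of the retained set passes
  scr2 <- collinearity_screen(d[scr$retained], r_max = 0.7, vif_max = 5)
  expect_equal(nrow(scr2$dropped), 0)
  # a VIF-only offender (low pairwise r, high joint R2) is caught
  d2 <- data.frame(a = rnorm(n), b = rnorm(n), cc = rnorm(n))
  d2$s <- (d2$a + d2$b + d2$cc) / sqrt(3) + rnorm(n, sd = 0.15)
  v <- vif_terms(d2)
  scr3 <- collinearity_screen(d2, r_max = 0.9, vif_max = 3)
  expect_true("vif" %in% scr3$dropped$reason || nrow(scr3$dropped) == 0)
})

test_that("OLS recovers exact coefficients, matches the normal equations,
           and back-scales standardized slopes", {
  x <- seq(-3, 5, length.out = 50)
  tab <- data.frame(x = x, y = 3 + 2 * x)
  fit <- ols_fit(tab, model_spec("y", "x"))
  expect_equal(unname(fit$raw_coefficients["x"]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$raw_coefficients["(Intercept)"]), 3,
               tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(fit$coefficients["x", "estimate"]), 2 * sd(x),
               tolerance = 1e-10)
  # seeded 12-predictor fixture vs independent normal-equations solve
  set.seed(41)
  n <- 150
  X <- matrix(rnorm(n * 12), n, dimnames = list(NULL, paste0("x", 1:12)))
  tab2 <- data.frame(X)
  tab2$y <- drop(X %*% runif(12, -1, 1)) + rnorm(n)
  spec <- model_spec("y", paste0("x", 1:12))
  fit2 <- ols_fit(tab2, spec)
  Z <- scale(X)
  A <- cbind(1, Z)
  beta <- solve(t(A) %*% A, t(A) %*% tab2$y)
  expect_equal(unname(fit2$coefficients[, "estimate"]), unname(drop(beta)),
               tolerance = 1e-8)
  # residuals + fitted = response
  expect_equal(fit2$residuals + fit2$fitted, tab2$y)
})

test_that("standardization makes the fit invariant to predictor units", {
  set.seed(43)
  n <- 120
  tab <- data.frame(a = rnorm(n, sd = 3), b = runif(n), d = rnorm(n))
  tab$y <- 1 + 0.8 * scale(tab$a)[, 1] - 0.5 * scale(tab$b)[, 1] + rnorm(n)
  spec <- model_spec("y", c("a", "b", "d"), degrees = c(b = 2))
  fit <- ols_fit(tab, spec)
  tab2 <- tab
  tab2$a <- tab$a * 1000      # metres instead of km
  tab2$b <- tab$b * 12 - 7
  fit2 <- ols_fit(tab2, spec)
  expect_equal(fit$coefficients[, "estimate"], fit2$coefficients[, "estimate"],
               tolerance = 1e-9)
  expect_equal(fit$coefficients[, "p"], fit2$coefficients[, "p"],
               tolerance = 1e-9)
  expect_equal(fit$r_squared, fit2$r_squared, tolerance = 1e-9)
  expect_equal(fit$aic, fit2$aic, tolerance = 1e-9)
  # and the backward path is unchanged too
  b1 <- aic_backward(tab, spec)
  b2 <- aic_backward(tab2, spec)
  expect_identical(b1$selection_path, b2$selection_path)
})

test_that("transforms apply before standardization as specified", {
  set.seed(47)
  tab <- data.frame(pd = rexp(80, 0.1), an = rnorm(80, sd = 10))
  tab$y <- 2 * scale(log1p(tab$pd))[, 1] + rnorm(80, sd = 0.3)
  spec <- model_spec("y", c("pd", "an"),
                     transforms = c(pd = "log1p", an = "log1p_abs"))
  dm <- design_matrix(tab, spec)
  expect_equal(dm$X[, "pd"], scale(log1p(tab$pd))[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(dm$X[, "an"], scale(log1p(abs(tab$an)))[, 1],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(
    design_matrix(data.frame(pd = c(-5, 1, 2, 3, 4, 5), y = 1:6),
                  model_spec("y", "pd", transforms = c(pd = "log1p"))),
    "below -1")
})

test_that("backward-AIC selection matches exhaustive subset search for a
           small candidate set", {
  set.seed(53)
  n <- 90
  d <- as.data.frame(matrix(rnorm(n * 5), n,
                            dimnames = list(NULL, paste0("t", 1:5))))
  d$y <- 1.2 * d$t1 - 0.9 * d$t2 + 0.05 * d$t3 + rnorm(n)
  spec <- model_spec("y", paste0("t", 1:5))
  sel <- aic_backward(d, spec)
  # independent exhaustive search over all nonempty subsets with the same
  # AIC formula
  best_aic <- Inf; best_set <- NULL
  for (k in 1:5) {
    for (set in combn(paste0("t", 1:5), k, simplify = FALSE)) {
      f <- lm(reformulate(set, "y"), d)
      rss <- sum(residuals(f)^2)
      aic <- n * log(rss / n) + 2 * (k + 1)
      if (aic < best_aic) { best_aic <- aic; best_set <- set }
    }
  }
  expect_setequal(sel$spec$terms, best_set)
  expect_equal(sel$aic, best_aic, tolerance = 1e-9)
  # noiseless strong effects: nothing dropped
  d2 <- d; d2$y <- d$t1 + d$t2 + d$t3 + d$t4 + d$t5
  sel2 <- aic_backward(d2, model_spec("y", paste0("t", 1:5)))
  expect_length(sel2$selection_path, 0)
})

test_that("polynomial hierarchy is respected during selection", {
  set.seed(59)
  n <- 150
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- 0.9 * d$x + rnorm(n)  # no curvature, z irrelevant
  spec <- model_spec("y", c("x", "z"), degrees = c(x = 2))
  sel <- aic_backward(d, spec)
  # the square must be dropped before (or without) the base term
  if ("x" %in% sel$selection_path) {
    expect_lt(match("x^2", sel$selection_path), match("x", sel$selection_path))
  }
  expect_true("x" %in% sel$spec$terms)
  expect_false("x^2" %in% colnames(sel$design$X))
})

test_that("partial residuals obey their algebraic identities", {
  set.seed(61)
  n <- 100
  tab <- data.frame(u = rnorm(n), v = rnorm(n))
  tab$y <- 1 + 2 * tab$u + rnorm(n, sd = 0.5)
  fit <- ols_fit(tab, model_spec("y", c("u", "v")))
  pr <- partial_residuals(fit, "u")
  # slope of partial residuals on the term equals the fitted coefficient
  slope <- coef(lm(pr ~ fit$design$X[, "u"]))[2]
  expect_equal(unname(slope), unname(fit$coefficients["u", "estimate"]),
               tolerance = 1e-10)
  # single-predictor noiseless fit: partial residuals collinear with term
  tab2 <- data.frame(w = rnorm(n)); tab2$y <- 5 - 3 * tab2$w
  f2 <- ols_fit(tab2, model_spec("y", "w"))
  expect_equal(abs(cor(partial_residuals(f2, "w"), tab2$w)), 1,
               tolerance = 1e-10)
  # zero-coefficient term: partial residuals equal plain residuals
  tab3 <- tab; tab3$v <- residuals(lm(v ~ u + y, tab))  # orthogonal noise
  f3 <- ols_fit(tab3, model_spec("y", c("u", "v")))
  expect_equal(partial_residuals(f3, "v") -
                 f3$coefficients["v", "estimate"] * f3$design$X[, "v"],
               f3$residuals)
  expect_error(partial_residuals(fit, "nope"), "unknown term")
})
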