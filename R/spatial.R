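#' Spatial weights objects
#'
#' A `spatial_weights` object stores a sparse neighbour structure as triplets
#' (`from`, `to`, `w`; 1-based indices, no self-links, positive weights) plus
#' the number of units `n` and a `row_standardized` flag. When
#' row-standardized, every nonempty row sums to 1.
#'
#' @param from,to integer vectors of 1-based unit indices.
#' @param w positive link weights.
#' @param n number of units.
#' @param row_standardized logical flag.
#' @param coords optional unit coordinates (kept for downstream use).
#' @return an object of class `spatial_weights`.
#' @export
spatial_weights <- function(from, to, w, n, row_standardized = FALSE,
                            coords = NULL) {
  from <- as.integer(from); to <- as.integer(to)
  if (length(from) != length(to) || length(from) != length(w))
    stop("from, to, w must have equal length")
  if (any(from == to)) stop("self-neighbours are not allowed")
  if (any(w <= 0)) stop("weights must be positive")
  if (any(from < 1L | from > n | to < 1L | to > n)) stop("index out of range")
  structure(list(from = from, to = to, w = as.double(w), n = as.integer(n),
                 row_standardized = row_standardized, coords = coords),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  deg <- tabulate(x$from, x$n)
  cat(sprintf(
    "spatial weights: n = %d, %d links, %s, mean degree %.2f, %d isolated\n",
    x$n, length(x$from),
    if (x$row_standardized) "row-standardized" else "binary/raw",
    mean(deg), sum(deg == 0)))
  invisible(x)
}

#' Row-standardize spatial weights
#'
#' Divides each unit's outgoing weights by their sum, so every nonempty row
#' of the weights matrix sums to one.
#'
#' @param W a [spatial_weights()] object.
#' @return a row-standardized [spatial_weights()].
#' @export
row_standardize <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  rs <- vapply(split(W$w, W$from), sum, numeric(1))
  W$w <- W$w / rs[as.character(W$from)]
  W$row_standardized <- TRUE
  W
}

#' Weights as a matrix
#'
#' @param W a [spatial_weights()] object.
#' @param sparse return a `Matrix::sparseMatrix` (default) or a dense matrix.
#' @return an `n x n` weights matrix.
#' @export
weights_matrix <- function(W, sparse = TRUE) {
  stopifnot(inherits(W, "spatial_weights"))
  m <- Matrix::sparseMatrix(i = W$from, j = W$to, x = W$w,
                            dims = c(W$n, W$n))
  if (sparse) m else as.matrix(m)
}

#' k-nearest-neighbour spatial weights
#'
#' Links every unit to its `k` nearest units by Euclidean distance (links may
#' be asymmetric); weights are binary, optionally row-standardized (each
#' neighbour then gets `1/k`). Exact distance ties and duplicate coordinates
#' are resolved by index order.
#'
#' @param coords two-column coordinate matrix.
#' @param k neighbours per unit (default 8, the conventional choice for
#'   lattice richness data); `n > k` required.
#' @param standardize row-standardize the result (default `TRUE`).
#' @return a [spatial_weights()] object.
#' @export
knn_neighbors <- function(coords, k = 8, standardize = TRUE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n <= k) stop("need more units than neighbours (n > k)")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  d <- as.matrix(stats::dist(coords))
  to <- integer(n * k)
  for (i in seq_len(n)) {
    nb <- order(d[i, -i])[seq_len(k)]
    # map back to full index space (order() breaks ties by position)
    idx <- seq_len(n)[-i][nb]
    to[(i - 1L) * k + seq_len(k)] <- idx
  }
  W <- spatial_weights(from = rep(seq_len(n), each = k), to = to,
                       w = rep(1, n * k), n = n, coords = coords)
  if (standardize) row_standardize(W) else W
}

#' Distance-band spatial weights
#'
#' Links every unit to all units within distance `d` (inclusive, excluding
#' itself). The default band is the median, over units, of the distance to
#' the unit's 8th nearest neighbour -- on a regular lattice of ~110-km cells
#' this is the familiar 157-km band that captures the 8 queen neighbours
#' (at 110 and ~155.6 km). Units left without neighbours are listed in the
#' `isolated` element and flagged with a warning.
#'
#' @param coords two-column coordinate matrix.
#' @param d band distance; `NULL` (default) uses the median 8th-nearest
#'   -neighbour distance.
#' @param standardize row-standardize the result (default `TRUE`).
#' @return a [spatial_weights()] with extra elements `d` and `isolated`.
#' @export
distance_band_neighbors <- function(coords, d = NULL, standardize = TRUE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least two units")
  dm <- as.matrix(stats::dist(coords))
  if (is.null(d)) {
    if (n <= 8L) stop("default band needs n > 8")
    d <- stats::median(apply(dm, 1L, function(r) sort(r[-which.min(r)])[8L]))
  }
  if (d <= 0) stop("d must be positive")
  diag(dm) <- NA  # self is never a neighbour, even at d = Inf
  link <- which(dm <= d, arr.ind = TRUE)
  deg <- tabulate(link[, 1L], n)
  isolated <- which(deg == 0L)
  if (length(isolated))
    warning(length(isolated), " unit(s) without neighbours at d = ",
            signif(d, 6))
  if (!nrow(link)) stop("no links at all within the band")
  W <- spatial_weights(from = link[, 1L], to = link[, 2L],
                       w = rep(1, nrow(link)), n = n, coords = coords)
  if (standardize) W <- row_standardize(W)  # nonempty rows only
  W$d <- d
  W$isolated <- isolated
  W
}

#' Moran's I and its permutation test
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' variable and `S0` the total weight. The permutation test randomly
#' relabels the values `n_perm` times and reports the two-sided p-value
#' `(1 + #{|I* - E| >= |I - E|}) / (n_perm + 1)` around the null expectation
#' `E = -1 / (n - 1)`.
#'
#' @param x numeric vector with positive variance.
#' @param W a [spatial_weights()] object with `W$n == length(x)`.
#' @param n_perm number of permutations (999 by convention).
#' @param seed integer seed for the permutations.
#' @return `morans_i()` returns the statistic; `morans_i_test()` returns a
#'   list with `I`, `expectation`, `p` and `n_perm`.
#' @export
morans_i <- function(x, W) {
  stopifnot(inherits(W, "spatial_weights"))
  if (length(x) != W$n) stop("x length must equal W$n")
  if (anyNA(x)) stop("x must be complete")
  if (stats::var(x) == 0) stop("Moran's I undefined for constant x")
  z <- x - mean(x)
  s0 <- sum(W$w)
  (W$n / s0) * sum(W$w * z[W$from] * z[W$to]) / sum(z^2)
}

#' @rdname morans_i
#' @export
morans_i_test <- function(x, W, n_perm = 999, seed = 1) {
  obs <- morans_i(x, W)
  e <- -1 / (W$n - 1)
  z <- x - mean(x)
  denom <- sum(z^2)
  cross <- function(zz) (W$n / sum(W$w)) * sum(W$w * zz[W$from] * zz[W$to]) /
    denom
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      zb <- z[sample.int(W$n)]
      abs(cross(zb) - e) >= abs(obs - e)
    }, logical(1)))
  })
  list(I = obs, expectation = e, p = (1 + exceed) / (n_perm + 1),
       n_perm = n_perm)
}

# log |I - lambda W| via the (possibly complex) eigenvalues of W
logdet_factor <- function(ev, lambda) sum(log(Mod(1 - lambda * ev)))

#' Maximum-likelihood SAR error model
#'
#' Fits the spatial simultaneous autoregressive error model
#' `y = X beta + u`, `u = lambda W u + eps`, `eps ~ N(0, sigma^2 I)`, by
#' profiling the Gaussian log-likelihood over `lambda`: for each `lambda`
#' the spatially filtered variables `(I - lambda W) y` and
#' `(I - lambda W) X` give GLS estimates of `beta` and `sigma^2`, and the
#' Jacobian `log|I - lambda W|` is evaluated from the (dense) eigenvalues of
#' `W`. The feasible `lambda` interval is set by the reciprocal extreme real
#' eigenvalues (for row-standardized weights the upper end is 1). Exact
#' dense eigenvalues keep the likelihood exact at the problem sizes this
#' package targets (n up to a few thousand).
#'
#' Coefficient standard errors come from the asymptotic information matrix
#' conditional on `lambda` (`sigma^2 [(Xs)'(Xs)]^{-1}`); residual spatial
#' autocorrelation is assessed by a permutation Moran test on the innovation
#' residuals `eps_hat = (I - lambda W)(y - X beta)`.
#'
#' @param X design matrix *without* intercept column (one is added), or the
#'   result of [design_matrix()].
#' @param y response vector.
#' @param W row-standardized [spatial_weights()].
#' @param moran_weights weights for the residual Moran test; default `W`.
#' @param n_perm permutations for the residual Moran test; 0 skips it.
#' @param seed seed for the permutation test.
#' @param fixed_lambda optional: hold `lambda` at this value instead of
#'   estimating it (at `fixed_lambda = 0` the fit reduces exactly to OLS).
#' @return an object of class `sar_fit`: `lambda`, `coefficients` (estimate,
#'   se, z, p), `sigma2`, `loglik`, `aic`, `r2_pred`, `r2_full`,
#'   `residuals` (innovations), `response_residuals` (`y - X beta`),
#'   `trend` (`X beta`), `signal` (trend plus spatially predicted
#'   residual), `moran` (test result or `NULL`), `interval`.
#' @export
sar_error_fit <- function(X, y, W, moran_weights = W, n_perm = 999,
                          seed = 1, fixed_lambda = NULL) {
  if (is.list(X) && !is.null(X$X)) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  stopifnot(inherits(W, "spatial_weights"))
  if (!isTRUE(W$row_standardized))
    stop("W must be row-standardized for the SAR error model")
  n <- length(y)
  if (nrow(X) != n || W$n != n) stop("dimension mismatch")
  Xi <- cbind(`(Intercept)` = 1, X)
  if (qr(Xi)$rank < ncol(Xi)) stop("singular design matrix")
  Wd <- weights_matrix(W, sparse = FALSE)
  ev <- eigen(Wd, only.values = TRUE)$values
  re <- Re(ev)[abs(Im(ev)) < 1e-8]
  lo <- if (any(re < 0)) 1 / min(re) else -1
  hi <- if (any(re > 0)) 1 / max(re) else 1
  interval <- c(lo, hi)
  Ws <- weights_matrix(W, sparse = TRUE)
  Wy <- as.vector(Ws %*% y)
  WX <- as.matrix(Ws %*% Xi)
  profile <- function(lambda) {
    ys <- y - lambda * Wy
    Xs <- Xi - lambda * WX
    f <- stats::lm.fit(Xs, ys)
    rss <- sum(f$residuals^2)
    -(n / 2) * (log(2 * pi * rss / n) + 1) + logdet_factor(ev, lambda)
  }
  if (is.null(fixed_lambda)) {
    eps <- 1e-6 * (hi - lo)
    opt <- stats::optimize(profile, c(lo + eps, hi - eps), maximum = TRUE,
                           tol = 1e-9)
    lambda <- opt$maximum
    loglik <- opt$objective
    if (min(lambda - lo, hi - lambda) < 1e-4 * (hi - lo))
      warning("lambda estimate on the feasible boundary")
  } else {
    if (fixed_lambda <= lo || fixed_lambda >= hi)
      stop("fixed_lambda outside the feasible interval")
    lambda <- fixed_lambda
    loglik <- profile(lambda)
  }
  ys <- y - lambda * Wy
  Xs <- Xi - lambda * WX
  f <- stats::lm.fit(Xs, ys)
  beta <- f$coefficients
  rss <- sum(f$residuals^2)
  sigma2 <- rss / n
  xtx_inv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  zst <- beta / se
  co <- cbind(estimate = beta, se = se, z = zst,
              p = 2 * stats::pnorm(-abs(zst)))
  k <- ncol(Xi)
  trend <- as.vector(Xi %*% beta)
  u <- y - trend
  signal <- trend + lambda * as.vector(Ws %*% u)
  r2_pred <- stats::cor(trend, y)^2
  r2_full <- stats::cor(signal, y)^2
  innov <- as.vector(ys - Xs %*% beta)
  moran <- if (n_perm > 0)
    morans_i_test(innov, moran_weights, n_perm = n_perm, seed = seed)
  else NULL
  structure(list(lambda = lambda, coefficients = co, sigma2 = sigma2,
                 loglik = loglik, aic = -2 * loglik + 2 * (k + 2),
                 r2_pred = r2_pred, r2_full = r2_full,
                 residuals = innov, response_residuals = u, trend = trend,
                 signal = signal, y = y, moran = moran,
                 interval = interval),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf(
    "SAR error fit: lambda = %.4f, logLik = %.2f, AIC = %.2f\n",
    x$lambda, x$loglik, x$aic))
  cat(sprintf("  pseudo-R2: pred = %.4f, full = %.4f\n",
              x$r2_pred, x$r2_full))
  if (!is.null(x$moran))
    cat(sprintf("  residual Moran's I = %.4f (perm p = %.4f)\n",
                x$moran$I, x$moran$p))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Pseudo-R2 of a SAR fit
#'
#' Squared Pearson correlations between observed values and (i) the trend
#' prediction `X beta` alone (`r2_pred`, the variance explained by the
#' environmental predictors) and (ii) the full signal
#' `X beta + lambda W (y - X beta)` (`r2_full`, trend plus the spatially
#' structured component). With `lambda = 0` the two coincide.
#'
#' @param fit a [sar_error_fit()] result.
#' @param y response; defaults to the vector stored in the fit.
#' @return list with `r2_pred` and `r2_full`.
#' @export
pseudo_r2 <- function(fit, y = fit$y) {
  stopifnot(inherits(fit, "sar_fit"))
  if (stats::var(fit$trend) == 0 || stats::var(fit$signal) == 0)
    stop("zero-variance prediction")
  list(r2_pred = stats::cor(fit$trend, y)^2,
       r2_full = stats::cor(fit$signal, y)^2)
}

#' Principal-coordinate spatial filters
#'
#' Eigenvectors of the double-centred matrix of squared pairwise distances
#' (`-1/2 * C D2 C`, the Gower centering of a principal coordinate
#' analysis), kept for the `n_keep` largest positive eigenvalues. Each
#' returned column is zero-mean and unit-norm; columns are mutually
#' orthogonal and ordered by non-increasing eigenvalue. Used as
#' spatially-structured covariates ("spatial filters") in SDMs and
#' regressions.
#'
#' @param coords two-column coordinate matrix (`n >= 3`).
#' @param n_keep number of filters to return.
#' @return list with `vectors` (`n x n_keep` matrix) and `values`
#'   (eigenvalues).
#' @export
mem_filters <- function(coords, n_keep) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 points")
  d2 <- as.matrix(stats::dist(coords))^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% d2 %*% C
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values))
  pos <- which(e$values > tol)
  if (n_keep > length(pos))
    stop("n_keep exceeds the number of positive eigenvalues (",
         length(pos), ")")
  V <- e$vectors[, pos[seq_len(n_keep)], drop = FALSE]
  V <- sweep(V, 2L, colMeans(V))
  V <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("MEM", seq_len(ncol(V)))
  list(vectors = V, values = e$values[pos[seq_len(n_keep)]])
}

#' Read and write spatial weights as sparse triplets
#'
#' The on-disk form is a CSV of `(i, j, w)` triplets next to a JSON header
#' carrying `n` and the `row_standardized` flag. A reader for the plain-text
#' "GAL" neighbour-list format (`n` on the first line, then alternating
#' `id count` / neighbour-id lines) is also provided; GAL carries no
#' weights, so links are binary.
#'
#' @param W a [spatial_weights()] object.
#' @param file CSV path; the JSON header is written to `paste0(file, ".json")`.
#' @return `read_weights_csv()` and `read_gal()` return [spatial_weights()].
#' @export
write_weights_csv <- function(W, file) {
  stopifnot(inherits(W, "spatial_weights"))
  utils::write.csv(data.frame(i = W$from, j = W$to, w = W$w), file,
                   row.names = FALSE)
  jsonlite::write_json(list(n = W$n, row_standardized = W$row_standardized),
                       paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(file) {
  tri <- utils::read.csv(file)
  hdr <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  spatial_weights(tri$i, tri$j, tri$w, n = hdr$n,
                  row_standardized = isTRUE(hdr$row_standardized))
}

#' @rdname write_weights_csv
#' @export
read_gal <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  first <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  # GAL headers are either "n" or "0 n <shapefile> <id>"
  n <- as.integer(if (length(first) > 1L) first[2L] else first[1L])
  from <- integer(); to <- integer()
  i <- 2L
  while (i <= length(lines)) {
    hd <- as.integer(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]])
    id <- hd[1L]; cnt <- hd[2L]
    if (cnt > 0L) {
      nb <- as.integer(strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1]])
      if (length(nb) != cnt) stop("malformed GAL record for unit ", id)
      from <- c(from, rep(id, cnt)); to <- c(to, nb)
      i <- i + 2L
    } else i <- i + 1L
  }
  spatial_weights(from, to, rep(1, length(from)), n = n)
}
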