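#' Spearman rank correlation with large-sample test
#'
#' The coefficient is the Pearson correlation of mid-ranks (ties averaged);
#' the p-value comes from the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y paired finite numeric vectors, `n >= 3`.
#' @return list with `rho`, `p` and `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Variance partitioning across predictor groups
#'
#' Fits an OLS model of `y` on the union of columns of every nonempty subset
#' of the groups and reports each subset's R-squared. The unique fraction of
#' a group is `R2(all) - R2(all minus that group)`; unique fractions plus the
#' shared remainder sum to the full-model R-squared by construction, and all
#' subset R-squared values are returned so any shared component can be
#' derived.
#'
#' @param y response vector.
#' @param groups named list; each element is a character vector of column
#'   names of `data` forming one predictor group.
#' @param data data.frame holding the predictor columns.
#' @return list with `subsets` (data.frame: `subset`, `r2`), `unique` (named
#'   vector), `shared` (full R2 minus the sum of unique fractions) and
#'   `full_r2`.
#' @export
variance_partition <- function(y, groups, data) {
  if (!length(groups) || is.null(names(groups)))
    stop("groups must be a nonempty named list")
  cols <- unique(unlist(groups))
  if (!all(cols %in% names(data)))
    stop("unknown predictor column(s): ",
         paste(setdiff(cols, names(data)), collapse = ", "))
  keep <- stats::complete.cases(data[cols]) & !is.na(y)
  y <- y[keep]; data <- data[keep, , drop = FALSE]
  r2_of <- function(colset) {
    X <- as.matrix(data[unlist(groups[colset])])
    fit <- stats::lm(y ~ X)
    if (anyNA(stats::coef(fit)))
      warning("rank-deficient subset {", paste(colset, collapse = ","),
              "}: R2 computed on its column space")
    summary(fit)$r.squared
  }
  gnames <- names(groups)
  subs <- unlist(lapply(seq_along(gnames),
                        function(k) utils::combn(gnames, k, simplify = FALSE)),
                 recursive = FALSE)
  r2 <- vapply(subs, r2_of, numeric(1))
  labels <- vapply(subs, paste, character(1), collapse = "+")
  full <- r2[length(r2)]
  uniq <- vapply(gnames, function(g) {
    rest <- setdiff(gnames, g)
    full - if (length(rest)) r2[match(paste(rest, collapse = "+"), labels)]
           else 0
  }, numeric(1))
  list(subsets = data.frame(subset = labels, r2 = r2),
       unique = uniq, shared = full - sum(uniq), full_r2 = full)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, with `R2_j` from regressing column `j` on the
#' remaining columns (with intercept). Perfect collinearity yields `Inf`.
#'
#' @param data data.frame of predictor columns.
#' @param terms column names to assess; default all.
#' @return named numeric vector of VIFs.
#' @export
vif_terms <- function(data, terms = names(data)) {
  if (length(terms) < 2L) stop("need at least 2 terms")
  X <- as.matrix(data[terms])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) <= length(terms)) stop("more terms than observations")
  vapply(seq_along(terms), function(j) {
    # perfectly collinear columns are a legitimate input here (reported Inf)
    r2 <- withCallingHandlers(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared,
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(terms)
}

#' Collinearity screen
#'
#' Two-stage predictor screen used before multi-predictor modelling. First,
#' while any pair of terms has absolute Spearman correlation above `r_max`,
#' the member of the worst pair with the larger mean absolute correlation to
#' all other remaining terms is dropped (ties broken by column order, the
#' later column dropped). Second, while any remaining term's VIF exceeds
#' `vif_max`, the term with the largest VIF is dropped. Every drop is
#' recorded with the statistic that triggered it.
#'
#' @param data data.frame of predictor columns.
#' @param terms candidate column names; default all columns.
#' @param r_max pairwise absolute Spearman threshold (default 0.70).
#' @param vif_max VIF threshold (default 5).
#' @return list with `retained` (character) and `dropped` (data.frame:
#'   `term`, `reason`, `statistic`, `partner`).
#' @export
collinearity_screen <- function(data, terms = names(data),
                                r_max = 0.70, vif_max = 5) {
  if (r_max <= 0 || vif_max <= 0) stop("thresholds must be positive")
  dropped <- data.frame(term = character(), reason = character(),
                        statistic = numeric(), partner = character())
  keep <- terms
  repeat {
    if (length(keep) < 2L) break
    R <- stats::cor(apply(data[keep], 2L, rank),
                    use = "pairwise.complete.obs")
    diag(R) <- 0
    if (max(abs(R)) <= r_max) break
    worst <- which(abs(R) == max(abs(R)), arr.ind = TRUE)[1L, ]
    i <- worst[1L]; j <- worst[2L]
    mean_abs <- rowMeans(abs(R))
    drop_j <- if (mean_abs[j] > mean_abs[i]) j
              else if (mean_abs[i] > mean_abs[j]) i
              else max(i, j)
    dropped <- rbind(dropped, data.frame(
      term = keep[drop_j], reason = "spearman",
      statistic = R[i, j], partner = keep[if (drop_j == i) j else i]))
    keep <- keep[-drop_j]
  }
  repeat {
    if (length(keep) < 2L) break
    v <- vif_terms(data, keep)
    if (max(v) <= vif_max) break
    w <- which.max(v)
    dropped <- rbind(dropped, data.frame(
      term = keep[w], reason = "vif", statistic = v[w], partner = NA))
    keep <- keep[-w]
  }
  if (!length(keep)) stop("collinearity screen dropped all terms")
  list(retained = keep, dropped = dropped)
}

#' Regression model specification
#'
#' Describes a multi-predictor OLS (or SAR) model on a cell table: the
#' response column, the predictor terms, optional per-term transforms
#' (`"none"`, `"log1p"` = log(x + 1), `"log1p_abs"` = log(|x| + 1) for
#' signed anomalies), optional polynomial degree per term, and whether
#' predictor columns are standardized.
#'
#' Polynomial columns are built from the transformed, centred base column
#' before squaring, then standardized like any other column, and selection
#' respects the hierarchy (a base term is never dropped while its square
#' remains).
#'
#' @param response response column name (left on its own scale).
#' @param terms character vector of predictor column names.
#' @param transforms named character vector (subset of `terms`).
#' @param degrees named integer vector of polynomial degrees (subset of
#'   `terms`; default 1 everywhere).
#' @param standardize logical; z-score every design column (default `TRUE`),
#'   making fitted coefficients standardized effect sizes.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response, terms, transforms = NULL, degrees = NULL,
                       standardize = TRUE) {
  tr <- stats::setNames(rep("none", length(terms)), terms)
  if (!is.null(transforms)) {
    bad <- setdiff(names(transforms), terms)
    if (length(bad)) stop("transform on unlisted term: ",
                          paste(bad, collapse = ", "))
    stopifnot(all(transforms %in% c("none", "log1p", "log1p_abs")))
    tr[names(transforms)] <- transforms
  }
  dg <- stats::setNames(rep(1L, length(terms)), terms)
  if (!is.null(degrees)) {
    bad <- setdiff(names(degrees), terms)
    if (length(bad)) stop("degree on unlisted term: ",
                          paste(bad, collapse = ", "))
    if (any(degrees < 1)) stop("degree must be >= 1")
    dg[names(degrees)] <- as.integer(degrees)
  }
  structure(list(response = response, terms = terms, transforms = tr,
                 degrees = dg, standardize = standardize),
            class = "model_spec")
}

apply_transform <- function(x, how) {
  switch(how,
         none = x,
         log1p = {
           if (any(x < -1, na.rm = TRUE))
             stop("log1p transform on values below -1")
           log1p(x)
         },
         log1p_abs = log1p(abs(x)),
         stop("unknown transform: ", how))
}

#' Build the design matrix of a model specification
#'
#' Applies the per-term transforms, centres each base column, raises centred
#' bases to the polynomial powers, and (when `spec$standardize`) scales every
#' resulting column to mean 0 / SD 1. Column `term` holds degree 1,
#' `term^2` holds the square of the centred base, and so on. Rows with any
#' missing value among the used columns (or the response) are dropped
#' (complete-case fitting).
#'
#' @param table cell-level data.frame.
#' @param spec a [model_spec()].
#' @return list with `X` (design matrix without intercept), `y`, `rows`
#'   (logical keep mask into `table`), `centers`, `scales` (per design
#'   column; scale 1 when not standardizing).
#' @export
design_matrix <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  used <- c(spec$response, spec$terms)
  miss <- setdiff(used, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  rows <- stats::complete.cases(table[used])
  dat <- table[rows, , drop = FALSE]
  cols <- list(); centers <- c(); scales <- c()
  for (tm in spec$terms) {
    x <- apply_transform(dat[[tm]], spec$transforms[[tm]])
    xc <- x - mean(x)
    for (d in seq_len(spec$degrees[[tm]])) {
      nm <- if (d == 1L) tm else paste0(tm, "^", d)
      col <- xc^d
      cen <- mean(col)
      scl <- if (spec$standardize) stats::sd(col) else 1
      if (spec$standardize) {
        if (scl == 0) stop("constant design column: ", nm)
        col <- (col - cen) / scl
      }
      cols[[nm]] <- col
      centers[nm] <- if (spec$standardize) cen + mean(x) * (d == 1L) else 0
      scales[nm] <- scl
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, y = dat[[spec$response]], rows = rows,
       centers = centers, scales = scales)
}

# Gaussian AIC without the additive constant: n log(RSS/n) + 2 (k + 1),
# k = number of coefficients excluding the intercept. Only differences
# matter for selection.
aic_gaussian <- function(rss, n, k) n * log(rss / n) + 2 * (k + 1)

#' Ordinary least squares fit of a model specification
#'
#' Fits the response (on its own scale) on the standardized design of
#' [design_matrix()]. Coefficients on the standardized columns are directly
#' comparable effect sizes; raw-scale coefficients for the constructed
#' columns are recovered by back-scaling (`beta_raw = beta_std / sd(col)`).
#'
#' @param table cell-level data.frame.
#' @param spec a [model_spec()].
#' @return an object of class `ols_fit`: list with `coefficients` (matrix:
#'   estimate, se, t, p on the design scale, intercept first),
#'   `raw_coefficients`, `residuals`, `fitted`, `r_squared`, `aic`, `n`,
#'   `spec`, `design` (the [design_matrix()] result).
#' @export
ols_fit <- function(table, spec) {
  dm <- design_matrix(table, spec)
  n <- length(dm$y); k <- ncol(dm$X)
  if (n < k + 2L) stop("need at least terms + 2 complete cases")
  df <- data.frame(.y = dm$y, dm$X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    stop("singular design; offending column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  # noiseless fixtures legitimately produce perfect fits
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- sm$coefficients
  colnames(co) <- c("estimate", "se", "t", "p")
  raw <- co[, "estimate"] / c(1, dm$scales)
  raw[1L] <- co[1L, "estimate"] -
    sum(co[-1L, "estimate"] * dm$centers / dm$scales)
  rss <- sum(stats::residuals(fit)^2)
  structure(list(coefficients = co, raw_coefficients = raw,
                 residuals = unname(stats::residuals(fit)),
                 fitted = unname(stats::fitted(fit)),
                 r_squared = sm$r.squared,
                 aic = aic_gaussian(rss, n, k),
                 n = n, spec = spec, design = dm),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, R2 = %.4f, AIC = %.2f\n",
              x$n, x$r_squared, x$aic))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

# droppable unit per term: its highest remaining polynomial degree
reduce_spec <- function(spec, term) {
  if (spec$degrees[[term]] > 1L) {
    spec$degrees[[term]] <- spec$degrees[[term]] - 1L
  } else {
    keep <- setdiff(spec$terms, term)
    if (!length(keep)) return(NULL)
    spec <- model_spec(spec$response, keep,
                       transforms = spec$transforms[keep],
                       degrees = spec$degrees[keep],
                       standardize = spec$standardize)
  }
  spec
}

#' Backward model selection by AIC
#'
#' Starting from the full model, repeatedly drops the single removable unit
#' whose removal lowers AIC the most, and stops when no removal lowers AIC.
#' Removable units respect the polynomial hierarchy: a term's highest
#' remaining power goes first, and a base column is never dropped while a
#' higher power of it remains. AIC is the Gaussian form
#' `n log(RSS / n) + 2 (k + 1)`.
#'
#' @param table cell-level data.frame.
#' @param spec the full-model [model_spec()].
#' @param trace logical; print the selection path.
#' @return the selected model's [ols_fit()], with the drop sequence in
#'   `$selection_path`.
#' @export
aic_backward <- function(table, spec, trace = FALSE) {
  fit <- ols_fit(table, spec)
  path <- character()
  repeat {
    cand <- spec$terms
    if (!length(cand)) break
    trials <- lapply(cand, function(tm) {
      sp <- reduce_spec(spec, tm)
      if (is.null(sp)) return(NULL)
      label <- if (spec$degrees[[tm]] > 1L)
        paste0(tm, "^", spec$degrees[[tm]]) else tm
      list(label = label, spec = sp, aic = ols_fit(table, sp)$aic)
    })
    trials <- Filter(Negate(is.null), trials)
    if (!length(trials)) break
    aics <- vapply(trials, `[[`, numeric(1), "aic")
    best <- which.min(aics)
    if (aics[best] >= fit$aic) break
    spec <- trials[[best]]$spec
    path <- c(path, trials[[best]]$label)
    if (trace) message("drop ", trials[[best]]$label,
                       " -> AIC ", round(aics[best], 3))
    fit <- ols_fit(table, spec)
  }
  fit$selection_path <- path
  fit
}

#' Partial residuals of a fitted term
#'
#' `residuals + coefficient(term) * design_column(term)`, on the
#' (standardized) design scale used in the fit. The slope of the partial
#' residuals regressed on the term equals the fitted coefficient.
#'
#' @param fit an [ols_fit()].
#' @param term a design column name (e.g. `"PREC_SEAS"` or `"PREC_SEAS^2"`).
#' @return numeric vector, one value per fitted cell.
#' @export
partial_residuals <- function(fit, term) {
  stopifnot(inherits(fit, "ols_fit"))
  if (!term %in% colnames(fit$design$X)) stop("unknown term: ", term)
  fit$residuals + fit$coefficients[term, "estimate"] * fit$design$X[, term]
}
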