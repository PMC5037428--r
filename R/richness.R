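#' Fit a surface range envelope (bioclimatic envelope) model
#'
#' The envelope of a species is the axis-aligned box whose sides are the
#' empirical `q` and `1 - q` quantiles of the predictor values at the
#' training presences (quantiles use the linear-interpolation rule, R type
#' 7). With `q = 0` the box is the min/max hull and contains every training
#' presence.
#'
#' Species with fewer than 5 records are below the modelling floor: fitting
#' is refused with a condition of class `sre_too_few_records`, and the caller
#' should fall back to the observed records themselves as the species'
#' range.
#'
#' @param presence_values data.frame or matrix, one row per presence record,
#'   one named column per predictor.
#' @param q envelope quantile in `[0, 0.5)`; default 0.025.
#' @return an object of class `sre_model`: list with `bounds` (matrix with
#'   rows `lower`/`upper`, one column per predictor) and `q`.
#' @export
fit_sre <- function(presence_values, q = 0.025) {
  pv <- as.matrix(presence_values)
  if (is.null(colnames(pv))) stop("presence_values must have named columns")
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q >= 0.5)
    stop("q must lie in [0, 0.5)")
  if (nrow(pv) < 5L) {
    stop(structure(
      class = c("sre_too_few_records", "error", "condition"),
      list(message = sprintf(
        "only %d records (< 5): use the observed records as the range",
        nrow(pv)),
        call = sys.call(-1))))
  }
  bounds <- apply(pv, 2L, stats::quantile, probs = c(q, 1 - q),
                  type = 7, names = FALSE)
  rownames(bounds) <- c("lower", "upper")
  structure(list(bounds = bounds, q = q), class = "sre_model")
}

#' @export
print.sre_model <- function(x, ...) {
  cat(sprintf("surface range envelope (q = %g) on %d predictors\n",
              x$q, ncol(x$bounds)))
  print(x$bounds)
  invisible(x)
}

#' Predict a binary range map from an envelope model
#'
#' A cell is predicted present (1) iff every predictor value lies inside the
#' model's bounds, inclusive on both sides; cells missing any predictor are
#' missing in the output.
#'
#' @param model an [sre_model][fit_sre()], or a list with a `bounds` element
#'   of the same shape.
#' @param predictors named list of [surface()]s covering every predictor the
#'   model was fitted on.
#' @return a binary (0/1) [surface()].
#' @export
predict_sre <- function(model, predictors) {
  b <- model$bounds
  miss <- setdiff(colnames(b), names(predictors))
  if (length(miss))
    stop("missing predictor surface(s): ", paste(miss, collapse = ", "))
  ref <- predictors[[colnames(b)[1L]]]
  inside <- matrix(TRUE, nrow(ref$values), ncol(ref$values))
  anyna <- matrix(FALSE, nrow(ref$values), ncol(ref$values))
  for (nm in colnames(b)) {
    v <- predictors[[nm]]$values
    anyna <- anyna | is.na(v)
    ok <- v >= b["lower", nm] & v <= b["upper", nm]
    ok[is.na(ok)] <- FALSE
    inside <- inside & ok
  }
  out <- ifelse(anyna, NA_real_, as.double(inside))
  surface(ref$grid, matrix(out, nrow(ref$values), ncol(ref$values)))
}

#' Evaluate a binary prediction against presence/absence labels
#'
#' Returns sensitivity, specificity, the True Skill Statistic
#' `TSS = sensitivity + specificity - 1`, and AUC. AUC uses the rank
#' (Mann-Whitney) statistic over a continuous `score` when one is supplied,
#' otherwise over the binary prediction itself (ties mid-ranked).
#'
#' @param pred 0/1 predictions.
#' @param truth 0/1 labels; both classes must be present.
#' @param score optional continuous suitability score for AUC.
#' @return list with `sensitivity`, `specificity`, `tss`, `auc` and the
#'   confusion counts `tp`, `fn`, `tn`, `fp`.
#' @export
evaluate_binary <- function(pred, truth, score = NULL) {
  keep <- !(is.na(pred) | is.na(truth))
  pred <- as.numeric(pred[keep]); truth <- as.numeric(truth[keep])
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("pred and truth must be 0/1")
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("truth must contain both classes")
  tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0); fp <- sum(pred == 1 & truth == 0)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  sc <- if (is.null(score)) pred else as.numeric(score[keep])
  r <- rank(sc)
  auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1,
       auc = auc, tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Stack binary range maps into a richness surface
#'
#' Overlays modelled binary ranges (and, for species below the modelling
#' floor, their observed records) onto the coarse analysis grid: a species
#' contributes 1 to a coarse cell iff at least one fine cell of its range or
#' record set falls inside that coarse cell; richness is the sum over
#' species.
#'
#' @param ranges list of binary [surface()]s on the fine grid (one per
#'   modelled species).
#' @param observed_only list of integer vectors of 0-based fine cell ids (one
#'   per unmodelled species); default none.
#' @param fine the fine [lattice_grid()].
#' @param factor aggregation factor to the coarse grid.
#' @return a [surface()] of species counts on the coarse grid.
#' @export
stack_richness <- function(ranges, observed_only = list(), fine, factor) {
  stopifnot(inherits(fine, "lattice_grid"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  cg <- aggregate_grid(fine, factor)
  rich <- matrix(0, cg$n_rows, cg$n_cols)
  block_any <- function(m) {
    block_reduce(m, factor, function(x) as.double(any(x > 0, na.rm = TRUE)))
  }
  for (s in ranges) {
    stopifnot(inherits(s, "surface"))
    if (!identical(dim(s$values), c(fine$n_rows, fine$n_cols)))
      stop("range map not on the fine grid")
    rich <- rich + block_any(s$values)
  }
  for (cells in observed_only) {
    m <- matrix(0, fine$n_rows, fine$n_cols)
    rc <- cell_to_rowcol(fine, cells)
    m[cbind(rc[, "row"] + 1L, rc[, "col"] + 1L)] <- 1
    rich <- rich + block_any(m)
  }
  surface(cg, rich)
}

#' Consensus of two binary range maps
#'
#' Cellwise intersection: present only where both maps predict presence.
#' Used when two models of the same species are indistinguishable on
#' evaluation statistics.
#'
#' @param a,b binary [surface()]s on the same grid.
#' @return a binary [surface()].
#' @export
consensus_range <- function(a, b) {
  stopifnot(inherits(a, "surface"), inherits(b, "surface"))
  if (!identical(dim(a$values), dim(b$values)))
    stop("maps must share a grid")
  surface(a$grid, (a$values > 0) * (b$values > 0))
}
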