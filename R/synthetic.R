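#' Synthetic landscape generator
#'
#' Builds a self-contained study region with the qualitative geography the
#' dispersal scenarios need: a contiguous ocean margin, two colonization
#' origins on the eastern edge of the land mass, a transverse desert band of
#' zero suitability that blocks straight-line spread from the origins to the
#' western part of the domain, one or two arid-corridor bands threading the
#' gaps in that desert and connecting the origins' side to the far side, a
#' low-suitability rainforest block, smooth climate gradients with seeded
#' Gaussian noise, a topography layer with localized high-relief patches, and
#' two paleoclimate realizations per variable for anomaly construction.
#'
#' All randomness is controlled by `seed`; the same seed reproduces the same
#' bundle exactly. Region masks are disjoint by construction (corridor rows
#' are carved out of the desert band).
#'
#' @param seed integer seed.
#' @param n_rows,n_cols fine-grid dimensions (each >= 20).
#' @param cell_size fine cell edge in km (default 10, the conventional
#'   simulation resolution).
#' @param border ocean margin width in cells.
#' @param noise_sd standard deviation of the Gaussian noise added to every
#'   climate surface, on that surface's own scale relative to a gradient
#'   range of order 10.
#' @return an object of class `landscape`: a list with elements `grid`
#'   ([lattice_grid()]), `masks` (logical matrices `desert`, `forest`,
#'   `corridor`), `climate` (surfaces `temp_max`, `temp_min`, `prec`,
#'   `prec_dry`, `prec_seas`), `topo` (surface), `origins` (0-based cell
#'   ids), and `paleo` (per-variable lists of past-climate surfaces).
#' @export
make_landscape <- function(seed = 1, n_rows = 120, n_cols = 100,
                           cell_size = 10, border = 3, noise_sd = 0.8) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 20L || n_cols < 20L)
    stop("domain too small to place desert, forest and corridors (need >= 20)")
  with_seed(seed, {
    # land mask: ocean frame, fuzzy coast ring, solid interior
    lf <- matrix(1, n_rows, n_cols)
    if (border > 0) {
      lf[c(seq_len(border), n_rows - seq_len(border) + 1L), ] <- 0
      lf[, c(seq_len(border), n_cols - seq_len(border) + 1L)] <- 0
    }
    coast <- border + 1L
    ring <- matrix(FALSE, n_rows, n_cols)
    ring[coast, coast:(n_cols - coast + 1L)] <- TRUE
    ring[n_rows - coast + 1L, coast:(n_cols - coast + 1L)] <- TRUE
    ring[coast:(n_rows - coast + 1L), coast] <- TRUE
    ring[coast:(n_rows - coast + 1L), n_cols - coast + 1L] <- TRUE
    lf[ring] <- stats::runif(sum(ring), 0.2, 1)

    rows <- function(a, b) seq(max(1L, round(a * n_rows)), round(b * n_rows))
    cols <- function(a, b) seq(max(1L, round(a * n_cols)), round(b * n_cols))
    land <- lf > 0

    # The geography is built so the four scenarios order the landscape
    # differently, not just at different speeds. A transverse desert close
    # to the origins leaves a large far (western) side whose single
    # crossing is a southern gap; the arid corridor runs through that gap
    # and then up the whole west coast (an L-shaped route). Open-land
    # spread therefore orders the west by distance from the southern gap,
    # while corridor-biased spread orders it by distance from the coastal
    # corridor -- reversing ranks in the north-west. The rainforest block
    # sits in the mid-western interior, directly in the path of the
    # gap-to-north fill, warping forest-averse scenarios only.
    gap_south <- rows(0.86, 0.92)
    desert <- matrix(FALSE, n_rows, n_cols)
    desert[, cols(0.62, 0.80)] <- TRUE
    desert[gap_south, ] <- FALSE

    # corridor: the southern crossing, then a ring along the west coast
    # and the northern edge of the far side -- so corridor-biased spread
    # arrives from the whole perimeter while open-land spread radiates
    # from the southern gap alone
    corridor <- matrix(FALSE, n_rows, n_cols)
    corridor[gap_south, ] <- TRUE
    corridor[, cols(0.04, 0.10)] <- TRUE
    corridor[rows(0.03, 0.09), cols(0.04, 0.61)] <- TRUE

    # rainforest block over the mid-western interior, abutting the coastal
    # corridor so no open strip shadows the corridor route: forest-averse
    # spread must detour east of the forest, corridor-biased spread hugs
    # the coast, and the two enter the northern plains from opposite ends
    forest <- matrix(FALSE, n_rows, n_cols)
    forest[rows(0.20, 0.78), cols(0.11, 0.50)] <- TRUE
    forest[desert | corridor] <- FALSE

    corridor[desert] <- FALSE
    desert[!land] <- FALSE; forest[!land] <- FALSE; corridor[!land] <- FALSE

    grid <- lattice_grid(n_rows, n_cols, cell_size = cell_size,
                         land_fraction = lf)

    # origins on the eastern land edge: a northern entry point and a
    # southern one near the gap latitude
    east <- n_cols - border - 1L
    origins <- rowcol_to_cell(grid,
                              c(rows(0.10, 0.10), gap_south[1L]) - 1L,
                              c(east, east) - 1L)

    ri <- matrix(seq_len(n_rows), n_rows, n_cols) / n_rows
    ci <- matrix(rep(seq_len(n_cols), each = n_rows), n_rows, n_cols) / n_cols
    noise <- function(sd = noise_sd) matrix(stats::rnorm(n_rows * n_cols,
                                                         sd = sd),
                                            n_rows, n_cols)
    onland <- function(m) { m[!land] <- NA_real_; surface(grid, m) }
    bump <- function(r0, c0, width, amp) {
      amp * exp(-((ri - r0)^2 + (ci - c0)^2) / (2 * width^2))
    }

    # geography of the climate: hottest over the desert band, wettest over
    # the forest block, latitudinal gradients elsewhere
    desert_ctr <- c(0.5, 0.71); forest_ctr <- c(0.49, 0.30)
    climate <- list(
      temp_max = onland(25 + 10 * (1 - ri) +
                          6 * bump(desert_ctr[1], desert_ctr[2], 0.12, 1) +
                          noise()),
      temp_min = onland(5 + 8 * ri + noise()),
      prec = onland(800 - 600 * ci +
                      500 * bump(forest_ctr[1], forest_ctr[2], 0.15, 1) -
                      300 * bump(desert_ctr[1], desert_ctr[2], 0.10, 1) +
                      40 * noise()),
      prec_dry = onland(pmax(0, 60 - 50 * ci +
                               30 * bump(forest_ctr[1], forest_ctr[2],
                                         0.15, 1) + 4 * noise())),
      prec_seas = onland(40 + 30 * (ri + ci) / 2 + 3 * noise())
    )

    # topographic relief: low background plus a few localized mountain blocks
    topo_m <- 100 + 30 * abs(noise(1))
    for (k in 1:4) {
      topo_m <- topo_m + bump(stats::runif(1, 0.15, 0.85),
                              stats::runif(1, 0.15, 0.85),
                              stats::runif(1, 0.03, 0.07),
                              stats::runif(1, 800, 1800))
    }
    topo <- onland(topo_m)

    # two paleo realizations per variable (cooler/drier past plus its own
    # smooth field), so anomaly construction can average across simulations
    paleo <- list(
      temp = lapply(1:2, function(k)
        onland(climate$temp_max$values - 4 - 2 * ri + noise(0.5))),
      prec = lapply(1:2, function(k)
        onland(climate$prec$values - 120 + 80 * ci + 20 * noise(0.5)))
    )

    structure(list(grid = grid,
                   masks = list(desert = desert, forest = forest,
                                corridor = corridor),
                   climate = climate, topo = topo, origins = origins,
                   paleo = paleo, seed = seed),
              class = "landscape")
  })
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("synthetic landscape: %d x %d cells, %d origins\n",
              x$grid$n_rows, x$grid$n_cols, length(x$origins)))
  cat(sprintf("  desert %d, forest %d, corridor %d cells\n",
              sum(x$masks$desert), sum(x$masks$forest), sum(x$masks$corridor)))
  invisible(x)
}

#' Response-generation specification
#'
#' Defines the data-generating process for a synthetic richness response:
#' `y = intercept + X beta + u`, with `X` the z-scored predictor columns
#' named by `coefficients` and `u` either i.i.d. normal errors or
#' SAR-correlated errors `u = lambda W u + eps`, i.e.
#' `u = (I - lambda W)^{-1} eps`.
#'
#' @param coefficients named numeric vector of effect sizes on standardized
#'   predictors.
#' @param error_model `"iid"` or `"sar"`.
#' @param lambda spatial error coefficient, strictly inside (-1, 1) when
#'   `error_model = "sar"`.
#' @param sigma standard deviation of the innovations `eps`.
#' @param intercept baseline response level.
#' @param seed integer seed.
#' @return an object of class `response_spec`.
#' @export
response_spec <- function(coefficients, error_model = c("iid", "sar"),
                          lambda = 0, sigma = 1, intercept = 0, seed = 1) {
  error_model <- match.arg(error_model)
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    stop("coefficients must be a named vector")
  if (error_model == "sar" && abs(lambda) >= 1)
    stop("lambda must lie strictly inside (-1, 1)")
  structure(list(coefficients = coefficients, error_model = error_model,
                 lambda = lambda, sigma = sigma, intercept = intercept,
                 seed = as.integer(seed)),
            class = "response_spec")
}

#' Generate a synthetic richness response
#'
#' @param table data.frame of cell-level predictors (one row per cell).
#' @param spec a [response_spec()]; its coefficient names must be columns of
#'   `table`.
#' @param weights a row-standardized [spatial weights][knn_neighbors()]
#'   object, required when `spec$error_model == "sar"`.
#' @return numeric response vector, one value per row of `table`;
#'   deterministic given `spec$seed`.
#' @export
make_richness_response <- function(table, spec, weights = NULL) {
  stopifnot(inherits(spec, "response_spec"))
  nm <- names(spec$coefficients)
  missing_cols <- setdiff(nm, names(table))
  if (length(missing_cols))
    stop("unknown coefficient name(s): ", paste(missing_cols, collapse = ", "))
  X <- scale(as.matrix(table[nm]))
  mu <- spec$intercept + drop(X %*% spec$coefficients)
  n <- nrow(table)
  with_seed(spec$seed, {
    eps <- stats::rnorm(n, sd = spec$sigma)
    u <- if (spec$error_model == "iid" || spec$lambda == 0) {
      eps
    } else {
      if (is.null(weights)) stop("SAR errors require a weights object")
      if (!isTRUE(weights$row_standardized))
        stop("weights must be row-standardized for SAR errors")
      if (weights$n != n) stop("weights dimension does not match table")
      W <- weights_matrix(weights, sparse = TRUE)
      as.vector(Matrix::solve(Matrix::Diagonal(n) - spec$lambda * W, eps))
    }
    mu + u
  })
}

#' Sample occurrence records inside an envelope's true range
#'
#' Draws `n_points` fine-grid cells uniformly without replacement from the
#' set of land cells where every predictor lies inside the envelope bounds
#' (the species' "true range"), one record per cell -- i.e. records are
#' spatially unique at the fine resolution.
#'
#' @param envelope an [sre_model()][fit_sre()] (or any object accepted by
#'   [predict_sre()]).
#' @param n_points number of records to draw.
#' @param seed integer seed.
#' @param landscape a [make_landscape()] bundle supplying the predictor
#'   surfaces (`climate` layers).
#' @return list with `cells` (0-based fine cell ids), `xy` (cell-centre
#'   coordinates) and `true_range` (all cell ids inside the envelope).
#' @export
make_occurrences <- function(envelope, n_points, seed, landscape) {
  pred <- predict_sre(envelope, landscape$climate)
  vals <- surface_values_by_id(pred)
  true_range <- which(!is.na(vals) & vals == 1) - 1L
  if (!length(true_range)) stop("envelope's true range is empty")
  if (n_points > length(true_range))
    stop("n_points exceeds the true-range size (", length(true_range), ")")
  cells <- with_seed(seed, sort(sample(true_range, n_points)))
  list(cells = cells, xy = cell_centers(landscape$grid, cells),
       true_range = true_range)
}
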