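#' Dispersal scenario definitions
#'
#' The four canonical colonization scenarios differ only in how per-cell
#' suitability `s` (the Bernoulli colonization/persistence probability of the
#' spread model) is assigned from region masks:
#'
#' * `DISP1` -- no barriers: all land `s = 1` (a null pattern);
#' * `DISP2` -- desert a full barrier (`s = 0`), all other land `s = 1`;
#' * `DISP3` -- as DISP2, plus rainforest at low suitability (`s = 0.2`);
#' * `DISP4` -- as DISP3, plus arid corridors at high suitability (`s = 1`)
#'   and all remaining land at intermediate suitability (`s = 0.5`).
#'
#' Region precedence when masks overlap is desert > forest > corridor >
#' default.
#'
#' @param id one of `"DISP1"`, `"DISP2"`, `"DISP3"`, `"DISP4"`, or a custom
#'   id when `region_s`/`default_s` are supplied.
#' @param region_s named numeric vector mapping region names (subset of
#'   `desert`, `forest`, `corridor`) to suitabilities in `[0, 1]`.
#' @param default_s suitability of land cells in no region.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(id, region_s = NULL, default_s = NULL) {
  presets <- list(
    DISP1 = list(region_s = c(desert = 1, forest = 1, corridor = 1),
                 default_s = 1),
    DISP2 = list(region_s = c(desert = 0, forest = 1, corridor = 1),
                 default_s = 1),
    DISP3 = list(region_s = c(desert = 0, forest = 0.2, corridor = 1),
                 default_s = 1),
    DISP4 = list(region_s = c(desert = 0, forest = 0.2, corridor = 1),
                 default_s = 0.5))
  if (is.null(region_s) && is.null(default_s)) {
    if (!id %in% names(presets)) stop("unknown scenario id: ", id)
    region_s <- presets[[id]]$region_s
    default_s <- presets[[id]]$default_s
  }
  if (any(region_s < 0 | region_s > 1) || default_s < 0 || default_s > 1)
    stop("suitabilities must lie in [0, 1]")
  structure(list(id = id, region_s = region_s, default_s = default_s),
            class = "scenario_spec")
}

#' Build a scenario suitability map
#'
#' Assigns per-cell suitability from region masks under the fixed precedence
#' desert > forest > corridor > default. Sea cells (zero land fraction) are
#' missing regardless of scenario.
#'
#' @param scenario a [scenario_spec()] or a scenario id string.
#' @param masks named list of logical `n_rows x n_cols` matrices (any of
#'   `desert`, `forest`, `corridor`); missing masks are treated as empty.
#' @param land a [lattice_grid()] whose `land_fraction` defines the land
#'   domain (cells with `land_fraction > 0`).
#' @return a [surface()] with values in `[0, 1]` on land and `NA` at sea.
#' @export
build_suitability <- function(scenario, masks, land) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  stopifnot(inherits(scenario, "scenario_spec"), inherits(land, "lattice_grid"))
  dims <- c(land$n_rows, land$n_cols)
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), dims))
      stop("mask '", nm, "' is not on the land grid")
  }
  empty <- matrix(FALSE, dims[1], dims[2])
  getm <- function(nm) if (is.null(masks[[nm]])) empty else masks[[nm]]
  rs <- scenario$region_s
  sval <- function(nm) if (nm %in% names(rs)) rs[[nm]] else scenario$default_s
  s <- matrix(scenario$default_s, dims[1], dims[2])
  # ascending precedence so the strongest region wins
  s[getm("corridor")] <- sval("corridor")
  s[getm("forest")] <- sval("forest")
  s[getm("desert")] <- sval("desert")
  s[!(land$land_fraction > 0)] <- NA_real_
  surface(land, s)
}

#' One stochastic spread step
#'
#' Advances a binary occupancy surface by one iteration of the 3x3-cell
#' spread model: a cell is occupied at `t + 1` iff at least one cell of its
#' 3x3 neighbourhood (the 8 neighbours plus itself, truncated at grid edges)
#' was occupied at `t` and an independent Bernoulli(`s`) trial for the cell
#' succeeds. An occupied cell with `s < 1` can therefore go locally extinct.
#' Uses R's global random number generator.
#'
#' @param occupancy a [surface()] of 0/1 (or logical) occupancy; occupied
#'   cells must have defined suitability.
#' @param s a [suitability surface][build_suitability()] on the same grid.
#' @return a 0/1 occupancy [surface()] (missing where `s` is missing).
#' @export
spread_step <- function(occupancy, s) {
  stopifnot(inherits(occupancy, "surface"), inherits(s, "surface"))
  if (!identical(dim(occupancy$values), dim(s$values)))
    stop("occupancy and s must be on the same grid")
  occ <- occupancy$values
  occ[is.na(occ)] <- 0
  nxt <- cpp_spread_step(occ > 0, s$values)
  out <- matrix(as.double(nxt), nrow(occ), ncol(occ))
  out[is.na(s$values)] <- NA_real_
  surface(s$grid, out)
}

#' Spread simulation configuration
#'
#' @param iterations number of spread iterations `T` (>= 1). The convention
#'   is to use the minimum number of iterations that lets the spread traverse
#'   the whole study region under the scenario.
#' @param replicates number of stochastic replicates averaged (>= 1).
#' @param seed integer seed making the simulation reproducible.
#' @return an object of class `spread_config`.
#' @export
spread_config <- function(iterations, replicates = 10, seed = 1) {
  iterations <- as.integer(iterations); replicates <- as.integer(replicates)
  if (is.na(iterations) || iterations < 1L) stop("iterations must be >= 1")
  if (is.na(replicates) || replicates < 1L) stop("replicates must be >= 1")
  structure(list(iterations = iterations, replicates = replicates,
                 seed = as.integer(seed)),
            class = "spread_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate accessibility from colonization origins
#'
#' Runs `replicates` independent spread simulations of `iterations` steps
#' from the origin set (origins occupied unconditionally at `t = 0` and
#' exempt from local extinction -- they model an external source pool) and
#' summarizes, per cell, how early the cell was first colonized: a replicate
#' scores `a(c) = (T + 1 - t_first(c)) / (T + 1)` with `t_first` the first
#' iteration at which `c` is occupied (0 for origins), and 0 if never.
#' Accessibility is the mean of `a(c)` over replicates, so it is 1 on
#' origins, 0 exactly on cells never colonized in any replicate, and
#' decreases with colonization lag.
#'
#' @param s a suitability [surface()] (values in `[0, 1]` on land, `NA` at
#'   sea); see [build_suitability()].
#' @param origins integer vector of 0-based row-major cell ids with defined
#'   suitability; nonempty.
#' @param config a [spread_config()].
#' @return an accessibility [surface()] with values in `[0, 1]` (`NA` where
#'   `s` is missing).
#' @export
simulate_accessibility <- function(s, origins, config) {
  stopifnot(inherits(s, "surface"), inherits(config, "spread_config"))
  origins <- as.integer(origins)
  if (!length(origins)) stop("empty origin set")
  g <- s$grid
  rc <- cell_to_rowcol(g, origins)
  # 0-based column-major index for the C++ kernel
  cm <- rc[, "row"] + rc[, "col"] * g$n_rows
  sv <- s$values
  if (any(is.na(sv[cm + 1L]))) stop("origin on a cell with missing suitability")
  n_iter <- config$iterations
  acc <- matrix(0, g$n_rows, g$n_cols)
  with_seed(config$seed, {
    for (r in seq_len(config$replicates)) {
      tf <- cpp_first_occurrence(sv, cm, n_iter)
      a <- (n_iter + 1 - tf) / (n_iter + 1)
      a[is.na(tf)] <- 0
      acc <- acc + a
    }
  })
  acc <- acc / config$replicates
  acc[is.na(sv)] <- NA_real_
  surface(g, acc)
}

#' Run the four-scenario accessibility battery
#'
#' Builds the four scenario suitability maps from a landscape's region masks,
#' simulates accessibility for each on the fine grid, and aggregates each
#' accessibility surface to the coarse analysis grid by [zonal_mean()].
#'
#' @param landscape a landscape bundle from [make_landscape()], or any list
#'   with elements `grid` ([lattice_grid()]), `masks` (list of logical
#'   matrices) and `origins` (0-based cell ids).
#' @param factor aggregation factor from the fine simulation grid to the
#'   coarse richness grid.
#' @param iterations named vector of per-scenario iteration counts; by
#'   convention the minimum needed to traverse the region, larger for DISP4
#'   whose intermediate suitability slows the spread.
#' @param replicates stochastic replicates per scenario.
#' @param seed integer; scenario k uses `seed + k`.
#' @param scenarios character vector of scenario ids to run.
#' @return named list of coarse accessibility [surface()]s.
#' @export
scenario_battery <- function(landscape, factor = 10,
                             iterations = c(DISP1 = 700, DISP2 = 700,
                                            DISP3 = 700, DISP4 = 1000),
                             replicates = 10, seed = 1,
                             scenarios = c("DISP1", "DISP2", "DISP3", "DISP4")) {
  out <- list()
  for (k in seq_along(scenarios)) {
    sc <- scenarios[k]
    if (!sc %in% names(iterations)) stop("no iteration count for ", sc)
    s <- build_suitability(sc, landscape$masks, landscape$grid)
    cfg <- spread_config(iterations[[sc]], replicates, seed + k)
    acc <- simulate_accessibility(s, landscape$origins, cfg)
    out[[sc]] <- zonal_mean(acc, factor)
  }
  out
}
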