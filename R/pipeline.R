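#' Assemble the coarse cell-level predictor table
#'
#' Glue between the raster stages and the regression stage: aggregates the
#' landscape's climate, topography and paleo-anomaly layers to the coarse
#' analysis grid by [zonal_mean()], joins the scenario accessibility
#' surfaces, and restricts to analysis cells (coarse cells with more than
#' `land_threshold` land). Anomalies are contemporary minus paleo (the mean
#' across the paleo realizations of each variable).
#'
#' @param landscape a [make_landscape()] bundle.
#' @param battery named list of coarse accessibility surfaces from
#'   [scenario_battery()] (may be `NULL` to omit).
#' @param factor aggregation factor fine -> coarse.
#' @param land_threshold land-fraction cut for analysis cells (strict
#'   inequality; default 0.5).
#' @return data.frame with `cell_id`, `row`, `col`, `x`, `y`,
#'   `land_fraction`, the scenario columns, `TEMP_MAX`, `TEMP_MIN`, `PREC`,
#'   `PREC_DRY`, `PREC_SEAS`, `TOPO`, `PALEO_TEMP`, `PALEO_PREC`; one row
#'   per analysis cell.
#' @export
assemble_predictor_table <- function(landscape, battery = NULL, factor = 10,
                                     land_threshold = 0.5) {
  g <- landscape$grid
  agg <- function(s) zonal_mean(s, factor)
  coarse <- list(
    TEMP_MAX = agg(landscape$climate$temp_max),
    TEMP_MIN = agg(landscape$climate$temp_min),
    PREC = agg(landscape$climate$prec),
    PREC_DRY = agg(landscape$climate$prec_dry),
    PREC_SEAS = agg(landscape$climate$prec_seas),
    TOPO = agg(landscape$topo),
    PALEO_TEMP = agg(climate_anomaly(landscape$climate$temp_max,
                                     landscape$paleo$temp)),
    PALEO_PREC = agg(climate_anomaly(landscape$climate$prec,
                                     landscape$paleo$prec))
  )
  if (!is.null(battery)) coarse <- c(battery, coarse)
  cg <- coarse[[1L]]$grid
  tab <- export_cell_table(cg, coarse)
  keep_ids <- land_filter(cg, land_threshold)
  tab[tab$cell_id %in% keep_ids, , drop = FALSE]
}
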