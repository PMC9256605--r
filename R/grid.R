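#' Gridded multi-model projection ensemble
#'
#' Container for a stack of lat/lon fields indexed by model run and year, with
#' a land/ocean mask. Values hold one variable (total consumer biomass density
#' for the fisheries sector, or rain-fed crop yield for a crop) for one
#' scenario, covering both the historical window and the projection years.
#'
#' @param lat,lon Strictly monotone increasing coordinate vectors, decimal
#'   degrees (cell centers, regular spacing).
#' @param mask Integer/logical matrix `length(lat)` x `length(lon)`;
#'   1/TRUE = land, 0/FALSE = ocean.
#' @param values 4-D numeric array `(run, year, lat, lon)`.
#' @param years Integer vector of years along dim 2.
#' @param runs Data frame of run metadata with at least `run_id`; typically
#'   also `impact_model` and `forcing`.
#' @param scenario Scenario label, e.g. `"ssp585"`.
#' @param sector `"fisheries"` or a crop name.
#' @param units Units string for `values`.
#' @return Object of class `grid_ensemble`.
#' @export
grid_ensemble <- function(lat, lon, mask, values, years, runs,
                          scenario = "historical", sector = "fisheries",
                          units = "") {
  stopifnot(is.numeric(lat), is.numeric(lon))
  if (any(diff(lat) <= 0) || any(diff(lon) <= 0))
    stop("lat and lon must be strictly increasing")
  mask <- matrix(as.integer(mask), length(lat), length(lon))
  dv <- dim(values)
  if (length(dv) != 4L || dv[3] != length(lat) || dv[4] != length(lon))
    stop("`values` must be a (run, year, lat, lon) array matching coordinates")
  if (dv[2] != length(years)) stop("`years` must match dim 2 of `values`")
  if (dv[1] != nrow(runs)) stop("`runs` must have one row per run")
  structure(list(lat = lat, lon = lon, mask = mask, values = values,
                 years = as.integer(years), runs = runs,
                 scenario = scenario, sector = sector, units = units),
            class = "grid_ensemble")
}

#' @export
print.grid_ensemble <- function(x, ...) {
  cat(sprintf("<grid_ensemble> %s / %s: %d runs, %d years (%d-%d), %d x %d cells (%.2f deg)\n",
              x$sector, x$scenario, dim(x$values)[1], length(x$years),
              min(x$years), max(x$years), length(x$lat), length(x$lon),
              if (length(x$lat) > 1) diff(x$lat[1:2]) else NA_real_))
  cat(sprintf("  land cells: %d, ocean cells: %d, units: %s\n",
              sum(x$mask == 1L), sum(x$mask == 0L), x$units))
  invisible(x)
}

#' Write / read a grid ensemble as NetCDF
#'
#' Writes dims `(lon, lat, year, run)`, a `mask` variable (1 = land,
#' 0 = ocean) and CF-style attributes. Requires the ncdf4 package; for a
#' dependency-free plain-text round trip use [write_grid_csv()].
#'
#' @param grid A [grid_ensemble()].
#' @param path Output file.
#' @return `path` (write) or a `grid_ensemble` (read), invisibly for write.
#' @export
write_grid_ncdf <- function(grid, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the ncdf4 package is required for NetCDF output; use write_grid_csv() instead")
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  dyear <- ncdf4::ncdim_def("year", "year", grid$years)
  drun <- ncdf4::ncdim_def("run", "index", seq_len(nrow(grid$runs)))
  vval <- ncdf4::ncvar_def("value", grid$units, list(dlon, dlat, dyear, drun),
                           missval = NA_real_, prec = "double")
  vmask <- ncdf4::ncvar_def("mask", "1=land 0=ocean", list(dlon, dlat), prec = "integer")
  nc <- ncdf4::nc_create(path, list(vval, vmask))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vval, aperm(grid$values, c(4, 3, 2, 1)))
  ncdf4::ncvar_put(nc, vmask, t(grid$mask))
  ncdf4::ncatt_put(nc, 0, "scenario", grid$scenario)
  ncdf4::ncatt_put(nc, 0, "sector", grid$sector)
  ncdf4::ncatt_put(nc, 0, "run_id", paste(grid$runs$run_id, collapse = ","))
  invisible(path)
}

#' @rdname write_grid_ncdf
#' @export
read_grid_ncdf <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the ncdf4 package is required for NetCDF input")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lat <- as.numeric(nc$dim$lat$vals); lon <- as.numeric(nc$dim$lon$vals)
  years <- as.integer(nc$dim$year$vals)
  vals <- ncdf4::ncvar_get(nc, "value", collapse_degen = FALSE)
  mask <- t(matrix(ncdf4::ncvar_get(nc, "mask"), length(lon), length(lat)))
  run_id <- strsplit(ncdf4::ncatt_get(nc, 0, "run_id")$value, ",")[[1]]
  grid_ensemble(lat, lon, mask, aperm(vals, c(4, 3, 2, 1)), years,
                data.frame(run_id = run_id, stringsAsFactors = FALSE),
                scenario = ncdf4::ncatt_get(nc, 0, "scenario")$value,
                sector = ncdf4::ncatt_get(nc, 0, "sector")$value,
                units = nc$var$value$units)
}

#' Write / read a grid ensemble as long-format CSV
#'
#' Plain-text interchange: one row per (run, year, lat, lon) cell plus a mask
#' column. Large but dependency-free and diffable.
#'
#' @param grid A [grid_ensemble()].
#' @param path Output file.
#' @param scenario,sector,units Metadata to restore on read.
#' @return `path` (write, invisibly) or a `grid_ensemble` (read).
#' @export
write_grid_csv <- function(grid, path) {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  dv <- dim(grid$values)
  df <- data.frame(
    run_id = rep(grid$runs$run_id, times = dv[2] * nlat * nlon),
    year = rep(rep(grid$years, each = dv[1]), times = nlat * nlon),
    lat = rep(rep(grid$lat, each = dv[1] * dv[2]), times = nlon),
    lon = rep(grid$lon, each = dv[1] * dv[2] * nlat),
    mask = rep(as.vector(grid$mask), each = dv[1] * dv[2]),
    value = as.vector(grid$values)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path, scenario = "historical", sector = "fisheries",
                          units = "") {
  df <- utils::read.csv(path)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  years <- sort(unique(df$year)); run_id <- unique(df$run_id)
  o <- order(match(df$lon, lon), match(df$lat, lat),
             match(df$year, years), match(df$run_id, run_id))
  vals <- array(df$value[o], dim = c(length(run_id), length(years),
                                     length(lat), length(lon)))
  msk <- df[!duplicated(df[c("lat", "lon")]), c("lat", "lon", "mask")]
  mask <- matrix(0L, length(lat), length(lon))
  mask[cbind(match(msk$lat, lat), match(msk$lon, lon))] <- msk$mask
  grid_ensemble(lat, lon, mask, vals, years,
                data.frame(run_id = run_id, stringsAsFactors = FALSE),
                scenario = scenario, sector = sector, units = units)
}
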