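#' Great-circle distance (haversine)
#'
#' Distance in kilometres between points on a sphere of radius 6371 km.
#' Vectorized over both arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @examples
#' haversine(0, 0, 0, 1)  # ~111.195 km
#' @export
haversine <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 360)) stop("longitude outside [-360, 360]")
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Nearest ocean cells to a site
#'
#' Orders the ocean-masked cell centers of a grid by haversine distance to the
#' site and returns the `n` nearest. Distance ties are broken by (latitude,
#' longitude) so the selection is deterministic.
#'
#' @param site List or data frame row with `lat`, `lon`.
#' @param grid A [grid_ensemble()].
#' @param n Number of cells (default 20).
#' @return Data frame `lat_idx`, `lon_idx`, `lat`, `lon`, `dist_km`, ordered
#'   nearest first.
#' @export
select_ocean_cells <- function(site, grid, n = 20) {
  if (n < 1L) stop("`n` must be at least 1")
  oc <- which(grid$mask == 0L, arr.ind = TRUE)
  if (nrow(oc) < n)
    stop("grid has only ", nrow(oc), " ocean cells; ", n, " requested")
  clat <- grid$lat[oc[, 1]]
  clon <- grid$lon[oc[, 2]]
  d <- haversine(site$lat, site$lon, clat, clon)
  o <- order(d, clat, clon)[seq_len(n)]
  data.frame(lat_idx = oc[o, 1], lon_idx = oc[o, 2],
             lat = clat[o], lon = clon[o], dist_km = d[o])
}

#' Land cells in a window around a site
#'
#' Takes the `window` x `window` block of cells centered on the cell whose
#' center is nearest (haversine) to the site, clips it at the grid edge, and
#' keeps the land cells.
#'
#' @param site List with `lat`, `lon`.
#' @param grid A [grid_ensemble()].
#' @param window Odd window side length (default 11).
#' @return Data frame `lat_idx`, `lon_idx`, `lat`, `lon`.
#' @export
select_land_window <- function(site, grid, window = 11) {
  if (window %% 2 != 1) stop("`window` must be odd")
  res_lat <- if (length(grid$lat) > 1) diff(grid$lat[1:2]) else 1
  res_lon <- if (length(grid$lon) > 1) diff(grid$lon[1:2]) else 1
  if (site$lat < min(grid$lat) - res_lat / 2 || site$lat > max(grid$lat) + res_lat / 2 ||
      site$lon < min(grid$lon) - res_lon / 2 || site$lon > max(grid$lon) + res_lon / 2)
    stop("site lies outside the grid bounds")
  # nearest cell center; on a regular grid the haversine-nearest center is
  # the one minimizing |dlat| and |dlon| separately (offsets < 180 deg)
  i <- which.min(abs(grid$lat - site$lat))
  j <- which.min(abs(grid$lon - site$lon))
  h <- (window - 1) / 2
  ii <- max(1, i - h):min(length(grid$lat), i + h)
  jj <- max(1, j - h):min(length(grid$lon), j + h)
  sub <- expand.grid(lat_idx = ii, lon_idx = jj)
  land <- grid$mask[cbind(sub$lat_idx, sub$lon_idx)] == 1L
  if (!any(land)) stop("no land cells in the ", window, "x", window, " window")
  sub <- sub[land, ]
  data.frame(lat_idx = sub$lat_idx, lon_idx = sub$lon_idx,
             lat = grid$lat[sub$lat_idx], lon = grid$lon[sub$lon_idx])
}

#' Per-run relative change between a historical and a future window
#'
#' For each model run, averages the field over the selected cells and the
#' years of each window (inclusive), and returns the percent change
#' `100 * (future - historical) / historical`. Runs whose historical mean is
#' at or below `baseline_tol` are returned as `NA` (flagged missing) so they
#' drop out of ensemble aggregation.
#'
#' @param grid A [grid_ensemble()] whose years cover both windows.
#' @param cells Data frame with `lat_idx`, `lon_idx` (from the selectors).
#' @param historical,future Length-2 year ranges, e.g. `c(1983, 2013)`.
#' @param baseline_tol Historical means at or below this are invalid (default
#'   `1e-12`).
#' @return Numeric vector of percent changes, one per run (NA = excluded).
#' @export
run_relative_change <- function(grid, cells, historical = c(1983, 2013),
                                future = c(2046, 2056), baseline_tol = 1e-12) {
  hy <- which(grid$years >= historical[1] & grid$years <= historical[2])
  fy <- which(grid$years >= future[1] & grid$years <= future[2])
  if (!length(hy)) stop("historical window not present in grid years")
  if (!length(fy)) stop("future window not present in grid years")
  dv <- dim(grid$values)
  v <- grid$values
  dim(v) <- c(dv[1], dv[2], dv[3] * dv[4])
  cidx <- (cells$lon_idx - 1L) * dv[3] + cells$lat_idx
  hist_mean <- rowMeans(v[, hy, cidx, drop = FALSE], dims = 1)
  fut_mean <- rowMeans(v[, fy, cidx, drop = FALSE], dims = 1)
  chg <- 100 * (fut_mean - hist_mean) / hist_mean
  chg[!is.finite(hist_mean) | hist_mean <= baseline_tol] <- NA_real_
  chg
}

#' Ensemble summary of per-run changes
#'
#' Mean, 25th/75th percentiles (linear interpolation), and the fraction of
#' runs whose direction of change agrees with the sign of the ensemble mean.
#' Zero-change runs agree with either direction; when the ensemble mean is
#' exactly zero the agreement is the larger of the non-positive and
#' non-negative fractions.
#'
#' @param changes Numeric vector of per-run percent changes; NAs are runs
#'   excluded at this site.
#' @return List `mean`, `p25`, `p75`, `agreement`, `n_runs`.
#' @examples
#' ensemble_stats(c(-4, -2, 0, 2))  # agreement 0.75
#' @export
ensemble_stats <- function(changes) {
  x <- changes[!is.na(changes)]
  if (length(x) < 2L) stop("need at least 2 non-missing runs")
  m <- mean(x)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  agreement <- if (m == 0) {
    max(mean(x <= 0), mean(x >= 0))
  } else {
    mean(sign(x) == sign(m) | x == 0)
  }
  list(mean = m, p25 = q[1], p75 = q[2], agreement = agreement,
       n_runs = length(x))
}

#' Combine per-crop changes into one agriculture metric
#'
#' Unweighted mean of the per-crop percent changes by default; optionally a
#' production-weighted mean with weights renormalized over the crops present
#' (non-NA).
#'
#' @param changes Named numeric vector of per-crop changes (NA = crop absent).
#' @param weights Optional non-negative weights, same names/order.
#' @return Composite percent change.
#' @export
crop_composite <- function(changes, weights = NULL) {
  present <- !is.na(changes)
  if (!any(present)) stop("no crop changes present")
  if (is.null(weights)) return(mean(changes[present]))
  if (length(weights) != length(changes))
    stop("`weights` must match `changes`")
  w <- weights[present]
  if (sum(w) == 0) stop("weights over present crops sum to 0")
  sum(changes[present] * w) / sum(w)
}

#' Composite fisheries-agriculture exposure
#'
#' The community's average change across the two sectors:
#' `E_AF = (E_A + E_F) / 2`.
#'
#' @param e_a,e_f Agriculture and fisheries percent changes.
#' @return Composite percent change.
#' @export
composite_exposure <- function(e_a, e_f) (e_a + e_f) / 2

#' Full exposure extraction for one site
#'
#' Runs cell selection, per-run relative change, and ensemble aggregation for
#' the fisheries ensemble and the per-crop ensembles, then combines crops into
#' the agriculture composite per run (averaging the crops available to each
#' model run, so model runs providing fewer crops still count once toward
#' agreement) and the two sectors into `E_AF`.
#'
#' @param site List with `lat`, `lon` (and optionally `site_id`).
#' @param ocean_grid Fisheries [grid_ensemble()].
#' @param crop_grids Named list of crop [grid_ensemble()]s (e.g. rice, maize,
#'   cassava), with run metadata carrying `run_id` shared across crops where
#'   the same model run simulated several crops.
#' @param n_ocean_cells Number of nearest ocean cells (default 20).
#' @param window Land window side (default 11).
#' @param historical,future Year windows.
#' @param crop_weights Optional per-crop production weights.
#' @return One-row data frame: `E_F`, `E_A`, `E_AF`, per-sector `p25`, `p75`,
#'   `agreement`, `n_runs`, and per-crop changes `E_A_<crop>`.
#' @export
site_exposure <- function(site, ocean_grid, crop_grids,
                          n_ocean_cells = 20, window = 11,
                          historical = c(1983, 2013), future = c(2046, 2056),
                          crop_weights = NULL) {
  ocells <- select_ocean_cells(site, ocean_grid, n = n_ocean_cells)
  f_chg <- run_relative_change(ocean_grid, ocells, historical, future)
  f_stats <- ensemble_stats(f_chg)

  per_crop <- lapply(crop_grids, function(g) {
    lcells <- select_land_window(site, g, window = window)
    chg <- run_relative_change(g, lcells, historical, future)
    names(chg) <- g$runs$run_id
    chg
  })
  crop_means <- vapply(per_crop, function(x) mean(x, na.rm = TRUE), numeric(1))

  # per-run agriculture composite keyed by run_id across crops
  all_runs <- unique(unlist(lapply(per_crop, names)))
  a_chg <- vapply(all_runs, function(r) {
    vals <- vapply(per_crop, function(x) if (r %in% names(x)) x[[r]] else NA_real_,
                   numeric(1))
    if (all(is.na(vals))) NA_real_ else crop_composite(vals, crop_weights)
  }, numeric(1))
  a_stats <- ensemble_stats(a_chg)

  out <- data.frame(
    site_id = if (!is.null(site$site_id)) site$site_id else NA,
    lat = site$lat, lon = site$lon,
    E_F = f_stats$mean, E_F_p25 = f_stats$p25, E_F_p75 = f_stats$p75,
    agreement_F = f_stats$agreement, n_runs_F = f_stats$n_runs,
    E_A = a_stats$mean, E_A_p25 = a_stats$p25, E_A_p75 = a_stats$p75,
    agreement_A = a_stats$agreement, n_runs_A = a_stats$n_runs,
    stringsAsFactors = FALSE
  )
  out$E_AF <- composite_exposure(out$E_A, out$E_F)
  out$agreement_AF <- (out$agreement_A + out$agreement_F) / 2
  for (cr in names(crop_means)) out[[paste0("E_A_", cr)]] <- crop_means[[cr]]
  out
}

#' Exposure for a table of sites
#'
#' @param sites Data frame with `site_id`, `lat`, `lon`.
#' @param ... Passed to [site_exposure()].
#' @inheritParams site_exposure
#' @return Data frame, one row per site.
#' @export
extract_exposure <- function(sites, ocean_grid, crop_grids, ...) {
  rows <- lapply(seq_len(nrow(sites)), function(i)
    site_exposure(as.list(sites[i, ]), ocean_grid, crop_grids, ...))
  out <- do.call(rbind, rows)
  out$scenario <- ocean_grid$scenario
  out
}

#' Sensitivity of site statistics to the number of ocean cells
#'
#' Recomputes the fisheries ensemble statistics using different numbers of
#' nearest ocean cells, to examine how cell count trades off model-run
#' agreement against inter-site variability.
#'
#' @param site List with `lat`, `lon`.
#' @param grid Fisheries [grid_ensemble()].
#' @param counts Cell counts to try (default `c(1, 3, 5, 10, 20, 50, 100)`).
#' @param historical,future Year windows.
#' @return Data frame: `n_cells`, `mean`, `p25`, `p75`, `agreement`, `n_runs`.
#' @export
cell_count_sensitivity <- function(site, grid,
                                   counts = c(1, 3, 5, 10, 20, 50, 100),
                                   historical = c(1983, 2013),
                                   future = c(2046, 2056)) {
  rows <- lapply(counts, function(n) {
    cells <- select_ocean_cells(site, grid, n = n)
    chg <- run_relative_change(grid, cells, historical, future)
    s <- ensemble_stats(chg)
    data.frame(n_cells = n, mean = s$mean, p25 = s$p25, p75 = s$p75,
               agreement = s$agreement, n_runs = s$n_runs)
  })
  do.call(rbind, rows)
}
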