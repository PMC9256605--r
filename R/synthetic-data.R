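# Occupation pools per sector used by the survey generator.
.occ_pool <- list(
  agriculture = c("farming", "cash_crop"),
  fisheries   = c("fishing", "mariculture", "gleaning", "fish_trading"),
  off         = c("salaried", "informal", "tourism", "other")
)

#' Generate a synthetic household survey
#'
#' Draws communities, households, ranked occupation lists and the 16
#' material-item flags with the statistical structure the downstream analysis
#' assumes: household sector membership is multinomial over (agriculture only,
#' fisheries only, both, neither), every household holds at least one ranked
#' occupation with distinct ranks, and in dual-sector households the best
#' fisheries occupation outranks the best agriculture occupation with
#' probability `rank_preference`. Item presence follows a logistic model on a
#' per-country latent wealth.
#'
#' @param config A [synthetic_config()].
#' @return List: `survey` (long occupation table), `items` (wide 0/1 item
#'   table), `communities` (community roster), `truth` (community-level
#'   generating probabilities and household latent wealth; for audit only,
#'   never consumed by pipeline stages).
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$sub_seeds[["survey"]], {
    n_comm <- sum(config$communities_per_country)
    comm_country <- rep(config$countries, config$communities_per_country)
    comm_id <- sprintf("C%02d", seq_len(n_comm))

    surveys <- vector("list", n_comm)
    item_rows <- vector("list", n_comm)
    truth_probs <- vector("list", n_comm)
    wealth_list <- vector("list", n_comm)

    for (ci in seq_len(n_comm)) {
      ctry <- comm_country[ci]
      k <- match(ctry, config$countries)
      p0 <- config$sector_engagement_probs[k, ]
      p0[4] <- p0[4] + max(0, 1 - sum(p0))  # shortfall folds into "neither"
      # community-level jitter around the country membership probabilities
      if (is.finite(config$prob_concentration)) {
        g <- stats::rgamma(4, shape = pmax(p0, 1e-6) * config$prob_concentration)
        p <- g / sum(g) * sum(p0)
      } else {
        p <- p0
      }
      n_hh <- if (diff(config$households_range) == 0) config$households_range[1]
      else sample(config$households_range[1]:config$households_range[2], 1)
      if (n_hh < 1L) stop("empty community requested")

      member <- sample(c("agriculture_only", "fisheries_only", "both", "neither"),
                       n_hh, replace = TRUE, prob = p)
      hh_ids <- sprintf("%s_h%03d", comm_id[ci], seq_len(n_hh))

      occ_rows <- vector("list", n_hh)
      for (h in seq_len(n_hh)) {
        occ <- character(0)
        if (member[h] %in% c("agriculture_only", "both"))
          occ <- c(occ, sample(.occ_pool$agriculture,
                               1 + stats::rbinom(1, 1, 0.3)))
        if (member[h] %in% c("fisheries_only", "both"))
          occ <- c(occ, sample(.occ_pool$fisheries,
                               1 + stats::rbinom(1, 1, 0.4)))
        if (member[h] == "neither" || stats::runif(1) < config$p_off_occupation)
          occ <- c(occ, sample(.occ_pool$off, 1))
        occ <- unique(occ)
        rk <- sample(length(occ))
        if (member[h] == "both") {
          sec <- unname(sector_map()[occ])
          bf <- min(rk[sec == "fisheries"]); ba <- min(rk[sec == "agriculture"])
          want_f <- stats::runif(1) < config$rank_preference
          if ((bf < ba) != want_f) {  # swap the two sector leaders
            i1 <- which(rk == bf); i2 <- which(rk == ba)
            rk[c(i1, i2)] <- rk[c(i2, i1)]
          }
        }
        occ_rows[[h]] <- data.frame(community_id = comm_id[ci], country = ctry,
                                    household_id = hh_ids[h], occupation = occ,
                                    rank = rk, stringsAsFactors = FALSE)
      }
      surveys[[ci]] <- do.call(rbind, occ_rows)

      w <- stats::rnorm(n_hh, config$wealth_mean[k], config$wealth_sd[k])
      pr <- stats::plogis(outer(w, config$item_loadings) +
                            matrix(config$item_intercepts, n_hh, 16, byrow = TRUE))
      it <- matrix(stats::rbinom(n_hh * 16, 1, pr), n_hh, 16)
      colnames(it) <- sprintf("item_%02d", 1:16)
      item_rows[[ci]] <- data.frame(community_id = comm_id[ci], country = ctry,
                                    household_id = hh_ids, it,
                                    stringsAsFactors = FALSE)
      names(p) <- colnames(config$sector_engagement_probs)
      truth_probs[[ci]] <- p
      wealth_list[[ci]] <- w
    }

    communities <- data.frame(community_id = comm_id, country = comm_country,
                              n_households = vapply(item_rows, nrow, integer(1)),
                              stringsAsFactors = FALSE)
    list(survey = do.call(rbind, surveys),
         items = do.call(rbind, item_rows),
         communities = communities,
         truth = list(membership_probs = do.call(rbind, truth_probs),
                      latent_wealth = wealth_list))
  })
}

# Internal: land/ocean mask on cell centers; land lies east of a wiggly
# meridional coastline through the middle of the box.
make_mask <- function(lat, lon, bbox) {
  coast <- (bbox[1] + bbox[2]) / 2 + 3 * sin(2 * pi * (lat - bbox[3]) /
                                               (bbox[4] - bbox[3]))
  outer(coast, lon, function(cst, x) as.integer(x > cst))
}

# Internal: cell-center coordinate vectors for a resolution inside a bbox.
grid_axes <- function(bbox, res) {
  list(lat = seq(bbox[3] + res / 2, bbox[4] - res / 2, by = res),
       lon = seq(bbox[1] + res / 2, bbox[2] - res / 2, by = res))
}

# Internal: moving-average smooth of a matrix with a (2r+1)^2 window.
smooth_field <- function(m, r) {
  if (r <= 0) return(m)
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - r):min(nr, i + r)
    jj <- max(1, j - r):min(nc, j + r)
    out[i, j] <- mean(m[ii, jj])
  }
  out
}

# Internal: spatial-noise field, i.i.d. per cell by default; smoothing (which
# shrinks the variance) is followed by rescaling back to the target SD so
# `spatial_sd` keeps its meaning.
make_eta <- function(nlat, nlon, sd, radius) {
  eta <- matrix(stats::rnorm(nlat * nlon, 0, sd), nlat, nlon)
  if (radius > 0 && sd > 0) {
    eta <- smooth_field(eta, radius)
    eta <- eta * sd / stats::sd(as.vector(eta))
  }
  eta
}

# Internal: one sector's ensemble for one scenario (historical + future years).
build_ensemble <- function(base, mask, lat, lon, runs, delta, run_offsets,
                           eta, config, scenario, sector, units, rng_seed) {
  with_seed(rng_seed, {
    years <- c(config$historical[1]:config$historical[2],
               config$future[1]:config$future[2])
    fut <- years >= config$future[1]
    nr <- nrow(runs); ny <- length(years)
    ncell <- length(lat) * length(lon)
    vals <- array(NA_real_, c(nr, ny, length(lat), length(lon)))
    bvec <- as.vector(base)
    noise <- if (config$interannual_sd > 0)
      array(stats::rnorm(nr * ny * ncell, 0, config$interannual_sd),
            c(nr, ny, ncell)) else array(0, c(1, 1, 1))
    for (r in seq_len(nr)) {
      scale_fut <- 1 + delta + run_offsets[r] + as.vector(eta)
      for (y in seq_len(ny)) {
        f <- if (fut[y]) bvec * scale_fut else bvec
        if (config$interannual_sd > 0) f <- f * (1 + noise[r, y, ])
        vals[r, y, , ] <- f
      }
    }
    grid_ensemble(lat, lon, mask, vals, years, runs,
                  scenario = scenario, sector = sector, units = units)
  })
}

#' Generate gridded projection ensembles
#'
#' Builds, for every scenario in the configuration, a fisheries ensemble
#' (total consumer biomass, 1 degree, 16 runs = 9 impact models x 1-2
#' forcings) and three crop ensembles (rain-fed yield, 0.5 degree; rice and
#' maize from 4 impact models x 5 forcings = 20 runs, cassava from a single
#' impact model = 5 runs). Historical cell values are a positive log-normal
#' base field; future values multiply the base by
#' `(1 + true change + run offset + spatial noise)`, optionally with
#' interannual multiplicative noise. Land and ocean share one coastline.
#'
#' @param config A [synthetic_config()].
#' @return List with one element per scenario (each holding `fisheries` and
#'   `crops = list(rice, maize, cassava)`), plus `truth` (true change, run
#'   offsets and spatial-noise fields per sector/scenario).
#' @export
generate_grids <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- with_seed(config$sub_seeds[["grids"]],
                     sample.int(.Machine$integer.max - 1L, 64L))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  oax <- grid_axes(config$bbox, config$ocean_res)
  cax <- grid_axes(config$bbox, config$crop_res)
  omask <- make_mask(oax$lat, oax$lon, config$bbox)
  cmask <- make_mask(cax$lat, cax$lon, config$bbox)

  # fisheries run roster: models 1-2 single forcing, 3-9 both (16 runs)
  f_runs <- do.call(rbind, lapply(1:9, function(m) {
    fo <- if (m <= 2) "esm_ipsl" else c("esm_gfdl", "esm_ipsl")
    data.frame(impact_model = sprintf("fishmodel_%d", m), forcing = fo,
               stringsAsFactors = FALSE)
  }))
  f_runs$run_id <- paste(f_runs$impact_model, f_runs$forcing, sep = ":")
  f_runs <- f_runs[seq_len(config$n_fishery_runs), ]

  c_runs <- expand.grid(impact_model = sprintf("cropmodel_%d",
                                               seq_len(config$n_crop_models)),
                        forcing = sprintf("esm_%d", seq_len(config$n_forcings)),
                        stringsAsFactors = FALSE)
  c_runs$run_id <- paste(c_runs$impact_model, c_runs$forcing, sep = ":")
  cassava_runs <- c_runs[c_runs$impact_model == "cropmodel_2", ]

  base_f <- with_seed(next_seed(), {
    b <- matrix(100 * exp(stats::rnorm(length(oax$lat) * length(oax$lon), 0, 0.3)),
                length(oax$lat), length(oax$lon))
    b[omask == 1L] <- NA_real_   # biomass defined on ocean only
    b
  })
  base_crop <- lapply(c(rice = 1, maize = 2, cassava = 3), function(i)
    with_seed(next_seed(), {
      b <- matrix(exp(stats::rnorm(length(cax$lat) * length(cax$lon),
                                   log(c(4, 3, 10)[i]), 0.3)),
                  length(cax$lat), length(cax$lon))
      b[cmask == 0L] <- NA_real_  # yield defined on land only
      b
    }))

  out <- list()
  truth <- list()
  for (sc in names(config$scenarios)) {
    delta <- config$scenarios[[sc]]
    d_f <- with_seed(next_seed(), stats::rnorm(nrow(f_runs), 0, config$run_sd))
    eta_f <- with_seed(next_seed(),
      make_eta(length(oax$lat), length(oax$lon), config$spatial_sd,
               config$smooth_radius))
    fisheries <- build_ensemble(base_f, omask, oax$lat, oax$lon, f_runs,
                                delta[["fisheries"]], d_f, eta_f, config, sc,
                                "fisheries", "g m-2", next_seed())

    d_c <- with_seed(next_seed(), stats::rnorm(nrow(c_runs), 0, config$run_sd))
    names(d_c) <- c_runs$run_id
    crops <- list(); eta_c <- list()
    for (crop in c("rice", "maize", "cassava")) {
      runs <- if (crop == "cassava") cassava_runs else c_runs
      eta <- with_seed(next_seed(),
        make_eta(length(cax$lat), length(cax$lon), config$spatial_sd,
                 config$smooth_radius))
      crops[[crop]] <- build_ensemble(base_crop[[crop]], cmask, cax$lat,
                                      cax$lon, runs, delta[["agriculture"]],
                                      d_c[runs$run_id], eta, config, sc, crop,
                                      "t ha-1", next_seed())
      eta_c[[crop]] <- eta
    }
    out[[sc]] <- list(fisheries = fisheries, crops = crops)
    truth[[sc]] <- list(true_change = delta, run_offsets_fisheries = d_f,
                        run_offsets_crops = d_c, eta_fisheries = eta_f,
                        eta_crops = eta_c)
  }
  out$truth <- truth
  out
}

#' Generate a coastal population-density grid
#'
#' Log-normal population density on land cells at the fine population-raster
#' resolution (much finer than the climate grids, as gridded population
#' products are), zero on ocean, with a coastal flag on every land cell that
#' touches (8-neighbour adjacency) at least one ocean cell.
#'
#' @param config A [synthetic_config()].
#' @return List of class `population_grid`: `lat`, `lon`, `mask`, `density`
#'   (people/km^2), `coastal` (logical matrix).
#' @export
generate_population_grid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$sub_seeds[["population"]], {
    ax <- grid_axes(config$bbox, config$pop_res)
    mask <- make_mask(ax$lat, ax$lon, config$bbox)
    mu <- log(config$pop_density_mean) - 0.5
    dens <- matrix(stats::rlnorm(length(ax$lat) * length(ax$lon), mu, 1),
                   length(ax$lat), length(ax$lon))
    dens[mask == 0L] <- 0
    structure(list(lat = ax$lat, lon = ax$lon, mask = mask, density = dens,
                   coastal = coastal_flags(mask)),
              class = "population_grid")
  })
}

#' Coastal adjacency flags for a land/ocean mask
#'
#' A land cell is coastal when at least one of its 8 neighbours is ocean.
#'
#' @param mask Integer matrix, 1 = land, 0 = ocean.
#' @return Logical matrix of the same shape (FALSE on ocean cells).
#' @export
coastal_flags <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(1L, nr + 2, nc + 2)  # beyond the grid edge is not ocean
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  near_ocean <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    near_ocean <- near_ocean |
      (pad[2:(nr + 1) + di, 2:(nc + 1) + dj] == 0L)
  }
  (mask == 1L) & near_ocean
}

#' Place community sites on the synthetic coastline
#'
#' Sites sit on coastal land cells of the 1-degree grid (so both extraction
#' geometries are exercised: nearby ocean cells and a land window). Cells are
#' drawn with replacement and site coordinates jittered within the cell;
#' countries occupy contiguous latitude blocks.
#'
#' @param config A [synthetic_config()].
#' @return Data frame: `site_id`, `country`, `lat`, `lon`.
#' @export
generate_sites <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$sub_seeds[["sites"]], {
    ax <- grid_axes(config$bbox, config$ocean_res)
    mask <- make_mask(ax$lat, ax$lon, config$bbox)
    cst <- which(coastal_flags(mask), arr.ind = TRUE)
    if (nrow(cst) == 0L) stop("bounding box contains no coastal land cells")
    n <- sum(config$communities_per_country)
    pick <- cst[sample.int(nrow(cst), n, replace = TRUE), , drop = FALSE]
    jit <- matrix(stats::runif(2 * n, -0.35, 0.35), n, 2) * config$ocean_res
    sites <- data.frame(site_id = sprintf("C%02d", seq_len(n)),
                        lat = ax$lat[pick[, 1]] + jit[, 1],
                        lon = ax$lon[pick[, 2]] + jit[, 2],
                        stringsAsFactors = FALSE)
    sites <- sites[order(sites$lat, sites$lon), ]
    sites$site_id <- sprintf("C%02d", seq_len(n))  # ids follow the lat order
    sites$country <- rep(config$countries, config$communities_per_country)
    rownames(sites) <- NULL
    sites[, c("site_id", "country", "lat", "lon")]
  })
}

#' Generate a complete synthetic study
#'
#' Bundles [generate_survey()], [generate_sites()], [generate_grids()] and
#' [generate_population_grid()] under one master seed. Community ids in the
#' survey match site ids, so survey-derived sensitivity and grid-derived
#' exposure join one-to-one.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_study`: `config`, `survey`, `items`,
#'   `communities`, `sites`, `grids`, `population`, `truth`.
#' @export
generate_study <- function(config = synthetic_config()) {
  sv <- generate_survey(config)
  sites <- generate_sites(config)
  grids <- generate_grids(config)
  pop <- generate_population_grid(config)
  # align survey country labels with the spatial country blocks
  structure(list(config = config, survey = sv$survey, items = sv$items,
                 communities = sv$communities, sites = sites,
                 grids = grids[setdiff(names(grids), "truth")],
                 population = pop,
                 truth = list(survey = sv$truth, grids = grids$truth)),
            class = "synthetic_study")
}
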