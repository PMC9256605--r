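# Internal: run a block with a private RNG state, restoring the caller's.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Internal: derive named sub-seeds from a master seed. The draw order is
# fixed (survey, sites, grids, population, extra) so adding a generator does
# not shift the streams of existing ones.
derive_seeds <- function(seed) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, 5L)
    names(s) <- c("survey", "sites", "grids", "population", "extra")
    s
  })
}

#' Configuration for the synthetic study generator
#'
#' Bundles every parameter the synthetic household-survey and gridded-ensemble
#' generators need. The defaults emulate the study conditions: five countries
#' contributing 25/6/10/25/6 communities (72 sites), 13-150 households per
#' community, a 16-run fisheries ensemble and a 20-run crop ensemble (cassava
#' simulated by a single impact model, so 5 of those runs carry cassava), a
#' 1983-2013 historical window and a 2046-2056 mid-century window under a
#' milder and a harsher emissions scenario.
#'
#' @param seed Master seed; all generator streams derive from it.
#' @param countries Character vector of country labels.
#' @param communities_per_country Integer vector (recycled) of communities per
#'   country.
#' @param households_range Min/max households per community (uniform draw).
#' @param sector_engagement_probs Matrix (country x 4) or single numeric
#'   vector of probabilities for household sector membership
#'   `(agriculture_only, fisheries_only, both, neither)`; must sum to <= 1
#'   per row (any shortfall is folded into `neither`).
#' @param prob_concentration Dirichlet-style concentration of the
#'   community-level jitter around the country membership probabilities;
#'   `Inf` disables the jitter so every community uses the country values.
#' @param p_off_occupation Probability a household also holds an off-sector
#'   occupation (households in "neither" always hold one, so everyone has at
#'   least one occupation).
#' @param rank_preference Probability that, in a household holding both
#'   sectors, its best fisheries occupation outranks its best agriculture
#'   occupation.
#' @param wealth_mean,wealth_sd Per-country latent wealth mean/SD (recycled).
#' @param item_loadings Length-16 logistic slopes of item presence on latent
#'   wealth.
#' @param item_intercepts Length-16 logistic intercepts.
#' @param bbox Bounding box `c(lon_min, lon_max, lat_min, lat_max)`; the
#'   resolutions must divide its extents.
#' @param ocean_res,crop_res Grid resolutions in degrees (1 and 0.5).
#' @param pop_res Population-raster resolution in degrees; much finer than
#'   the climate grids, mirroring km-scale gridded population products.
#' @param n_fishery_runs Fisheries ensemble size (16).
#' @param n_crop_models,n_forcings Crop impact models (4) x climate forcings
#'   (5) = 20 crop runs; cassava uses a single impact model (5 runs).
#' @param scenarios Named list: per scenario, per-sector true mean fractional
#'   change, e.g. `list(ssp585 = c(fisheries = -0.147, agriculture = 0.012))`.
#' @param run_sd Between-run SD of the fractional change.
#' @param spatial_sd Cell-level SD of the fractional change (site-to-site
#'   spread of the truth).
#' @param interannual_sd Year-to-year multiplicative noise SD.
#' @param smooth_radius Optional cell radius for moving-average smoothing of
#'   the spatial noise (0 = i.i.d. per cell).
#' @param historical,future Year windows.
#' @param pop_density_mean Mean coastal population density (people/km^2).
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    countries = c("country_A", "country_B", "country_C", "country_D", "country_E"),
    communities_per_country = c(25L, 6L, 10L, 25L, 6L),
    households_range = c(13L, 150L),
    sector_engagement_probs = c(agriculture_only = 0.25, fisheries_only = 0.35,
                                both = 0.25, neither = 0.15),
    prob_concentration = 60,
    p_off_occupation = 0.4,
    rank_preference = 0.6,
    wealth_mean = c(0, 0.4, -0.3, 0.2, -0.2),
    wealth_sd = 1,
    item_loadings = rep(c(1.2, 0.8, 1.6, 0.5), 4),
    item_intercepts = seq(-1.5, 1.5, length.out = 16),
    bbox = c(100, 120, -10, 10),
    ocean_res = 1, crop_res = 0.5, pop_res = 0.05,
    n_fishery_runs = 16L,
    n_crop_models = 4L, n_forcings = 5L,
    scenarios = list(ssp126 = c(fisheries = -0.060, agriculture = 0.025),
                     ssp585 = c(fisheries = -0.147, agriculture = 0.012)),
    run_sd = 0.05,
    spatial_sd = 0.08,
    interannual_sd = 0.02,
    smooth_radius = 0L,
    historical = c(1983L, 2013L),
    future = c(2046L, 2056L),
    pop_density_mean = 60) {

  cfg <- list(seed = as.integer(seed), countries = countries,
              communities_per_country =
                rep_len(as.integer(communities_per_country), length(countries)),
              households_range = as.integer(households_range),
              sector_engagement_probs = sector_engagement_probs,
              prob_concentration = prob_concentration,
              p_off_occupation = p_off_occupation,
              rank_preference = rank_preference,
              wealth_mean = rep_len(wealth_mean, length(countries)),
              wealth_sd = rep_len(wealth_sd, length(countries)),
              item_loadings = item_loadings,
              item_intercepts = item_intercepts,
              bbox = bbox, ocean_res = ocean_res, crop_res = crop_res,
              pop_res = pop_res,
              n_fishery_runs = as.integer(n_fishery_runs),
              n_crop_models = as.integer(n_crop_models),
              n_forcings = as.integer(n_forcings),
              scenarios = scenarios, run_sd = run_sd,
              spatial_sd = spatial_sd, interannual_sd = interannual_sd,
              smooth_radius = as.integer(smooth_radius),
              historical = as.integer(historical),
              future = as.integer(future),
              pop_density_mean = pop_density_mean)

  p <- cfg$sector_engagement_probs
  if (is.null(dim(p))) p <- matrix(p, nrow = length(countries), ncol = 4,
                                   byrow = TRUE,
                                   dimnames = list(countries,
                                                   c("agriculture_only",
                                                     "fisheries_only", "both",
                                                     "neither")))
  if (any(p < 0) || any(p > 1) || any(rowSums(p) > 1 + 1e-12))
    stop("sector engagement probabilities must be in [0,1] and sum to <= 1 per country")
  cfg$sector_engagement_probs <- p
  if (cfg$rank_preference < 0 || cfg$rank_preference > 1)
    stop("rank_preference must be a probability")
  if (any(cfg$households_range < 1L) || diff(cfg$households_range) < 0)
    stop("invalid households_range")
  if (any(cfg$communities_per_country < 1L))
    stop("every country needs at least one community")
  ext <- c(diff(cfg$bbox[1:2]), diff(cfg$bbox[3:4]))
  for (res in c(cfg$ocean_res, cfg$crop_res, cfg$pop_res))
    if (any(abs(ext / res - round(ext / res)) > 1e-9))
      stop("grid resolution must divide the bounding-box extents")
  if (cfg$historical[2] >= cfg$future[1])
    stop("historical and future windows must be disjoint")
  if (length(cfg$item_loadings) != 16L || length(cfg$item_intercepts) != 16L)
    stop("item loadings/intercepts must have length 16")
  cfg$sub_seeds <- derive_seeds(cfg$seed)
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> seed %d: %d countries, %d communities, %d + %d-crop runs\n",
              x$seed, length(x$countries), sum(x$communities_per_country),
              x$n_fishery_runs, x$n_crop_models * x$n_forcings))
  invisible(x)
}

#' Read / write a synthetic configuration as YAML
#'
#' @param cfg A [synthetic_config()].
#' @param path File path.
#' @return `path` (write, invisibly) or a `synthetic_config` (read).
#' @export
write_config_yaml <- function(cfg, path) {
  x <- unclass(cfg)
  x$sub_seeds <- NULL
  x$sector_engagement_probs <- as.data.frame(x$sector_engagement_probs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$sector_engagement_probs <-
    as.matrix(as.data.frame(x$sector_engagement_probs))
  rownames(x$sector_engagement_probs) <- x$countries
  x$scenarios <- lapply(x$scenarios, unlist)
  do.call(synthetic_config, x)
}
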