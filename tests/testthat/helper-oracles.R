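# Independent brute-force implementation of the sensitivity index: walks the
# households of one community directly with explicit set logic, never calling
# the package's counting code.
brute_force_sensitivity <- function(hh_list, focal) {
  fish <- c("fishing", "mariculture", "gleaning", "fish_trading")
  agri <- c("farming", "cash_crop")
  in_focal <- function(occ) {
    if (focal == "agriculture") occ %in% agri
    else if (focal == "fisheries") occ %in% fish
    else occ %in% c(agri, fish)
  }
  in_counter <- function(occ) {
    if (focal == "joint") !(occ %in% c(agri, fish)) else !in_focal(occ)
  }
  N <- length(hh_list)
  X <- 0; NX <- 0; r_x <- 0; r_nx <- 0
  for (h in hh_list) {
    f <- in_focal(h$occupation)
    cn <- in_counter(h$occupation)
    if (any(f)) X <- X + 1
    if (any(cn)) NX <- NX + 1
    if (any(f) && any(cn)) {
      if (min(h$rank[f]) < min(h$rank[cn])) r_x <- r_x + 1 else r_nx <- r_nx + 1
    }
  }
  (X / (X + NX)) * (N / (X + NX)) * ((r_x / 2 + 1) / (r_x + r_nx + 1))
}

# Random community in both representations: a list of per-household frames
# (for the oracle) and one long data frame (for the package).
random_community <- function(n_hh, id = "C01", country = "x") {
  cats <- names(sector_map())
  hh <- lapply(seq_len(n_hh), function(i) {
    k <- sample(1:4, 1)
    occ <- sample(cats, k)
    data.frame(household_id = sprintf("h%03d", i), occupation = occ,
               rank = sample(k), stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, hh)
  long$community_id <- id
  long$country <- country
  list(households = hh, long = long)
}

# Minimal single-sector grid for geometry tests: constant field `hist_value`
# over `years_hist`, `fut_value` over `years_fut`, optional custom mask.
toy_grid <- function(lat, lon, mask = NULL, n_runs = 2,
                     hist_value = 100, fut_value = 80,
                     years_hist = 1983:2013, years_fut = 2046:2056,
                     scenario = "test", sector = "fisheries") {
  if (is.null(mask)) mask <- matrix(0L, length(lat), length(lon))
  years <- c(years_hist, years_fut)
  vals <- array(NA_real_, c(n_runs, length(years), length(lat), length(lon)))
  vals[, seq_along(years_hist), , ] <- hist_value
  vals[, length(years_hist) + seq_along(years_fut), , ] <- fut_value
  grid_ensemble(lat, lon, mask, vals, years,
                data.frame(run_id = sprintf("run_%d", seq_len(n_runs))),
                scenario = scenario, sector = sector)
}

# Small fast study configuration shared across tests.
small_config <- function(seed = 7, ...) {
  synthetic_config(seed = seed, countries = c("a", "b", "c"),
                   communities_per_country = c(4, 3, 3),
                   households_range = c(15, 30),
                   bbox = c(100, 112, -6, 6), ...)
}
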