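#' Occupation categories and the sector map
#'
#' Household livelihood activities are recorded in ten occupation categories.
#' Fishing, mariculture, gleaning and fish trading make up the fisheries
#' sector; farming and cash cropping make up the agriculture sector; salaried
#' employment, informal work, tourism and other activities form the
#' "off" sector (everything outside the two natural-resource sectors).
#'
#' @return Named character vector mapping each occupation category to one of
#'   `"fisheries"`, `"agriculture"`, `"off"`.
#' @examples
#' sector_map()[["gleaning"]]
#' @export
sector_map <- function() {
  c(
    fishing      = "fisheries",
    mariculture  = "fisheries",
    gleaning     = "fisheries",
    fish_trading = "fisheries",
    farming      = "agriculture",
    cash_crop    = "agriculture",
    salaried     = "off",
    informal     = "off",
    tourism      = "off",
    other        = "off"
  )
}

#' Classify one household's ranked occupation list
#'
#' Maps a household's ranked occupations onto sectors and reports, per sector,
#' whether the household engages in it and the best (most important, i.e.
#' lowest-numbered) rank it holds there.
#'
#' @param occupations Character vector of occupation categories.
#' @param ranks Integer vector of distinct importance ranks (1 = most
#'   important), same length as `occupations`.
#' @param map Sector map; defaults to [sector_map()].
#' @return List with `engaged` (named logical over the three sectors) and
#'   `best_rank` (named numeric, `Inf` where not engaged).
#' @examples
#' classify_household(c("gleaning", "cash_crop", "salaried"), c(3, 1, 2))
#' @export
classify_household <- function(occupations, ranks, map = sector_map()) {
  if (length(occupations) < 1L)
    stop("household must list at least one occupation")
  if (length(ranks) != length(occupations))
    stop("`occupations` and `ranks` must have the same length")
  if (anyDuplicated(ranks))
    stop("ranks must be distinct within a household")
  unknown <- setdiff(occupations, names(map))
  if (length(unknown))
    stop("unknown occupation category: ", paste(unknown, collapse = ", "))
  sectors <- c("fisheries", "agriculture", "off")
  sec <- unname(map[occupations])
  best <- vapply(sectors, function(s) {
    r <- ranks[sec == s]
    if (length(r)) min(r) else Inf
  }, numeric(1))
  list(engaged = is.finite(best), best_rank = best)
}

#' Sector engagement and ranking-direction counts for a community
#'
#' Tallies the ingredients of the sensitivity index for one community. With
#' focal sector X and its counterpart, `X` counts households holding at least
#' one focal-sector occupation, `NX` counts households holding at least one
#' counterpart occupation (a dual household counts in both, so X + NX >= N
#' whenever every household lists an occupation), and `r_x` / `r_nx` count,
#' among households engaged on both sides, which side holds the better
#' (lower-numbered) best rank. Ranks are distinct within a household so ties
#' cannot occur; each dual household contributes exactly one increment.
#'
#' For the joint focal sector (`"joint"`), a focal occupation is any fisheries
#' or agriculture occupation and the counterpart is the off sector only.
#' For a single focal sector the counterpart is every occupation outside it
#' (the other natural-resource sector plus the off sector).
#'
#' @param households Data frame with columns `household_id`, `occupation`,
#'   `rank` (long format, one row per occupation held).
#' @param focal `"agriculture"`, `"fisheries"`, or `"joint"`.
#' @param map Sector map; defaults to [sector_map()].
#' @param per_pair If `TRUE`, `r_x`/`r_nx` count every focal-counterpart
#'   occupation pair ordered each way instead of one comparison of best ranks
#'   per household. Default `FALSE` (household-level rule).
#' @return List with elements `X`, `NX`, `N`, `r_x`, `r_nx`, `focal`.
#' @export
sector_counts <- function(households, focal = c("agriculture", "fisheries", "joint"),
                          map = sector_map(), per_pair = FALSE) {
  focal <- match.arg(focal)
  stopifnot(all(c("household_id", "occupation", "rank") %in% names(households)))
  if (nrow(households) == 0L) stop("community has no households")
  unknown <- setdiff(unique(households$occupation), names(map))
  if (length(unknown))
    stop("unknown occupation category: ", paste(unknown, collapse = ", "))

  sec <- unname(map[households$occupation])
  is_focal <- if (focal == "joint") sec %in% c("agriculture", "fisheries") else sec == focal
  is_counter <- if (focal == "joint") sec == "off" else !is_focal

  ids <- unique(households$household_id)
  N <- length(ids)
  hh <- match(households$household_id, ids)

  focal_by_hh <- tapply(is_focal, hh, any)
  counter_by_hh <- tapply(is_counter, hh, any)
  X <- sum(focal_by_hh)
  NX <- sum(counter_by_hh)

  r_x <- 0L; r_nx <- 0L
  dual <- which(focal_by_hh & counter_by_hh)
  for (i in dual) {
    rows <- hh == i
    rf <- households$rank[rows & is_focal]
    rc <- households$rank[rows & is_counter]
    if (per_pair) {
      cmp <- outer(rf, rc, "<")
      r_x <- r_x + sum(cmp)
      r_nx <- r_nx + sum(!cmp)
    } else {
      if (min(rf) < min(rc)) r_x <- r_x + 1L else r_nx <- r_nx + 1L
    }
  }
  list(X = as.integer(X), NX = as.integer(NX), N = as.integer(N),
       r_x = as.integer(r_x), r_nx = as.integer(r_nx), focal = focal)
}

#' Livelihood sensitivity index
#'
#' The community-level dependence score for a focal sector: the product of
#' engagement (share of sector-reliant households among all sector-engaged
#' ones), linkage (how exclusively those households sit inside the focal
#' sector), and ranking directionality (how often the focal sector outranks
#' its counterpart in dual households):
#'
#' \deqn{S = \frac{X}{X+NX} \times \frac{N}{X+NX} \times
#'       \frac{r_x/2 + 1}{r_x + r_{nx} + 1}}
#'
#' Each factor lies in \[0, 1\] when every household lists at least one
#' occupation, so S is in \[0, 1\], and S = 0 exactly when no household
#' engages the focal sector.
#'
#' @param counts List as returned by [sector_counts()], or the individual
#'   counts given as arguments.
#' @param X,NX,N,r_x,r_nx Individual counts (ignored when `counts` is given).
#' @return List with `S` and the three audit factors `engagement`, `linkage`,
#'   `directionality`.
#' @examples
#' sensitivity_index(X = 6, NX = 6, N = 10, r_x = 1, r_nx = 1)$S  # 0.2083...
#' @export
sensitivity_index <- function(counts = NULL, X, NX, N, r_x, r_nx) {
  if (!is.null(counts)) {
    X <- counts$X; NX <- counts$NX; N <- counts$N
    r_x <- counts$r_x; r_nx <- counts$r_nx
  }
  if (N < 1L) stop("community must contain at least one household")
  if (X + NX == 0L) stop("no occupations held in either the focal or counterpart sector")
  engagement <- X / (X + NX)
  linkage <- N / (X + NX)
  directionality <- (r_x / 2 + 1) / (r_x + r_nx + 1)
  list(S = engagement * linkage * directionality,
       engagement = engagement, linkage = linkage,
       directionality = directionality)
}

#' Per-community sensitivity table
#'
#' Applies [sector_counts()] and [sensitivity_index()] for agriculture,
#' fisheries, and the joint sector to every community in a long-format survey
#' table. Households listing zero occupations are dropped with a warning.
#'
#' @param survey Data frame with columns `community_id`, `country`,
#'   `household_id`, `occupation`, `rank`.
#' @param map Sector map; defaults to [sector_map()].
#' @param per_pair Passed to [sector_counts()].
#' @return Data frame, one row per community: `community_id`, `country`, `N`,
#'   `S_A`, `S_F`, `S_AF`, plus the raw counts per focal sector.
#' @export
community_sensitivity <- function(survey, map = sector_map(), per_pair = FALSE) {
  stopifnot(all(c("community_id", "country", "household_id", "occupation", "rank")
                %in% names(survey)))
  keep <- !is.na(survey$occupation)
  if (any(!keep)) {
    warning(sum(!keep), " occupation rows with missing category dropped")
    survey <- survey[keep, ]
  }
  out <- lapply(split(survey, survey$community_id), function(d) {
    res <- lapply(c(agriculture = "agriculture", fisheries = "fisheries",
                    joint = "joint"), function(f) {
      cnt <- sector_counts(d, focal = f, map = map, per_pair = per_pair)
      s <- if (cnt$X + cnt$NX == 0L) list(S = NA_real_) else sensitivity_index(cnt)
      c(cnt[c("X", "NX", "r_x", "r_nx")], S = s$S)
    })
    data.frame(
      community_id = d$community_id[1], country = d$country[1],
      N = length(unique(d$household_id)),
      S_A = res$agriculture$S, S_F = res$fisheries$S, S_AF = res$joint$S,
      A = res$agriculture$X, n_A = res$agriculture$NX,
      r_a = res$agriculture$r_x, r_na = res$agriculture$r_nx,
      F_ = res$fisheries$X, n_F = res$fisheries$NX,
      r_f = res$fisheries$r_x, r_nf = res$fisheries$r_nx,
      AF = res$joint$X, n_AF = res$joint$NX,
      r_af = res$joint$r_x, r_naf = res$joint$r_nx,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$country, res$community_id), , drop = FALSE]
}
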