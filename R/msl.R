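#' Material style of life scores
#'
#' Asset-based wealth from 16 household presence/absence items: the first
#' principal axis of the centered (covariance-form) binary item matrix is kept
#' as the household wealth score. The axis sign is oriented so that owning
#' more items gives a higher score. Community mean scores are min-max rescaled
#' to \[0, 1\] across communities.
#'
#' @param items Numeric 0/1 matrix, households x items.
#' @param community_id Vector of community ids, one per household row.
#' @return List of class `msl_result`: `household_scores`, `loadings` (first
#'   axis), `var_explained` (fraction of total variance on the first axis),
#'   `community` data frame (`community_id`, `msl_raw`, `msl_scaled`).
#' @examples
#' m <- matrix(rbinom(80, 1, 0.5), 20, 4)
#' msl_scores(m, rep(c("a", "b"), each = 10))$var_explained
#' @export
msl_scores <- function(items, community_id) {
  items <- as.matrix(items)
  if (nrow(items) < 2L) stop("need at least 2 households")
  if (length(community_id) != nrow(items))
    stop("`community_id` must have one entry per household")
  v <- apply(items, 2, stats::var)
  if (sum(v > 0) < 2L) stop("need at least 2 items with nonzero variance")

  pca <- stats::prcomp(items, center = TRUE, scale. = FALSE)
  scores <- pca$x[, 1]
  loadings <- pca$rotation[, 1]
  # wealthier (more items) = higher score
  orient <- stats::cov(scores, rowSums(items))
  if (orient < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  var_explained <- pca$sdev[1]^2 / sum(pca$sdev^2)

  raw <- tapply(scores, community_id, mean)
  rng <- range(raw)
  scaled <- if (diff(rng) == 0) rep(0, length(raw)) else (raw - rng[1]) / diff(rng)
  structure(list(
    household_scores = scores,
    loadings = loadings,
    var_explained = var_explained,
    community = data.frame(community_id = names(raw),
                           msl_raw = as.numeric(raw),
                           msl_scaled = as.numeric(scaled),
                           stringsAsFactors = FALSE)
  ), class = "msl_result")
}

#' Temporal trajectory of a community in wealth space
#'
#' For repeat survey waves of the same community, fits one principal component
#' analysis on the households pooled across all waves and projects each wave's
#' centroid into that common (PC1, PC2) plane, so displacement between waves is
#' comparable. Joint fisheries-agriculture sensitivity is recomputed per wave.
#'
#' @param waves Named list; each element is a list with `items` (household x
#'   item 0/1 matrix) and `survey` (long occupation table with `household_id`,
#'   `occupation`, `rank`, plus `community_id`, `country`).
#' @return Data frame, one row per wave: `wave`, `pc1`, `pc2`, `n_households`,
#'   `S_AF`. The pooled PCA loadings are attached as attribute `"loadings"`.
#' @export
temporal_trajectory <- function(waves) {
  if (length(waves) < 2L) stop("need at least 2 survey waves")
  n_hh <- vapply(waves, function(w) nrow(as.matrix(w$items)), integer(1))
  if (any(n_hh < 2L)) stop("every wave needs at least 2 households")

  pooled <- do.call(rbind, lapply(waves, function(w) as.matrix(w$items)))
  pca <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  ax <- pca$rotation[, 1:2, drop = FALSE]
  sgn <- sign(stats::cov(pca$x[, 1], rowSums(pooled)))
  if (sgn < 0) ax[, 1] <- -ax[, 1]
  ctr <- pca$center

  wave_names <- if (is.null(names(waves))) as.character(seq_along(waves)) else names(waves)
  rows <- lapply(seq_along(waves), function(i) {
    items <- as.matrix(waves[[i]]$items)
    proj <- scale(items, center = ctr, scale = FALSE) %*% ax
    cnt <- sector_counts(waves[[i]]$survey, focal = "joint")
    s <- if (cnt$X + cnt$NX == 0L) NA_real_ else sensitivity_index(cnt)$S
    data.frame(wave = wave_names[i],
               pc1 = mean(proj[, 1]), pc2 = mean(proj[, 2]),
               n_households = nrow(items), S_AF = s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "loadings") <- ax
  out
}
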