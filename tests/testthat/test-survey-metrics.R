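test_that("household classification maps occupations to sectors with best ranks", {
  r <- classify_household(c("fishing", "farming"), c(1, 2))
  expect_true(r$engaged[["fisheries"]] && r$engaged[["agriculture"]])
  expect_equal(r$best_rank[["fisheries"]], 1)
  expect_equal(r$best_rank[["agriculture"]], 2)

  r <- classify_household("tourism", 1)
  expect_equal(unname(r$engaged), c(FALSE, FALSE, TRUE))

  r <- classify_household(c("gleaning", "cash_crop", "salaried"), c(3, 1, 2))
  expect_equal(r$best_rank[["fisheries"]], 3)
  expect_equal(r$best_rank[["agriculture"]], 1)
  expect_equal(r$best_rank[["off"]], 2)

  expect_error(classify_household("piracy", 1), "piracy")
  expect_error(classify_household(c("fishing", "farming"), c(1, 1)), "distinct")
  expect_error(classify_household(character(0), integer(0)), "at least one")
})

test_that("sector counts match a hand enumeration and degenerate communities", {
  # 4 agriculture-only, 2 dual (one each ranking direction), 4 off-only
  hh <- rbind(
    data.frame(household_id = sprintf("h%d", 1:4), occupation = "farming", rank = 1),
    data.frame(household_id = "h5", occupation = c("farming", "fishing"), rank = c(1, 2)),
    data.frame(household_id = "h6", occupation = c("fishing", "farming"), rank = c(1, 2)),
    data.frame(household_id = sprintf("h%d", 7:10), occupation = "salaried", rank = 1)
  )
  cnt <- sector_counts(hh, focal = "agriculture")
  expect_equal(cnt[c("X", "NX", "N", "r_x", "r_nx")],
               list(X = 6L, NX = 6L, N = 10L, r_x = 1L, r_nx = 1L))

  only_f <- data.frame(household_id = sprintf("h%d", 1:5),
                       occupation = "fishing", rank = 1)
  cnt <- sector_counts(only_f, focal = "fisheries")
  expect_equal(cnt[c("X", "NX", "r_x", "r_nx")],
               list(X = 5L, NX = 0L, r_x = 0L, r_nx = 0L))
  expect_equal(sector_counts(only_f, focal = "agriculture")$X, 0L)
})

test_that("the sensitivity index reproduces hand-evaluated values", {
  s <- sensitivity_index(X = 6, NX = 6, N = 10, r_x = 1, r_nx = 1)
  expect_equal(s$S, (6 / 12) * (10 / 12) * (1.5 / 3), tolerance = 1e-15)
  expect_equal(s$S, 0.2083333, tolerance = 1e-6)

  expect_equal(sensitivity_index(X = 10, NX = 0, N = 10, r_x = 0, r_nx = 0)$S, 1)
  expect_equal(sensitivity_index(X = 0, NX = 10, N = 10, r_x = 0, r_nx = 0)$S, 0)
  expect_error(sensitivity_index(X = 0, NX = 0, N = 5, r_x = 0, r_nx = 0),
               "no occupations")
})

test_that("sensitivity stays in [0,1] and equals the brute-force oracle", {
  set.seed(101)
  for (i in 1:300) {
    cm <- random_community(sample(3:40, 1))
    for (f in c("agriculture", "fisheries", "joint")) {
      cnt <- sector_counts(cm$long, focal = f)
      if (cnt$X + cnt$NX == 0L) next
      s <- sensitivity_index(cnt)
      expect_gte(s$S, 0)
      expect_lte(s$S, 1)
      expect_equal(s$S, brute_force_sensitivity(cm$households, f),
                   tolerance = 1e-12)
    }
  }
})

test_that("engagement grows with focal-only households; no links means factor 3 is 1", {
  set.seed(11)
  cm <- random_community(20)
  cnt <- sector_counts(cm$long, focal = "fisheries")
  extra <- data.frame(household_id = "h999", occupation = "fishing", rank = 1,
                      community_id = "C01", country = "x")
  cnt2 <- sector_counts(rbind(cm$long, extra), focal = "fisheries")
  expect_gte(sensitivity_index(cnt2)$engagement, sensitivity_index(cnt)$engagement)

  # single-sector households only: no dual engagement anywhere
  solo <- rbind(
    data.frame(household_id = sprintf("a%d", 1:5), occupation = "farming", rank = 1),
    data.frame(household_id = sprintf("f%d", 1:5), occupation = "fishing", rank = 1)
  )
  for (f in c("agriculture", "fisheries")) {
    cnt <- sector_counts(solo, focal = f)
    expect_equal(cnt$r_x + cnt$r_nx, 0L)
    expect_equal(sensitivity_index(cnt)$directionality, 1)
  }
})

test_that("the per-pair ranking rule counts every ordered occupation pair", {
  hh <- data.frame(household_id = "h1",
                   occupation = c("fishing", "gleaning", "farming"),
                   rank = c(1, 3, 2))
  cnt <- sector_counts(hh, focal = "fisheries", per_pair = TRUE)
  # pairs: fishing<farming, gleaning>farming
  expect_equal(c(cnt$r_x, cnt$r_nx), c(1L, 1L))
  cnt_hh <- sector_counts(hh, focal = "fisheries")
  expect_equal(c(cnt_hh$r_x, cnt_hh$r_nx), c(1L, 0L))
})

test_that("wealth PCA separates archetypes and matches an eigensolver oracle", {
  # two household archetypes: all 16 items vs none
  items <- rbind(matrix(1, 5, 16), matrix(0, 5, 16))
  comm <- rep(c("rich", "poor"), each = 5)
  m <- msl_scores(items, comm)
  expect_length(unique(round(m$household_scores, 10)), 2)
  expect_setequal(m$community$msl_scaled, c(0, 1))
  expect_gt(m$household_scores[1], m$household_scores[6])  # orientation

  # duplicated households score identically
  set.seed(5)
  x <- matrix(rbinom(10 * 16, 1, 0.5), 10, 16)
  x[3, ] <- x[7, ]
  m2 <- msl_scores(x, rep("c1", 10))
  expect_equal(m2$household_scores[3], m2$household_scores[7])

  # small matrix against a direct covariance eigen-decomposition
  y <- matrix(c(1, 0, 1, 0,
                1, 1, 0, 0,
                0, 1, 1, 1), 4, 3)
  ev <- eigen(stats::cov(y))
  oracle <- scale(y, center = TRUE, scale = FALSE) %*% ev$vectors[, 1]
  m3 <- msl_scores(y, rep(c("u", "v"), 2))
  expect_equal(abs(as.numeric(stats::cor(m3$household_scores, oracle))), 1,
               tolerance = 1e-12)
  expect_equal(m3$var_explained, ev$values[1] / sum(ev$values), tolerance = 1e-12)

  expect_error(msl_scores(matrix(1, 4, 16), rep("c", 4)), "variance")
})

test_that("community rescaling preserves the wealth ordering", {
  set.seed(21)
  items <- matrix(rbinom(60 * 16, 1, runif(60 * 16, 0.2, 0.8)), 60, 16)
  comm <- rep(sprintf("C%02d", 1:6), each = 10)
  m <- msl_scores(items, comm)
  expect_equal(stats::cor(m$community$msl_raw, m$community$msl_scaled,
                          method = "spearman"), 1)
  expect_equal(range(m$community$msl_scaled), c(0, 1))
})

test_that("temporal trajectories live in one pooled wealth space", {
  set.seed(31)
  items <- matrix(rbinom(12 * 16, 1, 0.5), 12, 16)
  occ <- do.call(rbind, lapply(1:12, function(i)
    data.frame(community_id = "C01", country = "x",
               household_id = sprintf("h%d", i),
               occupation = sample(c("fishing", "farming"), 1), rank = 1)))
  wave <- list(items = items, survey = occ)

  tr <- temporal_trajectory(list(w1 = wave, w2 = wave))
  expect_equal(tr$pc1[1], tr$pc1[2])
  expect_equal(tr$pc2[1], tr$pc2[2])
  expect_equal(tr$S_AF[1], tr$S_AF[2])  # constant occupations, no change

  # wave 2 gains one fixed item: displacement parallel to that item's loading
  j <- which(colSums(items) == 0)[1]
  if (is.na(j)) { items[, 16] <- 0; j <- 16; wave$items <- items }
  items2 <- items; items2[, j] <- 1
  tr2 <- temporal_trajectory(list(w1 = wave, w2 = list(items = items2, survey = occ)))
  disp <- c(tr2$pc1[2] - tr2$pc1[1], tr2$pc2[2] - tr2$pc2[1])
  expect_equal(disp, unname(attr(tr2, "loadings")[j, ]), tolerance = 1e-10)

  expect_error(temporal_trajectory(list(wave)), "at least 2")
  tiny <- list(items = items[1, , drop = FALSE], survey = occ[1, ])
  expect_error(temporal_trajectory(list(wave, tiny)), "at least 2 households")
})

test_that("community sensitivity table covers all three sectors", {
  cfg <- small_config()
  sv <- generate_survey(cfg)
  out <- community_sensitivity(sv$survey)
  expect_equal(nrow(out), 10)
  for (col in c("S_A", "S_F", "S_AF")) {
    expect_true(all(out[[col]] >= 0 & out[[col]] <= 1))
  }
  expect_equal(out$N, sv$communities$n_households[
    match(out$community_id, sv$communities$community_id)])
})
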