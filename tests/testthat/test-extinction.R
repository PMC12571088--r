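test_that("APPD equals the exhaustive mean over all pairs", {
  set.seed(20)
  a <- rand_config(6L); b <- a + 1  # pure translation of aligned coords
  d <- procrustes_distance(a, b)
  expect_equal(appd(rbind(as.numeric(a), as.numeric(b))), d)
  same <- rbind(as.numeric(a), as.numeric(a), as.numeric(a))
  expect_equal(appd(same), 0)
  X <- matrix(rnorm(7 * 10), 7L)
  brute <- 0; n <- 7L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    brute <- brute + sqrt(sum((X[i, ] - X[j, ])^2))
  }
  brute <- 2 * brute / (n * (n - 1))
  expect_equal(appd(X), brute, tolerance = 1e-12)
  expect_error(appd(X[1, , drop = FALSE]), "fewer than 2")
})

test_that("removing the most peripheral configuration never raises APPD", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:12, 1L)
    X <- matrix(rnorm(n * 6L), n)
    D <- as.matrix(dist(X))
    worst <- which.max(rowSums(D) / (n - 1))
    expect_lte(appd(X[-worst, , drop = FALSE]), appd(X) + 1e-12)
  }
})

test_that("Procrustes variance matches its direct formula", {
  set.seed(22)
  X <- matrix(rnorm(12 * 8), 12L)
  g <- rep(c("a", "b"), each = 6L)
  pv <- procrustes_variance(X, g)
  for (lv in c("a", "b")) {
    rows <- X[g == lv, ]
    mn <- colMeans(rows)
    direct <- mean(apply(rows, 1L, function(r) sum((r - mn)^2)))
    expect_equal(unname(pv[lv]), direct, tolerance = 1e-12)
  }
  # identical members: zero variance; permutation invariance
  expect_equal(unname(procrustes_variance(X[c(1, 1, 1), ],
                                          rep("a", 3L))), 0)
  prm <- sample(12L)
  expect_equal(procrustes_variance(X[prm, ], g[prm]), pv)
  expect_warning(pv1 <- procrustes_variance(X, c("a", rep("b", 11L))),
                 "singleton")
  expect_true(is.na(pv1["a"]))
})

test_that("canonical scenarios are nested and give the printed removal counts", {
  sp <- small_species_space()
  scens <- canonical_scenarios()
  res <- lapply(scens, function(s) apply_scenario(sp$ord, sp$traits, s,
                                                  shapes = sp$shapes))
  expect_identical(vapply(res, `[[`, 0L, "n_removed"), c(4L, 12L, 22L, 26L))
  # nesting: each removal set contains the previous one
  for (i in 2:4) {
    expect_true(all(res[[i - 1L]]$removed %in% res[[i]]$removed))
    expect_true(all(res[[i]]$survivors %in% res[[i - 1L]]$survivors))
  }
  # survivors and removed partition the species set
  for (r in res) {
    expect_setequal(c(r$removed, r$survivors), sp$ord$ids)
    expect_length(intersect(r$removed, r$survivors), 0L)
  }
})

test_that("an empty removal set changes nothing", {
  sp <- small_species_space()
  r <- apply_scenario(sp$ord, sp$traits,
                      list(name = "none", removed_statuses = character(0)),
                      shapes = sp$shapes)
  expect_identical(r$n_removed, 0L)
  expect_equal(r$pct_area_loss, 0)
  expect_equal(r$centroid_shift$magnitude, 0)
  expect_equal(r$appd, appd(sp$shapes))
})

test_that("hull area never grows along the nested scenario sequence", {
  sp <- small_species_space(seed = 5L)
  scens <- canonical_scenarios()
  areas <- vapply(scens, function(s) {
    apply_scenario(sp$ord, sp$traits, s, shapes = sp$shapes)$hull_area
  }, 0)
  expect_true(all(diff(areas) <= 1e-12))
  expect_lte(areas[1L], hull_area(sp$ord$scores)$area)
})

test_that("random extinction nulls are reproducible and well-formed", {
  sp <- small_species_space(seed = 9L)
  n1 <- random_extinction_null(sp$ord, k = 12L, n_reps = 50L, seed = 42L)
  n2 <- random_extinction_null(sp$ord, k = 12L, n_reps = 50L, seed = 42L)
  expect_identical(n1$appd$values, n2$appd$values)
  for (nl in n1) {
    expect_length(nl$values, 50L)
    expect_lte(nl$lower, nl$mean)
    expect_lte(nl$mean, nl$upper)
  }
  # boundary: 2 survivors fine, 1 survivor is an error
  expect_no_error(random_extinction_null(sp$ord, k = 28L, n_reps = 5L,
                                         seed = 1L))
  expect_error(random_extinction_null(sp$ord, k = 29L, n_reps = 5L,
                                      seed = 1L), "fewer than 2")
  expect_error(random_extinction_null(sp$ord, k = 30L, n_reps = 5L,
                                      seed = 1L), "k must")
})

test_that("uniform removal is unbiased for the survivor mean PC1", {
  sp <- small_species_space(seed = 10L)
  nl <- random_extinction_null(sp$ord, k = 10L, n_reps = 400L, seed = 3L)
  base <- mean(sp$ord$scores[, 1L])
  se <- sd(nl$mean_PC1$values) / sqrt(400L)
  expect_lt(abs(nl$mean_PC1$mean - base), 3 * se)
})

test_that("null envelopes widen with extinction intensity on isotropic scores", {
  set.seed(30)
  shapes <- matrix(rnorm(30 * 2), 30L)  # isotropic PC scores
  rownames(shapes) <- sprintf("sp%03d", 1:30)
  ord <- ordinate(cbind(shapes, shapes[, 1] * 0))  # 2 informative axes
  widths <- vapply(c(4L, 12L, 22L, 26L), function(k) {
    nl <- random_extinction_null(ord, k = k, n_reps = 200L, seed = 8L)
    nl$mean_PC1$upper - nl$mean_PC1$lower
  }, 0)
  expect_true(all(diff(widths) >= -0.05 * widths[-length(widths)]))
  expect_gt(widths[4L], widths[1L])
})

test_that("targeted statistics are classified against the null envelope", {
  nl <- structure(list(statistic = "appd", k = 4L, values = 1:100 / 100,
                       mean = 0.5, lower = 0.1, upper = 0.9,
                       n_reps = 100L, seed = 1L, envelope = "percentile"),
                  class = "null_distribution")
  expect_identical(targeted_vs_null(0.5, nl), "within")
  expect_identical(targeted_vs_null(0.05, nl), "below")
  expect_identical(targeted_vs_null(0.95, nl), "above")
  expect_error(targeted_vs_null(0.5, nl, k = 12L), "mismatch")
})

test_that("threat aimed at peripheral species shrinks hulls monotonically", {
  ## assign threat by distance from the morphospace centroid: the most
  ## peripheral species get the highest threat ranks
  sp <- small_species_space(seed = 12L)
  d <- sqrt(rowSums(sweep(sp$ord$scores[, 1:2], 2L,
                          colMeans(sp$ord$scores[, 1:2]))^2))
  traits <- sp$traits
  traits$iucn <- rep(c("CR", "EN", "VU", "NT", "LC"),
                     c(4L, 8L, 10L, 4L, 4L))[rank(-d, ties.method = "first")]
  areas <- vapply(canonical_scenarios(), function(s) {
    apply_scenario(sp$ord, traits, s, shapes = sp$shapes)$hull_area
  }, 0)
  expect_true(all(diff(areas) <= 1e-12))
  expect_lt(areas[1L], hull_area(sp$ord$scores)$area)
})
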