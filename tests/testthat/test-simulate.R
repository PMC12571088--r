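test_that("pure-birth trees are ultrametric, unit depth, deterministic", {
  tr <- simulate_tree(2L, seed = 1L)
  d <- ape::node.depth.edgelength(tr)
  expect_equal(unname(d[1:2]), c(1, 1))
  expect_identical(tr$tip.label, c("sp001", "sp002"))
  t1 <- simulate_tree(12L, seed = 7L)
  t2 <- simulate_tree(12L, seed = 7L)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(t1)), 1, tolerance = 1e-10)
  expect_error(simulate_tree(1L), "at least 2")
})

test_that("tree shape matches an independent forward Yule oracle", {
  mpd <- function(tr) {
    d <- ape::cophenetic.phylo(tr)
    mean(d[upper.tri(d)])
  }
  gen <- vapply(1:300, function(i) mpd(simulate_tree(10L, seed = i)), 0)
  set.seed(99)
  oracle <- replicate(300L, yule_mpd_oracle(10L))
  expect_lt(abs(mean(gen) - mean(oracle)) / mean(oracle), 0.05)
})

test_that("zero-rate Brownian motion reproduces the template exactly", {
  tree <- simulate_tree(4L, seed = 2L)
  ssh <- simulate_species_shapes(tree, sigma2_b = c(0, 0, 0), seed = 3L)
  tpl <- tooth_template()
  for (sp in names(ssh$shapes)) {
    expect_equal(ssh$shapes[[sp]]$points, tpl$points)
  }
})

test_that("the apex stays the unique global y-maximum of every crown", {
  tree <- simulate_tree(15L, seed = 4L)
  ssh <- suppressWarnings(simulate_species_shapes(tree, seed = 5L))
  for (cf in ssh$shapes) {
    apex_y <- cf$points[2L, 2L]
    others <- cf$points[-2L, 2L]
    expect_gt(apex_y, max(others))
  }
  # out-of-range parameters are clipped with a warning
  expect_warning(tooth_template(obliquity = 2), "clipped")
})

test_that("tip parameters covary with shared branch lengths under BM", {
  tree <- simulate_tree(8L, seed = 6L)
  C <- ape::vcv(tree)
  reps <- vapply(1:300, function(i) {
    ## clipping warnings only affect the template mapping, not the params
    suppressWarnings(
      simulate_species_shapes(tree, sigma2_b = c(0.06, 0, 0),
                              seed = 1000L + i)$params[, 1L])
  }, numeric(8L))
  emp <- cov(t(reps))
  expect_gt(cor(emp[upper.tri(emp)], 0.06 * C[upper.tri(C)]), 0.9)
})

test_that("specimen noise and counts behave as configured", {
  tree <- simulate_tree(4L, seed = 8L)
  ssh <- simulate_species_shapes(tree, seed = 9L)
  # sigma_w = 0 and no jaw effect: specimens identical to the species mean
  cfgs0 <- simulate_specimens(ssh, teeth_per_species = c(3L, 3L),
                              sigma_w = 0, jaw_effect = 1,
                              transform = FALSE, seed = 10L)
  expect_length(cfgs0, 12L)
  for (cf in cfgs0) {
    expect_equal(cf$points, ssh$shapes[[cf$species_id]]$points,
                 tolerance = 1e-12)
  }
  # within-species Procrustes variance grows with sigma_w
  pv_at <- function(sw) {
    cf <- simulate_specimens(ssh, teeth_per_species = c(12L, 12L),
                             sigma_w = sw, seed = 11L)
    g <- superimpose(cf, slide = FALSE)
    mean(procrustes_variance(g$coordinates, g$species))
  }
  pv <- vapply(c(0.005, 0.02, 0.06), pv_at, 0)
  expect_true(all(diff(pv) > 0))
})

test_that("status counts are exact and selectivity behaves with beta", {
  tree <- simulate_tree(30L, seed = 12L)
  ssh <- simulate_species_shapes(tree, seed = 13L)
  at <- assign_statuses_and_traits(ssh$params, beta = 2, seed = 14L)
  expect_equal(unname(table(at$traits$iucn)[c("CR", "EN", "VU", "NT", "LC")]),
               c(4L, 8L, 10L, 4L, 4L), ignore_attr = TRUE)
  expect_error(assign_statuses_and_traits(ssh$params, counts = c(CR = 1L)),
               "counts sum")
  # beta = 0: threat rank independent of s1 (mean rank correlation ~ 0)
  rho <- vapply(1:200, function(i) {
    a <- assign_statuses_and_traits(ssh$params, beta = 0, seed = 100L + i)
    rank_threat <- match(a$traits$iucn, c("CR", "EN", "VU", "NT", "LC"))
    cor(rank_threat, ssh$params[a$traits$species_id, 1L],
        method = "spearman")
  }, 0)
  expect_lt(abs(mean(rho)), 0.05)
  # strong selectivity: CR species are morphologically extreme (and skew
  # negative) relative to the central least-concern species
  sel <- vapply(1:100, function(i) {
    a <- assign_statuses_and_traits(ssh$params, beta = 5, seed = 300L + i)
    s1 <- scale(ssh$params[, 1L])[match(a$traits$species_id,
                                        rownames(ssh$params))]
    c(mean(abs(s1[a$traits$iucn == "CR"])) >
        mean(abs(s1[a$traits$iucn == "LC"])),
      mean(s1[a$traits$iucn == "CR"]) < mean(s1[a$traits$iucn == "LC"]))
  }, logical(2L))
  expect_gte(mean(sel[1L, ]), 0.95)
  expect_gte(mean(sel[2L, ]), 0.90)
})

test_that("diet matrices are proportional with size-linked evenness", {
  tree <- simulate_tree(30L, seed = 15L)
  ssh <- simulate_species_shapes(tree, seed = 16L)
  at <- assign_statuses_and_traits(ssh$params, seed = 17L)
  expect_equal(unname(rowSums(at$diets)), rep(1, nrow(at$diets)),
               tolerance = 1e-12)
  expect_true(all(at$diets >= 0))
  expect_true(all(colSums(at$diets) > 0))
  expect_identical(ncol(at$diets), 10L)
})

test_that("one root seed reproduces the whole bundle bit-identically", {
  b1 <- simulate_dataset(n_species = 6L, teeth_per_species = c(3L, 5L),
                         seed = 21L)
  b2 <- simulate_dataset(n_species = 6L, teeth_per_species = c(3L, 5L),
                         seed = 21L)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  expect_identical(b1$params, b2$params)
  expect_identical(b1$traits, b2$traits)
  expect_identical(b1$diets, b2$diets)
  expect_identical(lapply(b1$configs, `[[`, "points"),
                   lapply(b2$configs, `[[`, "points"))
  b3 <- simulate_dataset(n_species = 6L, teeth_per_species = c(3L, 5L),
                         seed = 22L)
  expect_false(identical(b1$params, b3$params))
})

test_that("generated bundles satisfy the digitization scheme", {
  b <- simulate_dataset(n_species = 5L, teeth_per_species = c(3L, 4L),
                        seed = 23L)
  for (cf in b$configs) {
    expect_identical(sum(cf$roles == "fixed"), 3L)
    expect_identical(sum(cf$roles == "semilandmark"), 157L)
    expect_length(cf$curves, 2L)
    expect_identical(vapply(cf$curves, length, 0L), c(78L, 79L))
  }
})
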