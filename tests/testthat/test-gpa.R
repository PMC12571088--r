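test_that("equidistant resampling preserves endpoints and spacing", {
  seg <- resample_equidistant(rbind(c(0, 0), c(1, 0)), 5L)
  expect_equal(seg, cbind(c(0, .25, .5, .75, 1), 0))
  # parametrization invariance: uneven vertices on the same segment
  uneven <- rbind(c(0, 0), c(0.05, 0), c(0.9, 0), c(1, 0))
  expect_equal(resample_equidistant(uneven, 5L), seg)
  expect_error(resample_equidistant(rbind(c(1, 1), c(1, 1)), 3L),
               "zero-length")
})

test_that("resampled arcs have equal chords (dense arc-length oracle)", {
  th <- seq(0, pi, length.out = 100L)
  arc <- cbind(cos(th), sin(th))
  out <- resample_equidistant(arc, 10L)
  chords <- sqrt(rowSums(diff(out)^2))
  expect_lt(diff(range(chords)) / mean(chords), 0.01)
  # dense numerical integration oracle: equal arc-length spacing targets
  dense <- resample_equidistant(arc, 5000L)
  s <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  idx <- vapply(seq(0, max(s), length.out = 10L),
                function(t) which.min(abs(s - t)), 0L)
  expect_equal(out, dense[idx, ], tolerance = 1e-3)
})

test_that("centroid size matches its closed form and scales linearly", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2))
  set.seed(4)
  m <- rand_config(12L)
  expect_equal(centroid_size(2 * m), 2 * centroid_size(m))
  direct <- sqrt(sum(sweep(m, 2L, colMeans(m))^2))
  expect_equal(centroid_size(m), direct, tolerance = 1e-12)
  expect_error(centroid_size(rbind(c(1, 2), c(1, 2))), "coincident")
})

test_that("procrustes distance is a metric on aligned sets", {
  set.seed(9)
  a <- rand_config(8L)
  expect_identical(procrustes_distance(a, a), 0)
  b <- rand_config(8L); c3 <- rand_config(8L)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a))
  aligned <- replicate(10L, rand_config(8L), simplify = FALSE)
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(procrustes_distance(aligned[[i]], aligned[[j]]),
               procrustes_distance(aligned[[i]], aligned[[k]]) +
                 procrustes_distance(aligned[[k]], aligned[[j]]) + 1e-12)
  }
  expect_error(procrustes_distance(a, rand_config(9L)), "mismatch")
})

test_that("bending energy vanishes on affine transforms and is PSD", {
  set.seed(2)
  ref <- rand_config(15L)
  bem <- bending_energy_model(ref)
  expect_equal(bem$energy, t(bem$energy))
  ev <- eigen(bem$energy, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(abs(ev)))
  A <- matrix(c(1.3, 0.2, -0.4, 0.8), 2L)
  affine <- sweep(ref %*% A, 2L, c(3, -1), `+`)
  expect_lt(bending_energy(bem, affine), 1e-8)
  bent <- ref + cbind(0.1 * sin(ref[, 2L] * 4), 0)
  expect_gt(bending_energy(bem, bent), 1e-6)
})

test_that("superimposition removes similarity transforms exactly", {
  tpl <- tooth_template()
  moved <- tpl
  moved$points <- similar(tpl$points, th = pi / 2, v = c(5, -2))
  moved$specimen_id <- "copy"
  g <- superimpose(list(tpl, moved), slide = FALSE)
  expect_equal(g$coordinates[1L, ], g$coordinates[2L, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(procrustes_distance(g$coordinates[1L, ], g$coordinates[2L, ]),
               0, tolerance = 1e-8)
})

test_that("aligned configurations are centered with unit centroid size", {
  set.seed(21)
  mats <- replicate(6L, rand_config(10L), simplify = FALSE)
  g <- superimpose(mats, slide = FALSE)
  for (i in seq_len(6L)) {
    m <- matrix(g$coordinates[i, ], ncol = 2L)
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_equal(sqrt(sum(m^2)), 1, tolerance = 1e-9)
  }
  expect_equal(matrix(colMeans(g$coordinates), ncol = 2L), g$consensus,
               tolerance = 1e-9)
})

test_that("superimposition is invariant to input similarity transforms", {
  set.seed(33)
  mats <- replicate(5L, rand_config(12L), simplify = FALSE)
  g0 <- superimpose(mats, slide = FALSE, tol = 1e-12)
  jig <- mats
  for (i in seq_along(jig)) {
    jig[[i]] <- similar(jig[[i]], th = runif(1, -pi, pi),
                        s = runif(1, 0.2, 5), v = rnorm(2L, sd = 10))
  }
  g1 <- superimpose(jig, slide = FALSE, tol = 1e-12)
  ## mod out the global rotational gauge before comparing
  S0 <- do.call(rbind, lapply(seq_along(mats), function(i) {
    matrix(g0$coordinates[i, ], ncol = 2L)
  }))
  S1 <- do.call(rbind, lapply(seq_along(mats), function(i) {
    matrix(g1$coordinates[i, ], ncol = 2L)
  }))
  expect_equal(align_global(S1, S0), S0, tolerance = 1e-8)
})

test_that("GPA matches the brute-force rotation-grid oracle", {
  set.seed(5)
  mats <- replicate(3L, rand_config(10L), simplify = FALSE)
  g <- superimpose(mats, slide = FALSE, tol = 1e-12)
  oracle <- gpa_grid_oracle(mats)
  R <- crossprod(oracle$consensus, g$consensus)
  sv <- svd(R)
  Rot <- sv$u %*% diag(c(1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
  for (i in 1:3) {
    expect_equal(oracle$aligned[[i]] %*% Rot,
                 matrix(g$coordinates[i, ], ncol = 2L), tolerance = 1e-5)
  }
})

test_that("a set already in Procrustes position is a fixed point", {
  set.seed(8)
  mats <- replicate(4L, rand_config(9L), simplify = FALSE)
  g <- superimpose(mats, slide = FALSE)
  aligned <- lapply(seq_len(4L), function(i) {
    matrix(g$coordinates[i, ], ncol = 2L)
  })
  g2 <- superimpose(aligned, slide = FALSE)
  expect_identical(g2$iterations_run, 1L)
  expect_true(g2$converged)
})

test_that("sliding lowers bending energy and never moves fixed landmarks", {
  b <- simulate_dataset(n_species = 5L, teeth_per_species = c(3L, 5L),
                        seed = 14L)
  g1 <- superimpose(b$configs, slide = TRUE)
  g0 <- superimpose(b$configs, slide = FALSE)
  be_total <- function(g) {
    bem <- bending_energy_model(g$consensus)
    sum(apply(g$coordinates, 1L, function(r) {
      bending_energy(bem, matrix(r, ncol = 2L))
    }))
  }
  expect_lte(be_total(g1), be_total(g0))
  ## the sliding step itself leaves fixed landmarks untouched, exactly
  cons <- g0$consensus
  B <- bending_energy_model(cons)$energy
  pts <- matrix(g0$coordinates[1L, ], ncol = 2L)
  slid <- toothspace:::.slide_one(pts, b$configs[[1L]]$curves, B)
  fixed <- which(b$configs[[1L]]$roles == "fixed")
  expect_identical(slid[fixed, ], pts[fixed, ])
  expect_false(isTRUE(all.equal(slid, pts)))
})

test_that("degenerate and mismatched inputs are rejected", {
  flat <- matrix(1, 5L, 2L)
  expect_error(superimpose(list(flat, flat), slide = FALSE), "degenerate")
  expect_error(superimpose(list(rand_config(5L), rand_config(6L)),
                           slide = FALSE), "mismatch")
})
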