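## Independent oracles and small fixture builders shared across tests.

## random p-point 2D configuration
rand_config <- function(p, sd = 1) matrix(rnorm(2 * p, sd = sd), ncol = 2)

## apply a similarity transform (rotation th, scale s, translation v)
similar <- function(m, th = 0, s = 1, v = c(0, 0)) {
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  sweep(s * m %*% R, 2L, v, `+`)
}

## Brute-force generalized Procrustes superimposition: alternating
## consensus updates with the per-specimen rotation found by nested grid
## search over the rotation angle (refined well below the comparison
## tolerance). Mirrors the package's normalization conventions but shares
## no code with the analytic rotation solution.
gpa_grid_oracle <- function(mats, tol = 1e-12, max_iter = 200L) {
  nrm <- function(m) {
    m <- sweep(m, 2L, colMeans(m))
    m / sqrt(sum(m^2))
  }
  rot <- function(m, th) {
    m %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  }
  best_rot <- function(m, C) {
    centre <- 0; width <- pi
    repeat {
      th <- seq(centre - width, centre + width, length.out = 73L)
      obj <- vapply(th, function(a) sum((rot(m, a) - C)^2), 0)
      centre <- th[which.min(obj)]
      width <- th[2L] - th[1L]
      if (width < 1e-9) return(rot(m, centre))
    }
  }
  X <- lapply(mats, nrm)
  X <- lapply(X, best_rot, C = X[[1L]])
  C <- nrm(Reduce(`+`, X) / length(X))
  for (it in seq_len(max_iter)) {
    X <- lapply(X, best_rot, C = C)
    Cn <- nrm(Reduce(`+`, X) / length(X))
    delta <- sqrt(mean((Cn - C)^2))
    C <- Cn
    if (delta < tol) break
  }
  X <- lapply(X, best_rot, C = C)
  list(aligned = X, consensus = Reduce(`+`, X) / length(X))
}

## optimal proper rotation aligning matrix A onto B (to mod out the
## global rotational gauge before comparing two superimpositions)
align_global <- function(A, B) {
  M <- crossprod(A, B)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  A %*% (sv$u %*% diag(c(1, d)) %*% t(sv$v))
}

## Monte Carlo rejection estimate of the area of the convex hull of pts
hull_mc_area <- function(pts, n = 2e5L) {
  bb <- apply(pts, 2L, range)
  xs <- runif(n, bb[1L, 1L], bb[2L, 1L])
  ys <- runif(n, bb[1L, 2L], bb[2L, 2L])
  poly <- pts[grDevices::chull(pts), , drop = FALSE]
  m <- nrow(poly)
  nxt <- c(2:m, 1L)
  inside <- rep(TRUE, n)
  ## convex polygon: point is inside iff on one side of every edge
  sgn <- 0
  for (e in seq_len(m)) {
    a <- poly[e, ]; b <- poly[nxt[e], ]
    cr <- (b[1L] - a[1L]) * (ys - a[2L]) - (b[2L] - a[2L]) * (xs - a[1L])
    if (sgn == 0) sgn <- sign(sum(sign(cr)))
    inside <- inside & (sgn * cr >= 0)
  }
  mean(inside) * prod(bb[2L, ] - bb[1L, ])
}

## Independent forward Yule simulation: 2 lineages, Exp(k) waiting times,
## uniform lineage splits, an Exp(n) stretch to the present, depth scaled
## to 1. Returns the mean pairwise tip distance.
yule_mpd_oracle <- function(n) {
  k <- 2L; t <- 0
  M <- matrix(0, 2L, 2L)  # pairwise divergence times
  while (k < n) {
    t <- t + rexp(1L, k)
    i <- sample.int(k, 1L)
    M <- rbind(cbind(M, M[, i]), c(M[i, ], 0))
    M[i, k + 1L] <- M[k + 1L, i] <- t
    k <- k + 1L
  }
  t <- t + rexp(1L, n)
  D <- 2 * (t - M)
  diag(D) <- 0
  mean(D[upper.tri(D)]) / t
}

## canonical 30-species status fixture: counts CR 4, EN 8, VU 10, NT 4, LC 4
canonical_traits <- function() {
  data.frame(
    species_id = sprintf("sp%03d", 1:30),
    iucn = rep(c("CR", "EN", "VU", "NT", "LC"), c(4L, 8L, 10L, 4L, 4L)),
    max_depth_m = seq(20, 600, length.out = 30),
    stringsAsFactors = FALSE)
}

## small aligned species-mean bundle for scenario tests: shapes, pca, traits
small_species_space <- function(n_species = 30L, seed = 1L) {
  set.seed(seed)
  shapes <- matrix(rnorm(n_species * 8L, sd = 0.1), n_species)
  rownames(shapes) <- sprintf("sp%03d", seq_len(n_species))
  list(shapes = shapes, ord = ordinate(shapes), traits = canonical_traits())
}
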