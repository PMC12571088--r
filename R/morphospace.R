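#' Per-species mean shapes
#'
#' Arithmetic mean of the aligned Procrustes coordinates per species,
#' optionally restricted to upper- or lower-jaw teeth. Species with no
#' specimens in the requested subset are dropped with a warning.
#'
#' @param aligned a `gpa_fit` from [superimpose] (with species metadata),
#'   or a coordinate matrix if `species` is supplied.
#' @param subset `"both"`, `"upper"` or `"lower"` jaw teeth.
#' @param species,jaw optional vectors overriding the fit's metadata.
#' @return species-by-coordinate matrix with species ids as row names.
#' @export
species_mean_shapes <- function(aligned, subset = c("both", "upper", "lower"),
                                species = NULL, jaw = NULL) {
  subset <- match.arg(subset)
  coords <- if (inherits(aligned, "gpa_fit")) aligned$coordinates else
    as.matrix(aligned)
  species <- species %||% aligned$species
  jaw <- jaw %||% aligned$jaw
  if (is.null(species)) stop("species labels are required")
  keep <- if (subset == "both") rep(TRUE, nrow(coords)) else jaw == subset
  if (!any(keep)) stop("no specimens in subset '", subset, "'")
  lost <- setdiff(unique(species), unique(species[keep]))
  if (length(lost)) {
    warning("species with no specimens in subset '", subset, "': ",
            paste(lost, collapse = ", "))
  }
  m <- rowsum(coords[keep, , drop = FALSE], species[keep])
  m / as.numeric(table(species[keep])[rownames(m)])
}

#' Principal components ordination of shape data
#'
#' Eigendecomposition of the covariance of the centered rows; scores are
#' the centered rows projected on the eigenvectors. Axis signs follow a
#' deterministic rule: each axis is oriented so its largest-magnitude
#' loading is positive.
#'
#' @param x entity-by-coordinate matrix (e.g. from
#'   [species_mean_shapes]).
#' @return object of class `shape_pca`: `scores`, `eigenvalues`
#'   (descending), `percent_variance` (sums to 100), `center` (the mean
#'   shape vector), `loadings` (coordinate-by-axis matrix), `ids`.
#' @export
ordinate <- function(x) {
  X <- as.matrix(x)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 entities to ordinate")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = 0)
  k <- min(n - 1L, ncol(X))
  ev <- (sv$d^2 / (n - 1L))[seq_len(k)]
  V <- sv$v[, seq_len(k), drop = FALSE]
  flip <- apply(V, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  V <- sweep(V, 2L, flip, `*`)
  scores <- Xc %*% V
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(X)
  structure(list(ids = rownames(X), scores = scores, eigenvalues = ev,
                 percent_variance = 100 * ev / sum(ev),
                 center = ctr, loadings = V),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("Shape PCA of", nrow(x$scores), "entities,",
      length(x$eigenvalues), "axes\n")
  cat("  % variance:",
      paste(sprintf("%s %.2f%%", colnames(x$scores)[seq_len(k)],
                    x$percent_variance[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.shape_pca <- function(x, axes = c(1L, 2L), labels = FALSE, ...) {
  s <- x$scores[, axes, drop = FALSE]
  lab <- sprintf("PC%d (%.1f%%)", axes, x$percent_variance[axes])
  graphics::plot(s, xlab = lab[1L], ylab = lab[2L], pch = 21,
                 bg = "steelblue", asp = 1, ...)
  hull <- grDevices::chull(s)
  graphics::polygon(s[hull, ], border = "grey30")
  if (labels) graphics::text(s, labels = rownames(s), pos = 3, cex = 0.6)
  invisible(x)
}

.shoelace <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Convex hull of ordination scores
#'
#' Convex hull of (PC1, PC2) points with area by the shoelace formula on
#' the hull vertices; fewer than three non-collinear points give area 0.
#' The centroid is the mean of all member points, not just hull vertices.
#'
#' @param scores 2-column matrix of ordination scores.
#' @return object of class `hull_summary`: `vertices` (row indices or
#'   names), `area`, `centroid`.
#' @export
hull_area <- function(scores) {
  s <- as.matrix(scores)[, 1:2, drop = FALSE]
  centroid <- colMeans(s)
  if (nrow(s) < 3L) {
    return(structure(list(vertices = rownames(s) %||% seq_len(nrow(s)),
                          area = 0, centroid = centroid),
                     class = "hull_summary"))
  }
  h <- grDevices::chull(s)
  area <- .shoelace(s[h, , drop = FALSE])
  structure(list(vertices = (rownames(s) %||% seq_len(nrow(s)))[h],
                 area = area, centroid = centroid),
            class = "hull_summary")
}

#' @export
print.hull_summary <- function(x, ...) {
  cat(sprintf("Convex hull: %d vertices, area %.6g; centroid (%.4g, %.4g)\n",
              length(x$vertices), x$area, x$centroid[1L], x$centroid[2L]))
  invisible(x)
}

#' Centroid displacement between baseline and survivors
#'
#' Vector from the baseline mean to the survivor mean in the fixed
#' baseline ordination (scores are not re-ordinated after removal).
#'
#' @param baseline 2-column score matrix for all entities.
#' @param survivors 2-column score matrix for the surviving subset (rows
#'   must come from `baseline`).
#' @return list with `delta` (dPC1, dPC2), `magnitude`, `direction`
#'   (atan2 angle, radians) and `degenerate` (TRUE when the shift is
#'   exactly zero, in which case the angle is reported as 0).
#' @export
centroid_shift <- function(baseline, survivors) {
  b <- as.matrix(baseline)[, 1:2, drop = FALSE]
  s <- as.matrix(survivors)[, 1:2, drop = FALSE]
  if (nrow(s) == 0L) stop("empty survivor set")
  delta <- colMeans(s) - colMeans(b)
  mag <- sqrt(sum(delta^2))
  list(delta = delta, magnitude = mag,
       direction = if (mag == 0) 0 else atan2(delta[2L], delta[1L]),
       degenerate = mag == 0)
}

## ---- Delaunay triangulation (Bowyer-Watson) -------------------------------

.circumcircle <- function(a, b, c) {
  d <- 2 * (a[1L] * (b[2L] - c[2L]) + b[1L] * (c[2L] - a[2L]) +
              c[1L] * (a[2L] - b[2L]))
  if (abs(d) < .Machine$double.eps * 1e4) return(NULL)
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2L] - c[2L]) + b2 * (c[2L] - a[2L]) + c2 * (a[2L] - b[2L])) / d
  uy <- (a2 * (c[1L] - b[1L]) + b2 * (a[1L] - c[1L]) + c2 * (b[1L] - a[1L])) / d
  c(ux, uy, (a[1L] - ux)^2 + (a[2L] - uy)^2)
}

.delaunay <- function(pts) {
  n <- nrow(pts)
  rng <- apply(pts, 2L, range)
  span <- max(rng[2L, ] - rng[1L, ], 1e-12)
  mid <- colMeans(rng)
  big <- 20 * span
  super <- rbind(mid + c(-big, -big), mid + c(big, -big), mid + c(0, big))
  P <- rbind(pts, super)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  circ <- list(.circumcircle(super[1L, ], super[2L, ], super[3L, ]))
  for (i in seq_len(n)) {
    p <- P[i, ]
    bad <- vapply(circ, function(cc) {
      (p[1L] - cc[1L])^2 + (p[2L] - cc[2L])^2 <= cc[3L] * (1 + 1e-12)
    }, TRUE)
    edges <- do.call(rbind, lapply(tris[bad], function(tr) {
      rbind(tr[c(1L, 2L)], tr[c(2L, 3L)], tr[c(3L, 1L)])
    }))
    tris <- tris[!bad]; circ <- circ[!bad]
    key <- apply(edges, 1L, function(e) paste(sort(e), collapse = "-"))
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    for (j in seq_len(nrow(boundary))) {
      tr <- c(boundary[j, ], i)
      cc <- .circumcircle(P[tr[1L], ], P[tr[2L], ], P[tr[3L], ])
      if (is.null(cc)) next  # degenerate (collinear) triangle
      tris[[length(tris) + 1L]] <- tr
      circ[[length(circ) + 1L]] <- cc
    }
  }
  tri_mat <- do.call(rbind, tris)
  tri_mat[rowSums(tri_mat > n) == 0L, , drop = FALSE]
}

#' Piecewise-linear interpolation at arbitrary points
#'
#' Barycentric interpolation on a Delaunay triangulation of the data;
#' queries outside the convex hull return `NA`.
#'
#' @param points 2-column matrix of data locations.
#' @param values numeric vector of data values.
#' @param xo,yo query coordinates.
#' @return numeric vector of interpolated values (NA outside the hull).
#' @export
interp_linear <- function(points, values, xo, yo) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  stopifnot(length(values) == nrow(pts), length(xo) == length(yo))
  if (nrow(pts) < 3L) stop("need at least 3 points")
  if (.shoelace(pts[grDevices::chull(pts), , drop = FALSE]) <= 0) {
    stop("all points are collinear")
  }
  tri <- .delaunay(pts)
  out <- rep(NA_real_, length(xo))
  eps <- 1e-9
  for (t in seq_len(nrow(tri))) {
    a <- pts[tri[t, 1L], ]; b <- pts[tri[t, 2L], ]; c <- pts[tri[t, 3L], ]
    det <- (b[2L] - c[2L]) * (a[1L] - c[1L]) + (c[1L] - b[1L]) * (a[2L] - c[2L])
    if (abs(det) < .Machine$double.eps * 1e4) next
    w1 <- ((b[2L] - c[2L]) * (xo - c[1L]) + (c[1L] - b[1L]) * (yo - c[2L])) / det
    w2 <- ((c[2L] - a[2L]) * (xo - c[1L]) + (a[1L] - c[1L]) * (yo - c[2L])) / det
    w3 <- 1 - w1 - w2
    inside <- is.na(out) & w1 >= -eps & w2 >= -eps & w3 >= -eps
    if (any(inside)) {
      out[inside] <- w1[inside] * values[tri[t, 1L]] +
        w2[inside] * values[tri[t, 2L]] + w3[inside] * values[tri[t, 3L]]
    }
  }
  out
}

#' Interpolated value surface over an ordination
#'
#' Evaluates [interp_linear] on a regular grid spanning the bounding box
#' of the data (e.g. maximum depth over PC1-PC2 scores, the bathymetry
#' raster of the morphospace plots). Grid nodes outside the data's convex
#' hull are `NA`.
#'
#' @param points 2-column matrix of (PC1, PC2) locations.
#' @param values numeric data values (finite).
#' @param grid number of grid nodes per axis.
#' @return object of class `interp_surface`: `x`, `y` grid vectors and
#'   `z` value matrix (length(x) rows by length(y) columns).
#' @export
interpolate_surface <- function(points, values, grid = 200L) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  ok <- is.finite(values)
  if (sum(ok) < 3L) stop("need at least 3 finite values")
  pts <- pts[ok, , drop = FALSE]; values <- values[ok]
  gx <- seq(min(pts[, 1L]), max(pts[, 1L]), length.out = grid)
  gy <- seq(min(pts[, 2L]), max(pts[, 2L]), length.out = grid)
  gg <- expand.grid(x = gx, y = gy)
  z <- matrix(interp_linear(pts, values, gg$x, gg$y), nrow = grid)
  structure(list(x = gx, y = gy, z = z), class = "interp_surface")
}

#' @export
plot.interp_surface <- function(x, ...) {
  graphics::image(x$x, x$y, x$z, col = grDevices::hcl.colors(64, "Blues 3",
                                                             rev = TRUE),
                  xlab = "PC1", ylab = "PC2", ...)
  graphics::contour(x$x, x$y, x$z, add = TRUE, col = "grey25")
  invisible(x)
}
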