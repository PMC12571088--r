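#' Resample a curve to equidistant points
#'
#' Places `k` points along the input polyline with equal arc-length
#' spacing; the first and last input points are preserved exactly. Used to
#' regularize digitized semilandmark curves before superimposition, and
#' invariant to how densely the underlying curve was traced.
#'
#' @param curve_points ordered 2-column matrix of curve coordinates.
#' @param k number of output points (>= 2).
#' @return a k x 2 matrix of equidistant points on the polyline.
#' @export
resample_equidistant <- function(curve_points, k) {
  pts <- as.matrix(curve_points)
  if (nrow(pts) < 2L) stop("need at least 2 curve points")
  if (k < 2L) stop("k must be >= 2")
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] <= 0) stop("zero-length polyline")
  keep <- c(TRUE, seg > 0)  # drop duplicated vertices for interpolation
  s_u <- s[keep]; p_u <- pts[keep, , drop = FALSE]
  target <- seq(0, s_u[length(s_u)], length.out = k)
  out <- cbind(stats::approx(s_u, p_u[, 1L], xout = target)$y,
               stats::approx(s_u, p_u[, 2L], xout = target)$y)
  out[1L, ] <- pts[1L, ]
  out[k, ] <- pts[nrow(pts), ]
  out
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the points from their
#' centroid — the standard geometric-morphometric size measure removed
#' during Procrustes superimposition.
#'
#' @param points 2-column coordinate matrix.
#' @return a positive scalar.
#' @export
centroid_size <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 2L) stop("need at least 2 points")
  cs <- sqrt(sum(scale(pts, scale = FALSE)^2))
  if (cs == 0) stop("coincident points: centroid size is zero")
  cs
}

#' Procrustes distance between two aligned configurations
#'
#' Euclidean norm of the difference of the two coordinate vectors; only
#' meaningful for configurations from the same superimposition.
#'
#' @param a,b coordinate matrices or vectors of equal length.
#' @return a non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.numeric(as.matrix(a)); b <- as.numeric(as.matrix(b))
  if (length(a) != length(b)) stop("dimension mismatch")
  sqrt(sum((a - b)^2))
}

#' Thin-plate-spline bending energy model
#'
#' Builds the 2D thin-plate-spline system for a reference configuration
#' using the kernel U(r) = r^2 log r^2 and extracts the bending-energy
#' matrix (the upper p x p block of the inverted system). The bending
#' energy of any affine transform of the reference is zero; the matrix is
#' symmetric positive semi-definite.
#'
#' @param reference p x 2 reference coordinate matrix.
#' @return object of class `bending_energy_model` with elements
#'   `reference`, `kernel` and `energy` (the bending-energy matrix).
#' @export
bending_energy_model <- function(reference) {
  P <- as.matrix(reference)
  p <- nrow(P)
  if (p < 4L) stop("need at least 4 reference points")
  r2 <- as.matrix(stats::dist(P))^2
  K <- ifelse(r2 > 0, r2 * log(r2), 0)
  Q <- cbind(1, P)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  Linv <- tryCatch(solve(L), error = function(e) MASS::ginv(L))
  B <- Linv[seq_len(p), seq_len(p), drop = FALSE]
  B <- (B + t(B)) / 2
  structure(list(reference = P, kernel = K, energy = B),
            class = "bending_energy_model")
}

#' Bending energy of a target configuration
#'
#' Total thin-plate-spline bending energy of the mapping from the model's
#' reference onto `target`, summed over the x and y dimensions.
#'
#' @param model a [bending_energy_model].
#' @param target p x 2 coordinate matrix.
#' @return non-negative scalar (clamped at zero against roundoff).
#' @export
bending_energy <- function(model, target) {
  V <- as.matrix(target)
  if (!identical(dim(V), dim(model$reference))) stop("dimension mismatch")
  e <- sum(V[, 1L] %*% model$energy %*% V[, 1L],
           V[, 2L] %*% model$energy %*% V[, 2L])
  max(e, 0)
}

## center to origin and scale to unit centroid size
.normalize_config <- function(pts) {
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2L, ctr)
  cs <- sqrt(sum(pts^2))
  if (cs == 0) stop("degenerate configuration: all points coincident")
  list(pts = pts / cs, size = cs)
}

## optimal proper (det = +1) rotation of X onto target C
.rotate_onto <- function(X, C) {
  M <- crossprod(X, C)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  X %*% R
}

## unit tangent directions for the semilandmarks of one configuration:
## central differences along each curve's extended run anchor-curve-anchor
.semi_tangents <- function(pts, curves) {
  idx <- integer(0); tang <- NULL
  for (cv in curves) {
    anc <- attr(cv, "anchors")
    run <- c(anc[1L], as.integer(cv), anc[2L])
    m <- length(run)
    nxt <- pts[run[3:m], , drop = FALSE]
    prv <- pts[run[1:(m - 2L)], , drop = FALSE]
    tg <- nxt - prv
    nrm <- sqrt(rowSums(tg^2))
    nrm[nrm == 0] <- 1
    idx <- c(idx, as.integer(cv))
    tang <- rbind(tang, tg / nrm)
  }
  list(idx = idx, tangents = tang)
}

## slide one specimen's semilandmarks along their tangents to minimize
## TPS bending energy against the consensus; fixed landmarks never move
.slide_one <- function(pts, curves, B, damp = 1) {
  tg <- .semi_tangents(pts, curves)
  i <- tg$idx
  ux <- tg$tangents[, 1L]; uy <- tg$tangents[, 2L]
  Bss <- B[i, i, drop = FALSE]
  A <- Bss * (outer(ux, ux) + outer(uy, uy))
  b <- ux * (B %*% pts[, 1L])[i] + uy * (B %*% pts[, 2L])[i]
  tt <- tryCatch(solve(A + diag(1e-10 * mean(diag(A)), length(i)), -b),
                 error = function(e) as.numeric(MASS::ginv(A) %*% (-b)))
  pts[i, 1L] <- pts[i, 1L] + damp * tt * ux
  pts[i, 2L] <- pts[i, 2L] + damp * tt * uy
  pts
}

#' Generalized Procrustes superimposition with sliding semilandmarks
#'
#' Removes translation (centroid to origin), scale (unit centroid size)
#' and rotation (least-squares fit to the iteratively updated consensus,
#' proper rotations only) from a set of landmark configurations. With
#' `slide = TRUE`, each iteration additionally displaces every
#' semilandmark along its local curve tangent by the displacement that
#' minimizes thin-plate-spline bending energy against the current
#' consensus, then re-superimposes. Iterates until the root-mean-square
#' change of the consensus falls below `tol` or `max_iter` is reached.
#'
#' @param configs list of [landmark_config] objects with identical point
#'   count and role/curve structure, or a list of p x 2 matrices (sliding
#'   then requires `curves`).
#' @param slide slide semilandmarks by the bending-energy criterion?
#' @param max_iter maximum number of GPA iterations.
#' @param tol convergence tolerance on consensus RMS change.
#' @param damp step-damping factor for the sliding displacement.
#' @param slide_iter number of initial iterations in which sliding is
#'   applied. Sliding has a neutral direction (all configurations and the
#'   consensus drifting together along the curves leave the bending energy
#'   unchanged), so it is applied for a fixed number of passes after which
#'   plain superimposition iterates to convergence.
#' @return object of class `gpa_fit`: `coordinates` (n x 2p matrix, one
#'   row per specimen), `consensus` (p x 2), `centroid_sizes`,
#'   `iterations_run`, `converged`, plus the specimen metadata and curve
#'   structure carried through.
#' @export
superimpose <- function(configs, slide = TRUE, max_iter = 100L,
                        tol = 1e-8, damp = 1, slide_iter = 5L) {
  is_cfg <- all(vapply(configs, inherits, TRUE, "landmark_config"))
  pts_list <- if (is_cfg) lapply(configs, `[[`, "points") else
    lapply(configs, as.matrix)
  p <- nrow(pts_list[[1L]])
  if (!all(vapply(pts_list, nrow, 0L) == p)) {
    stop("structure mismatch: configurations differ in point count")
  }
  curves <- if (is_cfg) configs[[1L]]$curves else attr(configs, "curves")
  roles <- if (is_cfg) configs[[1L]]$roles else NULL
  if (is_cfg) {
    same <- vapply(configs, function(cf) {
      identical(cf$roles, roles) &&
        identical(lapply(cf$curves, as.integer), lapply(curves, as.integer))
    }, TRUE)
    if (!all(same)) stop("structure mismatch: roles/curves differ")
  }
  if (slide && (is.null(curves) || length(curves) == 0L)) slide <- FALSE

  norm <- lapply(pts_list, .normalize_config)
  X <- lapply(norm, `[[`, "pts")
  sizes <- vapply(norm, `[[`, 0, "size")
  n <- length(X)
  ## initial consensus: plain mean (so an already-superimposed set is a
  ## fixed point); fall back to the first configuration if rotations cancel
  consensus <- Reduce(`+`, X) / n
  if (sqrt(sum(consensus^2)) < 1e-8) consensus <- X[[1L]]
  else consensus <- .normalize_config(consensus)$pts
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    X <- lapply(X, .rotate_onto, C = consensus)
    if (slide && iterations <= slide_iter) {
      B <- bending_energy_model(consensus)$energy
      X <- lapply(X, function(pts) {
        pts <- .slide_one(pts, curves, B, damp)
        .rotate_onto(.normalize_config(pts)$pts, consensus)
      })
    }
    new_consensus <- .normalize_config(Reduce(`+`, X) / n)$pts
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  X <- lapply(X, .rotate_onto, C = consensus)
  coords <- t(vapply(X, as.numeric, numeric(2L * p)))
  consensus_mean <- matrix(colMeans(coords), ncol = 2L)
  ids <- if (is_cfg) vapply(configs, `[[`, "", "specimen_id") else
    names(configs) %||% paste0("config", seq_len(n))
  rownames(coords) <- ids
  structure(list(
    coordinates = coords,
    consensus = consensus_mean,
    centroid_sizes = stats::setNames(sizes, ids),
    iterations_run = iterations,
    converged = converged,
    slide = slide, tol = tol,
    n_points = p,
    roles = roles, curves = curves,
    species = if (is_cfg) vapply(configs, `[[`, "", "species_id") else NULL,
    jaw = if (is_cfg) vapply(configs, `[[`, "", "jaw") else NULL),
    class = "gpa_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes superimposition\n")
  cat("  ", nrow(x$coordinates), " configurations of ", x$n_points,
      " landmarks; sliding semilandmarks: ",
      if (x$slide) "bending energy" else "off", "\n", sep = "")
  cat("  ", x$iterations_run, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged",
      " (tol ", format(x$tol), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.gpa_fit <- function(x, ...) {
  coords <- x$coordinates
  p <- x$n_points
  xs <- coords[, seq_len(p), drop = FALSE]
  ys <- coords[, p + seq_len(p), drop = FALSE]
  graphics::plot(as.numeric(xs), as.numeric(ys), pch = 16, cex = 0.2,
                 col = grDevices::grey(0.6), asp = 1,
                 xlab = "x", ylab = "y",
                 main = "Superimposed landmarks", ...)
  graphics::points(x$consensus, pch = 21, bg = "tomato", cex = 0.6)
  invisible(x)
}

## rows of a gpa_fit coordinate matrix back to p x 2
coords_to_config <- function(row, p) matrix(row, ncol = 2L)
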