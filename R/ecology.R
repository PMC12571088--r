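#' Centered log-ratio transform of a diet composition matrix
#'
#' Rows are renormalized to sum to one, zeros are replaced by the chosen
#' strategy, and each entry becomes log(x / geometric row mean). Every
#' output row sums to zero, and the transform is invariant to rescaling a
#' raw row by a positive constant.
#'
#' Zero handling: `"multiplicative"` replaces zeros with
#' delta = 0.65 times the smallest nonzero proportion in the matrix and
#' shrinks the nonzero entries of each affected row so it still sums to
#' one; `"none"` errors on zeros.
#'
#' @param diets species-by-prey matrix of non-negative proportions.
#' @param zero_strategy `"multiplicative"` or `"none"`.
#' @param delta override for the replacement value.
#' @return matrix of CLR coordinates with the input dimnames.
#' @export
clr_transform <- function(diets, zero_strategy = c("multiplicative", "none"),
                          delta = NULL) {
  zero_strategy <- match.arg(zero_strategy)
  X <- as.matrix(diets)
  if (any(X < 0)) stop("negative diet proportions")
  rs <- rowSums(X)
  if (any(rs == 0)) {
    stop("all-zero diet row(s): ",
         paste(rownames(X)[rs == 0], collapse = ", "))
  }
  X <- X / rs
  if (any(X == 0)) {
    if (zero_strategy == "none") stop("zeros present with zero_strategy='none'")
    if (is.null(delta)) delta <- 0.65 * min(X[X > 0])
    for (i in seq_len(nrow(X))) {
      z <- X[i, ] == 0
      if (any(z)) {
        X[i, z] <- delta
        X[i, !z] <- X[i, !z] * (1 - sum(z) * delta)
      }
    }
  }
  L <- log(X)
  sweep(L, 1L, rowMeans(L))
}

#' Ordinated dietary niche breadth (ODB)
#'
#' Prey categories are embedded by principal coordinates analysis of the
#' Euclidean dissimilarity between their binary consumer-incidence
#' profiles. Each consumer's ODB is the sum of squared Euclidean
#' distances of its used prey from the centroid of those prey in the
#' ordination space: 0 for an extreme specialist (single prey), larger
#' for generalists. The 33rd and 66th ODB percentiles band species into
#' specialist / intermediate / generalist.
#'
#' @param incidence binary species-by-prey matrix (nonzero = used).
#' @return object of class `odb`: per-species `odb` values,
#'   `prey_coordinates`, `thresholds` (33rd/66th percentiles) and a
#'   `band` factor.
#' @export
ordinated_breadth <- function(incidence) {
  B <- as.matrix(incidence) > 0
  storage.mode(B) <- "double"
  used <- rowSums(B)
  if (any(used == 0)) {
    stop("species with empty diet: ",
         paste(rownames(B)[used == 0], collapse = ", "))
  }
  if (sum(colSums(B) > 0) < 2L) stop("need at least 2 used prey categories")
  D <- stats::dist(t(B))  # prey profiles across consumers
  k <- min(ncol(B) - 1L, nrow(B))
  pc <- stats::cmdscale(D, k = k, eig = TRUE)
  coords <- pc$points
  keep <- which(pc$eig[seq_len(ncol(coords))] > max(pc$eig) * 1e-10)
  coords <- coords[, keep, drop = FALSE]
  odb <- vapply(seq_len(nrow(B)), function(i) {
    pts <- coords[B[i, ] > 0, , drop = FALSE]
    ctr <- colMeans(pts)
    sum(sweep(pts, 2L, ctr)^2)
  }, 0)
  names(odb) <- rownames(B)
  thr <- stats::quantile(odb, c(0.33, 0.66), names = FALSE)
  band <- cut(odb, c(-Inf, thr, Inf),
              labels = c("specialist", "intermediate", "generalist"))
  names(band) <- names(odb)
  structure(list(odb = odb, prey_coordinates = coords,
                 eigenvalues = pc$eig, thresholds = thr, band = band),
            class = "odb")
}

#' @export
print.odb <- function(x, ...) {
  cat("Ordinated dietary breadth for", length(x$odb), "species\n")
  cat(sprintf("  33rd/66th percentiles: %.4g / %.4g\n",
              x$thresholds[1L], x$thresholds[2L]))
  print(table(x$band))
  invisible(x)
}

#' @export
plot.odb <- function(x, ...) {
  o <- sort(x$odb)
  graphics::plot(seq_along(o), o, pch = 21, bg = "darkseagreen",
                 xlab = "species (ranked)", ylab = "ODB (total breadth)", ...)
  graphics::abline(h = x$thresholds, lty = 3)
  invisible(x)
}

.dist_to_group_centroids <- function(X, groups) {
  mns <- rowsum(X, groups) / as.numeric(table(groups))
  sqrt(rowSums((X - mns[as.character(groups), , drop = FALSE])^2))
}

#' Multivariate dispersion homogeneity across groups
#'
#' Distance of each species to its group centroid in CLR diet space, with
#' a one-way F test for dispersion differences; the p value comes from
#' permuting group labels over the rows and recomputing the distances.
#' Degenerate inputs (no within- or between-group variation in the
#' distances) are flagged and reported with p = 1.
#'
#' @param clr_matrix species-by-prey CLR matrix.
#' @param groups group labels (e.g. IUCN categories).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return object of class `dispersion_test`: per-species `distances`,
#'   `group_means`, `overall_mean`, `F`, `p`, `degenerate`.
#' @export
group_dispersion <- function(clr_matrix, groups, n_perm = 999L, seed = 1L) {
  X <- as.matrix(clr_matrix)
  groups <- factor(as.character(groups))
  stopifnot(nrow(X) == length(groups))
  sizes <- table(groups)
  if (any(sizes == 1L)) {
    warning("singleton group(s), distance 0 by construction: ",
            paste(names(sizes)[sizes == 1L], collapse = ", "))
  }
  d_obs <- .dist_to_group_centroids(X, groups)
  f_stat <- function(d, g) {
    gm <- tapply(d, g, mean)
    ssb <- sum(table(g) * (gm - mean(d))^2)
    ssw <- sum((d - gm[as.character(g)])^2)
    dfb <- nlevels(g) - 1L
    dfw <- length(d) - nlevels(g)
    if (ssw == 0) {
      if (ssb == 0) return(NA_real_)
      return(Inf)
    }
    (ssb / dfb) / (ssw / dfw)
  }
  Fobs <- f_stat(d_obs, groups)
  degenerate <- is.na(Fobs)
  if (degenerate) {
    p <- 1
  } else {
    set.seed(seed)
    Fperm <- c(Fobs, replicate(n_perm, {
      g <- groups[sample.int(length(groups))]
      f_stat(.dist_to_group_centroids(X, g), g)
    }))
    p <- mean(Fperm >= Fobs, na.rm = TRUE)
  }
  structure(list(distances = stats::setNames(d_obs, rownames(X)),
                 group_means = tapply(d_obs, groups, mean),
                 overall_mean = mean(d_obs),
                 F = Fobs, p = p, degenerate = degenerate,
                 n_perm = n_perm, seed = seed),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat("Multivariate dispersion homogeneity\n")
  cat("  group mean distances:",
      paste(sprintf("%s=%.4g", names(x$group_means), x$group_means),
            collapse = " "), "\n")
  if (x$degenerate) {
    cat("  degenerate input (no dispersion); p = 1\n")
  } else {
    cat(sprintf("  F = %.4g, p = %.4g (%d permutations)\n",
                x$F, x$p, x$n_perm))
  }
  invisible(x)
}

#' Dietary dispersion under extinction scenarios
#'
#' For each scenario, the survivor centroid in CLR space is recomputed
#' and the mean and standard deviation of survivor distances to it are
#' reported — contraction of this spread under progressive extinction is
#' the signature of ecological homogenization.
#'
#' @param clr_matrix species-by-prey CLR matrix with species row names.
#' @param scenarios list of scenarios as in [canonical_scenarios], or a
#'   list with elements holding `removed` species vectors, or a named
#'   list of survivor id vectors.
#' @param traits trait table (needed when scenarios are status-based).
#' @return data frame with one row per scenario (`scenario`,
#'   `n_survivors`, `mean_dist`, `sd_dist`).
#' @export
scenario_dispersion <- function(clr_matrix, scenarios, traits = NULL) {
  X <- as.matrix(clr_matrix)
  sp <- rownames(X)
  if (is.null(sp)) stop("clr_matrix needs species row names")
  rows <- lapply(scenarios, function(sc) {
    survivors <- if (is.character(sc)) intersect(sp, sc)
    else if (!is.null(sc$removed_statuses)) {
      if (is.null(traits)) stop("traits required for status-based scenarios")
      status <- stats::setNames(as.character(traits$iucn), traits$species_id)
      sp[!(status[sp] %in% sc$removed_statuses)]
    } else setdiff(sp, sc$removed)
    if (length(survivors) < 2L) {
      stop("scenario leaves fewer than 2 survivors with diet data")
    }
    S <- X[survivors, , drop = FALSE]
    d <- sqrt(rowSums(sweep(S, 2L, colMeans(S))^2))
    data.frame(scenario = if (is.list(sc)) sc$name else NA_character_,
               n_survivors = length(survivors),
               mean_dist = mean(d), sd_dist = stats::sd(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(names(scenarios))) out$scenario <- names(scenarios)
  out
}
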