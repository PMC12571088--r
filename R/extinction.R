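#' Average pairwise Procrustes distance (APPD)
#'
#' Disparity of a set of aligned configurations:
#' APPD = 2/(n(n-1)) * sum_{i<j} d_ij, the arithmetic mean of all pairwise
#' Procrustes distances. Lower values indicate morphological
#' homogenization.
#'
#' @param coords n-by-coordinate matrix of aligned configurations (n >= 2),
#'   or a `dist` object of precomputed pairwise distances.
#' @return non-negative scalar.
#' @export
appd <- function(coords) {
  d <- if (inherits(coords, "dist")) coords else {
    m <- as.matrix(coords)
    if (nrow(m) < 2L) stop("APPD is undefined for fewer than 2 configurations")
    stats::dist(m)
  }
  if (attr(d, "Size") < 2L) stop("APPD is undefined for fewer than 2 configurations")
  mean(d)
}

#' Procrustes variance by group
#'
#' Per group, the mean squared Procrustes distance of members from the
#' group mean configuration — the trace-based within-group disparity
#' measure. Groups with a single member are reported as `NA` with a
#' warning.
#'
#' @param coords n-by-coordinate matrix of aligned configurations.
#' @param groups group labels, length n.
#' @return named numeric vector of per-group variances.
#' @export
procrustes_variance <- function(coords, groups) {
  m <- as.matrix(coords)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  out <- vapply(split(seq_len(nrow(m)), groups), function(i) {
    if (length(i) < 2L) return(NA_real_)
    g <- m[i, , drop = FALSE]
    sum(sweep(g, 2L, colMeans(g))^2) / length(i)
  }, 0)
  if (anyNA(out)) {
    warning("singleton group(s) reported as NA: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  }
  out
}

#' Canonical threat-ordered extinction scenarios
#'
#' The four nested scenarios removing species from the highest to the
#' lowest threat level: CR, then CR+EN, CR+EN+VU (all threatened), and
#' CR+EN+VU+NT.
#'
#' @return list of scenario definitions (`name`, `removed_statuses`).
#' @export
canonical_scenarios <- function() {
  list(
    list(name = "CR",          removed_statuses = "CR"),
    list(name = "CR+EN",       removed_statuses = c("CR", "EN")),
    list(name = "CR+EN+VU",    removed_statuses = c("CR", "EN", "VU")),
    list(name = "CR+EN+VU+NT", removed_statuses = c("CR", "EN", "VU", "NT")))
}

#' Apply one extinction scenario in a fixed baseline ordination
#'
#' Removes the species carrying the scenario's threat statuses and
#' summarizes the survivors against the baseline: convex-hull area and
#' percent area loss (100 * (1 - area_surv / area_base)), centroid shift
#' on PC1-PC2 (baseline scores are kept fixed; no re-ordination),
#' survivor APPD in the full shape space, and the survivors' depth range.
#'
#' @param ord a `shape_pca` of species mean shapes (ids = species).
#' @param traits species trait table with `species_id` and `iucn` (and
#'   optionally `max_depth_m`).
#' @param scenario one element of [canonical_scenarios], or a character
#'   vector of statuses to remove.
#' @param shapes species-by-coordinate matrix of aligned mean shapes used
#'   for APPD (row names = species). Defaults to reconstructing shapes
#'   from the ordination scores and center, which is equivalent.
#' @return object of class `scenario_result`.
#' @export
apply_scenario <- function(ord, traits, scenario, shapes = NULL) {
  if (is.character(scenario)) {
    scenario <- list(name = paste(scenario, collapse = "+"),
                     removed_statuses = scenario)
  }
  stopifnot(inherits(ord, "shape_pca"))
  bad <- setdiff(scenario$removed_statuses, c("CR", "EN", "VU", "NT", "LC"))
  if (length(bad)) stop("unknown statuses: ", paste(bad, collapse = ", "))
  status <- stats::setNames(as.character(traits$iucn), traits$species_id)
  sp <- ord$ids
  removed <- sp[status[sp] %in% scenario$removed_statuses]
  survivors <- setdiff(sp, removed)
  if (length(survivors) == 0L) stop("scenario removes all species")
  if (is.null(shapes)) {
    shapes <- ord$scores %*% t(ord$loadings)
    shapes <- sweep(shapes, 2L, ord$center, `+`)
    rownames(shapes) <- sp
  }
  base_hull <- hull_area(ord$scores)
  surv_scores <- ord$scores[survivors, , drop = FALSE]
  surv_hull <- hull_area(surv_scores)
  pct_loss <- if (base_hull$area > 0)
    100 * (1 - surv_hull$area / base_hull$area) else 0
  depth <- if ("max_depth_m" %in% names(traits)) {
    d <- stats::setNames(traits$max_depth_m, traits$species_id)[survivors]
    if (all(is.na(d))) c(NA_real_, NA_real_) else range(d, na.rm = TRUE)
  } else c(NA_real_, NA_real_)
  structure(list(
    name = scenario$name,
    removed_statuses = scenario$removed_statuses,
    removed = removed, survivors = survivors,
    n_removed = length(removed),
    baseline_area = base_hull$area,
    hull_area = surv_hull$area,
    pct_area_loss = pct_loss,
    centroid_shift = centroid_shift(ord$scores, surv_scores),
    appd = if (length(survivors) >= 2L)
      appd(shapes[survivors, , drop = FALSE]) else NA_real_,
    depth_range = depth),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Extinction scenario %s: %d removed, %d survive\n",
              x$name, x$n_removed, length(x$survivors)))
  cat(sprintf("  hull area %.4g (%.1f%% loss); centroid shift %.4g; APPD %.4g\n",
              x$hull_area, x$pct_area_loss, x$centroid_shift$magnitude,
              x$appd))
  if (!all(is.na(x$depth_range))) {
    cat(sprintf("  survivor depth range %.0f-%.0f m\n",
                x$depth_range[1L], x$depth_range[2L]))
  }
  invisible(x)
}

## deterministic substream seed for extinction intensity k
.null_seed <- function(seed, k) (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L

#' Monte Carlo random-extinction null distributions
#'
#' Removes `k` species uniformly at random (without replacement),
#' `n_reps` times, and records the survivors' mean PC1, mean PC2 and APPD
#' per replicate, together with the mean and 95% envelope of each
#' statistic. Reproducible given `seed`; each intensity uses its own
#' deterministic substream.
#'
#' @param ord a `shape_pca` of species mean shapes.
#' @param shapes species-by-coordinate matrix for APPD (defaults as in
#'   [apply_scenario]).
#' @param k extinction intensity (number of species removed,
#'   0 < k < n - 1 so that APPD stays defined).
#' @param n_reps number of replicates.
#' @param seed integer root seed.
#' @param envelope `"percentile"` (2.5/97.5 percentiles) or `"normal"`
#'   (mean +/- 1.96 sd).
#' @return list of three `null_distribution` objects named `mean_PC1`,
#'   `mean_PC2`, `appd`; each has `statistic`, `k`, `values`, `mean`,
#'   `lower`, `upper`.
#' @export
random_extinction_null <- function(ord, k, n_reps = 100L, seed = 1L,
                                   shapes = NULL,
                                   envelope = c("percentile", "normal")) {
  envelope <- match.arg(envelope)
  stopifnot(inherits(ord, "shape_pca"))
  n <- nrow(ord$scores)
  if (n_reps < 2L) stop("n_reps must be >= 2")
  if (k <= 0L || k >= n) stop("k must satisfy 0 < k < ", n)
  if (n - k < 2L) stop("k leaves fewer than 2 survivors; APPD undefined")
  if (is.null(shapes)) {
    shapes <- sweep(ord$scores %*% t(ord$loadings), 2L, ord$center, `+`)
  }
  D <- as.matrix(stats::dist(shapes))
  set.seed(.null_seed(seed, k))
  reps <- matrix(NA_real_, n_reps, 3L,
                 dimnames = list(NULL, c("mean_PC1", "mean_PC2", "appd")))
  for (r in seq_len(n_reps)) {
    surv <- sort(sample.int(n, n - k))
    reps[r, 1L] <- mean(ord$scores[surv, 1L])
    reps[r, 2L] <- mean(ord$scores[surv, 2L])
    Ds <- D[surv, surv]
    reps[r, 3L] <- sum(Ds) / (length(surv) * (length(surv) - 1L))
  }
  mk <- function(name) {
    v <- reps[, name]
    bounds <- if (envelope == "percentile") {
      stats::quantile(v, c(0.025, 0.975), names = FALSE)
    } else mean(v) + c(-1.96, 1.96) * stats::sd(v)
    structure(list(statistic = name, k = k, values = v, mean = mean(v),
                   lower = bounds[1L], upper = bounds[2L],
                   n_reps = n_reps, seed = seed, envelope = envelope),
              class = "null_distribution")
  }
  list(mean_PC1 = mk("mean_PC1"), mean_PC2 = mk("mean_PC2"),
       appd = mk("appd"))
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "Random-extinction null for %s at intensity k=%d (%d reps)\n",
    x$statistic, x$k, x$n_reps))
  cat(sprintf("  mean %.5g, 95%% envelope [%.5g, %.5g]\n",
              x$mean, x$lower, x$upper))
  invisible(x)
}

#' Classify a targeted-scenario statistic against its random null
#'
#' @param scenario_stat the statistic computed under the targeted
#'   (threat-ordered) scenario.
#' @param null a `null_distribution` at the matching intensity.
#' @param k intensity of the targeted scenario, checked against the null.
#' @return `"below"`, `"within"` or `"above"` the 95% envelope.
#' @export
targeted_vs_null <- function(scenario_stat, null, k = null$k) {
  stopifnot(inherits(null, "null_distribution"))
  if (k != null$k) {
    stop("intensity mismatch: scenario k=", k, " vs null k=", null$k)
  }
  if (scenario_stat < null$lower) "below"
  else if (scenario_stat > null$upper) "above"
  else "within"
}

#' Run all canonical scenarios with matching nulls
#'
#' Convenience wrapper applying each threat-ordered scenario and the
#' random-extinction null at the same intensity, classifying mean PC1,
#' mean PC2 and APPD against their envelopes.
#'
#' @inheritParams apply_scenario
#' @inheritParams random_extinction_null
#' @param scenarios list of scenarios (default [canonical_scenarios]).
#' @return object of class `extinction_summary`: per-scenario results,
#'   nulls and classifications, plus a tidy `table` data frame.
#' @export
run_extinction_analysis <- function(ord, traits, shapes = NULL,
                                    scenarios = canonical_scenarios(),
                                    n_reps = 100L, seed = 1L) {
  if (is.null(shapes)) {
    shapes <- sweep(ord$scores %*% t(ord$loadings), 2L, ord$center, `+`)
    rownames(shapes) <- ord$ids
  }
  res <- lapply(scenarios, function(sc) apply_scenario(ord, traits, sc, shapes))
  nulls <- lapply(res, function(r) {
    random_extinction_null(ord, k = r$n_removed, n_reps = n_reps,
                           seed = seed, shapes = shapes)
  })
  rows <- mapply(function(r, nl) {
    surv_pc <- colMeans(ord$scores[r$survivors, 1:2, drop = FALSE])
    data.frame(
      scenario = r$name, k = r$n_removed,
      hull_area = r$hull_area, pct_area_loss = r$pct_area_loss,
      centroid_shift = r$centroid_shift$magnitude,
      appd = r$appd,
      mean_PC1 = surv_pc[1L], mean_PC2 = surv_pc[2L],
      class_PC1 = targeted_vs_null(surv_pc[1L], nl$mean_PC1, r$n_removed),
      class_PC2 = targeted_vs_null(surv_pc[2L], nl$mean_PC2, r$n_removed),
      class_appd = targeted_vs_null(r$appd, nl$appd, r$n_removed),
      stringsAsFactors = FALSE)
  }, res, nulls, SIMPLIFY = FALSE)
  structure(list(results = res, nulls = nulls,
                 baseline_appd = appd(shapes),
                 baseline_area = hull_area(ord$scores)$area,
                 table = do.call(rbind, rows)),
            class = "extinction_summary")
}

#' @export
print.extinction_summary <- function(x, ...) {
  cat(sprintf("Baseline: hull area %.4g, APPD %.4g\n",
              x$baseline_area, x$baseline_appd))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.extinction_summary <- function(x, which = c("appd", "mean_PC1",
                                                 "mean_PC2"), ...) {
  which <- match.arg(which)
  ks <- x$table$k
  nullv <- t(vapply(x$nulls, function(nl) {
    nl <- nl[[which]]
    c(nl$mean, nl$lower, nl$upper)
  }, numeric(3L)))
  obs <- x$table[[if (which == "appd") "appd" else which]]
  ylim <- range(nullv, obs)
  graphics::plot(ks, nullv[, 1L], ylim = ylim, pch = 16,
                 xlab = "extinction intensity (species removed)",
                 ylab = which, ...)
  graphics::arrows(ks, nullv[, 2L], ks, nullv[, 3L], angle = 90, code = 3,
                   length = 0.04)
  graphics::points(ks, obs, pch = 17, col = "firebrick", cex = 1.2)
  base <- if (which == "appd") x$baseline_appd else NULL
  if (!is.null(base)) graphics::abline(h = base, lty = 2)
  graphics::legend("bottomleft", bty = "n",
                   legend = c("random null (95% CI)", "targeted"),
                   pch = c(16, 17), col = c("black", "firebrick"))
  invisible(x)
}
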