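## Synthetic data generator. Emulates the statistical structure of the
## tooth-shape study: a pure-birth phylogeny, Brownian evolution of a
## low-dimensional crown parameterization mapped through a smooth tooth
## template, within-species digitization noise with a dignathic
## (upper/lower jaw) effect, ordered threat statuses with tunable
## morphology selectivity, Dirichlet diet compositions, and log-normal
## depths.

.rgumbel <- function(n) -log(-log(stats::runif(n)))

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Pure-birth (Yule) tree conditioned on `n` tips, rescaled to unit root
#' depth, with tips labeled sp001...spN.
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer seed.
#' @return an `ape::phylo`.
#' @export
simulate_tree <- function(n_species, seed = 1L) {
  if (n_species < 2L) stop("need at least 2 species")
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tr
}

#' Parametric tooth-crown template
#'
#' Deterministic smooth map from three crown parameters to a 160-point
#' outline: 3 fixed anchors (mesial and distal crown-root corners, apex)
#' and two equidistantly resampled semilandmark curves on the mesial and
#' distal sides of the crown. The crown base spans x in [-1, 1].
#'
#' @param obliquity apex x-offset (cusp slant); valid range [-0.8, 0.8].
#' @param height cusp height over half the base width; valid [0.6, 3.5].
#' @param shoulder distal-shoulder curvature (outward bulge of the distal
#'   curve); valid [-0.3, 0.6].
#' @param n_mesial,n_distal semilandmarks per curve (157 in total by
#'   default, matching the digitization scheme).
#' @return a [landmark_config] for the template shape.
#' @export
tooth_template <- function(obliquity = 0, height = 1.8, shoulder = 0.15,
                           n_mesial = 78L, n_distal = 79L) {
  clip <- function(v, lo, hi, what) {
    if (v < lo || v > hi) {
      warning(what, " = ", format(v), " outside [", lo, ", ", hi,
              "]; clipped")
      v <- min(max(v, lo), hi)
    }
    v
  }
  obliquity <- clip(obliquity, -0.8, 0.8, "obliquity")
  height <- clip(height, 0.6, 3.5, "height")
  shoulder <- clip(shoulder, -0.3, 0.6, "shoulder")
  L <- c(-1, 0); R <- c(1, 0); A <- c(obliquity, height)
  ## quadratic Bezier with an outward-normal control bulge; control y is
  ## capped below the apex so the apex stays the unique global y-maximum
  bez <- function(p0, p1, bulge, m) {
    mid <- (p0 + p1) / 2
    v <- p1 - p0
    nrm <- c(-v[2L], v[1L]) / sqrt(sum(v^2))
    if (nrm[1L] * sign(mid[1L] - A[1L]) < 0) nrm <- -nrm  # bulge away from cusp axis
    ctl <- mid + bulge * nrm
    ctl[2L] <- min(ctl[2L], height * 0.93)
    tt <- seq(0, 1, length.out = 20L * (m + 2L))
    curve <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), ctl) +
      outer(tt^2, p1)
    resample_equidistant(curve, m + 2L)[-c(1L, m + 2L), , drop = FALSE]
  }
  mes <- bez(L, A, 0.12 * height, n_mesial)
  dis <- bez(A, R, shoulder * height, n_distal)
  pts <- rbind(L, A, R, mes, dis)
  roles <- c(rep("fixed", 3L), rep("semilandmark", n_mesial + n_distal))
  curves <- list(
    structure(3L + seq_len(n_mesial), anchors = c(1L, 2L)),
    structure(3L + n_mesial + seq_len(n_distal), anchors = c(2L, 3L)))
  landmark_config(pts, roles, curves, specimen_id = "template",
                  species_id = "template")
}

#' Simulate species mean tooth shapes by Brownian motion
#'
#' Evolves the three crown parameters along the tree under independent
#' Brownian motions (rates `sigma2_b`, per unit tree depth) and maps each
#' tip's parameters through [tooth_template]. Parameters falling outside
#' the template's valid range are clipped with a warning.
#'
#' @param tree ultrametric `phylo` from [simulate_tree].
#' @param sigma2_b length-3 BM rate vector for (obliquity, height,
#'   shoulder).
#' @param root root state, defaults to the template defaults.
#' @param seed integer seed.
#' @return list with `params` (tips-by-3 matrix) and `shapes` (named list
#'   of [landmark_config] species mean configurations).
#' @export
simulate_species_shapes <- function(tree, sigma2_b = c(0.08, 0.02, 0.005),
                                    root = c(0, 1.8, 0.15), seed = 1L) {
  if (any(sigma2_b < 0)) stop("rates must be non-negative")
  set.seed(seed)
  C <- ape::vcv(tree)
  n <- nrow(C)
  params <- sapply(1:3, function(j) {
    if (sigma2_b[j] == 0) rep(root[j], n)
    else MASS::mvrnorm(1L, mu = rep(root[j], n), Sigma = sigma2_b[j] * C)
  })
  dimnames(params) <- list(rownames(C), c("obliquity", "height", "shoulder"))
  shapes <- lapply(rownames(C), function(sp) {
    cf <- tooth_template(params[sp, 1L], params[sp, 2L], params[sp, 3L])
    cf$specimen_id <- cf$species_id <- sp
    cf
  })
  names(shapes) <- rownames(C)
  list(params = params, shapes = shapes)
}

## jaw effect: narrow the cusp of lower-jaw teeth by pulling x toward the
## apex axis, increasingly with height so the crown base is unchanged
.apply_jaw_effect <- function(pts, factor) {
  apex <- pts[2L, ]
  h <- apex[2L]
  wt <- pmax(pts[, 2L], 0) / h
  pts[, 1L] <- apex[1L] + (pts[, 1L] - apex[1L]) * (1 - (1 - factor) * wt)
  pts
}

#' Simulate tooth specimens around species mean shapes
#'
#' Draws a number of teeth per species, adds iid Gaussian landmark noise,
#' applies a fixed lower-jaw cusp-narrowing factor to emulate dignathic
#' heterodonty, and gives each specimen a random similarity transform
#' (rotation, translation, digitizer scale) that superimposition must
#' remove. Specimen ids follow the species__jaw__position__side__replicate
#' convention understood by [parse_tps].
#'
#' @param species_shapes result of [simulate_species_shapes] (or its
#'   `shapes` element).
#' @param teeth_per_species range (min, max) of teeth drawn per species.
#' @param sigma_w within-species landmark noise standard deviation.
#' @param jaw_effect lower-jaw cusp width multiplier at the apex.
#' @param transform apply the random similarity transform? Disable to get
#'   specimens expressed directly in the species-mean frame (pure noise
#'   plus jaw effect), e.g. when validating against generator truth.
#' @param seed integer seed.
#' @return list of [landmark_config] specimens.
#' @export
simulate_specimens <- function(species_shapes, teeth_per_species = c(14L, 69L),
                               sigma_w = 0.015, jaw_effect = 0.85,
                               transform = TRUE, seed = 1L) {
  if (sigma_w < 0) stop("sigma_w must be non-negative")
  shapes <- if (!is.null(species_shapes$shapes)) species_shapes$shapes
  else species_shapes
  set.seed(seed)
  out <- list()
  for (sp in names(shapes)) {
    tmpl <- shapes[[sp]]
    n_range <- seq(teeth_per_species[1L], teeth_per_species[2L])
    n_teeth <- n_range[sample.int(length(n_range), 1L)]
    jaw <- rep(c("upper", "lower"), length.out = n_teeth)
    pos <- stats::ave(seq_len(n_teeth), jaw, FUN = seq_along)
    for (t in seq_len(n_teeth)) {
      pts <- tmpl$points
      if (jaw[t] == "lower") pts <- .apply_jaw_effect(pts, jaw_effect)
      pts <- pts + matrix(stats::rnorm(length(pts), sd = sigma_w),
                          ncol = 2L)
      if (transform) {
        th <- stats::runif(1L, -pi / 12, pi / 12)
        Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
        sc <- exp(stats::rnorm(1L, 0, 0.1))
        pts <- sc * pts %*% Rm +
          matrix(stats::rnorm(2L, 0, 0.5), nrow(pts), 2L, byrow = TRUE)
      }
      id <- sprintf("%s__%s__%d__right__%d", sp, jaw[t], pos[t], t)
      out[[length(out) + 1L]] <- landmark_config(
        pts, tmpl$roles, tmpl$curves, specimen_id = id, species_id = sp,
        jaw = jaw[t], tooth_position = pos[t], side = "right",
        scale = exp(stats::rnorm(1L, 0, 0.2)))
    }
  }
  out
}

#' Assign threat statuses, traits and diets to simulated species
#'
#' Species are ranked by a noisy threat score
#' beta * (|z| - asym * z) + Gumbel noise, where z is the standardized
#' first crown parameter (cusp obliquity); the top ranks are filled into
#' CR, then EN, VU, NT and LC according to `counts`. The score grows with
#' morphological extremity in both directions but more steeply toward
#' negative z, so with beta > 0 threat concentrates on peripheral
#' morphologies with a directional bias and the least-concern species end
#' up near the center of the axis — the geometry in which targeted
#' extinction both displaces the mean shape and depresses disparity
#' relative to random extinction. beta = 0 makes threat independent of
#' morphology. Body length
#' (and hence size class) is correlated with s1, diets are Dirichlet
#' draws whose concentration grows with size class (larger species feed
#' more evenly), and depths are log-normal.
#'
#' @param params tips-by-3 parameter matrix from
#'   [simulate_species_shapes].
#' @param beta threat selectivity (slope of the threat score on the
#'   standardized first crown parameter).
#' @param asym directional asymmetry of the selectivity (0 = purely
#'   peripheral threat, larger values weight the negative tail more).
#' @param counts named status counts (CR, EN, VU, NT, LC) summing to the
#'   species count.
#' @param diet_coverage fraction of species with diet data.
#' @param seed integer seed.
#' @return list with `traits` (data frame) and `diets`
#'   (species-by-10-prey proportion matrix).
#' @export
assign_statuses_and_traits <- function(params, beta = 2, asym = 0.4,
                                       counts = c(CR = 4L, EN = 8L, VU = 10L,
                                                  NT = 4L, LC = 4L),
                                       diet_coverage = 0.9, seed = 1L) {
  sp <- rownames(params)
  n <- length(sp)
  if (sum(counts) != n) {
    stop("status counts sum to ", sum(counts), " but there are ", n,
         " species")
  }
  set.seed(seed)
  s1 <- as.numeric(scale(params[, 1L]))
  score <- beta * (abs(s1) - asym * s1) + .rgumbel(n)
  status <- character(n)
  ord <- order(score, decreasing = TRUE)
  status[ord] <- rep(names(counts), counts)
  len <- exp(log(150) + 0.45 * s1 + stats::rnorm(n, 0, 0.45))
  size_class <- cut(len, c(0, 150, 300, Inf),
                    labels = c("small", "medium", "large"))
  habitat <- sample(c("coastal", "pelagic"), n, replace = TRUE,
                    prob = c(0.8, 0.2))
  reef <- ifelse(habitat == "coastal",
                 stats::runif(n) < 0.5, stats::runif(n) < 0.1)
  depth <- stats::rlnorm(n, log(100), 0.8)
  traits <- data.frame(
    species_id = sp,
    iucn = status,
    body_size_class = as.character(size_class),
    habitat = habitat,
    reef_associated = reef,
    max_depth_m = round(depth, 1),
    total_length_cm = round(len, 1),
    stringsAsFactors = FALSE)

  prey <- c("teleost", "chondrichthyan", "cephalopod", "decapod",
            "mollusc", "annelid", "reptile", "bird", "mammal", "plant")
  base_w <- c(0.50, 0.08, 0.12, 0.12, 0.05, 0.04, 0.03, 0.01, 0.02, 0.03)
  conc <- c(small = 6, medium = 12, large = 25)[as.character(size_class)]
  diets <- t(vapply(seq_len(n), function(i) {
    g <- stats::rgamma(length(prey), shape = conc[i] * base_w)
    d <- g / sum(g)
    d[d < 0.02] <- 0           # structural zeros for rare prey
    d / sum(d)
  }, numeric(length(prey))))
  dimnames(diets) <- list(sp, prey)
  keep <- sort(sample.int(n, round(diet_coverage * n)))
  diets <- diets[keep, , drop = FALSE]
  ## guard: keep every prey represented somewhere so the loader's all-zero
  ## column drop is exercised only by purpose-built fixtures
  for (j in which(colSums(diets) == 0)) {
    i <- which.max(diets[, 1L])
    diets[i, j] <- 0.02
    diets[i, ] <- diets[i, ] / sum(diets[i, ])
  }
  list(traits = traits, diets = diets)
}

#' Status counts scaled from the canonical 30-species composition
#'
#' The canonical composition is CR 4, EN 8, VU 10, NT 4, LC 4 (30
#' species); other species counts are allocated proportionally by
#' largest remainder, keeping every category non-empty where possible.
#'
#' @param n_species total number of species.
#' @return named integer vector summing to `n_species`.
#' @export
scaled_status_counts <- function(n_species) {
  ref <- c(CR = 4, EN = 8, VU = 10, NT = 4, LC = 4)
  if (n_species == 30L) return(stats::setNames(as.integer(ref), names(ref)))
  if (n_species < length(ref)) stop("need at least 5 species")
  exact <- ref / sum(ref) * n_species
  cnt <- pmax(floor(exact), 1)
  rem <- n_species - sum(cnt)
  if (rem > 0) {
    ord <- order(exact - floor(exact), decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(cnt, decreasing = TRUE)
    for (i in seq_len(-rem)) cnt[ord[i]] <- cnt[ord[i]] - 1
  }
  stats::setNames(as.integer(cnt), names(ref))
}

#' Simulate a full synthetic dataset bundle
#'
#' One call wiring the generator stages together under a single root
#' seed: tree, species shapes, specimens, statuses, traits and diets.
#' The defaults mirror the study conditions (30 species, 14-69 teeth per
#' species, 160 landmarks, status counts 4/8/10/4/4).
#'
#' @param n_species number of species.
#' @param beta threat-morphology selectivity.
#' @param sigma2_b BM rates for the crown parameters.
#' @param sigma_w within-species landmark noise sd.
#' @param teeth_per_species range of teeth per species.
#' @param counts status counts (scaled defaults apply only to 30 species).
#' @param diet_coverage fraction of species with diets.
#' @param seed root seed; stage seeds are derived deterministically.
#' @return object of class `synthetic_bundle`: `tree`, `params`,
#'   `species_shapes`, `configs`, `traits`, `diets`, `seed`.
#' @export
simulate_dataset <- function(n_species = 30L, beta = 2,
                             sigma2_b = c(0.08, 0.02, 0.005),
                             sigma_w = 0.015,
                             teeth_per_species = c(14L, 69L),
                             counts = NULL,
                             diet_coverage = 0.9, seed = 1L) {
  if (is.null(counts)) counts <- scaled_status_counts(n_species)
  sub <- function(i) (as.integer(seed) * 11L + i * 7919L) %% 2147483647L
  tree <- simulate_tree(n_species, seed = sub(1L))
  ssh <- simulate_species_shapes(tree, sigma2_b = sigma2_b, seed = sub(2L))
  configs <- simulate_specimens(ssh, teeth_per_species = teeth_per_species,
                                sigma_w = sigma_w, seed = sub(3L))
  at <- assign_statuses_and_traits(ssh$params, beta = beta, counts = counts,
                                   diet_coverage = diet_coverage,
                                   seed = sub(4L))
  structure(list(tree = tree, params = ssh$params,
                 species_shapes = ssh$shapes, configs = configs,
                 traits = at$traits, diets = at$diets, seed = seed),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic tooth-shape bundle (seed ", x$seed, ")\n", sep = "")
  cat("  ", nrow(x$params), " species, ", length(x$configs),
      " specimens, diets for ", nrow(x$diets), " species\n", sep = "")
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Serializes a bundle as the external formats the loader consumes: a TPS
#' landmark file, traits and diets CSVs and a newick tree.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tps = file.path(dir, "landmarks.tps"),
             traits = file.path(dir, "traits.csv"),
             diets = file.path(dir, "diets.csv"),
             tree = file.path(dir, "tree.nwk"))
  write_tps(bundle$configs, paths["tps"])
  utils::write.csv(bundle$traits, paths["traits"], row.names = FALSE)
  diets <- data.frame(species_id = rownames(bundle$diets), bundle$diets,
                      check.names = FALSE)
  utils::write.csv(diets, paths["diets"], row.names = FALSE)
  ape::write.tree(bundle$tree, paths["tree"])
  invisible(paths)
}
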