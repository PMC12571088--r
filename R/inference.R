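## Residual-randomization permutation inference for multivariate shape
## data. Sums of squares are trace-based (Goodall-style): squared
## Procrustes distances pooled over all coordinates, so the full data
## space is used rather than single ordination axes.

.rss <- function(Q, Y) max(sum(Y^2) - sum(crossprod(Q, Y)^2), 0)

#' Permutation ANOVA for shape data (RRPP)
#'
#' Linear models on an entity-by-coordinate response with significance by
#' residual randomization. Terms enter sequentially (Type I); for each
#' term the residuals of the reduced model (all preceding terms) are
#' permuted, added back to the reduced fit, and the term's F statistic is
#' recomputed. For a one-way design this reduces to label permutation.
#' The observed statistic is included in the reference set, so
#' p >= 1/(n_perm + 1). Effect sizes Z are standard deviates of the
#' log-transformed F statistics.
#'
#' @param formula model formula; left side is a coordinate matrix (or a
#'   numeric vector), e.g. `shape ~ log(size) + species`.
#' @param data data frame (or environment) holding the predictors.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return object of class `rrpp_anova` with an ANOVA `table` (Df, SS,
#'   MS, Rsq, F, Z, p) and the permutation settings.
#' @export
perm_anova <- function(formula, data = NULL, n_perm = 999L, seed = 1L) {
  mf <- stats::model.frame(formula, data = data)
  Y <- as.matrix(stats::model.response(mf))
  n <- nrow(Y)
  tl <- attr(stats::terms(mf), "term.labels")
  if (length(tl) == 0L) stop("model has no terms")
  for (v in names(mf)[-1L]) {
    if (is.factor(mf[[v]]) || is.character(mf[[v]])) {
      f <- factor(mf[[v]])
      if (any(table(f) == 0L)) stop("factor level with zero members: ", v)
      mf[[v]] <- f
    }
  }
  ## design matrices for the nested sequence intercept, +term1, +term2, ...
  Xs <- vector("list", length(tl) + 1L)
  Xs[[1L]] <- matrix(1, n, 1L)
  for (i in seq_along(tl)) {
    fm <- stats::reformulate(tl[seq_len(i)])
    Xs[[i + 1L]] <- stats::model.matrix(fm, mf)
  }
  Qs <- lapply(Xs, function(X) qr.Q(qr(X)))
  dfs <- vapply(Xs, function(X) qr(X)$rank, 0L)
  df_terms <- diff(dfs)
  df_res <- n - dfs[length(dfs)]
  if (df_res <= 0L) stop("no residual degrees of freedom")
  ss_total <- .rss(Qs[[1L]], Y)
  Q_full <- Qs[[length(Qs)]]

  set.seed(seed)
  perms <- cbind(seq_len(n),
                 replicate(n_perm, sample.int(n)))
  Fperm <- matrix(NA_real_, length(tl), n_perm + 1L)
  for (i in seq_along(tl)) {
    Q_red <- Qs[[i]]; Q_ful <- Qs[[i + 1L]]
    fit_red <- Q_red %*% crossprod(Q_red, Y)
    res_red <- Y - fit_red
    for (j in seq_len(ncol(perms))) {
      Yp <- fit_red + res_red[perms[, j], , drop = FALSE]
      ss_i <- max(.rss(Q_red, Yp) - .rss(Q_ful, Yp), 0)
      ms_res <- .rss(Q_full, Yp) / df_res
      Fperm[i, j] <- (ss_i / df_terms[i]) / ms_res
    }
  }
  Fobs <- Fperm[, 1L]
  ss_obs <- vapply(seq_along(tl), function(i) {
    .rss(Qs[[i]], Y) - .rss(Qs[[i + 1L]], Y)
  }, 0)
  p <- vapply(seq_along(tl), function(i) mean(Fperm[i, ] >= Fobs[i]), 0)
  z <- vapply(seq_along(tl), function(i) {
    lf <- suppressWarnings(log(Fperm[i, ]))
    ok <- is.finite(lf)
    if (is.infinite(Fobs[i])) return(Inf)  # perfect separation
    if (Fobs[i] <= 0 || sum(ok) < 2L) return(0)
    s <- stats::sd(lf[ok])
    if (s == 0) 0 else (log(Fobs[i]) - mean(lf[ok])) / s
  }, 0)
  rss_full <- .rss(Q_full, Y)
  tab <- data.frame(
    Df = c(df_terms, df_res),
    SS = c(ss_obs, rss_full),
    MS = c(ss_obs / df_terms, rss_full / df_res),
    Rsq = c(ss_obs / ss_total, rss_full / ss_total),
    F = c(Fobs, NA),
    Z = c(z, NA),
    p = c(p, NA),
    row.names = c(tl, "Residuals"))
  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 ss_total = ss_total, call = match.call()),
            class = "rrpp_anova")
}

#' @export
print.rrpp_anova <- function(x, ...) {
  cat("Permutation ANOVA (residual randomization,", x$n_perm,
      "permutations)\n")
  tab <- x$table
  tab$p <- format.pval(tab$p, digits = 3)
  print(format(tab, digits = 4))
  invisible(x)
}

#' Pairwise group contrasts in shape space
#'
#' For every unordered pair of groups, the Euclidean distance between
#' group mean shapes, with a permutation reference distribution obtained
#' by reshuffling group labels. Z and p follow the same conventions as
#' [perm_anova] (log-transformed statistic, observed included).
#' Singleton groups are allowed (the distance is defined) but flagged.
#'
#' @param Y entity-by-coordinate response matrix.
#' @param groups group labels.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return object of class `pairwise_shape`: data frame with one row per
#'   pair (`group1`, `group2`, `d`, `Z`, `p`).
#' @export
pairwise_groups <- function(Y, groups, n_perm = 999L, seed = 1L) {
  Y <- as.matrix(Y)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  singleton <- names(which(table(groups) == 1L))
  lev <- levels(groups)
  ij <- utils::combn(length(lev), 2L)
  pairs <- cbind(lev[ij[1L, ]], lev[ij[2L, ]])
  pair_d <- function(g) {
    mns <- rowsum(Y, g) / as.numeric(table(g))
    mns <- mns[lev, , drop = FALSE]
    d <- as.matrix(stats::dist(mns))
    d[t(ij)]
  }
  set.seed(seed)
  obs <- pair_d(groups)
  dperm <- matrix(NA_real_, length(obs), n_perm + 1L)
  dperm[, 1L] <- obs
  for (j in seq_len(n_perm)) {
    dperm[, j + 1L] <- pair_d(groups[sample.int(length(groups))])
  }
  p <- rowMeans(dperm >= obs)
  z <- vapply(seq_along(obs), function(i) {
    v <- dperm[i, ]
    if (any(v <= 0)) return(NA_real_)
    lv <- log(v)
    s <- stats::sd(lv)
    if (s == 0) 0 else (log(obs[i]) - mean(lv)) / s
  }, 0)
  out <- data.frame(group1 = pairs[, 1L], group2 = pairs[, 2L],
                    d = obs, Z = z, p = p, stringsAsFactors = FALSE)
  structure(list(table = out, singleton_groups = singleton,
                 n_perm = n_perm, seed = seed),
            class = "pairwise_shape")
}

#' @export
print.pairwise_shape <- function(x, ...) {
  cat("Pairwise shape contrasts (", x$n_perm, " permutations)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$singleton_groups)) {
    cat("  note: singleton group(s): ",
        paste(x$singleton_groups, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Multivariate phylogenetic signal (Blomberg-type K)
#'
#' Generalization of Blomberg's K to multivariate data via the
#' phylogenetic covariance matrix: the observed ratio of tip-level to
#' phylogenetically transformed sums of squares about the GLS root
#' estimate, divided by its Brownian-motion expectation, pooled across
#' coordinates. K has expectation 1 under Brownian motion on the supplied
#' tree. Significance comes from permuting species across tips; the
#' effect size Z standardizes log K against its permutation distribution.
#'
#' @param Y species-by-coordinate matrix with species row names.
#' @param tree an `ape::phylo` with branch lengths; tips must match the
#'   row names of `Y` exactly.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return object of class `phylo_signal_fit` with elements `K`, `Z`,
#'   `p`, `n_perm`, `permuted` (the permutation K values).
#' @export
phylo_signal <- function(Y, tree, n_perm = 999L, seed = 1L) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) stop("Y needs species row names")
  if (!setequal(rownames(Y), tree$tip.label) ||
      nrow(Y) != length(tree$tip.label)) {
    stop("tree tips and species ids do not match: ",
         paste(c(setdiff(rownames(Y), tree$tip.label),
                 setdiff(tree$tip.label, rownames(Y))), collapse = ", "))
  }
  if (any(tree$edge.length <= 0)) stop("branch lengths must be positive")
  Y <- Y[tree$tip.label, , drop = FALSE]
  if (sum(apply(Y, 2L, stats::var)) == 0) {
    stop("zero-variance data: phylogenetic signal is undefined")
  }
  C <- ape::vcv(tree)
  n <- nrow(C)
  eig <- eigen(C, symmetric = TRUE)
  if (any(eig$values <= 0)) stop("phylogenetic covariance is singular")
  Cinv <- eig$vectors %*% (t(eig$vectors) / eig$values)
  Cinv_sqrt <- eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
  one <- rep(1, n)
  w <- as.numeric(Cinv %*% one) / sum(Cinv)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  k_stat <- function(Ym) {
    a <- crossprod(w, Ym)                      # GLS root estimate
    R <- sweep(Ym, 2L, a)
    num <- sum(R^2)
    den <- sum((Cinv_sqrt %*% R)^2)
    (num / den) / expected
  }
  K <- k_stat(Y)
  set.seed(seed)
  perm <- c(K, replicate(n_perm, k_stat(Y[sample.int(n), , drop = FALSE])))
  p <- mean(perm >= K)
  lk <- log(perm)
  s <- stats::sd(lk)
  Z <- if (s == 0) 0 else (log(K) - mean(lk)) / s
  structure(list(K = K, Z = Z, p = p, n_perm = n_perm, seed = seed,
                 permuted = perm),
            class = "phylo_signal_fit")
}

#' @export
print.phylo_signal_fit <- function(x, ...) {
  cat(sprintf(
    "Multivariate phylogenetic signal: K = %.4g, Z = %.3g, p = %.4g (%d perms)\n",
    x$K, x$Z, x$p, x$n_perm))
  invisible(x)
}
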