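#' Landmark configuration constructor
#'
#' Bundles one specimen's ordered 2D points with their fixed/semilandmark
#' roles and curve membership. Curves are ordered runs of semilandmarks
#' strung between two fixed anchor landmarks.
#'
#' @param points numeric matrix (p x 2) of landmark coordinates.
#' @param roles character vector, one of `"fixed"` or `"semilandmark"` per point.
#' @param curves list of integer vectors; each vector indexes the
#'   semilandmarks of one curve in order, with an `anchors` attribute giving
#'   the indices of the two fixed landmarks the curve runs between.
#' @param specimen_id,species_id identifiers.
#' @param jaw `"upper"` or `"lower"`.
#' @param tooth_position positive integer, 1 = nearest the symphysis.
#' @param side `"left"` or `"right"`.
#' @param scale physical length per coordinate unit (already applied to
#'   `points`).
#' @return an object of class `landmark_config`.
#' @export
landmark_config <- function(points, roles, curves,
                            specimen_id, species_id = specimen_id,
                            jaw = "upper", tooth_position = 1L,
                            side = "right", scale = 1) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be a two-column matrix")
  if (!all(is.finite(points))) stop("non-finite coordinates in '", specimen_id, "'")
  if (length(roles) != nrow(points)) stop("roles length must match point count")
  if (!all(roles %in% c("fixed", "semilandmark"))) {
    stop("roles must be 'fixed' or 'semilandmark'")
  }
  jaw <- match.arg(jaw, c("upper", "lower"))
  side <- match.arg(side, c("left", "right"))
  semi <- which(roles == "semilandmark")
  in_curves <- as.integer(sort(unlist(lapply(curves, as.integer),
                                      use.names = FALSE)))
  if (!identical(as.integer(semi), in_curves)) {
    stop("every semilandmark must belong to exactly one curve ('",
         specimen_id, "')")
  }
  for (cv in curves) {
    anc <- attr(cv, "anchors")
    if (is.null(anc) || length(anc) != 2L || any(roles[anc] != "fixed")) {
      stop("each curve needs an 'anchors' attribute naming two fixed landmarks")
    }
    run <- c(anc[1L], cv, anc[2L])
    d <- sqrt(rowSums((points[run[-1L], , drop = FALSE] -
                         points[run[-length(run)], , drop = FALSE])^2))
    if (any(d == 0)) {
      stop("coincident consecutive curve points in '", specimen_id, "'")
    }
  }
  structure(
    list(specimen_id = specimen_id, species_id = species_id, jaw = jaw,
         tooth_position = as.integer(tooth_position), side = side,
         points = unname(points), roles = roles, curves = curves,
         scale = scale),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration '", x$specimen_id, "' (", x$species_id, ", ",
      x$jaw, " jaw, position ", x$tooth_position, ", ", x$side, " side)\n",
      sep = "")
  cat("  ", sum(x$roles == "fixed"), " fixed landmarks, ",
      sum(x$roles == "semilandmark"), " semilandmarks in ",
      length(x$curves), " curve(s); scale ", format(x$scale), "\n", sep = "")
  invisible(x)
}

## Specimen ids carry their metadata as
## species__jaw__position__side__replicate; anything else falls back to
## defaults (species = id, upper jaw, position 1, right side).
.parse_specimen_id <- function(id) {
  parts <- strsplit(id, "__", fixed = TRUE)[[1L]]
  if (length(parts) == 5L && parts[2L] %in% c("upper", "lower") &&
      parts[4L] %in% c("left", "right") &&
      !is.na(suppressWarnings(as.integer(parts[3L])))) {
    list(species_id = parts[1L], jaw = parts[2L],
         tooth_position = as.integer(parts[3L]), side = parts[4L])
  } else {
    list(species_id = id, jaw = "upper", tooth_position = 1L, side = "right")
  }
}

#' Parse a TPS landmark file
#'
#' Reads the TpsDig dialect used for 2D tooth digitization: `LM=` blocks of
#' fixed landmarks, optional `CURVES=`/`POINTS=` semilandmark curve blocks,
#' `ID=`, `SCALE=` and (ignored) `IMAGE=` records. Coordinates are
#' multiplied by `SCALE` when present. Left-side specimens are mirrored
#' about the vertical axis at load time so all configurations share the
#' standard orientation (labial view, apex up, right side). Each curve's
#' anchor landmarks are identified as the fixed landmarks nearest its two
#' ends.
#'
#' @param path path to a TPS file, or a character vector of lines via
#'   `text`.
#' @param text optional character vector of file lines (overrides `path`).
#' @return a list of [landmark_config] objects.
#' @export
parse_tps <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  i <- 1L
  n <- length(lines)
  out <- list()
  rec <- 0L
  read_coords <- function(start, count, what) {
    if (start + count - 1L > n) {
      stop("record ", rec, ": expected ", count, " ", what,
           " coordinate lines but file ended")
    }
    block <- lines[start:(start + count - 1L)]
    xy <- suppressWarnings(lapply(strsplit(block, "[ \t,]+"), as.numeric))
    bad <- vapply(xy, function(v) length(v) != 2L || anyNA(v), logical(1L))
    if (any(bad)) {
      stop("record ", rec, ": expected ", count, " ", what,
           " coordinate lines; line '", block[which(bad)[1L]],
           "' is not an x y pair")
    }
    matrix(unlist(xy), ncol = 2L, byrow = TRUE)
  }
  while (i <= n) {
    if (!grepl("^LM=", lines[i])) {
      i <- i + 1L
      next
    }
    rec <- rec + 1L
    n_fixed <- as.integer(sub("^LM=", "", lines[i]))
    i <- i + 1L
    fixed_pts <- read_coords(i, n_fixed, "fixed-landmark")
    i <- i + n_fixed
    curve_pts <- list()
    if (i <= n && grepl("^CURVES=", lines[i])) {
      n_curves <- as.integer(sub("^CURVES=", "", lines[i]))
      i <- i + 1L
      for (k in seq_len(n_curves)) {
        if (i > n || !grepl("^POINTS=", lines[i])) {
          stop("record ", rec, ": CURVES=", n_curves,
               " but curve ", k, " has no POINTS= header")
        }
        m <- as.integer(sub("^POINTS=", "", lines[i]))
        i <- i + 1L
        curve_pts[[k]] <- read_coords(i, m, paste0("curve-", k))
        i <- i + m
      }
    }
    id <- NULL
    scale <- 1
    while (i <= n && !grepl("^LM=", lines[i])) {
      if (grepl("^ID=", lines[i])) {
        id <- sub("^ID=", "", lines[i])
      } else if (grepl("^SCALE=", lines[i])) {
        scale <- as.numeric(sub("^SCALE=", "", lines[i]))
      } else if (!grepl("^IMAGE=", lines[i])) {
        warning("record ", rec, ": ignoring unrecognized line '",
                lines[i], "'")
      }
      i <- i + 1L
    }
    if (is.null(id)) stop("record ", rec, ": missing ID= line")
    pts <- rbind(fixed_pts, do.call(rbind, curve_pts)) * scale
    roles <- c(rep("fixed", n_fixed),
               rep("semilandmark", sum(vapply(curve_pts, nrow, 0L))))
    curves <- list()
    at <- n_fixed
    for (k in seq_along(curve_pts)) {
      idx <- at + seq_len(nrow(curve_pts[[k]]))
      at <- at + nrow(curve_pts[[k]])
      ends <- pts[c(idx[1L], idx[length(idx)]), , drop = FALSE]
      anchors <- apply(ends, 1L, function(e) {
        which.min(colSums((t(pts[seq_len(n_fixed), , drop = FALSE]) - e)^2))
      })
      curves[[k]] <- structure(idx, anchors = as.integer(anchors))
    }
    meta <- .parse_specimen_id(id)
    if (meta$side == "left") pts[, 1L] <- -pts[, 1L]
    out[[length(out) + 1L]] <- landmark_config(
      pts, roles, curves, specimen_id = id, species_id = meta$species_id,
      jaw = meta$jaw, tooth_position = meta$tooth_position,
      side = meta$side, scale = scale)
  }
  if (rec == 0L) stop("no LM= records found")
  out
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [parse_tps]: emits `LM=`/`CURVES=`/`POINTS=`/`ID=`/`SCALE=`
#' records. Coordinates are divided by each configuration's scale (so the
#' file stores digitizer units) and left-side specimens are un-mirrored, so
#' `parse_tps(write_tps(x))` reproduces `x`.
#'
#' @param configs a list of [landmark_config] objects.
#' @param path output path; omit to return the lines invisibly.
#' @param digits coordinate precision in the file.
#' @return invisibly, the character vector of file lines.
#' @export
write_tps <- function(configs, path = NULL, digits = 6) {
  fmt <- function(p) sprintf(paste0("%.", digits, "f %.", digits, "f"),
                             p[, 1L], p[, 2L])
  lines <- unlist(lapply(configs, function(cf) {
    pts <- cf$points / cf$scale
    if (cf$side == "left") pts[, 1L] <- -pts[, 1L]
    fixed <- which(cf$roles == "fixed")
    rec <- c(paste0("LM=", length(fixed)), fmt(pts[fixed, , drop = FALSE]))
    if (length(cf$curves)) {
      rec <- c(rec, paste0("CURVES=", length(cf$curves)))
      for (cv in cf$curves) {
        rec <- c(rec, paste0("POINTS=", length(cv)),
                 fmt(pts[cv, , drop = FALSE]))
      }
    }
    c(rec, paste0("ID=", cf$specimen_id), paste0("SCALE=", format(cf$scale)))
  }))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
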