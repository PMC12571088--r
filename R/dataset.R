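#' Assemble a cross-validated analysis dataset
#'
#' Joins digitized landmark configurations with the species trait table,
#' the proportional diet matrix and (optionally) a phylogeny, checking that
#' the pieces refer to the same species. Species present in the landmark
#' data but missing from the traits table are a hard error; species missing
#' from the diet matrix or the tree are retained and flagged (shape and
#' diet coverage can legitimately differ).
#'
#' @param tps character vector of TPS file paths, or a list of
#'   [landmark_config] objects.
#' @param traits path to a CSV with columns `species_id`, `iucn`
#'   (CR/EN/VU/NT/LC), `body_size_class` (small/medium/large), `habitat`
#'   (coastal/pelagic), `reef_associated` (logical), `max_depth_m`,
#'   `total_length_cm` — or an equivalent data frame.
#' @param diets path to a species-by-prey CSV of proportional diet
#'   compositions (first column `species_id`), or an equivalent matrix with
#'   species row names. Rows are renormalized to sum to one; all-zero prey
#'   columns are dropped with a warning.
#' @param tree optional path to a newick file, or an `ape::phylo` object.
#'   Tip labels must match trait species ids.
#' @return an object of class `tooth_dataset`: list with `configs`,
#'   `traits`, `diets`, `tree`, and per-species coverage flags
#'   `has_diet` / `in_tree`.
#' @export
load_dataset <- function(tps, traits, diets = NULL, tree = NULL) {
  configs <- if (is.character(tps)) {
    unlist(lapply(tps, parse_tps), recursive = FALSE)
  } else tps
  ids <- vapply(configs, `[[`, "", "specimen_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate specimen_id: ", paste(dup, collapse = ", "))
  }
  if (is.character(traits)) {
    traits <- utils::read.csv(traits, stringsAsFactors = FALSE)
  }
  traits <- as.data.frame(traits)
  iucn_levels <- c("CR", "EN", "VU", "NT", "LC")
  if (!all(c("species_id", "iucn") %in% names(traits))) {
    stop("traits table needs at least species_id and iucn columns")
  }
  bad <- setdiff(unique(traits$iucn), iucn_levels)
  if (length(bad)) stop("unknown IUCN categories: ", paste(bad, collapse = ", "))
  traits$iucn <- factor(traits$iucn, levels = iucn_levels, ordered = TRUE)
  traits$threatened <- traits$iucn %in% c("CR", "EN", "VU")
  lm_species <- unique(vapply(configs, `[[`, "", "species_id"))
  missing_tr <- setdiff(lm_species, traits$species_id)
  if (length(missing_tr)) {
    stop("species in landmark data but absent from traits: ",
         paste(missing_tr, collapse = ", "))
  }

  diet_mat <- NULL
  if (!is.null(diets)) {
    if (is.character(diets)) {
      d <- utils::read.csv(diets, stringsAsFactors = FALSE, check.names = FALSE)
      diet_mat <- as.matrix(d[, -1L, drop = FALSE])
      rownames(diet_mat) <- d[[1L]]
    } else {
      diet_mat <- as.matrix(diets)
    }
    if (any(diet_mat < 0)) stop("diet proportions must be non-negative")
    zero_col <- colSums(diet_mat) == 0
    if (any(zero_col)) {
      warning("dropping all-zero prey categories: ",
              paste(colnames(diet_mat)[zero_col], collapse = ", "))
      diet_mat <- diet_mat[, !zero_col, drop = FALSE]
    }
    rs <- rowSums(diet_mat)
    if (any(rs == 0)) {
      stop("all-zero diet rows: ",
           paste(rownames(diet_mat)[rs == 0], collapse = ", "))
    }
    diet_mat <- diet_mat / rs
  }

  if (!is.null(tree)) {
    if (is.character(tree)) tree <- ape::read.tree(tree)
    extra <- setdiff(tree$tip.label, traits$species_id)
    if (length(extra)) {
      stop("tree tips not matching species ids: ",
           paste(extra, collapse = ", "))
    }
  }

  traits$has_diet <- traits$species_id %in% rownames(diet_mat)
  traits$in_tree <- if (is.null(tree)) FALSE else
    traits$species_id %in% tree$tip.label

  structure(list(configs = configs, traits = traits, diets = diet_mat,
                 tree = tree),
            class = "tooth_dataset")
}

#' @export
print.tooth_dataset <- function(x, ...) {
  sp <- unique(vapply(x$configs, `[[`, "", "species_id"))
  cat("Tooth shape dataset: ", length(x$configs), " specimens, ",
      length(sp), " species\n", sep = "")
  cat("  IUCN: ",
      paste(names(table(x$traits$iucn)), table(x$traits$iucn),
            sep = "=", collapse = " "), "\n", sep = "")
  cat("  diet coverage: ", sum(x$traits$has_diet), "/", nrow(x$traits),
      " species; tree: ",
      if (is.null(x$tree)) "absent" else paste0(length(x$tree$tip.label), " tips"),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.tooth_dataset <- function(object, ...) {
  sp <- vapply(object$configs, `[[`, "", "species_id")
  jaw <- vapply(object$configs, `[[`, "", "jaw")
  out <- list(n_specimens = length(sp),
              teeth_per_species = table(sp),
              jaw = table(jaw),
              iucn = table(object$traits$iucn),
              threatened_pct = 100 * mean(object$traits$threatened))
  class(out) <- "summary.tooth_dataset"
  out
}

#' @export
print.summary.tooth_dataset <- function(x, ...) {
  cat("Specimens:", x$n_specimens, "in", length(x$teeth_per_species),
      "species (teeth per species:",
      paste(range(x$teeth_per_species), collapse = "-"), ")\n")
  cat("Jaws:", paste(names(x$jaw), x$jaw, sep = "=", collapse = " "), "\n")
  cat("IUCN:", paste(names(x$iucn), x$iucn, sep = "=", collapse = " "),
      sprintf("(%.1f%% threatened)\n", x$threatened_pct))
  invisible(x)
}
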