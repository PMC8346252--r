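# Plaque segmentation and atlas-region density mapping.
#
# The measurement chain is: remove local autofluorescent background from the
# plaque-dye channel by scaled channel subtraction, apply one global
# intensity threshold (held constant across sections and subjects of a run)
# to form the plaque mask, then map masked-pixel density onto atlas regions
# as fractional area = total masked pixels / total region pixels pooled over
# all sections.

#' Subtract autofluorescence background from the signal channel
#'
#' @param ch3 signal-channel image (matrix) containing the plaque dye.
#' @param ch1 autofluorescence-channel image, same shape.
#' @param scale non-negative factor applied to `ch1` before subtraction
#'   (default 1).
#' @return `pmax(ch3 - scale * ch1, 0)`, element-wise.
#' @export
subtract_background <- function(ch3, ch1, scale = 1) {
  if (!identical(dim(ch3), dim(ch1)))
    stop_invalid("channel shapes must match")
  check_scalar_number(scale, "scale", lower = 0)
  pmax(ch3 - scale * ch1, 0)
}

#' Threshold a background-subtracted image into a plaque mask
#'
#' @param signal background-subtracted image (matrix).
#' @param threshold global intensity threshold, strictly positive; pixels
#'   strictly above it are masked.
#' @param min_area_px optional minimum object size in pixels; 4-connected
#'   components smaller than this are dropped. Default 0 (no size filter).
#' @return A logical matrix, TRUE where plaque.
#' @export
segment_plaques <- function(signal, threshold, min_area_px = 0) {
  check_scalar_number(threshold, "threshold", lower = 1e-12)
  mask <- signal > threshold
  if (min_area_px > 0) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_area_px)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  mask
}

# 4-connected component labelling by flood fill (iterative stack).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  cur <- 0L
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- cur
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      nb <- c(if (i > 1) p - 1L, if (i < nr) p + 1L,
              if (j > 1) p - nr, if (j < nc) p + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Upsample an atlas label image to the imaging resolution
#'
#' Nearest-neighbor interpolation: labels are categorical, so no averaging is
#' permissible. The label set is preserved. Works for downsampling too.
#'
#' @param labels integer label matrix.
#' @param target_shape integer vector `c(rows, cols)` of the output.
#' @return An integer label matrix of the target shape.
#' @export
upsample_labels <- function(labels, target_shape) {
  nr <- nrow(labels); nc <- ncol(labels)
  ri <- floor((seq_len(target_shape[1]) - 0.5) * nr / target_shape[1]) + 1L
  ci <- floor((seq_len(target_shape[2]) - 0.5) * nc / target_shape[2]) + 1L
  labels[ri, ci, drop = FALSE]
}

#' Fractional plaque area per atlas region
#'
#' Per region, masked and region pixel counts are pooled over all sections
#' first and divided once (a ratio of pooled counts, not a mean of
#' per-section ratios). The background label 0 is excluded. A region present
#' in the hierarchy but with zero pixels in the images gets `NA` density.
#'
#' @param masks list of logical plaque masks (or a single matrix).
#' @param labels list of integer label matrices matching `masks` (or a single
#'   matrix, recycled across sections).
#' @param region_ids optional integer vector of regions to report; defaults
#'   to all nonzero labels observed.
#' @return A data.frame: `region_id`, `masked_pixels`, `region_pixels`,
#'   `fractional_area`.
#' @export
region_density <- function(masks, labels, region_ids = NULL) {
  if (is.matrix(masks)) masks <- list(masks)
  if (is.matrix(labels)) labels <- rep(list(labels), length(masks))
  if (length(masks) != length(labels))
    stop_invalid("masks and labels must have the same number of sections")
  acc_m <- new.env(); acc_r <- new.env()
  for (s in seq_along(masks)) {
    if (!identical(dim(masks[[s]]), dim(labels[[s]])))
      stop_invalid("mask and label shapes must match per section")
    lab <- as.integer(labels[[s]])
    msk <- as.logical(masks[[s]])
    nz <- lab != 0L
    rp <- table(lab[nz])
    mp <- table(lab[nz & msk])
    for (k in names(rp)) {
      acc_r[[k]] <- (if (is.null(acc_r[[k]])) 0 else acc_r[[k]]) + rp[[k]]
    }
    for (k in names(mp)) {
      acc_m[[k]] <- (if (is.null(acc_m[[k]])) 0 else acc_m[[k]]) + mp[[k]]
    }
  }
  seen <- sort(as.integer(ls(acc_r)))
  if (is.null(region_ids)) region_ids <- seen
  rows <- lapply(region_ids, function(r) {
    k <- as.character(r)
    rp <- if (is.null(acc_r[[k]])) 0 else acc_r[[k]]
    mp <- if (is.null(acc_m[[k]])) 0 else acc_m[[k]]
    data.frame(region_id = r, masked_pixels = mp, region_pixels = rp,
               fractional_area = if (rp > 0) mp / rp else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# All descendants (inclusive) of `id` in a (region_id, parent_id) forest.
region_descendants <- function(hierarchy, id) {
  out <- id
  frontier <- id
  while (length(frontier)) {
    kids <- hierarchy$region_id[hierarchy$parent_id %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Aggregate a region density table up a hierarchy
#'
#' Pools masked and region pixel counts over the descendant set of each major
#' region, then divides. Children with zero area contribute nothing.
#'
#' @param table a \code{\link{region_density}} table at leaf resolution.
#' @param hierarchy data.frame with `region_id`, `name`, `parent_id`
#'   (`parent_id` 0 or NA for roots); must form a forest.
#' @param major_ids integer vector of region ids to aggregate to.
#' @return A `region_density`-shaped data.frame over `major_ids` with a
#'   `name` column when names are available.
#' @export
aggregate_to_major_regions <- function(table, hierarchy, major_ids) {
  rows <- lapply(major_ids, function(id) {
    desc <- region_descendants(hierarchy, id)
    sel <- table$region_id %in% desc
    mp <- sum(table$masked_pixels[sel])
    rp <- sum(table$region_pixels[sel])
    data.frame(region_id = id, masked_pixels = mp, region_pixels = rp,
               fractional_area = if (rp > 0) mp / rp else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(hierarchy$name))
    out$name <- hierarchy$name[match(out$region_id, hierarchy$region_id)]
  rownames(out) <- NULL
  out
}

#' Build a rectangular grid atlas
#'
#' Tiles the image into an `n_rows` x `n_cols` grid of equal rectangular
#' regions labelled 1..(n_rows*n_cols), with an optional flat hierarchy
#' grouping grid rows under major regions.
#'
#' @param shape image shape `c(rows, cols)`.
#' @param n_rows,n_cols grid dimensions.
#' @return A list: `labels` (integer matrix), `hierarchy` (region_id, name,
#'   parent_id; one parent per grid row, ids offset by 1000).
#' @export
grid_atlas <- function(shape, n_rows = 2, n_cols = 2) {
  ri <- pmin(floor((seq_len(shape[1]) - 1) * n_rows / shape[1]) + 1, n_rows)
  ci <- pmin(floor((seq_len(shape[2]) - 1) * n_cols / shape[2]) + 1, n_cols)
  labels <- outer(ri, ci, function(a, b) (a - 1L) * n_cols + b)
  leaf_ids <- seq_len(n_rows * n_cols)
  parent_ids <- 1000L + (leaf_ids - 1L) %/% n_cols + 1L
  hierarchy <- rbind(
    data.frame(region_id = unique(parent_ids),
               name = paste0("major_", unique(parent_ids)), parent_id = 0L),
    data.frame(region_id = leaf_ids, name = paste0("region_", leaf_ids),
               parent_id = parent_ids)
  )
  list(labels = labels, hierarchy = hierarchy)
}
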