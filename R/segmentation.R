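#' Segmentation parameters
#'
#' Controls the conversion of one intensity channel into labelled objects.
#' The default threshold is Otsu's method per channel, which is robust to
#' overall intensity scaling; a fixed threshold is available for
#' reproducibility studies. `min_area_px` defaults to 30 px (about 120 um^2
#' at 2 um/px, below any plausible cell) to suppress noise specks - a
#' scale-dependent choice that should be revisited at other magnifications.
#'
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity cutoff, used only when
#'   `threshold_method = "fixed"`; must lie within the channel bit depth.
#' @param min_area_px components smaller than this are removed (>= 1).
#' @param fill_holes fill enclosed background holes inside components.
#' @param split_touching split touching blobs by a distance-transform
#'   watershed seeded at local maxima.
#' @param watershed_min_distance_px neighbourhood radius (px) for the
#'   watershed's local-maximum detection; roughly the minimum seed spacing.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area_px = 30L, fill_holes = TRUE,
                                split_touching = FALSE,
                                watershed_min_distance_px = 9L) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold is required when threshold_method = 'fixed'",
         call. = FALSE)
  if (min_area_px < 1) stop("min_area_px must be >= 1", call. = FALSE)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area_px = as.integer(min_area_px),
                 fill_holes = isTRUE(fill_holes),
                 split_touching = isTRUE(split_touching),
                 watershed_min_distance_px = as.integer(watershed_min_distance_px)),
            class = "segmentation_params")
}

#' Segment one intensity channel into labelled objects
#'
#' Thresholds the channel, optionally fills holes and splits touching blobs,
#' removes components below `min_area_px`, and returns an integer label
#' matrix with background 0 and contiguous labels `1..n`. An all-constant
#' channel yields an empty mask (0 labels), not an error.
#'
#' @param channel 2-D integer intensity matrix.
#' @param params a [segmentation_params()].
#' @param bit_depth intensity bit depth (8 or 16).
#' @return Integer label matrix.
#' @export
segment_channel <- function(channel, params = segmentation_params(),
                            bit_depth = 8L) {
  if (length(dim(channel)) != 2L)
    stop("channel must be a 2-D matrix", call. = FALSE)
  maxv <- 2^bit_depth - 1
  if (params$threshold_method == "fixed" &&
      (params$fixed_threshold < 0 || params$fixed_threshold > maxv))
    stop("fixed_threshold outside the bit depth", call. = FALSE)
  if (max(channel) == min(channel))
    return(matrix(0L, nrow(channel), ncol(channel)))
  thr <- if (params$threshold_method == "otsu")
    EBImage::otsu(EBImage::Image(channel / maxv), range = c(0, 1)) * maxv
  else params$fixed_threshold
  binary <- (channel > thr) * 1
  if (params$fill_holes)
    binary <- as_label_matrix(EBImage::fillHull(binary)) > 0
  labels <- if (params$split_touching) {
    dmap <- EBImage::distmap(binary * 1)
    as_label_matrix(EBImage::watershed(dmap, tolerance = 1,
                                       ext = params$watershed_min_distance_px))
  } else {
    as_label_matrix(EBImage::bwlabel(binary * 1))
  }
  relabel_filtered(labels, params$min_area_px)
}

# drop components under min_area and relabel contiguously (order preserved)
relabel_filtered <- function(labels, min_area) {
  if (max(labels) == 0L) return(labels)
  sizes <- tabulate(labels, nbins = max(labels))
  keep <- which(sizes >= min_area)
  lut <- integer(max(labels) + 1L)            # lut[old_label + 1] -> new label
  lut[keep + 1L] <- seq_along(keep)
  matrix(lut[labels + 1L], nrow(labels), ncol(labels))
}

# Vossepoel-Smeulders chain-code step weights: near-unbiased digital
# perimeter (axial steps 0.980, diagonal steps 1.406)
PERIM_W_AXIAL <- 0.980
PERIM_W_DIAG <- 1.406

# perimeter per label from the traced object contour; a single-pixel object
# (no steps) gets the unit-square perimeter 4
contour_perimeters <- function(mask) {
  n <- max(mask)
  if (n == 0L) return(numeric(0))
  oc <- EBImage::ocontour(EBImage::Image(mask))
  if (is.null(names(oc))) names(oc) <- as.character(seq_along(oc))
  vapply(seq_len(n), function(i) {
    pts <- oc[[as.character(i)]]
    if (is.null(pts) || nrow(pts) < 2L) return(4)
    d <- rbind(diff(pts), pts[1L, ] - pts[nrow(pts), ])  # closed contour
    diag_step <- abs(d[, 1L]) == 1 & abs(d[, 2L]) == 1
    sum(ifelse(diag_step, PERIM_W_DIAG, PERIM_W_AXIAL))
  }, numeric(1))
}

#' Extract per-object measurements from a label mask
#'
#' One `cell_object` per label, ordered by label: pixel set (linear indices),
#' area, centroid (0-based row/col of pixel centres), chain-code perimeter,
#' half-open bounding box, and a flag for objects touching the image border
#' (border-touching hosts cannot demonstrate complete engulfment and are
#' excluded from CIC calls downstream).
#'
#' @param mask integer label matrix.
#' @param class object class, `"viable"`, `"dead"` or `"nucleus"` (viable
#'   objects come from the green channel, dead from the red).
#' @return A list of `cell_object` lists with fields `id`, `class`,
#'   `pixel_count`, `centroid` (row, col), `perimeter_px`, `bbox`
#'   (r0, r1, c0, c1, half-open, 0-based), `border_touching`, `nucleus_id`
#'   and `pixels`; class `cic_objects`.
#' @export
extract_objects <- function(mask, class = c("viable", "dead", "nucleus")) {
  class <- match.arg(class)
  dm <- dim(mask)
  n <- max(mask)
  perims <- contour_perimeters(mask)
  idx <- which(mask > 0)
  objs <- vector("list", n)
  if (n > 0L) {
    by_label <- split(idx, mask[idx])
    for (lab in seq_len(n)) {
      px <- by_label[[as.character(lab)]]
      if (is.null(px)) next   # non-contiguous labels tolerated
      rc <- idx_to_rc(px, dm)
      objs[[lab]] <- structure(list(
        id = lab, class = class, pixel_count = length(px),
        centroid = c(row = mean(rc[, 1L]) - 1, col = mean(rc[, 2L]) - 1),
        perimeter_px = perims[lab],
        bbox = c(r0 = min(rc[, 1L]) - 1L, r1 = max(rc[, 1L]),
                 c0 = min(rc[, 2L]) - 1L, c1 = max(rc[, 2L])),
        border_touching = any(rc[, 1L] %in% c(1L, dm[1L]) |
                              rc[, 2L] %in% c(1L, dm[2L])),
        nucleus_id = NA_integer_,
        pixels = px, dim = dm), class = "cell_object")
    }
    objs <- objs[!vapply(objs, is.null, logical(1))]
  }
  structure(objs, class = "cic_objects")
}

#' @export
print.cic_objects <- function(x, ...) {
  cat(sprintf("%d %s object(s)\n", length(x),
              if (length(x)) x[[1L]]$class else ""))
  invisible(x)
}

#' Tabulate object measurements
#'
#' @param objects a `cic_objects` list from [extract_objects()].
#' @return A data frame, one row per object (pixel sets omitted).
#' @export
objects_table <- function(objects) {
  if (!length(objects))
    return(data.frame(id = integer(0), class = character(0),
                      pixel_count = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), perimeter_px = numeric(0),
                      border_touching = logical(0), nucleus_id = integer(0)))
  do.call(rbind, lapply(objects, function(o) data.frame(
    id = o$id, class = o$class, pixel_count = o$pixel_count,
    centroid_row = o$centroid[["row"]], centroid_col = o$centroid[["col"]],
    perimeter_px = o$perimeter_px, border_touching = o$border_touching,
    nucleus_id = o$nucleus_id)))
}

#' Link viable cells to their nuclei
#'
#' Each nucleus is assigned to the viable cell whose pixel set contains the
#' nucleus centroid; if several candidate cells contain it (possible only
#' for overlapping object sets), the largest pixel overlap wins, then the
#' lowest cell label. Nuclei whose centroid lies in no cell stay unassigned
#' and are reported in the `unassigned_nuclei` attribute; cells without a
#' nucleus keep `nucleus_id = NA` and are reported in `cells_without_nucleus`.
#'
#' @param viable a `cic_objects` list of viable cells.
#' @param nuclei a `cic_objects` list from the DAPI channel.
#' @return The viable list with `nucleus_id` filled in, plus attributes
#'   `unassigned_nuclei` and `cells_without_nucleus` (integer id vectors).
#' @export
assign_nuclei <- function(viable, nuclei) {
  claimed <- list()   # cell id -> (nucleus id, overlap)
  unassigned <- integer(0)
  for (nu in nuclei) {
    ctr_px <- rc_to_idx(round(nu$centroid[["row"]]) + 1L,
                        round(nu$centroid[["col"]]) + 1L, nu$dim)
    cand <- Filter(function(v) ctr_px %in% v$pixels, viable)
    if (!length(cand)) { unassigned <- c(unassigned, nu$id); next }
    ov <- vapply(cand, function(v) length(intersect(nu$pixels, v$pixels)),
                 numeric(1))
    ids <- vapply(cand, function(v) v$id, numeric(1))
    best <- ids[order(-ov, ids)][1L]
    key <- as.character(best)
    prev <- claimed[[key]]
    my_ov <- ov[ids == best]
    # a cell already holding a nucleus keeps the larger-overlap one
    if (is.null(prev) || my_ov > prev[2L] ||
        (my_ov == prev[2L] && nu$id < prev[1L])) {
      if (!is.null(prev)) unassigned <- c(unassigned, prev[1L])
      claimed[[key]] <- c(nu$id, my_ov)
    } else unassigned <- c(unassigned, nu$id)
  }
  for (k in seq_along(viable)) {
    hit <- claimed[[as.character(viable[[k]]$id)]]
    viable[[k]]$nucleus_id <- if (is.null(hit)) NA_integer_
                              else as.integer(hit[1L])
  }
  no_nuc <- vapply(Filter(function(v) is.na(v$nucleus_id), viable),
                   function(v) v$id, numeric(1))
  attr(viable, "unassigned_nuclei") <- sort(unassigned)
  attr(viable, "cells_without_nucleus") <- as.integer(no_nuc)
  viable
}
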