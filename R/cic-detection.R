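#' Cell-in-cell detection parameters
#'
#' Operationalizes the morphological criteria for a cell-in-cell (CIC)
#' structure: a dead, red-stained cell swallowed by a viable, green-stained
#' cell, with the host nucleus deformed into a crescent by the engulfed
#' cell. "Swallowed" is scored as a pixelwise containment fraction with
#' default cutoff 0.90 rather than strict 1.0, because segmentation boundary
#' jitter would fail true positives at 1.0. The engulfed cell must be
#' near-circular (it has nothing to adhere to inside the host), and the host
#' nucleus must show a solidity deficit (the crescent imprint). Setting
#' `require_crescent = FALSE` reproduces a pure overlap-based count.
#'
#' @param containment_min minimum fraction of engulfed-cell pixels inside
#'   the host, default 0.90.
#' @param circularity_min minimum engulfed-cell circularity, default 0.70.
#' @param crescent_min minimum host-nucleus solidity deficit, default 0.10.
#' @param require_crescent require the nuclear imprint criterion.
#' @param exclude_border_hosts reject hosts touching the image border
#'   (partial hosts cannot demonstrate complete engulfment).
#' @return An object of class `cic_params`.
#' @export
cic_params <- function(containment_min = 0.90, circularity_min = 0.70,
                       crescent_min = 0.10, require_crescent = TRUE,
                       exclude_border_hosts = TRUE) {
  for (v in c(containment_min, circularity_min, crescent_min))
    if (v < 0 || v > 1) stop("thresholds must lie in [0, 1]", call. = FALSE)
  structure(list(containment_min = containment_min,
                 circularity_min = circularity_min,
                 crescent_min = crescent_min,
                 require_crescent = isTRUE(require_crescent),
                 exclude_border_hosts = isTRUE(exclude_border_hosts)),
            class = "cic_params")
}

#' Containment fraction of one object inside another
#'
#' The fraction of the dead cell's pixels that also belong to the host
#' (intersection size over dead-cell size). 1 means fully engulfed, 0
#' disjoint.
#'
#' @param dead,host `cell_object`s from the same image frame.
#' @return Fraction in \[0, 1\].
#' @export
containment_fraction <- function(dead, host) {
  if (!length(dead$pixels)) stop("dead object has no pixels", call. = FALSE)
  if (!identical(dead$dim, host$dim))
    stop("objects come from different image frames", call. = FALSE)
  length(intersect(dead$pixels, host$pixels)) / length(dead$pixels)
}

#' Circularity of an object
#'
#' `4 * pi * area / perimeter^2` with the package's chain-code perimeter
#' estimator (the same one [extract_objects()] stores), capped at 1. An
#' ideal disk scores 1; elongated objects score near 0.
#'
#' @param obj a `cell_object`.
#' @return Dimensionless circularity in \[0, 1\].
#' @export
circularity <- function(obj) {
  if (is.null(obj$perimeter_px) || obj$perimeter_px <= 0)
    stop("object has zero perimeter", call. = FALSE)
  min(1, 4 * pi * obj$pixel_count / obj$perimeter_px^2)
}

# rasterized convex hull of a pixel set: indices of all pixels whose centres
# lie in the convex hull of the object's pixel centres
hull_pixels <- function(pixels, dm) {
  rc <- idx_to_rc(pixels, dm)
  h <- grDevices::chull(rc[, 1L], rc[, 2L])
  hr <- rc[h, 1L]; hc <- rc[h, 2L]
  if (length(h) < 3L) return(pixels)   # collinear set: hull adds nothing
  rows <- min(rc[, 1L]):max(rc[, 1L]); cols <- min(rc[, 2L]):max(rc[, 2L])
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  # a point is inside the convex polygon iff it sits on the inner side of
  # every directed edge; the polygon orientation fixes which side that is
  nv <- length(h)
  jj <- c(seq_len(nv)[-1L], 1L)
  signed2a <- sum(hr * hc[jj] - hr[jj] * hc)
  s <- if (signed2a >= 0) 1 else -1
  inside <- matrix(TRUE, length(rows), length(cols))
  for (i in seq_len(nv)) {
    j <- jj[i]
    cross <- (hr[j] - hr[i]) * (cc - hc[i]) - (hc[j] - hc[i]) * (rr - hr[i])
    inside <- inside & (s * cross >= -1e-9)
  }
  rc_to_idx(rr[inside], cc[inside], dm)
}

#' Nuclear crescent score (solidity deficit)
#'
#' `1 - area / convex_hull_area` of the nucleus pixel set. A convex (intact)
#' nucleus scores 0; the score grows with the depth of the semicircular
#' imprint left by an engulfed cell pressing into the host nucleus.
#'
#' @param nucleus_pixels linear pixel indices of the host's nucleus.
#' @param dm image dimension `c(rows, cols)`.
#' @return Fraction in \[0, 1\].
#' @export
crescent_score <- function(nucleus_pixels, dm) {
  if (!length(nucleus_pixels)) stop("empty nucleus pixel set", call. = FALSE)
  hull <- hull_pixels(nucleus_pixels, dm)
  1 - length(nucleus_pixels) / length(hull)
}

# is the nuclear indentation adjacent to the engulfed cell? The centroid of
# the hull-minus-nucleus defect component nearest the engulfed cell must lie
# within 2x the engulfed cell's equivalent radius of its centroid -- this
# stops unrelated nuclear lobulation from passing as an imprint.
crescent_adjacent_to <- function(nucleus_pixels, dm, engulfed) {
  defect <- setdiff(hull_pixels(nucleus_pixels, dm), nucleus_pixels)
  if (!length(defect)) return(FALSE)
  dmask <- matrix(0L, dm[1L], dm[2L]); dmask[defect] <- 1L
  comps <- as_label_matrix(EBImage::bwlabel(dmask))
  ec <- engulfed$centroid + 1  # back to 1-based
  r_eq <- sqrt(engulfed$pixel_count / pi)
  dists <- vapply(seq_len(max(comps)), function(lab) {
    rc <- idx_to_rc(which(comps == lab), dm)
    sqrt((mean(rc[, 1L]) - ec[["row"]])^2 + (mean(rc[, 2L]) - ec[["col"]])^2)
  }, numeric(1))
  min(dists) <= 2 * r_eq
}

#' Detect cell-in-cell events
#'
#' Scores every (dead, viable) object pair with nonzero pixel overlap on
#' three criteria - containment of the dead cell in the host, circularity of
#' the dead cell, and the crescent imprint on the host nucleus (including
#' its adjacency to the engulfed cell) - and accepts pairs meeting all
#' thresholds. Each dead cell is assigned to at most one host: highest
#' containment wins, ties broken by larger host, then lower host label.
#' Rejected candidates are retained with `accepted = FALSE` for audit, the
#' computational analogue of manual verification of automatic calls.
#'
#' @param viable `cic_objects` of viable cells, after [assign_nuclei()].
#' @param dead `cic_objects` of dead cells.
#' @param nuclei `cic_objects` from the DAPI channel (provides the nucleus
#'   pixel sets referenced by `nucleus_id`).
#' @param params a [cic_params()].
#' @return A data frame of candidate events: `host_id`, `engulfed_id`,
#'   `containment_fraction`, `circularity`, `crescent_score`, `accepted`.
#' @export
detect_cic <- function(viable, dead, nuclei, params = cic_params()) {
  nuc_by_id <- list()
  for (nu in nuclei) nuc_by_id[[as.character(nu$id)]] <- nu
  rows <- list()
  for (d in dead) {
    circ <- circularity(d)
    for (v in viable) {
      cf <- containment_fraction(d, v)
      if (cf <= 0) next
      cres <- NA_real_; cres_ok <- FALSE
      if (!is.na(v$nucleus_id)) {
        nu <- nuc_by_id[[as.character(v$nucleus_id)]]
        if (!is.null(nu)) {
          cres <- crescent_score(nu$pixels, nu$dim)
          cres_ok <- cres >= params$crescent_min &&
            crescent_adjacent_to(nu$pixels, nu$dim, d)
        }
      }
      if (!params$require_crescent) {
        if (is.na(cres))
          warning(sprintf("host %d has no assigned nucleus; crescent not scored",
                          v$id), call. = FALSE)
        cres_ok <- TRUE
      }
      ok <- cf >= params$containment_min &&
        circ >= params$circularity_min && cres_ok &&
        !(params$exclude_border_hosts && v$border_touching)
      rows[[length(rows) + 1L]] <- data.frame(
        host_id = v$id, engulfed_id = d$id, containment_fraction = cf,
        circularity = circ, crescent_score = cres, accepted = ok,
        host_pixels = v$pixel_count)
    }
  }
  if (!length(rows))
    return(data.frame(host_id = integer(0), engulfed_id = integer(0),
                      containment_fraction = numeric(0),
                      circularity = numeric(0), crescent_score = numeric(0),
                      accepted = logical(0)))
  ev <- do.call(rbind, rows)
  # single assignment: per dead cell keep the best accepted host only
  for (eid in unique(ev$engulfed_id[ev$accepted])) {
    k <- which(ev$engulfed_id == eid & ev$accepted)
    if (length(k) > 1L) {
      best <- k[order(-ev$containment_fraction[k], -ev$host_pixels[k],
                      ev$host_id[k])][1L]
      ev$accepted[setdiff(k, best)] <- FALSE
    }
  }
  ev$host_pixels <- NULL
  rownames(ev) <- NULL
  ev
}

#' Run the full fluorescence pipeline on one scene
#'
#' Segments the three channels, extracts objects, links nuclei, and detects
#' CIC events.
#'
#' @param image an [image_stack()] with channels `green`, `red`, `dapi`.
#' @param seg_params a [segmentation_params()].
#' @param params a [cic_params()].
#' @return A list with `viable`, `dead`, `nuclei` object lists, `events`
#'   data frame, and label masks per channel.
#' @export
analyze_scene <- function(image, seg_params = segmentation_params(),
                          params = cic_params()) {
  need <- c("green", "red", "dapi")
  if (!all(need %in% names(image$channels)))
    stop("fluorescence mode needs channels green, red and dapi; found: ",
         paste(names(image$channels), collapse = ", "), call. = FALSE)
  masks <- lapply(image$channels[need], segment_channel, params = seg_params,
                  bit_depth = image$bit_depth)
  viable <- extract_objects(masks$green, "viable")
  dead <- extract_objects(masks$red, "dead")
  nuclei <- extract_objects(masks$dapi, "nucleus")
  viable <- assign_nuclei(viable, nuclei)
  events <- detect_cic(viable, dead, nuclei, params)
  list(viable = viable, dead = dead, nuclei = nuclei, events = events,
       masks = masks)
}

#' Score detected events against planted ground truth
#'
#' Maps each planted pair to segmentation labels by looking up which viable
#' and dead label contains the planted centre, then counts accepted events
#' that hit a planted pair (true positives), accepted events that hit none
#' (false positives), and planted pairs with no accepted event (false
#' negatives).
#'
#' @param analysis result of [analyze_scene()].
#' @param truth the `truth` element of [generate_coincubation_scene()].
#' @return A list: `tp`, `fp`, `fn`, `precision`, `recall` (both 1 when
#'   nothing is planted and nothing is called).
#' @export
evaluate_recovery <- function(analysis, truth) {
  dm <- dim(analysis$masks$green)
  label_at <- function(mask, row0, col0)
    mask[rc_to_idx(round(row0) + 1L, round(col0) + 1L, dm)]
  obj <- truth$objects
  truth_keys <- character(0)
  if (nrow(truth$pairs)) {
    truth_keys <- vapply(seq_len(nrow(truth$pairs)), function(k) {
      h <- obj[obj$object_id == truth$pairs$host_id[k], ]
      e <- obj[obj$object_id == truth$pairs$engulfed_id[k], ]
      paste(label_at(analysis$masks$green, h$center_row, h$center_col),
            label_at(analysis$masks$red, e$center_row, e$center_col))
    }, character(1))
  }
  ev <- analysis$events[analysis$events$accepted, , drop = FALSE]
  ev_keys <- paste(ev$host_id, ev$engulfed_id)
  tp <- sum(ev_keys %in% truth_keys)
  fp <- sum(!ev_keys %in% truth_keys)
  fn <- sum(!truth_keys %in% ev_keys)
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp == 0) 1 else tp / (tp + fp),
       recall = if (tp + fn == 0) 1 else tp / (tp + fn))
}
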