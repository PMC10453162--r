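#' Specification of a synthetic co-incubation scene
#'
#' Describes a two-colour co-incubation field: viable (CellTracker-green)
#' cells, dead (CyTRAK-red) cells, and cell-in-cell (CIC) pairs in which a
#' circular dead cell sits fully inside a viable host whose DAPI nucleus
#' carries a semicircular imprint from the engulfed cell.
#'
#' Radii are in pixels at `pixel_size_um` micrometres per pixel.
#' `crescent_depth` is the fraction of the host-nucleus radius by which the
#' engulfed cell indents it (0 = untouched disk, 1 = bite through the
#' centre). Defaults emulate melanoma co-incubations imaged at high
#' magnification (0.5 um/px): host cells 21-27 um across, nuclei 12-16 um,
#' engulfed (rounded-up dead) cells 6-8 um, and a pronounced imprint
#' (`crescent_depth = 0.75`, giving a nuclear solidity deficit of about
#' 0.13-0.19 - safely above the 0.10 detection criterion so planted truth is
#' unambiguous).
#'
#' @param width_px,height_px frame size in pixels.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param n_viable_free,n_dead_free,n_cic object counts (>= 0).
#' @param cell_radius_px,nucleus_radius_px,engulfed_radius_px length-2
#'   `(min, max)` ranges in pixels; the engulfed maximum must be below the
#'   cell minimum so an engulfed cell always fits inside its host.
#' @param crescent_depth fraction in \[0, 1\] of the nucleus radius.
#' @param background_level,noise_sigma background intensity and additive
#'   Gaussian noise SD, in 8-bit grey levels.
#' @param seed integer RNG seed; identical spec + seed give identical output.
#' @return An object of class `scene_spec`.
#' @seealso [generate_coincubation_scene()]
#' @export
scene_spec <- function(width_px = 256L, height_px = 256L, pixel_size_um = 0.5,
                       n_viable_free = 4L, n_dead_free = 3L, n_cic = 2L,
                       cell_radius_px = c(21, 27),
                       nucleus_radius_px = c(12, 16),
                       engulfed_radius_px = c(6, 8),
                       crescent_depth = 0.75,
                       background_level = 10, noise_sigma = 8,
                       seed = 1L) {
  spec <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
               pixel_size_um = pixel_size_um,
               n_viable_free = as.integer(n_viable_free),
               n_dead_free = as.integer(n_dead_free), n_cic = as.integer(n_cic),
               cell_radius_px = as.numeric(cell_radius_px),
               nucleus_radius_px = as.numeric(nucleus_radius_px),
               engulfed_radius_px = as.numeric(engulfed_radius_px),
               crescent_depth = crescent_depth,
               background_level = background_level, noise_sigma = noise_sigma,
               seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot_scalar_number(spec$pixel_size_um, "pixel_size_um", min = 1e-9)
  for (f in c("n_viable_free", "n_dead_free", "n_cic"))
    stopifnot_scalar_number(spec[[f]], f, min = 0)
  for (f in c("cell_radius_px", "nucleus_radius_px", "engulfed_radius_px")) {
    r <- spec[[f]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1L] <= 0 || r[2L] < r[1L])
      stop(sprintf("'%s' must be an increasing positive (min, max) pair", f),
           call. = FALSE)
  }
  if (max(spec$engulfed_radius_px) >= min(spec$cell_radius_px))
    stop("engulfed_radius_px max must be below cell_radius_px min ",
         "(an engulfed cell must fit inside its host)", call. = FALSE)
  if (spec$crescent_depth < 0 || spec$crescent_depth > 1)
    stop("crescent_depth must lie in [0, 1]", call. = FALSE)
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  invisible(spec)
}

# foreground intensities (8-bit) for the three stains
SCENE_LEVELS <- c(green = 180, red = 200, dapi = 220)
PLACEMENT_MAX_ATTEMPTS <- 10000L
PLACEMENT_MARGIN <- 3   # minimum gap between object boundaries, px

# rejection-sample a center for a disk of radius `rad` that keeps 2 px off
# the border and PLACEMENT_MARGIN away from already placed disks
place_disk <- function(rad, placed, dm) {
  for (i in seq_len(PLACEMENT_MAX_ATTEMPTS)) {
    cr <- stats::runif(1, rad + 2, dm[1L] - rad - 2)
    cc <- stats::runif(1, rad + 2, dm[2L] - rad - 2)
    ok <- TRUE
    if (nrow(placed) > 0) {
      d2 <- (placed[, 1L] - cr)^2 + (placed[, 2L] - cc)^2
      ok <- all(d2 > (placed[, 3L] + rad + PLACEMENT_MARGIN)^2)
    }
    if (ok) return(c(cr, cc))
  }
  stop(sprintf(paste0("could not place an object of radius %.1f px after %d ",
                      "attempts: the frame is too crowded for the requested counts"),
       rad, PLACEMENT_MAX_ATTEMPTS), call. = FALSE)
}

#' Generate a synthetic co-incubation scene with planted ground truth
#'
#' Renders a three-channel 8-bit image stack (`green` viable cells, `red`
#' dead cells, `dapi` nuclei) containing free viable cells, free dead cells,
#' and `n_cic` planted CIC pairs. In each pair the dead cell is rendered as a
#' disk geometrically contained in the host disk, and the host nucleus is a
#' disk carved by the engulfed disk so that the radial bite depth equals
#' `crescent_depth * nucleus_radius` - the semicircular imprint that marks a
#' genuine engulfment. Objects never overlap except planted pairs. Additive
#' Gaussian noise (`noise_sigma`) is clipped to 8-bit range.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{image}{an [image_stack()] with channels `green`, `red`, `dapi`.}
#'     \item{truth}{a list: `objects`, a data frame with `object_id`, `class`
#'       (`viable_free`, `dead_free`, `cic_host`, `cic_engulfed`),
#'       `center_row`, `center_col` (0-based pixel coordinates) and
#'       `radius_px`; and `pairs`, a data frame with `host_id`,
#'       `engulfed_id`.}
#'   }
#' @export
generate_coincubation_scene <- function(spec) {
  validate_scene_spec(spec)
  dm <- c(spec$height_px, spec$width_px)
  with_seed(spec$seed, {
    placed <- matrix(numeric(0), 0, 3)  # (row, col, radius) of outer disks
    objects <- list(); pairs <- list(); nuclei <- list()
    next_id <- 1L
    add_obj <- function(class, cr, cc, rad) {
      objects[[length(objects) + 1L]] <<- data.frame(
        object_id = next_id, class = class,
        center_row = cr - 1, center_col = cc - 1, radius_px = rad)
      next_id <<- next_id + 1L
      next_id - 1L
    }

    # hosts first (largest footprint: host disk + planted contents)
    for (i in seq_len(spec$n_cic)) {
      R <- stats::runif(1, spec$cell_radius_px[1L], spec$cell_radius_px[2L])
      ctr <- place_disk(R, placed, dm)
      placed <- rbind(placed, c(ctr, R))
      r_eng <- stats::runif(1, spec$engulfed_radius_px[1L], spec$engulfed_radius_px[2L])
      r_nuc <- stats::runif(1, spec$nucleus_radius_px[1L], spec$nucleus_radius_px[2L])
      dep <- spec$crescent_depth * r_nuc
      span <- r_nuc + r_eng - dep   # center distance nucleus <-> engulfed
      a_hi <- R - 2 - r_eng         # engulfed offset limit from host center
      b_hi <- R - 2 - r_nuc         # nucleus offset limit
      lo <- max(0, span - b_hi); hi <- min(a_hi, span)
      if (lo > hi)
        stop("host cell too small to hold both the engulfed cell and its ",
             "indented nucleus; widen cell_radius_px", call. = FALSE)
      a <- stats::runif(1, lo, hi); b <- span - a
      th <- stats::runif(1, 0, 2 * pi)
      eng_ctr <- ctr + a * c(cos(th), sin(th))
      nuc_ctr <- ctr - b * c(cos(th), sin(th))
      hid <- add_obj("cic_host", ctr[1L], ctr[2L], R)
      eid <- add_obj("cic_engulfed", eng_ctr[1L], eng_ctr[2L], r_eng)
      pairs[[length(pairs) + 1L]] <- data.frame(host_id = hid, engulfed_id = eid)
      nuclei[[length(nuclei) + 1L]] <- list(
        ctr = nuc_ctr, rad = r_nuc, bite_ctr = eng_ctr, bite_rad = r_eng)
    }

    for (i in seq_len(spec$n_viable_free)) {
      R <- stats::runif(1, spec$cell_radius_px[1L], spec$cell_radius_px[2L])
      ctr <- place_disk(R, placed, dm)
      placed <- rbind(placed, c(ctr, R))
      r_nuc <- stats::runif(1, spec$nucleus_radius_px[1L], spec$nucleus_radius_px[2L])
      add_obj("viable_free", ctr[1L], ctr[2L], R)
      # nucleus centered in the cell with a small jitter
      jit <- stats::runif(1, 0, max(0, R - 2 - r_nuc))
      th <- stats::runif(1, 0, 2 * pi)
      nuclei[[length(nuclei) + 1L]] <- list(
        ctr = ctr + jit * c(cos(th), sin(th)), rad = r_nuc,
        bite_ctr = NULL, bite_rad = NULL)
    }

    for (i in seq_len(spec$n_dead_free)) {
      r <- stats::runif(1, spec$engulfed_radius_px[1L], spec$engulfed_radius_px[2L])
      ctr <- place_disk(r, placed, dm)
      placed <- rbind(placed, c(ctr, r))
      add_obj("dead_free", ctr[1L], ctr[2L], r)
    }

    objects <- if (length(objects)) do.call(rbind, objects) else
      data.frame(object_id = integer(0), class = character(0),
                 center_row = numeric(0), center_col = numeric(0),
                 radius_px = numeric(0))
    pairs <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(host_id = integer(0), engulfed_id = integer(0))

    # render channels
    green <- matrix(spec$background_level, dm[1L], dm[2L])
    red <- green; dapi <- green
    for (k in seq_len(nrow(objects))) {
      o <- objects[k, ]
      px <- disk_pixels(o$center_row + 1, o$center_col + 1, o$radius_px, dm)
      if (o$class %in% c("viable_free", "cic_host")) green[px] <- SCENE_LEVELS["green"]
      else red[px] <- SCENE_LEVELS["red"]
    }
    for (nu in nuclei) {
      px <- disk_pixels(nu$ctr[1L], nu$ctr[2L], nu$rad, dm)
      if (!is.null(nu$bite_ctr))
        px <- setdiff(px, disk_pixels(nu$bite_ctr[1L], nu$bite_ctr[2L],
                                      nu$bite_rad, dm))
      dapi[px] <- SCENE_LEVELS["dapi"]
    }
    if (spec$noise_sigma > 0) {
      n <- length(green)
      green <- green + stats::rnorm(n, 0, spec$noise_sigma)
      red <- red + stats::rnorm(n, 0, spec$noise_sigma)
      dapi <- dapi + stats::rnorm(n, 0, spec$noise_sigma)
    }
    clip8 <- function(m) matrix(as.integer(pmin(255, pmax(0, round(m)))),
                                nrow(m), ncol(m))
    img <- image_stack(list(green = clip8(green), red = clip8(red),
                            dapi = clip8(dapi)),
                       pixel_size_um = spec$pixel_size_um, bit_depth = 8L)
    list(image = img, truth = list(objects = objects, pairs = pairs))
  })
}

#' Write scene ground truth to JSON and a flat CSV
#'
#' @param truth the `truth` element returned by
#'   [generate_coincubation_scene()].
#' @param json_path,csv_path output file paths; either may be `NULL` to skip.
#' @return Invisibly, the truth object.
#' @export
write_ground_truth <- function(truth, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(truth, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(csv_path))
    utils::write.csv(truth$objects, csv_path, row.names = FALSE)
  invisible(truth)
}
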