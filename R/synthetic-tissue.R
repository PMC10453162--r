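#' Specification of a synthetic tissue-microarray core
#'
#' One immunostained core: a circular tissue spot (default 1 mm diameter, the
#' standard TMA spot size) carrying cells drawn as membrane rings whose
#' intensity encodes membranous E-cadherin, a planted number of cell-in-cell
#' figures (ring inside ring), and TNM stage labels.
#'
#' @param core_diameter_mm spot diameter in millimetres.
#' @param pixel_size_um micrometres per pixel.
#' @param n_cells number of cells rendered in the core.
#' @param n_cic number of planted CIC figures (must be <= `n_cells`).
#' @param ecad_level integer 0-3; membrane ring intensity increases strictly
#'   with the level (0 = no specific staining ... 3 = high).
#' @param t_stage,n_stage,m_stage stage labels; `"unknown"` if not recorded.
#' @param seed integer RNG seed.
#' @return An object of class `tissue_core_spec`.
#' @export
tissue_core_spec <- function(core_diameter_mm = 1.0, pixel_size_um = 2,
                             n_cells = 150L, n_cic = 0L, ecad_level = 1L,
                             t_stage = "unknown", n_stage = "unknown",
                             m_stage = "unknown", seed = 1L) {
  spec <- list(core_diameter_mm = core_diameter_mm,
               pixel_size_um = pixel_size_um,
               n_cells = as.integer(n_cells), n_cic = as.integer(n_cic),
               ecad_level = as.integer(ecad_level),
               t_stage = as.character(t_stage), n_stage = as.character(n_stage),
               m_stage = as.character(m_stage), seed = as.integer(seed))
  class(spec) <- "tissue_core_spec"
  validate_tissue_core_spec(spec)
  spec
}

validate_tissue_core_spec <- function(spec) {
  stopifnot_scalar_number(spec$core_diameter_mm, "core_diameter_mm", min = 1e-9)
  stopifnot_scalar_number(spec$pixel_size_um, "pixel_size_um", min = 1e-9)
  if (spec$n_cic > spec$n_cells)
    stop("n_cic must not exceed n_cells", call. = FALSE)
  if (spec$n_cic < 0 || spec$n_cells < 0)
    stop("counts must be >= 0", call. = FALSE)
  if (!spec$ecad_level %in% 0:3)
    stop("ecad_level must be one of 0, 1, 2, 3", call. = FALSE)
  invisible(spec)
}

# membrane ring amplitude above background per E-cadherin level 0..3;
# level 0 keeps a faint nonspecific rim so membranes remain visible
ECAD_LEVEL_AMPLITUDE <- c(8, 70, 140, 210)
TISSUE_BACKGROUND <- 15
TISSUE_NOISE_SIGMA <- 3

#' Nominal area of a circular tissue core
#'
#' @param diameter_mm core diameter in millimetres.
#' @return Area in mm^2 (`pi * d^2 / 4`; 0.7854 mm^2 for a 1-mm spot).
#' @export
core_area_mm2 <- function(diameter_mm) pi * diameter_mm^2 / 4

#' Generate a synthetic immunostained tissue core
#'
#' Renders a single-channel 8-bit image of a circular core. Cells are
#' membrane rings (annuli); the mean ring intensity increases strictly with
#' `ecad_level`. Exactly `n_cic` cells carry an inner ring - the
#' cell-in-cell figure. The returned truth record carries everything needed
#' for density and score computations without re-detecting.
#'
#' @param spec a [tissue_core_spec()].
#' @return A list with elements `image` (intensity matrix), `membrane_mask`
#'   (logical matrix of stained membrane pixels), and `truth` (list with
#'   `n_cells`, `n_cic`, `area_mm2`, `ecad_level`, stage labels and the
#'   geometry used).
#' @export
generate_tissue_core <- function(spec) {
  validate_tissue_core_spec(spec)
  d_px <- spec$core_diameter_mm * 1000 / spec$pixel_size_um
  side <- as.integer(ceiling(d_px)) + 20L
  dm <- c(side, side)
  ctr <- (side + 1) / 2
  with_seed(spec$seed, {
    img <- matrix(TISSUE_BACKGROUND, side, side)
    mask <- matrix(FALSE, side, side)
    amp <- ECAD_LEVEL_AMPLITUDE[spec$ecad_level + 1L]
    placed <- matrix(numeric(0), 0, 3)
    core_r <- d_px / 2
    is_cic <- rep(FALSE, spec$n_cells)
    if (spec$n_cic > 0) is_cic[seq_len(spec$n_cic)] <- TRUE
    for (i in seq_len(spec$n_cells)) {
      rc <- stats::runif(1, 7, 10)      # outer membrane radius, px
      pos <- NULL
      for (att in seq_len(PLACEMENT_MAX_ATTEMPTS)) {
        th <- stats::runif(1, 0, 2 * pi)
        rho <- sqrt(stats::runif(1)) * (core_r - rc - 2)
        cand <- c(ctr + rho * cos(th), ctr + rho * sin(th))
        ok <- TRUE
        if (nrow(placed) > 0) {
          d2 <- (placed[, 1L] - cand[1L])^2 + (placed[, 2L] - cand[2L])^2
          ok <- all(d2 > (placed[, 3L] + rc + 2)^2)
        }
        if (ok) { pos <- cand; break }
      }
      if (is.null(pos))
        stop(sprintf(paste0("could not place cell %d of %d in the core after %d ",
                            "attempts: reduce n_cells or enlarge the core"),
             i, spec$n_cells, PLACEMENT_MAX_ATTEMPTS), call. = FALSE)
      placed <- rbind(placed, c(pos, rc))
      ring <- setdiff(disk_pixels(pos[1L], pos[2L], rc, dm),
                      disk_pixels(pos[1L], pos[2L], rc - 2, dm))
      img[ring] <- TISSUE_BACKGROUND + amp
      mask[ring] <- TRUE
      if (is_cic[i]) {   # inner ring: the engulfed-cell figure
        ri <- rc / 2.5
        inner <- setdiff(disk_pixels(pos[1L], pos[2L], ri, dm),
                         disk_pixels(pos[1L], pos[2L], ri - 1.5, dm))
        img[inner] <- TISSUE_BACKGROUND + amp
        mask[inner] <- TRUE
      }
    }
    if (TISSUE_NOISE_SIGMA > 0)
      img <- img + stats::rnorm(length(img), 0, TISSUE_NOISE_SIGMA)
    img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), side, side)
    list(image = img, membrane_mask = mask,
         truth = list(n_cells = spec$n_cells, n_cic = spec$n_cic,
                      area_mm2 = core_area_mm2(spec$core_diameter_mm),
                      ecad_level = spec$ecad_level,
                      t_stage = spec$t_stage, n_stage = spec$n_stage,
                      m_stage = spec$m_stage,
                      core_diameter_mm = spec$core_diameter_mm,
                      pixel_size_um = spec$pixel_size_um))
  })
}

#' Generate a cohort of tissue-core specifications with group-wise CIC density
#'
#' Per-core CIC counts are drawn Poisson with mean `density * core area`, the
#' simplest defensible null for counts of rare spatial events. The group
#' label is stored in the field named by `group_field` (default the nodal
#' stage, the grouping the density contrasts are usually reported over).
#'
#' @param n_cores number of cores per group.
#' @param density_by_group named numeric vector of mean CIC structures per
#'   mm^2, one entry per group; all densities >= 0.
#' @param seed integer RNG seed; core seeds are derived deterministically.
#' @param core_diameter_mm,pixel_size_um,n_cells passed to each core spec.
#' @param ecad_levels integer vector the per-core E-cadherin level is sampled
#'   from (uniformly); a single value fixes the level.
#' @param group_field which stage field carries the group label.
#' @return A list of [tissue_core_spec()] objects, one per core, with the
#'   group label attached.
#' @export
generate_cohort <- function(n_cores, density_by_group, seed = 1L,
                            core_diameter_mm = 1.0, pixel_size_um = 2,
                            n_cells = 150L, ecad_levels = 0:3,
                            group_field = c("n_stage", "t_stage", "m_stage")) {
  group_field <- match.arg(group_field)
  if (is.null(names(density_by_group)) || any(names(density_by_group) == ""))
    stop("density_by_group must be a named vector", call. = FALSE)
  if (any(density_by_group < 0)) stop("densities must be >= 0", call. = FALSE)
  area <- core_area_mm2(core_diameter_mm)
  with_seed(seed, {
    specs <- list()
    for (g in names(density_by_group)) {
      lam <- density_by_group[[g]] * area
      counts <- stats::rpois(n_cores, lam)
      levels_g <- if (length(ecad_levels) == 1L) rep(ecad_levels, n_cores)
                  else sample(ecad_levels, n_cores, replace = TRUE)
      core_seeds <- sample.int(.Machine$integer.max - 1L, n_cores)
      for (i in seq_len(n_cores)) {
        s <- tissue_core_spec(core_diameter_mm = core_diameter_mm,
                              pixel_size_um = pixel_size_um,
                              n_cells = max(n_cells, counts[i]),
                              n_cic = counts[i], ecad_level = levels_g[i],
                              seed = core_seeds[i])
        s[[group_field]] <- g
        specs[[length(specs) + 1L]] <- s
      }
    }
    specs
  })
}
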