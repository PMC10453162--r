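#' Multi-channel image container
#'
#' A named set of 2-D integer intensity matrices sharing one shape, plus the
#' physical pixel size and bit depth. Fluorescence mode uses channels
#' `green` (viable cells), `red` (dead cells) and `dapi` (nuclei); tissue
#' mode uses a single `ihc` channel.
#'
#' @param channels named list of integer matrices of identical dimension.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param bit_depth 8 or 16.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size_um, bit_depth = 8L) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop("channels must be a named list of matrices", call. = FALSE)
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop("all channels must share one shape", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  stopifnot_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-9)
  maxv <- 2^bit_depth - 1
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (any(ch < 0 | ch > maxv))
      stop(sprintf("channel '%s' has intensities outside the %d-bit range",
                   nm, bit_depth), call. = FALSE)
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  dm <- dim(x$channels[[1L]])
  cat(sprintf("image_stack: %d x %d px, %d-bit, %.3g um/px, channels: %s\n",
              dm[1L], dm[2L], x$bit_depth, x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write / read a multi-channel image stack as multi-page TIFF
#'
#' Pages are written in the order of `stack$channels`; channel identity is
#' not stored in the TIFF (tags are fragile across writers) but in the run
#' configuration's `channel_map`. The round trip is lossless for integer
#' data at the declared bit depth.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @return `write_image` returns the path invisibly.
#' @export
write_image <- function(stack, path) {
  maxv <- 2^stack$bit_depth - 1
  pages <- lapply(stack$channels, function(m) m / maxv)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = stack$bit_depth)
  invisible(path)
}

#' @rdname write_image
#' @param channel_map named integer vector mapping channel name to TIFF page,
#'   e.g. `c(green = 1, red = 2, dapi = 3)`; every page used must be named.
#' @param pixel_size_um micrometres per pixel of the stored image.
#' @export
read_image <- function(path, channel_map, pixel_size_um) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  if (is.data.frame(meta)) meta <- split(meta, seq_len(nrow(meta)))
  bit_depth <- as.integer(meta[[1L]]$bits.per.sample)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(names(channel_map)) || any(names(channel_map) == ""))
    stop("channel_map must be a named vector of page indices", call. = FALSE)
  bad <- channel_map[channel_map < 1 | channel_map > length(pages)]
  if (length(bad))
    stop(sprintf("channel_map requests page(s) %s but the file has %d page(s)",
                 paste(bad, collapse = ", "), length(pages)), call. = FALSE)
  chans <- lapply(channel_map, function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1L]   # greyscale stored with 1 sample
    storage.mode(m) <- "integer"
    m
  })
  names(chans) <- names(channel_map)
  image_stack(chans, pixel_size_um = pixel_size_um, bit_depth = bit_depth)
}

#' Write / read a labelled mask as 16-bit TIFF
#'
#' Background is 0; labels are preserved exactly. At most 65535 labels fit
#' the 16-bit container.
#'
#' @param mask integer matrix of labels (0 = background).
#' @param path TIFF file path.
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535L)
    stop("mask has more than 65535 labels; 16-bit TIFF cannot store it",
         call. = FALSE)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  storage.mode(m) <- "integer"
  m
}

RESULTS_COUNT_COLS <- c("n_viable", "n_dead", "n_cic", "n_cells")

#' Write / read a per-sample results table as CSV
#'
#' Rows are sorted by `sample_id`, floating-point fields are printed with 4
#' decimals and counts as integers, so two writes of the same table are
#' byte-identical (no timestamps in the payload).
#'
#' @param results a data frame with a `sample_id` column (e.g. built from
#'   [summarize_sample()] rows).
#' @param path CSV file path.
#' @export
write_results <- function(results, path) {
  if (!"sample_id" %in% names(results))
    stop("results must have a 'sample_id' column", call. = FALSE)
  res <- results[order(results$sample_id), , drop = FALSE]
  out <- res
  for (nm in names(out)) {
    if (nm %in% RESULTS_COUNT_COLS) out[[nm]] <- as.integer(out[[nm]])
    else if (is.numeric(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA, sprintf("%.4f", out[[nm]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the run-level configuration
#'
#' One YAML file holds the run's paths, `channel_map`, segmentation and
#' detection parameters, and seeds, so a run is reproducible from the config
#' alone.
#'
#' @param config a named list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
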