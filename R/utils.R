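## internal helpers shared across modules

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Coerce an EBImage result back to a plain integer matrix.
as_label_matrix <- function(x) {
  if (methods::is(x, "Image")) x <- EBImage::imageData(x)
  storage.mode(x) <- "integer"
  x
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    stop(sprintf("'%s' must be a single finite number >= %s", name, min), call. = FALSE)
  invisible(x)
}

# linear index <-> (row, col) for a matrix of dimension `dm`
idx_to_rc <- function(idx, dm) {
  cbind(row = ((idx - 1L) %% dm[1L]) + 1L,
        col = ((idx - 1L) %/% dm[1L]) + 1L)
}

rc_to_idx <- function(row, col, dm) {
  (col - 1L) * dm[1L] + row
}

# pixel indices of a filled disk at continuous center (cr, cc), radius rad,
# clipped to the matrix dimension; pixel centers sit at integer coordinates
disk_pixels <- function(cr, cc, rad, dm) {
  r0 <- max(1L, floor(cr - rad)); r1 <- min(dm[1L], ceiling(cr + rad))
  c0 <- max(1L, floor(cc - rad)); c1 <- min(dm[2L], ceiling(cc + rad))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  rr <- matrix(rows, length(rows), length(cols))
  cc2 <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  inside <- (rr - cr)^2 + (cc2 - cc)^2 <= rad^2
  rc_to_idx(rr[inside], cc2[inside], dm)
}
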