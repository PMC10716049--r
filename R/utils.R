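#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed` and restores
#' the caller's RNG state afterwards, so every generator in the package is a
#' pure function of its arguments.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Ground-truth record attached to synthetic data
#'
#' Every generator returns the parameters used to produce its output alongside
#' the data, so downstream estimators can be tested by parameter recovery.
#'
#' @param params named list of true parameter values.
#' @param seed the integer seed the generator was called with.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(params, seed) {
  stopifnot(is.list(params))
  structure(list(params = params, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth (seed ", x$seed, ")\n", sep = "")
  scal <- x$params[vapply(x$params, function(p)
    is.atomic(p) && length(p) == 1L, logical(1))]
  for (nm in names(scal)) cat("  ", nm, ": ", format(scal[[nm]]), "\n", sep = "")
  big <- setdiff(names(x$params), names(scal))
  if (length(big))
    cat("  [", paste(big, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Multi-dimensional image container
#'
#' Stores pixel data with axes (t, z, y, x, channel), the physical pixel size
#' in nanometres and the nominal bit depth. Matrices and 3-d arrays are
#' promoted to the full five axes.
#'
#' @param pixels numeric array: a `y x x` matrix, a `(y, x, channel)` array or
#'   a full `(t, z, y, x, channel)` array.
#' @param pixel_size physical pixel size in nm (> 0).
#' @param bit_depth 8 or 16.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(pixels, pixel_size, bit_depth = 16L) {
  if (is.matrix(pixels)) {
    dim(pixels) <- c(1L, 1L, nrow(pixels), ncol(pixels), 1L)
  } else if (length(dim(pixels)) == 3L) {
    d <- dim(pixels)
    dim(pixels) <- c(1L, 1L, d[1L], d[2L], d[3L])
  } else if (length(dim(pixels)) != 5L) {
    stop("'pixels' must have 2, 3 or 5 dimensions (t,z,y,x,channel)")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be a positive length in nm")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_stack: t=%d z=%d y=%d x=%d c=%d, %d-bit, %g nm px\n",
              d[1], d[2], d[3], d[4], d[5], x$bit_depth, x$pixel_size))
  invisible(x)
}

#' Extract one 2-d frame from an image stack
#'
#' @param stack an [image_stack].
#' @param t,z,channel indices (1-based).
#' @return a numeric matrix (y, x).
#' @export
stack_frame <- function(stack, t = 1L, z = 1L, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  stack$pixels[t, z, , , channel]
}

#' Rasterize a polygon to a logical pixel mask
#'
#' Uses the even-odd rule with pixel-center coordinates: pixel (row i, col j)
#' of the mask has center (x = j - 1, y = i - 1), y increasing downward.
#'
#' @param vertices data frame or matrix with columns `x`, `y` (polygon
#'   vertices, in pixel units, 0-based).
#' @param dim integer vector `c(ny, nx)`.
#' @return logical matrix of dimension `dim`.
#' @export
polygon_mask <- function(vertices, dim) {
  vertices <- as.data.frame(vertices)
  stopifnot(all(c("x", "y") %in% names(vertices)), length(dim) == 2L)
  ny <- dim[1L]; nx <- dim[2L]
  px <- rep(seq_len(nx) - 1, each = ny)
  py <- rep(seq_len(ny) - 1, times = nx)
  vx <- vertices$x; vy <- vertices$y
  n <- length(vx)
  crossings <- integer(ny * nx)
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    hit <- ((y1 <= py) != (y2 <= py))
    if (any(hit)) {
      xint <- x1 + (py[hit] - y1) * (x2 - x1) / (y2 - y1)
      crossings[hit] <- crossings[hit] + (px[hit] < xint)
    }
    j <- i
  }
  matrix(crossings %% 2L == 1L, ny, nx)
}

#' Coerce a region-of-interest argument to a logical mask
#'
#' Accepts a logical matrix of the right dimension or a polygon vertex table.
#' @keywords internal
as_roi_mask <- function(roi, dim) {
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == dim)) stop("ROI mask dimension does not match image")
    return(roi)
  }
  if (is.data.frame(roi) || (is.matrix(roi) && ncol(roi) == 2L)) {
    v <- as.data.frame(roi)
    if (is.null(names(v)) || !all(c("x", "y") %in% names(v)))
      names(v) <- c("x", "y")
    if (any(v$x < 0 | v$x > dim[2L] - 1 | v$y < 0 | v$y > dim[1L] - 1))
      stop("ROI polygon extends outside the image frame")
    return(polygon_mask(v, dim))
  }
  stop("ROI must be a logical mask or a polygon vertex table")
}

# population standard deviation (divisor n)
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
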