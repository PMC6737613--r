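#' Frame sequence container
#'
#' A `frame_sequence` is the universal in-memory representation of a
#' grayscale fluoroscopy clip: a 3-D double array indexed `(t, row, col)`
#' holding pixel values in arbitrary units (a.u.), typically normalized to
#' `[0, 1]` from the detector's integer scale. All filters, estimators and
#' phantom generators in this package consume and return this class.
#'
#' @param frames A numeric 3-D array with dimensions `(n_frames, height,
#'   width)`, or a matrix (interpreted as a single frame). All values must
#'   be finite.
#' @param bit_depth_hint Optional integer recording the bit depth of the
#'   source digitization (e.g. `16L` for a 16-bit detector). Purely
#'   informational.
#' @param metadata A named list of free-form metadata (seeds, provenance,
#'   clamp counters). Carried along by the operations that transform a
#'   sequence.
#'
#' @return An object of class `frame_sequence` with elements `frames`,
#'   `n_frames`, `height`, `width`, `bit_depth_hint` and `metadata`.
#' @examples
#' seq <- frame_sequence(array(runif(2 * 4 * 5), dim = c(2, 4, 5)))
#' seq$n_frames
#' @export
frame_sequence <- function(frames, bit_depth_hint = NULL, metadata = list()) {
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(1L, nrow(frames), ncol(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a (t, row, col) 3-D array or a single-frame matrix")
  }
  if (!is.numeric(frames)) stop("`frames` must be numeric")
  storage.mode(frames) <- "double"
  if (anyNA(frames) || !all(is.finite(frames))) {
    stop("all pixel values must be finite")
  }
  d <- dim(frames)
  if (any(d < 1L)) stop("`frames` must have positive extent in every dimension")
  if (!is.null(bit_depth_hint)) bit_depth_hint <- as.integer(bit_depth_hint)
  structure(
    list(
      frames = frames,
      n_frames = d[[1L]],
      height = d[[2L]],
      width = d[[3L]],
      bit_depth_hint = bit_depth_hint,
      metadata = metadata
    ),
    class = "frame_sequence"
  )
}

#' Test for a frame sequence
#' @param x Object to test.
#' @return `TRUE` if `x` is a `frame_sequence`.
#' @export
is_frame_sequence <- function(x) inherits(x, "frame_sequence")

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf(
    "<frame_sequence> %d frame(s) of %d x %d px, values in [%.4g, %.4g]\n",
    x$n_frames, x$height, x$width, min(x$frames), max(x$frames)
  ))
  if (!is.null(x$bit_depth_hint)) {
    cat(sprintf("  source bit depth: %d\n", x$bit_depth_hint))
  }
  invisible(x)
}

#' @export
as.array.frame_sequence <- function(x, ...) x$frames

# Extract a single frame as a plain matrix (1-based frame index).
#' Extract one frame
#' @param seq A `frame_sequence`.
#' @param t Frame index, 1-based.
#' @return A `height x width` matrix.
#' @export
get_frame <- function(seq, t) {
  stopifnot(is_frame_sequence(seq))
  t <- as.integer(t)
  if (t < 1L || t > seq$n_frames) stop("frame index out of range")
  matrix(seq$frames[t, , ], seq$height, seq$width)
}

#' Rectangular region of interest
#'
#' ROIs are expressed in 0-based pixel coordinates with half-open
#' intervals, i.e. the ROI covers rows `top .. top + height - 1` and
#' columns `left .. left + width - 1` of a frame (0-based). This is the
#' single coordinate convention used throughout the package.
#'
#' @param top,left 0-based row/column of the upper-left corner.
#' @param height,width Extent in pixels (positive integers).
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec(10, 20, 32, 32)
#' @export
roi_spec <- function(top, left, height, width) {
  v <- c(top = top, left = left, height = height, width = width)
  if (any(v != round(v))) stop("ROI coordinates must be integers")
  if (top < 0 || left < 0) stop("ROI `top` and `left` must be >= 0")
  if (height < 1 || width < 1) stop("ROI extent must be positive")
  structure(
    list(
      top = as.integer(top), left = as.integer(left),
      height = as.integer(height), width = as.integer(width)
    ),
    class = "roi_spec"
  )
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf(
    "<roi_spec> rows [%d, %d), cols [%d, %d) (0-based)\n",
    x$top, x$top + x$height, x$left, x$left + x$width
  ))
  invisible(x)
}

# Validate that an ROI fits a frame of given size; returns 1-based index
# vectors (rows, cols).
roi_indices <- function(roi, height, width) {
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$top + roi$height > height || roi$left + roi$width > width) {
    stop(sprintf(
      "ROI [%d,%d,%d,%d] does not fit inside a %d x %d frame",
      roi$top, roi$left, roi$height, roi$width, height, width
    ))
  }
  list(
    rows = seq.int(roi$top + 1L, roi$top + roi$height),
    cols = seq.int(roi$left + 1L, roi$left + roi$width)
  )
}

# Extract ROI pixels: from a matrix -> matrix; from a frame_sequence ->
# (t, roi_rows, roi_cols) array.
roi_extract <- function(x, roi) {
  if (is_frame_sequence(x)) {
    ix <- roi_indices(roi, x$height, x$width)
    return(x$frames[, ix$rows, ix$cols, drop = FALSE])
  }
  if (is.matrix(x)) {
    ix <- roi_indices(roi, nrow(x), ncol(x))
    return(x[ix$rows, ix$cols, drop = FALSE])
  }
  stop("`x` must be a matrix or a frame_sequence")
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
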