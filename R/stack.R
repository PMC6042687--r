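#' Multi-channel 3D image stack
#'
#' The raw-data container used throughout the package: a 4D intensity array
#' with spatial dimensions ordered `(z, y, x)` and channels as the fourth
#' dimension, plus the physical voxel spacing in micrometres. Voxel `(k, j, i)`
#' (0-based) has its center at `(k*sz, j*sy, i*sx)` um; volumes are voxel
#' counts times `prod(spacing)` um^3.
#'
#' @param voxels numeric array, either 3D `(z, y, x)` for a single channel or
#'   4D `(z, y, x, channel)`. Intensities must be finite and non-negative.
#' @param spacing numeric length-3, voxel spacing `(z, y, x)` in um.
#' @param channels character vector of channel names, one per channel.
#' @param cell_id optional identifier carried through to measurements.
#' @return An object of class `ct_stack`.
#' @examples
#' vox <- array(runif(2 * 4 * 8 * 8), c(4, 8, 8, 2))
#' st <- ct_stack(vox, spacing = c(0.25, 0.1, 0.1), channels = c("dna", "chr2L"))
#' st
#' @export
ct_stack <- function(voxels, spacing, channels, cell_id = "cell") {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L) {
    stop("`voxels` must be a 3D (z,y,x) or 4D (z,y,x,channel) array", call. = FALSE)
  }
  spacing <- .spacing_check(spacing)
  if (missing(channels)) channels <- paste0("ch", seq_len(dim(voxels)[4]))
  if (length(channels) != dim(voxels)[4]) {
    stop(sprintf("%d channel names given for %d channels",
                 length(channels), dim(voxels)[4]), call. = FALSE)
  }
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    stop("intensities must be finite", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing = spacing,
         channels = as.character(channels), cell_id = as.character(cell_id)),
    class = "ct_stack"
  )
}

#' @export
print.ct_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_stack '%s'> %d x %d x %d voxels (z,y,x), %d channel(s)\n",
              x$cell_id, d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing (z,y,x): %s um\n", paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' @export
dim.ct_stack <- function(x) dim(x$voxels)

#' Extract one channel of a stack as a 3D array
#'
#' @param stack a [ct_stack()].
#' @param channel channel name or integer index.
#' @return 3D numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "ct_stack"))
  if (is.character(channel)) {
    idx <- match(channel, stack$channels)
    if (is.na(idx)) {
      stop(sprintf("channel '%s' not found (have: %s)", channel,
                   paste(stack$channels, collapse = ", ")), call. = FALSE)
    }
  } else {
    idx <- as.integer(channel)
    if (idx < 1L || idx > length(stack$channels)) {
      stop("channel index out of range", call. = FALSE)
    }
  }
  stack$voxels[, , , idx, drop = TRUE]
}

# voxel-count volume in um^3
mask_volume <- function(mask, spacing) sum(mask) * prod(spacing)
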