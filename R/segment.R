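#' Otsu threshold
#'
#' Maximises between-class variance over a 256-bin histogram of the values;
#' returns a cut value such that foreground is `> threshold`.
#'
#' @param values numeric vector.
#' @return threshold value.
#' @export
otsu_threshold <- function(values) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) <= 0) {
    stop("cannot threshold a constant image (degenerate histogram)", call. = FALSE)
  }
  nb <- 256L
  br <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE), nbins = nb)
  w <- cumsum(h)
  mids <- (br[-1] + br[-(nb + 1L)]) / 2
  m <- cumsum(h * mids)
  n <- w[nb]; mt <- m[nb]
  w0 <- w[-nb]; m0 <- m[-nb]
  valid <- w0 > 0 & w0 < n
  bcv <- rep(-Inf, nb - 1L)
  bcv[valid] <- (mt * w0[valid] - n * m0[valid])^2 /
    (as.numeric(w0[valid]) * (n - w0[valid]))
  br[which.max(bcv) + 1L]   # upper edge of the best background bin
}

#' Segment the nucleus from the DNA counterstain
#'
#' Otsu threshold on the DNA channel, 3D hole filling, then the largest
#' 26-connected component. A nucleus touching the stack border is flagged in
#' the provenance attribute (`attr(mask, "border_touching")`), the
#' conventional exclusion criterion for clipped cells.
#'
#' @param stack a [ct_stack()].
#' @param dna_channel name or index of the DNA counterstain channel.
#' @return 3D logical mask with attributes `threshold` and
#'   `border_touching`.
#' @export
segment_nucleus <- function(stack, dna_channel = "dna") {
  img <- get_channel(stack, dna_channel)
  thr <- otsu_threshold(img)
  fg <- img > thr
  if (!any(fg)) stop("no nucleus: empty foreground after thresholding", call. = FALSE)
  fg <- fill_holes_3d(fg)
  lab <- cpp_label_components(fg, dim(fg), 26L)
  sizes <- tabulate(lab[lab > 0L])
  mask <- array(lab == which.max(sizes), dim(fg))
  d <- dim(mask)
  border <- any(mask[1, , ]) || any(mask[d[1], , ]) ||
    any(mask[, 1, ]) || any(mask[, d[2], ]) ||
    any(mask[, , 1]) || any(mask[, , d[3]])
  attr(mask, "threshold") <- thr
  attr(mask, "border_touching") <- border
  mask
}

#' Fill interior holes of a 3D binary mask
#'
#' Background components (6-connectivity) not reaching the stack border are
#' holes and become foreground.
#'
#' @param mask 3D logical array.
#' @return filled mask.
#' @export
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  bg <- cpp_label_components(!mask, d, 6L)
  border_labels <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                            bg[, , 1], bg[, , d[3]]))
  border_labels <- border_labels[border_labels > 0L]
  out <- mask | (bg > 0L & !(bg %in% border_labels))
  dim(out) <- d
  out
}

#' Default low/high thresholds for territory segmentation
#'
#' `high` is the Otsu threshold over the in-nucleus voxels of the channel;
#' `low = low_factor * high`. Config values override both verbatim.
#'
#' @param stack a [ct_stack()].
#' @param channel channel name or index.
#' @param nucleus nucleus mask.
#' @param low,high optional overrides, returned verbatim when given.
#' @param low_factor ratio `low / high` for the automatic rule.
#' @return named numeric `c(low =, high =)`.
#' @export
auto_thresholds <- function(stack, channel, nucleus, low = NULL, high = NULL,
                            low_factor = 0.5) {
  if (!is.null(low) && !is.null(high)) {
    if (low > high) stop("`low` must not exceed `high`", call. = FALSE)
    return(c(low = low, high = high))
  }
  if (!any(nucleus)) stop("empty nucleus mask", call. = FALSE)
  img <- get_channel(stack, channel)
  hi <- if (is.null(high)) otsu_threshold(img[nucleus]) else high
  lo <- if (is.null(low)) low_factor * hi else low
  if (lo > hi) stop("`low` must not exceed `high`", call. = FALSE)
  c(low = lo, high = hi)
}

#' 3D hysteresis segmentation of one channel
#'
#' Voxels `>= high` seed regions that grow through 26-connected voxels
#' `>= low`. Components are clipped to the nucleus, components smaller than
#' `min_volume` um^3 are discarded, and labels are renumbered by descending
#' volume (label 1 = largest).
#'
#' @param stack a [ct_stack()] (or 3D numeric array).
#' @param channel channel name/index (ignored for a bare array).
#' @param low,high thresholds, `0 <= low <= high`.
#' @param min_volume minimum component volume um^3.
#' @param nucleus nucleus mask (`NULL` to skip clipping).
#' @param spacing voxel spacing; defaults to the stack's.
#' @return list of class `ct_components`: `labels` (integer array),
#'   `volumes` (tibble: label, n_voxels, volume), `low`, `high`.
#' @export
hysteresis_segment <- function(stack, channel = NULL, low, high,
                               min_volume = 0.05, nucleus = NULL,
                               spacing = NULL) {
  if (low > high) stop("`low` must not exceed `high`", call. = FALSE)
  if (inherits(stack, "ct_stack")) {
    img <- get_channel(stack, channel)
    if (is.null(spacing)) spacing <- stack$spacing
  } else {
    img <- stack
    if (is.null(spacing)) stop("`spacing` required for a bare array", call. = FALSE)
  }
  spacing <- .spacing_check(spacing)
  d <- dim(img)
  lab <- cpp_hysteresis(as.numeric(img), d, low, high)
  if (!is.null(nucleus)) lab[!nucleus] <- 0L
  voxvol <- prod(spacing)
  nlab <- max(lab)
  if (nlab > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = nlab)
    keep <- which(sizes * voxvol >= min_volume)
    ord <- keep[order(sizes[keep], decreasing = TRUE)]
    remap0 <- integer(nlab + 1L)
    remap0[ord + 1L] <- seq_along(ord)
    lab <- array(remap0[lab + 1L], d)
    sizes <- sizes[ord]
  } else {
    sizes <- integer(0)
  }
  structure(
    list(labels = lab,
         volumes = tibble::tibble(label = seq_along(sizes),
                                  n_voxels = as.integer(sizes),
                                  volume = sizes * voxvol),
         low = low, high = high, spacing = spacing),
    class = "ct_components"
  )
}

#' @export
print.ct_components <- function(x, ...) {
  cat(sprintf("<ct_components> %d component(s), thresholds low=%.4g high=%.4g\n",
              nrow(x$volumes), x$low, x$high))
  if (nrow(x$volumes)) print(x$volumes, n = 5)
  invisible(x)
}

#' 3D spot detection (Laplacian of Gaussian)
#'
#' Computes the negated, scale-normalised Laplacian-of-Gaussian response at
#' `scale_sigma` and returns the physical coordinates of 26-neighbourhood
#' local maxima above `peak_threshold` inside the nucleus. The default
#' threshold is `median + k_mad * MAD` of the in-nucleus response.
#'
#' @param stack a [ct_stack()].
#' @param channel channel name or index.
#' @param scale_sigma LoG scale `(z, y, x)` um (the expected focus radius).
#' @param peak_threshold absolute response threshold, or `NULL` for the
#'   MAD-based default.
#' @param nucleus nucleus mask.
#' @param k_mad multiplier for the MAD-based default threshold.
#' @return tibble with columns `z`, `y`, `x` (um) and `response`; one row
#'   per focus.
#' @export
detect_spots_3d <- function(stack, channel, scale_sigma, peak_threshold = NULL,
                            nucleus = NULL, k_mad = 8) {
  stopifnot(inherits(stack, "ct_stack"))
  if (any(scale_sigma <= 0)) stop("`scale_sigma` must be positive per axis", call. = FALSE)
  img <- get_channel(stack, channel)
  d <- dim(img)
  sp <- stack$spacing
  sig_vox <- scale_sigma / sp
  g <- cpp_gaussian_blur(as.numeric(img), d, sig_vox)
  dim(g) <- d
  # scale-normalised negative Laplacian (bright blobs -> positive peaks)
  resp <- array(0, d)
  lap <- array(0, d)
  lap[2:(d[1] - 1), , ] <- (g[3:d[1], , ] - 2 * g[2:(d[1] - 1), , ] +
                              g[1:(d[1] - 2), , ]) / sp[1]^2
  resp <- resp + lap
  lap[] <- 0
  lap[, 2:(d[2] - 1), ] <- (g[, 3:d[2], ] - 2 * g[, 2:(d[2] - 1), ] +
                              g[, 1:(d[2] - 2), ]) / sp[2]^2
  resp <- resp + lap
  lap[] <- 0
  lap[, , 2:(d[3] - 1)] <- (g[, , 3:d[3]] - 2 * g[, , 2:(d[3] - 1)] +
                              g[, , 1:(d[3] - 2)]) / sp[3]^2
  resp <- resp + lap
  resp <- -mean(scale_sigma)^2 * resp
  if (is.null(nucleus)) nucleus <- array(TRUE, d)
  if (is.null(peak_threshold)) {
    inside <- resp[nucleus]
    peak_threshold <- median(inside) + k_mad * mad(inside)
  }
  idx <- cpp_local_maxima(as.numeric(resp), d, nucleus, peak_threshold)
  ai <- arrayInd(idx, d)
  tibble::tibble(
    z = (ai[, 1] - 1) * sp[1],
    y = (ai[, 2] - 1) * sp[2],
    x = (ai[, 3] - 1) * sp[3],
    response = resp[idx]
  )
}

#' Homolog pairing state of one channel
#'
#' A channel is scored as paired when it presents a single FISH signal:
#' `n_signals` counts components at least `relative_min` times the largest
#' component's volume (specks below that are hybridisation debris), and
#' `paired` is `TRUE` iff exactly one such signal exists.
#'
#' @param components a [hysteresis_segment()] result, or a numeric vector of
#'   component volumes.
#' @param relative_min fraction of the largest component's volume below
#'   which a component is ignored.
#' @return list `(n_signals, paired)`; with zero components `n_signals = 0`
#'   and `paired = NA`.
#' @export
pairing_state <- function(components, relative_min = 0.1) {
  vols <- if (inherits(components, "ct_components")) components$volumes$volume
          else as.numeric(components)
  if (length(vols) == 0L || all(vols <= 0)) {
    return(list(n_signals = 0L, paired = NA))
  }
  n <- sum(vols >= relative_min * max(vols))
  list(n_signals = as.integer(n), paired = n == 1L)
}

#' Refine segmented components to their half-maximum boundary
#'
#' Hysteresis with automatic thresholds recovers each structure together
#' with a halo of partial-volume voxels created by PSF blur. For a symmetric
#' PSF the volume-preserving boundary of a blurred object sits at half its
#' interior intensity, so each component is re-thresholded at
#' `fraction * quantile(intensity, peak_quantile)` of its own voxels,
#' re-labelled (refinement can split touching structures), filtered by
#' `min_volume` and re-sorted by volume.
#'
#' @param components a [hysteresis_segment()] result.
#' @param img the intensity array the components were segmented from.
#' @param min_volume minimum component volume um^3.
#' @param fraction boundary level as a fraction of the component peak.
#' @param peak_quantile robust "peak" of a component (quantile of its
#'   voxel intensities).
#' @return a `ct_components` with refined labels/volumes.
#' @export
fwhm_refine <- function(components, img, min_volume = 0.05, fraction = 0.44,
                        peak_quantile = 0.9) {
  stopifnot(inherits(components, "ct_components"))
  lab <- components$labels
  d <- dim(lab)
  keep <- array(FALSE, d)
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l)
    if (length(idx) == 0L) next
    thr <- fraction * quantile(img[idx], peak_quantile, names = FALSE, type = 7)
    keep[idx[img[idx] >= thr]] <- TRUE
  }
  voxvol <- prod(components$spacing)
  lab2 <- cpp_label_components(keep, d, 26L)
  nlab <- max(lab2)
  sizes <- if (nlab > 0L) tabulate(lab2[lab2 > 0L], nbins = nlab) else integer(0)
  kept <- which(sizes * voxvol >= min_volume)
  ord <- kept[order(sizes[kept], decreasing = TRUE)]
  remap0 <- integer(nlab + 1L)
  remap0[ord + 1L] <- seq_along(ord)
  lab2 <- array(remap0[lab2 + 1L], d)
  sizes <- sizes[ord]
  structure(
    list(labels = lab2,
         volumes = tibble::tibble(label = seq_along(sizes),
                                  n_voxels = as.integer(sizes),
                                  volume = sizes * voxvol),
         low = components$low, high = components$high,
         spacing = components$spacing),
    class = "ct_components"
  )
}

#' Segment a full cell
#'
#' Nucleus from the DNA channel, then per-channel hysteresis components with
#' automatic (or configured) thresholds; thresholds and exclusion flags are
#' recorded in `provenance`.
#'
#' @param stack a [ct_stack()].
#' @param dna_channel DNA counterstain channel name.
#' @param channels channels to segment (default: all but the DNA channel).
#' @param thresholds optional named list `channel -> c(low, high)` overrides
#'   (on the background-subtracted scale when `background_subtract` is on).
#' @param min_volume minimum component volume um^3.
#' @param relative_min speck filter for [pairing_state()].
#' @param refine apply [fwhm_refine()] to each channel after hysteresis.
#' @param background_subtract subtract the camera offset (median intensity
#'   outside the nucleus) from each paint channel before thresholding. The
#'   automatic `low = 0.5 * high` rule assumes a zero-based intensity scale,
#'   so a camera offset must be removed first or `low` lands inside the
#'   background peak and hysteresis floods the nucleus.
#' @return object of class `ct_cell`: `nucleus`, `territories` (named list
#'   of [hysteresis_segment()] results), `spacing`, `cell_id`, `provenance`.
#' @export
segment_cell <- function(stack, dna_channel = "dna", channels = NULL,
                         thresholds = NULL, min_volume = 0.05,
                         relative_min = 0.1, background_subtract = TRUE,
                         refine = TRUE) {
  stopifnot(inherits(stack, "ct_stack"))
  if (is.null(channels)) channels <- setdiff(stack$channels, dna_channel)
  nucleus <- segment_nucleus(stack, dna_channel)
  prov <- list(
    dna_threshold = attr(nucleus, "threshold"),
    border_touching = attr(nucleus, "border_touching"),
    thresholds = list(), relative_min = relative_min, min_volume = min_volume,
    background_subtract = background_subtract
  )
  territories <- vector("list", length(channels))
  names(territories) <- channels
  for (ch in channels) {
    img <- get_channel(stack, ch)
    if (background_subtract) {
      out_nuc <- which(!nucleus)
      bg <- median(img[out_nuc[seq.int(1L, length(out_nuc), by = 7L)]])
      img <- pmax(img - bg, 0)
      dim(img) <- dim(nucleus)
      prov$thresholds[[ch]] <- c(camera_offset = bg)
    }
    ov <- thresholds[[ch]]
    sub <- ct_stack(img, stack$spacing, ch, stack$cell_id)
    thr <- tryCatch(
      auto_thresholds(sub, ch, nucleus,
                      low = if (is.null(ov)) NULL else unname(ov[["low"]]),
                      high = if (is.null(ov)) NULL else unname(ov[["high"]])),
      error = function(e) NULL
    )
    if (is.null(thr)) {
      territories[ch] <- list(NULL)
      prov$thresholds[[ch]] <- c(prov$thresholds[[ch]],
                                 c(low = NA_real_, high = NA_real_))
      next
    }
    comp <- hysteresis_segment(sub, ch, low = thr[["low"]],
                               high = thr[["high"]],
                               min_volume = min_volume,
                               nucleus = nucleus)
    if (refine) comp <- fwhm_refine(comp, img, min_volume = min_volume)
    territories[[ch]] <- comp
    prov$thresholds[[ch]] <- c(prov$thresholds[[ch]], thr)
  }
  structure(
    list(nucleus = nucleus, territories = territories,
         spacing = stack$spacing, cell_id = stack$cell_id, provenance = prov),
    class = "ct_cell"
  )
}

#' @export
print.ct_cell <- function(x, ...) {
  cat(sprintf("<ct_cell '%s'> nucleus %d voxels%s\n", x$cell_id, sum(x$nucleus),
              if (isTRUE(x$provenance$border_touching)) " [border-touching]" else ""))
  for (ch in names(x$territories)) {
    tt <- x$territories[[ch]]
    cat(sprintf("  %s: %s component(s)\n", ch,
                if (is.null(tt)) "un-segmentable, 0" else nrow(tt$volumes)))
  }
  invisible(x)
}
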