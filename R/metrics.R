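# Per-cell territory metrics. All functions take 3D logical arrays on one
# voxel grid; spacing is (z, y, x) um and only enters where physics demands
# (distances, surfaces). Overlap-type ratios are pure voxel-count ratios.

#' Volume of a structure as a fraction of the nuclear volume
#'
#' @param ct_mask,nucleus_mask 3D logical arrays on one grid.
#' @return fraction in `[0, 1]` (spacing cancels).
#' @export
volume_fraction <- function(ct_mask, nucleus_mask) {
  .mask_check(ct_mask, "ct_mask"); .mask_check(nucleus_mask, "nucleus_mask")
  stopifnot(identical(dim(ct_mask), dim(nucleus_mask)))
  nv <- sum(nucleus_mask)
  if (nv == 0L) stop("empty nucleus mask", call. = FALSE)
  sum(ct_mask) / nv
}

#' Overlap of one mask with a reference mask
#'
#' `O(A | ref) = |A n ref| / |ref|`: the fraction of the reference structure's
#' voxels shared with A. Asymmetric by design; both directions of every pair
#' are reported by [measure_cell()].
#'
#' @param mask_a,mask_ref 3D logical arrays on one grid.
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(mask_a, mask_ref) {
  stopifnot(identical(dim(mask_a), dim(mask_ref)))
  nref <- sum(mask_ref)
  if (nref == 0L) stop("empty reference mask", call. = FALSE)
  sum(mask_a & mask_ref) / nref
}

#' Intermixing of one territory with all others
#'
#' The fraction of the target's voxels shared with the union of the other
#' masks.
#'
#' @param target_mask 3D logical array.
#' @param other_masks list of 3D logical arrays on the same grid.
#' @return fraction in `[0, 1]`.
#' @export
intermixing_fraction <- function(target_mask, other_masks) {
  if (length(other_masks) < 1L) stop("need at least one other mask", call. = FALSE)
  nt <- sum(target_mask)
  if (nt == 0L) stop("empty target mask", call. = FALSE)
  u <- Reduce(`|`, other_masks)
  sum(target_mask & u) / nt
}

#' Are two structures in contact?
#'
#' Contact means overlapping or abutting: true iff the masks intersect or
#' any voxel of A is 26-adjacent to a voxel of B (one-step 26-dilation of A
#' intersects B). Diffraction-limited signals from abutting domains overlap
#' after PSF blur, so intersection-only would miss one voxel layer;
#' `mode = "intersection"` gives the stricter rule.
#'
#' @param mask_a,mask_b 3D logical arrays on one grid.
#' @param mode `"adjacency"` (default) or `"intersection"`.
#' @return logical.
#' @export
in_contact <- function(mask_a, mask_b, mode = c("adjacency", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  if (any(mask_a & mask_b)) return(TRUE)
  if (mode == "intersection") return(FALSE)
  bb <- .bounding_box(mask_a | mask_b)
  a <- mask_a[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2], drop = FALSE]
  b <- mask_b[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2], drop = FALSE]
  any(cpp_dilate26(a, dim(a)) & b)
}

#' Minimal edge-to-edge distance between two structures
#'
#' Zero when the masks intersect, else the minimum anisotropic Euclidean
#' distance between voxel centers of the two masks, computed via a distance
#' transform (exact: equals the brute-force pairwise minimum).
#'
#' @param mask_a,mask_b non-empty 3D logical arrays on one grid.
#' @param spacing voxel spacing `(z, y, x)` um.
#' @return distance in um.
#' @export
min_edge_distance <- function(mask_a, mask_b, spacing) {
  spacing <- .spacing_check(spacing)
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  if (!any(mask_a) || !any(mask_b)) stop("empty mask", call. = FALSE)
  if (any(mask_a & mask_b)) return(0)
  # joint bounding box: the nearest pair of voxels lies inside it
  bb <- .bounding_box(mask_a | mask_b)
  a <- mask_a[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2], drop = FALSE]
  b <- mask_b[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2], drop = FALSE]
  d <- cpp_edt(b, dim(b), spacing)
  min(d[a])
}

#' Compacity (sphericity) of a voxel structure
#'
#' `psi = pi^(1/3) * (6 V)^(2/3) / S`, 1 for a ball and decreasing with
#' elongation or surface roughness. `V` is the physical voxel volume. `S` is
#' a staircase-corrected isosurface area: every exposed voxel face is
#' weighted by the face-normal component of the local unit normal, estimated
#' from a Gaussian-smoothed indicator field (`sigma_vox` voxels per axis,
#' face-centered evaluation). The estimator is exact for axis-aligned faces
#' and consistent for smooth surfaces, so a large digital ball scores
#' close to 1 and a cube close to the closed form `(pi/6)^(1/3) ~ 0.806`.
#'
#' Masks of fewer than 8 voxels are returned with attribute
#' `unreliable = TRUE` (the normal field is undersampled).
#'
#' @param mask non-empty 3D logical array (use the union of a channel's
#'   retained components).
#' @param spacing voxel spacing `(z, y, x)` um.
#' @param sigma_vox smoothing of the normal field, voxels per axis.
#' @return sphericity in `(0, 1]` (clamped at 1).
#' @export
compacity <- function(mask, spacing, sigma_vox = 1.05) {
  spacing <- .spacing_check(spacing)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  # crop to bounding box for speed; pad so the surface never touches the edge
  bb <- .bounding_box(mask)
  sub <- mask[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2], drop = FALSE]
  S <- .surface_area_proj(sub, spacing, rep(sigma_vox, 3))
  V <- sum(sub) * prod(spacing)
  psi <- pi^(1 / 3) * (6 * V)^(2 / 3) / S
  psi <- min(psi, 1)
  if (sum(sub) < 8L) attr(psi, "unreliable") <- TRUE
  psi
}

.bounding_box <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  t(apply(idx, 2, range))
}

# staircase-corrected exposed-face surface area (see compacity docs)
.surface_area_proj <- function(mask, spacing, sigma_vox) {
  pad <- max(5L, as.integer(ceiling(3 * max(sigma_vox))))
  d0 <- dim(mask)
  f <- array(0, d0 + 2L * pad)
  f[pad + seq_len(d0[1]), pad + seq_len(d0[2]), pad + seq_len(d0[3])] <-
    as.numeric(mask)
  m <- f > 0.5
  dd <- dim(f)
  g <- cpp_gaussian_blur(f, dd, sigma_vox)
  dim(g) <- dd
  grads <- list(array(0, dd), array(0, dd), array(0, dd))
  grads[[1]][2:(dd[1] - 1), , ] <-
    (g[3:dd[1], , ] - g[1:(dd[1] - 2), , ]) / (2 * spacing[1])
  grads[[2]][, 2:(dd[2] - 1), ] <-
    (g[, 3:dd[2], ] - g[, 1:(dd[2] - 2), ]) / (2 * spacing[2])
  grads[[3]][, , 2:(dd[3] - 1)] <-
    (g[, , 3:dd[3]] - g[, , 1:(dd[3] - 2)]) / (2 * spacing[3])
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  S <- 0
  for (ax in 1:3) {
    n <- dd[ax]
    iA <- list(seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3]))
    iB <- iA
    iA[[ax]] <- seq_len(n - 1L)
    iB[[ax]] <- 2:n
    mA <- m[iA[[1]], iA[[2]], iA[[3]], drop = FALSE]
    mB <- m[iB[[1]], iB[[2]], iB[[3]], drop = FALSE]
    face <- xor(mA, mB)
    if (!any(face)) next
    # normal at the face: axial part one-sided across the face, tangential
    # parts averaged from the two adjacent voxels
    ga <- (g[iB[[1]], iB[[2]], iB[[3]]] - g[iA[[1]], iA[[2]], iA[[3]]]) / spacing[ax]
    tax <- setdiff(1:3, ax)
    t1 <- (grads[[tax[1]]][iA[[1]], iA[[2]], iA[[3]]] +
             grads[[tax[1]]][iB[[1]], iB[[2]], iB[[3]]]) / 2
    t2 <- (grads[[tax[2]]][iA[[1]], iA[[2]], iA[[3]]] +
             grads[[tax[2]]][iB[[1]], iB[[2]], iB[[3]]]) / 2
    ga <- ga[face]; t1 <- t1[face]; t2 <- t2[face]
    nrm <- sqrt(ga^2 + t1^2 + t2^2)
    w <- ifelse(nrm > 0, abs(ga) / nrm, 1)
    S <- S + sum(w) * face_area[ax]
  }
  S
}

#' Partition the nucleus into equal-volume concentric shells
#'
#' Voxels are ranked by their anisotropic Euclidean distance to the nearest
#' background voxel (ties broken by linear index) and split into
#' `n_shells` equal-count groups: shell 1 hugs the nuclear periphery,
#' shell `n_shells` is the nuclear center. Equal voxel count = equal volume,
#' exactly by construction.
#'
#' @param nucleus_mask non-empty 3D logical array.
#' @param n_shells number of shells.
#' @param spacing voxel spacing `(z, y, x)` um.
#' @return integer array: shell index 1..n_shells inside the nucleus, 0
#'   outside.
#' @export
shell_partition <- function(nucleus_mask, n_shells = 5L, spacing) {
  spacing <- .spacing_check(spacing)
  nvox <- sum(nucleus_mask)
  if (nvox < n_shells) {
    stop("nucleus smaller than the number of shells", call. = FALSE)
  }
  d <- dim(nucleus_mask)
  dist <- cpp_edt(!nucleus_mask, d, spacing)
  idx <- which(nucleus_mask)
  ord <- idx[order(dist[idx], idx)]
  counts <- rep(nvox %/% n_shells, n_shells)
  rem <- nvox %% n_shells
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  shells <- array(0L, d)
  shells[ord] <- rep(seq_len(n_shells), times = counts)
  shells
}

#' Radial shell distribution of a territory
#'
#' @param ct_mask non-empty 3D logical array, inside the nucleus.
#' @param shell_labels a [shell_partition()] result.
#' @return numeric vector of per-shell voxel fractions, summing to 1.
#' @export
shell_distribution <- function(ct_mask, shell_labels) {
  if (!any(ct_mask)) stop("empty territory mask", call. = FALSE)
  n_shells <- max(shell_labels)
  sh <- shell_labels[ct_mask]
  if (any(sh == 0L)) {
    stop("territory mask has voxels outside the nucleus partition", call. = FALSE)
  }
  tabulate(sh, nbins = n_shells) / length(sh)
}

#' Measure every per-cell quantity from a segmented cell
#'
#' Computes, per channel (union of retained components): volume, nuclear
#' volume fraction, signal count and pairing state, compacity, intermixing
#' with the union of all other channels, and the 5-shell radial profile; per
#' ordered channel pair: intersection volume and overlap fraction
#' `O(A|B) = |A n B| / |B|`; per unordered pair: contact and minimal
#' edge-to-edge distance. Channels that failed to segment yield `NA` fields,
#' never an aborted cell. With territories named `cen`, `mid`, `tel` the
#' three-probe fold configuration is classified as well.
#'
#' @param segmented a [segment_cell()] result (`ct_cell`).
#' @param n_shells number of radial shells.
#' @param contact_mode passed to [in_contact()].
#' @return one-row tibble; pair columns are named `ovf_A_given_B`,
#'   `contact_A_B`, `dist_A_B`, shells `shell1_CH` ... `shell5_CH`.
#' @export
measure_cell <- function(segmented, n_shells = 5L,
                         contact_mode = c("adjacency", "intersection")) {
  stopifnot(inherits(segmented, "ct_cell"))
  contact_mode <- match.arg(contact_mode)
  sp <- segmented$spacing
  voxvol <- prod(sp)
  nuc <- segmented$nucleus
  chans <- names(segmented$territories)
  masks <- lapply(segmented$territories, function(tt) {
    if (is.null(tt) || nrow(tt$volumes) == 0L) NULL else tt$labels > 0L
  })
  shells <- shell_partition(nuc, n_shells, sp)
  # band probes are sub-regions of a painted arm: they join distance/contact/
  # configuration readouts but are excluded from inter-CT overlap/intermixing
  probes <- intersect(c("cen", "mid", "tel"), chans)
  paints <- setdiff(chans, probes)

  row <- list(cell_id = segmented$cell_id,
              nucleus_volume = sum(nuc) * voxvol,
              border_touching = isTRUE(segmented$provenance$border_touching))
  for (ch in chans) {
    m <- masks[[ch]]
    tt <- segmented$territories[[ch]]
    empty <- is.null(m)
    ps <- if (empty) list(n_signals = 0L, paired = NA)
          else pairing_state(tt$volumes$volume,
                             segmented$provenance$relative_min %||% 0.1)
    row[[paste0("vol_", ch)]] <- if (empty) NA_real_ else sum(m) * voxvol
    row[[paste0("volfrac_", ch)]] <- if (empty) NA_real_ else volume_fraction(m, nuc)
    row[[paste0("nsignals_", ch)]] <- ps$n_signals
    row[[paste0("paired_", ch)]] <- if (empty) NA else ps$paired
    row[[paste0("compacity_", ch)]] <-
      if (empty) NA_real_ else as.numeric(compacity(m, sp))
    others <- masks[setdiff(paints, ch)]
    others <- others[!vapply(others, is.null, TRUE)]
    row[[paste0("intermix_", ch)]] <-
      if (empty || !(ch %in% paints) || length(others) == 0L) NA_real_
      else intermixing_fraction(m, others)
    sf <- if (empty) rep(NA_real_, n_shells) else shell_distribution(m, shells)
    for (s in seq_len(n_shells)) row[[sprintf("shell%d_%s", s, ch)]] <- sf[s]
  }
  pair_sets <- c(if (length(paints) >= 2L) utils::combn(paints, 2L, simplify = FALSE),
                 if (length(probes) >= 2L) utils::combn(probes, 2L, simplify = FALSE))
  if (length(pair_sets)) {
    for (pr in pair_sets) {
      a <- pr[1]; b <- pr[2]
      ma <- masks[[a]]; mb <- masks[[b]]
      ok <- !is.null(ma) && !is.null(mb)
      inter <- if (ok) sum(ma & mb) * voxvol else NA_real_
      row[[paste0("ivol_", a, "_", b)]] <- inter
      row[[paste0("ovf_", a, "_given_", b)]] <-
        if (ok) overlap_fraction(ma, mb) else NA_real_
      row[[paste0("ovf_", b, "_given_", a)]] <-
        if (ok) overlap_fraction(mb, ma) else NA_real_
      row[[paste0("contact_", a, "_", b)]] <-
        if (ok) in_contact(ma, mb, contact_mode) else NA
      row[[paste0("dist_", a, "_", b)]] <-
        if (ok) min_edge_distance(ma, mb, sp) else NA_real_
    }
  }
  if (all(c("cen", "mid", "tel") %in% chans)) {
    cfg <- classify_configuration(masks[["cen"]], masks[["mid"]], masks[["tel"]],
                                  contact_mode = contact_mode)
    row$cfg_state <- cfg$state_id
    row$cfg_closed <- cfg$closed
  }
  tibble::as_tibble(row)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure a list of segmented cells
#'
#' @param cells list of `ct_cell` objects.
#' @param ... passed to [measure_cell()].
#' @return tibble, one row per cell.
#' @export
measure_cells <- function(cells, ...) {
  dplyr::bind_rows(lapply(cells, measure_cell, ...))
}
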