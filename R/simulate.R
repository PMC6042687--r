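#' Simulation parameters for synthetic nuclei
#'
#' Describes one simulated interphase nucleus: an ellipsoidal nucleus,
#' per-channel chromosome territories modelled as anchored bead chains, and
#' the microscope used to render them. The defaults describe a flattened
#' Drosophila-like cultured-cell nucleus on an anisotropic widefield grid,
#' with three whole-arm paint channels, two homologous chains per channel,
#' and strong somatic pairing.
#'
#' `confinement` is the compaction dial: at each step of a chain the bead is
#' pulled back toward its territory anchor by this fraction of its current
#' displacement (0 = free random walk that fills the nucleus, 1 = collapse
#' onto the anchor). It stands in for condensin II activity: higher values
#' give compact, spherical, little-intermixed territories.
#'
#' @param nucleus_radii ellipsoid semi-axes `(z, y, x)` um.
#' @param voxel_spacing voxel spacing `(z, y, x)` um.
#' @param grid_dim voxel grid `(z, y, x)`.
#' @param channels list of channel specs; each a list with `name`,
#'   `n_chains`, `beads_per_chain`, `bead_radius` (um), `step_length` (um).
#' @param confinement fraction in `[0, 1]`, pull toward the anchor per step.
#' @param anchor_min_sep minimum distance (um) between the anchors of
#'   *unpaired* homolog chains, so that an unpaired channel presents two
#'   spatially distinct territories.
#' @param pairing_prob probability that homologous chains of a channel share
#'   one anchor (scored as somatic pairing).
#' @param translocation `NULL`, or list `(donor, acceptor, fraction)`: the
#'   terminal `fraction` of each donor-channel chain is re-folded at the
#'   acceptor channel's anchor while keeping the donor's label.
#' @param band_probes `NULL`, or list `(channel, cen, mid, tel)` where
#'   `cen`/`mid`/`tel` are disjoint bead index ranges on chain 1 of
#'   `channel`; rendered as three extra probe channels.
#' @param psf_sigma Gaussian PSF sigma `(z, y, x)` um.
#' @param photon_scale expected photon count inside a structure.
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param background camera offset (counts).
#' @param shot_noise apply Poisson shot noise? (disable for noiseless
#'   ground-truth renders).
#' @param seed integer RNG seed; all outputs are pure functions of
#'   `(params, seed)`.
#' @return object of class `ct_sim_params`.
#' @export
sim_params <- function(nucleus_radii = c(2.5, 4.0, 4.0),
                       voxel_spacing = c(0.25, 0.1, 0.1),
                       grid_dim = c(64L, 128L, 128L),
                       channels = default_channels(),
                       confinement = 0.3,
                       anchor_min_sep = 2.0,
                       pairing_prob = 0.9,
                       translocation = NULL,
                       band_probes = NULL,
                       psf_sigma = c(0.25, 0.12, 0.12),
                       photon_scale = 150,
                       read_noise_sd = 3,
                       background = 100,
                       shot_noise = TRUE,
                       seed = 1L) {
  p <- structure(
    list(nucleus_radii = as.numeric(nucleus_radii),
         voxel_spacing = .spacing_check(voxel_spacing),
         grid_dim = as.integer(grid_dim),
         channels = channels,
         confinement = confinement,
         anchor_min_sep = anchor_min_sep,
         pairing_prob = pairing_prob,
         translocation = translocation,
         band_probes = band_probes,
         psf_sigma = as.numeric(psf_sigma),
         photon_scale = photon_scale,
         read_noise_sd = read_noise_sd,
         background = background,
         shot_noise = isTRUE(shot_noise),
         seed = as.integer(seed)),
    class = "ct_sim_params"
  )
  validate_sim_params(p)
}

#' @rdname sim_params
#' @export
default_channels <- function() {
  # step_length <= 2 * bead_radius keeps consecutive beads touching, so a
  # chain renders as one connected tube rather than a string of specks
  spec <- function(name) list(name = name, n_chains = 2L, beads_per_chain = 120L,
                              bead_radius = 0.3, step_length = 0.5)
  list(spec("chr2L"), spec("chr2R"), spec("chrX"))
}

validate_sim_params <- function(p) {
  frac01 <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  if (any(p$nucleus_radii <= 0) || any(p$psf_sigma < 0) ||
      any(p$grid_dim < 4L)) {
    stop("nucleus radii must be positive, psf_sigma non-negative, grid >= 4 voxels",
         call. = FALSE)
  }
  if (!frac01(p$confinement)) stop("`confinement` must be in [0, 1]", call. = FALSE)
  if (!frac01(p$pairing_prob)) stop("`pairing_prob` must be in [0, 1]", call. = FALSE)
  if (p$photon_scale <= 0 || p$read_noise_sd < 0 || p$background < 0) {
    stop("photon_scale must be positive; noise terms non-negative", call. = FALSE)
  }
  nm <- vapply(p$channels, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate channel names", call. = FALSE)
  for (ch in p$channels) {
    if (ch$bead_radius < max(p$voxel_spacing)) {
      stop(sprintf("bead_radius %.3g um of '%s' is below max voxel spacing %.3g um (would render < 1 voxel)",
                   ch$bead_radius, ch$name, max(p$voxel_spacing)), call. = FALSE)
    }
    if (ch$step_length <= 0 || ch$n_chains < 1L || ch$beads_per_chain < 1L) {
      stop("chain spec of '", ch$name, "' invalid", call. = FALSE)
    }
  }
  if (!is.null(p$translocation)) {
    tr <- p$translocation
    if (!all(c(tr$donor, tr$acceptor) %in% nm) || tr$donor == tr$acceptor ||
        !frac01(tr$fraction)) {
      stop("translocation must name two distinct channels and a fraction in [0, 1]",
           call. = FALSE)
    }
  }
  if (!is.null(p$band_probes)) {
    bp <- p$band_probes
    if (!bp$channel %in% nm) stop("band_probes channel not found", call. = FALSE)
    rngs <- list(bp$cen, bp$mid, bp$tel)
    nb <- p$channels[[match(bp$channel, nm)]]$beads_per_chain
    if (any(unlist(rngs) < 1L) || any(unlist(rngs) > nb)) {
      stop("band probe bead indices out of chain range", call. = FALSE)
    }
    if (length(unique(unlist(rngs))) != length(unlist(rngs))) {
      stop("band probe index ranges must be disjoint", call. = FALSE)
    }
  }
  p
}

# physical center of the voxel grid (um)
.grid_center <- function(p) (p$grid_dim - 1L) * p$voxel_spacing / 2

# uniform point inside the ellipsoid with semi-axes `radii*shrink` around center
.runif_ellipsoid <- function(center, radii, shrink = 1) {
  repeat {
    q <- runif(3, -1, 1)
    if (sum(q^2) <= 1) return(center + q * radii * shrink)
  }
}

.inside_ellipsoid <- function(pt, center, radii) {
  sum(((pt - center) / radii)^2) <= 1
}

#' Generate one territory chain as an anchored biased random walk
#'
#' Beads start at `anchor`; each subsequent bead is the previous one plus a
#' random step of length `step_length` plus a pull of `confinement` times the
#' displacement back toward the anchor. Positions leaving the nuclear
#' ellipsoid are reflected radially back inside.
#'
#' @param anchor 3D point `(z, y, x)` um, inside the nucleus ellipsoid.
#' @param n_beads number of beads.
#' @param step_length step length um.
#' @param confinement fraction in `[0, 1]`.
#' @param center,radii nucleus ellipsoid center and semi-axes `(z, y, x)` um.
#' @param seed optional integer; when given, the chain is a pure function of
#'   it (otherwise the caller's RNG stream is used).
#' @return `n_beads` x 3 matrix of bead positions um.
#' @export
generate_territory_chain <- function(anchor, n_beads, step_length, confinement,
                                     center, radii, seed = NULL) {
  if (!.inside_ellipsoid(anchor, center, radii)) {
    stop("anchor lies outside the nucleus ellipsoid", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  out <- matrix(0, n_beads, 3)
  pos <- as.numeric(anchor)
  out[1, ] <- pos
  if (n_beads > 1L) for (b in 2:n_beads) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    pos <- pos + step_length * u + confinement * (anchor - pos)
    # radial reflection at the ellipsoid boundary
    q <- (pos - center) / radii
    r <- sqrt(sum(q^2))
    if (r > 1) {
      r2 <- max(2 - r, 1e-6)          # |q| -> 2 - |q|
      if (r2 > 1) r2 <- 1 / r2        # very long excursions fold back inside
      pos <- center + q / r * r2 * radii
    }
    out[b, ] <- pos
  }
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate one nucleus with ground truth
#'
#' Draws territory anchors, generates bead chains (homologs share one anchor
#' with probability `pairing_prob`), applies any translocation, voxelises
#' every chain as a union of digital balls clipped to the nucleus, and
#' records ground truth: per-channel true masks, bead coordinates, pairwise
#' intersection-over-reference overlap fractions, the pairing draw, and (with
#' band probes) the true three-probe contact configuration.
#'
#' @param params a [sim_params()].
#' @return object of class `ct_truth`: list with `nucleus` (logical array),
#'   `masks` (per paint channel), `probe_masks` (cen/mid/tel, or `NULL`),
#'   `beads`, `overlap` (matrix, `[A, B]` = |A n B| / |B|), `pairing`
#'   (named logical), `configuration` (see [classify_configuration()]),
#'   `params`.
#' @export
simulate_cell <- function(params) {
  p <- validate_sim_params(params)
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(p$seed)

  d <- p$grid_dim
  sp <- p$voxel_spacing
  center <- .grid_center(p)
  if (any(p$nucleus_radii >= center * 0.999)) {
    stop("nucleus ellipsoid does not fit the voxel grid", call. = FALSE)
  }
  # nucleus mask: voxel centers inside the ellipsoid
  zz <- ((seq_len(d[1]) - 1) * sp[1] - center[1]) / p$nucleus_radii[1]
  yy <- ((seq_len(d[2]) - 1) * sp[2] - center[2]) / p$nucleus_radii[2]
  xx <- ((seq_len(d[3]) - 1) * sp[3] - center[3]) / p$nucleus_radii[3]
  nucleus <- outer(outer(zz^2, yy^2, `+`), xx^2, `+`) <= 1

  nm <- vapply(p$channels, `[[`, "", "name")
  nch <- length(nm)
  anchors <- vector("list", nch)   # one anchor per chain
  pairing <- logical(nch)
  for (ci in seq_len(nch)) {
    ch <- p$channels[[ci]]
    a1 <- .runif_ellipsoid(center, p$nucleus_radii, shrink = 0.6)
    paired <- runif(1) < p$pairing_prob
    pairing[ci] <- paired
    anchors[[ci]] <- lapply(seq_len(ch$n_chains), function(k) {
      if (k == 1L || paired) return(a1)
      # unpaired homologs occupy distinct territories: keep their anchors
      # well separated so "unpaired" is a geometric fact, not a coin flip
      for (try in 1:200) {
        a2 <- .runif_ellipsoid(center, p$nucleus_radii, 0.6)
        if (sqrt(sum((a2 - a1)^2)) >= p$anchor_min_sep) return(a2)
      }
      a2
    })
  }
  names(pairing) <- nm

  beads <- vector("list", nch)
  names(beads) <- nm
  for (ci in seq_len(nch)) {
    ch <- p$channels[[ci]]
    beads[[ci]] <- lapply(seq_len(ch$n_chains), function(k) {
      generate_territory_chain(anchors[[ci]][[k]], ch$beads_per_chain,
                               ch$step_length, p$confinement,
                               center, p$nucleus_radii)
    })
  }

  if (!is.null(p$translocation)) {
    tr <- p$translocation
    di <- match(tr$donor, nm); ai <- match(tr$acceptor, nm)
    ch <- p$channels[[di]]
    n_move <- round(tr$fraction * ch$beads_per_chain)
    if (n_move > 0) for (k in seq_along(beads[[di]])) {
      # terminal beads re-fold at the acceptor territory anchor
      moved <- generate_territory_chain(anchors[[ai]][[1]], n_move,
                                        ch$step_length, p$confinement,
                                        center, p$nucleus_radii)
      nb <- ch$beads_per_chain
      beads[[di]][[k]][(nb - n_move + 1):nb, ] <- moved
    }
  }

  masks <- vector("list", nch)
  names(masks) <- nm
  for (ci in seq_len(nch)) {
    ch <- p$channels[[ci]]
    centers <- do.call(rbind, beads[[ci]])
    m <- cpp_stamp_balls(centers, d, sp, ch$bead_radius)
    masks[[ci]] <- m & nucleus
  }

  probe_masks <- NULL
  if (!is.null(p$band_probes)) {
    bp <- p$band_probes
    ci <- match(bp$channel, nm)
    ch <- p$channels[[ci]]
    probe_masks <- lapply(list(cen = bp$cen, mid = bp$mid, tel = bp$tel),
                          function(idx) {
      m <- cpp_stamp_balls(beads[[ci]][[1]][idx, , drop = FALSE], d, sp,
                           ch$bead_radius)
      m & nucleus
    })
  }

  overlap <- matrix(NA_real_, nch, nch, dimnames = list(nm, nm))
  vols <- vapply(masks, sum, 0)
  for (a in seq_len(nch)) for (b in seq_len(nch)) {
    if (a != b && vols[b] > 0) overlap[a, b] <- sum(masks[[a]] & masks[[b]]) / vols[b]
  }

  configuration <- if (!is.null(probe_masks)) {
    classify_configuration(probe_masks$cen, probe_masks$mid, probe_masks$tel)
  } else NULL

  structure(
    list(nucleus = nucleus, masks = masks, probe_masks = probe_masks,
         beads = beads, overlap = overlap, pairing = pairing,
         configuration = configuration, params = p),
    class = "ct_truth"
  )
}

#' @export
print.ct_truth <- function(x, ...) {
  cat(sprintf("<ct_truth> %s voxels, %d paint channel(s)%s\n",
              paste(dim(x$nucleus), collapse = "x"), length(x$masks),
              if (!is.null(x$probe_masks)) " + 3 band probes" else ""))
  cat("  pairing:", paste(sprintf("%s=%s", names(x$pairing), x$pairing),
                          collapse = " "), "\n")
  invisible(x)
}

#' Render a simulated nucleus as a noisy microscope stack
#'
#' Per channel: expected signal `photon_scale * mask` (the DNA channel uses
#' the nucleus mask modulated by a smooth nucleoplasm texture), convolved
#' with an anisotropic Gaussian PSF, Poisson shot noise, then Gaussian read
#' noise and a constant background offset, clipped to 16-bit. With
#' `psf_sigma = 0`, `shot_noise = FALSE` and `read_noise_sd = 0` the output
#' is exactly `photon_scale * mask + background`.
#'
#' @param truth a [simulate_cell()] result.
#' @param params the matching [sim_params()] (defaults to `truth$params`).
#' @param cell_id identifier for the output stack.
#' @return A [ct_stack()] with channels `dna`, the paint channels, and (when
#'   band probes are present) `cen`, `mid`, `tel`.
#' @export
render_microscopy <- function(truth, params = truth$params,
                              cell_id = "cell") {
  p <- validate_sim_params(params)
  if (!identical(dim(truth$nucleus), as.integer(p$grid_dim))) {
    stop("truth grids do not match params$grid_dim", call. = FALSE)
  }
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(derive_seed(p$seed, 2L))   # render substream, distinct from geometry

  sp <- p$voxel_spacing
  if (any(p$psf_sigma > 0 & p$psf_sigma < sp / 4)) {
    warning("psf_sigma below spacing/4: the PSF is undersampled by this grid")
  }
  d <- as.integer(p$grid_dim)
  sig_vox <- ifelse(p$psf_sigma > 0, p$psf_sigma / sp, 0)

  chans <- list(dna = NULL)
  for (nmi in names(truth$masks)) chans[[nmi]] <- truth$masks[[nmi]]
  if (!is.null(truth$probe_masks)) {
    for (nmi in names(truth$probe_masks)) chans[[nmi]] <- truth$probe_masks[[nmi]]
  }
  vox <- array(0, c(d, length(chans)))
  for (ci in seq_along(chans)) {
    if (names(chans)[ci] == "dna") {
      # nucleoplasm texture: smooth positive field, mean ~1; generated on a
      # 4x coarser grid and replicated (cheap, same length scale)
      dc <- pmax(d %/% 4L, 2L)
      tex <- array(runif(prod(dc)), dc)
      tex <- cpp_gaussian_blur(tex, dc, c(0.8, 0.8, 0.8))
      tex <- 1 + 0.25 * (tex - mean(tex)) / max(stats::sd(tex), 1e-12)
      tex[tex < 0.2] <- 0.2
      tex <- tex[pmin(rep(seq_len(dc[1]), each = 4L), dc[1])[seq_len(d[1])],
                 pmin(rep(seq_len(dc[2]), each = 4L), dc[2])[seq_len(d[2])],
                 pmin(rep(seq_len(dc[3]), each = 4L), dc[3])[seq_len(d[3])]]
      signal <- p$photon_scale * as.numeric(truth$nucleus) * tex
    } else {
      signal <- p$photon_scale * as.numeric(chans[[ci]])
    }
    dim(signal) <- d
    if (any(sig_vox > 0)) signal <- .blur_sparse(signal, sig_vox)
    vox[, , , ci] <- cpp_camera_noise(signal, p$read_noise_sd, p$background,
                                      p$shot_noise)
  }
  ct_stack(vox, spacing = sp, channels = names(chans), cell_id = cell_id)
}

# blur only the bounding box of the non-zero signal (plus kernel support);
# identical to a full-grid blur because the field is zero elsewhere
.blur_sparse <- function(signal, sig_vox) {
  d <- dim(signal)
  nz <- which(signal != 0)
  if (length(nz) == 0L) return(signal)
  ai <- arrayInd(nz, d)
  pad <- as.integer(ceiling(4 * sig_vox))
  lo <- pmax(apply(ai, 2, min) - pad, 1L)
  hi <- pmin(apply(ai, 2, max) + pad, d)
  sub <- signal[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub <- cpp_gaussian_blur(sub, dim(sub), sig_vox)
  out <- array(0, d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  out
}

#' Simulate a population of cells
#'
#' Cell `i` uses the seed substream `derive_seed(seed, i)`, so any cell can
#' be regenerated on its own and populations are reproducible cell-by-cell.
#'
#' @param params a [sim_params()]; its `seed` field is ignored in favour of
#'   the per-cell substream.
#' @param n_cells number of cells.
#' @param seed integer population seed.
#' @param render also render microscopy stacks?
#' @return list with `truths` and (if `render`) `stacks`; cell ids are
#'   `cell_001`, `cell_002`, ...
#' @export
simulate_population <- function(params, n_cells, seed = params$seed,
                                render = TRUE) {
  ids <- sprintf("cell_%03d", seq_len(n_cells))
  truths <- vector("list", n_cells)
  stacks <- if (render) vector("list", n_cells) else NULL
  for (i in seq_len(n_cells)) {
    pi <- params
    pi$seed <- derive_seed(seed, i)
    truths[[i]] <- simulate_cell(pi)
    if (render) stacks[[i]] <- render_microscopy(truths[[i]], cell_id = ids[i])
  }
  names(truths) <- ids
  if (render) names(stacks) <- ids
  list(truths = truths, stacks = stacks, ids = ids)
}
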