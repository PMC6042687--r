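# Independent brute-force oracles and fixture builders. Everything here
# deliberately avoids the package's compiled kernels: labelling goes through
# igraph on an explicit voxel-adjacency edge list, distances through
# exhaustive pairwise enumeration, contact through explicit 26 shifts.

# all 26 neighbour offsets
.offsets26 <- local({
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  as.matrix(g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ])
})

# shift a 3D array by (dz, dy, dx), filling with `fill`
shift3 <- function(a, dz, dy, dx, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, s) {
    if (s >= 0) list(dst = seq_len(n - s) + s, src = seq_len(n - s))
    else list(dst = seq_len(n + s), src = seq_len(n + s) - s)
  }
  z <- src(d[1], dz); y <- src(d[2], dy); x <- src(d[3], dx)
  if (length(z$dst) && length(y$dst) && length(x$dst)) {
    out[z$dst, y$dst, x$dst] <- a[z$src, y$src, x$src]
  }
  out
}

# connected-component labels via igraph (26- or 6-connectivity)
bf_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(array(0L, d))
  id <- array(0L, d)
  id[idx] <- seq_along(idx)
  offs <- if (connectivity == 26) .offsets26 else
    .offsets26[rowSums(abs(.offsets26)) == 1, , drop = FALSE]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    sh <- shift3(id, offs[r, 1], offs[r, 2], offs[r, 3], 0L)
    both <- mask & sh > 0L
    if (any(both)) edges <- rbind(edges, cbind(id[both], sh[both]))
  }
  lab <- array(0L, d)
  if (is.null(edges)) {            # all foreground voxels isolated
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp[seq_along(idx)]
  lab
}

# do two labelings define the same partition of the same foreground?
same_partition <- function(l1, l2) {
  if (!identical(l1 > 0L, l2 > 0L)) return(FALSE)
  fg <- l1 > 0L
  if (!any(fg)) return(TRUE)
  tab <- table(l1[fg], l2[fg])
  all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
}

# brute-force hysteresis: components of (img >= low) that contain a seed
bf_hysteresis <- function(img, low, high) {
  lab <- bf_label(img >= low, 26)
  seeds <- unique(lab[img >= high & lab > 0L])
  out <- array(0L, dim(img))
  keep <- lab > 0L & lab %in% seeds
  out[keep] <- match(lab[keep], sort(seeds))
  out
}

bf_overlap <- function(a, ref) sum(a & ref) / sum(ref)

bf_intermix <- function(target, others) {
  u <- Reduce(`|`, others)
  sum(target & u) / sum(target)
}

bf_contact <- function(a, b) {
  if (any(a & b)) return(TRUE)
  for (r in seq_len(nrow(.offsets26))) {
    if (any(shift3(a, .offsets26[r, 1], .offsets26[r, 2], .offsets26[r, 3]) & b)) {
      return(TRUE)
    }
  }
  FALSE
}

bf_min_dist <- function(a, b, spacing) {
  pa <- (which(a, arr.ind = TRUE) - 1) %*% diag(spacing)
  pb <- (which(b, arr.ind = TRUE) - 1) %*% diag(spacing)
  dmin <- Inf
  for (i in seq_len(nrow(pa))) {
    dmin <- min(dmin, sqrt(min(colSums((t(pb) - pa[i, ])^2))))
  }
  dmin
}

# exhaustive Otsu: best between-class-variance cut over all observed values
bf_otsu <- function(values) {
  cuts <- sort(unique(values))
  cuts <- cuts[-length(cuts)]
  bcv <- vapply(cuts, function(t) {
    lo <- values[values <= t]; hi <- values[values > t]
    length(lo) * length(hi) / length(values)^2 * (mean(hi) - mean(lo))^2
  }, 1)
  cuts[which.max(bcv)]
}

# fixture builders ----------------------------------------------------------

rand_mask <- function(dims, p = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(prod(dims)) < p, dims)
}

ball_mask <- function(r, margin = 2L) {
  n <- 2L * (r + margin) + 1L
  g <- seq_len(n) - (r + margin + 1L)
  array(outer(outer(g^2, g^2, `+`), g^2, `+`) <= r^2, c(n, n, n))
}

cuboid_mask <- function(dims, z, y, x) {
  m <- array(FALSE, dims)
  m[z, y, x] <- TRUE
  m
}

# desk-scale simulation parameters for fast unit tests
tiny_params <- function(...) {
  spec <- function(name) list(name = name, n_chains = 2L, beads_per_chain = 40L,
                              bead_radius = 0.3, step_length = 0.5)
  sim_params(
    nucleus_radii = c(1.6, 2.2, 2.2),
    grid_dim = c(32L, 64L, 64L),
    channels = list(spec("chA"), spec("chB"), spec("chC")),
    ...
  )
}
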