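# Internal 3D array utilities: shifts, separable Gaussian smoothing,
# neighbourhood extrema, connected components, flood fill.
# Arrays are indexed [z, y, x]; spacing vectors are (sz, sy, sx) in um.

.shift_axis <- function(a, axis, s) {
  # b[i] = a[clamp(i + s)] along `axis`, edge replication elsewhere
  d <- dim(a)
  idx <- pmin.int(pmax.int(seq_len(d[axis]) + s, 1L), d[axis])
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

.shift3 <- function(a, dz, dy, dx) {
  d <- dim(a)
  iz <- pmin.int(pmax.int(seq_len(d[1]) + dz, 1L), d[1])
  iy <- pmin.int(pmax.int(seq_len(d[2]) + dy, 1L), d[2])
  ix <- pmin.int(pmax.int(seq_len(d[3]) + dx, 1L), d[3])
  a[iz, iy, ix, drop = FALSE]
}

.smooth_axis <- function(a, axis, sigma_vox) {
  if (sigma_vox <= 1e-8) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  off <- seq.int(-r, r)
  w <- exp(-(off^2) / (2 * sigma_vox^2))
  w <- w / sum(w)
  out <- array(0, dim(a))
  for (k in seq_along(off)) out <- out + w[k] * .shift_axis(a, axis, off[k])
  out
}

# Separable anisotropic Gaussian; sigma_um is scalar (um), spacing (sz,sy,sx)
.gaussian_smooth <- function(a, sigma_um, spacing) {
  if (sigma_um <= 0) return(a)
  for (axis in 1:3) a <- .smooth_axis(a, axis, sigma_um / spacing[axis])
  a
}

.offsets26 <- local({
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  as.matrix(g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ])
})

.offsets6 <- matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1),
                    ncol = 3, byrow = TRUE,
                    dimnames = list(NULL, c("dz", "dy", "dx")))

# Elementwise max (or min) over the 26- or 6-neighbourhood, edge-replicated
.nbhd_extreme <- function(a, which = c("max", "min"), connectivity = 26L) {
  which <- match.arg(which)
  offs <- if (connectivity == 26L) .offsets26 else .offsets6
  out <- a
  f <- if (which == "max") pmax else pmin
  for (i in seq_len(nrow(offs)))
    out <- f(out, .shift3(a, offs[i, 1], offs[i, 2], offs[i, 3]))
  out
}

# Connected components of a sparse logical mask (26- or 6-connectivity).
# Returns list(index = linear indices of TRUE voxels, label = component id).
.cc_sparse <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  pos <- which(mask)
  n <- length(pos)
  if (n == 0L) return(list(index = integer(0), label = integer(0)))
  lab <- array(0L, d)
  lab[pos] <- seq_len(n)
  ai <- arrayInd(pos, d)
  offs <- if (connectivity == 26L) .offsets26 else .offsets6
  keep <- offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
    (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0)  # half the offsets
  offs <- offs[keep, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(offs))) {
    ni <- cbind(ai[, 1] + offs[i, 1], ai[, 2] + offs[i, 2], ai[, 3] + offs[i, 3])
    ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] & ni[, 2] >= 1 & ni[, 2] <= d[2] &
      ni[, 3] >= 1 & ni[, 3] <= d[3]
    if (!any(ok)) next
    nb <- lab[ni[ok, , drop = FALSE]]
    hit <- nb > 0L
    if (any(hit)) {
      from <- c(from, which(ok)[hit])
      to <- c(to, nb[hit])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  list(index = pos, label = as.integer(memb))
}

# Region growing from seed linear indices, restricted to mask (6-connectivity)
.flood <- function(mask, seed_lin) {
  reg <- array(FALSE, dim(mask))
  reg[seed_lin] <- mask[seed_lin]
  repeat {
    grown <- reg
    for (i in seq_len(nrow(.offsets6)))
      grown <- grown | .shift3(reg, .offsets6[i, 1], .offsets6[i, 2], .offsets6[i, 3])
    grown <- grown & mask
    if (identical(grown, reg)) break
    reg <- grown
  }
  reg
}

# Fill interior cavities: complement voxels not reachable from the border
.fill_holes <- function(mask) {
  d <- dim(mask)
  comp <- !mask
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  seeds <- which(comp & border)
  if (length(seeds) == 0L) return(mask)
  outside <- .flood(comp, seeds)
  mask | (comp & !outside)
}

.weighted_centroid_zyx <- function(idx_zyx, w) {
  w <- w / sum(w)
  c(sum(idx_zyx[, 1] * w), sum(idx_zyx[, 2] * w), sum(idx_zyx[, 3] * w))
}
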