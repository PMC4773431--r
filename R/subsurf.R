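#' Parameters for subjective-surface segmentation
#'
#' The segmentation function evolves under
#' `u_t = w_d |grad u|_eps div( g grad u / |grad u|_eps ) + w_c grad g . grad u`,
#' an edge-stopped diffusion (weight `w_d`) plus an advection that attracts
#' level sets towards edges (weight `w_c`). The conductance `g` is the edge
#' indicator of the image: `g = 1/(1 + K |grad G_sigma * I|^2)` for nucleus
#' and embryo targets, `g = 1/(1 + K (G_sigma * I)^2)` for membrane targets
#' (the membrane signal itself marks the boundary).
#'
#' @param eps regularization of `|grad u|` (> 0); large values put the flow
#'   in its diffusion-dominated "graph" regime, which lets the function
#'   flood regions bounded by edges and complete missing contour parts.
#' @param w_c convection weight (>= 0).
#' @param w_d diffusion weight (>= 0).
#' @param K edge-indicator coefficient (same semantics as in
#'   [gmcf_params()]).
#' @param g_sigma pre-smoothing (um) applied to the image before computing
#'   the edge indicator.
#' @param n_iter number of explicit steps (>= 1).
#' @param tau step size; `NULL` picks a stability-bounded default.
#' @param iso_fraction fraction of `max(u)` defining the output mask, in
#'   `(0, 1)` (default 0.5).
#' @param seed_width h (um) of the initial peak
#'   `u0 = 1/(1 + (|x - seed|/h)^2)`; the squared decay keeps the exterior
#'   tail low so the relative threshold cleanly separates object from
#'   background.
#' @return An object of class `subsurf_params`.
#' @export
subsurf_params <- function(eps = 1, w_c = 2, w_d = 1, K = 50, g_sigma = 1,
                           n_iter = 200L, tau = NULL, iso_fraction = 0.5,
                           seed_width = 5) {
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (iso_fraction <= 0 || iso_fraction >= 1)
    stop("iso_fraction must be in (0, 1)", call. = FALSE)
  structure(list(eps = eps, w_c = w_c, w_d = w_d, K = K, g_sigma = g_sigma,
                 n_iter = as.integer(n_iter), tau = tau,
                 iso_fraction = iso_fraction, seed_width = seed_width),
            class = "subsurf_params")
}

#' Construct a segmentation mask
#'
#' @param mask logical 3D array, same geometry as the source grid.
#' @param spacing voxel size `(sz, sy, sx)` um.
#' @param label `"nucleus"`, `"cell"` or `"embryo"`.
#' @param seed_centre_id optional id of the seeding centre.
#' @param border_touch `TRUE` if the mask touches the image border.
#' @return An object of class `segmentation_mask` with the physical volume
#'   (um^3) precomputed.
#' @export
segmentation_mask <- function(mask, spacing, label = "nucleus",
                              seed_centre_id = NA_integer_,
                              border_touch = FALSE) {
  structure(list(mask = mask, spacing = spacing, label = label,
                 seed_centre_id = seed_centre_id, border_touch = border_touch,
                 volume_um3 = sum(mask) * prod(spacing)),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> label=%s, %d voxels, volume %.1f um^3%s\n",
              x$label, sum(x$mask), x$volume_um3,
              if (x$border_touch) " (touches border)" else ""))
  invisible(x)
}

.touches_border <- function(mask) {
  d <- dim(mask)
  any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) || any(mask[, , c(1, d[3])])
}

# Core evolution shared by per-object and whole-embryo segmentation.
.subsurf_run <- function(grid, seed_pos, params, target) {
  .check_pde_grid(grid)
  h <- grid$spacing
  d <- dim(grid$values)
  img_s <- .gaussian_smooth(grid$values, params$g_sigma, h)
  g <- if (target == "membrane") {
    edge_indicator(img_s, params$K)
  } else {
    edge_indicator(.grad_mag_central(img_s, h), params$K)
  }
  gg <- .grad_central(g, h)
  # initial segmentation function: radially decreasing peak at the seed
  cz <- .axis_coords(d[1], h[1]); cy <- .axis_coords(d[2], h[2]); cx <- .axis_coords(d[3], h[3])
  rz <- (cz - seed_pos[3])^2
  ry <- (cy - seed_pos[2])^2
  rx <- (cx - seed_pos[1])^2
  r <- sqrt(outer(outer(rz, ry, `+`), rx, `+`))
  u <- 1 / (1 + (r / params$seed_width)^2)
  tau <- params$tau
  if (is.null(tau)) {
    tau_d <- .default_tau(h, coef = max(params$w_d, 1e-12))
    vmax <- max(params$w_c * sqrt(gg$gz^2 + gg$gy^2 + gg$gx^2), 1e-12)
    tau_a <- 0.5 * min(h) / vmax
    tau <- min(tau_d, tau_a)
  }
  for (it in seq_len(params$n_iter)) {
    upd <- 0
    if (params$w_d != 0)
      upd <- params$w_d * .curvature_flow_update(u, g, h, params$eps)
    if (params$w_c != 0)
      upd <- upd + .advect_upwind(u, params$w_c * gg$gz, params$w_c * gg$gy,
                                  params$w_c * gg$gx, h)
    u_new <- u + tau * upd
    .check_finite(u_new, "subsurf")
    u <- .limit_update(u, u_new)
  }
  u
}

.mask_from_function <- function(u, grid, seed_pos, iso_fraction, label,
                                seed_id = NA_integer_) {
  mask <- u >= iso_fraction * max(u)
  seed_lin <- sum((.pos_to_rindex(seed_pos, grid) - c(1L, 1L, 1L)) *
                    c(1L, dim(u)[1], dim(u)[1] * dim(u)[2])) + 1L
  if (!mask[seed_lin]) {
    # fall back to the nearest above-threshold voxel of the component
    stop("segmentation produced an empty mask at the seed", call. = FALSE)
  }
  mask <- .flood(mask, seed_lin)
  mask <- .fill_holes(mask)
  if (!any(mask)) stop("empty segmentation mask", call. = FALSE)
  bt <- .touches_border(mask)
  if (bt) warning("segmentation mask touches the image border")
  segmentation_mask(mask, grid$spacing, label = label, seed_centre_id = seed_id,
                    border_touch = bt)
}

#' Segment one object by subjective-surface evolution
#'
#' A peaked segmentation function is planted at the seed centre and evolved
#' under the edge-stopped diffusion--advection flow; the mask is the
#' connected component containing the seed of
#' `{u >= iso_fraction * max(u)}`, with interior holes filled.
#'
#' @param grid the [voxel_grid()] of the channel matching the target
#'   (nuclei for nucleus shapes, membranes for cell shapes).
#' @param seed a single-row [centre_set()] / data.frame with `x, y, z` (um),
#'   or a numeric `(x, y, z)` vector; must lie inside the grid.
#' @param params a [subsurf_params()].
#' @param target `"nucleus"`, `"membrane"` (cell body bounded by membrane
#'   signal) -- selects how the edge indicator is computed.
#' @return A [segmentation_mask()]; a warning flag is set if the mask
#'   touches the image border.
#' @export
subsurf_evolve <- function(grid, seed, params = subsurf_params(),
                           target = c("nucleus", "membrane")) {
  target <- match.arg(target)
  if (is.data.frame(seed)) {
    seed_pos <- c(seed$x[1], seed$y[1], seed$z[1])
    seed_id <- if (!is.null(seed$id)) seed$id[1] else NA_integer_
  } else {
    seed_pos <- as.numeric(seed); seed_id <- NA_integer_
  }
  ext <- dim(grid$values)[c(3, 2, 1)] * grid$spacing[c(3, 2, 1)]
  if (any(seed_pos < 0) || any(seed_pos > ext))
    stop("seed lies outside the grid", call. = FALSE)
  u <- .subsurf_run(grid, seed_pos, params, target)
  label <- if (target == "membrane") "cell" else "nucleus"
  .mask_from_function(u, grid, seed_pos, params$iso_fraction, label, seed_id)
}

#' Segment the whole embryo volume
#'
#' The same subjective-surface flow, seeded at the intensity centroid of a
#' strongly pre-smoothed nucleus channel so that the tissue appears as one
#' bright mass. Because the object spans the whole field of view, the
#' evolution runs on a block-averaged coarse grid (`downsample` voxels per
#' cell per axis) where the diffusion can traverse the tissue in a few
#' hundred steps; the mask is then upsampled back to the input geometry.
#' The reported volume (um^3) supports cell-density estimates.
#'
#' @param grid a nucleus-channel [voxel_grid()].
#' @param params a [subsurf_params()]; embryo-scale defaults are
#'   `K = 20`, `g_sigma = 8` um (of the order of the internuclear distance,
#'   so individual nuclei merge into one tissue-scale region),
#'   `seed_width = 20` um and `n_iter = 400`.
#' @param downsample integer block size for the coarse grid (default 3).
#' @return A [segmentation_mask()] with `label = "embryo"` in the input
#'   geometry.
#' @export
segment_embryo <- function(grid, params = NULL, downsample = 3L) {
  if (max(grid$values) <= 0) stop("empty (zero) frame", call. = FALSE)
  if (is.null(params))
    params <- subsurf_params(K = 20, g_sigma = 8, seed_width = 20,
                             n_iter = 400L)
  f <- as.integer(downsample)
  cg <- if (f > 1L)
    voxel_grid(.block_average(grid$values, f), grid$spacing * f,
               t = grid$t, channel = grid$channel)
  else grid
  d <- dim(cg$values)
  w <- cg$values / sum(cg$values)
  cz <- sum(apply(w, 1, sum) * seq_len(d[1]))
  cy <- sum(apply(w, 2, sum) * seq_len(d[2]))
  cx <- sum(apply(w, 3, sum) * seq_len(d[3]))
  seed_pos <- to_physical(c(cz, cy, cx) - 1, cg$spacing)
  u <- .subsurf_run(cg, seed_pos, params, target = "nucleus")
  mk <- .mask_from_function(u, cg, seed_pos, params$iso_fraction, "embryo")
  if (f == 1L) return(mk)
  # upsample the coarse mask to the input geometry
  d0 <- dim(grid$values)
  iz <- pmin((seq_len(d0[1]) - 1L) %/% f + 1L, d[1])
  iy <- pmin((seq_len(d0[2]) - 1L) %/% f + 1L, d[2])
  ix <- pmin((seq_len(d0[3]) - 1L) %/% f + 1L, d[3])
  segmentation_mask(mk$mask[iz, iy, ix], grid$spacing, label = "embryo",
                    border_touch = mk$border_touch)
}

# Block-average an array by an integer factor per axis (edge replication on
# the ragged remainder)
.block_average <- function(a, f) {
  d <- dim(a)
  d2 <- as.integer(ceiling(d / f))
  pad <- d2 * f
  a <- a[c(seq_len(d[1]), rep(d[1], pad[1] - d[1])),
         c(seq_len(d[2]), rep(d[2], pad[2] - d[2])),
         c(seq_len(d[3]), rep(d[3], pad[3] - d[3])), drop = FALSE]
  out <- array(0, d2)
  for (i in 0:(f - 1L)) for (j in 0:(f - 1L)) for (k in 0:(f - 1L))
    out <- out + a[seq.int(1L + i, pad[1], by = f),
                   seq.int(1L + j, pad[2], by = f),
                   seq.int(1L + k, pad[3], by = f)]
  out / f^3
}

#' Cell count and density inside a segmented volume
#'
#' @param centres a [centre_set()] (one time step).
#' @param embryo_mask a [segmentation_mask()] with positive volume.
#' @return list with `count` (centres inside the mask) and `density`
#'   (cells per um^3).
#' @export
cell_density <- function(centres, embryo_mask) {
  if (embryo_mask$volume_um3 <= 0) stop("zero-volume mask", call. = FALSE)
  d <- dim(embryo_mask$mask)
  inside <- vapply(seq_len(nrow(centres)), function(i) {
    idx <- .pos_to_rindex(c(centres$x[i], centres$y[i], centres$z[i]),
                          list(values = embryo_mask$mask, spacing = embryo_mask$spacing))
    embryo_mask$mask[idx[1], idx[2], idx[3]]
  }, logical(1))
  # positions outside the array bounds were clamped; reject them explicitly
  ext <- d[c(3, 2, 1)] * embryo_mask$spacing[c(3, 2, 1)]
  inb <- centres$x >= 0 & centres$x <= ext[1] &
    centres$y >= 0 & centres$y <= ext[2] &
    centres$z >= 0 & centres$z <= ext[3]
  count <- sum(inside & inb)
  list(count = count, density = count / embryo_mask$volume_um3)
}

#' Write a segmentation mask as an 8-bit TIFF stack
#'
#' Foreground voxels are stored as 255, background as 0, aligned to the
#' source grid geometry (one page per z-slice).
#'
#' @param mask a [segmentation_mask()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  pages <- lapply(seq_len(dim(mask$mask)[1]), function(z)
    mask$mask[z, , ] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}
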