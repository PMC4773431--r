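# Shared explicit finite-difference machinery for the level-set PDEs
# (geodesic mean curvature flow, flux-based level-set simplification,
# subjective-surface segmentation). All operators honour anisotropic voxel
# spacing h = (hz, hy, hx) in um and zero-flux (reflective) boundaries, which
# arise automatically from edge replication in the shift operators.

.grad_central <- function(u, h) {
  list(
    gz = (.shift_axis(u, 1L, 1L) - .shift_axis(u, 1L, -1L)) / (2 * h[1]),
    gy = (.shift_axis(u, 2L, 1L) - .shift_axis(u, 2L, -1L)) / (2 * h[2]),
    gx = (.shift_axis(u, 3L, 1L) - .shift_axis(u, 3L, -1L)) / (2 * h[3])
  )
}

.grad_mag_central <- function(u, h) {
  g <- .grad_central(u, h)
  sqrt(g$gz^2 + g$gy^2 + g$gx^2)
}

# One explicit step of u_t = |grad u|_eps div( g * grad u / |grad u|_eps ),
# returned as the raw update (to be scaled by tau). g is a conductance field
# in (0,1]. eps is the Evans-Spruck regularization, in intensity/um units.
.curvature_flow_update <- function(u, g, h, eps) {
  q <- sqrt(.grad_mag_central(u, h)^2 + eps^2)
  upd <- array(0, dim(u))
  for (axis in 1:3) {
    dplus <- (.shift_axis(u, axis, 1L) - u) / h[axis]       # gradient at upper face
    gf <- 0.5 * (g + .shift_axis(g, axis, 1L))
    qf <- 0.5 * (q + .shift_axis(q, axis, 1L))
    fplus <- gf * dplus / qf                                # flux through upper face
    fminus <- .shift_axis(fplus, axis, -1L)                 # flux through lower face
    upd <- upd + (fplus - fminus) / h[axis]
  }
  q * upd
}

# Osher-Sethian upwind gradient magnitude for u_t + delta |grad u| = 0,
# delta > 0 (level sets of bright objects shrink).
.upwind_grad_plus <- function(u, h) {
  acc <- array(0, dim(u))
  for (axis in 1:3) {
    dminus <- (u - .shift_axis(u, axis, -1L)) / h[axis]
    dplus <- (.shift_axis(u, axis, 1L) - u) / h[axis]
    acc <- acc + pmax(dminus, 0)^2 + pmin(dplus, 0)^2
  }
  sqrt(acc)
}

# Upwind discretization of the advection term  v . grad u  (v given per axis):
# information is taken from the side the characteristics come from.
.advect_upwind <- function(u, vz, vy, vx, h) {
  out <- array(0, dim(u))
  vs <- list(vz, vy, vx)
  for (axis in 1:3) {
    v <- vs[[axis]]
    dminus <- (u - .shift_axis(u, axis, -1L)) / h[axis]
    dplus <- (.shift_axis(u, axis, 1L) - u) / h[axis]
    out <- out + ifelse(v > 0, v * dplus, v * dminus)
  }
  out
}

# Monotone limiter: clamp the updated field into the local 6-neighbourhood
# range of the previous iterate. Guarantees the discrete maximum principle
# (global extrema can never amplify) for every scheme built on it.
.limit_update <- function(u_old, u_new) {
  lo <- .nbhd_extreme(u_old, "min", 6L)
  hi <- .nbhd_extreme(u_old, "max", 6L)
  pmin(pmax(u_new, lo), hi)
}

.check_finite <- function(u, stage) {
  if (!all(is.finite(u)))
    stop(sprintf("%s produced non-finite values: the explicit scheme is unstable; reduce tau", stage),
         call. = FALSE)
  invisible(u)
}

# Conservative default explicit step size for curvature/diffusion terms
.default_tau <- function(h, coef = 1) {
  0.2 / (coef * sum(1 / h^2))
}
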