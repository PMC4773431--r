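#' Parameters for geodesic mean curvature flow filtering
#'
#' @param K edge-sensitivity coefficient of the edge indicator
#'   `g(s) = 1 / (1 + K s^2)` (>= 0; units 1/(intensity/um)^2). `K = 0`
#'   reduces the flow to pure mean curvature motion of the level sets.
#' @param sigma_pre standard deviation (um) of the Gaussian `G_sigma` that
#'   pre-smooths the intensity gradient before the edge indicator is applied.
#' @param n_iter number of explicit PDE steps (default 5).
#' @param tau step size in scheme units; `NULL` chooses a stability-bounded
#'   default `0.2 / sum(1 / h^2)` from the voxel spacing `h`.
#' @return An object of class `gmcf_params`.
#' @export
gmcf_params <- function(K = 0.01, sigma_pre = 1, n_iter = 5L, tau = NULL) {
  if (K < 0) stop("K must be >= 0", call. = FALSE)
  if (sigma_pre < 0) stop("sigma_pre must be >= 0", call. = FALSE)
  if (n_iter < 0) stop("n_iter must be >= 0", call. = FALSE)
  if (!is.null(tau) && tau <= 0) stop("tau must be > 0", call. = FALSE)
  structure(list(K = K, sigma_pre = sigma_pre, n_iter = as.integer(n_iter),
                 tau = tau), class = "gmcf_params")
}

#' Edge indicator function
#'
#' `g(s) = 1 / (1 + K s^2)`: equals 1 on flat regions and decreases towards
#' 0 with increasing gradient magnitude, so that the curvature flow slows
#' down (preserves) strong edges.
#'
#' @param s nonnegative gradient magnitude(s).
#' @param K edge-sensitivity coefficient (>= 0).
#' @return Values in `(0, 1]`.
#' @export
edge_indicator <- function(s, K) {
  if (any(s < 0)) stop("s must be >= 0", call. = FALSE)
  if (K < 0) stop("K must be >= 0", call. = FALSE)
  1 / (1 + K * s^2)
}

#' Denoise an image by geodesic mean curvature flow
#'
#' Evolves the intensity field under edge-stopped level-set mean curvature
#' motion, `u_t = |grad u|_eps div( g(|grad G_sigma * u|) grad u / |grad
#' u|_eps )`, which smooths homogeneous regions while preserving and
#' sharpening edges. The explicit scheme uses zero-flux boundaries, the
#' regularization `|grad u|_eps = sqrt(|grad u|^2 + eps^2)` with
#' `eps = 1e-4 * intensity range`, and a monotone limiter that enforces the
#' discrete maximum principle: output values never leave the input range.
#'
#' @param grid a [voxel_grid()] (>= 3 voxels per axis).
#' @param params a [gmcf_params()].
#' @return A filtered `voxel_grid` (same geometry); attribute
#'   `extrema_log` records the per-iteration global min/max.
#' @export
gmcf_filter <- function(grid, params = gmcf_params()) {
  .check_pde_grid(grid)
  u <- grid$values
  h <- grid$spacing
  tau <- if (is.null(params$tau)) .default_tau(h) else params$tau
  eps <- 1e-4 * max(diff(range(u)), 1e-12)
  log <- data.frame(iter = 0L, min = min(u), max = max(u))
  if (params$n_iter > 0) for (it in seq_len(params$n_iter)) {
    us <- .gaussian_smooth(u, params$sigma_pre, h)
    g <- edge_indicator(.grad_mag_central(us, h), params$K)
    u_new <- u + tau * .curvature_flow_update(u, g, h, eps)
    .check_finite(u_new, "gmcf_filter")
    u <- .limit_update(u, u_new)
    log <- rbind(log, data.frame(iter = it, min = min(u), max = max(u)))
  }
  out <- voxel_grid(u, h, t = grid$t, channel = grid$channel)
  attr(out, "extrema_log") <- log
  out
}
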