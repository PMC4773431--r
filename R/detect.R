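#' Construct a centre set
#'
#' Detected nucleus centres at one time step: continuous physical positions
#' in micrometres.
#'
#' @param x,y,z numeric positions (um).
#' @param t time index (recycled).
#' @param id integer ids (default sequential).
#' @param intensity detection intensity (>= 0).
#' @param virtual logical; `TRUE` only for tracker-inserted centres.
#' @return data.frame of class `centre_set` with columns
#'   `id, t, x, y, z, intensity, virtual`.
#' @export
centre_set <- function(x, y, z, t = 0L, id = seq_along(x), intensity = 0,
                       virtual = FALSE) {
  n <- length(x)
  df <- data.frame(id = as.integer(rep_len(id, n)), t = as.integer(rep_len(t, n)),
                   x = x, y = y, z = z,
                   intensity = rep_len(intensity, n),
                   virtual = rep_len(virtual, n))
  class(df) <- c("centre_set", "data.frame")
  df
}

.empty_centres <- function(t = 0L) centre_set(numeric(0), numeric(0), numeric(0),
                                              t = integer(0), id = integer(0),
                                              intensity = numeric(0),
                                              virtual = logical(0))

#' Parameters for flux-based level-set centre detection
#'
#' The evolving intensity function moves its isosurfaces with normal
#' velocity `V = delta + mu k` (`k` the mean curvature): all level sets
#' shrink and smooth, so spurious maxima vanish while nucleus humps survive
#' as isolated local maxima.
#'
#' @param delta constant normal-velocity component (um per scheme time
#'   unit); positive values shrink the level sets of bright objects.
#' @param mu curvature-velocity coefficient.
#' @param n_iter number of explicit steps (>= 1).
#' @param tau step size; `NULL` picks a stability-bounded default.
#' @param intensity_floor fraction of the frame maximum in `[0, 1)` below
#'   which local maxima are discarded.
#' @return An object of class `fbls_params`.
#' @export
fbls_params <- function(delta = 0.5, mu = 1, n_iter = 10L, tau = NULL,
                        intensity_floor = 0.1) {
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (intensity_floor < 0 || intensity_floor >= 1)
    stop("intensity_floor must be in [0, 1)", call. = FALSE)
  structure(list(delta = delta, mu = mu, n_iter = as.integer(n_iter), tau = tau,
                 intensity_floor = intensity_floor), class = "fbls_params")
}

#' Simplify an image by flux-based level-set evolution
#'
#' Advection--diffusion evolution `u_t = -delta |grad u| + mu |grad u|_eps
#' div(grad u / |grad u|_eps)`: every level set moves inward with speed
#' `delta + mu k`. The advection term uses the Osher--Sethian upwind
#' gradient; the curvature term shares the regularized scheme of
#' [gmcf_filter()]; a monotone limiter enforces the maximum principle.
#'
#' @param grid a filtered nucleus-channel [voxel_grid()].
#' @param params an [fbls_params()].
#' @return The simplified `voxel_grid`.
#' @export
fbls_smooth <- function(grid, params = fbls_params()) {
  .check_pde_grid(grid)
  u <- grid$values
  h <- grid$spacing
  mu <- params$mu; delta <- params$delta
  tau <- params$tau
  if (is.null(tau)) {
    tau_d <- .default_tau(h, coef = max(mu, 1e-12))
    tau_a <- 0.5 * min(h) / max(abs(delta), 1e-12)
    tau <- min(tau_d, tau_a)
  }
  eps <- 1e-4 * max(diff(range(u)), 1e-12)
  g1 <- array(1, dim(u))
  for (it in seq_len(params$n_iter)) {
    upd <- 0
    if (mu != 0) upd <- mu * .curvature_flow_update(u, g1, h, eps)
    if (delta != 0) upd <- upd - delta * .upwind_grad_plus(u, h)
    u_new <- u + tau * upd
    .check_finite(u_new, "fbls_smooth")
    u <- .limit_update(u, u_new)
  }
  voxel_grid(u, h, t = grid$t, channel = grid$channel)
}

#' Extract local intensity maxima as candidate nucleus centres
#'
#' A voxel is a candidate if it is >= all of its 26 neighbours and exceeds
#' `intensity_floor * max(frame)`. Connected plateaus of equal-valued maxima
#' are merged to a single centre at the plateau centroid. Positions are
#' returned in physical micrometres (centre-of-voxel convention).
#'
#' @param grid a [voxel_grid()].
#' @param intensity_floor fraction of the frame maximum in `[0, 1)`.
#' @return A [centre_set()] (possibly empty).
#' @export
extract_local_maxima <- function(grid, intensity_floor = 0) {
  u <- grid$values
  floorv <- intensity_floor * max(u)
  cand <- (u >= .nbhd_extreme(u, "max", 26L)) & (u > floorv)
  if (!any(cand)) return(.empty_centres(grid$t))
  cc <- .cc_sparse(cand, 26L)
  ai <- arrayInd(cc$index, dim(u))
  ints <- u[cc$index]
  pos <- t(vapply(sort(unique(cc$label)), function(l) {
    sel <- cc$label == l
    ctr <- .weighted_centroid_zyx(ai[sel, , drop = FALSE], rep(1, sum(sel)))
    c(to_physical(ctr - 1, grid$spacing), max(ints[sel]))
  }, numeric(4)))
  centre_set(pos[, 1], pos[, 2], pos[, 3], t = grid$t, intensity = pos[, 4])
}

#' Parameters for difference-of-Gaussians centre detection
#'
#' Suited to low-density, high-contrast data: nuclei appear as isolated
#' blobs whose band-pass response is well separated.
#'
#' @param sigma_small standard deviation (um) of the narrow Gaussian
#'   (default 2.0, sensible range 1.5--2.5).
#' @param sigma_large standard deviation (um) of the wide Gaussian (default
#'   14.0, sensible range 12--16).
#' @param threshold_pct percent of the maximum response kept (default 5,
#'   sensible range 1--10).
#' @return An object of class `dog_params`.
#' @export
dog_params <- function(sigma_small = 2, sigma_large = 14, threshold_pct = 5) {
  if (!(sigma_small > 0 && sigma_small < sigma_large))
    stop("need 0 < sigma_small < sigma_large", call. = FALSE)
  if (threshold_pct <= 0 || threshold_pct >= 100)
    stop("threshold_pct must be in (0, 100)", call. = FALSE)
  structure(list(sigma_small = sigma_small, sigma_large = sigma_large,
                 threshold_pct = threshold_pct), class = "dog_params")
}

#' Detect nucleus centres by difference of Gaussians
#'
#' The response `G_small * u - G_large * u` is thresholded at
#' `threshold_pct`% of its maximum (a scale-free, per-frame reference:
#' detection is equivariant to intensity rescaling); each 26-connected
#' component above threshold yields one centre at its response-weighted
#' centroid.
#'
#' @param grid a nucleus-channel [voxel_grid()].
#' @param params a [dog_params()].
#' @return A [centre_set()]; empty (with a warning) if the response is
#'   nowhere positive.
#' @export
dog_detect <- function(grid, params = dog_params()) {
  u <- grid$values
  resp <- .gaussian_smooth(u, params$sigma_small, grid$spacing) -
    .gaussian_smooth(u, params$sigma_large, grid$spacing)
  m <- max(resp)
  if (m <= 0) {
    warning("DoG response is nowhere positive; returning empty centre set")
    return(.empty_centres(grid$t))
  }
  mask <- resp > (params$threshold_pct / 100) * m
  cc <- .cc_sparse(mask, 26L)
  ai <- arrayInd(cc$index, dim(u))
  w <- resp[cc$index]
  pos <- t(vapply(sort(unique(cc$label)), function(l) {
    sel <- cc$label == l
    ctr <- .weighted_centroid_zyx(ai[sel, , drop = FALSE], w[sel])
    c(to_physical(ctr - 1, grid$spacing), max(w[sel]))
  }, numeric(4)))
  centre_set(pos[, 1], pos[, 2], pos[, 3], t = grid$t, intensity = pos[, 4])
}

#' Score DoG parameter combinations against a gold standard
#'
#' Grid-scans `sigma_small`, `sigma_large` and `threshold_pct`, scoring each
#' combination by centre-detection sensitivity and false-detection rate
#' against curated centres at the same time step. This replaces interactive
#' visual parameter picking with a quantitative scan.
#'
#' @param grid a nucleus-channel [voxel_grid()].
#' @param gold_centres a [centre_set()] of curated centres at `grid$t`.
#' @param sigma_small,sigma_large,threshold_pct numeric vectors of candidate
#'   values.
#' @param r_factor matching radius as a fraction of the mean internuclear
#'   distance (default 0.5).
#' @return data.frame with one row per combination: parameters, TP, FP, FN,
#'   sensitivity and false-detection rate, sorted by decreasing sensitivity
#'   then increasing false-detection rate.
#' @export
dog_parameter_scan <- function(grid, gold_centres,
                               sigma_small = c(1.5, 2, 2.5),
                               sigma_large = c(12, 14, 16),
                               threshold_pct = c(1, 5, 10),
                               r_factor = 0.5) {
  combos <- expand.grid(sigma_small = sigma_small, sigma_large = sigma_large,
                        threshold_pct = threshold_pct)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    p <- dog_params(combos$sigma_small[i], combos$sigma_large[i],
                    combos$threshold_pct[i])
    det <- suppressWarnings(dog_detect(grid, p))
    mc <- match_centres(det, gold_centres, r_factor = r_factor)
    cbind(combos[i, ], TP = mc$counts$TP, FP = mc$counts$FP, FN = mc$counts$FN,
          sensitivity = mc$counts$TP / max(mc$counts$TP + mc$counts$FN, 1),
          false_detection_rate = mc$counts$FP / max(mc$counts$TP + mc$counts$FP, 1))
  })
  out <- do.call(rbind, res)
  out[order(-out$sensitivity, out$false_detection_rate), ]
}

#' Detect centres with either method
#'
#' @param grid a nucleus-channel [voxel_grid()] (already filtered for FBLS).
#' @param method `"fbls"` or `"dog"`.
#' @param params an [fbls_params()] or [dog_params()] matching `method`.
#' @return A [centre_set()].
#' @export
detect_centres <- function(grid, method = c("fbls", "dog"), params = NULL) {
  method <- match.arg(method)
  if (method == "fbls") {
    if (is.null(params)) params <- fbls_params()
    sm <- fbls_smooth(grid, params)
    extract_local_maxima(sm, params$intensity_floor)
  } else {
    if (is.null(params)) params <- dog_params()
    dog_detect(grid, params)
  }
}
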