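#' Configuration of the synthetic embryo generator
#'
#' The generator emulates the imaging regime of early-embryo nuclear
#' time-lapse recordings: hundreds of nuclei rendered as bright Gaussian
#' blobs over a dim background, coherent motion with a stochastic
#' component, cell divisions, no cell death, and signal-to-noise degrading
#' with imaging depth. Defaults describe a late-gastrulation-like field of
#' 100 cells followed for 30 frames at roughly one-minute intervals.
#'
#' @param n_cells_initial starting cell count.
#' @param n_frames number of frames (>= 2).
#' @param box_size physical field of view `(x, y, z)` in um.
#' @param domain `"box"` (cells fill the field of view) or `"ball"` (cells
#'   confined to the inscribed ellipsoid, giving the rendered tissue a
#'   compact embryo-like outline for whole-volume segmentation).
#' @param spacing voxel size `(sz, sy, sx)` um.
#' @param drift coherent drift velocity `(x, y, z)` um/frame.
#' @param walk_sd isotropic random-walk standard deviation, um/frame.
#' @param swirl amplitude of an optional rotational (xy-swirl) velocity
#'   field, um/frame at the box edge (0 disables).
#' @param division_prob_per_frame per-eligible-cell division probability per
#'   frame.
#' @param min_division_interval refractory period in frames: a newborn
#'   daughter cannot divide again before this many frames have passed
#'   (cells cannot re-divide within minutes; the default, 30 frames at the
#'   default 67 s interval, is a conservative lower bound on the cell-cycle
#'   length of the emulated stages).
#' @param min_separation soft-repulsion target distance between nuclei
#'   (um); each frame, overlapping pairs are pushed apart in two passes,
#'   each removing a quarter of the remaining overlap per cell (newborn
#'   sister nuclei are subject to the same exclusion from their first
#'   frame).
#' @param nucleus_sigma Gaussian blob standard deviation (um).
#' @param peak_intensity blob peak above background, camera counts.
#' @param background background level, camera counts.
#' @param noise_sd Gaussian noise standard deviation, counts.
#' @param depth_attenuation fractional signal loss per um of depth (applied
#'   as `exp(-depth_attenuation * z)` to blob peaks).
#' @param membrane_shell also render a membrane channel of bright shells of
#'   radius `1.8 * nucleus_sigma` around each centre.
#' @param dt_seconds frame interval (s), metadata only.
#' @param seed RNG seed; simulation and rendering are bit-reproducible.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells_initial = 100L, n_frames = 30L,
                             box_size = c(110, 110, 55),
                             domain = c("box", "ball"),
                             spacing = c(1.37, 1.37, 1.37),
                             drift = c(0.4, 0.2, 0.1), walk_sd = 0.5,
                             swirl = 0,
                             division_prob_per_frame = 0.01,
                             min_division_interval = 30L,
                             min_separation = 8, nucleus_sigma = 2,
                             peak_intensity = 100, background = 10,
                             noise_sd = 4, depth_attenuation = 0.003,
                             membrane_shell = FALSE, dt_seconds = 67,
                             seed = 1L) {
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (min_separation <= 0) stop("min_separation must be > 0", call. = FALSE)
  if (division_prob_per_frame < 0 || division_prob_per_frame > 1)
    stop("division_prob_per_frame must be in [0, 1]", call. = FALSE)
  domain <- match.arg(domain)
  structure(list(n_cells_initial = as.integer(n_cells_initial),
                 n_frames = as.integer(n_frames), box_size = box_size,
                 domain = domain,
                 spacing = spacing, drift = drift, walk_sd = walk_sd,
                 swirl = swirl,
                 division_prob_per_frame = division_prob_per_frame,
                 min_division_interval = as.integer(min_division_interval),
                 min_separation = min_separation,
                 nucleus_sigma = nucleus_sigma,
                 peak_intensity = peak_intensity, background = background,
                 noise_sd = noise_sd, depth_attenuation = depth_attenuation,
                 membrane_shell = membrane_shell, dt_seconds = dt_seconds,
                 seed = as.integer(seed)), class = "synthetic_config")
}

.repel <- function(P, config, passes = 2L) {
  min_sep <- config$min_separation
  n <- nrow(P)
  if (n < 2L) return(P)
  for (pass in seq_len(passes)) {
    D <- as.matrix(stats::dist(P))
    diag(D) <- Inf
    pairs <- which(D < min_sep & upper.tri(D), arr.ind = TRUE)
    if (!nrow(pairs)) break
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      d <- sqrt(sum((P[i, ] - P[j, ])^2))
      dir <- if (d > 1e-9) (P[i, ] - P[j, ]) / d else c(1, 0, 0)
      push <- (min_sep - d) / 4
      P[i, ] <- P[i, ] + push * dir
      P[j, ] <- P[j, ] - push * dir
    }
    P <- .clamp_domain(P, config)
  }
  P
}

.clamp_box <- function(P, box) {
  for (a in 1:3) P[, a] <- pmin(pmax(P[, a], 0.5), box[a] - 0.5)
  P
}

# confine positions to the domain: box clamp, plus radial projection into the
# inscribed ellipsoid for ball domains
.clamp_domain <- function(P, config) {
  P <- .clamp_box(P, config$box_size)
  if (identical(config$domain, "ball")) {
    ctr <- config$box_size / 2
    rad <- config$box_size / 2 - 0.5
    Q <- sweep(P, 2, ctr)
    rho <- sqrt((Q[, 1] / rad[1])^2 + (Q[, 2] / rad[2])^2 + (Q[, 3] / rad[3])^2)
    out <- rho > 1
    if (any(out)) P[out, ] <- sweep(Q[out, , drop = FALSE] / rho[out], 2, ctr, `+`)
  }
  P
}

#' Simulate a ground-truth lineage forest
#'
#' Initial positions are sampled by rejection so that all nuclei respect
#' `min_separation`; each frame every cell moves by drift + random walk
#' (+ optional swirl), divides with the configured probability (daughters
#' placed at +/- one `nucleus_sigma` around the mother along a random
#' direction), and overlapping nuclei are pushed apart by soft repulsion.
#' No cell ever disappears. The result is deterministic for a fixed seed
#' and satisfies all lineage-forest invariants by construction.
#'
#' @param config a [synthetic_config()].
#' @return A [gold_standard()] whose forest spans all frames.
#' @export
simulate_ground_truth <- function(config) {
  box <- config$box_size
  n0 <- config$n_cells_initial
  if (n0 * (4 / 3) * pi * (config$min_separation / 2)^3 > 2 * prod(box))
    stop("box too small for the requested population at min_separation",
         call. = FALSE)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(config$seed)
  P <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(P) < n0) {
    cand <- stats::runif(3) * (box - 1) + 0.5
    in_dom <- TRUE
    if (identical(config$domain, "ball")) {
      rel <- (cand - box / 2) / (box / 2 - 0.5)
      in_dom <- sum(rel^2) <= 1
    }
    if (in_dom &&
        (!nrow(P) || min(sqrt(colSums((t(P) - cand)^2))) >= config$min_separation))
      P <- rbind(P, cand)
    tries <- tries + 1L
    if (tries > 200L * n0)
      stop("box too small for the requested population at min_separation",
           call. = FALSE)
  }
  next_id <- 1L
  ids <- seq_len(n0); next_id <- n0 + 1L
  centres <- data.frame(id = ids, t = 0L, x = P[, 1], y = P[, 2], z = P[, 3],
                        intensity = 1, virtual = FALSE)
  links <- data.frame(mother_id = integer(0), daughter_id = integer(0))
  cur_ids <- ids
  cooldown <- rep(0L, n0)
  for (tt in seq_len(config$n_frames - 1L)) {
    n <- nrow(P)
    # motion
    V <- matrix(rep(config$drift, each = n), n, 3)
    V <- V + matrix(stats::rnorm(3 * n, sd = config$walk_sd), n, 3)
    if (config$swirl != 0) {
      cx <- box[1] / 2; cy <- box[2] / 2
      rx <- P[, 1] - cx; ry <- P[, 2] - cy
      rr <- pmax(sqrt(cx^2 + cy^2), 1e-9)
      V[, 1] <- V[, 1] - config$swirl * ry / rr
      V[, 2] <- V[, 2] + config$swirl * rx / rr
    }
    P2 <- .clamp_domain(P + V, config)
    # divisions (only cells past the cell-cycle refractory period)
    divide <- stats::runif(n) < config$division_prob_per_frame & cooldown == 0L
    newP <- list(); new_ids <- integer(0); new_int <- numeric(0)
    new_cd <- integer(0)
    lk_m <- integer(0); lk_d <- integer(0)
    for (i in seq_len(n)) {
      if (divide[i]) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        a <- P2[i, ] + config$nucleus_sigma * u
        b <- P2[i, ] - config$nucleus_sigma * u
        newP[[length(newP) + 1L]] <- a; newP[[length(newP) + 1L]] <- b
        new_ids <- c(new_ids, next_id, next_id + 1L)
        new_int <- c(new_int, 0.5, 0.5)           # telophase: half-intensity pair
        lk_m <- c(lk_m, cur_ids[i], cur_ids[i])
        lk_d <- c(lk_d, next_id, next_id + 1L)
        new_cd <- c(new_cd, config$min_division_interval,
                    config$min_division_interval)
        next_id <- next_id + 2L
      } else {
        newP[[length(newP) + 1L]] <- P2[i, ]
        new_ids <- c(new_ids, next_id)
        new_int <- c(new_int, 1)
        new_cd <- c(new_cd, max(cooldown[i] - 1L, 0L))
        lk_m <- c(lk_m, cur_ids[i]); lk_d <- c(lk_d, next_id)
        next_id <- next_id + 1L
      }
    }
    cooldown <- new_cd
    P <- .clamp_domain(do.call(rbind, newP), config)
    P <- .repel(P, config)
    centres <- rbind(centres,
                     data.frame(id = new_ids, t = tt, x = P[, 1], y = P[, 2],
                                z = P[, 3], intensity = new_int, virtual = FALSE))
    links <- rbind(links, data.frame(mother_id = lk_m, daughter_id = lk_d))
    cur_ids <- new_ids
  }
  gold_standard(lineage_forest(centres, links))
}

# Add one anisotropy-aware Gaussian blob in a local window (+/- 4 sigma)
.add_blob <- function(arr, pos_xyz, sigma, peak, spacing) {
  d <- dim(arr)
  cz <- .axis_coords(d[1], spacing[1])
  cy <- .axis_coords(d[2], spacing[2])
  cx <- .axis_coords(d[3], spacing[3])
  rz <- which(abs(cz - pos_xyz[3]) <= 4 * sigma)
  ry <- which(abs(cy - pos_xyz[2]) <= 4 * sigma)
  rx <- which(abs(cx - pos_xyz[1]) <= 4 * sigma)
  if (!length(rz) || !length(ry) || !length(rx)) return(arr)
  wz <- exp(-(cz[rz] - pos_xyz[3])^2 / (2 * sigma^2))
  wy <- exp(-(cy[ry] - pos_xyz[2])^2 / (2 * sigma^2))
  wx <- exp(-(cx[rx] - pos_xyz[1])^2 / (2 * sigma^2))
  arr[rz, ry, rx] <- arr[rz, ry, rx] + peak * outer(outer(wz, wy), wx)
  arr
}

.add_shell <- function(arr, pos_xyz, radius, width, peak, spacing) {
  d <- dim(arr)
  cz <- .axis_coords(d[1], spacing[1])
  cy <- .axis_coords(d[2], spacing[2])
  cx <- .axis_coords(d[3], spacing[3])
  ext <- radius + 3 * width
  rz <- which(abs(cz - pos_xyz[3]) <= ext)
  ry <- which(abs(cy - pos_xyz[2]) <= ext)
  rx <- which(abs(cx - pos_xyz[1]) <= ext)
  if (!length(rz) || !length(ry) || !length(rx)) return(arr)
  dz2 <- (cz[rz] - pos_xyz[3])^2
  dy2 <- (cy[ry] - pos_xyz[2])^2
  dx2 <- (cx[rx] - pos_xyz[1])^2
  r <- sqrt(outer(outer(dz2, dy2, `+`), dx2, `+`))
  arr[rz, ry, rx] <- arr[rz, ry, rx] + peak * exp(-(r - radius)^2 / (2 * width^2))
  arr
}

#' Render a ground-truth lineage as image stacks
#'
#' The nuclei channel is the sum of Gaussian blobs (peak scaled by
#' `exp(-depth_attenuation * z)` and by the per-centre intensity factor,
#' e.g. 0.5 for just-divided telophase nuclei) over a constant background
#' plus Gaussian noise; intensities are quantized to integer camera counts.
#' An optional membrane channel renders bright shells of radius
#' `1.8 * nucleus_sigma`. Rendering is bit-reproducible for a fixed seed.
#'
#' @param gold a [gold_standard()] from [simulate_ground_truth()].
#' @param config the [synthetic_config()] used for the simulation.
#' @return A [timelapse_dataset()].
#' @export
render_embryo <- function(gold, config) {
  cn <- gold$forest$centres
  dims <- c(ceiling(config$box_size[3] / config$spacing[1]),
            ceiling(config$box_size[2] / config$spacing[2]),
            ceiling(config$box_size[1] / config$spacing[3]))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(config$seed + 1L)
  frames <- vector("list", config$n_frames)
  for (tt in seq_len(config$n_frames) - 1L) {
    sub <- cn[cn$t == tt, , drop = FALSE]
    arr <- array(config$background, dims)
    marr <- if (config$membrane_shell) array(config$background, dims)
    for (i in seq_len(nrow(sub))) {
      peak <- config$peak_intensity * sub$intensity[i] *
        exp(-config$depth_attenuation * sub$z[i])
      arr <- .add_blob(arr, c(sub$x[i], sub$y[i], sub$z[i]),
                       config$nucleus_sigma, peak, config$spacing)
      if (config$membrane_shell)
        marr <- .add_shell(marr, c(sub$x[i], sub$y[i], sub$z[i]),
                           1.8 * config$nucleus_sigma,
                           0.3 * config$nucleus_sigma, peak, config$spacing)
    }
    if (config$noise_sd > 0)
      arr <- arr + array(stats::rnorm(length(arr), sd = config$noise_sd), dims)
    arr <- pmin(pmax(round(arr), 0), 65535)
    fr <- list(nuclei = voxel_grid(arr, config$spacing, t = tt, channel = "nuclei"))
    if (config$membrane_shell) {
      if (config$noise_sd > 0)
        marr <- marr + array(stats::rnorm(length(marr), sd = config$noise_sd), dims)
      marr <- pmin(pmax(round(marr), 0), 65535)
      fr$membranes <- voxel_grid(marr, config$spacing, t = tt, channel = "membranes")
    }
    frames[[tt + 1L]] <- fr
  }
  timelapse_dataset(frames, config$dt_seconds)
}

#' Generate a complete synthetic embryo
#'
#' @param config a [synthetic_config()].
#' @return list with `gold` (a [gold_standard()]) and `dataset` (a
#'   [timelapse_dataset()]).
#' @export
synthetic_embryo <- function(config = synthetic_config()) {
  gold <- simulate_ground_truth(config)
  list(gold = gold, dataset = render_embryo(gold, config))
}
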