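# Shared phantom builders and brute-force oracles for the test suite.

# Sum of Gaussian blobs on a grid; ctrs is a matrix of (x, y, z) um rows.
make_blobs <- function(dims, ctrs, sigma, peaks, spacing = c(1, 1, 1),
                       background = 0) {
  cz <- (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2]
  cx <- (seq_len(dims[3]) - 0.5) * spacing[3]
  a <- array(background, dims)
  for (i in seq_len(nrow(ctrs))) {
    wz <- exp(-(cz - ctrs[i, 3])^2 / (2 * sigma^2))
    wy <- exp(-(cy - ctrs[i, 2])^2 / (2 * sigma^2))
    wx <- exp(-(cx - ctrs[i, 1])^2 / (2 * sigma^2))
    a <- a + peaks[i] * outer(outer(wz, wy), wx)
  }
  a
}

# Binary sphere phantom (value inside, 0 outside), 1 um voxels
make_sphere <- function(n = 24, radius = 6, value = 100) {
  cc <- seq_len(n) - 0.5
  ctr <- n / 2
  r <- sqrt(outer(outer((cc - ctr)^2, (cc - ctr)^2, `+`), (cc - ctr)^2, `+`))
  list(values = ifelse(r <= radius, value, 0), r = r, ctr = ctr)
}

# A straight identity track: one cell per frame at the given positions
straight_forest <- function(pos, t0 = 0L) {
  n <- nrow(pos)
  centres <- data.frame(id = seq_len(n), t = t0 + seq_len(n) - 1L,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3])
  links <- data.frame(mother_id = seq_len(n - 1L), daughter_id = 2:n)
  lineage_forest(centres, links)
}

# Exhaustive minimum tracking cost over all valid (out-degree <= 2) mother
# assignments of a 2-frame instance. The independent oracle for the annealer.
enumerate_min_cost <- function(cn, cfg) {
  f0 <- cn[cn$t == 0, ]
  f1 <- cn[cn$t == 1, ]
  opts <- lapply(seq_len(nrow(f1)), function(i) {
    d <- sqrt((f0$x - f1$x[i])^2 + (f0$y - f1$y[i])^2 + (f0$z - f1$z[i])^2)
    c(NA_integer_, f0$id[d <= cfg$d_max])
  })
  best <- Inf
  grid <- expand.grid(lapply(opts, seq_along))
  for (r in seq_len(nrow(grid))) {
    mid <- mapply(function(o, k) o[k], opts, unlist(grid[r, ]))
    has <- !is.na(mid)
    if (any(has) && any(table(mid[has]) > 2)) next
    lk <- data.frame(mother_id = mid[has], daughter_id = f1$id[has])
    cost <- forest_cost(lineage_forest(cn, lk), cfg)$total
    if (cost < best) best <- cost
  }
  best
}

# Brute-force optimal one-to-one matching (max cardinality, then min total
# distance) between two small point sets, admissible within `radius`.
brute_force_match <- function(detected, gold, radius) {
  nd <- nrow(detected); ng <- nrow(gold)
  D <- sqrt(outer(detected$x, gold$x, `-`)^2 +
              outer(detected$y, gold$y, `-`)^2 +
              outer(detected$z, gold$z, `-`)^2)
  best <- list(k = -1L, dist = Inf)
  recurse <- function(i, used, k, dist) {
    if (i > nd) {
      if (k > best$k || (k == best$k && dist < best$dist - 1e-12))
        best <<- list(k = k, dist = dist)
      return(invisible())
    }
    recurse(i + 1L, used, k, dist)               # leave detected i unmatched
    for (j in seq_len(ng)) {
      if (!used[j] && D[i, j] <= radius) {
        used[j] <- TRUE
        recurse(i + 1L, used, k + 1L, dist + D[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, ng), 0L, 0)
  best
}

# Deterministic small random forest for IO round-trips
random_forest <- function(n = 200L, n_frames = 5L, seed = 1L) {
  set.seed(seed)
  t <- sort(sample.int(n_frames, n, replace = TRUE)) - 1L
  centres <- data.frame(id = seq_len(n), t = t,
                        x = round(runif(n, 0, 200), 6),
                        y = round(runif(n, 0, 200), 6),
                        z = round(runif(n, 0, 80), 6),
                        intensity = 0, virtual = FALSE)
  links <- do.call(rbind, lapply(seq_len(n), function(i) {
    prev <- which(centres$t == centres$t[i] - 1L)
    if (!length(prev)) return(NULL)
    data.frame(mother_id = sample(prev, 1L), daughter_id = i)
  }))
  # enforce the two-daughter limit
  keep <- unlist(lapply(split(seq_len(nrow(links)), links$mother_id),
                        function(ix) utils::head(ix, 2)))
  lineage_forest(centres, links[sort(keep), ])
}
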