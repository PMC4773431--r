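test_that("FBLS leaves constant images constant", {
  g <- voxel_grid(array(3, c(6, 6, 6)), c(1, 1, 1))
  f <- fbls_smooth(g, fbls_params(n_iter = 5))
  expect_equal(f$values, g$values)
})

test_that("FBLS does not increase the number of local maxima", {
  set.seed(2)
  d <- c(24, 24, 24)
  # two merged-shoulder blobs with a shallow saddle, plus noise
  a <- make_blobs(d, rbind(c(9, 12, 12), c(15, 12, 12)), sigma = 2,
                  peaks = c(100, 100)) + array(rnorm(prod(d), 0, 4), d)
  g <- voxel_grid(a, c(1, 1, 1))
  n_prev <- Inf
  for (it in c(1, 3, 5, 10)) {
    f <- fbls_smooth(g, fbls_params(delta = 0.2, mu = 1, n_iter = it))
    n <- nrow(extract_local_maxima(f, 0))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  # the saddle-separated pair survives while noise maxima vanish
  f <- fbls_smooth(g, fbls_params(delta = 0.2, mu = 1, n_iter = 10))
  peaks <- extract_local_maxima(f, 0.2)
  expect_equal(nrow(peaks), 2L)
})

test_that("FBLS keeps a single blob's maximum within one voxel of its centre", {
  d <- c(21, 21, 21)
  a <- make_blobs(d, matrix(c(10.5, 10.5, 10.5), 1), sigma = 2, peaks = 100)
  f <- fbls_smooth(voxel_grid(a, c(1, 1, 1)),
                   fbls_params(delta = 0.2, mu = 1, n_iter = 10))
  m <- extract_local_maxima(f, 0.2)
  expect_equal(nrow(m), 1L)
  expect_lte(max(abs(c(m$x, m$y, m$z) - 10.5)), 1)
})

test_that("local maxima extraction handles floors, singletons and plateaus", {
  z <- voxel_grid(array(0, c(5, 5, 5)), c(1, 1, 1))
  expect_equal(nrow(extract_local_maxima(z, 0)), 0L)
  a <- array(0, c(7, 7, 7)); a[3, 4, 5] <- 1
  m <- extract_local_maxima(voxel_grid(a, c(1, 1, 1)), 0.5)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$x, m$y, m$z), c(4.5, 3.5, 2.5))
  # 3x3x3 plateau of equal maxima merges to the plateau centroid
  p <- array(0, c(9, 9, 9)); p[4:6, 4:6, 4:6] <- 2
  mp <- extract_local_maxima(voxel_grid(p, c(1, 1, 1)), 0.1)
  expect_equal(nrow(mp), 1L)
  expect_equal(c(mp$x, mp$y, mp$z), c(4.5, 4.5, 4.5))
})

test_that("DoG detection finds isolated nuclei with sub-voxel accuracy", {
  flat <- voxel_grid(array(1, c(10, 10, 10)), c(1, 1, 1))
  expect_warning(r <- dog_detect(flat), "nowhere positive")
  expect_equal(nrow(r), 0L)
  d <- c(30, 30, 30)
  a <- make_blobs(d, matrix(c(15, 15, 15), 1), sigma = 2, peaks = 100)
  m <- dog_detect(voxel_grid(a, c(1, 1, 1)), dog_params(2, 14, 5))
  expect_equal(nrow(m), 1L)
  expect_lte(max(abs(c(m$x, m$y, m$z) - 15)), 1)
})

test_that("DoG recalls 20 well-separated nuclei and is intensity-scale equivariant", {
  set.seed(7)
  gx <- rep(seq(12, 92, by = 20), 4)[1:20]
  gy <- rep(seq(12, 72, by = 20), each = 5)[1:20]
  gz <- rep(c(12, 30), 10)
  ctr <- cbind(gx, gy, gz) + matrix(runif(60, -2, 2), 20, 3)
  a <- make_blobs(c(42, 84, 104), ctr, sigma = 2, peaks = rep(100, 20),
                  background = 5)
  g <- voxel_grid(a, c(1, 1, 1))
  det <- dog_detect(g, dog_params(2, 14, 5))
  expect_equal(nrow(det), 20L)
  mc <- match_centres(det, centre_set(ctr[, 1], ctr[, 2], ctr[, 3]),
                      r_factor = 0.5)
  expect_equal(mc$counts$TP, 20L)
  expect_equal(mc$counts$FN, 0L)
  det2 <- dog_detect(voxel_grid(a * 3.7, c(1, 1, 1)), dog_params(2, 14, 5))
  expect_equal(nrow(det2), 20L)
  expect_equal(det2[c("x", "y", "z")], det[c("x", "y", "z")], tolerance = 1e-9)
})

test_that("DoG parameter scan ranks combinations against curated centres", {
  d <- c(30, 60, 60)
  ctr <- rbind(c(15, 15, 15), c(45, 15, 15), c(15, 45, 15), c(45, 45, 15))
  a <- make_blobs(d, ctr, sigma = 2, peaks = rep(100, 4))
  gold <- centre_set(ctr[, 1], ctr[, 2], ctr[, 3])
  scan <- dog_parameter_scan(voxel_grid(a, c(1, 1, 1)), gold,
                             sigma_small = c(1.5, 2), sigma_large = 14,
                             threshold_pct = c(5, 10))
  expect_equal(nrow(scan), 4L)
  expect_true(all(scan$sensitivity >= 0 & scan$sensitivity <= 1))
  expect_equal(scan$sensitivity[1], 1)
})

test_that("detection respects anisotropic voxel spacing", {
  # same physical phantom sampled with 2 um z-spacing
  d <- c(15, 30, 30)
  a <- make_blobs(d, matrix(c(15, 15, 15), 1), sigma = 2, peaks = 100,
                  spacing = c(2, 1, 1))
  m <- dog_detect(voxel_grid(a, c(2, 1, 1)), dog_params(2, 14, 5))
  expect_equal(nrow(m), 1L)
  expect_lte(max(abs(c(m$x, m$y, m$z) - 15)), 1)
})

test_that("each detector reaches near-perfect recall in its density regime", {
  # DoG: sparse, high-contrast synthetic embryo (its intended regime);
  # the dense-tissue FBLS gate runs in the end-to-end recovery test
  sc <- synthetic_config(n_cells_initial = 12, n_frames = 3,
                         box_size = c(130, 130, 65), min_separation = 28,
                         division_prob_per_frame = 0, noise_sd = 2,
                         seed = 14)
  emb <- synthetic_embryo(sc)
  tp <- 0L; tot <- 0L
  for (k in seq_along(emb$dataset$frames)) {
    det <- dog_detect(emb$dataset$frames[[k]]$nuclei, dog_params(2, 14, 5))
    gcn <- emb$gold$forest$centres
    gsub <- gcn[gcn$t == k - 1L, ]
    mc <- match_centres(det, centre_set(gsub$x, gsub$y, gsub$z, id = gsub$id),
                        r_factor = 0.5)
    tp <- tp + mc$counts$TP; tot <- tot + nrow(gsub)
  }
  expect_gte(tp / tot, 0.99)
})
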