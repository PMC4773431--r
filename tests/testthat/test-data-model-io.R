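test_that("voxel_grid validates its invariants", {
  expect_error(voxel_grid(matrix(0, 3, 3), c(1, 1, 1)), "3D")
  expect_error(voxel_grid(array(NA_real_, c(3, 3, 3)), c(1, 1, 1)), "finite")
  expect_error(voxel_grid(array(0, c(3, 3, 3)), c(1, 0, 1)), "positive")
  g <- voxel_grid(array(1, c(3, 4, 5)), c(1.37, 1.37, 1.37), t = 2)
  expect_identical(dim(g$values), c(3L, 4L, 5L))
  expect_identical(g$t, 2L)
})

test_that("voxel index to physical coordinate conversion uses voxel centres", {
  expect_equal(to_physical(c(0, 0, 0), c(1, 1, 1)),
               c(x = 0.5, y = 0.5, z = 0.5))
  # index (z=0, y=0, x=2) at 1.37 um spacing
  p <- to_physical(c(0, 0, 2), c(1.37, 1.37, 1.37))
  expect_equal(unname(p["x"]), 3.425)
  # inverse is the identity on all indices of a small grid
  idx <- as.matrix(expand.grid(z = 0:3, y = 0:4, x = 0:5))
  sp <- c(1.37, 0.7, 2.1)
  back <- to_index(to_physical(idx, sp), sp)
  expect_equal(unname(back), unname(idx))
})

test_that("lineage forest invariants reject bad graphs", {
  cn <- data.frame(id = 1:4, t = c(0, 0, 1, 1), x = 0, y = 0, z = 0)
  # two mothers for one daughter
  expect_error(lineage_forest(cn, data.frame(mother_id = c(1, 2),
                                             daughter_id = c(3, 3))),
               "more than one mother")
  # three daughters
  cn5 <- data.frame(id = 1:5, t = c(0, 1, 1, 1, 1), x = 0, y = 0, z = 0)
  expect_error(lineage_forest(cn5, data.frame(mother_id = c(1, 1, 1),
                                              daughter_id = c(2, 3, 4))),
               "more than two daughters")
  # link spanning two frames
  cn2 <- data.frame(id = 1:2, t = c(0, 2), x = 0, y = 0, z = 0)
  expect_error(lineage_forest(cn2, data.frame(mother_id = 1, daughter_id = 2)),
               "exactly one frame")
  # duplicate ids
  expect_error(lineage_forest(data.frame(id = c(1, 1), t = 0:1,
                                         x = 0, y = 0, z = 0)),
               "duplicate")
})

test_that("lineage CSV round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  # one centre, no links
  f1 <- lineage_forest(data.frame(id = 7L, t = 0L, x = 1, y = 2, z = 3))
  write_lineage(f1, tmp)
  df <- read.csv(tmp)
  expect_equal(nrow(df), 1L)
  expect_equal(df$mother_id, -1L)
  # division: both daughters carry the mother's id
  f2 <- lineage_forest(data.frame(id = 1:3, t = c(0, 1, 1),
                                  x = c(0, 1, -1), y = 0, z = 0),
                       data.frame(mother_id = c(1, 1), daughter_id = c(2, 3)))
  write_lineage(f2, tmp)
  df <- read.csv(tmp)
  expect_equal(df$mother_id[df$id %in% 2:3], c(1L, 1L))
  # random 200-centre forest: read(write(f)) == f
  f3 <- random_forest(200L, seed = 42L)
  write_lineage(f3, tmp)
  f3b <- read_lineage(tmp)
  expect_equal(f3b$centres[c("id", "t", "x", "y", "z")],
               f3$centres[c("id", "t", "x", "y", "z")])
  o <- order(f3$links$daughter_id)
  ob <- order(f3b$links$daughter_id)
  expect_equal(f3b$links[ob, ], f3$links[o, ], ignore_attr = TRUE)
})

test_that("lineage CSV reader flags unknown mothers and duplicate ids", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,t,x,y,z,mother_id,virtual",
               "1,0,0,0,0,-1,0", "2,1,0,0,0,99,0"), tmp)
  expect_error(read_lineage(tmp), "unknown mother_id")
  writeLines(c("id,t,x,y,z,mother_id,virtual",
               "1,0,0,0,0,-1,0", "1,1,0,0,0,-1,0"), tmp)
  expect_error(read_lineage(tmp), "duplicate")
})

test_that("TIFF time-lapse IO round-trips integer data exactly", {
  dir <- withr::local_tempdir()
  set.seed(3)
  frames <- lapply(0:2, function(tt)
    list(nuclei = voxel_grid(array(sample(0:4095, 8 * 16 * 16, TRUE),
                                   c(8, 16, 16)),
                             c(1.37, 1.37, 1.37), t = tt)))
  ds <- timelapse_dataset(frames, dt_seconds = 67)
  write_timelapse(ds, dir, prefix = "tst")
  ds2 <- read_timelapse(c(nuclei = "tst_nuclei_t{t}.tif"), dir,
                        c(1.37, 1.37, 1.37), 67)
  expect_length(ds2$frames, 3L)
  for (k in 1:3) {
    v <- ds2$frames[[k]]$nuclei$values
    expect_type(v, "double")               # cast to float, never rescaled
    expect_identical(v, ds$frames[[k]]$nuclei$values * 1.0)
  }
})

test_that("time-lapse reader reports gaps, mismatches and empty manifests", {
  dir <- withr::local_tempdir()
  g <- function(d) array(0L, d)
  tiff::writeTIFF(lapply(1:4, function(z) matrix(0, 8, 8)),
                  file.path(dir, "s_t000.tif"), bits.per.sample = 16L)
  tiff::writeTIFF(lapply(1:4, function(z) matrix(0, 8, 8)),
                  file.path(dir, "s_t002.tif"), bits.per.sample = 16L)
  expect_error(read_timelapse("s_t{t}.tif", dir, c(1, 1, 1), 1),
               "missing frame index")
  tiff::writeTIFF(lapply(1:4, function(z) matrix(0, 9, 8)),
                  file.path(dir, "s_t001.tif"), bits.per.sample = 16L)
  expect_error(read_timelapse("s_t{t}.tif", dir, c(1, 1, 1), 1),
               "shape")
  expect_error(read_timelapse("nope_{t}.tif", dir, c(1, 1, 1), 1),
               "no files")
})

test_that("frames of a dataset must share geometry", {
  f1 <- list(nuclei = voxel_grid(array(0, c(4, 4, 4)), c(1, 1, 1), t = 0))
  f2 <- list(nuclei = voxel_grid(array(0, c(4, 4, 5)), c(1, 1, 1), t = 1))
  expect_error(timelapse_dataset(list(f1, f2), 1), "shape")
})
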