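test_that("mean internuclear distance is the mean nearest-neighbour distance", {
  cs2 <- centre_set(x = c(0, 10), y = c(0, 0), z = c(0, 0))
  expect_equal(mean_internuclear_distance(cs2), 10)
  cs3 <- centre_set(x = c(0, 10, 30), y = 0, z = 0)
  expect_equal(mean_internuclear_distance(cs3), mean(c(10, 10, 20)))
  # regular cubic lattice with spacing a
  g <- expand.grid(x = (0:2) * 7, y = (0:2) * 7, z = (0:2) * 7)
  expect_equal(mean_internuclear_distance(centre_set(g$x, g$y, g$z)), 7)
  expect_error(mean_internuclear_distance(centre_set(1, 1, 1)), "at least 2")
})

test_that("centre matching obeys the validation counting conventions", {
  gold <- centre_set(x = c(0, 10), y = 0, z = 0, id = 1:2)
  # identical sets
  mc <- match_centres(gold, gold, r_factor = 0.5)
  expect_equal(mc$counts$TP, 2L)
  expect_equal(mc$counts$FP, 0L)
  expect_equal(mc$counts$FN, 0L)
  # empty detection
  mc0 <- match_centres(centre_set(numeric(0), numeric(0), numeric(0)),
                       gold, r_factor = 0.5)
  expect_equal(mc0$counts$TP, 0L)
  expect_equal(mc0$counts$FN, 2L)
  # one detected centre closer to gold A: matched to A, the other gold is FN
  det <- centre_set(x = 4, y = 0, z = 0, id = 7L)
  mc1 <- match_centres(det, gold, r_factor = 0.5)
  expect_equal(mc1$matching$gold_id, 1L)
  expect_equal(mc1$counts$TP, 1L)
  expect_equal(mc1$counts$FP, 0L)
  expect_equal(mc1$counts$FN, 1L)
})

test_that("centre accounting conserves totals on random instances", {
  set.seed(13)
  for (rep in 1:20) {
    ng <- sample(2:6, 1); nd <- sample(0:6, 1)
    gold <- centre_set(x = runif(ng, 0, 30), y = runif(ng, 0, 30),
                       z = runif(ng, 0, 10), id = seq_len(ng))
    det <- centre_set(x = runif(nd, 0, 30), y = runif(nd, 0, 30),
                      z = runif(nd, 0, 10), id = seq_len(nd) + 100L)
    mc <- match_centres(det, gold, r_factor = 0.5)
    expect_equal(mc$counts$TP + mc$counts$FN, ng)
    expect_equal(mc$counts$TP + mc$counts$FP, nd)
  }
})

test_that("matching equals brute-force enumeration on small instances", {
  set.seed(29)
  for (rep in 1:25) {
    ng <- sample(2:6, 1); nd <- sample(1:6, 1)
    gold <- centre_set(x = runif(ng, 0, 25), y = runif(ng, 0, 25),
                       z = runif(ng, 0, 8), id = seq_len(ng))
    det <- centre_set(x = runif(nd, 0, 25), y = runif(nd, 0, 25),
                      z = runif(nd, 0, 8), id = seq_len(nd) + 100L)
    radius <- 0.5 * mean_internuclear_distance(gold)
    bf <- brute_force_match(det, gold, radius)
    mc <- match_centres(det, gold, r_factor = 0.5)
    expect_equal(nrow(mc$matching), bf$k)
    if (bf$k > 0) expect_equal(sum(mc$matching$distance), bf$dist,
                               tolerance = 1e-6)
  }
})

test_that("link errors split into wrong and missing links", {
  # gold: 11 straight tracks over 2 frames
  n <- 11
  gcn <- data.frame(id = 1:(2 * n), t = rep(0:1, each = n),
                    x = rep(seq(0, 100, by = 10), 2), y = 0, z = 0)
  glk <- data.frame(mother_id = 1:n, daughter_id = n + 1:n)
  gold <- lineage_forest(gcn, glk)
  # detected: same centres; 9 correct links, one wrong (to the neighbour
  # track's mother), one missing; the 11th track's daughter is not detected
  dcn <- gcn[-(2 * n), ]
  dlk <- data.frame(mother_id = c(1:8, 10), daughter_id = c(n + 1:8, n + 9))
  det <- lineage_forest(dcn, dlk)
  rep_all <- score_lineages(det, gold_standard(gold), r_factor = 0.5)
  lc <- rep_all$counts$links
  expect_equal(lc$TP, 8L)
  expect_equal(lc$WL, 1L)
  expect_equal(lc$ML, 1L)
  expect_equal(lc$FP, 1L)                  # WL contributes to FP and FN
  expect_equal(lc$FN, lc$WL + lc$ML)
  # the FN centre's gold link is excluded from link accounting:
  # 10 TP centres at t=1 with gold mothers -> TP + WL + ML = 10
  expect_equal(lc$TP + lc$FN, 10L)
})

test_that("mitosis scoring requires both daughter links within the TP subset", {
  gcn <- data.frame(id = 1:5, t = c(0, 1, 1, 0, 1),
                    x = c(0, 2, -2, 30, 31), y = 0, z = 0)
  glk <- data.frame(mother_id = c(1, 1, 4), daughter_id = c(2, 3, 5))
  gold <- lineage_forest(gcn, glk)
  # correct division
  repc <- score_lineages(gold, gold_standard(gold), r_factor = 0.6)
  expect_equal(repc$counts$mitoses$TP, 1L)
  expect_equal(repc$counts$mitoses$FN, 0L)
  expect_equal(repc$counts$mitoses$FP, 0L)
  # only one daughter link made: division is an FN
  det1 <- lineage_forest(gcn, glk[-1, ])
  rep1 <- score_lineages(det1, gold_standard(gold), r_factor = 0.6)
  expect_equal(rep1$counts$mitoses$TP, 0L)
  expect_equal(rep1$counts$mitoses$FN, 1L)
  # spurious division on a non-dividing gold track is an FP
  dlk3 <- data.frame(mother_id = c(4, 4, 1), daughter_id = c(5, 2, 3))
  det3 <- lineage_forest(gcn, dlk3)
  rep3 <- score_lineages(det3, gold_standard(gold), r_factor = 0.6)
  expect_equal(rep3$counts$mitoses$FP, 1L)
})

test_that("rates derive from counts with undefined markers on empty denominators", {
  r <- metrics(confusion_counts(TP = 8, FP = 0, FN = 2))
  expect_equal(r$sensitivity, 0.8)
  expect_equal(r$fn_rate, 0.2)
  expect_equal(r$false_detection_rate, 0)
  # sensitivity and FN rate are complements on the same denominator
  r2 <- metrics(confusion_counts(TP = 9789, FP = 0, FN = 211))
  expect_equal(r2$sensitivity, 0.9789)
  expect_equal(r2$fn_rate, 0.0211)
  expect_equal(r2$sensitivity + r2$fn_rate, 1)
  r0 <- metrics(confusion_counts(TP = 0, FP = 0, FN = 0))
  expect_true(is.na(r0$sensitivity))
  expect_true(is.na(r0$false_detection_rate))
})

test_that("the lineage score is the product of the two sensitivities", {
  expect_equal(lineage_score(1.0, 1.0), 1.0)
  expect_equal(lineage_score(0.98, 0.9789), 0.959322)
  expect_equal(lineage_score(0, 0.97), 0)
  expect_true(is.na(lineage_score(NA_real_, 0.5)))
})

test_that("self-scoring yields perfect rates and is id-permutation invariant", {
  f <- random_forest(80L, n_frames = 4L, seed = 17L)
  rep1 <- score_lineages(f, gold_standard(f), r_factor = 0.5)
  expect_equal(rep1$metrics$centres$sensitivity, 1)
  expect_equal(rep1$metrics$links$sensitivity, 1)
  expect_equal(rep1$metrics$centres$false_detection_rate, 0)
  expect_equal(rep1$metrics$links$false_detection_rate, 0)
  expect_equal(rep1$lineage_score, 1)
  # permute detected ids: metrics unchanged
  map <- stats::setNames(sample(5000:6000, nrow(f$centres)), f$centres$id)
  f2 <- lineage_forest(transform(f$centres, id = map[as.character(id)]),
                       data.frame(mother_id = map[as.character(f$links$mother_id)],
                                  daughter_id = map[as.character(f$links$daughter_id)]))
  rep2 <- score_lineages(f2, gold_standard(f), r_factor = 0.5)
  expect_equal(rep2$counts$centres$TP, rep1$counts$centres$TP)
  expect_equal(rep2$metrics$links$sensitivity, 1)
})

test_that("scope boxes restrict scoring to curated regions", {
  cn <- data.frame(id = 1:4, t = 0L, x = c(5, 5, 50, 50), y = c(5, 6, 50, 51),
                   z = 0)
  f <- lineage_forest(cn)
  scope <- data.frame(xmin = 0, xmax = 20, ymin = 0, ymax = 20,
                      zmin = -5, zmax = 5, tmin = 0, tmax = 10)
  gs <- gold_standard(f, scope)
  det <- lineage_forest(data.frame(id = 11:12, t = 0L, x = c(5, 70),
                                   y = c(5, 70), z = 0))
  rep_s <- score_lineages(det, gs, r_factor = 0.6)
  # only the two in-scope gold centres count; the out-of-scope detection
  # is not an FP
  expect_equal(rep_s$counts$centres$TP + rep_s$counts$centres$FN, 2L)
  expect_equal(rep_s$counts$centres$FP, 0L)
})
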