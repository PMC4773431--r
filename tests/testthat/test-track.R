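test_that("nearest-neighbour initialization links daughters to mothers", {
  cn <- data.frame(id = 1:2, t = c(0, 1), x = c(0, 1), y = 0, z = 0)
  f <- init_nearest_neighbour(cn, d_max = 10)
  expect_equal(f$links, data.frame(mother_id = 1L, daughter_id = 2L))
  # convergence: two centres at t+1 both pick the same mother
  cn2 <- data.frame(id = 1:3, t = c(0, 1, 1), x = c(0, 2, -2), y = 0, z = 0)
  f2 <- init_nearest_neighbour(cn2, d_max = 10)
  expect_equal(sort(f2$links$daughter_id[f2$links$mother_id == 1]), c(2L, 3L))
  # a centre beyond d_max stays unlinked
  cn3 <- data.frame(id = 1:2, t = c(0, 1), x = c(0, 50), y = 0, z = 0)
  expect_equal(nrow(init_nearest_neighbour(cn3, d_max = 10)$links), 0L)
})

test_that("nearest-neighbour init matches the identity permutation for small motion", {
  set.seed(4)
  base <- cbind(x = runif(5, 0, 50), y = runif(5, 0, 50), z = runif(5, 0, 20))
  cn <- do.call(rbind, lapply(0:2, function(tt)
    data.frame(id = tt * 5 + 1:5, t = tt, x = base[, 1] + 0.01 * tt,
               y = base[, 2], z = base[, 3])))
  f <- init_nearest_neighbour(cn, d_max = 5)
  expect_equal(nrow(f$links), 10L)
  expect_true(all(f$links$daughter_id - f$links$mother_id == 5L))
})

test_that("forest cost decomposes into hand-computable terms", {
  cfg <- anneal_config(d_max = 10, seed = 1)
  # perfect identity tracking with zero displacement costs nothing
  cn <- do.call(rbind, lapply(0:2, function(tt)
    data.frame(id = tt * 2 + 1:2, t = tt, x = c(0, 20), y = 0, z = 0)))
  lk <- data.frame(mother_id = c(1, 2, 3, 4), daughter_id = c(3, 4, 5, 6))
  cb <- forest_cost(lineage_forest(cn, lk), cfg)
  expect_equal(cb$total, 0)
  expect_equal(sum(cb$per_term), cb$total)
  # a single motherless centre at t = 1
  cn1 <- data.frame(id = 1:2, t = c(0, 1), x = c(0, 0), y = 0, z = 0)
  cb1 <- forest_cost(lineage_forest(cn1, NULL), cfg)
  expect_equal(unname(cb1$per_term["motherless"]),
               unname(cfg$weights["motherless"]))
  # hand-built: 1 mother, 3 daughters at distances 3, 4, 5
  cn3 <- data.frame(id = 1:4, t = c(0, 1, 1, 1),
                    x = c(0, 3, 0, 0), y = c(0, 0, 4, 0), z = c(0, 0, 0, 5))
  f3 <- lineage_forest(cn3, data.frame(mother_id = c(1, 1, 1),
                                       daughter_id = c(2, 3, 4)),
                       validate = FALSE)
  cb3 <- forest_cost(f3, cfg)
  expect_equal(unname(cb3$per_term["excess_daughters"]),
               unname(cfg$weights["excess_daughters"]) * 1)
  expect_equal(unname(cb3$per_term["displacement"]),
               (9 + 16 + 25) / 100)
  # sister pairs (2,3), (2,4), (3,4): squared separations 25, 34, 41
  expect_equal(unname(cb3$per_term["sister_symmetry"]),
               0.5 * (25 + 34 + 41) / 100)
  expect_equal(cb3$total, sum(cb3$per_term))
})

test_that("forest cost is invariant to id relabelling and rigid translation", {
  set.seed(8)
  cfg <- anneal_config(d_max = 10, seed = 1)
  f <- random_forest(40L, n_frames = 4L, seed = 8L)
  c0 <- forest_cost(f, cfg)$total
  # relabel ids
  perm <- sample(1000:2000, nrow(f$centres))
  map <- stats::setNames(perm, f$centres$id)
  f2 <- lineage_forest(transform(f$centres, id = map[as.character(id)]),
                       data.frame(mother_id = map[as.character(f$links$mother_id)],
                                  daughter_id = map[as.character(f$links$daughter_id)]))
  expect_equal(forest_cost(f2, cfg)$total, c0)
  # rigid translation
  f3 <- f
  f3$centres$x <- f3$centres$x + 17.3
  f3$centres$y <- f3$centres$y - 4.2
  f3$centres$z <- f3$centres$z + 0.9
  expect_equal(forest_cost(f3, cfg)$total, c0)
})

test_that("annealing returns cost-consistent, hard-constraint-satisfying forests", {
  set.seed(21)
  cn <- data.frame(id = 1:12, t = rep(0:2, each = 4),
                   x = runif(12, 0, 30), y = runif(12, 0, 30), z = 0)
  cfg <- anneal_config(d_max = 15, n_sweeps = 100, seed = 5)
  f <- anneal(init_nearest_neighbour(cn, cfg$d_max), cfg)
  validate_forest(f)   # in-degree <= 1, out-degree <= 2, consecutive spans
  expect_equal(attr(f, "cost")$total, forest_cost(f, cfg)$total)
})

test_that("an already-optimal forest survives annealing unchanged", {
  cn <- do.call(rbind, lapply(0:2, function(tt)
    data.frame(id = tt * 3 + 1:3, t = tt,
               x = c(0, 20, 40) + 0.1 * tt, y = 0, z = 0)))
  cfg <- anneal_config(d_max = 5, T0 = 1e-9, n_sweeps = 50, seed = 2)
  init <- init_nearest_neighbour(cn, cfg$d_max)
  f <- anneal(init, cfg)
  o <- function(l) l[order(l$daughter_id), ]
  expect_equal(o(f$links), o(init$links), ignore_attr = TRUE)
})

test_that("annealing recovers a mitosis against a distant distractor", {
  # 1 mother, 2 nearby daughters, 1 distant distractor cell
  cn <- data.frame(id = 1:5, t = c(0, 1, 1, 0, 1),
                   x = c(0, 2, -2, 30, 30.5), y = c(0, 1, -1, 0, 0), z = 0)
  cfg <- anneal_config(d_max = 10, n_sweeps = 100, seed = 3)
  f <- anneal(init_nearest_neighbour(cn, cfg$d_max), cfg)
  expect_equal(sort(f$links$daughter_id[f$links$mother_id == 1]), c(2L, 3L))
  expect_equal(f$links$daughter_id[f$links$mother_id == 4], 5L)
})

test_that("annealing is deterministic for a fixed seed", {
  set.seed(99)
  cn <- data.frame(id = 1:20, t = rep(0:3, each = 5),
                   x = runif(20, 0, 40), y = runif(20, 0, 40), z = runif(20, 0, 10))
  cfg <- anneal_config(d_max = 20, n_sweeps = 60, seed = 7)
  f1 <- anneal(init_nearest_neighbour(cn, cfg$d_max), cfg)
  f2 <- anneal(init_nearest_neighbour(cn, cfg$d_max), cfg)
  expect_identical(f1$links, f2$links)
  cfg2 <- cfg; cfg2$seed <- 8L
  f3 <- anneal(init_nearest_neighbour(cn, cfg$d_max), cfg2)
  expect_identical(sort(f3$centres$id), sort(f1$centres$id)) # same centres either way
})

test_that("repair deletes short spurious branches and bridges one-frame gaps", {
  cfg <- anneal_config(d_max = 8, L_min = 3, seed = 4)
  # straight track 0..8 plus an isolated one-frame centre far away
  pos <- cbind(2 * (0:8), 0, 0)
  f <- straight_forest(pos)
  spur <- data.frame(id = 99L, t = 3L, x = 60, y = 60, z = 0,
                     intensity = 0, virtual = FALSE)
  f2 <- lineage_forest(rbind(f$centres, spur), f$links)
  r <- repair(f2, cfg)
  expect_false(99L %in% r$centres$id)
  expect_true(all(f$centres$id %in% r$centres$id))
  # missing detection at t = 5: bridge with a virtual centre at the midpoint
  keep <- f$centres$t != 5L
  f3 <- lineage_forest(f$centres[keep, ],
                       f$links[f$links$mother_id != 6L &
                                 f$links$daughter_id != 6L, ])
  r3 <- repair(f3, cfg)
  v <- r3$centres[r3$centres$virtual, ]
  expect_equal(nrow(v), 1L)
  expect_equal(v$t, 5L)
  expect_equal(c(v$x, v$y, v$z), c(10, 0, 0))   # midpoint of x = 8 and x = 12
  m <- embryotrack:::.mother_vector(r3)
  expect_false(any(is.na(m[r3$centres$t > 0])))  # track reconnected
  # a fully coherent forest is returned unchanged
  r0 <- repair(f, cfg)
  expect_equal(r0$centres, f$centres)
  expect_equal(r0$links, f$links)
})

test_that("labels propagate to all descendants and never mix clones", {
  cn <- data.frame(id = 1:7, t = c(0, 1, 1, 2, 2, 2, 2),
                   x = c(0, -2, 2, -3, -1, 1, 3), y = 0, z = 0)
  lk <- data.frame(mother_id = c(1, 1, 2, 2, 3, 3),
                   daughter_id = c(2, 3, 4, 5, 6, 7))
  f <- lineage_forest(cn, lk)
  lab <- propagate_labels(f, c("1" = "epiblast"))
  expect_length(lab, 7L)
  expect_true(all(lab == "epiblast"))
  # two roots with different labels: no centre carries both
  cn2 <- data.frame(id = 1:4, t = c(0, 0, 1, 1), x = c(0, 10, 0, 10),
                    y = 0, z = 0)
  f2 <- lineage_forest(cn2, data.frame(mother_id = c(1, 2),
                                       daughter_id = c(3, 4)))
  lab2 <- propagate_labels(f2, c("1" = "A", "2" = "B"))
  expect_equal(unname(lab2[c("3", "4")]), c("A", "B"))
  expect_error(propagate_labels(f2, c("42" = "X")), "unknown")
})

test_that("propagated clones equal the generator's clone partition", {
  sc <- synthetic_config(n_cells_initial = 3, n_frames = 8,
                         box_size = c(60, 60, 30), division_prob_per_frame = 0.1,
                         min_division_interval = 2, seed = 6)
  gold <- simulate_ground_truth(sc)
  f <- gold$forest
  roots <- f$centres$id[f$centres$t == 0]
  lab <- propagate_labels(f, stats::setNames(paste0("clone", seq_along(roots)),
                                             roots))
  expect_length(lab, nrow(f$centres))
  # every link joins same-label centres: clones never mix
  expect_true(all(lab[as.character(f$links$mother_id)] ==
                    lab[as.character(f$links$daughter_id)]))
})
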