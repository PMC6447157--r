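make_forest <- function(v, ids) build_forest(object_matrix(v, cell_ids = ids))

test_that("fate: divides after reference but before horizon is proliferative", {
  # cell alive at 374 divides at 500; daughters never divide
  v <- matrix(0L, 700, 3)
  v[1:500, 1] <- 1L; v[501:700, 2] <- 1L; v[501:700, 3] <- 2L
  f <- make_forest(v, c("A", "B", "C"))
  fl <- classify_fate(f, 374, 672)
  expect_equal(fl$fate[fl$cell_id == "A"], "proliferative")

  # alive at 374, never divides, tracked through horizon -> senescent
  v2 <- matrix(1L, 700, 1)
  f2 <- make_forest(v2, "S")
  expect_equal(classify_fate(f2, 374, 672)$fate, "senescent")

  # born exactly at the reference frame is assessed
  v3 <- matrix(0L, 700, 3)
  v3[1:373, 1] <- 1L; v3[374:700, 2] <- 1L; v3[374:700, 3] <- 2L
  f3 <- make_forest(v3, c("A", "B", "C"))
  fl3 <- classify_fate(f3, 374, 672)
  expect_setequal(fl3$cell_id, c("B", "C"))

  # track ending before horizon without division -> censored
  v4 <- matrix(0L, 500, 1); v4[1:500, 1] <- 1L
  f4 <- make_forest(v4, "X")
  expect_equal(classify_fate(f4, 374, 672)$fate, "censored")

  expect_error(classify_fate(f4, 800, 900), "beyond")
})

test_that("every cell alive at the reference frame gets exactly one fate label", {
  e <- simulate_colony(simulation_config(n_frames = 672, rng_seed = 31))
  f <- build_forest(export_tracking_matrix(e))
  fl <- classify_fate(f, 374, 672)
  expect_setequal(fl$cell_id, as.character(living_cells(e, 374)))
  expect_equal(anyDuplicated(fl$cell_id), 0L)
  expect_true(all(fl$fate %in% c("proliferative", "senescent", "censored")))
  # simulation truth: senescent-typed cells alive at 374 classify senescent
  truth <- e$cells$fate[match(as.integer(fl$cell_id), e$cells$cell_id)]
  expect_true(all(fl$fate[truth == "senescent"] == "senescent"))
})

test_that("progeny classes are a total order-preserving step function of n", {
  cls <- classify_progeny(stats::setNames(0:100, paste0("f", 0:100)))$class
  oracle <- ifelse(0:100 < 8, "slow", ifelse(0:100 > 16, "fast", "moderate"))
  expect_identical(cls, oracle)
  expect_equal(classify_progeny(7)$class, "slow")
  expect_equal(classify_progeny(8)$class, "moderate")
  expect_equal(classify_progeny(12)$class, "moderate")
  expect_equal(classify_progeny(16)$class, "moderate")
  expect_equal(classify_progeny(17)$class, "fast")
})

test_that("twin asynchrony uses a strict threshold and excludes undefined lifetimes", {
  # hand-built forest with one division; lifetimes 1.0 vs 1.4 d
  v <- matrix(0L, 500, 7)
  v[1:96, 1] <- 1L                     # founder
  v[97:192, 2] <- 1L                   # B: 96 frames = 1.0 d, divides
  v[97:231, 3] <- 2L                   # C: 135 frames ~ 1.406 d, divides
  v[193:500, 4] <- 1L; v[193:500, 5] <- 3L  # B's daughters
  v[232:500, 6] <- 1L; v[232:500, 7] <- 4L  # C's daughters
  f <- make_forest(v, c("F", "B", "C", "B1", "B2", "C1", "C2"))
  out <- classify_asynchrony(f, sd_d = 0.27)
  bc <- out[out$cell_1 %in% c("B", "C") & out$cell_2 %in% c("B", "C"), ]
  expect_equal(nrow(bc), 1L)
  expect_true(bc$asynchronous)         # |1.40625 - 1| > 0.27

  # equal lifetimes are synchronous; exactly-at-threshold is synchronous
  expect_false(0.27 > 0.27)
  out2 <- classify_asynchrony(f, sd_d = bc$delta_d)  # threshold == delta
  bc2 <- out2[out2$cell_1 %in% c("B", "C") & out2$cell_2 %in% c("B", "C"), ]
  expect_false(bc2$asynchronous)

  # pairs with undefined lifetime (leaf daughters) are excluded
  expect_false(any(out$cell_1 %in% c("B1", "C1")))
})

test_that("colony origin: SCD vs MCD, with infiltration flagged separately", {
  # single founder
  e1 <- simulate_colony(clockwork_config())
  f1 <- build_forest(export_tracking_matrix(e1))
  o1 <- classify_origin(f1, f1$records$cell_id)
  expect_equal(o1$origin, "SCD")
  expect_false(o1$infiltrated)

  # two founders
  e2 <- simulate_colony(simulation_config(n_frames = 420, n_founders = 2,
                                          rng_seed = 33))
  f2 <- build_forest(export_tracking_matrix(e2))
  o2 <- classify_origin(f2, f2$records$cell_id)
  expect_equal(o2$origin, "MCD")
  expect_equal(o2$n_founders, 2L)

  # SCD plus a late-joining root: still SCD, infiltrated
  v <- matrix(0L, 100, 4)
  v[1:50, 1] <- 1L; v[51:100, 2] <- 1L; v[51:100, 3] <- 2L
  v[80:100, 4] <- 3L   # migrates in at frame 80 (no coincident division)
  f3 <- make_forest(v, c("A", "B", "C", "Z"))
  o3 <- classify_origin(f3, c("B", "C", "Z"))
  expect_equal(o3$origin, "SCD")
  expect_true(o3$infiltrated)
  expect_error(classify_origin(f3, "nope"), "unknown member")
})

test_that("the colony predicate flips at 50 cells", {
  expect_false(is_colony(49))
  expect_true(is_colony(50))
  expect_false(is_colony(0))
  expect_identical(is_colony(c(10, 50, 120)), c(FALSE, TRUE, TRUE))
})

test_that("isolation scores follow the staged field-of-view schedule", {
  # foreign cell inside the initial 1.7 x 1.3 mm FOV at t = 0 -> 1
  s1 <- isolation_score(data.frame(time_d = 0, x_um = 500, y_um = 300))
  expect_equal(s1$score, 1L)
  # enters the initial FOV during the first two days -> 2
  s2 <- isolation_score(data.frame(time_d = c(0, 1), x_um = c(2000, 700),
                                   y_um = c(0, 0)))
  expect_equal(s2$score, 2L)
  # first visible when the FOV grows to 2.6 x 2.1 mm at Day 2 -> 3
  s3 <- isolation_score(data.frame(time_d = 0, x_um = 1100, y_um = 0))
  expect_equal(s3$score, 3L)
  # migrates into the expanded FOV between Days 2 and 6 -> 4
  s4 <- isolation_score(data.frame(time_d = c(0, 4), x_um = c(4000, 1200),
                                   y_um = c(0, 0)))
  expect_equal(s4$score, 4L)
  # nothing until the 3.5 x 2.6 mm grid at Day 6 (or never) -> 5
  s5 <- isolation_score(data.frame(time_d = 0, x_um = 1600, y_um = 0))
  expect_equal(s5$score, 5L)
  s5b <- isolation_score(data.frame(time_d = 0, x_um = 99999, y_um = 0))
  expect_equal(s5b$score, 5L)
  expect_true(is.na(s5b$first_visible_d))
})
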