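test_that("spearman coefficient: monotone sequences and the hand-ranked example", {
  expect_equal(spearman_rs(1:8, (1:8)^3)$r_s, 1)
  expect_equal(spearman_rs(1:8, -(1:8))$r_s, -1)
  # ranks d = (0,1,1,1,1), sum d^2 = 4: r = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_rs(1:5, c(1, 3, 2, 5, 4))$r_s, 0.8)
  # midrank tie handling matches the reference implementation
  x <- c(1, 2, 2, 3, 4, 5, 5, 6)
  y <- c(2, 1, 3, 3, 5, 4, 6, 7)
  expect_equal(spearman_rs(x, y)$r_s,
               unname(cor(x, y, method = "spearman")))
})

test_that("exact small-n p-values equal the exhaustive permutation oracle", {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  set.seed(99)
  for (n in c(4, 5, 6, 7)) {
    x <- sample(100, n)
    y <- sample(100, n)
    sp <- spearman_rs(x, y)
    rx <- rank(x)
    all_r <- vapply(perms(rank(y)), function(p) cor(rx, p), numeric(1))
    p_oracle <- mean(abs(all_r) >= abs(sp$r_s) - 1e-12)
    expect_equal(sp$p_value, p_oracle)
    # and the established implementation agrees (no ties, exact mode)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(sp$p_value, ct$p.value, tolerance = 1e-12)
  }
})

test_that("Bonferroni thresholds reproduce the published values", {
  expect_equal(bonferroni_threshold(0.05, 276), 0.05 / 276)
  expect_equal(signif(bonferroni_threshold(0.05, 276), 2), 1.8e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 105), 1), 5e-4)
})

test_that("correlation screen: pair count, masking, duplicates, symmetry", {
  set.seed(1)
  tab <- as.data.frame(matrix(rnorm(50 * 24), 50, 24))
  names(tab) <- paste0("p", 1:24)
  rep24 <- correlation_matrix(tab)
  expect_equal(rep24$m, choose(24, 2))  # 276
  expect_equal(rep24$bonferroni_p, 0.05 / 276)

  # fully masked property: n_used 0, no highlight
  tab$masked <- NA_real_
  rep2 <- correlation_matrix(tab, properties = c("p1", "p2", "masked"))
  mrow <- rep2$pairs[rep2$pairs$property_2 == "masked" |
                       rep2$pairs$property_1 == "masked", ]
  expect_true(all(mrow$n_used == 0))
  expect_true(all(mrow$highlight == "none"))

  # duplicated column: r_s = 1, pass_both
  tab$dup <- tab$p1
  rep3 <- correlation_matrix(tab, properties = c("p1", "dup", "p2"))
  drow <- rep3$pairs[rep3$pairs$property_1 == "p1" &
                       rep3$pairs$property_2 == "dup", ]
  expect_equal(drow$r_s, 1)
  expect_equal(drow$highlight, "pass_both")

  # symmetric matrix, invariant to property order
  repA <- correlation_matrix(tab, properties = c("p1", "p2", "p3"))
  repB <- correlation_matrix(tab, properties = c("p3", "p1", "p2"))
  expect_equal(repA$r_matrix, t(repA$r_matrix))
  nm <- c("p1", "p2", "p3")
  expect_equal(repA$r_matrix[nm, nm], repB$r_matrix[nm, nm])

  # r_critical gate downgrades weak-but-significant correlations
  repC <- correlation_matrix(tab, properties = c("p1", "dup", "p2"),
                             r_critical = 0.99)
  expect_equal(repC$pairs$highlight[repC$pairs$property_2 == "dup"][1],
               "pass_both")
})

test_that("binary t-tests: null vs separated groups and per-filter thresholds", {
  set.seed(2)
  n <- 50
  tab <- data.frame(a = rnorm(2 * n), b = c(rnorm(n), rnorm(n, 5)),
                    parent_max_area = rnorm(2 * n),
                    parent_lifetime = rnorm(2 * n),
                    parent_area_before_division = rnorm(2 * n))
  attr(tab, "filters") <- c(a = "none", b = "none",
                            parent_max_area = "parent",
                            parent_lifetime = "parent",
                            parent_area_before_division = "parent")
  g <- rep(c("x", "y"), each = n)
  out <- binary_ttests(tab, g)
  # identical-distribution property: not significant
  expect_false(out$significant[out$property == "a"])
  # strongly separated: significant at any per-filter threshold
  expect_true(out$significant[out$property == "b"])
  expect_lt(out$p_value[out$property == "b"], 1e-10)
  # Welch statistic agrees with the closed form
  brow <- out[out$property == "b", ]
  x1 <- tab$b[g == "x"]; x2 <- tab$b[g == "y"]
  welch <- (mean(x1) - mean(x2)) / sqrt(var(x1) / n + var(x2) / n)
  expect_equal(brow$t, welch)
  # three parent properties share filter "parent": threshold 0.05/3
  expect_equal(unique(out$threshold[out$filter_id == "parent"]), 0.05 / 3)
  expect_equal(unique(out$threshold[out$filter_id == "none"]), 0.05 / 2)
})

test_that("generation-area trends: exact halving, constant areas, simulated majority negative", {
  tab <- data.frame(generation = rep(1:5, each = 2),
                    avg_area_first_083d = 1000 / 2^rep(1:5, each = 2),
                    colony_id = "c1")
  tr <- generation_area_trend(tab)
  expect_equal(tr$r_s, -1)

  tab2 <- data.frame(generation = 1:6, avg_area_first_083d = 7,
                     colony_id = "c2")
  tr2 <- generation_area_trend(tab2)
  expect_true(is.na(tr2$r_s))
  expect_equal(tr2$p_value, 1)
  expect_true(tr2$degenerate)

  # simulated defaults: most progenies trend negative
  trs <- c()
  for (s in 1:12) {
    e <- simulate_colony(simulation_config(n_frames = 384, rng_seed = 600 + s))
    f <- build_forest(export_tracking_matrix(e))
    ft <- build_feature_table(f, e$tracks, day4_frame = NULL)
    trs <- c(trs, generation_area_trend(ft)$r_s)
  }
  trs <- trs[!is.na(trs)]
  expect_gt(mean(trs < 0), 0.5)
})

test_that("generation dispersion: uniform colonies score 0, {4,4,5,5} scores 0.577", {
  e <- simulate_colony(clockwork_config())
  f <- build_forest(export_tracking_matrix(e))
  expect_equal(unname(generation_dispersion(f, 374)), 0)

  # a stochastic tree: dispersion equals the sample SD of living generations
  cfg <- simulation_config(n_frames = 300, n_founders = 1,
                           lifetime_mean_d = 1, lifetime_sd_d = 0.4,
                           founder_lag_mean_d = 0.5,
                           p_senescent_daughter = 0, rng_seed = 8)
  e2 <- simulate_colony(cfg)
  f2 <- build_forest(export_tracking_matrix(e2))
  r <- f2$records
  found <- FALSE
  for (fr in seq(50, 300, by = 10)) {
    gg <- sort(r$generation[r$birth_frame <= fr & r$last_frame >= fr])
    if (length(gg) >= 3 && stats::sd(gg) > 0) {
      expect_equal(unname(generation_dispersion(f2, fr)), stats::sd(gg))
      found <- TRUE
      break
    }
  }
  expect_true(found)
  # hand value: sample SD of {4,4,5,5}
  expect_equal(stats::sd(c(4, 4, 5, 5)), 0.5773503, tolerance = 1e-6)
})

test_that("PCA embedding: cluster-count rule, variance bookkeeping, duplicates, loadings", {
  # k = round(sqrt(N/2)): N = 1384 -> 26
  expect_equal(round(sqrt(1384 / 2)), 26)
  set.seed(3)
  tab <- as.data.frame(matrix(rnorm(200 * 6), 200, 6))
  emb <- pca_embed(tab)
  expect_equal(emb$k, round(sqrt(200 / 2)))
  expect_equal(sum(emb$explained_variance), 6, tolerance = 1e-9)
  # scores are orthogonal
  cp <- crossprod(emb$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)

  # variation in one column only -> PC1 loading concentrated there
  tab2 <- data.frame(a = rnorm(100), b = rnorm(100, sd = 1))
  tab2$b <- tab2$b * 1  # both standardized; use a mixed third instead
  tab3 <- data.frame(u = rnorm(100), v = rnorm(100))
  tab3$w <- tab3$u + rnorm(100, sd = 1e-6)  # w duplicates u
  emb3 <- pca_embed(tab3, k = 2)
  l1 <- abs(emb3$loadings[, 1])
  expect_setequal(names(sort(l1, decreasing = TRUE))[1:2], c("u", "w"))

  # duplicated rows get identical scores and clusters
  tab4 <- rbind(tab, tab)
  emb4 <- pca_embed(tab4, k = 5)
  n <- nrow(tab)
  expect_equal(emb4$scores[1:n, ], emb4$scores[n + (1:n), ])
  expect_equal(unname(emb4$cluster[1:n]), unname(emb4$cluster[n + (1:n)]))
  # masked rows are dropped
  tab$V1[1] <- NA
  emb5 <- pca_embed(tab)
  expect_equal(emb5$rows_used, 2:200)
})

test_that("pipeline recovers the generator lifetime parameters", {
  forests <- lapply(1:30, function(i) {
    build_forest(export_tracking_matrix(simulate_colony(
      simulation_config(n_frames = 384, rng_seed = 800 + i))))
  })
  s <- dividing_lifetime_stats(forests)
  expect_lt(abs(s$mean_d - 0.83), 0.05)
  expect_lt(abs(s$sd_d - 0.27), 0.05)
})
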