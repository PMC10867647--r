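test_that("timepoint medians follow the odd/even conventions", {
  meta <- toy_meta(1:3, c(0, 14))
  m <- matrix(c(1, 2, 9, 1, 3, 5), 1, 6,
              dimnames = list("met", meta$sample_id[order(meta$day)]))
  m <- m[, meta$sample_id, drop = FALSE]
  mm <- metabolite_matrix(m, meta)
  prof <- timepoint_medians(mm, "C")
  # day 0 samples are (1,2,9) -> median 2; day 14 (1,3,5) -> 3;
  # profiles are kept on the log2 scale
  expect_equal(unname(2^prof$profile["met", ]), c(2, 3))

  meta2 <- toy_meta(1:2, c(0, 14))
  m2 <- matrix(c(1, 3, 7, 7), 1, 4,
               dimnames = list("met", meta2$sample_id))
  mm2 <- metabolite_matrix(m2[, meta2$sample_id, drop = FALSE], meta2)
  prof2 <- timepoint_medians(mm2, "C")
  # even n: mean of the middle pair
  expect_equal(unname(2^prof2$profile["met", "0"]), 2)

  m3 <- m2; m3[1, meta2$day == 14] <- NA
  expect_error(timepoint_medians(
    metabolite_matrix(m3, meta2), "C"), "met.*14|14.*met")
})

test_that("standardization z-scores rows, drops zero variance, is idempotent", {
  x <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 2, 2, 2, 2),
             c = c(5, 1, 4, 2, 3))
  prof <- standardize_profile(as_profile(x, c(0, 14, 28, 63, 91)))
  expect_identical(prof$dropped_zero_variance, "b")
  expect_equal(unname(rowMeans(prof$profile)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(prof$profile, 1, sd)), c(1, 1),
               tolerance = 1e-9)
  # standardizing an already-standardized row changes nothing
  again <- standardize_profile(as_profile(prof$profile,
                                          prof$timepoints))
  expect_equal(again$profile, prof$profile, tolerance = 1e-9)
  expect_error(standardize_profile(prof), "already")
  expect_error(standardize_profile(as_profile(rbind(c(1, 1, 1)))),
               "zero variance")
})

test_that("fuzzy c-means honors forced cases: c = 1 and symmetric ties", {
  prof <- random_profile(10, 5, seed = 2L)
  fit1 <- fuzzy_cmeans(prof, 1, seed = 1L)
  expect_true(all(fit1$membership == 1))
  expect_equal(unname(fit1$centroids[1, ]),
               unname(colMeans(prof$profile)), tolerance = 1e-9)

  # a point equidistant from two symmetric centroids gets (0.5, 0.5)
  x <- rbind(c(-1, 0), c(-1, 0), c(1, 0), c(1, 0), c(0, 0))
  prof2 <- as_profile(x, 1:2, standardized = TRUE)
  fit2 <- fuzzy_cmeans(prof2, 2, m = 2, seed = 3L,
                       init = rbind(c(-1, 0), c(1, 0)))
  expect_equal(unname(fit2$membership[5, ]), c(0.5, 0.5),
               tolerance = 1e-9)

  expect_error(fuzzy_cmeans(prof, 0), "c must")
  expect_error(fuzzy_cmeans(prof, 11), "c must")
  expect_error(fuzzy_cmeans(prof, 2, m = 1), "m must")
  expect_error(fuzzy_cmeans(as_profile(matrix(1:10, 5, 2)), 2),
               "standardized")
})

test_that("fuzzy c-means matches the naive reference from a shared init", {
  for (s in 1:5) {
    prof <- random_profile(20, 5, seed = 100L + s)
    c <- 2L + (s %% 3L)
    init <- prof$profile[seq_len(c) * 3L, , drop = FALSE]
    fit <- fuzzy_cmeans(prof, c, m = 2, init = init)
    ref <- naive_fcm(prof$profile, c, m = 2, init = init)
    expect_lt(max(abs(fit$membership - ref$membership)), 1e-8)
    expect_lt(abs(fit$objective - ref$objective), 1e-8)
  }
})

test_that("memberships normalize and the objective never increases", {
  for (s in 1:20) {
    prof <- random_profile(12L + (s %% 5L), 5, seed = 300L + s)
    c <- 2L + (s %% 3L)
    m <- c(1.5, 2, 2.5)[1L + (s %% 3L)]
    fit <- fuzzy_cmeans(prof, c, m = m, seed = s)
    expect_lt(max(abs(rowSums(fit$membership) - 1)), 1e-9)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
  }
})

test_that("the fuzzifier heuristic returns configured or estimated values", {
  prof <- random_profile(50, 5, seed = 4L)
  expect_equal(estimate_fuzzifier(prof, 2), 2)
  expect_equal(estimate_fuzzifier(prof, 1.5), 1.5)
  expect_gt(estimate_fuzzifier(prof, "estimate"), 1)
  expect_error(estimate_fuzzifier(prof, 0.9), "> 1")
})

test_that("the Dmin curve is deterministic, non-negative, and drops past the true c", {
  tp <- c(0, 14, 28, 63, 91)
  templates <- archetype_templates(tp)
  tm <- as.matrix(templates[templates$pattern_id %in% c(1, 3, 5),
                            as.character(tp)])
  x <- withr::with_seed(5L, {
    base <- tm[rep(1:3, each = 15), ]
    base + matrix(rnorm(length(base), 0, 0.1), nrow(base))
  })
  prof <- standardize_profile(as_profile(x, tp))
  curve1 <- dmin_curve(prof, c_min = 2L, c_max = 6L, m = 2, seed = 9L)
  curve2 <- dmin_curve(prof, c_min = 2L, c_max = 6L, m = 2, seed = 9L)
  expect_identical(curve1, curve2)
  expect_true(all(curve1$dmin >= 0))
  d3 <- curve1$dmin[curve1$c == 3]
  d4 <- curve1$dmin[curve1$c == 4]
  expect_lt(d4, 0.5 * d3)
  expect_equal(suppressWarnings(select_optimal_c(curve1)), 3L,
               ignore_attr = TRUE)
})

test_that("select_optimal_c follows the relative-drop rule on a stated curve", {
  fake <- structure(data.frame(c = 2:6, dmin = c(10, 9.5, 4, 3.8, 3.7)),
                    class = c("DminCurve", "data.frame"))
  # r = {0.05, 0.58, 0.05, 0.026}: only the c = 3 drop qualifies
  expect_equal(select_optimal_c(fake), 3L)
  flat <- structure(data.frame(c = 2:6, dmin = rep(5, 5)),
                    class = c("DminCurve", "data.frame"))
  expect_warning(got <- select_optimal_c(flat), "c_min")
  expect_equal(as.integer(got), 2L)
  expect_true(attr(got, "flat_curve"))
  expect_equal(select_optimal_c(fake, force_c = 4L), 4L)
})

test_that("core membership uses a strict threshold and ties break low", {
  u <- rbind(a = c(0.71, 0.29), b = c(0.70, 0.30), c = c(0.5, 0.5),
             d = c(0.05, 0.95))
  fit <- structure(list(c = 2L, m = 2, membership = u,
                        centroids = matrix(0, 2, 3)),
                   class = "ClusterResult")
  core <- core_members(fit, 0.7)
  expect_identical(core$metabolite, c("a", "d"))
  expect_identical(core$cluster, c(1L, 2L))
  # exact tie 0.5/0.5 assigns to cluster 1 but fails the 0.7 cut
  all_core <- core_members(fit, 0.2)
  expect_equal(all_core$cluster[all_core$metabolite == "c"], 1L)
  # c = 1: everything is core with membership 1
  prof <- random_profile(6, 4, seed = 6L)
  fit1 <- fuzzy_cmeans(prof, 1, seed = 1L)
  expect_equal(nrow(core_members(fit1)), 6L)
})

test_that("heatmap rows sort by (cluster, descending membership)", {
  prof <- random_profile(30, 5, seed = 12L)
  fit <- fuzzy_cmeans(prof, 3, seed = 12L)
  core <- core_members(fit, 0.5)
  hm <- heatmap_matrix(fit, core, prof)
  ord <- order(core$cluster, -core$membership)
  expect_identical(rownames(hm), core$metabolite[ord])
  expect_equal(unname(hm[1, ]), unname(prof$profile[rownames(hm)[1], ]))
  empty <- core[0, , drop = FALSE]
  expect_warning(hm0 <- heatmap_matrix(fit, empty, prof), "empty core")
  expect_equal(nrow(hm0), 0L)
})
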