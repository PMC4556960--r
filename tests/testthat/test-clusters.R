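test_that("connectivity semantics separate corner-touching blobs", {
  m <- array(FALSE, c(6, 6, 6))
  m[1:2, 1:2, 1] <- TRUE                   # blob of 4
  m[3, 3, 2] <- TRUE                       # touches (2,2,1) only at a corner
  lab6 <- label_components(m, 6)
  lab18 <- label_components(m, 18)
  lab26 <- label_components(m, 26)
  expect_equal(max(lab6), 2)
  expect_equal(max(lab18), 2)              # corner contact is not an edge
  expect_equal(max(lab26), 1)
  # edge contact joins under 18 but not 6
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 1] <- TRUE
  expect_equal(max(label_components(m2, 6)), 2)
  expect_equal(max(label_components(m2, 18)), 1)
  expect_error(label_components(m2, 10), "connectivity")
})

test_that("cluster extraction reports peaks, extents and volumes", {
  mask <- array(TRUE, c(6, 6, 6))
  stat <- array(0, c(6, 6, 6)); p <- array(1, c(6, 6, 6))
  blob4 <- rbind(c(2, 2, 2), c(3, 2, 2), c(2, 3, 2), c(2, 2, 3))
  for (i in seq_len(4)) {
    stat[blob4[i, 1], blob4[i, 2], blob4[i, 3]] <- 4 + i
    p[blob4[i, 1], blob4[i, 2], blob4[i, 3]] <- 0.001
  }
  stat[6, 6, 6] <- 9; p[6, 6, 6] <- 0.001
  stat[6, 6, 5] <- 3; p[6, 6, 5] <- 0.01   # blob of 2
  sr <- fcdmap:::stat_result(stat, "F", c(2, 10), p, mask, 3)
  tab <- extract_clusters(sr, voxel_p = 0.05, extent_threshold = 3,
                          connectivity = 6, voxel_size_mm = 3)
  expect_equal(nrow(tab), 1)               # the 2-blob is filtered out
  expect_equal(tab$extent_voxels, 4)
  expect_equal(tab$extent_mm3, 108)        # 4 voxels x 27 mm^3
  expect_equal(tab$peak_stat, 8)           # peak at (2,2,3)
  expect_equal(c(tab$peak_x_mm, tab$peak_y_mm, tab$peak_z_mm),
               (c(2, 2, 3) - 1) * 3)
  # peak ties break at the lowest linear index
  stat2 <- array(0, c(4, 4, 4)); p2 <- array(1, c(4, 4, 4))
  stat2[2:3, 2, 2] <- 5; p2[2:3, 2, 2] <- 0.001
  sr2 <- fcdmap:::stat_result(stat2, "F", c(2, 10), p2,
                              array(TRUE, c(4, 4, 4)), 3)
  tab2 <- extract_clusters(sr2, 0.05, 1, 6, 3)
  expect_equal(tab2$peak_x_mm, 3)          # voxel (2,2,2), not (3,2,2)
  # nothing suprathreshold gives an empty table
  sr3 <- fcdmap:::stat_result(stat2 * 0, "F", c(2, 10),
                              array(1, c(4, 4, 4)),
                              array(TRUE, c(4, 4, 4)), 3)
  expect_equal(nrow(extract_clusters(sr3, 0.05, 1)), 0)
})

test_that("one-sided extraction selects the requested direction", {
  mask <- array(TRUE, c(4, 4, 4))
  stat <- array(0, c(4, 4, 4)); p <- array(1, c(4, 4, 4))
  stat[1, 1, 1] <- 4; p[1, 1, 1] <- 0.004
  stat[4, 4, 4] <- -4; p[4, 4, 4] <- 0.004
  sr <- fcdmap:::stat_result(stat, "t", 10, p, mask, 3)
  both <- extract_clusters(sr, 0.05, 1, 6, 3)
  pos <- extract_clusters(sr, 0.05, 1, 6, 3, alternative = "greater")
  neg <- extract_clusters(sr, 0.05, 1, 6, 3, alternative = "less")
  expect_equal(nrow(both), 2)
  expect_equal(nrow(pos), 1); expect_gt(pos$peak_stat, 0)
  expect_equal(nrow(neg), 1); expect_lt(neg$peak_stat, 0)
})

test_that("Monte-Carlo extent threshold honors its definition", {
  mask <- array(TRUE, c(8, 8, 8))
  # alpha = 1 accepts every cluster
  mc1 <- monte_carlo_extent_threshold(mask, 0.05, 6, 3, 18, alpha = 1,
                                      n_iterations = 100, seed = 1)
  expect_equal(mc1$extent_threshold, 1)
  # determinism
  mc2 <- monte_carlo_extent_threshold(mask, 0.05, 6, 3, 18, 0.05,
                                      n_iterations = 150, seed = 7)
  mc3 <- monte_carlo_extent_threshold(mask, 0.05, 6, 3, 18, 0.05,
                                      n_iterations = 150, seed = 7)
  expect_identical(mc2$max_cluster_sizes, mc3$max_cluster_sizes)
  expect_identical(mc2$extent_threshold, mc3$extent_threshold)
  # the threshold is the smallest k with P(max >= k) <= alpha
  k <- mc2$extent_threshold
  expect_lte(mean(mc2$max_cluster_sizes >= k), 0.05)
  if (k > 1) expect_gt(mean(mc2$max_cluster_sizes >= k - 1), 0.05)
})

test_that("a single-voxel mask reduces to a Bernoulli(voxel_p) null", {
  mask <- array(FALSE, c(3, 3, 3)); mask[2, 2, 2] <- TRUE
  mc <- monte_carlo_extent_threshold(mask, 0.05, 8, 3, 18, 0.05,
                                     n_iterations = 2000, seed = 3)
  expect_equal(mean(mc$max_cluster_sizes >= 1), 0.05, tolerance = 0.4)
  expect_true(all(mc$max_cluster_sizes %in% c(0L, 1L)))
})

test_that("extent threshold responds monotonically to its drivers", {
  mask <- array(TRUE, c(10, 10, 10))
  th <- function(vp, fw)
    monte_carlo_extent_threshold(mask, vp, fw, 3, 18, 0.05,
                                 n_iterations = 200,
                                 seed = 5)$extent_threshold
  # stricter voxel threshold -> smaller clusters needed
  expect_lte(th(0.01, 6), th(0.05, 6))
  # more smoothing -> larger clusters needed
  expect_lte(th(0.05, 4), th(0.05, 9))
})

test_that("the ANOVA-field null yields smaller thresholds than Gaussian", {
  # an F field built from smooth components is effectively rougher than a
  # single Gaussian field at the same nominal smoothness
  mask <- array(TRUE, c(10, 10, 10))
  g <- monte_carlo_extent_threshold(mask, 0.05, 8, 3, 18, 0.05,
                                    n_iterations = 200, seed = 6)
  a <- monte_carlo_extent_threshold(mask, 0.05, 8, 3, 18, 0.05,
                                    n_iterations = 200, seed = 6,
                                    null_model = "anova",
                                    groups = rep(1:3, each = 8),
                                    n_covariates = 3)
  expect_lt(a$extent_threshold, g$extent_threshold)
  expect_error(monte_carlo_extent_threshold(mask, 0.05, 8, 3, 18, 0.05,
                                            100, 1, null_model = "anova"),
               "groups")
})
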