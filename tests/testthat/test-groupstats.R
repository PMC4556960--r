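test_that("covariate residualization matches a normal-equations oracle", {
  set.seed(31)
  n <- 20
  cov <- data.frame(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
                    edu = rnorm(n, 10, 3))
  # values exactly 2*age are fully explained (constant residuals)
  v <- 2 * cov$age
  r <- regress_covariates(v, cov)
  expect_lt(max(abs(r - mean(v))), 1e-8)
  # covariates orthogonal to the values leave them unchanged up to mean
  v2 <- rnorm(n)
  v2o <- unname(residuals(lm(v2 ~ age + sex + edu, data = cov)))
  r2 <- regress_covariates(v2o, cov)
  expect_equal(r2 - mean(r2), v2o - mean(v2o), tolerance = 1e-8,
               ignore_attr = TRUE)
  # random case against lm(), matrix-valued
  V <- matrix(rnorm(n * 5), n)
  R <- regress_covariates(V, cov)
  for (j in 1:5) {
    o <- residuals(lm(V[, j] ~ age + sex + edu, data = cov)) + mean(V[, j])
    expect_equal(unname(R[, j]), unname(o), tolerance = 1e-10)
  }
  expect_equal(attr(R, "n_covariates"), 3L)
  expect_error(regress_covariates(v, cbind(cov, age2 = cov$age * 1)),
               "collinear")
})

test_that("one-sample t matches a scalar t.test oracle voxelwise", {
  mask <- array(TRUE, c(4, 4, 4))
  maps <- random_maps(5, c(4, 4, 4), seed = 32)
  st <- one_sample_t(maps, mask)
  expect_equal(st$df, 4)
  Y <- sapply(maps, function(m) m[2, 3, 4])
  o <- t.test(Y)
  expect_equal(st$stat_map[2, 3, 4], unname(o$statistic), tolerance = 1e-10)
  expect_equal(st$p_map[2, 3, 4], o$p.value, tolerance = 1e-10)
  # degenerate cases
  const <- lapply(1:4, function(i) array(2, c(2, 2, 2)))
  expect_warning(stc <- one_sample_t(const, array(TRUE, c(2, 2, 2))),
                 "degenerate")
  expect_true(all(is.infinite(stc$stat_map)))
  expect_equal(max(stc$p_map), 0)
  anti <- list(array(1, c(2, 2, 2)), array(-1, c(2, 2, 2)))
  sta <- one_sample_t(anti, array(TRUE, c(2, 2, 2)))
  expect_equal(max(abs(sta$stat_map)), 0)
  expect_equal(min(sta$p_map), 1)
})

test_that("two-group ANOVA without covariates equals the squared pooled t", {
  mask <- array(TRUE, c(4, 4, 4))
  maps <- random_maps(11, c(4, 4, 4), seed = 33)
  gr <- rep(c("a", "b"), c(5, 6))
  an <- one_way_anova(maps, gr, mask)
  expect_equal(an$df, c(1, 9))
  Y1 <- sapply(maps[1:5], function(m) m[1, 2, 3])
  Y2 <- sapply(maps[6:11], function(m) m[1, 2, 3])
  tt <- t.test(Y1, Y2, var.equal = TRUE)
  expect_equal(an$stat_map[1, 2, 3], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(an$p_map[1, 2, 3], tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA p-values are calibrated under the null", {
  mask <- array(TRUE, c(10, 10, 10))  # 1000 independent voxels
  maps <- random_maps(18, c(10, 10, 10), seed = 34)
  gr <- rep(c("a", "b", "c"), each = 6)
  an <- one_way_anova(maps, gr, mask)
  frac <- mean(an$p_map < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  # with a planted shift, F is large at the planted voxel, null elsewhere
  at <- 271
  maps2 <- random_maps(18, c(10, 10, 10), seed = 35,
                       shift = rep(c(0, 0, 8), each = 6),
                       shift_at = at)
  an2 <- one_way_anova(maps2, gr, mask)
  expect_gt(an2$stat_map[at], qf(0.999, 2, 15))
  expect_lt(mean(an2$p_map[-at] < 0.05), 0.1)
})

test_that("constant covariate columns are dropped, not fatal", {
  # single-sex subsamples happen in small cohorts; the indicator carries
  # no information beyond the intercept and must not abort the analysis
  maps <- random_maps(9, c(3, 3, 3), seed = 40)
  gr <- rep(c("a", "b", "c"), each = 3)
  cov <- data.frame(age = rnorm(9), sex01 = rep(1, 9), edu = rnorm(9))
  an <- one_way_anova(maps, gr, array(TRUE, c(3, 3, 3)), cov)
  expect_equal(an$df, c(2, 9 - 3 - 2))
})

test_that("ANOVA respects covariate degrees of freedom", {
  mask <- array(TRUE, c(3, 3, 3))
  maps <- random_maps(15, c(3, 3, 3), seed = 36)
  gr <- rep(c("a", "b", "c"), each = 5)
  cov <- data.frame(age = rnorm(15), sex = rbinom(15, 1, 0.5))
  an <- one_way_anova(maps, gr, mask, cov)
  expect_equal(an$df, c(2, 15 - 3 - 2))
  expect_error(one_way_anova(maps[1:7], rep(c("a", "b"), c(6, 1)), mask),
               "at least 2")
})

test_that("post-hoc t is antisymmetric and matches the scalar oracle", {
  mask <- array(TRUE, c(4, 4, 4))
  maps <- random_maps(14, c(4, 4, 4), seed = 37)
  gr <- rep(c("a", "b"), each = 7)
  ph <- posthoc_t(maps, gr, c("a", "b"), mask, mask)
  Y1 <- sapply(maps[1:7], function(m) m[4, 4, 4])
  Y2 <- sapply(maps[8:14], function(m) m[4, 4, 4])
  tt <- t.test(Y1, Y2, var.equal = TRUE)
  expect_equal(ph$stat_map[4, 4, 4], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(ph$df, 12)
  # swapping the pair negates the map exactly
  ph2 <- posthoc_t(maps, gr, c("b", "a"), mask, mask)
  expect_equal(ph$stat_map, -ph2$stat_map, tolerance = 1e-12)
  # identical groups give a null map
  same <- c(maps[1:7], maps[1:7])
  ph3 <- posthoc_t(same, gr, c("a", "b"), mask, mask)
  expect_equal(max(abs(ph3$stat_map)), 0)
  # restriction mask confines the test
  rm <- array(FALSE, c(4, 4, 4)); rm[1:2, 1, 1] <- TRUE
  ph4 <- posthoc_t(maps, gr, c("a", "b"), rm, mask)
  expect_equal(ph4$stat_map[4, 4, 4], 0)
  expect_equal(ph4$p_map[4, 4, 4], 1)
  expect_equal(ph4$stat_map[1, 1, 1], ph$stat_map[1, 1, 1])
  expect_warning(posthoc_t(maps, gr, c("a", "b"),
                           array(FALSE, c(4, 4, 4)), mask), "empty")
})

test_that("subject-order permutation leaves the statistics unchanged", {
  mask <- array(TRUE, c(3, 3, 3))
  maps <- random_maps(12, c(3, 3, 3), seed = 38)
  gr <- rep(c("a", "b", "c"), each = 4)
  cov <- data.frame(age = rnorm(12))
  set.seed(39); perm <- sample(12)
  an1 <- one_way_anova(maps, gr, mask, cov)
  an2 <- one_way_anova(maps[perm], gr[perm], mask,
                       cov[perm, , drop = FALSE])
  expect_equal(an1$stat_map, an2$stat_map, tolerance = 1e-10)
})
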