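test_that("the 3 mm local sphere on a 3 mm grid holds exactly 7 voxels", {
  off <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  d <- sqrt(rowSums((off * 3)^2))
  expect_equal(sum(d <= 3), 7)  # seed + 6 face neighbors
  # and the implementation's local sum ranges over the 6 non-seed members:
  # three voxels sharing a noise-free sinusoid, one adjacent to the seed
  nt <- 48
  s <- sin(2 * pi * seq_len(nt) / 16)
  b <- noise_bold(c(6, 6, 6), nt = nt, seed = 1)
  # orthogonalize the background against the sinusoid so its correlations
  # with the planted voxels are exactly zero
  Y <- matrix(b$data, 216, nt)
  Y <- Y - (Y %*% s) %*% t(s) / sum(s^2)
  b$data <- array(Y, c(6, 6, 6, nt))
  b$data[3, 3, 3, ] <- s
  b$data[4, 3, 3, ] <- s            # face neighbor, d = 3 mm
  b$data[6, 6, 6, ] <- s            # far corner, d = sqrt(3)*9 mm > 3
  f <- compute_fcd(b, distant_radius_mm = 12)
  # each of the three has two perfectly correlated partners: total = 2
  expect_equal(f$total[3, 3, 3], 2, tolerance = 1e-6)
  expect_equal(f$local[3, 3, 3], 1, tolerance = 1e-6)  # only the neighbor
  d_corner <- sqrt(sum((c(6, 6, 6) - c(3, 3, 3))^2)) * 3
  expect_gt(d_corner, 12)
  expect_equal(f$distant[3, 3, 3], 1, tolerance = 1e-6)
})

test_that("mutually orthogonal series give all-zero maps", {
  nt <- 64
  freqs <- seq_len(8)
  dat <- array(0, c(2, 2, 2, nt))
  k <- 1
  for (i in 1:2) for (j in 1:2) for (l in 1:2) {
    dat[i, j, l, ] <- sin(2 * pi * freqs[k] * seq_len(nt) / nt)
    k <- k + 1
  }
  f <- compute_fcd(bold_image(dat), distant_radius_mm = 4)
  expect_equal(max(abs(f$total)), 0)
  expect_equal(max(abs(f$local)), 0)
  expect_equal(max(abs(f$distant)), 0)
})

test_that("blocked implementation matches the all-pairs oracle elementwise", {
  # masked 10x10x10 grid (= 1000 voxels, ~700 in mask)
  set.seed(21)
  mask <- array(runif(1000) < 0.7, c(10, 10, 10))
  b <- noise_bold(c(10, 10, 10), nt = 30, seed = 22, mask = mask)
  f <- compute_fcd(b, distant_radius_mm = 12)
  o <- fcd_oracle(b, distant_mm = 12)
  expect_lt(max(abs(f$total[o$idx] - o$total)), 1e-10)
  expect_lt(max(abs(f$local[o$idx] - o$local)), 1e-10)
  expect_lt(max(abs(f$distant[o$idx] - o$distant)), 1e-10)
  expect_lt(max(abs(f$gap[o$idx] - o$gap)), 1e-10)
  # out-of-mask voxels stay zero
  expect_equal(max(abs(f$total[!mask])), 0)
})

test_that("results are independent of the processing block size", {
  b <- noise_bold(c(6, 6, 6), nt = 25, seed = 3)
  f1 <- compute_fcd(b, distant_radius_mm = 10, block_size = 256)
  f2 <- compute_fcd(b, distant_radius_mm = 10, block_size = 7)
  f3 <- compute_fcd(b, distant_radius_mm = 10, block_size = 1)
  expect_equal(f1$total, f2$total, tolerance = 1e-12)
  expect_equal(f1$total, f3$total, tolerance = 1e-12)
  expect_equal(f1$distant, f3$distant, tolerance = 1e-12)
})

test_that("local + gap + distant decompose the total at every voxel", {
  for (seed in 1:3) {
    b <- noise_bold(c(7, 7, 7), nt = 20, seed = seed)
    f <- compute_fcd(b, distant_radius_mm = 10)
    expect_lt(max(abs(f$total - (f$local + f$gap + f$distant))), 1e-10)
  }
})

test_that("raising the threshold never increases any map value", {
  b <- noise_bold(c(6, 6, 6), nt = 30, seed = 6)
  f1 <- compute_fcd(b, r_threshold = 0.25, distant_radius_mm = 10)
  f2 <- compute_fcd(b, r_threshold = 0.4, distant_radius_mm = 10)
  expect_true(all(f2$total <= f1$total + 1e-12))
  expect_true(all(f2$local <= f1$local + 1e-12))
  expect_true(all(f2$distant <= f1$distant + 1e-12))
})

test_that("maps are invariant to positive rescaling of any series", {
  b <- noise_bold(c(5, 5, 5), nt = 25, seed = 8)
  f1 <- compute_fcd(b, distant_radius_mm = 9)
  b$data[2, 3, 4, ] <- 17.5 * b$data[2, 3, 4, ]
  b$data[5, 5, 5, ] <- 0.01 * b$data[5, 5, 5, ]
  f2 <- compute_fcd(b, distant_radius_mm = 9)
  expect_equal(f1$total, f2$total, tolerance = 1e-10)
  expect_equal(f1$local, f2$local, tolerance = 1e-10)
})

test_that("zero-variance in-mask voxels are rejected with guidance", {
  b <- noise_bold(c(4, 4, 4), nt = 20, seed = 9)
  b$data[2, 2, 2, ] <- 5
  expect_error(compute_fcd(b), "zero temporal variance")
  b$mask[2, 2, 2] <- FALSE
  expect_s3_class(compute_fcd(b, distant_radius_mm = 8), "fcd_maps")
})

test_that("normalization divides by the in-mask mean", {
  b <- noise_bold(c(6, 6, 6), nt = 30, seed = 10)
  f <- compute_fcd(b, distant_radius_mm = 10)
  fn <- normalize_fcd(f)
  for (m in c("total", "local", "distant"))
    expect_equal(mean(fn[[m]][fn$brain_mask]), 1, tolerance = 1e-10)
  expect_true(fn$normalized)
  # arithmetic: a {1, 3} map over two voxels normalizes to {0.5, 1.5}
  x <- c(1, 3)
  expect_equal(x / mean(x), c(0.5, 1.5))
  # constant maps normalize to all ones (via the total divisor)
  f2 <- f
  for (m in c("total", "local", "gap", "distant"))
    f2[[m]] <- array(4, dim(f$total))
  fn2 <- normalize_fcd(f2, divisor = "total")
  expect_equal(unique(as.vector(fn2$total[fn2$brain_mask])), 1)
  # degenerate all-zero map cannot be normalized
  f3 <- f; f3$distant <- array(0, dim(f$total))
  expect_error(normalize_fcd(f3), "not positive")
})

test_that("Gaussian smoothing has the stated FWHM and preserves constants", {
  # fwhm = 0 is the identity
  m <- array(rnorm(27), c(3, 3, 3))
  expect_identical(smooth_map(m, 0), m)
  # impulse response has 8 mm FWHM within half a voxel
  d <- array(0, c(15, 15, 15)); d[8, 8, 8] <- 1
  s <- smooth_map(d, 8, 3)
  prof <- s[, 8, 8]
  half <- max(prof) / 2
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  # linear interpolation of the half-maximum crossings
  x_lo <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  x_hi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm_mm <- (x_hi - x_lo) * 3
  expect_equal(fwhm_mm, 8, tolerance = 1.5 / 8)  # within half a voxel
  # constants are exactly preserved under mask renormalization
  cst <- array(3.7, c(8, 8, 8))
  mask <- array(TRUE, c(8, 8, 8)); mask[1:2, , ] <- FALSE
  sm <- smooth_map(cst, 8, 3, mask)
  expect_equal(unique(round(sm[mask], 10)), 3.7)
  expect_equal(max(abs(sm[!mask])), 0)
  expect_error(smooth_map(cst, -1), ">= 0")
})

test_that("FCD maps round-trip through NIfTI with a JSON sidecar", {
  b <- noise_bold(c(6, 6, 6), nt = 25, seed = 12)
  f <- normalize_fcd(compute_fcd(b, distant_radius_mm = 10))
  pre <- file.path(withr::local_tempdir(), "sub-001")
  paths <- write_fcd_maps(f, pre)
  expect_true(all(file.exists(paths)))
  back <- RNifti::readNifti(paths["total"])
  expect_equal(array(as.numeric(back), dim(f$total)), f$total,
               tolerance = 1e-6)
  meta <- jsonlite::read_json(paste0(pre, "_fcd.json"))
  expect_equal(meta$r_threshold, 0.25)
  expect_true(meta$normalized)
})
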