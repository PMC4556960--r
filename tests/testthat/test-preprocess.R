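test_that("initial-volume discarding shortens the run and keeps provenance", {
  b <- noise_bold(c(3, 3, 3), nt = 250)
  expect_equal(dim(discard_initial_volumes(b, 10)$data)[4], 240)
  expect_identical(discard_initial_volumes(b, 0)$data, b$data)
  b12 <- noise_bold(c(3, 3, 3), nt = 12)
  out <- discard_initial_volumes(b12, 10)
  expect_equal(dim(out$data)[4], 2)
  expect_match(out$provenance[length(out$provenance)], "discard_initial:10")
  expect_error(discard_initial_volumes(b12, 12), "cannot discard")
})

test_that("linear detrending removes exactly the least-squares line", {
  nt <- 50
  tt <- seq_len(nt)
  # a pure line vanishes
  b <- bold_image(array(rep(3 + 0.5 * tt, each = 8), c(2, 2, 2, nt)))
  expect_equal(max(abs(detrend_linear(b)$data)), 0, tolerance = 1e-10)
  # a zero-mean sinusoid symmetric about the series center is orthogonal
  # to both the intercept and the linear trend, hence untouched
  s <- cos(2 * pi * 5 * (tt - (nt + 1) / 2) / nt)
  bs <- bold_image(array(rep(s, each = 8), c(2, 2, 2, nt)))
  expect_equal(detrend_linear(bs)$data, bs$data, tolerance = 1e-8)
  # arbitrary series match an independent lm() oracle elementwise
  br <- noise_bold(c(3, 3, 2), nt = 21, seed = 4)
  out <- detrend_linear(br)
  for (v in list(c(1, 1, 1), c(3, 2, 2), c(2, 3, 1))) {
    y <- br$data[v[1], v[2], v[3], ]
    expect_equal(out$data[v[1], v[2], v[3], ],
                 unname(residuals(lm(y ~ seq_along(y)))), tolerance = 1e-10)
  }
  expect_error(detrend_linear(noise_bold(c(2, 2, 2), nt = 2)), "3 time")
})

test_that("ideal bandpass keeps in-band and kills out-of-band content", {
  nt <- 100; tr <- 2
  tt <- (seq_len(nt) - 1) * tr
  inband <- sin(2 * pi * 0.05 * tt)
  outband <- sin(2 * pi * 0.2 * tt)
  b <- bold_image(array(rep(inband + outband, each = 8), c(2, 2, 2, nt)),
                  tr_s = tr)
  f <- bandpass_filter(b)$data[1, 1, 1, ]
  amp <- function(x, hz) {
    sp <- fft(x); k <- round(hz * nt * tr) + 1
    2 * Mod(sp[k]) / nt
  }
  expect_equal(amp(f, 0.05), 1, tolerance = 0.01)
  expect_lt(amp(f, 0.2), 0.01)
  # white noise matches a direct DFT-masking oracle and is idempotent
  br <- noise_bold(c(2, 2, 2), nt = nt, seed = 7, tr_s = tr)
  out <- bandpass_filter(br)
  y <- br$data[2, 1, 2, ]
  sp <- fft(y)
  fr <- pmin(0:(nt - 1), nt - (0:(nt - 1))) / (nt * tr)
  sp[fr < 0.01 | fr > 0.08] <- 0
  expect_equal(out$data[2, 1, 2, ], Re(fft(sp, inverse = TRUE)) / nt,
               tolerance = 1e-10)
  expect_equal(bandpass_filter(out)$data, out$data, tolerance = 1e-10)
  expect_error(bandpass_filter(br, 0.01, 0.3), "Nyquist")
})

test_that("nuisance regression residualizes against the full design", {
  b <- noise_bold(c(3, 3, 3), nt = 30, seed = 2)
  nt <- 30
  # a voxel equal to the mean of all others equals the global mean too,
  # and is fully explained by global-signal regression
  b$data[1, 1, 1, ] <- colMeans(matrix(b$data, 27, nt)[-1, ])
  out <- regress_nuisance(b, use_global = TRUE)
  expect_lt(max(abs(out$data[1, 1, 1, ])), 1e-6)
  # residuals orthogonal to every regressor
  set.seed(3)
  mot <- matrix(rnorm(nt * 6, 0, 0.1), nt, 6)
  csf <- array(FALSE, c(3, 3, 3)); csf[1, , 1] <- TRUE
  wm <- array(FALSE, c(3, 3, 3)); wm[3, , 3] <- TRUE
  b2 <- noise_bold(c(3, 3, 3), nt = nt, seed = 9)
  X <- cbind(1, mot,
             colMeans(matrix(b2$data, 27, nt)[which(csf), ]),
             colMeans(matrix(b2$data, 27, nt)[which(wm), ]),
             colMeans(matrix(b2$data, 27, nt)))
  out2 <- regress_nuisance(b2, mot, csf, wm, use_global = TRUE)
  r <- out2$data[2, 2, 2, ]
  expect_lt(max(abs(crossprod(X, r))), 1e-8)
  # and match an independent lm() oracle
  y <- b2$data[2, 2, 2, ]
  expect_equal(r, unname(residuals(lm(y ~ X - 1))), tolerance = 1e-8)
  # collinear design is reported with column names
  mot_dup <- mot; mot_dup[, 6] <- mot_dup[, 1]
  expect_error(regress_nuisance(b2, mot_dup), "collinear")
})

test_that("masked-out voxels are untouched and excluded from nuisance means", {
  mask <- array(TRUE, c(3, 3, 3)); mask[1, 1, 1] <- FALSE
  b <- noise_bold(c(3, 3, 3), nt = 20, seed = 5, mask = mask)
  orig <- b$data[1, 1, 1, ]
  out <- regress_nuisance(b, use_global = TRUE)
  expect_identical(out$data[1, 1, 1, ], orig)
  # global mean must be the in-mask mean
  gm <- colMeans(matrix(b$data, 27, 20)[which(mask), ])
  gm_all <- colMeans(matrix(b$data, 27, 20))
  y <- b$data[2, 2, 2, ]
  expect_equal(out$data[2, 2, 2, ],
               unname(residuals(lm(y ~ gm))), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(out$data[2, 2, 2, ],
                                unname(residuals(lm(y ~ gm_all))))))
})

test_that("motion exclusion uses strict 1 mm / 1 degree limits", {
  m <- matrix(0, 50, 6)
  expect_false(motion_excluded(m))
  m1 <- m; m1[20, 2] <- 1.2
  expect_true(motion_excluded(m1))
  m2 <- m; m2[20, 2] <- 1.0; m2[30, 5] <- 1.0
  expect_false(motion_excluded(m2))  # "more than" is strict
  m3 <- m; m3[10, 6] <- -1.01
  expect_true(motion_excluded(m3))
})

test_that("motion spikes are counted by framewise displacement", {
  m <- matrix(0.3, 40, 6)
  expect_equal(count_motion_spikes(m, 0.5), 0)
  m2 <- matrix(0, 40, 6); m2[15, 1] <- 1.0   # one step of 2x threshold
  expect_equal(count_motion_spikes(m2, 0.5), 2)  # up and back down
  m3 <- matrix(0, 40, 6); m3[15:40, 1] <- 1.0    # a single sustained step
  expect_equal(count_motion_spikes(m3, 0.5), 1)
  # random trace equals a literal per-volume loop oracle
  set.seed(11)
  mr <- matrix(rnorm(40 * 6, 0, 0.3), 40, 6)
  fd <- numeric(40)
  for (t in 2:40) {
    s <- 0
    for (j in 1:3) s <- s + abs(mr[t, j] - mr[t - 1, j])
    for (j in 4:6) s <- s + abs(mr[t, j] - mr[t - 1, j]) * pi / 180 * 50
    fd[t] <- s
  }
  expect_equal(framewise_displacement(mr), fd, tolerance = 1e-12)
  expect_equal(count_motion_spikes(mr, 0.7), sum(fd > 0.7))
  expect_error(count_motion_spikes(mr, 0), "positive")
})

test_that("the preprocessing pipeline applies steps in the fixed order", {
  sp <- connectivity_spec(grid_shape = c(4, 4, 4), n_volumes = 40,
                          hub_seeds = list())
  sim <- simulate_subject_bold(sp, seed = 2)
  out <- preprocess_bold(sim$bold, sim$motion, n_discard = 5)
  expect_equal(nrow(out$motion), 35)
  steps <- out$bold$provenance
  expect_equal(grep("discard", steps), 2L)  # after "simulated"
  expect_lt(grep("detrend", steps), grep("bandpass", steps))
  expect_lt(grep("bandpass", steps), grep("regress", steps))
})
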