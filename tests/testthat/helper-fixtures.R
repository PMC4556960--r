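# shared in-code fixtures

# bold_image filled with seeded Gaussian noise
noise_bold <- function(dims = c(6, 6, 6), nt = 40, seed = 1,
                       voxel_size_mm = 3, tr_s = 2, mask = NULL) {
  set.seed(seed)
  bold_image(array(rnorm(prod(dims) * nt), c(dims, nt)),
             voxel_size_mm = voxel_size_mm, tr_s = tr_s, mask = mask)
}

# brute-force all-pairs FCD oracle: literal per-voxel loops over the full
# correlation matrix, independent of the blocked implementation
fcd_oracle <- function(bold, r_threshold = 0.25, local_mm = 3,
                       distant_mm = 25) {
  d <- dim(bold$mask)
  idx <- which(bold$mask)
  Y <- t(matrix(bold$data, prod(d), dim(bold$data)[4])[idx, , drop = FALSE])
  C <- cor(Y)
  co <- (lin_to_ijk_test(idx, d) - 1) * bold$voxel_size_mm
  D <- as.matrix(dist(co))
  n <- length(idx)
  tot <- loc <- dis <- gap <- numeric(n)
  for (i in seq_len(n)) {
    r <- C[i, ]
    keep <- r > r_threshold
    keep[i] <- FALSE
    tot[i] <- sum(r[keep])
    loc[i] <- sum(r[keep & D[i, ] <= local_mm])
    dis[i] <- sum(r[keep & D[i, ] > distant_mm])
    gap[i] <- sum(r[keep & D[i, ] > local_mm & D[i, ] <= distant_mm])
  }
  list(total = tot, local = loc, gap = gap, distant = dis, idx = idx)
}

lin_to_ijk_test <- function(idx, dims) {
  i0 <- idx - 1
  cbind(i0 %% dims[1] + 1, (i0 %/% dims[1]) %% dims[2] + 1,
        i0 %/% (dims[1] * dims[2]) + 1)
}

# per-subject random maps for group-statistics tests
random_maps <- function(n, dims = c(5, 5, 5), seed = 1, shift = NULL,
                        shift_at = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a <- array(rnorm(prod(dims)), dims)
    if (!is.null(shift) && !is.null(shift_at) && shift[i] != 0)
      a[shift_at] <- a[shift_at] + shift[i]
    a
  })
}
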