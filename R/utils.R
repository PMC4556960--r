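# internal helpers shared across modules

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never clobbers user seeds.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive `n` child seeds (< 2^31) from a root seed, deterministically.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# voxel-center coordinates in mm for a 3D grid, column-major order.
# Convention: voxel (1,1,1) sits at 0 mm on each axis.
voxel_coords_mm <- function(dims, voxel_size_mm) {
  g <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                             z = seq_len(dims[3])))
  t((g - 1) * voxel_size_mm)
}

# linear index -> (i,j,k) for a 3D grid
lin_to_ijk <- function(idx, dims) {
  idx0 <- idx - 1L
  cbind(idx0 %% dims[1] + 1L,
        (idx0 %/% dims[1]) %% dims[2] + 1L,
        idx0 %/% (dims[1] * dims[2]) + 1L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
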