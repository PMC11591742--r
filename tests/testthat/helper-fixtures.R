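# Small in-code fixtures shared across test files.

random_stress_grid <- function(n = c(3L, 4L, 2L), spacing = c(0.5, 0.4, 0.7),
                               origin = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  spec <- grid_spec(n, spacing, origin)
  stress_grid(spec, array(rnorm(prod(n) * 9), dim = c(n, 3L, 3L)))
}

# coarse tube: one axial voxel, 0.1 nm transverse voxels over a 16 nm box
small_tube_spec <- function(noise_sd = 0, n_frames = 1L, seed = 1L, ...) {
  tube_spec(box = c(16, 16, 4), spacing = c(0.1, 0.1, 4),
            noise_sd = noise_sd, n_frames = n_frames, seed = seed, ...)
}

# independent double-loop virial oracle: its own minimum image and forces
brute_force_virial <- function(sys, model) {
  n <- nrow(sys$positions)
  kin <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    v <- sys$velocities[i, ]
    kin <- kin - sys$masses[i] * outer(v, v)
  }
  vir <- matrix(0, 3, 3)
  pair_list <- if (model$kind == "harmonic") {
    lapply(seq_len(nrow(model$pairs)), function(k) model$pairs[k, ])
  } else {
    unlist(lapply(seq_len(n - 1), function(i)
      lapply((i + 1):n, function(j) c(i, j))), recursive = FALSE)
  }
  for (p in pair_list) {
    dr <- sys$positions[p[1], ] - sys$positions[p[2], ]
    for (ax in 1:3) {
      if (sys$pbc[ax]) dr[ax] <- dr[ax] - sys$box[ax] * round(dr[ax] / sys$box[ax])
    }
    r <- sqrt(sum(dr^2))
    if (model$kind == "harmonic") {
      dVdr <- model$k * (r - model$r0)
    } else {
      if (r > model$cutoff) next
      sr6 <- (model$sigma / r)^6
      dVdr <- -24 * model$epsilon * (2 * sr6^2 - sr6) / r
    }
    f_on_1 <- -dVdr * dr / r
    vir <- vir - outer(dr, f_on_1)
  }
  (kin + vir) / prod(sys$box)
}

expect_tensor_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
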