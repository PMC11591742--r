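# a one-voxel grid placed so the voxel center sits at angle theta from the
# frame's axis point
one_voxel_at_angle <- function(theta, tensor, rho = 1) {
  spec <- grid_spec(c(1, 1, 1), c(1, 1, 1))
  fr <- cylinder_frame(axis = 3,
                       axis_point = c(0.5 - rho * cos(theta),
                                      0.5 - rho * sin(theta)),
                       r_max = 4, dr = 0.05)
  list(grid = stress_grid(spec, tensor), frame = fr)
}

test_that("per-voxel rotation matches the explicit matrix-product oracle", {
  # theta = 30 degrees, diag(1,2,3): (1.25, 1.75, sqrt(3)/4)
  th <- pi / 6
  fx <- one_voxel_at_angle(th, diag(c(1, 2, 3)))
  rot <- rotate_to_cylindrical(fx$grid, fx$frame)
  expect_equal(rot$tensors[1, 1, 1, 1, 1], 1.25)
  expect_equal(rot$tensors[1, 1, 1, 2, 2], 1.75)
  expect_equal(rot$tensors[1, 1, 1, 1, 2], sqrt(3) / 4)

  # explicit oracle on random tensors and angles
  set.seed(31)
  for (k in 1:25) {
    th <- runif(1, -pi, pi)
    S <- matrix(rnorm(9), 3, 3)
    fx <- one_voxel_at_angle(th, S)
    rot <- rotate_to_cylindrical(fx$grid, fx$frame)
    A <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    expect_tensor_equal(rot$tensors[1, 1, 1, , ], t(A) %*% S %*% A, 1e-10)
  }
})

test_that("rotation fixes isotropic tensors and is the identity at theta = 0", {
  fx <- one_voxel_at_angle(1.1, 7 * diag(3))
  rot <- rotate_to_cylindrical(fx$grid, fx$frame)
  expect_tensor_equal(rot$tensors[1, 1, 1, , ], 7 * diag(3), 1e-12)

  S <- matrix(rnorm(9), 3, 3)
  fx0 <- one_voxel_at_angle(0, S)
  rot0 <- rotate_to_cylindrical(fx0$grid, fx0$frame)
  expect_tensor_equal(rot0$tensors[1, 1, 1, , ], S, 1e-12)
})

test_that("rotation preserves trace and eigenvalues and inverts exactly", {
  g <- random_stress_grid(n = c(6L, 6L, 2L), spacing = c(1, 1, 2), seed = 32)
  g <- symmetrize(g)
  fr <- cylinder_frame(axis = 3)
  rot <- rotate_to_cylindrical(g, fr)
  for (i in 1:6) for (j in 1:6) {
    S0 <- g$tensors[i, j, 1, , ]
    S1 <- rot$tensors[i, j, 1, , ]
    expect_lt(abs(sum(diag(S0)) - sum(diag(S1))), 1e-10)
    expect_lt(max(abs(sort(eigen(S0)$values) - sort(eigen(S1)$values))), 1e-10)
  }
  back <- rotate_from_cylindrical(rot, fr)
  expect_tensor_equal(back$tensors, g$tensors, 1e-12)
})

test_that("radial binning reproduces the reference shell layout", {
  # default frame on a 40 nm transverse box with dr = 0.05:
  # 400 shells, centers 0.00 ... 19.95 nm
  spec <- grid_spec(c(40, 40, 1), c(1, 1, 1))
  g <- stress_grid(spec, array(0, dim = c(40, 40, 1, 3, 3)))
  prof <- radial_bin(rotate_to_cylindrical(g, cylinder_frame(axis = 3)))
  expect_identical(nrow(prof), 400L)
  expect_equal(prof$r[1], 0)
  expect_equal(prof$r[400], 19.95)
  expect_equal(diff(prof$r), rep(0.05, 399))
})

test_that("shell means are unweighted voxel means with half-open assignment", {
  # uniform field: every non-empty shell reports the value
  spec <- grid_spec(c(10, 10, 1), c(0.4, 0.4, 1))
  g <- stress_grid(spec, 3.5 * diag(3))
  prof <- radial_bin(rotate_to_cylindrical(g, cylinder_frame(axis = 3, dr = 0.2)))
  ne <- prof$count > 0
  expect_true(all(abs(prof$stt[ne] - 3.5) < 1e-12))
  expect_true(all(is.na(prof$stt[!ne])))

  # two voxels in one shell average arithmetically
  spec2 <- grid_spec(c(2, 1, 1), c(1, 1, 1))
  arr <- array(0, dim = c(2, 1, 1, 3, 3))
  arr[1, 1, 1, , ] <- diag(c(2, 2, 2))
  arr[2, 1, 1, , ] <- diag(c(8, 8, 8))
  g2 <- stress_grid(spec2, arr)
  # axis point equidistant from both voxel centers
  fr <- cylinder_frame(axis = 3, axis_point = c(1, -1), r_max = 3, dr = 0.5)
  prof2 <- radial_bin(rotate_to_cylindrical(g2, fr))
  shell <- which(prof2$count == 2)
  expect_length(shell, 1L)
  expect_equal(prof2$szz[shell], 5)
})

test_that("anisotropy, max shear and off-diagonals recover generator ground truth", {
  ts <- small_tube_spec()
  ts$offdiag_curve <- function(r) 4 * exp(-(r - 6.5)^2)
  out <- gen_tube_grid(ts)
  rot <- rotate_to_cylindrical(mean_grid(out$frames), out$frame)
  prof <- radial_bin(rot)
  keep <- prof$count > 0 & prof$r > 3 & prof$r < 7.9

  ani <- anisotropy_profile(prof)
  # voxel-exact oracle: shell means of the injected curves over voxel radii
  pol <- tubestress:::voxel_polar(rot$spec, out$frame)
  shell <- floor(pol$rad / 0.05 + 0.5)
  truth_shell <- function(f) {
    agg <- tapply(f(pol$rad), shell, mean)
    as.numeric(agg[match(round(prof$r / 0.05), as.integer(names(agg)))])
  }
  expect_equal(unname(ani$A[keep]), truth_shell(ts$A_curve)[keep],
               tolerance = 1e-10)

  shear <- max_shear_profile(prof)
  expect_equal(shear$shear, ani$A / 2)
  od <- offdiagonal_profile(prof, "tz")
  expect_equal(unname(od$value[keep]), truth_shell(ts$offdiag_curve)[keep],
               tolerance = 1e-10)
  expect_tensor_equal(offdiagonal_profile(prof, "rt")$value[keep], 0, 1e-10)
  expect_error(offdiagonal_profile(prof, "xy"))
})

test_that("max shear equals the theta-z eigen-oracle", {
  prof <- radial_profile(c(1, 2), srr = c(0, 0), stt = c(10, 3),
                         szz = c(-10, 5), srt = c(0, 0), srz = c(0, 0),
                         stz = c(0, 0))
  s <- max_shear_profile(prof)
  expect_equal(s$shear, c(10, -1))
  # eigen-decomposition in the theta-z plane: max shear = (lmax - lmin)/2
  for (k in 1:2) {
    M <- matrix(c(prof$stt[k], prof$stz[k], prof$stz[k], prof$szz[k]), 2, 2)
    ev <- eigen(M)$values
    expect_equal(abs(s$shear[k]), (max(ev) - min(ev)) / 2)
  }
})

test_that("equilibrium residual vanishes for constant fields and r^2 test functions", {
  r <- seq(1, 4, 0.05)
  cns <- radial_profile(r, srr = rep(7, length(r)), stt = rep(7, length(r)),
                        szz = rep(7, length(r)))
  res <- equilibrium_residual(cns)
  inner <- res$residual[2:(length(r) - 1)]
  expect_tensor_equal(inner, rep(0, length(inner)), 1e-10)
  expect_true(is.na(res$residual[1]) && is.na(res$residual[length(r)]))

  # d/dr (r * r^2) = 3 r^2, exact for central differences up to O(dr^2)
  quad <- radial_profile(r, srr = r^2, stt = 3 * r^2, szz = r^2)
  res2 <- equilibrium_residual(quad)
  expect_lt(max(abs(res2$residual), na.rm = TRUE), 1e-2)

  # gaps make the residual undefined next to them
  gap <- cns
  gap$count[10] <- 0L
  gap$srr[10] <- NA_real_
  res3 <- equilibrium_residual(gap)
  expect_true(all(is.na(res3$residual[9:11])))
})

test_that("monolayer decomposition is exact by construction", {
  r <- seq(4, 9, 0.1)
  n <- length(r)
  mk <- function(stt, szz) radial_profile(r, srr = rep(0, n), stt = stt,
                                          szz = szz)
  inner <- mk(10 * exp(-(r - 5.5)^2), rep(0, n))
  outer <- mk(-8 * exp(-(r - 7.5)^2), rep(0, n))
  cross <- 3 * exp(-(r - 6.5)^2 / 0.5)
  total <- mk(inner$stt + outer$stt + cross, rep(0, n))
  inter <- decompose_contributions(total, inner, outer)
  expect_equal(inter$stt, cross)
  # no cross terms: interaction is identically zero
  tot0 <- mk(inner$stt + outer$stt, rep(0, n))
  expect_tensor_equal(decompose_contributions(tot0, inner, outer)$stt,
                      rep(0, n))
  # definitional identity on arbitrary profiles
  set.seed(33)
  a <- mk(rnorm(n), rnorm(n)); b <- mk(rnorm(n), rnorm(n))
  tt <- mk(rnorm(n), rnorm(n))
  ii <- decompose_contributions(tt, a, b)
  expect_equal(a$stt + b$stt + ii$stt, tt$stt)
  expect_error(decompose_contributions(tt, a, mk(rnorm(n), rnorm(n))[1:10, ]),
               "mismatched")
})

test_that("planar profiles recover slab structure and symmetry", {
  gp <- gen_planar_grid(planar_spec(noise_sd = 0, n_frames = 1))
  prof <- planar_profiles(gp$frames[[1]])
  expect_equal(prof$lateral, gp$truth$lateral)
  expect_equal(prof$difference, rep(0, nrow(prof)))
  expect_equal(prof$normal, rep(0, nrow(prof)))
  # mirror symmetry about the midplane
  expect_equal(prof$lateral, rev(prof$lateral))
  # pressure convention negates at the boundary
  profp <- planar_profiles(gp$frames[[1]], pressure_convention = TRUE)
  expect_equal(profp$lateral, -prof$lateral)
})

test_that("profiles survive a text round trip", {
  prof <- radial_profile(seq(0.5, 2, 0.5), srr = 1:4 / 2, stt = c(1, 2, 3, 4),
                         szz = rep(0, 4))
  tf <- withr::local_tempfile()
  write_profile(prof, tf, comment = "fixture")
  back <- read_profile(tf)
  expect_equal(back$stt, prof$stt)
  expect_s3_class(back, "radial_profile")
})
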