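flat_profile <- function(sigma0 = 0, E = 100, lambda_S = 50, thickness = 2) {
  elastic_profile(c(0, thickness), sigma0, E, lambda_S)
}

test_that("energy densities evaluate term by term", {
  z <- c(0, 2)
  m <- full_moduli(z, lambda1 = 120, lambda2 = 80, lambda12 = 30,
                   lambda_S = 50, lambda_T = 40, sigma_l = -12, sigma_z = -2)
  expect_equal(energy_density_full(strain_state(), m, 1), 0)
  # pure in-plane shear uxy = t: w = 2 lambda_S t^2
  t0 <- 0.07
  expect_equal(as.numeric(energy_density_full(strain_state(uxy = t0), m, 1)),
               2 * 50 * t0^2)
  # pure tilt uxz = t: w = 2 lambda_T t^2, flagged out of scope
  wt <- energy_density_full(strain_state(uxz = t0), m, 1)
  expect_equal(as.numeric(wt), 2 * 40 * t0^2)
  expect_match(attr(wt, "tilt_note"), "tilt")

  p <- flat_profile()
  expect_equal(energy_density_incompressible(strain_state(), p, 1), 0)
  # sigma0 = 0, E = 100, lS = 50, uxx = 0.1, uyy = -0.05:
  # w = 50 * 0.05^2 + 25 * 0.15^2 = 0.6875
  expect_equal(energy_density_incompressible(
    strain_state(uxx = 0.1, uyy = -0.05), p, 1), 0.6875)
  # isotropic stretch leaves the shear term silent
  p2 <- flat_profile(sigma0 = 3, E = 10, lambda_S = 1e4)
  expect_equal(energy_density_incompressible(
    strain_state(uxx = 0.02, uyy = 0.02), p2, 1),
    3 * 0.04 + 5 * 0.04^2)
})

test_that("the reduced profile matches the full moduli combination", {
  z <- seq(0, 2, 0.5)
  m <- full_moduli(z, lambda1 = function(z) 100 + z, lambda2 = 50,
                   lambda12 = 10, lambda_S = function(z) sin(z),
                   lambda_T = 0, sigma_l = -5, sigma_z = 2)
  p <- as_elastic_profile(m)
  expect_equal(p$sigma0, rep(-7, length(z)))
  expect_equal(p$E, 100 + z + 50 - 20)
  expect_equal(p$lambda_S, sin(z))
})

test_that("local-fluidity energy is minimized at eps = -sigma0/E", {
  p <- flat_profile(sigma0 = -10, E = 100)
  expect_equal(energy_density_local_fluidity(0, p, 1), 0)
  expect_equal(energy_density_local_fluidity(0.1, p, 1), -0.5)
  # golden-section oracle over eps
  opt <- optimize(function(e) energy_density_local_fluidity(e, p, 1),
                  c(-0.5, 0.5), tol = 1e-10)
  expect_equal(opt$minimum, 10 / 100, tolerance = 1e-6)
})

test_that("planar Cauchy stress reproduces the worked values", {
  p0 <- flat_profile(sigma0 = -10, E = 100, lambda_S = 50)
  S <- cauchy_stress_planar(strain_state(), p0, 1, P = 5)
  expect_equal(diag(S), c(-5, -5, 5))

  p <- flat_profile()
  S2 <- cauchy_stress_planar(strain_state(uxx = 0.1, uyy = -0.05), p, 1, P = 0)
  expect_equal(S2[1, 1], 13.75)
  expect_equal(S2[2, 2], -2.375)
  expect_equal(S2[3, 3], 0)
  expect_tensor_equal(S2 - diag(diag(S2)), matrix(0, 3, 3))

  expect_error(cauchy_stress_planar(strain_state(uxx = -0.6), p, 1),
               "invalid deformation")
})

test_that("analytic stress agrees with finite differences of the energy density", {
  set.seed(21)
  p <- elastic_profile(seq(0, 2, 0.1),
                       sigma0 = function(z) -10 + 3 * z,
                       E = function(z) 200 + 50 * sin(z),
                       lambda_S = function(z) 40 * cos(z))
  h <- 1e-6
  for (k in 1:100) {
    uxx <- runif(1, -0.2, 0.2); uyy <- runif(1, -0.2, 0.2)
    z <- runif(1, 0, 2); P <- runif(1, -5, 5)
    S <- cauchy_stress_planar(strain_state(uxx = uxx, uyy = uyy), p, z, P)
    w <- function(a, b) energy_density_incompressible(
      strain_state(uxx = a, uyy = b), p, z)
    dw_dx <- (w(uxx + h, uyy) - w(uxx - h, uyy)) / (2 * h)
    dw_dy <- (w(uxx, uyy + h) - w(uxx, uyy - h)) / (2 * h)
    expect_equal(S[1, 1], dw_dx * (1 + uxx) + P, tolerance = 1e-6)
    expect_equal(S[2, 2], dw_dy * (1 + uyy) + P, tolerance = 1e-6)
  }
})

test_that("the stress difference identity holds exactly", {
  p <- flat_profile()
  expect_equal(lateral_stress_difference(0.07, 0.07, p, 1), 0)
  expect_equal(lateral_stress_difference(0.1, -0.05, p, 1), 16.125)
  # no pre-stress, no shear modulus, area-preserving shear: difference vanishes
  p0 <- flat_profile(sigma0 = 0, E = 100, lambda_S = 0)
  expect_equal(lateral_stress_difference(0.04, -0.04, p0, 1), 0)
  # symbolic identity with the full stress tensor
  set.seed(22)
  for (k in 1:50) {
    uxx <- runif(1, -0.2, 0.2); uyy <- runif(1, -0.2, 0.2)
    S <- cauchy_stress_planar(strain_state(uxx = uxx, uyy = uyy), p, 1,
                              P = runif(1, -10, 10))
    expect_equal(S[1, 1] - S[2, 2],
                 lateral_stress_difference(uxx, uyy, p, 1),
                 tolerance = 1e-12)
  }
})

test_that("the cylindrical bend map is exactly volume preserving", {
  # inward map: r_p = 7.5 reached at z_p; r = 6 gives uxx = -0.18
  map <- cylindrical_bend_map(7.5, 1, orientation = "inward")
  z6 <- depth_from_radius(map, 6)
  st <- strain_from_bend_map(map, z6)
  expect_equal(st$r, 6)
  expect_equal(st$uxx, -0.18)
  expect_equal(st$uyy, 0)  # beta = 1: no axial strain

  st_p <- strain_from_bend_map(map, 1)
  expect_equal(st_p$r, 7.5)
  expect_equal(st_p$uxx, 0)

  # det F = 1 for random maps at all depths
  set.seed(23)
  for (k in 1:20) {
    m2 <- cylindrical_bend_map(runif(1, 3, 10), runif(1, 0, 2),
                               beta = runif(1, 0.8, 1.2),
                               orientation = sample(c("inward", "outward"), 1))
    z <- seq(0, 2, 0.25)
    st2 <- tryCatch(strain_from_bend_map(m2, z), error = function(e) NULL)
    if (is.null(st2)) next
    detF <- (st2$r / m2$r_p) * m2$beta * (m2$r_p / (st2$r * m2$beta))
    expect_tensor_equal(detF, rep(1, length(z)), 1e-12)
  }
  expect_error(strain_from_bend_map(
    cylindrical_bend_map(1, 0, orientation = "inward"), 3), "degenerate")
})

test_that("cylindrical stress: local mode is isotropic, global matches the planar difference", {
  p <- flat_profile()
  map <- cylindrical_bend_map(7.5, 1, orientation = "inward")
  loc <- stress_cylindrical(p, map, "local")
  expect_equal(loc$stt, loc$szz)

  z6 <- depth_from_radius(map, 6)
  st <- strain_from_bend_map(map, z6)
  sc <- stress_cylindrical(elastic_profile(c(0, 2, z6, z6 + 1), 0, 100, 50),
                           map, "global")
  k <- which(sc$z == z6)
  expect_equal(sc$stt[k] - sc$szz[k],
               lateral_stress_difference(st$uxx, st$uyy, p, z6))

  # flat limit: anisotropy vanishes, linearly in 1/r_p
  a_of <- function(rp) {
    m <- cylindrical_bend_map(rp, 1, orientation = "outward")
    max(abs(predict_anisotropy(elastic_profile(seq(0, 2, 0.1), -10, 100, 50),
                               m, "global")$A))
  }
  expect_lt(a_of(1e6), 1e-3)
  expect_lt(a_of(1e6), 2e-3 * a_of(1e3) / 1)
  expect_equal(a_of(1e3) / a_of(1e6), 1e3, tolerance = 0.01)
})

test_that("radial equilibrium solver matches closed forms and converges at order 2", {
  r <- seq(5, 7, 0.01)
  expect_equal(solve_radial_equilibrium(r, rep(0, length(r))),
               rep(0, length(r)))
  srr <- solve_radial_equilibrium(r, rep(10, length(r)))
  expect_equal(srr, 10 * (r - 5) / r, tolerance = 1e-12)
  expect_equal(srr[length(r)], 20 / 7, tolerance = 1e-10)

  srr2 <- solve_radial_equilibrium(r, 3 * r^2)
  expect_equal(srr2, (r^3 - 5^3) / r, tolerance = 1e-4)

  expect_error(solve_radial_equilibrium(c(1, 0.5, 2), c(1, 1, 1)),
               "increasing")

  # discrete equilibrium residual decays at order >= 1.9 under halving
  resid <- function(h) {
    rr <- seq(3, 8, h)
    stt <- 40 * exp(-(rr - 6.5)^2)
    prof <- radial_profile(rr, srr = solve_radial_equilibrium(rr, stt),
                           stt = stt, szz = stt)
    max(abs(equilibrium_residual(prof)$residual), na.rm = TRUE)
  }
  order <- log2(resid(0.05) / resid(0.025))
  expect_gte(order, 1.9)
})

test_that("anisotropy prediction and shear-modulus recovery are mutually inverse", {
  p <- elastic_profile(seq(0, 2, 0.05),
                       sigma0 = function(z) -20 * sin(pi * z / 2),
                       E = function(z) 300 * (1 + 0.2 * cos(z)),
                       lambda_S = function(z) 60 * sin(pi * z))
  map <- cylindrical_bend_map(5.5, 1, orientation = "inward")
  loc <- predict_anisotropy(p, map, "local")
  expect_equal(loc$A, rep(0, length(p$z)))

  glob <- predict_anisotropy(p, map, "global")
  st <- strain_from_bend_map(map, p$z)
  rec <- recover_lateral_shear_modulus(glob$A, st$uxx, st$uyy,
                                       p$sigma0, p$E)
  keep <- !is.na(rec)
  expect_gt(sum(keep), length(p$z) - 3)
  expect_lt(max(abs(rec[keep] - p$lambda_S[keep])), 1e-9)

  # degenerate strains are excluded and reported
  dg <- recover_lateral_shear_modulus(c(1, 2), c(0.1, 0.2), c(0.1, 0.1),
                                      0, 0)
  expect_true(is.na(dg[1]))
  expect_identical(attr(dg, "excluded"), 1L)

  # worked inversion: A = 16.125 at strains (0.1, -0.05), sigma0 = 0, E = 100
  expect_equal(as.numeric(
    recover_lateral_shear_modulus(16.125, 0.1, -0.05, 0, 100)), 50)
  expect_equal(as.numeric(recover_lateral_shear_modulus(0, 0.1, -0.05, 0, 0)),
               0)
})

test_that("the lambda_S-dependent part of the anisotropy scales linearly", {
  base <- elastic_profile(seq(0, 2, 0.1), -10, 200,
                          function(z) 50 * sin(pi * z))
  map <- cylindrical_bend_map(7.5, 1, orientation = "outward")
  a1 <- predict_anisotropy(base, map, "global")$A
  zero <- elastic_profile(base$z, -10, 200, 0)
  a0 <- predict_anisotropy(zero, map, "global")$A
  scaled <- elastic_profile(base$z, -10, 200, function(z) 150 * sin(pi * z))
  a3 <- predict_anisotropy(scaled, map, "global")$A
  expect_equal(a3 - a0, 3 * (a1 - a0), tolerance = 1e-12)

  # with lambda_S = 0 and sigma0 = 0 but E > 0, the prediction is generally
  # non-zero: the stretch coupling survives
  e_only <- elastic_profile(base$z, 0, 200, 0)
  a_e <- predict_anisotropy(e_only, map, "global")$A
  expect_gt(max(abs(a_e)), 1)
})

test_that("global-fluidity integral distinguishes fluid from non-fluid profiles", {
  h <- 2
  z <- seq(0, h, 0.005)
  zero <- elastic_profile(z, 0, 100, 0)
  expect_equal(as.numeric(global_fluidity_integral(zero)), 0)
  expect_true(attr(global_fluidity_integral(zero), "globally_fluid"))

  fluid <- elastic_profile(z, 0, 100, function(z) 37 * sin(2 * pi * z / h))
  gi <- global_fluidity_integral(fluid)
  expect_lt(abs(as.numeric(gi)), 1e-4)
  expect_true(attr(gi, "globally_fluid"))

  solid <- elastic_profile(z, 0, 100, 5)
  gs <- global_fluidity_integral(solid)
  expect_equal(as.numeric(gs), 5 * h)
  expect_false(attr(gs, "globally_fluid"))
})

test_that("bilayer prediction flips sign between the monolayers", {
  p <- demo_monolayer_profile()
  maps <- demo_bend_maps()
  both <- bilayer_anisotropy(p, maps$inner, maps$outer, "global")
  inner <- both[both$monolayer == "inner" & abs(both$z - 0.5) < 0.26, ]
  outer <- both[both$monolayer == "outer" & abs(both$z - 0.5) < 0.26, ]
  expect_true(all(inner$r < outer$r))
  expect_true(mean(sign(inner$A)) * mean(sign(outer$A)) < 0)
})
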