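# Synthetic stress-field and particle-system generators with stored ground
# truth. These emulate the statistical structure the analysis assumes —
# a planar bilayer with a three-peak lateral profile, and a cylindrically
# symmetric tube whose field satisfies radial mechanical equilibrium by
# construction and carries a prescribed azimuthal-axial anisotropy with
# opposite-sign lobes in the two monolayers — without any MD. Every generator
# stores its ground truth next to its output and is bit-reproducible under a
# fixed seed.

gaussian_bump <- function(x, center, width, amplitude) {
  amplitude * exp(-(x - center)^2 / (2 * width^2))
}

#' Default anisotropy ground-truth curve for a synthetic tube
#'
#' Derivative-of-Gaussian in the signed distance from the midsurface radius
#' R: zero at R, a positive lobe inside (the inner monolayer), a negative
#' lobe outside, extrema of magnitude \code{amplitude} at \code{R -/+ width}.
#'
#' @param R midsurface radius (nm).
#' @param amplitude extremum magnitude (bar).
#' @param width lobe position offset from R (nm).
#' @return Function of r returning A(r) in bar.
#' @export
default_anisotropy_curve <- function(R = 6.5, amplitude = 15, width = 1) {
  force(R); force(amplitude); force(width)
  function(r) {
    x <- r - R
    -amplitude * exp(0.5) * (x / width) * exp(-x^2 / (2 * width^2))
  }
}

#' Default azimuthal-stress ground-truth curve for a synthetic tube
#'
#' A lateral-stress-profile-like shape mirrored about the midsurface radius
#' (repulsive core and head-group peaks, attractive transition troughs) plus
#' half of the anisotropy curve.
#'
#' @param R midsurface radius (nm).
#' @param A_curve anisotropy curve; its half is added so that
#'   \code{szz = stt - A} has the mirrored base shape minus A/2.
#' @return Function of r returning azimuthal stress (bar).
#' @export
default_stt_curve <- function(R = 6.5, A_curve = default_anisotropy_curve(R)) {
  force(R); force(A_curve)
  function(r) {
    x <- r - R
    base <- gaussian_bump(x, 0, 0.35, 80) +
      gaussian_bump(x, -1.2, 0.3, -150) + gaussian_bump(x, 1.2, 0.3, -150) +
      gaussian_bump(x, -2.0, 0.3, 100) + gaussian_bump(x, 2.0, 0.3, 100)
    base + A_curve(r) / 2
  }
}

#' Synthetic cylindrical-bilayer specification
#'
#' @param box length-3 box (nm); the cylinder axis runs along \code{axis}.
#' @param spacing length-3 voxel spacing (nm).
#' @param axis grid axis of the cylinder (default 3).
#' @param R midsurface radius (nm, default 6.5).
#' @param thickness monolayer thickness (nm, default 2).
#' @param stt_curve azimuthal stress ground truth, function of r (bar).
#' @param A_curve anisotropy ground truth, function of r (bar), zero at R.
#' @param offdiag_curve optional theta-z off-diagonal injection, function of
#'   r (bar), or \code{NULL}.
#' @param noise_sd additive Gaussian voxel noise per frame (bar).
#' @param n_frames number of frames to generate.
#' @param seed RNG seed.
#' @return Object of class \code{tube_spec}.
#' @export
tube_spec <- function(box = c(20, 20, 10), spacing = c(0.1, 0.1, box[3]),
                      axis = 3L, R = 6.5, thickness = 2,
                      A_curve = default_anisotropy_curve(R),
                      stt_curve = default_stt_curve(R, A_curve),
                      offdiag_curve = NULL,
                      noise_sd = 20, n_frames = 100L, seed = 1L) {
  if (R <= thickness) stop("midsurface radius must exceed monolayer thickness")
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (abs(A_curve(R)) > 1e-9)
    stop("anisotropy curve must vanish at the midsurface radius")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  structure(list(box = box, spacing = spacing, axis = as.integer(axis),
                 R = R, thickness = thickness, stt_curve = stt_curve,
                 A_curve = A_curve, offdiag_curve = offdiag_curve,
                 noise_sd = noise_sd, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "tube_spec")
}

tube_grid_spec <- function(spec) {
  n <- pmax(1L, as.integer(round(spec$box / spec$spacing)))
  grid_spec(n, spec$spacing, origin = c(0, 0, 0))
}

# Sigma_rr on a fine radial grid, by integrating the equilibrium condition
# from near the axis outward (boundary Sigma_rr -> 0 at the axis, where the
# curves vanish).
tube_srr_interp <- function(spec, r_max, h = 0.005) {
  r <- seq(h, r_max + h, by = h)
  srr <- solve_radial_equilibrium(r, spec$stt_curve(r), boundary = 0)
  stats::approxfun(r, srr, rule = 2)
}

#' Ground-truth radial profile of a synthetic tube
#'
#' Tabulates the generator's curves (and the equilibrated radial component)
#' on a shell grid, for convergence studies and round-trip tests.
#'
#' @param spec a \code{tube_spec}.
#' @param dr shell width (nm).
#' @param r_in,r_max radial range (nm); \code{r_in} defaults to 0.1.
#' @return A \code{radial_profile} with \code{srr, stt, szz, srt, srz, stz}.
#' @export
tube_truth_profile <- function(spec, dr = 0.05, r_in = 0.1,
                               r_max = min(spec$box[transverse_axes(spec$axis)]) / 2) {
  r <- seq(r_in, r_max, by = dr)
  stt <- spec$stt_curve(r)
  A <- spec$A_curve(r)
  srr <- solve_radial_equilibrium(r, stt, boundary = 0)
  stz <- if (is.null(spec$offdiag_curve)) rep(0, length(r)) else spec$offdiag_curve(r)
  radial_profile(r, srr = srr, stt = stt, szz = stt - A,
                 srt = rep(0, length(r)), srz = rep(0, length(r)), stz = stz)
}

#' Generate a synthetic cylindrical-bilayer stress field
#'
#' Builds the noiseless field in cylindrical components at every voxel
#' (azimuthal from the curve, axial as azimuthal minus the anisotropy, radial
#' from the equilibrium condition so the field is equilibrated by
#' construction), rotates it to the lab frame with the exact inverse of the
#' analysis rotation, and adds i.i.d. symmetric Gaussian voxel noise per
#' frame.
#'
#' @param spec a \code{tube_spec}.
#' @return List with \code{frames} (a \code{frame_set}), \code{truth}
#'   (\code{radial_profile} at 0.05 nm shells plus the curves), and
#'   \code{frame} (the matching \code{cylinder_frame}).
#' @export
gen_tube_grid <- function(spec) {
  gspec <- tube_grid_spec(spec)
  cf <- resolve_frame(gspec, cylinder_frame(axis = spec$axis))
  pol <- voxel_polar(gspec, cf)
  rad <- pol$rad
  srr_f <- tube_srr_interp(spec, max(rad))
  n <- gspec$n
  stt <- spec$stt_curve(rad)
  A <- spec$A_curve(rad)
  cyl <- array(0, dim = c(n, 3L, 3L))
  cyl[, , , 1, 1] <- srr_f(rad)
  cyl[, , , 2, 2] <- stt
  cyl[, , , 3, 3] <- stt - A
  if (!is.null(spec$offdiag_curve)) {
    g <- spec$offdiag_curve(rad)
    cyl[, , , 2, 3] <- g
    cyl[, , , 3, 2] <- g
  }
  base <- rotate_from_cylindrical(stress_grid(gspec, cyl), cf)
  frames <- with_seed(spec$seed, lapply(seq_len(spec$n_frames), function(k) {
    if (spec$noise_sd == 0) return(base)
    stress_grid(gspec, base$tensors + symmetric_noise(n, spec$noise_sd))
  }))
  list(frames = frame_set(frames),
       truth = tube_truth_profile(spec),
       spec = spec, frame = cf)
}

# i.i.d. Gaussian noise on the 6 independent components of a symmetric tensor
symmetric_noise <- function(n, sd) {
  noise <- array(0, dim = c(n, 3L, 3L))
  for (ab in list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))) {
    field <- array(stats::rnorm(prod(n), sd = sd), dim = n)
    noise[, , , ab[1], ab[2]] <- field
    if (ab[1] != ab[2]) noise[, , , ab[2], ab[1]] <- field
  }
  noise
}

#' Generate total / inner-only / outer-only synthetic tube fields
#'
#' Emulates the monolayer-decomposition experiment: the inner-only and
#' outer-only fields are built from their own curves, and the total adds an
#' interaction cross-term; all three are equilibrated independently.
#'
#' @param spec a \code{tube_spec} used for geometry, noise and seed.
#' @param inner_A,outer_A,interaction_A anisotropy contribution curves
#'   (functions of r, bar); defaults split the spec's curve at the
#'   midsurface with zero interaction.
#' @param inner_stt,outer_stt,interaction_stt azimuthal contribution curves;
#'   defaults split the spec's azimuthal curve at the midsurface.
#' @return List of three generator outputs (\code{total}, \code{inner_only},
#'   \code{outer_only}) plus the interaction ground truth.
#' @export
gen_component_grids <- function(spec,
                                inner_A = function(r) spec$A_curve(r) * (r < spec$R),
                                outer_A = function(r) spec$A_curve(r) * (r >= spec$R),
                                interaction_A = function(r) rep(0, length(r)),
                                inner_stt = function(r) spec$stt_curve(r) * (r < spec$R),
                                outer_stt = function(r) spec$stt_curve(r) * (r >= spec$R),
                                interaction_stt = NULL) {
  if (is.null(interaction_stt)) interaction_stt <- interaction_A
  mk <- function(sttc, Ac, seed_off) {
    s <- spec
    s$stt_curve <- sttc
    s$A_curve <- Ac
    s$seed <- spec$seed + seed_off
    gen_tube_grid_unchecked(s)
  }
  total <- mk(function(r) inner_stt(r) + outer_stt(r) + interaction_stt(r),
              function(r) inner_A(r) + outer_A(r) + interaction_A(r), 0L)
  inner <- mk(inner_stt, inner_A, 1L)
  outer <- mk(outer_stt, outer_A, 2L)
  list(total = total, inner_only = inner, outer_only = outer,
       interaction = list(A = interaction_A, stt = interaction_stt))
}

# gen_tube_grid without the A(R) = 0 requirement (component curves are
# one-sided and need not vanish at the midsurface individually)
gen_tube_grid_unchecked <- function(spec) {
  class(spec) <- "tube_spec"
  gen_tube_grid(spec)
}

#' Synthetic planar-bilayer specification
#'
#' Three lateral-stress peaks per leaflet, mirrored about the midplane:
#' a repulsive peak at the bilayer center, an attractive trough in the
#' hydrophobic-hydrophilic transition zone, and a repulsive head-group peak.
#'
#' @param box length-3 box (nm); the normal runs along \code{normal_axis}.
#' @param spacing length-3 voxel spacing (nm); default: one voxel in-plane,
#'   0.05 nm along the normal.
#' @param normal_axis grid axis of the bilayer normal.
#' @param peaks data frame with columns \code{center} (nm from the midplane,
#'   mirrored), \code{width} (nm) and \code{amplitude} (bar).
#' @param normal_offset constant normal-stress offset (bar).
#' @param noise_sd additive Gaussian voxel noise per frame (bar).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return Object of class \code{planar_spec}.
#' @export
planar_spec <- function(box = c(9, 9, 10.5),
                        spacing = c(box[1], box[2], 0.05),
                        normal_axis = 3L,
                        peaks = data.frame(
                          center = c(0, 1.4, 2.2),
                          width = c(0.35, 0.35, 0.3),
                          amplitude = c(150, -280, 230)),
                        normal_offset = 0, noise_sd = 50,
                        n_frames = 50L, seed = 1L) {
  if (any(peaks$width <= 0)) stop("peak widths must be > 0")
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  structure(list(box = box, spacing = spacing,
                 normal_axis = as.integer(normal_axis), peaks = peaks,
                 normal_offset = normal_offset, noise_sd = noise_sd,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "planar_spec")
}

#' Ground-truth lateral profile of a synthetic planar bilayer
#'
#' @param spec a \code{planar_spec}.
#' @param z coordinates along the normal (nm, midplane at box/2).
#' @return Lateral stress (bar) at \code{z}.
#' @export
planar_truth_curve <- function(spec, z) {
  x <- z - spec$box[spec$normal_axis] / 2
  out <- rep(0, length(z))
  for (k in seq_len(nrow(spec$peaks))) {
    pk <- spec$peaks[k, ]
    out <- out + gaussian_bump(x, pk$center, pk$width, pk$amplitude)
    if (pk$center != 0)
      out <- out + gaussian_bump(x, -pk$center, pk$width, pk$amplitude)
  }
  out
}

#' Generate a synthetic planar-bilayer stress field
#'
#' Both lateral diagonal components equal the three-peak profile in
#' expectation; the normal component is a constant offset; i.i.d. Gaussian
#' noise is added per diagonal component, voxel and frame.
#'
#' @param spec a \code{planar_spec}.
#' @return List with \code{frames} (a \code{frame_set}) and \code{truth}
#'   (function of z plus the spec).
#' @export
gen_planar_grid <- function(spec) {
  n <- pmax(1L, as.integer(round(spec$box / spec$spacing)))
  gspec <- grid_spec(n, spec$spacing, origin = c(0, 0, 0))
  z <- voxel_centers(gspec, spec$normal_axis)
  prof <- planar_truth_curve(spec, z)
  tr <- transverse_axes(spec$normal_axis)
  base <- array(0, dim = c(n, 3L, 3L))
  profile_field <- array(0, dim = n)
  idx <- slice.index(profile_field, spec$normal_axis)
  profile_field[] <- prof[idx]
  base[, , , tr[1], tr[1]] <- profile_field
  base[, , , tr[2], tr[2]] <- profile_field
  base[, , , spec$normal_axis, spec$normal_axis] <- spec$normal_offset
  frames <- with_seed(spec$seed, lapply(seq_len(spec$n_frames), function(k) {
    if (spec$noise_sd == 0) return(stress_grid(gspec, base))
    noisy <- base
    for (ax in 1:3) {
      noisy[, , , ax, ax] <- noisy[, , , ax, ax] +
        array(stats::rnorm(prod(n), sd = spec$noise_sd), dim = n)
    }
    stress_grid(gspec, noisy)
  }))
  list(frames = frame_set(frames),
       truth = list(curve = function(zz) planar_truth_curve(spec, zz),
                    z = z, lateral = prof, normal = spec$normal_offset),
       spec = spec)
}

#' Random Lennard-Jones fluid configuration
#'
#' Uniform random positions with minimum-separation rejection and
#' Maxwell-Boltzmann velocities at temperature T.
#'
#' @param n number of particles (>= 1).
#' @param box length-3 box (nm).
#' @param temperature K.
#' @param seed RNG seed.
#' @param mass particle mass (amu).
#' @param min_sep minimum allowed pair separation (nm).
#' @param max_tries packing attempts per particle before giving up.
#' @return A \code{particle_system}.
#' @export
gen_lj_fluid <- function(n, box = c(5, 5, 5), temperature = 300, seed = 1L,
                         mass = 72, min_sep = 0.4, max_tries = 2000L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    pos <- matrix(NA_real_, n, 3L)
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- stats::runif(3) * box
        if (k == 1L) { placed <- TRUE; pos[1, ] <- cand; break }
        dr <- min_image(sweep(pos[seq_len(k - 1L), , drop = FALSE], 2L, cand),
                        box, c(TRUE, TRUE, TRUE))
        if (min(sqrt(rowSums(dr^2))) >= min_sep) {
          placed <- TRUE; pos[k, ] <- cand; break
        }
      }
      if (!placed) stop("packing failed: box too dense for min_sep")
    }
    vsd <- sqrt(KB_KJ_MOL_K * temperature / mass)  # nm/ps
    vel <- matrix(stats::rnorm(3L * n, sd = vsd), n, 3L)
    if (temperature == 0) vel[] <- 0
    particle_system(pos, vel, rep(mass, n), box)
  })
}

#' Harmonically bonded dimer fixture
#'
#' Two particles along the first axis at separation d about the box center,
#' zero velocities, one harmonic bond.
#'
#' @param d separation (nm).
#' @param k force constant (kJ mol^-1 nm^-2).
#' @param r0 equilibrium length (nm).
#' @param box length-3 box (nm).
#' @param mass particle mass (amu).
#' @return List with \code{system} (a \code{particle_system}) and
#'   \code{model} (a \code{pair_force_model}).
#' @export
gen_bonded_dimer <- function(d, k = 100, r0 = 1, box = c(5, 5, 5), mass = 72) {
  center <- box / 2
  pos <- rbind(center - c(d / 2, 0, 0), center + c(d / 2, 0, 0))
  list(system = particle_system(pos, NULL, rep(mass, 2), box),
       model = harmonic_bonds(matrix(c(1L, 2L), 1L), k = k, r0 = r0))
}

#' Apportion lipids between the monolayers of a tube
#'
#' Counts proportional to the cylindrical pivotal-surface areas at radii
#' \code{R +/- pivot_offset}: the outer monolayer receives
#' \code{round(total (R + delta) / (2R))} lipids (an exact half rounds down)
#' and the inner monolayer the remainder, conserving the total exactly.
#'
#' @param total total lipid count (>= 2).
#' @param R midsurface radius (nm).
#' @param pivot_offset pivotal-plane distance from the midsurface (nm),
#'   with \code{R > pivot_offset > 0}.
#' @return Named integer vector \code{c(outer, inner)}.
#' @export
allocate_tube_lipids <- function(total, R = 6.5, pivot_offset = 1.0) {
  if (!(R > pivot_offset && pivot_offset > 0)) stop("need R > pivot_offset > 0")
  if (total < 2) stop("total must be >= 2")
  x <- total * (R + pivot_offset) / (2 * R)
  n_outer <- floor(x + 0.5)
  if (n_outer == x + 0.5) n_outer <- n_outer - 1  # tie: round down
  n_outer <- as.integer(n_outer)
  c(outer = n_outer, inner = as.integer(total) - n_outer)
}

#' Demonstration monolayer elastic profile
#'
#' A smooth, globally fluid reference profile over the monolayer thickness:
#' all three material functions vanish at both faces (so the predicted
#' anisotropy is continuous at the membrane boundary), the stretching modulus
#' peaks mid-monolayer, and the shear modulus changes sign with an exactly
#' vanishing thickness integral.
#' \itemize{
#'   \item \code{sigma0(z) = -sigma0_amp * sin(pi z / t)} (bar)
#'   \item \code{E(z) = E_amp * sin(pi z / t)^2} (bar)
#'   \item \code{lambda_S(z) = lS_amp * sin(2 pi z / t)} (bar)
#' }
#'
#' @param thickness monolayer thickness t (nm).
#' @param dz tabulation step (nm).
#' @param E_amp,sigma0_amp,lS_amp amplitudes (bar).
#' @return An \code{elastic_profile}.
#' @export
demo_monolayer_profile <- function(thickness = 2, dz = 0.02, E_amp = 600,
                                   sigma0_amp = 30, lS_amp = 60) {
  elastic_profile(seq(0, thickness, by = dz),
                  sigma0 = function(z) -sigma0_amp * sin(pi * z / thickness),
                  E = function(z) E_amp * sin(pi * z / thickness)^2,
                  lambda_S = function(z) lS_amp * sin(2 * pi * z / thickness),
                  thickness = thickness)
}

#' Demonstration bend maps of a 6.5 nm tube
#'
#' Pivotal surfaces 1 nm from the midsurface on either side (pivotal radii
#' 5.5 and 7.5 nm), fixed tube length (axial stretch 1), reference depth
#' z = 0 at the midsurface for both leaflets.
#'
#' @param inner_rp,outer_rp pivotal radii (nm).
#' @param pivot_depth reference depth of the pivotal surface (nm).
#' @return List with \code{inner} and \code{outer}
#'   \code{cylindrical_bend_map}s.
#' @export
demo_bend_maps <- function(inner_rp = 5.5, outer_rp = 7.5, pivot_depth = 1) {
  list(inner = cylindrical_bend_map(inner_rp, pivot_depth,
                                    orientation = "inward"),
       outer = cylindrical_bend_map(outer_rp, pivot_depth,
                                    orientation = "outward"))
}

#' Tube specification whose ground truth is a continuum-model prediction
#'
#' Builds the global-fluidity anisotropy prediction of the given elastic
#' profile and bend maps, turns it into generator curves (zero outside the
#' bilayer; the azimuthal curve adds a mirrored base shape), and returns the
#' matching \code{tube_spec}.
#'
#' @param profile an \code{elastic_profile}.
#' @param maps list with \code{inner} and \code{outer} bend maps.
#' @param noise_sd,n_frames,seed passed to \code{\link{tube_spec}}.
#' @param box,spacing grid geometry.
#' @return A \code{tube_spec} whose \code{A_curve} is the model prediction.
#' @export
model_tube_spec <- function(profile, maps = demo_bend_maps(), noise_sd = 20,
                            n_frames = 100L, seed = 1L,
                            box = c(20, 20, 10),
                            spacing = c(0.1, 0.1, box[3])) {
  pred <- bilayer_anisotropy(profile, maps$inner, maps$outer, "global")
  pred <- pred[!duplicated(pred$r), , drop = FALSE]
  R0 <- strain_from_bend_map(maps$inner, 0)$r
  pad <- 1e-9
  A_fun <- stats::approxfun(c(min(pred$r) - pad, pred$r, max(pred$r) + pad),
                            c(0, pred$A, 0), rule = 2)
  stt_fun <- function(r) {
    x <- r - R0
    base <- gaussian_bump(x, 0, 0.35, 80) +
      gaussian_bump(x, -1.2, 0.3, -150) + gaussian_bump(x, 1.2, 0.3, -150)
    base + A_fun(r) / 2
  }
  tube_spec(box = box, spacing = spacing, R = R0,
            thickness = profile$thickness, A_curve = A_fun,
            stt_curve = stt_fun, noise_sd = noise_sd,
            n_frames = n_frames, seed = seed)
}
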