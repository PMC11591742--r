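# Irving-Kirkwood-Noll local stress on a rectangular grid for toy particle
# systems with pairwise central forces. Kinetic terms spread each particle's
# -m v (x) v trilinearly over the 8 voxels around it; virial terms discretize
# the straight contour between minimum-image partners into short segments and
# spread each segment's force flux trilinearly at the segment midpoint.
# Internal accumulation is in kJ mol^-1 nm^-3; conversion to bar happens once,
# when the stress_grid is created.

BAR_PER_KJ_MOL_NM3 <- 16.6054
KB_KJ_MOL_K <- 0.0083144621

#' Toy particle system in a periodic box
#'
#' @param positions numeric matrix (n x 3), nm.
#' @param velocities numeric matrix (n x 3), nm/ps, or \code{NULL} for a
#'   static system.
#' @param masses numeric vector (amu), all > 0.
#' @param box numeric length-3 box edge lengths (nm).
#' @param pbc logical length-3, periodicity per axis.
#' @return Object of class \code{particle_system}.
#' @export
particle_system <- function(positions, velocities = NULL, masses,
                            box, pbc = c(TRUE, TRUE, TRUE)) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3L, length(box) == 3L, length(pbc) == 3L)
  if (is.null(velocities)) velocities <- matrix(0, n, 3L)
  velocities <- as.matrix(velocities)
  masses <- rep_len(as.numeric(masses), n)
  if (nrow(velocities) != n) stop("positions and velocities length mismatch")
  if (any(masses <= 0)) stop("masses must be > 0")
  if (any(pbc & box <= 0)) stop("periodic box components must be > 0")
  structure(list(positions = positions, velocities = velocities,
                 masses = masses, box = as.numeric(box), pbc = as.logical(pbc)),
            class = "particle_system")
}

#' Pairwise force models
#'
#' \code{harmonic_bonds} lists explicit bonded pairs with a harmonic
#' potential \code{V = k/2 (r - r0)^2}; \code{lj_model} applies a truncated
#' Lennard-Jones potential \code{4 eps ((sigma/r)^12 - (sigma/r)^6)} to all
#' pairs within the cutoff.
#'
#' @param pairs integer matrix (m x 2) of 1-based particle indices.
#' @param k harmonic force constant, kJ mol^-1 nm^-2 (>= 0).
#' @param r0 equilibrium length, nm.
#' @param epsilon LJ well depth, kJ mol^-1 (>= 0).
#' @param sigma LJ diameter, nm (> 0).
#' @param cutoff interaction cutoff, nm (> 0).
#' @return Object of class \code{pair_force_model}.
#' @export
harmonic_bonds <- function(pairs, k, r0) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (k < 0) stop("k must be >= 0")
  structure(list(kind = "harmonic", pairs = pairs, k = k, r0 = r0),
            class = "pair_force_model")
}

#' @rdname harmonic_bonds
#' @export
lj_model <- function(epsilon, sigma, cutoff) {
  if (epsilon < 0 || sigma <= 0 || cutoff <= 0)
    stop("invalid Lennard-Jones parameters")
  structure(list(kind = "lj", epsilon = epsilon, sigma = sigma,
                 cutoff = cutoff),
            class = "pair_force_model")
}

#' Contour discretization rule for virial spreading
#'
#' @param max_segment_frac maximum contour segment length as a fraction of
#'   the smallest voxel edge, in (0, 1].
#' @return Object of class \code{spreading_config}.
#' @export
spreading_config <- function(max_segment_frac = 0.5) {
  if (max_segment_frac <= 0 || max_segment_frac > 1)
    stop("max_segment_frac must lie in (0, 1]")
  structure(list(max_segment_frac = max_segment_frac),
            class = "spreading_config")
}

min_image <- function(dr, box, pbc) {
  for (ax in 1:3) {
    if (pbc[ax]) dr[, ax] <- dr[, ax] - box[ax] * round(dr[, ax] / box[ax])
  }
  dr
}

#' Pairwise central forces
#'
#' Evaluates the force model on a particle system under the minimum-image
#' convention. Forces are central (parallel to the separation vector) and
#' satisfy Newton's third law pairwise.
#'
#' @param system a \code{particle_system}.
#' @param model a \code{pair_force_model}.
#' @return List with integer vectors \code{i}, \code{j}, matrix \code{f}
#'   (force on particle i, kJ mol^-1 nm^-1) and matrix \code{rij}
#'   (minimum-image \code{r_i - r_j}, nm).
#' @export
pair_forces <- function(system, model) {
  stopifnot(inherits(system, "particle_system"),
            inherits(model, "pair_force_model"))
  pos <- system$positions
  if (model$kind == "harmonic") {
    i <- model$pairs[, 1]; j <- model$pairs[, 2]
  } else {
    n <- nrow(pos)
    if (n < 2L) {
      return(list(i = integer(0), j = integer(0),
                  f = matrix(0, 0, 3), rij = matrix(0, 0, 3)))
    }
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
  }
  rij <- min_image(pos[i, , drop = FALSE] - pos[j, , drop = FALSE],
                   system$box, system$pbc)
  r <- sqrt(rowSums(rij^2))
  if (model$kind == "lj") {
    keep <- r <= model$cutoff
    i <- i[keep]; j <- j[keep]
    rij <- rij[keep, , drop = FALSE]; r <- r[keep]
  }
  if (any(r == 0)) stop("pair at zero separation: force is singular")
  # scalar dV/dr; force on i is -dV/dr * rhat
  if (model$kind == "harmonic") {
    dVdr <- model$k * (r - model$r0)
  } else {
    sr6 <- (model$sigma / r)^6
    dVdr <- -24 * model$epsilon * (2 * sr6^2 - sr6) / r
  }
  f <- -dVdr / r * rij
  list(i = i, j = j, f = f, rij = rij)
}

# Trilinear scatter-add of per-point 3x3 tensors onto voxel-center nodes.
# points: m x 3; tensors: m x 9 (column-major 3x3). Returns n1*n2*n3 x 9.
deposit_trilinear <- function(points, tensors, spec, pbc, box) {
  m <- nrow(points)
  n <- spec$n
  acc <- matrix(0, prod(n), 9L)
  if (m == 0L) return(acc)
  u <- sweep(sweep(points, 2L, spec$origin), 2L, spec$spacing, "/") - 0.5
  i0 <- floor(u)
  fr <- u - i0
  for (corner in 0:7) {
    off <- c(corner %% 2L, (corner %/% 2L) %% 2L, corner %/% 4L)
    idx <- sweep(i0, 2L, off, "+")
    w <- rep(1, m)
    for (ax in 1:3) {
      w <- w * if (off[ax] == 1L) fr[, ax] else 1 - fr[, ax]
      if (pbc[ax]) {
        idx[, ax] <- idx[, ax] %% n[ax]
      } else if (any(idx[, ax] < 0 | idx[, ax] >= n[ax])) {
        stop("particle or contour segment outside a non-periodic grid")
      }
    }
    lin <- 1L + idx[, 1] + n[1] * (idx[, 2] + n[2] * idx[, 3])
    dep <- rowsum(w * tensors, group = lin, reorder = FALSE)
    rows <- as.integer(rownames(dep))
    acc[rows, ] <- acc[rows, ] + dep
  }
  acc
}

flat_to_tensors <- function(flat, n) {
  arr <- array(flat, dim = c(n, 3L, 3L))
  arr
}

#' Kinetic part of the Irving-Kirkwood stress
#'
#' Each particle deposits \code{-m v (x) v}, spread trilinearly over the 8
#' voxels surrounding its position and divided by the voxel volume. The
#' voxel-sum times voxel volume equals \code{-sum(m v (x) v)} exactly.
#'
#' @param system a \code{particle_system} with velocities.
#' @param spec a \code{grid_spec} covering the box.
#' @param units \code{"bar"} (default) or \code{"kJ/mol/nm^3"}.
#' @return A \code{stress_grid}.
#' @export
kinetic_stress <- function(system, spec, units = c("bar", "kJ/mol/nm^3")) {
  units <- match.arg(units)
  v <- system$velocities
  outer9 <- cbind(v[, 1] * v, v[, 2] * v, v[, 3] * v)  # m x 9, column-major
  tens <- -system$masses * outer9
  flat <- deposit_trilinear(system$positions, tens, spec,
                            system$pbc, system$box) / voxel_volume(spec)
  if (units == "bar") flat <- flat * BAR_PER_KJ_MOL_NM3
  stress_grid(spec, flat_to_tensors(flat, spec$n))
}

#' Virial (configurational) part of the Irving-Kirkwood stress
#'
#' For each interacting pair the straight Irving-Kirkwood contour between the
#' minimum-image positions is cut into segments no longer than
#' \code{max_segment_frac} of the smallest voxel edge; each segment deposits
#' \code{-(segment vector) (x) f_ij} trilinearly at its midpoint, divided by
#' the voxel volume. The voxel-sum times voxel volume equals
#' \code{-sum(r_ij (x) f_ij)} exactly for any segment count.
#'
#' @param system the \code{particle_system} the pairs came from.
#' @param pairs output of \code{\link{pair_forces}}.
#' @param spec a \code{grid_spec}.
#' @param cfg a \code{spreading_config}.
#' @param units \code{"bar"} (default) or \code{"kJ/mol/nm^3"}.
#' @return A \code{stress_grid}.
#' @export
virial_stress <- function(system, pairs, spec, cfg = spreading_config(),
                          units = c("bar", "kJ/mol/nm^3")) {
  units <- match.arg(units)
  npair <- length(pairs$i)
  n <- spec$n
  if (npair == 0L) {
    flat <- matrix(0, prod(n), 9L)
  } else {
    maxlen <- cfg$max_segment_frac * min(spec$spacing)
    rlen <- sqrt(rowSums(pairs$rij^2))
    nseg <- pmax(1L, ceiling(rlen / maxlen))
    total <- sum(nseg)
    pid <- rep.int(seq_len(npair), nseg)
    # fractional midpoints (k - 1/2)/nseg along the contour from j' to i
    k <- sequence(nseg)
    tfrac <- (k - 0.5) / nseg[pid]
    pi_ <- system$positions[pairs$i[pid], , drop = FALSE]
    rij <- pairs$rij[pid, , drop = FALSE]
    mid <- pi_ - rij * (1 - tfrac)
    seg <- rij / nseg[pid]
    f <- pairs$f[pid, , drop = FALSE]
    tens <- -cbind(seg * f[, 1], seg * f[, 2], seg * f[, 3])  # -(seg (x) f)
    # wrap midpoints into the box where periodic (deposition wraps indices too,
    # but keeping coordinates near the grid avoids large index excursions)
    flat <- deposit_trilinear(mid, tens, spec, system$pbc, system$box) /
      voxel_volume(spec)
  }
  if (units == "bar") flat <- flat * BAR_PER_KJ_MOL_NM3
  stress_grid(spec, flat_to_tensors(flat, n))
}

#' Irving-Kirkwood stress grid of a trajectory
#'
#' Per-frame kinetic plus virial stress, averaged over frames, in bar
#' (1 kJ mol^-1 nm^-3 = 16.6054 bar).
#'
#' @param frames a single \code{particle_system} or a list of them.
#' @param model a \code{pair_force_model}.
#' @param spec a \code{grid_spec}.
#' @param cfg a \code{spreading_config}.
#' @return A \code{stress_grid} in bar.
#' @export
compute_stress_grid <- function(frames, model, spec, cfg = spreading_config()) {
  if (inherits(frames, "particle_system")) frames <- list(frames)
  if (length(frames) < 1L) stop("at least one frame is required")
  grids <- lapply(frames, function(sys) {
    kin <- kinetic_stress(sys, spec, units = "kJ/mol/nm^3")
    vir <- virial_stress(sys, pair_forces(sys, model), spec, cfg,
                         units = "kJ/mol/nm^3")
    stress_grid(spec, (kin$tensors + vir$tensors) * BAR_PER_KJ_MOL_NM3)
  })
  mean_grid(frame_set(grids))
}

#' Global virial stress tensor of one frame
#'
#' The box-averaged tension-positive stress
#' \code{-(sum m v (x) v + sum r_ij (x) f_ij) / V}, the quantity the
#' voxel-integrated Irving-Kirkwood grid must reproduce.
#'
#' @param system a \code{particle_system}.
#' @param pairs output of \code{\link{pair_forces}}.
#' @param units \code{"bar"} or \code{"kJ/mol/nm^3"}.
#' @return A 3x3 matrix.
#' @export
global_virial <- function(system, pairs, units = c("bar", "kJ/mol/nm^3")) {
  units <- match.arg(units)
  v <- system$velocities
  kin <- -t(v * system$masses) %*% v
  vir <- if (length(pairs$i) > 0) -t(pairs$rij) %*% pairs$f else matrix(0, 3, 3)
  out <- (kin + vir) / prod(system$box)
  if (units == "bar") out <- out * BAR_PER_KJ_MOL_NM3
  out
}

#' Volume-weighted integral of a stress grid
#'
#' @param grid a \code{stress_grid}.
#' @return 3x3 matrix: voxel-sum of tensors times voxel volume.
#' @export
grid_integral <- function(grid) {
  flat <- matrix(grid$tensors, ncol = 9L)
  matrix(colSums(flat), 3L, 3L) * voxel_volume(grid$spec)
}
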