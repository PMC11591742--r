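# Measurement pipeline for cylindrically curved membranes: per-voxel rotation
# of the stress tensor into cylindrical components, radial shell binning,
# anisotropy / maximum-shear / off-diagonal profiles, the discrete radial
# equilibrium residual, monolayer decomposition, and planar (slab-binned)
# profiles.

#' Cylindrical analysis frame
#'
#' @param axis which grid axis (1..3) is the cylinder axis.
#' @param axis_point 2D point (nm) where the axis crosses the transverse
#'   plane; \code{NULL} (default) means the transverse grid center.
#' @param r_max maximum shell radius (nm); \code{NULL} means half the
#'   smaller transverse grid extent.
#' @param dr shell width (nm), default 0.05.
#' @return Object of class \code{cylinder_frame}.
#' @export
cylinder_frame <- function(axis = 3L, axis_point = NULL, r_max = NULL,
                           dr = 0.05) {
  stopifnot(axis %in% 1:3, dr > 0)
  if (!is.null(r_max) && r_max <= 0) stop("r_max must be > 0")
  structure(list(axis = as.integer(axis), axis_point = axis_point,
                 r_max = r_max, dr = dr),
            class = "cylinder_frame")
}

transverse_axes <- function(axis) setdiff(1:3, axis)

resolve_frame <- function(spec, frame) {
  tr <- transverse_axes(frame$axis)
  if (is.null(frame$axis_point)) {
    frame$axis_point <- vapply(tr, function(ax)
      spec$origin[ax] + spec$n[ax] * spec$spacing[ax] / 2, numeric(1))
  }
  if (is.null(frame$r_max)) {
    frame$r_max <- min(vapply(tr, function(ax)
      spec$n[ax] * spec$spacing[ax] / 2, numeric(1)))
  }
  frame
}

# Per-voxel transverse polar coordinates relative to the axis point.
voxel_polar <- function(spec, frame) {
  frame <- resolve_frame(spec, frame)
  tr <- transverse_axes(frame$axis)
  c1 <- voxel_centers(spec, tr[1]) - frame$axis_point[1]
  c2 <- voxel_centers(spec, tr[2]) - frame$axis_point[2]
  full <- array(0, dim = spec$n)
  t1 <- slice.index(full, tr[1])
  t2 <- slice.index(full, tr[2])
  x1 <- c1[t1]
  x2 <- c2[t2]
  rad <- sqrt(x1^2 + x2^2)
  theta <- atan2(x2, x1)
  theta[rad == 0] <- 0  # voxel exactly on the axis: theta defined as 0
  list(rad = rad, theta = theta, frame = frame, tr = tr)
}

#' Rotate a stress grid into cylindrical tensor components
#'
#' At each voxel the tensor is conjugated with the rotation by the azimuthal
#' angle \code{theta} of the voxel center about the cylinder axis,
#' \code{S' = t(A) S A}, and the components are reordered to
#' (radial, azimuthal, axial). Trace and eigenvalues are preserved per voxel.
#'
#' @param grid a \code{stress_grid} in lab components.
#' @param frame a \code{cylinder_frame}.
#' @return A \code{stress_grid} whose tensor slots are
#'   (r, theta, axial); the resolved frame is attached as attribute
#'   \code{"cylinder_frame"}.
#' @export
rotate_to_cylindrical <- function(grid, frame = cylinder_frame()) {
  pol <- voxel_polar(grid$spec, frame)
  tr <- pol$tr
  ax <- pol$frame$axis
  co <- cos(pol$theta); si <- sin(pol$theta)
  S <- function(a, b) grid_component(grid, a, b)
  A <- S(tr[1], tr[1]); B <- S(tr[1], tr[2]); Cc <- S(tr[2], tr[1])
  D <- S(tr[2], tr[2])
  E1 <- S(tr[1], ax); F1 <- S(tr[2], ax)
  G <- S(ax, tr[1]); H <- S(ax, tr[2]); I3 <- S(ax, ax)
  out <- array(0, dim = c(grid$spec$n, 3L, 3L))
  out[, , , 1, 1] <- co^2 * A + co * si * (B + Cc) + si^2 * D
  out[, , , 1, 2] <- -co * si * A + co^2 * B - si^2 * Cc + co * si * D
  out[, , , 2, 1] <- -co * si * A - si^2 * B + co^2 * Cc + co * si * D
  out[, , , 2, 2] <- si^2 * A - co * si * (B + Cc) + co^2 * D
  out[, , , 1, 3] <- co * E1 + si * F1
  out[, , , 2, 3] <- -si * E1 + co * F1
  out[, , , 3, 1] <- co * G + si * H
  out[, , , 3, 2] <- -si * G + co * H
  out[, , , 3, 3] <- I3
  res <- stress_grid(grid$spec, out, n_frames = grid$n_frames)
  attr(res, "cylinder_frame") <- pol$frame
  attr(res, "components") <- c("r", "theta", "axial")
  res
}

#' Rotate a cylindrical-component grid back to the lab frame
#'
#' Exact inverse of \code{\link{rotate_to_cylindrical}} for the same frame.
#'
#' @param grid a \code{stress_grid} in cylindrical components.
#' @param frame the \code{cylinder_frame} used for the forward rotation.
#' @return A \code{stress_grid} in lab components.
#' @export
rotate_from_cylindrical <- function(grid, frame = cylinder_frame()) {
  pol <- voxel_polar(grid$spec, frame)
  tr <- pol$tr
  ax <- pol$frame$axis
  co <- cos(pol$theta); si <- sin(pol$theta)
  Srr <- grid$tensors[, , , 1, 1]; Srt <- grid$tensors[, , , 1, 2]
  Str <- grid$tensors[, , , 2, 1]; Stt <- grid$tensors[, , , 2, 2]
  Srz <- grid$tensors[, , , 1, 3]; Stz <- grid$tensors[, , , 2, 3]
  Szr <- grid$tensors[, , , 3, 1]; Szt <- grid$tensors[, , , 3, 2]
  Szz <- grid$tensors[, , , 3, 3]
  out <- array(0, dim = c(grid$spec$n, 3L, 3L))
  out[, , , tr[1], tr[1]] <- co^2 * Srr - co * si * (Srt + Str) + si^2 * Stt
  out[, , , tr[1], tr[2]] <- co * si * Srr + co^2 * Srt - si^2 * Str - co * si * Stt
  out[, , , tr[2], tr[1]] <- co * si * Srr - si^2 * Srt + co^2 * Str - co * si * Stt
  out[, , , tr[2], tr[2]] <- si^2 * Srr + co * si * (Srt + Str) + co^2 * Stt
  out[, , , tr[1], ax] <- co * Srz - si * Stz
  out[, , , tr[2], ax] <- si * Srz + co * Stz
  out[, , , ax, tr[1]] <- co * Szr - si * Szt
  out[, , , ax, tr[2]] <- si * Szr + co * Szt
  out[, , , ax, ax] <- Szz
  stress_grid(grid$spec, out, n_frames = grid$n_frames)
}

#' Radial shell binning of a cylindrical-component grid
#'
#' A voxel belongs to shell k (center radius \code{k*dr}) when its center
#' radius lies in \code{[k*dr - dr/2, k*dr + dr/2)}. Shell means are
#' unweighted over voxels; empty shells carry \code{NA} and count 0.
#'
#' @param rotgrid output of \code{\link{rotate_to_cylindrical}}.
#' @param frame the \code{cylinder_frame}; defaults to the one attached to
#'   \code{rotgrid}.
#' @return A \code{radial_profile}: data frame with shell centers \code{r},
#'   voxel \code{count} and mean components \code{srr, stt, szz, srt, srz,
#'   stz} (bar).
#' @export
radial_bin <- function(rotgrid, frame = NULL) {
  if (is.null(frame)) frame <- attr(rotgrid, "cylinder_frame")
  if (is.null(frame)) stop("no cylinder_frame given or attached")
  pol <- voxel_polar(rotgrid$spec, frame)
  frame <- pol$frame
  nshell <- as.integer(round(frame$r_max / frame$dr))
  shell <- as.integer(floor(pol$rad / frame$dr + 0.5))
  keep <- shell < nshell
  shellk <- shell[keep]
  comp_names <- c("srr", "stt", "szz", "srt", "srz", "stz")
  comp_idx <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  counts <- tabulate(shellk + 1L, nbins = nshell)
  out <- data.frame(r = (seq_len(nshell) - 1L) * frame$dr, count = counts)
  for (m in seq_along(comp_names)) {
    field <- rotgrid$tensors[, , , comp_idx[[m]][1], comp_idx[[m]][2]]
    sums <- rep(0, nshell)
    agg <- rowsum(as.vector(field)[keep], group = shellk, reorder = FALSE)
    sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    out[[comp_names[m]]] <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  }
  structure(out, class = c("radial_profile", "data.frame"),
            cylinder_frame = frame)
}

#' Construct a radial profile from tabulated values
#'
#' Used by generators (ground truth) and tests.
#'
#' @param r shell center radii (nm).
#' @param ... named numeric columns among \code{srr, stt, szz, srt, srz,
#'   stz} and optional \code{*_ci} half-widths.
#' @param count voxel counts (default 1).
#' @return A \code{radial_profile}.
#' @export
radial_profile <- function(r, ..., count = 1L) {
  out <- data.frame(r = r, count = rep_len(count, length(r)), ...)
  structure(out, class = c("radial_profile", "data.frame"))
}

ci_col <- function(p, name) {
  cn <- paste0(name, "_ci")
  if (cn %in% names(p)) p[[cn]] else NULL
}

#' Anisotropy profile A(r) = Sigma_thetatheta - Sigma_zz
#'
#' @param p a \code{radial_profile} with \code{stt} and \code{szz}.
#' @return Data frame with \code{r}, \code{count}, \code{A} and, when both
#'   component bands are present, quadrature-propagated \code{A_ci}.
#' @export
anisotropy_profile <- function(p) {
  stopifnot(all(c("stt", "szz") %in% names(p)))
  out <- data.frame(r = p$r, count = p$count, A = p$stt - p$szz)
  ctt <- ci_col(p, "stt"); czz <- ci_col(p, "szz")
  if (!is.null(ctt) && !is.null(czz)) out$A_ci <- sqrt(ctt^2 + czz^2)
  out
}

#' Maximum lateral shear stress profile
#'
#' With zero off-diagonals the cylindrical directions are principal, and the
#' maximum lateral shear stress, attained after rotating the azimuthal/axial
#' axes by -pi/4 about the radial direction, is
#' \code{s(r) = (Sigma_thetatheta - Sigma_zz)/2}. The value is also computed
#' as the theta-z off-diagonal after an explicit -pi/4 rotation of the mean
#' shell tensor and the two must agree to \code{check_tol}.
#'
#' @param p a \code{radial_profile}.
#' @param check_tol tolerance for the internal rotation cross-check.
#' @return Data frame with \code{r}, \code{count}, \code{shear} and optional
#'   \code{shear_ci}.
#' @export
max_shear_profile <- function(p, check_tol = 1e-12) {
  s_half <- (p$stt - p$szz) / 2
  # explicit -pi/4 rotation of the mean shell tensor about the radial axis
  ang <- -pi / 4
  R <- rbind(c(1, 0, 0),
             c(0, cos(ang), -sin(ang)),
             c(0, sin(ang), cos(ang)))
  getc <- function(nm) if (nm %in% names(p)) p[[nm]] else rep(0, nrow(p))
  srr <- getc("srr"); srt <- getc("srt"); srz <- getc("srz")
  stz <- getc("stz")
  rot_offdiag <- vapply(seq_len(nrow(p)), function(k) {
    comps <- c(srr[k], p$stt[k], p$szz[k], srt[k], srz[k], stz[k])
    if (any(is.na(comps))) return(NA_real_)
    S <- matrix(c(comps[1], comps[4], comps[5],
                  comps[4], comps[2], comps[6],
                  comps[5], comps[6], comps[3]), 3, 3)
    (t(R) %*% S %*% R)[2, 3]
  }, numeric(1))
  # the theta'-z' off-diagonal of the rotated tensor equals (stt - szz)/2
  # because cos(-pi/4)^2 = sin(-pi/4)^2 kills the stz term
  ok <- is.na(s_half) | is.na(rot_offdiag) |
    abs(rot_offdiag - s_half) <= check_tol * pmax(1, abs(s_half))
  if (!all(ok)) stop("explicit -pi/4 rotation disagrees with (stt - szz)/2")
  out <- data.frame(r = p$r, count = p$count, shear = s_half)
  ctt <- ci_col(p, "stt"); czz <- ci_col(p, "szz")
  if (!is.null(ctt) && !is.null(czz)) out$shear_ci <- sqrt(ctt^2 + czz^2) / 2
  attr(out, "rotation_check") <- rot_offdiag
  out
}

#' Off-diagonal component profile
#'
#' @param p a \code{radial_profile}.
#' @param which one of \code{"rt"}, \code{"rz"}, \code{"tz"} (radial-azimuthal,
#'   radial-axial, azimuthal-axial).
#' @return Data frame with \code{r}, \code{count}, \code{value} and optional
#'   \code{value_ci}.
#' @export
offdiagonal_profile <- function(p, which = c("tz", "rt", "rz")) {
  which <- match.arg(which)
  col <- c(rt = "srt", rz = "srz", tz = "stz")[[which]]
  if (!col %in% names(p)) stop("component not present in profile: ", col)
  out <- data.frame(r = p$r, count = p$count, value = p[[col]])
  ci <- ci_col(p, col)
  if (!is.null(ci)) out$value_ci <- ci
  out
}

#' Discrete radial-equilibrium residual
#'
#' \code{rho(r) = d/dr (r Sigma_rr) - Sigma_thetatheta}, with the derivative
#' approximated by central differences on interior shells; endpoint shells
#' and shells adjacent to gaps are excluded (\code{NA}).
#'
#' @param p a \code{radial_profile} with \code{srr} and \code{stt}.
#' @return Data frame with \code{r}, \code{residual} and optional
#'   \code{residual_ci}.
#' @export
equilibrium_residual <- function(p) {
  stopifnot(all(c("srr", "stt") %in% names(p)))
  n <- nrow(p)
  if (n < 3L) stop("at least 3 shells are required")
  ok <- p$count > 0 & !is.na(p$srr)
  if (sum(ok) < 3L) stop("fewer than 3 non-empty shells")
  rs <- p$r * p$srr
  res <- rep(NA_real_, n)
  idx <- 2:(n - 1)
  good <- ok[idx - 1] & ok[idx] & ok[idx + 1]
  res[idx[good]] <- (rs[idx[good] + 1] - rs[idx[good] - 1]) /
    (p$r[idx[good] + 1] - p$r[idx[good] - 1]) - p$stt[idx[good]]
  out <- data.frame(r = p$r, residual = res)
  crr <- ci_col(p, "srr"); ctt <- ci_col(p, "stt")
  if (!is.null(crr) && !is.null(ctt)) {
    rci <- rep(NA_real_, n)
    denom <- p$r[idx + 1] - p$r[idx - 1]
    rci[idx] <- sqrt(((p$r[idx + 1] * crr[idx + 1])^2 +
                        (p$r[idx - 1] * crr[idx - 1])^2) / denom^2 +
                       ctt[idx]^2)
    out$residual_ci <- rci
  }
  out
}

#' Monolayer decomposition of a profile
#'
#' \code{interaction = total - inner_only - outer_only}, per component and
#' per shell, mirroring the removal of one monolayer from a saved trajectory.
#' The identity \code{inner + outer + interaction = total} is exact by
#' construction.
#'
#' @param total,inner_only,outer_only \code{radial_profile}s on identical
#'   shell grids.
#' @return A \code{radial_profile} of the interaction contribution; component
#'   bands combine in quadrature.
#' @export
decompose_contributions <- function(total, inner_only, outer_only) {
  if (!isTRUE(all.equal(total$r, inner_only$r)) ||
      !isTRUE(all.equal(total$r, outer_only$r)))
    stop("mismatched shell grids")
  out <- data.frame(r = total$r, count = total$count)
  for (col in intersect(names(total), c("srr", "stt", "szz", "srt", "srz", "stz"))) {
    if (!col %in% names(inner_only) || !col %in% names(outer_only)) next
    out[[col]] <- total[[col]] - inner_only[[col]] - outer_only[[col]]
    cis <- lapply(list(total, inner_only, outer_only), ci_col, col)
    if (!any(vapply(cis, is.null, logical(1))))
      out[[paste0(col, "_ci")]] <- sqrt(cis[[1]]^2 + cis[[2]]^2 + cis[[3]]^2)
  }
  structure(out, class = c("radial_profile", "data.frame"))
}

#' Planar (slab-binned) stress profiles
#'
#' Means over slabs perpendicular to the stated normal axis (slab thickness =
#' voxel spacing): the lateral stress \code{(S11 + S22)/2}, the lateral
#' difference \code{S11 - S22}, and the normal component, in the
#' tension-positive convention (\code{pressure_convention = TRUE} negates
#' the output at reporting time).
#'
#' @param grid a \code{stress_grid} in lab components.
#' @param normal_axis grid axis (1..3) perpendicular to the bilayer.
#' @param pressure_convention emit pressure-convention profiles instead.
#' @return An \code{axial_profile} data frame with \code{z}, \code{lateral},
#'   \code{difference}, \code{normal}.
#' @export
planar_profiles <- function(grid, normal_axis = 3L,
                            pressure_convention = FALSE) {
  tr <- transverse_axes(normal_axis)
  slab_mean <- function(a, b) {
    apply(grid_component(grid, a, b), normal_axis, mean)
  }
  s11 <- slab_mean(tr[1], tr[1])
  s22 <- slab_mean(tr[2], tr[2])
  s33 <- slab_mean(normal_axis, normal_axis)
  sgn <- if (pressure_convention) -1 else 1
  out <- data.frame(z = voxel_centers(grid$spec, normal_axis),
                    lateral = sgn * (s11 + s22) / 2,
                    difference = sgn * (s11 - s22),
                    normal = sgn * s33)
  structure(out, class = c("axial_profile", "data.frame"))
}

#' Export a profile as tab-separated text
#'
#' @param profile a profile data frame.
#' @param path output path.
#' @param comment optional provenance lines written as \code{#} headers.
#' @return Invisibly, \code{path}.
#' @export
write_profile <- function(profile, path, comment = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: bar (tension-positive); lengths: nm",
               paste0("# ", comment)), con)
  utils::write.table(profile, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a profile written by \code{\link{write_profile}}
#'
#' @param path file path.
#' @return A data frame (class \code{radial_profile} if it has an \code{r}
#'   column).
#' @export
read_profile <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  if ("r" %in% names(out))
    class(out) <- c("radial_profile", "data.frame")
  out
}
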