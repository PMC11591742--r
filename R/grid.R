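# Stress-grid data model: rectangular 3D grids of 3x3 Cauchy stress tensors.
#
# Convention used throughout the package: tension-positive Cauchy stress in
# bar, so a homogeneous fluid at pressure P has Sigma = -P * I.

#' Grid geometry specification
#'
#' Defines the lattice on which local stress tensors are stored: voxel counts
#' and edge lengths per axis, the position of the corner of voxel
#' \code{(0,0,0)}, and axis labels identifying the cylinder/bilayer axis for
#' downstream analysis. Voxel \code{(i1,i2,i3)} (0-based) spans the half-open
#' box \code{[origin + i*d, origin + (i+1)*d)}; its nominal position is its
#' center.
#'
#' @param n integer vector of length 3, voxel counts per axis (all >= 1).
#' @param spacing numeric vector of length 3, voxel edge lengths in nm (> 0).
#' @param origin numeric vector of length 3, corner of voxel (0,0,0) in nm.
#' @param axis_labels character vector of length 3 naming the grid axes.
#' @return An object of class \code{grid_spec}.
#' @export
grid_spec <- function(n, spacing, origin = c(0, 0, 0),
                      axis_labels = c("x", "y", "z")) {
  n <- as.integer(n)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(n) == 3L, length(spacing) == 3L, length(origin) == 3L,
            length(axis_labels) == 3L)
  if (any(n < 1L)) stop("voxel counts must all be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacings must all be > 0")
  if (any(!is.finite(origin))) stop("origin must be finite")
  structure(list(n = n, spacing = spacing, origin = origin,
                 axis_labels = as.character(axis_labels)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, spacing (%g, %g, %g) nm\n",
              x$n[1], x$n[2], x$n[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) nm; axes: %s\n",
              x$origin[1], x$origin[2], x$origin[3],
              paste(x$axis_labels, collapse = ", ")))
  invisible(x)
}

#' Voxel-center coordinates along one grid axis
#'
#' @param spec a \code{grid_spec}.
#' @param axis integer 1..3.
#' @return Numeric vector of voxel-center coordinates (nm).
#' @export
voxel_centers <- function(spec, axis) {
  stopifnot(inherits(spec, "grid_spec"), axis %in% 1:3)
  spec$origin[axis] + (seq_len(spec$n[axis]) - 0.5) * spec$spacing[axis]
}

#' Voxel volume of a grid
#'
#' @param spec a \code{grid_spec}.
#' @return Voxel volume in nm^3.
#' @export
voxel_volume <- function(spec) prod(spec$spacing)

same_spec <- function(a, b, tol = 0) {
  identical(a$n, b$n) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol
}

#' Stress-tensor grid
#'
#' The central container of the package: one 3x3 stress tensor per voxel, in
#' bar, tension-positive Cauchy convention.
#'
#' @param spec a \code{grid_spec}.
#' @param tensors numeric array of dimension \code{c(n1, n2, n3, 3, 3)}; all
#'   entries must be finite. A single 3x3 matrix is broadcast to every voxel.
#' @param n_frames number of trajectory frames accumulated into this grid.
#' @return An object of class \code{stress_grid}.
#' @export
stress_grid <- function(spec, tensors, n_frames = 1L) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.matrix(tensors) && all(dim(tensors) == c(3L, 3L))) {
    tensors <- aperm(array(tensors, dim = c(3L, 3L, spec$n)), c(3L, 4L, 5L, 1L, 2L))
  }
  expected <- c(spec$n, 3L, 3L)
  if (!is.array(tensors) || !identical(dim(tensors), as.integer(expected)))
    stop("tensor array shape inconsistent with grid_spec")
  if (any(!is.finite(tensors)))
    stop("stress grid entries must all be finite")
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames_accumulated must be >= 1")
  structure(list(spec = spec, tensors = tensors, n_frames = n_frames,
                 convention = "tension-positive Cauchy stress"),
            class = "stress_grid")
}

#' @export
print.stress_grid <- function(x, ...) {
  cat(sprintf("stress_grid: %d x %d x %d voxels (bar, %s), %d frame(s)\n",
              x$spec$n[1], x$spec$n[2], x$spec$n[3],
              x$convention, x$n_frames))
  invisible(x)
}

#' Ordered collection of stress grids sharing one geometry
#'
#' @param ... \code{stress_grid} objects, or a single list of them.
#' @return An object of class \code{frame_set}.
#' @export
frame_set <- function(...) {
  frames <- list(...)
  if (length(frames) == 1L && !inherits(frames[[1]], "stress_grid"))
    frames <- frames[[1]]
  if (length(frames) == 0L) stop("frame_set must be non-empty")
  if (!all(vapply(frames, inherits, logical(1), "stress_grid")))
    stop("all members must be stress_grid objects")
  ref <- frames[[1]]$spec
  for (f in frames[-1]) {
    if (!same_spec(ref, f$spec)) stop("all frames must share one grid_spec")
  }
  structure(frames, class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("frame_set of %d stress grid(s)\n", length(x)))
  invisible(x)
}

#' Translate positions so their geometric center is the box center
#'
#' Pure translation: relative positions are unchanged, and the arithmetic
#' mean of the result equals \code{box/2}.
#'
#' @param positions numeric matrix, one row per particle, 3 columns (nm).
#' @param box numeric vector of length 3, box edge lengths (nm, > 0).
#' @return Matrix of translated positions.
#' @export
center_positions <- function(positions, box) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L) stop("at least one position is required")
  stopifnot(ncol(positions) == 3L, length(box) == 3L)
  if (any(box <= 0)) stop("box components must be > 0")
  shift <- box / 2 - colMeans(positions)
  sweep(positions, 2L, shift, "+")
}

#' Voxel-wise mean of a frame set
#'
#' @param frames a \code{frame_set}.
#' @return A \code{stress_grid} whose tensors are the arithmetic mean over
#'   members and whose frame count is the sum of the members' counts.
#' @export
mean_grid <- function(frames) {
  if (inherits(frames, "stress_grid")) return(frames)
  if (!inherits(frames, "frame_set")) frames <- frame_set(frames)
  acc <- frames[[1]]$tensors
  if (length(frames) > 1L) {
    for (f in frames[-1]) acc <- acc + f$tensors
  }
  acc <- acc / length(frames)
  stress_grid(frames[[1]]$spec, acc,
              n_frames = sum(vapply(frames, function(f) f$n_frames, integer(1))))
}

#' Symmetrize every voxel tensor
#'
#' Replaces each voxel tensor by \code{(S + t(S))/2}. The maximum asymmetry
#' removed, \code{max |S - t(S)|/2}, is attached as attribute
#' \code{"max_asymmetry"}.
#'
#' @param grid a \code{stress_grid}.
#' @return Symmetrized \code{stress_grid}.
#' @export
symmetrize <- function(grid) {
  stopifnot(inherits(grid, "stress_grid"))
  tt <- aperm(grid$tensors, c(1L, 2L, 3L, 5L, 4L))
  sym <- (grid$tensors + tt) / 2
  out <- stress_grid(grid$spec, sym, n_frames = grid$n_frames)
  attr(out, "max_asymmetry") <- max(abs(grid$tensors - tt)) / 2
  out
}

#' Extract one tensor component as a 3D field
#'
#' @param grid a \code{stress_grid}.
#' @param a,b row/column indices in 1..3.
#' @return Numeric array of dimension \code{n1 x n2 x n3}.
#' @export
grid_component <- function(grid, a, b) {
  out <- grid$tensors[, , , a, b, drop = FALSE]
  dim(out) <- grid$spec$n
  out
}
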