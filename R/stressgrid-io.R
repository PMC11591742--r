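# STRESSGRID v1: a portable on-disk format for stress-tensor grids.
#
# ASCII header:
#   STRESSGRID 1
#   dims n1 n2 n3
#   spacing d1 d2 d3 nm
#   origin ox oy oz nm
#   units bar
#   frames k
#   data binary|text
# followed by the payload: 9 tensor components per voxel in row order
# (11,12,13,21,22,23,31,32,33), last grid index fastest; binary payload is
# 64-bit little-endian floats, text payload is whitespace-separated decimals.

# Flatten tensors to payload order: i1 slowest ... i3, then a, then b fastest.
payload_order <- function(tensors) as.vector(aperm(tensors, c(5L, 4L, 3L, 2L, 1L)))

payload_unorder <- function(vec, n) {
  arr <- array(vec, dim = c(3L, 3L, n[3], n[2], n[1]))
  aperm(arr, c(5L, 4L, 3L, 2L, 1L))
}

#' Write a stress grid to a STRESSGRID v1 file
#'
#' Output is deterministic: two writes of the same grid produce identical
#' bytes. The grid is validated (finite entries) before any bytes are
#' written.
#'
#' @param grid a \code{stress_grid}.
#' @param path output file path.
#' @param data payload encoding, \code{"binary"} (64-bit little-endian) or
#'   \code{"text"}.
#' @return Invisibly, \code{path}.
#' @export
write_stress_grid <- function(grid, path, data = c("binary", "text")) {
  data <- match.arg(data)
  stopifnot(inherits(grid, "stress_grid"))
  if (any(!is.finite(grid$tensors)))
    stop("refusing to write a grid with non-finite entries")
  spec <- grid$spec
  header <- c(
    "STRESSGRID 1",
    paste("dims", paste(spec$n, collapse = " ")),
    paste("spacing", paste(sprintf("%.17g", spec$spacing), collapse = " "), "nm"),
    paste("origin", paste(sprintf("%.17g", spec$origin), collapse = " "), "nm"),
    "units bar",
    paste("frames", grid$n_frames),
    paste("data", data)
  )
  vec <- payload_order(grid$tensors)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (data == "binary") {
    writeBin(as.double(vec), con, size = 8L, endian = "little")
  } else {
    lines <- apply(matrix(sprintf("%.17g", vec), nrow = 9L), 2L,
                   paste, collapse = " ")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a STRESSGRID v1 file
#'
#' @param path path to a file written by \code{\link{write_stress_grid}}.
#' @return A \code{stress_grid}.
#' @export
read_stress_grid <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(7)
  for (k in 1:7) hdr[k] <- readLines(con, n = 1L)
  fail <- function(k) stop(sprintf("malformed STRESSGRID header at line %d: '%s'",
                                   k, hdr[k]))
  if (!identical(hdr[1], "STRESSGRID 1")) fail(1)
  tok <- strsplit(trimws(hdr), "[[:space:]]+")
  if (tok[[2]][1] != "dims" || length(tok[[2]]) != 4L) fail(2)
  n <- suppressWarnings(as.integer(tok[[2]][2:4]))
  if (any(is.na(n))) fail(2)
  if (tok[[3]][1] != "spacing" || length(tok[[3]]) != 5L || tok[[3]][5] != "nm") fail(3)
  spacing <- suppressWarnings(as.numeric(tok[[3]][2:4]))
  if (any(is.na(spacing))) fail(3)
  if (tok[[4]][1] != "origin" || length(tok[[4]]) != 5L || tok[[4]][5] != "nm") fail(4)
  origin <- suppressWarnings(as.numeric(tok[[4]][2:4]))
  if (any(is.na(origin))) fail(4)
  if (!identical(tok[[5]], c("units", "bar"))) fail(5)
  if (tok[[6]][1] != "frames" || length(tok[[6]]) != 2L) fail(6)
  n_frames <- suppressWarnings(as.integer(tok[[6]][2]))
  if (is.na(n_frames)) fail(6)
  if (tok[[7]][1] != "data" || !(tok[[7]][2] %in% c("binary", "text"))) fail(7)
  nval <- prod(n) * 9L
  if (tok[[7]][2] == "binary") {
    vec <- readBin(con, "double", n = nval + 1L, size = 8L, endian = "little")
  } else {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    vec <- as.numeric(unlist(strsplit(trimws(txt), "[[:space:]]+")))
  }
  if (length(vec) != nval)
    stop(sprintf(paste0("truncated or oversized payload: header declares %d ",
                        "values (%d voxels) but file holds %d"),
                 nval, prod(n), length(vec)))
  spec <- grid_spec(n, spacing, origin)
  stress_grid(spec, payload_unorder(vec, n), n_frames = n_frames)
}

#' Write a frame set as a directory of STRESSGRID files plus a manifest
#'
#' @param frames a \code{frame_set}.
#' @param dir output directory (created if absent).
#' @param data payload encoding passed to \code{\link{write_stress_grid}}.
#' @return Invisibly, the manifest path.
#' @export
write_frame_set <- function(frames, dir, data = "binary") {
  frames <- if (inherits(frames, "frame_set")) frames else frame_set(frames)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names <- sprintf("frame%04d.stressgrid", seq_along(frames))
  for (k in seq_along(frames))
    write_stress_grid(frames[[k]], file.path(dir, names[k]), data = data)
  manifest <- file.path(dir, "manifest.txt")
  writeLines(names, manifest)
  invisible(manifest)
}

#' Read a frame set written by \code{\link{write_frame_set}}
#'
#' @param dir directory containing a \code{manifest.txt} and STRESSGRID files.
#' @return A \code{frame_set} in manifest order.
#' @export
read_frame_set <- function(dir) {
  manifest <- file.path(dir, "manifest.txt")
  if (!file.exists(manifest)) stop("no manifest.txt in ", dir)
  names <- readLines(manifest)
  frame_set(lapply(file.path(dir, names), read_stress_grid))
}
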