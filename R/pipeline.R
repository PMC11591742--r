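# End-to-end orchestration: tube and planar analysis reports and the
# local-vs-global fluidity model comparison, with optional file output and a
# YAML run configuration.

#' Read a run configuration file
#'
#' A flat YAML file with key groups \code{frame} (cylinder frame), \code{plan}
#' (resampling plan), \code{tube} / \code{planar} (generator specs) and
#' \code{shell} (radius range for the shell-average statistic). Unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return Named list with resolved \code{cylinder_frame},
#'   \code{resampling_plan} and raw generator parameter lists.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("frame", "plan", "tube", "planar", "shell", "output")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  out <- list()
  out$frame <- do.call(cylinder_frame, as.list(cfg$frame %||% list()))
  out$plan <- do.call(resampling_plan, as.list(cfg$plan %||% list()))
  out$tube <- cfg$tube
  out$planar <- cfg$planar
  out$shell <- unlist(cfg$shell %||% c(4, 6))
  out$output <- cfg$output
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full radial analysis of a tube stress field
#'
#' Rotates, bins and band-estimates every cylindrical component, then derives
#' the anisotropy, maximum-shear, off-diagonal and equilibrium-residual
#' profiles, optional monolayer decomposition, and a machine-readable summary
#' (per-monolayer anisotropy extrema and the shell-average shear).
#'
#' @param frames a \code{frame_set} of lab-frame stress grids.
#' @param frame a \code{cylinder_frame}.
#' @param plan a \code{resampling_plan}.
#' @param midsurface midsurface radius (nm) separating the monolayers;
#'   \code{NULL} (default) uses the zero crossing of the anisotropy profile
#'   between its two extrema.
#' @param shell length-2 radius range (nm) for the shell-average shear.
#' @param decomposition optional list with \code{inner_only} and
#'   \code{outer_only} frame sets on the same grid.
#' @param output_dir optional directory; profiles are written as
#'   tab-separated text and the summary as YAML.
#' @return Object of class \code{tube_report}.
#' @export
analyze_tube <- function(frames, frame = cylinder_frame(),
                         plan = resampling_plan(), midsurface = NULL,
                         shell = c(4, 6), decomposition = NULL,
                         output_dir = NULL) {
  prof <- binned_profile_with_bands(frames, frame, plan)
  rframe <- attr(prof, "cylinder_frame")
  ani <- anisotropy_profile(prof)
  ani$A_lo <- prof$stt_lo - prof$szz_hi
  ani$A_hi <- prof$stt_hi - prof$szz_lo
  shear <- max_shear_profile(prof, check_tol = 1e-9)
  offdiags <- list(tz = offdiagonal_profile(prof, "tz"),
                   rt = offdiagonal_profile(prof, "rt"),
                   rz = offdiagonal_profile(prof, "rz"))
  resid <- equilibrium_residual(prof)
  if (is.null(midsurface)) midsurface <- find_midsurface(ani)
  inner_ext <- extremum_with_ci(ani, c(max(0, midsurface - 3), midsurface),
                                value_col = "A")
  outer_ext <- extremum_with_ci(ani, c(midsurface, midsurface + 3),
                                value_col = "A")
  savg <- shell_average_shear(frames, shell[1], shell[2],
                              plan = plan, frame = frame)
  decomp <- NULL
  if (!is.null(decomposition)) {
    reduce <- function(fs) radial_bin(rotate_to_cylindrical(mean_grid(fs), frame))
    decomp <- decompose_contributions(
      radial_bin(rotate_to_cylindrical(mean_grid(frames), frame)),
      reduce(decomposition$inner_only), reduce(decomposition$outer_only))
  }
  # "consistent with zero" when >= 90% of non-empty shells' bands contain 0
  # (about 5% are expected to exclude it by chance at the 95% level)
  iso <- mean((ani$A_lo <= 0 & ani$A_hi >= 0)[ani$count > 0],
              na.rm = TRUE) >= 0.9
  report <- structure(list(
    components = prof, anisotropy = ani, max_shear = shear,
    offdiagonals = offdiags, equilibrium = resid, decomposition = decomp,
    summary = list(
      midsurface_r = midsurface,
      inner_extremum = inner_ext, outer_extremum = outer_ext,
      shell_average_shear = list(value = as.numeric(savg),
                                 lower = attr(savg, "lower"),
                                 upper = attr(savg, "upper"),
                                 r_in = shell[1], r_out = shell[2]),
      anisotropy_consistent_with_zero = iso,
      n_frames = length(frames), dr = rframe$dr,
      n_blocks = plan$n_blocks, n_resamples = plan$n_resamples,
      seed = plan$seed)), class = "tube_report")
  if (!is.null(output_dir)) write_tube_report(report, output_dir)
  report
}

# Zero crossing of the anisotropy profile between its two extrema.
find_midsurface <- function(ani) {
  ok <- which(!is.na(ani$A) & ani$count > 0)
  v <- ani$A[ok]
  imax <- ok[which.max(v)]
  imin <- ok[which.min(v)]
  lohi <- sort(c(imax, imin))
  seg <- seq(lohi[1], lohi[2])
  seg <- seg[!is.na(ani$A[seg])]
  flips <- which(diff(sign(ani$A[seg])) != 0)
  if (length(flips) == 0) return(mean(ani$r[lohi]))
  k <- seg[flips[1]]
  k2 <- seg[flips[1] + 1]
  # linear interpolation of the crossing
  ani$r[k] + (ani$r[k2] - ani$r[k]) * ani$A[k] / (ani$A[k] - ani$A[k2])
}

write_tube_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_profile(report$components, file.path(dir, "components.tsv"),
                comment = sprintf("blocks=%d resamples=%d seed=%d",
                                  report$summary$n_blocks,
                                  report$summary$n_resamples,
                                  report$summary$seed))
  write_profile(report$anisotropy, file.path(dir, "anisotropy.tsv"))
  write_profile(report$max_shear, file.path(dir, "max_shear.tsv"))
  for (nm in names(report$offdiagonals))
    write_profile(report$offdiagonals[[nm]],
                  file.path(dir, sprintf("offdiagonal_%s.tsv", nm)))
  write_profile(report$equilibrium, file.path(dir, "equilibrium_residual.tsv"))
  if (!is.null(report$decomposition))
    write_profile(report$decomposition, file.path(dir, "decomposition.tsv"))
  yaml::write_yaml(report$summary, file.path(dir, "summary.yaml"))
  invisible(dir)
}

#' @export
print.tube_report <- function(x, ...) {
  s <- x$summary
  cat("Tube stress analysis\n")
  cat(sprintf("  frames: %d, shells of %.3g nm, %d blocks x %d resamples\n",
              s$n_frames, s$dr, s$n_blocks, s$n_resamples))
  cat(sprintf("  midsurface radius: %.3f nm\n", s$midsurface_r))
  cat(sprintf("  anisotropy extrema: inner %+.2f bar at r = %.2f nm [%.2f, %.2f]\n",
              s$inner_extremum$value, s$inner_extremum$r,
              s$inner_extremum$lower, s$inner_extremum$upper))
  cat(sprintf("                      outer %+.2f bar at r = %.2f nm [%.2f, %.2f]\n",
              s$outer_extremum$value, s$outer_extremum$r,
              s$outer_extremum$lower, s$outer_extremum$upper))
  cat(sprintf("  shell-average shear (%.3g-%.3g nm): %.2f bar [%.2f, %.2f]\n",
              s$shell_average_shear$r_in, s$shell_average_shear$r_out,
              s$shell_average_shear$value, s$shell_average_shear$lower,
              s$shell_average_shear$upper))
  cat(sprintf("  anisotropy consistent with zero: %s\n",
              s$anisotropy_consistent_with_zero))
  invisible(x)
}

#' Planar bilayer analysis
#'
#' Slab-binned lateral, lateral-difference and normal stress profiles with
#' block-bootstrap bands.
#'
#' @param frames a \code{frame_set} of lab-frame stress grids.
#' @param normal_axis grid axis perpendicular to the bilayer.
#' @param plan a \code{resampling_plan}.
#' @param output_dir optional directory for tab-separated output.
#' @return Object of class \code{planar_report}: an \code{axial_profile} with
#'   band columns plus a summary.
#' @export
analyze_planar <- function(frames, normal_axis = 3L, plan = resampling_plan(),
                           output_dir = NULL) {
  blocks <- block_profiles(frames, plan,
                           function(g) planar_profiles(g, normal_axis))
  out <- blocks[[1]]["z"]
  for (col in c("lateral", "difference", "normal")) {
    band <- bootstrap_band(lapply(blocks, function(b) b[[col]]), plan)
    out[[col]] <- band$mean
    out[[paste0(col, "_lo")]] <- band$lower
    out[[paste0(col, "_hi")]] <- band$upper
  }
  report <- structure(list(
    profiles = out,
    summary = list(n_frames = length(frames),
                   normal_mean = mean(out$normal),
                   difference_consistent_with_zero =
                     mean(out$difference_lo <= 0 & out$difference_hi >= 0,
                          na.rm = TRUE) >= 0.9)),
    class = "planar_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_profile(out, file.path(output_dir, "planar_profiles.tsv"))
    yaml::write_yaml(report$summary, file.path(output_dir, "summary.yaml"))
  }
  report
}

#' Compare local- and global-fluidity predictions against measured anisotropy
#'
#' Overlays the measured anisotropy profile with the local-fluidity
#' prediction (identically zero) and the global-fluidity prediction from the
#' elastic profile and the two monolayer bend maps, counts at how many
#' informative shells each prediction lies inside the measured band, and
#' inverts the measured anisotropy for the depth-resolved lateral shear
#' modulus with its global-fluidity integral.
#'
#' @param anisotropy measured profile: data frame with \code{r}, \code{A} and
#'   band columns \code{A_lo}, \code{A_hi}.
#' @param profile an \code{elastic_profile}.
#' @param inner_map,outer_map \code{cylindrical_bend_map}s of the two
#'   monolayers.
#' @param midsurface radius separating the monolayers (nm); defaults to the
#'   radius both maps assign to depth zero.
#' @param min_count minimum voxel count for a shell to be informative.
#' @param strain_tol shells with \code{|uxx - uyy|} at or below this value are
#'   strain-degenerate for the inversion and excluded from the recovered
#'   modulus (the anisotropy overlay still uses them).
#' @return Object of class \code{model_comparison}.
#' @export
model_compare <- function(anisotropy, profile, inner_map, outer_map,
                          midsurface = NULL, min_count = 1L,
                          strain_tol = 0.02) {
  if (is.null(midsurface))
    midsurface <- strain_from_bend_map(inner_map, 0)$r
  r <- anisotropy$r
  use_inner <- r <= midsurface
  z <- ifelse(use_inner, depth_from_radius(inner_map, r),
              depth_from_radius(outer_map, r))
  in_monolayer <- z >= min(profile$z) & z <= max(profile$z)
  strains <- matrix(NA_real_, length(r), 2L)
  ok <- which(in_monolayer)
  for (k in ok) {
    map <- if (use_inner[k]) inner_map else outer_map
    st <- strain_from_bend_map(map, z[k])
    strains[k, ] <- c(st$uxx, st$uyy)
  }
  s0 <- profile_value(profile, "sigma0", z)
  E <- profile_value(profile, "E", z)
  lS_true <- profile_value(profile, "lambda_S", z)
  s <- strains[, 1] + strains[, 2]
  d <- strains[, 1] - strains[, 2]
  A_global <- (s0 + E * s + lS_true * (2 + s)) * d
  A_local <- rep(0, length(r))
  informative <- in_monolayer & !is.na(anisotropy$A) &
    anisotropy$count >= min_count
  inside <- function(pred) informative & !is.na(pred) &
    anisotropy$A_lo <= pred & pred <= anisotropy$A_hi
  lam <- recover_lateral_shear_modulus(anisotropy$A, strains[, 1],
                                       strains[, 2], s0, E,
                                       tol = strain_tol)
  lam[!informative] <- NA_real_
  lam_ci <- NULL
  if (all(c("A_lo", "A_hi") %in% names(anisotropy))) {
    half <- (anisotropy$A_hi - anisotropy$A_lo) / 2
    lam_ci <- abs(half / (d * (2 + s)))
    lam_ci[!informative | abs(d) <= strain_tol] <- NA_real_
  }
  rec_profile <- data.frame(r = r, z = z, lambda_S = lam,
                            lambda_S_ci = if (is.null(lam_ci)) NA_real_ else lam_ci,
                            monolayer = ifelse(use_inner, "inner", "outer"))
  # global-fluidity integral of the recovered modulus, per monolayer
  integrals <- vapply(c("inner", "outer"), function(side) {
    sel <- rec_profile$monolayer == side & !is.na(rec_profile$lambda_S)
    if (sum(sel) < 2) return(NA_real_)
    ordz <- order(rec_profile$z[sel])
    pracma::trapz(rec_profile$z[sel][ordz], rec_profile$lambda_S[sel][ordz])
  }, numeric(1))
  n_inf <- sum(informative)
  tab <- c(global = sum(inside(A_global)), local = sum(inside(A_local)))
  structure(list(
    overlay = data.frame(r = r, A_measured = anisotropy$A,
                         A_global = A_global, A_local = A_local,
                         informative = informative),
    recovered = rec_profile,
    fluidity_integral = integrals,
    n_informative = n_inf,
    shells_inside = tab,
    preferred = if (n_inf == 0) NA_character_
                else names(tab)[which.max(tab)]),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Fluidity model comparison\n")
  cat(sprintf("  informative shells: %d\n", x$n_informative))
  cat(sprintf("  prediction inside measured band: global %d, local %d\n",
              x$shells_inside["global"], x$shells_inside["local"]))
  cat(sprintf("  preferred model: %s\n", x$preferred))
  cat(sprintf("  recovered integral of lambda_S dz (bar nm): inner %.3g, outer %.3g\n",
              x$fluidity_integral["inner"], x$fluidity_integral["outer"]))
  invisible(x)
}

#' Shear-modulus recovery study on a model-generated tube
#'
#' End-to-end loop: predict the global-fluidity anisotropy of an elastic
#' profile bent into a tube, generate a synthetic stress field carrying that
#' prediction, run the measurement pipeline (rotation, binning, block
#' bootstrap), invert the measured anisotropy for the lateral shear modulus,
#' and score the recovery against the stored truth. Shells are scored only
#' where the strain anisotropy is informative
#' (\code{|uxx - uyy| >= min_strain}) and the depth is interior to the
#' monolayer.
#'
#' @param seed RNG seed for generator and resampling.
#' @param noise_sd voxel noise (bar); 0 gives the noiseless round trip.
#' @param n_frames frames to generate.
#' @param profile elastic profile (default \code{demo_monolayer_profile()}).
#' @param maps bend maps (default \code{demo_bend_maps()}).
#' @param min_strain informative-strain threshold (dimensionless).
#' @param edge_margin depth margin (nm) excluded at the monolayer faces.
#' @return List with the \code{model_comparison}, relative RMS recovery error
#'   \code{rms_rel}, band coverage of the truth \code{coverage}, number of
#'   scored shells, and the generated data.
#' @export
shear_recovery_study <- function(seed = 1L, noise_sd = 20, n_frames = 100L,
                                 profile = demo_monolayer_profile(),
                                 maps = demo_bend_maps(),
                                 min_strain = 0.02, edge_margin = 0.05) {
  spec <- model_tube_spec(profile, maps, noise_sd = noise_sd,
                          n_frames = n_frames, seed = seed)
  gen <- gen_tube_grid(spec)
  plan <- resampling_plan(seed = seed)
  if (noise_sd == 0 || n_frames < plan$n_blocks) {
    prof <- radial_bin(rotate_to_cylindrical(mean_grid(gen$frames), gen$frame))
    ani <- anisotropy_profile(prof)
    half <- rep(0, nrow(ani))
  } else {
    prof <- binned_profile_with_bands(gen$frames, gen$frame, plan)
    ani <- anisotropy_profile(prof)
    ani$A_lo <- prof$stt_lo - prof$szz_hi
    ani$A_hi <- prof$stt_hi - prof$szz_lo
    half <- (ani$A_hi - ani$A_lo) / 2
  }
  if (is.null(ani$A_lo)) { ani$A_lo <- ani$A; ani$A_hi <- ani$A }
  cmp <- model_compare(ani, profile, maps$inner, maps$outer,
                       midsurface = spec$R)
  rec <- cmp$recovered
  z <- rec$z
  strains <- vapply(seq_along(z), function(k) {
    if (is.na(z[k]) || z[k] < 0 || z[k] > profile$thickness)
      return(c(NA_real_, NA_real_))
    map <- if (rec$monolayer[k] == "inner") maps$inner else maps$outer
    st <- strain_from_bend_map(map, z[k])
    c(st$uxx - st$uyy, st$uxx + st$uyy)
  }, numeric(2))
  d <- strains[1, ]
  s_sum <- strains[2, ]
  score <- !is.na(rec$lambda_S) & !is.na(d) & abs(d) >= min_strain &
    z >= edge_margin & z <= profile$thickness - edge_margin
  truth <- profile_value(profile, "lambda_S", z)
  err <- rec$lambda_S[score] - truth[score]
  rms_rel <- sqrt(mean(err^2)) / sqrt(mean(truth[score]^2))
  # per-shell lambda_S half-width propagated from the A band
  lam_half <- abs(half / (d * (2 + s_sum)))
  coverage <- mean(abs(rec$lambda_S[score] - truth[score]) <=
                     lam_half[score])
  list(comparison = cmp, rms_rel = rms_rel, coverage = coverage,
       n_scored = sum(score), spec = spec, anisotropy = ani,
       recovered = rec, truth = truth, informative = score)
}
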