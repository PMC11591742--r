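# Continuum elasticity of an incompressible, transversely isotropic lipid
# monolayer: quadratic energy densities, the Cauchy stress of a laterally
# uniform deformation, finite-strain cylindrical bending about the pivotal
# surface, the radial-equilibrium Lagrange multiplier, the predicted
# azimuthal-axial stress anisotropy, and its inversion for the depth-resolved
# lateral shear modulus lambda_S(z).
#
# Fluidity dichotomy: the local fluidity assumption sets lambda_S(z) = 0 at
# every depth, making the lateral stress isotropic; the global fluidity
# assumption only constrains the integral of lambda_S over the monolayer
# thickness to vanish, so the lateral stress of a bent monolayer is
# anisotropic wherever the azimuthal and axial stretches differ.

#' Full set of transversely isotropic moduli profiles
#'
#' Tabulations over the reference depth coordinate z of the five elastic
#' moduli and two pre-stress terms of the quadratic energy density of a
#' transversely isotropic medium. The tilt modulus \code{lambda_T} is stored
#' and enters the energy evaluation, but tilt mechanics is otherwise outside
#' the implemented analysis.
#'
#' @param z strictly increasing depth grid (nm).
#' @param lambda1,lambda2,lambda12,lambda_S,lambda_T moduli (bar); scalars,
#'   vectors over \code{z}, or functions of z.
#' @param sigma_l,sigma_z lateral/normal pre-stress (bar).
#' @return Object of class \code{full_moduli}.
#' @export
full_moduli <- function(z, lambda1, lambda2, lambda12, lambda_S, lambda_T,
                        sigma_l, sigma_z) {
  if (is.unsorted(z, strictly = TRUE)) stop("z grid must be strictly increasing")
  tab <- function(v) {
    if (is.function(v)) v <- v(z)
    v <- rep_len(as.numeric(v), length(z))
    if (any(!is.finite(v))) stop("moduli tabulations must be finite")
    v
  }
  structure(list(z = as.numeric(z), lambda1 = tab(lambda1),
                 lambda2 = tab(lambda2), lambda12 = tab(lambda12),
                 lambda_S = tab(lambda_S), lambda_T = tab(lambda_T),
                 sigma_l = tab(sigma_l), sigma_z = tab(sigma_z)),
            class = "full_moduli")
}

#' Reduced elastic profile of an incompressible monolayer
#'
#' Houses the three depth-resolved material functions the incompressible
#' energy density needs: the pre-stress \code{sigma0 = sigma_l - sigma_z},
#' the local stretching modulus \code{E = lambda1 + lambda2 - 2 lambda12},
#' and the local lateral shear modulus \code{lambda_S}.
#'
#' @param z strictly increasing depth grid (nm) covering \code{[0, thickness]}.
#' @param sigma0,E,lambda_S bar; scalars, vectors over \code{z}, or functions.
#' @param thickness reference monolayer thickness (nm); defaults to
#'   \code{max(z)}.
#' @return Object of class \code{elastic_profile}.
#' @export
elastic_profile <- function(z, sigma0, E, lambda_S, thickness = max(z)) {
  z <- as.numeric(z)
  if (is.unsorted(z, strictly = TRUE)) stop("z grid must be strictly increasing")
  tab <- function(v) {
    if (is.function(v)) v <- v(z)
    v <- rep_len(as.numeric(v), length(z))
    if (any(!is.finite(v))) stop("profile tabulations must be finite")
    v
  }
  structure(list(z = z, sigma0 = tab(sigma0), E = tab(E),
                 lambda_S = tab(lambda_S), thickness = thickness),
            class = "elastic_profile")
}

#' Reduce full moduli to an incompressible elastic profile
#'
#' @param m a \code{full_moduli}.
#' @return An \code{elastic_profile} with \code{sigma0 = sigma_l - sigma_z}
#'   and \code{E = lambda1 + lambda2 - 2 lambda12}.
#' @export
as_elastic_profile <- function(m) {
  stopifnot(inherits(m, "full_moduli"))
  elastic_profile(m$z, m$sigma_l - m$sigma_z,
                  m$lambda1 + m$lambda2 - 2 * m$lambda12, m$lambda_S)
}

profile_value <- function(p, what, z) {
  stats::approx(p$z, p[[what]], xout = z, rule = 2)$y
}

#' Green-Lagrange strain state
#'
#' @param uxx,uyy,uzz,uxy,uxz,uyz strain components (dimensionless).
#' @param F optional 3x3 deformation gradient; if given, \code{(t(F) F - I)/2}
#'   must match the stated components to 1e-12.
#' @return Object of class \code{strain_state}.
#' @export
strain_state <- function(uxx = 0, uyy = 0, uzz = 0, uxy = 0,
                         uxz = 0, uyz = 0, F = NULL) {
  u <- list(uxx = uxx, uyy = uyy, uzz = uzz, uxy = uxy, uxz = uxz, uyz = uyz)
  if (!is.null(F)) {
    U <- (t(F) %*% F - diag(3)) / 2
    comp <- c(U[1, 1], U[2, 2], U[3, 3], U[1, 2], U[1, 3], U[2, 3])
    if (max(abs(comp - unlist(u))) > 1e-12)
      stop("deformation gradient inconsistent with stated strain components")
    u$F <- F
  }
  structure(u, class = "strain_state")
}

#' Quadratic energy density of the transversely isotropic monolayer
#'
#' Full expression, in bar:
#' \deqn{w = \sigma_l(u_{xx}+u_{yy}) + \sigma_z u_{zz}
#'   + \tfrac{1}{2}\lambda_1 (u_{xx}+u_{yy})^2 + \tfrac{1}{2}\lambda_2 u_{zz}^2
#'   + \lambda_{12}(u_{xx}+u_{yy}) u_{zz}
#'   + \tfrac{1}{2}\lambda_S [(u_{xx}-u_{yy})^2 + 4 u_{xy}^2]
#'   + 2\lambda_T (u_{xz}^2 + u_{yz}^2)}
#'
#' @param u a \code{strain_state}.
#' @param m a \code{full_moduli}.
#' @param z depth (nm) at which moduli are interpolated.
#' @return Energy density in bar. When tilt strains are non-zero the result
#'   carries attribute \code{"tilt_note"} flagging that tilt mechanics is out
#'   of the analysis scope.
#' @export
energy_density_full <- function(u, m, z) {
  s <- u$uxx + u$uyy
  w <- profile_value(m, "sigma_l", z) * s +
    profile_value(m, "sigma_z", z) * u$uzz +
    0.5 * profile_value(m, "lambda1", z) * s^2 +
    0.5 * profile_value(m, "lambda2", z) * u$uzz^2 +
    profile_value(m, "lambda12", z) * s * u$uzz +
    0.5 * profile_value(m, "lambda_S", z) *
      ((u$uxx - u$uyy)^2 + 4 * u$uxy^2) +
    2 * profile_value(m, "lambda_T", z) * (u$uxz^2 + u$uyz^2)
  if (any(u$uxz != 0) || any(u$uyz != 0))
    attr(w, "tilt_note") <- "tilt out of analysis scope"
  w
}

#' Energy density under linearized incompressibility
#'
#' With \code{uzz = -(uxx + uyy)} eliminated and no tilt:
#' \deqn{w = \sigma_0 (u_{xx}+u_{yy}) + \tfrac{E}{2}(u_{xx}+u_{yy})^2
#'   + \tfrac{\lambda_S}{2}[(u_{xx}-u_{yy})^2 + 4 u_{xy}^2]}
#'
#' @param u a \code{strain_state} with \code{uxz = uyz = 0}.
#' @param p an \code{elastic_profile}.
#' @param z depth (nm).
#' @return Energy density in bar.
#' @export
energy_density_incompressible <- function(u, p, z) {
  if (any(u$uxz != 0) || any(u$uyz != 0))
    stop("incompressible energy density requires uxz = uyz = 0")
  s <- u$uxx + u$uyy
  profile_value(p, "sigma0", z) * s +
    0.5 * profile_value(p, "E", z) * s^2 +
    0.5 * profile_value(p, "lambda_S", z) *
      ((u$uxx - u$uyy)^2 + 4 * u$uxy^2)
}

#' Energy density under the local fluidity assumption
#'
#' With a pointwise-zero shear modulus the only energetic mode is the local
#' relative area change \code{eps}:
#' \deqn{w = \sigma_0 \epsilon + \tfrac{E}{2} \epsilon^2}
#'
#' @param eps local area stretch (dimensionless, > -1).
#' @param p an \code{elastic_profile}.
#' @param z depth (nm).
#' @return Energy density in bar.
#' @export
energy_density_local_fluidity <- function(eps, p, z) {
  if (any(eps <= -1)) stop("area stretch must exceed -1")
  profile_value(p, "sigma0", z) * eps +
    0.5 * profile_value(p, "E", z) * eps^2
}

#' Cauchy stress of a laterally uniform planar deformation
#'
#' Principal-axis strains, exact incompressibility applied through the normal
#' stretch, and the Lagrange multiplier P carrying the normal stress:
#' \deqn{\Sigma_{xx} = [\sigma_0 + E(u_{xx}+u_{yy}) +
#'   \lambda_S(u_{xx}-u_{yy})](1+u_{xx}) + P}
#' \deqn{\Sigma_{yy} = [\sigma_0 + E(u_{xx}+u_{yy}) -
#'   \lambda_S(u_{xx}-u_{yy})](1+u_{yy}) + P, \quad \Sigma_{zz} = P}
#' with all off-diagonals zero.
#'
#' @param u a \code{strain_state} with \code{uxy = uxz = uyz = 0}.
#' @param p an \code{elastic_profile}.
#' @param z depth (nm).
#' @param P Lagrange-multiplier pressure term (bar).
#' @return 3x3 stress tensor (bar, tension-positive).
#' @export
cauchy_stress_planar <- function(u, p, z, P = 0) {
  if (u$uxy != 0 || u$uxz != 0 || u$uyz != 0)
    stop("cauchy_stress_planar requires principal-axis strains")
  if (1 + 2 * u$uxx <= 0 || 1 + 2 * u$uyy <= 0)
    stop("invalid deformation: 1 + 2u must be positive")
  s0 <- profile_value(p, "sigma0", z)
  E <- profile_value(p, "E", z)
  lS <- profile_value(p, "lambda_S", z)
  s <- u$uxx + u$uyy
  d <- u$uxx - u$uyy
  diag(c((s0 + E * s + lS * d) * (1 + u$uxx) + P,
         (s0 + E * s - lS * d) * (1 + u$uyy) + P,
         P))
}

#' Lateral stress difference of a planar deformation
#'
#' \deqn{\Sigma_{xx}-\Sigma_{yy} = [\sigma_0 + E(u_{xx}+u_{yy}) +
#'   \lambda_S(2 + u_{xx}+u_{yy})](u_{xx}-u_{yy})}
#'
#' @param uxx,uyy principal-axis strains.
#' @param p an \code{elastic_profile}.
#' @param z depth (nm).
#' @return Stress difference in bar (the Lagrange multiplier cancels).
#' @export
lateral_stress_difference <- function(uxx, uyy, p, z) {
  s <- uxx + uyy
  (profile_value(p, "sigma0", z) + profile_value(p, "E", z) * s +
     profile_value(p, "lambda_S", z) * (2 + s)) * (uxx - uyy)
}

#' Finite-strain map from a flat monolayer to a cylindrical shell
#'
#' The reference depth \code{z_p} maps to the pivotal radius \code{r_p}
#' (zero azimuthal stretch there); \code{beta} is a uniform axial stretch.
#' Exact volume conservation (det F = 1) fixes the radial placement:
#' \code{r(z)^2 = r_p^2 + 2 (r_p / beta) s (z - z_p)}, where \code{s = +1}
#' when increasing z points away from the cylinder axis
#' (\code{orientation = "outward"}) and \code{s = -1} otherwise.
#'
#' @param r_p pivotal radius (nm, > 0).
#' @param z_p reference depth mapped to \code{r_p} (nm).
#' @param beta uniform axial stretch (> 0, default 1).
#' @param orientation \code{"outward"} or \code{"inward"}: which way
#'   increasing reference z points relative to the axis.
#' @return Object of class \code{cylindrical_bend_map}.
#' @export
cylindrical_bend_map <- function(r_p, z_p, beta = 1,
                                 orientation = c("outward", "inward")) {
  orientation <- match.arg(orientation)
  if (r_p <= 0) stop("r_p must be > 0")
  if (beta <= 0) stop("beta must be > 0")
  structure(list(r_p = r_p, z_p = z_p, beta = beta,
                 orientation = orientation,
                 s = if (orientation == "outward") 1 else -1),
            class = "cylindrical_bend_map")
}

#' Strains of the cylindrical bend map at depth z
#'
#' @param map a \code{cylindrical_bend_map}.
#' @param z reference depth(s) (nm).
#' @return List with vectors \code{uxx} (azimuthal Green-Lagrange strain
#'   \code{((r/r_p)^2 - 1)/2}), \code{uyy} (axial strain
#'   \code{(beta^2 - 1)/2}) and \code{r} (nm). The implied deformation
#'   gradient has det F = 1 exactly.
#' @export
strain_from_bend_map <- function(map, z) {
  r2 <- map$r_p^2 + 2 * (map$r_p / map$beta) * map$s * (z - map$z_p)
  if (any(r2 <= 0)) stop("degenerate bend map: r^2 <= 0 inside the monolayer")
  r <- sqrt(r2)
  list(uxx = ((r / map$r_p)^2 - 1) / 2,
       uyy = rep_len((map$beta^2 - 1) / 2, length(r)),
       r = r)
}

#' Radius-to-depth inverse of the bend map
#'
#' @param map a \code{cylindrical_bend_map}.
#' @param r radius (nm).
#' @return Reference depth z (nm) with \code{r(z) = r}.
#' @export
depth_from_radius <- function(map, r) {
  map$z_p + map$beta * (r^2 - map$r_p^2) / (2 * map$r_p * map$s)
}

#' Cylindrical stress components of a bent monolayer (before closure)
#'
#' Tabulates \code{Sigma_thetatheta - P} and \code{Sigma_zz - P} over the
#' profile's depth grid. In \code{"global"} mode the planar stress formulas
#' apply with the azimuthal strain in the x slot and the axial strain in the
#' y slot; in \code{"local"} mode both lateral components equal
#' \code{sigma0 + E * eps} at the local area stretch
#' \code{eps = (r/r_p) beta - 1} (laterally isotropic by construction).
#'
#' @param profile an \code{elastic_profile}.
#' @param map a \code{cylindrical_bend_map}.
#' @param mode \code{"global"} or \code{"local"} fluidity.
#' @return Data frame with columns \code{z}, \code{r}, \code{stt} and
#'   \code{szz} (bar, Lagrange multiplier excluded).
#' @export
stress_cylindrical <- function(profile, map, mode = c("global", "local")) {
  mode <- match.arg(mode)
  z <- profile$z
  st <- strain_from_bend_map(map, z)
  if (mode == "local") {
    eps <- (st$r / map$r_p) * map$beta - 1
    w <- profile$sigma0 + profile$E * eps
    data.frame(z = z, r = st$r, stt = w, szz = w)
  } else {
    s <- st$uxx + st$uyy
    d <- st$uxx - st$uyy
    data.frame(
      z = z, r = st$r,
      stt = (profile$sigma0 + profile$E * s + profile$lambda_S * d) * (1 + st$uxx),
      szz = (profile$sigma0 + profile$E * s - profile$lambda_S * d) * (1 + st$uyy))
  }
}

#' Solve the radial mechanical-equilibrium condition
#'
#' Integrates \code{d/dr (r Sigma_rr) = Sigma_thetatheta} by trapezoidal
#' quadrature with boundary condition \code{Sigma_rr(r_in) = boundary}:
#' \code{Sigma_rr(r) = [r_in * boundary + integral_{r_in}^{r} stt dr'] / r}.
#'
#' @param r strictly increasing radius grid (nm, \code{r[1] > 0}).
#' @param stt azimuthal stress tabulated on \code{r} (bar).
#' @param boundary \code{Sigma_rr} at \code{r[1]} (bar).
#' @return Vector \code{Sigma_rr(r)} (equal to the Lagrange multiplier
#'   \code{P(r)}).
#' @export
solve_radial_equilibrium <- function(r, stt, boundary = 0) {
  if (is.unsorted(r, strictly = TRUE)) stop("r grid must be strictly increasing")
  if (r[1] <= 0) stop("r_in must be > 0")
  (r[1] * boundary + pracma::cumtrapz(r, stt)[, 1]) / r
}

#' Predicted stress anisotropy of a bent monolayer
#'
#' \code{A(r) = Sigma_thetatheta - Sigma_zz}; the Lagrange multiplier
#' cancels. Local fluidity predicts identically zero; global fluidity gives
#' the lateral stress difference evaluated on the bend strains.
#'
#' @param profile an \code{elastic_profile}.
#' @param map a \code{cylindrical_bend_map}.
#' @param mode \code{"global"} or \code{"local"}.
#' @return Data frame with columns \code{z}, \code{r}, \code{A} (bar).
#' @export
predict_anisotropy <- function(profile, map, mode = c("global", "local")) {
  mode <- match.arg(mode)
  z <- profile$z
  st <- strain_from_bend_map(map, z)
  if (mode == "local") {
    return(data.frame(z = z, r = st$r, A = rep(0, length(z))))
  }
  s <- st$uxx + st$uyy
  A <- (profile$sigma0 + profile$E * s + profile$lambda_S * (2 + s)) *
    (st$uxx - st$uyy)
  data.frame(z = z, r = st$r, A = A)
}

#' Recover the lateral shear modulus from measured anisotropy
#'
#' Inverts the stress-difference relation:
#' \deqn{\lambda_S = \frac{A/(u_{xx}-u_{yy}) - \sigma_0 - E(u_{xx}+u_{yy})}
#'   {2 + u_{xx} + u_{yy}}}
#' Points where \code{|uxx - uyy| <= tol} are strain-degenerate, excluded
#' and returned as \code{NA}.
#'
#' @param A measured anisotropy (bar).
#' @param uxx,uyy strains at the matching radii.
#' @param sigma0,E moduli at the matching depths (bar).
#' @param tol strain-degeneracy tolerance.
#' @return Vector of \code{lambda_S} values (bar) with attribute
#'   \code{"excluded"} giving the indices of degenerate points.
#' @export
recover_lateral_shear_modulus <- function(A, uxx, uyy, sigma0, E,
                                          tol = 1e-8) {
  d <- uxx - uyy
  s <- uxx + uyy
  out <- (A / d - sigma0 - E * s) / (2 + s)
  bad <- which(abs(d) <= tol)
  out[bad] <- NA_real_
  attr(out, "excluded") <- bad
  out
}

#' Global-fluidity integral of the shear-modulus profile
#'
#' Trapezoidal \code{integral of lambda_S(z) dz} over the monolayer
#' thickness. A profile is globally fluid when the integral vanishes within
#' tolerance.
#'
#' @param profile an \code{elastic_profile}.
#' @param tol relative tolerance for the \code{"globally_fluid"} flag.
#' @return Integral in bar nm, with attribute \code{"globally_fluid"}.
#' @export
global_fluidity_integral <- function(profile, tol = 1e-6) {
  val <- pracma::trapz(profile$z, profile$lambda_S)
  scale <- diff(range(profile$z)) * max(abs(profile$lambda_S), 1e-300)
  attr(val, "globally_fluid") <- abs(val) <= tol * scale
  val
}

#' Bilayer anisotropy prediction from two monolayer bend maps
#'
#' Each monolayer gets its own bend map with opposite orientation (the two
#' leaflets of a tube are curved in opposite directions); the bilayer
#' prediction concatenates the two tabulations, inner monolayer first,
#' ordered by radius.
#'
#' @param profile an \code{elastic_profile} (shared by both monolayers).
#' @param inner_map,outer_map \code{cylindrical_bend_map}s for the leaflet
#'   facing the axis and the leaflet facing away.
#' @param mode \code{"global"} or \code{"local"}.
#' @return Data frame with columns \code{z}, \code{r}, \code{A},
#'   \code{monolayer}.
#' @export
bilayer_anisotropy <- function(profile, inner_map, outer_map,
                               mode = c("global", "local")) {
  mode <- match.arg(mode)
  inner <- predict_anisotropy(profile, inner_map, mode)
  outer <- predict_anisotropy(profile, outer_map, mode)
  inner$monolayer <- "inner"
  outer$monolayer <- "outer"
  out <- rbind(inner, outer)
  out[order(out$r), , drop = FALSE]
}
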