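# Pair configurations and rigid-body placement of two scaffolds.
#
# The scaffold centres sit at (-d/2, 0) and (+d/2, 0).  Each scaffold is
# rotated in-plane by phi about its vertical axis (phi = angle between the
# scaffold long axis and the connecting line) and tilted by theta about the
# in-plane axis perpendicular to the connecting line, so that the centre
# normal rotates within the vertical plane containing the connecting line;
# positive theta tilts the two normals away from each other.  In symmetric
# mode scaffold 2 is the mirror image of scaffold 1 across the bisecting
# plane x = 0.

#' Pair configuration: distance and mutual orientation
#'
#' @param d centre-to-centre distance (length units of the shape), `> 0`.
#' @param phi in-plane orientation angle in degrees, in `[0, 90]`
#'   (symmetric mode).
#' @param theta tilt angle of the centre normals in degrees, in `[0, 180]`
#'   (symmetric mode); `theta = 0` is the untilted placement.
#' @param phi1,phi2,theta1,theta2 optional per-scaffold angles for the
#'   asymmetric-orientation control; supplying any of them switches
#'   `symmetric` off and the angles are not range-restricted.
#' @return an object of class `pair_config`.
#' @export
pair_config <- function(d, phi = 0, theta = 0,
                        phi1 = NULL, phi2 = NULL, theta1 = NULL, theta2 = NULL) {
  if (!(d > 0)) stop("d must be positive")
  symmetric <- is.null(phi1) && is.null(phi2) && is.null(theta1) && is.null(theta2)
  if (symmetric) {
    if (phi < 0 || phi > 90) stop("phi must lie in [0, 90] degrees")
    if (theta < 0 || theta > 180) stop("theta must lie in [0, 180] degrees")
    phi1 <- phi2 <- phi
    theta1 <- theta2 <- theta
  } else {
    if (is.null(phi1)) phi1 <- phi
    if (is.null(phi2)) phi2 <- phi
    if (is.null(theta1)) theta1 <- theta
    if (is.null(theta2)) theta2 <- theta
  }
  structure(list(d = d, phi = phi, theta = theta, symmetric = symmetric,
                 phi1 = phi1, phi2 = phi2, theta1 = theta1, theta2 = theta2),
            class = "pair_config")
}

#' @export
print.pair_config <- function(x, ...) {
  if (x$symmetric) {
    cat(sprintf("Symmetric pair: d = %.4g, phi = %.4g deg, theta = %.4g deg\n",
                x$d, x$phi, x$theta))
  } else {
    cat(sprintf("Asymmetric pair: d = %.4g, phi = (%.4g, %.4g), theta = (%.4g, %.4g) deg\n",
                x$d, x$phi1, x$phi2, x$theta1, x$theta2))
  }
  invisible(x)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# footprint support radius along the connecting line after in-plane rotation
support_radius <- function(shape, phi) {
  sqrt((shape$r_a * cos(phi * pi / 180))^2 + (shape$r_b * sin(phi * pi / 180))^2)
}

#' Minimum allowed centre-to-centre distance
#'
#' Sum of the footprint support radii along the connecting line plus two mesh
#' edge lengths.
#'
#' @param shape a [scaffold_shape()].
#' @param config a [pair_config()] (only the angles are used).
#' @param h mesh edge length (0 for the purely geometric bound).
#' @export
min_distance <- function(shape, config, h = 0) {
  support_radius(shape, config$phi1) + support_radius(shape, config$phi2) + 2 * h
}

#' Rigid-body placement of a scaffold pair
#'
#' Builds the two local-to-world transforms.  Scaffold 1 maps local points
#' `p` to `R1 p + c1` with `c1 = (-d/2, 0, 0)`; in symmetric mode scaffold 2
#' is its mirror image across the plane `x = 0` (the same shape, since the
#' quadric is even in both footprint coordinates).
#'
#' @param shape a [scaffold_shape()].
#' @param config a [pair_config()].
#' @param h mesh edge length used in the overlap guard (default 0).
#' @return a list of two transforms, each `list(R, t)`, with the centre
#'   normals `n_c` and the fronting-face rim azimuth (degrees) attached.
#' @export
place_pair <- function(shape, config, h = 0) {
  dmin <- min_distance(shape, config, h)
  if (config$d < dmin) {
    stop(sprintf("scaffold footprints overlap: d = %.4g < minimum allowed d = %.4g",
                 config$d, dmin))
  }
  M <- diag(c(-1, 1, 1))
  R1 <- rot_y(-config$theta1) %*% rot_z(config$phi1)
  R2 <- M %*% (rot_y(-config$theta2) %*% rot_z(config$phi2)) %*% M
  t1 <- c(-config$d / 2, 0, 0)
  t2 <- c(config$d / 2, 0, 0)
  mk <- function(R, t, toward) {
    # fronting azimuth: footprint parameter t where the rim crosses the
    # horizontal direction pointing toward the partner
    dir_loc <- crossprod(R, c(toward, 0, 0))
    az <- atan2(dir_loc[2] / shape$r_b, dir_loc[1] / shape$r_a) * 180 / pi
    list(R = R, t = t, n_c = as.numeric(R %*% c(0, 0, 1)),
         fronting_azimuth = az)
  }
  structure(list(mk(R1, t1, +1), mk(R2, t2, -1)),
            shape = shape, config = config, class = "pair_placement")
}

#' Apply a rigid transform to points
#'
#' @param tr one element of a [place_pair()] result (`list(R, t)`).
#' @param pts an `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(tr, pts) {
  sweep(pts %*% t(tr$R), 2, tr$t, "+")
}

#' Default membrane model parameters
#'
#' @param kappa bending modulus in units of kT (default 20).
#' @param gamma lateral tension in kT per squared length unit (default 0,
#'   tensionless).
#' @param L membrane patch radius; `NULL` selects `30 * max(d, r_a)` at mesh
#'   build time.
#' @param h target mesh edge length near the scaffold rims; `NULL` selects
#'   `h_frac * min(r_a, r_b)` by resolution profile.
#' @param profile resolution profile: `"coarse"` (fast, used by default and
#'   in the test-suite) or `"production"` (finer rim resolution and angular
#'   grids).
#' @param grading geometric growth factor of the mesh edge length away from
#'   the scaffolds.
#' @param patch_extent extent of the scaffold-attached fine mesh region, in
#'   units of the shape scale `sqrt(r_a r_b)`.
#' @param collar_frac in-plane offset of the interior collar ring, as a
#'   fraction of `h`.
#' @param refine_levels number of uniform refinement (subdivision) levels run
#'   after the base-level minimization.
#' @param maxit L-BFGS iteration cap per inner call; `outer_max` caps the
#'   minimize-regularize cycles per level.
#' @param pgtol projected-gradient tolerance passed to L-BFGS-B (kT per
#'   length unit).
#' @param tol_energy energy tolerance (kT): outer cycles stop when the energy
#'   change per cycle falls below it.
#' @param d_ref_factor reference separation (the numerical "infinity") in
#'   units of `r_a`.
#' @param n_phi,n_theta angular grid sizes for the Boltzmann orientation
#'   integral (Gauss-Legendre nodes in phi, adaptive nodes in theta).
#' @param theta_window energy window (kT) above the orientation minimum
#'   within which theta is sampled.
#' @param seed seed for the optional jitter restart (unused unless jitter is
#'   requested).
#' @param outer_fixed pin the outer ring on the asymptotic far-field profile
#'   (the default); `FALSE` leaves it free, which admits soft global fold
#'   modes and is kept only for experimentation.
#' @return a list of class `model_params`.
#' @export
model_params <- function(kappa = 20, gamma = 0, L = NULL, h = NULL,
                         profile = c("coarse", "production"),
                         grading = 1.3, patch_extent = 2.5, collar_frac = 0.6,
                         refine_levels = 0, maxit = 2000, outer_max = 4,
                         pgtol = 1e-6, tol_energy = 0.05,
                         d_ref_factor = 20, n_phi = NULL, n_theta = NULL,
                         theta_window = 4, seed = 1L, outer_fixed = TRUE) {
  profile <- match.arg(profile)
  if (!(kappa > 0)) stop("kappa must be positive")
  if (gamma < 0) stop("gamma must be >= 0")
  h_frac <- if (profile == "coarse") 0.3 else 0.16
  if (is.null(n_phi)) n_phi <- if (profile == "coarse") 5 else 9
  if (is.null(n_theta)) n_theta <- if (profile == "coarse") 5 else 7
  structure(list(kappa = kappa, gamma = gamma, L = L, h = h, h_frac = h_frac,
                 profile = profile, grading = grading,
                 patch_extent = patch_extent, collar_frac = collar_frac,
                 refine_levels = refine_levels, maxit = maxit,
                 outer_max = outer_max, pgtol = pgtol,
                 tol_energy = tol_energy, d_ref_factor = d_ref_factor,
                 n_phi = n_phi, n_theta = n_theta,
                 theta_window = theta_window, seed = as.integer(seed),
                 outer_fixed = isTRUE(outer_fixed)),
            class = "model_params")
}

# resolve h and L for a given shape / distance
resolve_h <- function(params, shape) {
  if (!is.null(params$h)) params$h else params$h_frac * min(shape$r_a, shape$r_b)
}
resolve_L <- function(params, shape, d) {
  if (!is.null(params$L)) params$L else 30 * max(d, shape$r_a)
}

#' Reference separation used as the numerical infinity
#' @param params a [model_params()].
#' @param shape a [scaffold_shape()].
#' @export
d_reference <- function(params, shape) params$d_ref_factor * shape$r_a
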