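# Rigid scaffold geometry: segments of ellipsoids / hyperboloids cut by an
# elliptical cylinder.  The scaffold surface is the upper sheet of
#   (x/rho_a)^2 + sign(rho_b) (y/rho_b)^2 + (z/rho_a)^2 = 1
# restricted to the elliptical footprint (x/r_a)^2 + (y/r_b)^2 <= 1, and is
# reported in apex-referenced coordinates (the central point sits at z = 0).

#' Construct a rigid scaffold shape
#'
#' A scaffold is a rigid surface patch with principal curvatures
#' `c_a = 1/rho_a` and `c_b = 1/rho_b` at its central point and an elliptical
#' footprint with semi-axes `r_a`, `r_b` on the initial membrane plane.
#' Positive `rho_b` gives an ellipsoidal (dome-like) patch, negative `rho_b` a
#' hyperboloidal (saddle-like) patch and `rho_b = Inf` a cylinder-like patch
#' curved only along its long axis.
#'
#' @param rho_a curvature radius along the long (x) axis; must be `> r_a`.
#' @param rho_b signed curvature radius along the short (y) axis; `abs(rho_b)`
#'   must exceed `r_b`.  May be `Inf` for vanishing second curvature.
#' @param r_a,r_b footprint semi-axes (`r_a >= r_b > 0` by convention).
#' @param units unit tag carried through outputs ("a" for scaffold-radius
#'   units, "nm" for nanometres).
#' @return An object of class `scaffold_shape` with derived curvatures
#'   `c_a`, `c_b`, contact angles `phi_a`, `phi_b` (degrees, `phi_b` signed
#'   like `rho_b`), surface area `A` and in-plane scale `scale_a =
#'   sqrt(r_a r_b)`.
#' @examples
#' sc <- scaffold_shape(rho_a = 5, rho_b = 5, r_a = 1, r_b = 1)
#' sc$phi_a  # arcsin(0.2) in degrees
#' @export
scaffold_shape <- function(rho_a, rho_b, r_a, r_b, units = c("a", "nm")) {
  units <- match.arg(units)
  stopifnot(is.numeric(rho_a), is.numeric(rho_b), is.numeric(r_a), is.numeric(r_b))
  if (!(rho_a > 0)) stop("rho_a must be positive")
  if (rho_b == 0) stop("rho_b must be nonzero (use Inf for a flat short axis)")
  if (!(r_a > 0 && r_b > 0)) stop("footprint semi-axes must be positive")
  if (!(r_a < rho_a)) stop("need r_a < rho_a (arcsin argument in (0,1))")
  if (is.finite(rho_b) && !(r_b < abs(rho_b)))
    stop("need r_b < |rho_b| (arcsin argument in (0,1))")
  obj <- structure(list(
    rho_a = rho_a, rho_b = rho_b, r_a = r_a, r_b = r_b,
    c_a = 1 / rho_a, c_b = if (is.finite(rho_b)) 1 / rho_b else 0,
    phi_a = asin(r_a / rho_a) * 180 / pi,
    phi_b = if (is.finite(rho_b)) asin(r_b / rho_b) * 180 / pi else 0,
    scale_a = sqrt(r_a * r_b),
    units = units
  ), class = "scaffold_shape")
  obj$A <- scaffold_area(obj)
  obj
}

#' @export
print.scaffold_shape <- function(x, ...) {
  kind <- if (!is.finite(x$rho_b)) "cylinder-like"
  else if (x$rho_b > 0) "ellipsoidal" else "saddle-like (hyperboloidal)"
  cat(sprintf("Rigid scaffold (%s), lengths in %s\n", kind, x$units))
  cat(sprintf("  footprint semi-axes r_a = %.4g, r_b = %.4g (aspect %.3g)\n",
              x$r_a, x$r_b, x$r_a / x$r_b))
  cat(sprintf("  curvatures c_a = %.4g, c_b = %.4g (c_b/c_a = %.3g)\n",
              x$c_a, x$c_b, x$c_b / x$c_a))
  cat(sprintf("  contact angles phi_a = %.3g deg, phi_b = %.3g deg\n",
              x$phi_a, x$phi_b))
  cat(sprintf("  area A = %.5g, scale a = %.4g\n", x$A, x$scale_a))
  invisible(x)
}

#' Scaffold surface height above the footprint
#'
#' Solves the quadric for the upper-sheet `z` and shifts it so that the
#' scaffold central point (apex) is the reference: the returned height is 0 at
#' the origin and negative where the surface falls below the apex (everywhere,
#' for convex shapes; saddle shapes rise along the weakly curved axis).
#'
#' @param shape a [scaffold_shape()].
#' @param x,y footprint coordinates (vectorized); must lie inside the
#'   elliptical footprint.
#' @return apex-referenced heights, same length as `x`.
#' @export
surface_height <- function(shape, x, y) {
  r2 <- (x / shape$r_a)^2 + (y / shape$r_b)^2
  if (any(r2 > 1 + 1e-9)) stop("point outside the scaffold footprint")
  sgn <- if (is.finite(shape$rho_b)) sign(shape$rho_b) else 0
  yterm <- if (is.finite(shape$rho_b)) sgn * (y / shape$rho_b)^2 else 0
  arg <- 1 - (x / shape$rho_a)^2 - yterm
  if (any(arg < 0)) stop("non-real root: scaffold surface undefined here")
  shape$rho_a * (sqrt(arg) - 1)
}

#' Unit outward (upward) normal of the scaffold surface
#'
#' @inheritParams surface_height
#' @return an `n x 3` matrix of unit normals.
#' @export
scaffold_normal <- function(shape, x, y) {
  z <- surface_height(shape, x, y) + shape$rho_a   # unshifted upper-sheet z
  ny <- if (is.finite(shape$rho_b)) y / (shape$rho_b * abs(shape$rho_b)) else 0 * y
  n <- cbind(x / shape$rho_a^2, ny, z / shape$rho_a^2)
  n / sqrt(rowSums(n^2))
}

#' Contact angle along the scaffold rim
#'
#' Signed angle between the surface normal at a rim point and the normal at
#' the scaffold centre.  The sign is positive where the rim normal tilts
#' outward (convex attachment) and negative where it tilts inward
#' (saddle-like attachment), matching the sign of `rho_b` along the short
#' axis.  For a circular isotropic cap the contact angle is
#' `asin(r_a/rho_a)` at every azimuth.
#'
#' @param shape a [scaffold_shape()].
#' @param azimuth footprint parameter angle(s) in degrees (0 = long axis,
#'   90 = short axis); the rim point is `(r_a cos t, r_b sin t)`.
#' @return signed contact angles in degrees.
#' @export
contact_angle <- function(shape, azimuth) {
  t <- azimuth * pi / 180
  x <- shape$r_a * cos(t)
  y <- shape$r_b * sin(t)
  n <- scaffold_normal(shape, x, y)
  ang <- acos(pmin(1, pmax(-1, n[, 3]))) * 180 / pi
  # sign: outward tilt positive
  s <- sign(n[, 1] * x + n[, 2] * y)
  s[s == 0] <- 1
  as.numeric(ang * s)
}

#' Sample the scaffold rim with analytic surface normals
#'
#' Returns `n` points on the rim curve (quadric intersected with the
#' footprint cylinder), approximately equally spaced in arclength along the
#' footprint ellipse, together with the outward unit normals of the analytic
#' scaffold surface.  The samples close the loop (the first point follows the
#' last).
#'
#' @param shape a [scaffold_shape()].
#' @param n number of samples, at least 12.
#' @return a list with `points` (`n x 3`, apex-referenced), `normals`
#'   (`n x 3`, unit length) and `azimuth` (degrees).
#' @export
rim_samples <- function(shape, n) {
  if (n < 12) stop("need at least 12 rim samples")
  t <- ellipse_arc_params(shape$r_a, shape$r_b, n)
  x <- shape$r_a * cos(t)
  y <- shape$r_b * sin(t)
  list(points = cbind(x, y, surface_height(shape, x, y)),
       normals = scaffold_normal(shape, x, y),
       azimuth = t * 180 / pi)
}

# parameter angles giving ~equal-arclength samples on an ellipse
ellipse_arc_params <- function(ra, rb, n) {
  tt <- seq(0, 2 * pi, length.out = 2048 + 1)
  ds <- sqrt((ra * sin(tt))^2 + (rb * cos(tt))^2)
  s <- cumsum(c(0, 0.5 * (ds[-1] + ds[-length(ds)]) * diff(tt)))
  target <- seq(0, s[length(s)], length.out = n + 1)[-(n + 1)]
  approx(s, tt, xout = target, ties = "ordered")$y
}

ellipse_perimeter <- function(ra, rb) {
  # Ramanujan approximation, ample for mesh sizing
  h <- ((ra - rb) / (ra + rb))^2
  pi * (ra + rb) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Scaffold surface area
#'
#' Area of the curved scaffold patch over its elliptical footprint, by
#' tensor-product Gauss-Legendre quadrature.
#'
#' @param shape a [scaffold_shape()].
#' @param n quadrature order per dimension.
#' @return the area (squared length units of the shape).
#' @export
scaffold_area <- function(shape, n = 48) {
  gr <- pracma::gaussLegendre(n, 0, 1)
  gt <- pracma::gaussLegendre(n, 0, 2 * pi)
  rho <- rep(gr$x, times = n)
  tt <- rep(gt$x, each = n)
  wt <- rep(gr$w, times = n) * rep(gt$w, each = n)
  x <- rho * shape$r_a * cos(tt)
  y <- rho * shape$r_b * sin(tt)
  # metric sqrt(1 + |grad h|^2)
  eps <- 1e-6 * min(shape$r_a, shape$r_b)
  sc <- 1 - 1e-9
  hx <- (surface_height(shape, sc * x + eps, sc * y) -
           surface_height(shape, sc * x - eps, sc * y)) / (2 * eps)
  hy <- (surface_height(shape, sc * x, sc * y + eps) -
           surface_height(shape, sc * x, sc * y - eps)) / (2 * eps)
  sum(wt * sqrt(1 + hx^2 + hy^2) * rho * shape$r_a * shape$r_b)
}

#' Named scaffold presets
#'
#' `"shallow_circular"` is a circular-footprint shallow scaffold with
#' `r_a = r_b = a = 1` and `a/rho_a = 0.2` (lengths in units of the scaffold
#' radius); its second curvature is set through `cb_over_ca`.
#' `"endophilin_nbar"` uses the BAR-domain geometry `r_a = 6.5` nm,
#' `r_b = 1.5` nm, `rho_a = 8.5` nm, with the short-axis curvature `c_b`
#' (1/nm) as a parameter.
#'
#' @param name preset name.
#' @param cb_over_ca ratio `c_b / c_a` for the shallow preset (in `[-1, 1]`).
#' @param c_b short-axis curvature in 1/nm for the BAR preset.
#' @return a [scaffold_shape()].
#' @export
shape_preset <- function(name = c("shallow_circular", "endophilin_nbar"),
                         cb_over_ca = 1, c_b = 0.2) {
  name <- match.arg(name)
  if (name == "shallow_circular") {
    rho_a <- 5
    rho_b <- if (cb_over_ca == 0) Inf else rho_a / cb_over_ca
    scaffold_shape(rho_a = rho_a, rho_b = rho_b, r_a = 1, r_b = 1, units = "a")
  } else {
    rho_b <- if (c_b == 0) Inf else 1 / c_b
    scaffold_shape(rho_a = 8.5, rho_b = rho_b, r_a = 6.5, r_b = 1.5, units = "nm")
  }
}
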