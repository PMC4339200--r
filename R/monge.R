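# Linearized Monge-gauge solver: independent cross-check for shallow
# scaffolds.  In the small-gradient limit the bending energy reduces to
#   E = kappa/2 * int (laplacian w)^2 dx dy
# over the plane outside the scaffold footprints, with w prescribed on the
# footprints (the clamped height values carry the normal-continuity
# condition to O(h)).  Minimizing the discrete quadratic on a uniform grid
# is a sparse least-squares problem solved exactly, with no shared code with
# the triangulated-mesh engine.

#' Linearized (Monge-gauge) pair energy on a finite-difference grid
#'
#' Minimizes the discrete biharmonic energy with the membrane height clamped
#' to the scaffold surface on both footprints (placed at `(+/- d/2, 0)` with
#' in-plane rotation `phi` and optional tilt `theta`) and the box edge
#' clamped on the asymptotic single-scaffold tail profile, the same matched
#' far-field condition the triangulated engine uses.
#'
#' @param shape a [scaffold_shape()].
#' @param d centre-to-centre distance; `Inf` gives the single-scaffold
#'   reference (one footprint, doubled energy).
#' @param params a [model_params()] (only `kappa` is used).
#' @param half_width half-width of the square box (default `12 * r_a` or
#'   large enough to hold the pair).
#' @param n grid points per side (odd preferred).
#' @param phi in-plane rotation of scaffold 1 in degrees (mirror-symmetric
#'   placement).
#' @param theta mirror-symmetric tilt in degrees (normals rotate away from
#'   each other; linearized).
#' @return list with `energy` (kT), the grid spacing `h_grid` and box size.
#' @export
monge_pair_energy <- function(shape, d, params = model_params(),
                              half_width = NULL, n = 201, phi = 0,
                              theta = 0) {
  single <- !is.finite(d)
  if (is.null(half_width)) {
    half_width <- max(12 * shape$r_a,
                      (if (single) 0 else d / 2) + 8 * shape$r_a)
  }
  xs <- seq(-half_width, half_width, length.out = n)
  hg <- xs[2] - xs[1]
  X <- matrix(rep(xs, each = n), n, n)     # column = x index
  Y <- matrix(rep(xs, times = n), n, n)
  centers <- if (single) 0 else c(-d / 2, d / 2)
  w_clamp <- matrix(NA_real_, n, n)
  for (k in seq_along(centers)) {
    sgn <- if (k == 1) 1 else -1           # mirror image across x = 0
    a <- sgn * phi * pi / 180
    xl <- cos(a) * (X - centers[k]) + sin(a) * Y
    yl <- -sin(a) * (X - centers[k]) + cos(a) * Y
    inside <- (xl / shape$r_a)^2 + (yl / shape$r_b)^2 <= 1
    if (any(inside)) {
      # small mirror-symmetric tilt away from the partner (linearized)
      w_clamp[inside] <- surface_height(shape, xl[inside], yl[inside]) +
        sgn * tan(theta * pi / 180) * xl[inside]
    }
  }
  idx <- matrix(seq_len(n * n), n, n)
  edge <- matrix(FALSE, n, n)
  edge[1, ] <- edge[n, ] <- TRUE
  edge[, 1] <- edge[, n] <- TRUE
  # the box edge is clamped on the asymptotic single-scaffold tail profile,
  # the same matched far-field condition the triangulated engine pins its
  # outer ring to
  if (!single) {
    pl <- place_pair(shape, pair_config(d, phi = phi, theta = theta), 0)
  } else {
    pl <- list(list(R = diag(3), t = c(0, 0, 0)))
  }
  w_clamp[edge] <- tail_field(shape, pl, cbind(X[edge], Y[edge]))
  clamped <- !is.na(w_clamp)
  free <- !clamped & !edge
  # Laplacian rows at interior nodes.  The deep scaffold interior carries no
  # membrane energy, but the one-node rim band of clamped nodes (those with a
  # free neighbour) keeps its row: it is the discrete hinge that enforces the
  # normal-continuity condition, exactly as the rim ring does in the
  # triangulated engine.
  deep <- clamped &
    rbind(clamped[-1, ], FALSE) & rbind(FALSE, clamped[-n, ]) &
    cbind(clamped[, -1], FALSE) & cbind(FALSE, clamped[, -n])
  ri <- idx[2:(n - 1), 2:(n - 1)]
  rows <- ri[!deep[2:(n - 1), 2:(n - 1)]]
  m <- length(rows)
  row_id <- integer(n * n)
  row_id[rows] <- seq_len(m)
  nb <- cbind(rows - 1, rows + 1, rows - n, rows + n)
  ti <- rep(seq_len(m), 5)
  tj <- c(rows, nb[, 1], nb[, 2], nb[, 3], nb[, 4])
  tx <- c(rep(-4, m), rep(1, 4 * m))
  Lfull <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(m, n * n))
  wvec <- as.numeric(w_clamp)
  wvec[is.na(wvec)] <- 0
  fidx <- which(as.logical(free))
  Lf <- Lfull[, fidx, drop = FALSE]
  rhs <- as.numeric(Lfull %*% wvec)       # clamped and edge values
  # minimize |Lf wf + rhs|^2
  A <- Matrix::crossprod(Lf)
  b <- -Matrix::crossprod(Lf, rhs)
  wf <- as.numeric(Matrix::solve(A, b))
  res <- as.numeric(Lf %*% wf + rhs)
  energy <- params$kappa / (2 * hg^2) * sum(res^2)
  list(energy = energy, h_grid = hg, half_width = half_width, n = n)
}

#' Monge-gauge elastic interaction reference curve
#'
#' `F_el(d) = E(d) - E(d_ref)` from the linearized solver, for cross-checks
#' against the triangulated-mesh engine in the shallow regime.
#'
#' @inheritParams monge_pair_energy
#' @param d_values distances.
#' @param d_ref reference separation.
#' @return data frame with `d` and `F_el`.
#' @export
monge_interaction <- function(shape, d_values, params = model_params(),
                              d_ref = NULL, n = 201, phi = 0) {
  if (is.null(d_ref)) d_ref <- d_reference(params, shape)
  hw <- d_ref / 2 + 8 * shape$r_a
  e_ref <- monge_pair_energy(shape, d_ref, params, half_width = hw, n = n,
                             phi = phi)$energy
  F_el <- vapply(d_values, function(dd)
    monge_pair_energy(shape, dd, params, half_width = hw, n = n,
                      phi = phi)$energy - e_ref, numeric(1))
  data.frame(d = d_values, F_el = F_el)
}
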