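# Discrete curvature and energies on a membrane mesh.

# Bending energy is carried by the free interior vertices plus the rim ring:
# the rim vertices' curvature spans the fixed scaffold strip and the adjacent
# membrane, so their energy is the discrete hinge that enforces the
# normal-continuity boundary condition (the strip interior stays rigid and
# energy-free).
energy_mask <- function(mesh) {
  fixed <- if (is.null(mesh$fixed)) rep(FALSE, nrow(mesh$V)) else mesh$fixed
  m <- mesh$interior & !fixed
  if (!is.null(mesh$tags)) m <- m | (mesh$tags$kind == "rim" & mesh$interior)
  m
}

#' Per-vertex total curvature
#'
#' Discrete total curvature J (twice the mean curvature) from the
#' area-gradient (cotangent) operator with obtuse-safe mixed Voronoi areas.
#' Boundary vertices have no complete star and are reported as `NA`.
#'
#' @param mesh a `membrane_mesh`, or any list with `V` and `F` (closed
#'   meshes get values at every vertex).
#' @return a `curvature_field`: data frame with columns `J` and `A_mixed`.
#' @export
vertex_total_curvature <- function(mesh) {
  n <- nrow(mesh$V)
  mask <- rep(TRUE, n)
  res <- mesh_energy_cpp(mesh$V, mesh$F - 1L, mask, 1, 0, 0, FALSE)
  J <- res$J
  if (!is.null(mesh$boundary)) J[mesh$boundary] <- NA_real_
  structure(data.frame(J = J, A_mixed = res$A_mixed),
            area = res$area, class = c("curvature_field", "data.frame"))
}

#' Helfrich bending energy of a mesh
#'
#' `F = sum_v 1/2 kappa J_v^2 A_v` over the free interior vertices (the
#' rigid scaffold strip and the mesh boundaries carry no bending energy), in
#' units of kT.
#'
#' @param mesh a `membrane_mesh` (or closed mesh with `V`, `F`).
#' @param params a [model_params()] supplying `kappa` and `gamma`.
#' @return a list with `bending`, `tension`, `total` (kT) and `area`.
#' @export
bending_energy <- function(mesh, params = model_params()) {
  mask <- if (!is.null(mesh$interior)) energy_mask(mesh) else rep(TRUE, nrow(mesh$V))
  ref <- if (!is.null(mesh$area_ref) && is.finite(mesh$area_ref)) mesh$area_ref else 0
  res <- mesh_energy_cpp(mesh$V, mesh$F - 1L, mask, params$kappa, params$gamma,
                         ref, FALSE)
  list(bending = res$E_bend, tension = res$E_tension,
       total = res$E, area = res$area)
}

#' Lateral-tension energy of a mesh
#'
#' `gamma * (current area - reference area)`, where the reference is the
#' flat projected area of the patch recorded at build time.
#'
#' @inheritParams bending_energy
#' @export
tension_energy <- function(mesh, params = model_params()) {
  if (params$gamma == 0) return(0)
  params$gamma * (mesh_area(mesh) - mesh$area_ref)
}

# energy and gradient closure over the movable vertices
energy_closures <- function(mesh, params) {
  movable <- which(!mesh$fixed)
  mask <- energy_mask(mesh)
  V <- mesh$V
  ref <- if (is.finite(mesh$area_ref)) mesh$area_ref else 0
  nmov <- length(movable)
  env <- new.env(parent = emptyenv())
  env$last_grad <- numeric(3 * nmov)
  fn <- function(x) {
    V[movable, ] <- matrix(x, ncol = 3)
    out <- tryCatch(mesh_energy_cpp(V, mesh$F - 1L, mask, params$kappa,
                                    params$gamma, ref, FALSE)$E,
                    error = function(e) 1e10)
    out
  }
  gr <- function(x) {
    V[movable, ] <- matrix(x, ncol = 3)
    out <- tryCatch(mesh_energy_cpp(V, mesh$F - 1L, mask, params$kappa,
                                    params$gamma, ref, TRUE),
                    error = function(e) NULL)
    if (is.null(out)) return(env$last_grad * 0)
    g <- as.numeric(out$grad[movable, ])
    env$last_grad <- g
    g
  }
  # diagonal preconditioner: the bending stiffness per vertex scales like
  # kappa / h_v^2, so scaling coordinates by the local spacing equalizes it
  sp <- mesh$tags$sp[movable]
  sp[!is.finite(sp) | sp <= 0] <- mesh$h
  list(fn = fn, gr = gr, movable = movable, mask = mask,
       parscale = rep(sp, 3))
}

#' Discretization error estimate
#'
#' Reports the maximum dihedral angle between adjacent triangles and, when a
#' minimization has been run at two or more refinement levels, the energy
#' difference between the last two levels as an a posteriori error estimate.
#'
#' @param x a `minimized_shape` or `membrane_mesh`.
#' @return a list with `max_dihedral` (degrees) and `energy_error` (kT;
#'   `NA` with a single level).
#' @export
error_estimate <- function(x) {
  mesh <- if (inherits(x, "minimized_shape")) x$mesh else x
  err <- if (inherits(x, "minimized_shape")) x$error_estimate else NA_real_
  list(max_dihedral = max_dihedral(mesh), energy_error = err)
}

max_dihedral <- function(mesh) {
  V <- mesh$V; F <- mesh$F
  u <- V[F[, 2], ] - V[F[, 1], ]
  v <- V[F[, 3], ] - V[F[, 1], ]
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n <- n / sqrt(rowSums(n^2))
  m <- nrow(F)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  tri <- rep(seq_len(m), 3)
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ord <- order(ekey)
  ekey <- ekey[ord]; tri <- tri[ord]
  same <- ekey[-1] == ekey[-length(ekey)]
  t1 <- tri[c(same, FALSE)]
  t2 <- tri[c(FALSE, same)]
  if (!length(t1)) return(0)
  cosd <- pmin(1, pmax(-1, rowSums(n[t1, , drop = FALSE] * n[t2, , drop = FALSE])))
  max(acos(cosd)) * 180 / pi
}
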