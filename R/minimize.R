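# Membrane shape minimization: quasi-Newton (L-BFGS-B) descent on the free
# vertex positions, interleaved with mesh regularization, optionally followed
# by uniform refinement with an a posteriori energy error estimate.

#' Minimize the membrane energy at fixed scaffold placement
#'
#' Runs the minimize-regularize schedule on the free vertices of the mesh:
#' each cycle is an L-BFGS descent on all free vertex coordinates followed by
#' tangential averaging and edge flips; cycles repeat until the energy change
#' per cycle is negligible.  With `refine > 0` the converged mesh is
#' subdivided (new fixed vertices re-projected onto the analytic scaffold
#' surface) and re-minimized; the energy difference between successive levels
#' is reported as the discretization error estimate.
#'
#' @param mesh a `membrane_mesh` from [build_membrane_mesh()].
#' @param params a [model_params()].
#' @param warm_start optional previous `minimized_shape` (any nearby
#'   configuration); its height field seeds the free vertices.
#' @param refine number of refinement levels (default `params$refine_levels`).
#' @return an object of class `minimized_shape` with the deformed mesh, the
#'   bending energy `F_m` (kT), convergence diagnostics and the error
#'   estimate.
#' @export
minimize_shape <- function(mesh, params = model_params(), warm_start = NULL,
                           refine = NULL) {
  if (is.null(refine)) refine <- params$refine_levels
  if (!is.null(warm_start)) {
    mesh <- warm_apply(mesh, warm_start)
  } else if (all(mesh$V[!mesh$fixed, 3] == 0)) {
    mesh <- init_heights(mesh)
  }
  history <- data.frame(stage = character(), energy = numeric())
  energy_error <- NA_real_
  E_level <- NA_real_
  total_iter <- 0L
  converged <- FALSE

  run_level <- function(mesh, maxit, outer_max) {
    E_prev <- Inf
    for (it in seq_len(outer_max)) {
      nw <- newton_z(mesh, params)
      mesh <- nw$mesh
      total_iter <<- total_iter + nw$n_iter
      history <<- rbind(history, data.frame(stage = "minimize", energy = nw$E))
      # loop exits right after a minimize, so the reported state is a minimum
      if (nw$ok && abs(nw$E - E_prev) < 1e-3 && it > 1) {
        converged <<- TRUE
        break
      }
      E_prev <- nw$E
      mesh <- regularize_mesh(mesh, n_smooth = 1, lambda = 0.4, flips = TRUE)
      E_reg <- bending_energy(mesh, params)$total
      history <<- rbind(history, data.frame(stage = "regularize", energy = E_reg))
    }
    mesh
  }

  mesh <- run_level(mesh, params$maxit, params$outer_max)
  comp <- bending_energy(mesh, params)
  E_level <- comp$total
  for (lev in seq_len(refine)) {
    E_prev_level <- E_level
    mesh <- subdivide_mesh(mesh)
    mesh <- run_level(mesh, params$maxit, max(2L, params$outer_max %/% 2L))
    comp <- bending_energy(mesh, params)
    E_level <- comp$total
    energy_error <- abs(E_level - E_prev_level)
  }

  cls <- energy_closures(mesh, params)
  g <- tryCatch(mesh_energy_cpp(mesh$V, mesh$F - 1L, cls$mask, params$kappa,
                                params$gamma,
                                if (is.finite(mesh$area_ref)) mesh$area_ref else 0,
                                TRUE)$grad[cls$movable, ],
                error = function(e) matrix(NA_real_, 1, 3))
  structure(list(mesh = mesh, F_m = comp$bending, E_tension = comp$tension,
                 E_total = comp$total, area = comp$area,
                 grad_norm = max(abs(g)), history = history,
                 converged = converged, n_iter = total_iter,
                 level = mesh$level, error_estimate = energy_error),
            class = "minimized_shape")
}

# Superposed catenoid-like logarithmic tails of the single-scaffold far
# field, z_k(r) = zbar_k - r0 tan(phibar_k) log(r/r0), with the partner
# cross-term removed so each rim matches its fixed ring.  Used both as the
# cold-start initial guess and as the height profile the outer ring is
# pinned to (asymptotically matched far-field condition).
tail_field <- function(shape, placements, xy) {
  if (is.null(shape) || !length(placements)) return(numeric(nrow(xy)))
  r0 <- shape$scale_a
  phibar <- mean(contact_angle(shape, seq(0, 359, by = 3))) * pi / 180
  m <- tan(phibar)
  # catenoid matched to the mean rim slope: r(z) = c cosh(z/c) with
  # c = m r0 / sqrt(1 + m^2); its tail is the minimal-energy far field
  cc <- abs(m) * r0 / sqrt(1 + m^2)
  fk <- function(r, zbar) {
    if (cc < 1e-8 * r0) return(rep(zbar, length(r)))
    zbar - sign(m) * cc * (acosh(pmax(r, r0) / cc) - acosh(r0 / cc))
  }
  z <- numeric(nrow(xy))
  zbars <- numeric(length(placements))
  rim <- rim_samples(shape, 36)
  for (k in seq_along(placements)) {
    tr <- placements[[k]]
    zbars[k] <- mean(apply_transform(tr, rim$points)[, 3])
    rk <- sqrt((xy[, 1] - tr$t[1])^2 + (xy[, 2] - tr$t[2])^2)
    z <- z + fk(rk, zbars[k])
  }
  if (length(placements) == 2) {
    d <- sqrt(sum((placements[[1]]$t - placements[[2]]$t)^2))
    z <- z - mean(fk(d, zbars))
  }
  z
}

init_heights <- function(mesh) {
  if (is.null(mesh$shape) || !length(mesh$placements)) return(mesh)
  idx <- which(!mesh$fixed)
  mesh$V[idx, 3] <- tail_field(mesh$shape, mesh$placements,
                               mesh$V[idx, 1:2, drop = FALSE])
  mesh
}

# Seed the free vertices of `mesh` with the height field of a previously
# minimized shape (inverse-distance interpolation in the membrane plane).
# When the source was solved at a different separation its dimples sit in
# the wrong place, so near the target rims the interpolant is blended into
# the analytic tail field.
warm_apply <- function(mesh, warm) {
  wm <- if (inherits(warm, "minimized_shape")) warm$mesh else warm
  src <- wm$V
  idx <- which(!mesh$fixed)
  if (!length(idx)) return(mesh)
  z_idw <- numeric(length(idx))
  for (start in seq(1, length(idx), by = 1000)) {
    jj <- start:min(start + 999, length(idx))
    ii <- idx[jj]
    dx <- outer(mesh$V[ii, 1], src[, 1], "-")
    dy <- outer(mesh$V[ii, 2], src[, 2], "-")
    d2 <- dx^2 + dy^2 + (1e-4 * mesh$h)^2
    w <- 1 / d2
    # 4 nearest neighbours only
    for (r in seq_along(jj)) {
      ord <- order(d2[r, ])[1:4]
      ww <- w[r, ord]
      z_idw[jj[r]] <- sum(ww * src[ord, 3]) / sum(ww)
    }
  }
  same_d <- !is.null(wm$config) && !is.null(mesh$config) &&
    abs(wm$config$d - mesh$config$d) < 0.01 * mesh$shape$scale_a
  if (same_d) {
    mesh$V[idx, 3] <- z_idw
  } else {
    z_tail <- tail_field(mesh$shape, mesh$placements,
                         mesh$V[idx, 1:2, drop = FALSE])
    rho <- rep(Inf, length(idx))
    for (k in seq_along(mesh$placements)) {
      tr <- mesh$placements[[k]]
      rho <- pmin(rho, sqrt((mesh$V[idx, 1] - tr$t[1])^2 +
                            (mesh$V[idx, 2] - tr$t[2])^2))
    }
    blend <- pmin(1, pmax(0, (rho / mesh$shape$scale_a - 1.5) / 2))
    mesh$V[idx, 3] <- blend * z_idw + (1 - blend) * z_tail
  }
  mesh
}

#' @export
print.minimized_shape <- function(x, ...) {
  cat(sprintf("Minimized membrane shape: F_m = %.6g kT", x$F_m))
  if (x$E_tension != 0) cat(sprintf(" (+ %.6g kT tension)", x$E_tension))
  cat("\n")
  cat(sprintf("  level %d, %d L-BFGS iterations, max|grad| = %.3g, converged: %s\n",
              x$level, x$n_iter, x$grad_norm, x$converged))
  if (is.finite(x$error_estimate))
    cat(sprintf("  energy error estimate (level difference): %.3g kT\n",
                x$error_estimate))
  invisible(x)
}

#' @export
summary.minimized_shape <- function(object, ...) {
  est <- error_estimate(object)
  cat(sprintf("F_m = %.6g kT, area = %.6g, max dihedral = %.3g deg\n",
              object$F_m, object$area, est$max_dihedral))
  print(object)
  invisible(object)
}

#' @export
plot.minimized_shape <- function(x, zoom = NULL, ...) {
  mesh <- x$mesh
  if (is.null(zoom))
    zoom <- 2.5 * max(mesh$shape$r_a,
                      if (!is.null(mesh$config)) mesh$config$d / 2 else mesh$shape$r_a)
  sel <- abs(mesh$V[, 1]) < zoom & abs(mesh$V[, 2]) < zoom
  z <- mesh$V[sel, 3]
  cols <- grDevices::hcl.colors(64, "Blue-Red 3")
  iz <- findInterval(z, seq(min(z), max(z), length.out = 65), all.inside = TRUE)
  plot(mesh$V[sel, 1], mesh$V[sel, 2], col = cols[iz], pch = 16, cex = 0.5,
       asp = 1, xlab = "x", ylab = "y",
       main = sprintf("membrane height field (F_m = %.3g kT)", x$F_m), ...)
  invisible(x)
}

#' Minimize a sweep of pair configurations
#'
#' Runs [minimize_shape()] for each configuration, warm-starting each
#' minimization from the previous one (order the configurations so that
#' neighbours are geometrically close).  Per-configuration failures are
#' recorded and the sweep continues.
#'
#' @param shape a [scaffold_shape()].
#' @param configs list of [pair_config()]s.
#' @param params a [model_params()].
#' @param warm_start warm-start along the sweep?
#' @param keep_shapes retain the minimized shapes (memory-heavy)?
#' @return a data frame with columns `d, phi, theta, F_m, E_tension,
#'   converged, error`; minimized shapes in `attr(, "shapes")` if requested.
#' @export
sweep_membrane_energy <- function(shape, configs, params = model_params(),
                                  warm_start = TRUE, keep_shapes = FALSE) {
  res <- data.frame(d = numeric(), phi = numeric(), theta = numeric(),
                    F_m = numeric(), E_tension = numeric(),
                    converged = logical(), error = character())
  shapes <- list()
  prev <- NULL
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    ms <- tryCatch({
      mesh <- build_membrane_mesh(shape, cfg, params)
      minimize_shape(mesh, params, warm_start = if (warm_start) prev else NULL)
    }, error = function(e) e)
    if (inherits(ms, "error")) {
      res[i, ] <- list(cfg$d, cfg$phi, cfg$theta, NA_real_, NA_real_, FALSE,
                       conditionMessage(ms))
    } else {
      res[i, ] <- list(cfg$d, cfg$phi, cfg$theta, ms$F_m, ms$E_tension,
                       ms$converged, "")
      prev <- ms
      if (keep_shapes) shapes[[length(shapes) + 1L]] <- ms
    }
  }
  if (keep_shapes) attr(res, "shapes") <- shapes
  res
}
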