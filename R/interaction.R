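# Orientation-optimized elastic interaction, free energy of interaction from
# Boltzmann integration over the mutual-orientation angles, and far-field
# power-law fits.

# Memoized evaluator of F_m(phi, theta) at fixed d.  Each evaluation may be
# warm-started, but only from an already-solved state at a nearby
# orientation (or a nearby distance, via the `warm` argument): warm starts
# from distant orientations leave hysteresis in the converged energies.
fm_evaluator <- function(shape, d, params, warm = NULL) {
  env <- new.env(parent = emptyenv())
  env$cache <- list()
  env$pool <- list()
  env$warm <- NULL          # best shape so far (exposed for cross-d chaining)
  env$best_F <- Inf
  env$n_solve <- 0L
  theta_tol <- 0.9 * max(max(abs(shape$phi_a), abs(shape$phi_b)) / 11.5, 0.3)
  phi_tol <- 30
  if (!is.null(warm)) {
    wcfg <- (if (inherits(warm, "minimized_shape")) warm$mesh else warm)$config
    if (!is.null(wcfg)) {
      env$pool[[1]] <- list(phi = wcfg$phi, theta = wcfg$theta, ms = warm)
    }
  }
  eval_fm <- function(phi, theta) {
    phi <- max(0, min(90, phi))
    theta <- max(0, min(180, theta))
    key <- sprintf("%.5f_%.5f", phi, theta)
    hit <- env$cache[[key]]
    if (!is.null(hit)) return(hit)
    warm_use <- NULL
    if (length(env$pool)) {
      d2 <- vapply(env$pool, function(p)
        ((p$theta - theta) / theta_tol)^2 + ((p$phi - phi) / phi_tol)^2,
        numeric(1))
      if (min(d2) <= 1) warm_use <- env$pool[[which.min(d2)]]$ms
    }
    ms <- tryCatch({
      mesh <- build_membrane_mesh(shape, pair_config(d, phi = phi, theta = theta),
                                  params)
      minimize_shape(mesh, params, warm_start = warm_use)
    }, error = function(e) e)
    if (inherits(ms, "error")) {
      val <- NA_real_
    } else {
      val <- ms$F_m + ms$E_tension
      env$pool[[length(env$pool) + 1L]] <- list(phi = phi, theta = theta, ms = ms)
      if (length(env$pool) > 8) env$pool <- env$pool[-2]  # keep the seed
      if (val < env$best_F) {
        env$best_F <- val
        env$warm <- ms
      }
    }
    env$cache[[key]] <- val
    env$n_solve <- env$n_solve + 1L
    val
  }
  list(fm = eval_fm, env = env)
}

# one round of parabolic refinement of a 1-d minimum through three points
refine_parabolic <- function(f, xs, fs, lo, hi) {
  i <- which.min(fs)
  if (i == 1 || i == length(xs)) return(xs[i])
  x1 <- xs[i - 1]; x2 <- xs[i]; x3 <- xs[i + 1]
  f1 <- fs[i - 1]; f2 <- fs[i]; f3 <- fs[i + 1]
  den <- (x2 - x1) * (f2 - f3) - (x2 - x3) * (f2 - f1)
  if (abs(den) < 1e-300) return(x2)
  xv <- x2 - 0.5 * ((x2 - x1)^2 * (f2 - f3) - (x2 - x3)^2 * (f2 - f1)) / den
  max(lo, min(hi, xv))
}

default_theta_grid <- function(shape) {
  s <- max(abs(shape$phi_a), abs(shape$phi_b)) / 11.5
  c(0, 1, 2, 4, 8) * max(s, 0.25)
}

is_axisymmetric <- function(shape) {
  shape$r_a == shape$r_b && abs(shape$c_a - shape$c_b) < 1e-12
}

#' Energy-minimizing mutual orientation at fixed distance
#'
#' Minimizes the membrane energy `F_m(phi, theta, d)` over the symmetric
#' orientation angles by a coarse grid search followed by parabolic
#' refinement along each angle.  Ties are broken toward smaller `phi`, then
#' smaller `theta`.  For axisymmetric scaffolds the energy is independent of
#' `phi` (reported as 0).
#'
#' @param shape a [scaffold_shape()].
#' @param d centre-to-centre distance.
#' @param params a [model_params()].
#' @param phi_grid,theta_grid coarse grids in degrees (sensible defaults).
#' @param evaluator optionally a [fm_evaluator()]-style cache to reuse.
#' @param warm optional minimized shape from a nearby configuration used to
#'   seed the evaluations.
#' @return a list with `phi_star`, `theta_star`, `F_min` (kT),
#'   `fronting_azimuth` (degrees), the evaluation table `evals` and the
#'   evaluator for reuse.
#' @export
optimal_orientation <- function(shape, d, params = model_params(),
                                phi_grid = NULL, theta_grid = NULL,
                                evaluator = NULL, warm = NULL) {
  if (is.null(phi_grid)) {
    phi_grid <- if (is_axisymmetric(shape)) 0 else c(0, 22.5, 45, 67.5, 90)
  }
  if (is.null(theta_grid)) theta_grid <- default_theta_grid(shape)
  ev <- if (is.null(evaluator)) fm_evaluator(shape, d, params, warm = warm) else evaluator
  best <- list(phi = phi_grid[1], theta = theta_grid[1], F = Inf)
  for (ph in phi_grid) {
    for (th in theta_grid) {
      val <- ev$fm(ph, th)
      if (is.finite(val) && val < best$F - 1e-9) {
        best <- list(phi = ph, theta = th, F = val)
      }
    }
  }
  if (!is.finite(best$F)) stop("all orientation evaluations failed at d = ", d)
  # coordinate-wise parabolic refinement (theta first: the stiffer angle)
  for (round in 1:2) {
    step <- diff(range(theta_grid)) / (8 * round)
    th_loc <- if (best$theta <= step / 2) {
      c(0, step / 2, step)        # resolve minima adjacent to the boundary
    } else {
      c(best$theta - step, best$theta, best$theta + step)
    }
    th_loc <- sort(unique(pmin(180, pmax(0, th_loc))))
    fs <- vapply(th_loc, function(t) ev$fm(best$phi, t), numeric(1))
    i_best <- which.min(fs)
    if (is.finite(fs[i_best]) && fs[i_best] < best$F - 1e-9)
      best <- list(phi = best$phi, theta = th_loc[i_best], F = fs[i_best])
    th_new <- refine_parabolic(NULL, th_loc, fs, 0, 180)
    f_new <- ev$fm(best$phi, th_new)
    if (is.finite(f_new) && f_new < best$F - 1e-9) best <- list(phi = best$phi, theta = th_new, F = f_new)
    if (length(phi_grid) > 1) {
      dphi <- max(diff(phi_grid)) / (2 * round)
      ph_loc <- sort(unique(pmax(0, pmin(90, c(best$phi - dphi, best$phi, best$phi + dphi)))))
      fs <- vapply(ph_loc, function(pp) ev$fm(pp, best$theta), numeric(1))
      ph_new <- refine_parabolic(NULL, ph_loc, fs, 0, 90)
      f_new <- ev$fm(ph_new, best$theta)
      if (is.finite(f_new) && f_new < best$F - 1e-9) best <- list(phi = ph_new, theta = best$theta, F = f_new)
    }
  }
  pl <- place_pair(shape, pair_config(d, phi = best$phi, theta = best$theta),
                   resolve_h(params, shape))
  keys <- names(ev$env$cache)
  evals <- do.call(rbind, lapply(keys, function(k) {
    ang <- as.numeric(strsplit(k, "_")[[1]])
    data.frame(phi = ang[1], theta = ang[2], F_m = ev$env$cache[[k]])
  }))
  list(phi_star = best$phi, theta_star = best$theta, F_min = best$F,
       fronting_azimuth = pl[[1]]$fronting_azimuth, evals = evals,
       evaluator = ev)
}

#' Orientation-optimized elastic interaction curve
#'
#' Computes `F_el(d) = F_min(d) - F_min(d_ref)`, where `F_min` is the
#' membrane energy minimized over the mutual orientation angles at each
#' distance and `d_ref` is the reference separation standing in for infinite
#' separation.
#'
#' @param shape a [scaffold_shape()].
#' @param d_values distances; the reference distance is appended if absent.
#' @param params a [model_params()].
#' @param d_ref reference separation (default [d_reference()]).
#' @param phi_grid,theta_grid optional coarse orientation grids passed to
#'   [optimal_orientation()].
#' @param refine refinement levels applied to the energy at each per-distance
#'   optimal orientation; the level difference is reported as `error` per
#'   point.
#' @return an `interaction_curve`: data frame with `d`, `F_el`, `phi_star`,
#'   `theta_star`, `F_min`, `error`, plus attributes `d_ref`, `F_min_ref`,
#'   `shape`.
#' @export
elastic_interaction <- function(shape, d_values, params = model_params(),
                                d_ref = NULL, phi_grid = NULL,
                                theta_grid = NULL, refine = 0) {
  if (is.null(d_ref)) d_ref <- d_reference(params, shape)
  ds <- sort(unique(c(d_values, d_ref)), decreasing = TRUE)
  rows <- vector("list", length(ds))
  opts <- vector("list", length(ds))
  warm <- NULL
  for (i in seq_along(ds)) {
    opt <- optimal_orientation(shape, ds[i], params, phi_grid = phi_grid,
                               theta_grid = theta_grid, warm = warm)
    warm <- opt$evaluator$env$warm
    err <- NA_real_
    if (refine > 0) {
      ms <- tryCatch(minimize_shape(
        build_membrane_mesh(shape, pair_config(ds[i], phi = opt$phi_star,
                                               theta = opt$theta_star), params),
        params, warm_start = warm, refine = refine), error = function(e) NULL)
      if (!is.null(ms)) {
        err <- abs(ms$F_m + ms$E_tension - opt$F_min)
        opt$F_min <- ms$F_m + ms$E_tension
      }
    }
    opts[[i]] <- opt
    rows[[i]] <- data.frame(d = ds[i], F_min = opt$F_min,
                            phi_star = opt$phi_star,
                            theta_star = opt$theta_star,
                            fronting_azimuth = opt$fronting_azimuth,
                            error = err)
  }
  tab <- do.call(rbind, rows)
  F_ref <- tab$F_min[tab$d == d_ref][1]
  # the reference is solved first (cold); re-minimize it warm-started from
  # the nearest distance so that its convergence depth matches the sweep
  if (length(ds) > 1 && refine == 0) {
    iref <- which(tab$d == d_ref)[1]
    oref <- opts[[iref]]
    ms <- tryCatch(minimize_shape(
      build_membrane_mesh(shape, pair_config(d_ref, phi = oref$phi_star,
                                             theta = oref$theta_star), params),
      params, warm_start = warm), error = function(e) NULL)
    if (!is.null(ms) && is.finite(ms$F_m + ms$E_tension) &&
        ms$F_m + ms$E_tension < F_ref) {
      F_ref <- ms$F_m + ms$E_tension
      tab$F_min[iref] <- F_ref
    }
  }
  tab$F_el <- tab$F_min - F_ref
  tab <- tab[order(tab$d), c("d", "F_el", "phi_star", "theta_star",
                             "F_min", "fronting_azimuth", "error")]
  rownames(tab) <- NULL
  structure(tab, d_ref = d_ref, F_min_ref = F_ref, shape = shape,
            params = params, orientations = opts,
            class = c("interaction_curve", "data.frame"))
}

#' @export
print.interaction_curve <- function(x, ...) {
  cat(sprintf("Elastic interaction curve (reference d_ref = %.4g):\n",
              attr(x, "d_ref")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
plot.interaction_curve <- function(x, ...) {
  plot(x$d, x$F_el, type = "b", pch = 16, xlab = "d", ylab = "F_el (kT)", ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Location and depth of the interaction-energy minimum
#'
#' Quadratic interpolation through the three lowest points of the curve.
#'
#' @param curve an `interaction_curve` (or data frame with `d` and a value
#'   column).
#' @param value column to minimize (default `"F_el"`).
#' @return list with `d_star`, `depth` (value at the minimum, kT) and
#'   `interior` (TRUE if the minimum is bracketed).
#' @export
curve_minimum <- function(curve, value = "F_el") {
  d <- curve$d
  f <- curve[[value]]
  i <- which.min(f)
  if (i == 1 || i == length(d)) {
    return(list(d_star = d[i], depth = f[i], interior = FALSE))
  }
  x <- d[(i - 1):(i + 1)]
  y <- f[(i - 1):(i + 1)]
  co <- coef(lm(y ~ x + I(x^2)))
  if (!is.finite(co[3]) || co[3] <= 0) {
    return(list(d_star = d[i], depth = f[i], interior = TRUE))
  }
  ds <- -co[2] / (2 * co[3])
  list(d_star = as.numeric(ds),
       depth = as.numeric(co[1] + co[2] * ds + co[3] * ds^2),
       interior = TRUE)
}

# inner Boltzmann integral over theta at one phi node:
# returns log of integral of exp(-(F_m - F_shift)) dtheta (radians)
theta_log_integral <- function(ev, phi, theta_start, params, F_shift, step0) {
  w <- params$theta_window
  # geometrically forbidden (overlapping) configurations carry zero
  # Boltzmann weight: treat failed evaluations as infinite energy
  fmi <- function(phi, theta) {
    v <- ev$fm(phi, theta)
    if (!is.finite(v)) Inf else v
  }
  # local minimum along theta starting from theta_start
  th <- theta_start
  f0 <- fmi(phi, th)
  repeat {
    cand <- c(max(0, th - step0), min(180, th + step0))
    fc <- vapply(cand, function(t) fmi(phi, t), numeric(1))
    if (all(f0 <= fc + 1e-9)) break
    th <- cand[which.min(fc)]
    f0 <- min(fc, na.rm = TRUE)
  }
  xs <- c(max(0, th - step0), th, min(180, th + step0))
  fs <- vapply(xs, function(t) fmi(phi, t), numeric(1))
  th <- refine_parabolic(NULL, xs, fs, 0, 180)
  f_min <- fmi(phi, th)
  if (!is.finite(f_min)) return(-Inf)
  # bracket the window edges where F_m = f_min + w
  edge <- function(dir) {
    lim <- if (dir > 0) 180 else 0
    x1 <- th
    x2 <- th
    for (i in 1:12) {
      x2 <- x2 + dir * step0 * 2^(i - 1)
      if ((dir > 0 && x2 >= lim) || (dir < 0 && x2 <= lim)) { x2 <- lim; break }
      if (fmi(phi, x2) >= f_min + w) break
      x1 <- x2
    }
    if (abs(x2 - lim) < 1e-12 && fmi(phi, x2) < f_min + w) return(list(x = lim, open = TRUE))
    for (i in 1:3) {
      xm <- (x1 + x2) / 2
      if (fmi(phi, xm) >= f_min + w) x2 <- xm else x1 <- xm
    }
    list(x = x2, open = FALSE)
  }
  lo <- edge(-1)
  hi <- edge(+1)
  # sample nodes inside the window, spline in between
  n_nodes <- max(4, params$n_theta)
  nodes <- sort(unique(c(th, seq(lo$x, hi$x, length.out = n_nodes))))
  fv <- vapply(nodes, function(t) fmi(phi, t), numeric(1))
  okn <- is.finite(fv)
  nodes <- nodes[okn]; fv <- fv[okn]
  if (length(nodes) < 3) return(-Inf)
  sf <- splinefun(nodes, fv, method = "natural")
  # quadratic tails matched at the window edges, growing away from the window
  cl <- (max(sf(lo$x), f_min + 1e-6) - f_min) / max((lo$x - th)^2, 1e-4)
  ch <- (max(sf(hi$x), f_min + 1e-6) - f_min) / max((hi$x - th)^2, 1e-4)
  fmod <- function(t) {
    out <- numeric(length(t))
    inw <- t >= lo$x & t <= hi$x
    out[inw] <- sf(t[inw])
    out[t < lo$x] <- f_min + cl * (t[t < lo$x] - th)^2
    out[t > hi$x] <- f_min + ch * (t[t > hi$x] - th)^2
    out
  }
  tt <- seq(0, 180, length.out = 721)
  ft <- pmax(fmod(tt), f_min)
  log_sum_exp_trapz(-(ft - F_shift), tt * pi / 180)
}

# log of the trapezoid integral of exp(g) over x
log_sum_exp_trapz <- function(g, x) {
  m <- max(g)
  m + log(sum(diff(x) * (exp(g[-1] - m) + exp(g[-length(g)] - m)) / 2))
}

#' Free energy and orientational-entropy energy of interaction
#'
#' The free energy integrates the Boltzmann weight of the membrane energy
#' over the symmetric orientation angles,
#' `F(d) = -kT log \int exp(-F_m(phi, theta, d)/kT) dtheta dphi`, with
#' Gauss-Legendre nodes in `phi` over (0, 90) degrees and adaptive `theta`
#' sampling inside the energy window `F_m <= F_min + theta_window` (quadratic
#' growth matched at the window edges outside it); angles enter in radians.
#' Both `F(d)` and `F_ent(d) = F(d) - F_el(d)` are reported relative to the
#' reference separation.
#'
#' @param shape a [scaffold_shape()].
#' @param d_values distances.
#' @param params a [model_params()].
#' @param d_ref reference separation.
#' @param phi_grid,theta_grid optional orientation grids for the
#'   per-distance optimization step.
#' @return a `free_energy_curve`: data frame with `d`, `F`, `F_el`, `F_ent`
#'   and the orientation optima.
#' @export
free_energy_curve <- function(shape, d_values, params = model_params(),
                              d_ref = NULL, phi_grid = NULL,
                              theta_grid = NULL) {
  if (is.null(d_ref)) d_ref <- d_reference(params, shape)
  ds <- sort(unique(c(d_values, d_ref)), decreasing = TRUE)
  rows <- vector("list", length(ds))
  warm <- NULL
  h <- resolve_h(params, shape)
  for (i in seq_along(ds)) {
    opt <- optimal_orientation(shape, ds[i], params, phi_grid = phi_grid,
                               theta_grid = theta_grid, warm = warm)
    ev <- opt$evaluator
    warm <- ev$env$warm
    step0 <- max(diff(range(default_theta_grid(shape))) / 4, 0.5)
    axi <- is_axisymmetric(shape)
    # place the phi nodes inside the geometrically allowed window: at close
    # approach elongated scaffolds only fit with their long axes rotated
    # away from the connecting line, and forbidden phi carry zero weight
    phi_lo <- 0
    s_max <- (ds[i] / 2) - h
    if (s_max < shape$r_a && shape$r_a > shape$r_b) {
      c2 <- (max(s_max, shape$r_b)^2 - shape$r_b^2) / (shape$r_a^2 - shape$r_b^2)
      phi_lo <- min(89, acos(sqrt(pmax(0, pmin(1, c2)))) * 180 / pi + 1)
    }
    gl <- pracma::gaussLegendre(params$n_phi, phi_lo, 90)
    phis <- if (axi) opt$phi_star else gl$x
    logI_phi <- vapply(phis, function(ph)
      theta_log_integral(ev, ph, opt$theta_star, params, opt$F_min, step0),
      numeric(1))
    logI <- if (axi) log(pi / 2) + logI_phi[1]
            else log_weighted_sum_exp(logI_phi, gl$w * pi / 180)
    # F(d) = F_min(d) - log integral of exp(-(Fm - F_min))
    rows[[i]] <- data.frame(d = ds[i], F_min = opt$F_min, logI = logI,
                            phi_star = opt$phi_star, theta_star = opt$theta_star,
                            n_solve = ev$env$n_solve)
  }
  tab <- do.call(rbind, rows)
  iref <- which(tab$d == d_ref)[1]
  F_abs <- tab$F_min - tab$logI
  tab$F <- F_abs - F_abs[iref]
  tab$F_el <- tab$F_min - tab$F_min[iref]
  tab$F_ent <- tab$F - tab$F_el
  tab <- tab[order(tab$d), c("d", "F", "F_el", "F_ent", "phi_star",
                             "theta_star", "n_solve")]
  rownames(tab) <- NULL
  structure(tab, d_ref = d_ref, shape = shape, params = params,
            class = c("free_energy_curve", "data.frame"))
}

log_weighted_sum_exp <- function(logv, w) {
  keep <- is.finite(logv)
  if (!any(keep)) return(-Inf)
  m <- max(logv[keep])
  m + log(sum(w[keep] * exp(logv[keep] - m)))
}

#' @export
print.free_energy_curve <- function(x, ...) {
  cat(sprintf("Free-energy curve (reference d_ref = %.4g):\n", attr(x, "d_ref")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
plot.free_energy_curve <- function(x, ...) {
  rng <- range(c(x$F, x$F_el, x$F_ent))
  plot(x$d, x$F, type = "b", pch = 16, ylim = rng, xlab = "d",
       ylab = "energy (kT)", ...)
  lines(x$d, x$F_el, type = "b", pch = 1, col = 2)
  lines(x$d, x$F_ent, type = "b", pch = 2, col = 4)
  legend("topright", c("F", "F_el", "F_ent"), col = c(1, 2, 4),
         pch = c(16, 1, 2), bty = "n")
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Far-field power-law fit of an interaction curve
#'
#' Least-squares fit of `log |F_el|` against `log d` inside a distance
#' window; all points in the window must carry the same sign.
#'
#' @param curve an `interaction_curve` (or data frame with `d` and `F_el`).
#' @param window `c(dmin, dmax)`; defaults to the whole curve.
#' @return a `power_law_fit` with the exponent (slope), prefactor and
#'   standard error; `coef()` returns the exponent.
#' @export
fit_power_law <- function(curve, window = range(curve$d)) {
  sel <- curve$d >= window[1] & curve$d <= window[2] & is.finite(curve$F_el)
  d <- curve$d[sel]
  f <- curve$F_el[sel]
  if (length(d) < 4) stop("need at least 4 points in the fit window")
  if (length(unique(sign(f))) != 1 || any(f == 0))
    stop("F_el changes sign inside the window; split the window at the crossing")
  fit <- lm(log(abs(f)) ~ log(d))
  structure(list(exponent = unname(coef(fit)[2]),
                 log_prefactor = unname(coef(fit)[1]),
                 se = summary(fit)$coefficients[2, 2],
                 sign = sign(f[1]), n = length(d), window = window,
                 fit = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit over d in [%.3g, %.3g] (%d points, %s branch):\n",
              x$window[1], x$window[2], x$n,
              if (x$sign > 0) "repulsive" else "attractive"))
  cat(sprintf("  F_el ~ d^%.3f (s.e. %.3f)\n", x$exponent, x$se))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(exponent = object$exponent, log_prefactor = object$log_prefactor)
}

#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  d <- if (is.data.frame(newdata)) newdata$d else newdata
  object$sign * exp(object$log_prefactor + object$exponent * log(d))
}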