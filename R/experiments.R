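# Scripted parameter sweeps reproducing the figure-level computations:
# shallow circular scaffolds with anisotropic curvature, free energies,
# elliptical footprints, the BAR-domain geometry, and the lateral-tension and
# asymmetric-orientation controls.

default_d_grid <- function(shape, params, n = 12, d_max = NULL) {
  if (is.null(d_max)) d_max <- d_reference(params, shape)
  d_min <- 2 * shape$r_a + 3 * resolve_h(params, shape)
  exp(seq(log(d_min), log(d_max), length.out = n))
}

#' Elastic interaction of shallow circular scaffolds vs curvature anisotropy
#'
#' `F_el(d)` for circular-footprint shallow scaffolds (`r_a = r_b = a`,
#' `a/rho_a = 0.2`) over a grid of curvature ratios `c_b / c_a`.
#'
#' @param ratios values of `c_b / c_a`.
#' @param d_grid distances (default: geometric grid from the overlap bound
#'   to the reference separation).
#' @param params a [model_params()].
#' @param n_d number of distances when `d_grid` is `NULL`.
#' @param outdir optional directory for CSV output via [write_curve()].
#' @param ... passed to [elastic_interaction()] (orientation grids, refine).
#' @return named list of `interaction_curve`s.
#' @export
run_shallow_curvature_sweep <- function(ratios = c(1, 0.75, 0, -0.75, -1),
                                        d_grid = NULL,
                                        params = model_params(), n_d = 12,
                                        outdir = NULL, ...) {
  out <- list()
  for (r in ratios) {
    shape <- shape_preset("shallow_circular", cb_over_ca = r)
    dg <- if (is.null(d_grid)) default_d_grid(shape, params, n_d) else d_grid
    cur <- elastic_interaction(shape, dg, params, ...)
    nm <- sprintf("cb_over_ca_%g", r)
    out[[nm]] <- cur
    if (!is.null(outdir)) {
      write_curve(cur, file.path(outdir, paste0("shallow_", nm, ".csv")),
                  config = list(preset = "shallow_circular", cb_over_ca = r))
    }
  }
  out
}

#' Free energy and entropic interaction of shallow circular scaffolds
#'
#' @inheritParams run_shallow_curvature_sweep
#' @return named list of `free_energy_curve`s.
#' @export
run_free_energy_sweep <- function(ratios = c(1, 0.75, 0, -0.75, -1),
                                  d_grid = NULL, params = model_params(),
                                  n_d = 8, outdir = NULL, ...) {
  out <- list()
  for (r in ratios) {
    shape <- shape_preset("shallow_circular", cb_over_ca = r)
    dg <- if (is.null(d_grid)) default_d_grid(shape, params, n_d) else d_grid
    cur <- free_energy_curve(shape, dg, params, ...)
    nm <- sprintf("cb_over_ca_%g", r)
    out[[nm]] <- cur
    if (!is.null(outdir)) {
      write_curve(cur, file.path(outdir, paste0("free_energy_", nm, ".csv")),
                  config = list(preset = "shallow_circular", cb_over_ca = r))
    }
  }
  out
}

#' Elastic interaction vs footprint aspect ratio
#'
#' Shallow elliptical scaffolds with isotropic curvature
#' (`rho_a = rho_b = rho`), fixed geometric-mean radius
#' `r = sqrt(r_a r_b) = 0.2 rho`, and varying aspect ratio `r_a / r_b`.
#'
#' @param aspects values of `r_a / r_b` (1 = circular).
#' @inheritParams run_shallow_curvature_sweep
#' @return named list of `interaction_curve`s.
#' @export
run_aspect_ratio_sweep <- function(aspects = c(1, 1.5, 2),
                                   d_grid = NULL, params = model_params(),
                                   n_d = 10, outdir = NULL, ...) {
  out <- list()
  for (ar in aspects) {
    r <- 1                       # geometric mean radius, lengths in r-units
    rho <- r / 0.2
    shape <- scaffold_shape(rho_a = rho, rho_b = rho,
                            r_a = r * sqrt(ar), r_b = r / sqrt(ar), units = "a")
    dg <- if (is.null(d_grid)) default_d_grid(shape, params, n_d) else d_grid
    cur <- elastic_interaction(shape, dg, params, ...)
    nm <- sprintf("aspect_%g", ar)
    out[[nm]] <- cur
    if (!is.null(outdir)) {
      write_curve(cur, file.path(outdir, paste0("aspect_", nm, ".csv")),
                  config = list(aspect = ar))
    }
  }
  out
}

#' Elastic interaction for the BAR-domain scaffold geometry
#'
#' `r_a = 6.5` nm, `r_b = 1.5` nm, `rho_a = 8.5` nm, over a grid of
#' short-axis curvatures `c_b` (1/nm).
#'
#' @param c_b_values short-axis curvatures in 1/nm.
#' @param with_entropy also compute the free energy (and hence the entropy
#'   contribution) at the optimum distance?
#' @inheritParams run_shallow_curvature_sweep
#' @param mesh_outdir optional directory for minimized-mesh PLY exports at
#'   the equilibrium distance.
#' @return named list of `interaction_curve`s (entropy summaries attached as
#'   attributes when requested).
#' @export
run_bar_sweep <- function(c_b_values = c(0, 0.05, 0.1, 0.2),
                          d_grid = NULL, params = model_params(), n_d = 10,
                          outdir = NULL, mesh_outdir = NULL,
                          with_entropy = FALSE, ...) {
  out <- list()
  for (cb in c_b_values) {
    shape <- shape_preset("endophilin_nbar", c_b = cb)
    dg <- if (is.null(d_grid)) default_d_grid(shape, params, n_d) else d_grid
    cur <- elastic_interaction(shape, dg, params, ...)
    nm <- sprintf("cb_%g", cb)
    if (with_entropy) {
      mn <- curve_minimum(cur)
      fe <- free_energy_curve(shape, mn$d_star, params,
                              d_ref = attr(cur, "d_ref"))
      attr(cur, "entropy_at_optimum") <- fe$F_ent[which.min(abs(fe$d - mn$d_star))]
    }
    out[[nm]] <- cur
    if (!is.null(outdir)) {
      write_curve(cur, file.path(outdir, paste0("bar_", nm, ".csv")),
                  config = list(preset = "endophilin_nbar", c_b = cb))
    }
    if (!is.null(mesh_outdir)) {
      mn <- curve_minimum(cur)
      i <- which.min(abs(cur$d - mn$d_star))
      ms <- minimize_shape(build_membrane_mesh(
        shape, pair_config(mn$d_star, phi = cur$phi_star[i],
                           theta = cur$theta_star[i]), params), params)
      write_mesh_ply(ms$mesh,
                     file.path(mesh_outdir, paste0("bar_", nm, "_dstar.ply")))
    }
  }
  out
}

#' Lateral-tension control
#'
#' Verifies that under a small lateral tension (decay length
#' `xi = sqrt(kappa/gamma)` far larger than the scaffold) the interaction
#' decomposes into a gamma-dependent tension part and a curvature part that
#' matches the tensionless result.  Scaffold geometry:
#' `r_a = 0.23 rho_a`, `r_b = 0.175 rho_a`, `rho_b = rho_a`.
#'
#' @param xi_factors decay lengths in units of `r_a`.
#' @param d_values distances to test.
#' @param params a [model_params()].
#' @return data frame with per-gamma bending and tension parts of `F_el`.
#' @export
run_tension_check <- function(xi_factors = c(Inf, 100, 50),
                              d_values = NULL, params = model_params()) {
  rho <- 1 / 0.23
  shape <- scaffold_shape(rho_a = rho, rho_b = rho, r_a = 1,
                          r_b = 0.175 * rho, units = "a")
  if (is.null(d_values)) d_values <- c(3, 5)
  d_ref <- d_reference(params, shape)
  rows <- list()
  for (xf in xi_factors) {
    gamma <- if (is.finite(xf)) params$kappa / (xf * shape$r_a)^2 else 0
    pg <- params
    pg$gamma <- gamma
    for (d in c(d_values, d_ref)) {
      ms <- minimize_shape(build_membrane_mesh(shape, pair_config(d), pg), pg)
      rows[[length(rows) + 1L]] <-
        data.frame(xi_factor = xf, gamma = gamma, d = d,
                   F_bend = ms$F_m, F_tension = ms$E_tension)
    }
  }
  tab <- do.call(rbind, rows)
  # reference-subtract within each gamma
  tab$F_el_bend <- NA_real_
  tab$F_el_tension <- NA_real_
  for (xf in unique(tab$xi_factor)) {
    sel <- tab$xi_factor == xf
    refrow <- sel & tab$d == d_ref
    tab$F_el_bend[sel] <- tab$F_bend[sel] - tab$F_bend[refrow][1]
    tab$F_el_tension[sel] <- tab$F_tension[sel] - tab$F_tension[refrow][1]
  }
  tab
}

#' Asymmetric-orientation control
#'
#' For circular saddle-like scaffolds (`rho_b = -rho_a`) compares the
#' symmetric orientation optimum against designed asymmetric perturbations
#' (`phi1 != phi2`, `theta1 != theta2`).
#'
#' @param d distance at which to probe.
#' @param deltas angular perturbations in degrees applied to each side.
#' @param params a [model_params()].
#' @return data frame of configurations and energies; the symmetric optimum
#'   is the first row.
#' @export
run_asymmetry_check <- function(d = 4, deltas = c(10, 30),
                                params = model_params()) {
  shape <- shape_preset("shallow_circular", cb_over_ca = -1)
  opt <- optimal_orientation(shape, d, params)
  rows <- list(data.frame(phi1 = opt$phi_star, phi2 = opt$phi_star,
                          theta1 = opt$theta_star, theta2 = opt$theta_star,
                          F_m = opt$F_min, kind = "symmetric optimum"))
  warm <- opt$evaluator$env$warm
  probe <- function(phi1, phi2, theta1, theta2, kind) {
    cfg <- pair_config(d, phi1 = phi1, phi2 = phi2,
                       theta1 = theta1, theta2 = theta2)
    ms <- minimize_shape(build_membrane_mesh(shape, cfg, params), params,
                         warm_start = warm)
    data.frame(phi1 = phi1, phi2 = phi2, theta1 = theta1, theta2 = theta2,
               F_m = ms$F_m, kind = kind)
  }
  for (dl in deltas) {
    rows[[length(rows) + 1L]] <- probe(opt$phi_star + dl, opt$phi_star - dl,
                                       opt$theta_star, opt$theta_star,
                                       sprintf("phi +/- %g", dl))
    rows[[length(rows) + 1L]] <- probe(opt$phi_star, opt$phi_star,
                                       opt$theta_star + dl,
                                       max(0, opt$theta_star - dl),
                                       sprintf("theta +/- %g", dl))
  }
  do.call(rbind, rows)
}
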