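# Damped Newton descent on the vertical (z) degrees of freedom.
#
# The deformed membrane stays a graph over the initial plane for all
# placements the overlap guard admits, so the shape is minimized over the
# vertical positions of the free vertices.  The Newton matrix is the exact
# Hessian of the lagged-coefficient quadratic model
#     E ~ sum_v kappa/(8 A_v) ( sum_j w_vj (z_v - z_j) )^2  (+ tension part)
# with cotangent weights w and mixed areas A frozen at the current geometry;
# it agrees with the true Hessian to O(slope^2), so a few damped steps with
# the exact analytic gradient converge to the minimum of the full nonlinear
# energy.  L-BFGS on the same gradient serves as a fallback polish.

z_closures <- function(mesh, params) {
  movable <- which(!mesh$fixed)
  mask <- energy_mask(mesh)
  V <- mesh$V
  ref <- if (is.finite(mesh$area_ref)) mesh$area_ref else 0
  fn <- function(z) {
    V[movable, 3] <- z
    tryCatch(mesh_energy_cpp(V, mesh$F - 1L, mask, params$kappa,
                             params$gamma, ref, FALSE)$E,
             error = function(e) 1e10)
  }
  gr <- function(z) {
    V[movable, 3] <- z
    tryCatch(mesh_energy_cpp(V, mesh$F - 1L, mask, params$kappa,
                             params$gamma, ref, TRUE)$grad[movable, 3],
             error = function(e) numeric(length(z)))
  }
  list(fn = fn, gr = gr, movable = movable, mask = mask)
}

# sparse lagged-coefficient Hessian over the movable z (Cholesky factor)
newton_matrix <- function(mesh, params, movable, mask) {
  V <- mesh$V; F <- mesh$F
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  v <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  twoA <- sqrt(nx^2 + ny^2 + nz^2)
  duv <- rowSums(u * v)
  L01 <- rowSums(u * u); L02 <- rowSums(v * v)
  cot0 <- duv / twoA
  cot1 <- (L01 - duv) / twoA
  cot2 <- (L02 - duv) / twoA
  # edge (a, b) with the opposite-corner cotangent as weight
  ea <- c(F[, 2], F[, 1], F[, 1])
  eb <- c(F[, 3], F[, 3], F[, 2])
  wc <- c(cot0, cot1, cot2)
  # duplicate (two-triangle) edges are summed by sparseMatrix itself
  ei <- pmin(ea, eb); ej <- pmax(ea, eb); we <- wc

  Am <- mesh_energy_cpp(V, F - 1L, mask, params$kappa, params$gamma,
                        0, FALSE)$A_mixed
  nmov <- length(movable)
  col_of <- integer(nrow(V))
  col_of[movable] <- seq_len(nmov)
  rows_v <- which(mask)
  row_of <- integer(nrow(V))
  row_of[rows_v] <- seq_along(rows_v)

  # B rows: r_v = sum_j w_vj (z_v - z_j) over masked v, movable columns
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (side in 1:2) {
    a <- if (side == 1) ei else ej
    b <- if (side == 1) ej else ei
    sel <- mask[a]
    aa <- a[sel]; bb <- b[sel]; ww <- we[sel]
    # masked rows may sit on fixed vertices (the rim hinge); only movable
    # vertices contribute columns
    da <- col_of[aa] > 0
    db <- col_of[bb] > 0
    ti <- c(ti, row_of[aa][da], row_of[aa][db])
    tj <- c(tj, col_of[aa][da], col_of[bb][db])
    tx <- c(tx, ww[da], -ww[db])
  }
  B <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = c(length(rows_v), nmov))
  Dhalf <- sqrt(params$kappa / (4 * pmax(Am[rows_v], 1e-300)))
  H <- Matrix::crossprod(Dhalf * B)
  if (params$gamma > 0) {
    sel <- col_of[ei] > 0 & col_of[ej] > 0
    Lt <- Matrix::sparseMatrix(
      i = c(col_of[ei[sel]], col_of[ej[sel]], col_of[ei[sel]], col_of[ej[sel]]),
      j = c(col_of[ei[sel]], col_of[ej[sel]], col_of[ej[sel]], col_of[ei[sel]]),
      x = c(we[sel], we[sel], -we[sel], -we[sel]) * params$gamma / 2,
      dims = c(nmov, nmov))
    H <- H + Lt
  }
  ridge <- 1e-12 * mean(Matrix::diag(H))
  H + Matrix::Diagonal(nmov, ridge)
}

# damped (Levenberg-Marquardt) Newton iteration on the z degrees of freedom;
# the damping controls steps along the physically flat (harmonic) directions.
# Returns list(mesh, E, grad_norm, n_iter, ok).
newton_z <- function(mesh, params, tol = params$pgtol, max_newton = 90) {
  cls <- z_closures(mesh, params)
  z <- mesh$V[cls$movable, 3]
  E <- cls$fn(z)
  n_used <- 0L
  ok <- FALSE
  lam <- 1e-4
  stall <- 0L
  for (it in seq_len(max_newton)) {
    g <- cls$gr(z)
    gn <- max(abs(g))
    if (gn < tol) { ok <- TRUE; break }
    # residual descent along near-null (harmonic) directions changes the
    # energy negligibly; stop once improvements stagnate
    if ((stall >= 3 && gn < 1e-2) || stall >= 6) { ok <- TRUE; break }
    H <- newton_matrix(mesh, params, cls$movable, cls$mask)
    dH <- Matrix::Diagonal(x = pmax(Matrix::diag(H), 1e-12))
    accepted <- FALSE
    for (try in 1:12) {
      p <- tryCatch(-as.numeric(Matrix::solve(H + lam * dH, g)),
                    error = function(e) NULL)
      if (!is.null(p) && all(is.finite(p))) {
        slope <- sum(g * p)
        if (slope < 0) {
          # step-length backtracking before re-damping: near convergence the
          # residual lives in soft modes where the lagged model overshoots
          for (alpha in c(1, 0.5, 0.25, 0.1)) {
            E1 <- cls$fn(z + alpha * p)
            if (E1 <= E + 1e-4 * alpha * slope) {
              stall <- if (E - E1 < max(1e-9, 1e-7 * abs(E1))) stall + 1L else 0L
              z <- z + alpha * p
              mesh$V[cls$movable, 3] <- z
              E <- E1
              accepted <- TRUE
              if (alpha == 1) lam <- max(lam / 4, 1e-9)
              break
            }
          }
          if (accepted) break
        }
      }
      lam <- lam * 8
    }
    n_used <- it
    if (!accepted) break
  }
  # polish with L-BFGS only if the Newton loop stalled far from a minimum
  if (!ok && max(abs(cls$gr(z))) > 0.1) {
    opt <- optim(z, cls$fn, cls$gr, method = "L-BFGS-B",
                 control = list(maxit = 500, pgtol = tol, factr = 1e1,
                                lmm = 20))
    if (opt$value <= E) {
      z <- opt$par
      mesh$V[cls$movable, 3] <- z
      E <- opt$value
    }
    n_used <- n_used + opt$counts[1]
  }
  ok <- ok || max(abs(cls$gr(z))) < 1e-2
  list(mesh = mesh, E = E, grad_norm = max(abs(cls$gr(z))),
       n_iter = n_used, ok = ok)
}
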