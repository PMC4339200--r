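# Analytic mesh fixtures built in code: icosphere, cylinder tube, catenoid,
# flat patches.  Returned as plain lists with V / F (1-based) plus boundary
# and interior flags, the minimal surface the curvature and energy operators
# accept.

make_icosphere <- function(n_subdiv = 3, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  V <- matrix(c(-1, t, 0, 1, t, 0, -1, -t, 0, 1, -t, 0,
                0, -1, t, 0, 1, t, 0, -1, -t, 0, 1, -t,
                t, 0, -1, t, 0, 1, -t, 0, -1, -t, 0, 1),
              ncol = 3, byrow = TRUE)
  V <- V / sqrt(rowSums(V^2))
  F <- matrix(c(1, 12, 6, 1, 6, 2, 1, 2, 8, 1, 8, 11, 1, 11, 12,
                2, 6, 10, 6, 12, 5, 12, 11, 3, 11, 8, 7, 8, 2, 9,
                4, 10, 5, 4, 5, 3, 4, 3, 7, 4, 7, 9, 4, 9, 10,
                5, 10, 6, 3, 5, 12, 7, 3, 11, 9, 7, 8, 10, 9, 2),
              ncol = 3, byrow = TRUE)
  for (i in seq_len(n_subdiv)) {
    e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
    a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
    k <- paste(a, b)
    first <- !duplicated(k)
    eid <- match(k, k[first])
    newV <- (V[a[first], ] + V[b[first], ]) / 2
    newV <- newV / sqrt(rowSums(newV^2))
    n0 <- nrow(V); m <- nrow(F)
    m01 <- n0 + eid[seq_len(m)]
    m12 <- n0 + eid[m + seq_len(m)]
    m20 <- n0 + eid[2 * m + seq_len(m)]
    V <- rbind(V, newV)
    F <- rbind(cbind(F[, 1], m01, m20), cbind(F[, 2], m12, m01),
               cbind(F[, 3], m20, m12), cbind(m01, m12, m20))
  }
  list(V = V * radius, F = F,
       boundary = rep(FALSE, nrow(V)), interior = rep(TRUE, nrow(V)))
}

# open tube meshed between z = 0 and z = height
make_cylinder <- function(radius = 1, height = 6, n_theta = 48, n_z = 36) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zz <- seq(0, height, length.out = n_z)
  V <- NULL
  for (j in seq_len(n_z)) {
    off <- if (j %% 2 == 0) (th[2] - th[1]) / 2 else 0
    V <- rbind(V, cbind(radius * cos(th + off), radius * sin(th + off), zz[j]))
  }
  F <- NULL
  id <- function(j, i) (j - 1) * n_theta + ((i - 1) %% n_theta) + 1
  for (j in seq_len(n_z - 1)) {
    for (i in seq_len(n_theta)) {
      F <- rbind(F, c(id(j, i), id(j, i + 1), id(j + 1, i)),
                 c(id(j, i + 1), id(j + 1, i + 1), id(j + 1, i)))
    }
  }
  boundary <- rep(FALSE, nrow(V))
  boundary[c(seq_len(n_theta), (n_z - 1) * n_theta + seq_len(n_theta))] <- TRUE
  list(V = V, F = F, boundary = boundary, interior = !boundary)
}

# catenoid r(z) = c cosh(z/c), meshed between two symmetric rings
make_catenoid <- function(c0 = 1, zmax = 1, n_theta = 48, n_z = 30) {
  m <- make_cylinder(1, 1, n_theta, n_z)
  zz <- m$V[, 3] * 2 * zmax - zmax
  rr <- c0 * cosh(zz / c0)
  phi <- atan2(m$V[, 2], m$V[, 1])
  m$V <- cbind(rr * cos(phi), rr * sin(phi), zz)
  m
}

# flat triangulated rectangle; fixed boundary, free interior
make_flat_patch <- function(nx = 10, ny = 10, lx = 1, ly = 1, jitter = 0) {
  g <- expand.grid(x = seq(0, lx, length.out = nx),
                   y = seq(0, ly, length.out = ny))
  set.seed(7)
  x <- g$x + jitter * runif(nrow(g), -1, 1) * lx / nx
  y <- g$y + jitter * runif(nrow(g), -1, 1) * ly / ny
  F <- memscaffold:::delaunay_cpp(x + 1e-9 * sin(seq_along(x)),
                                  y + 1e-9 * cos(seq_along(x)))
  V <- cbind(x, y, 0)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  k <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(k)
  bv <- unique(as.integer(unlist(strsplit(names(cnt)[cnt == 1], " "))))
  boundary <- rep(FALSE, nrow(V)); boundary[bv] <- TRUE
  list(V = V, F = F, boundary = boundary, interior = !boundary)
}

# equilateral-triangular flat lattice (exact fixed point of uniform
# tangential averaging)
make_flat_hex <- function(n = 9, s = 0.1) {
  pts <- NULL
  for (j in 0:(n - 1)) {
    x <- (seq_len(n) - 1) * s + (j %% 2) * s / 2
    pts <- rbind(pts, cbind(x, j * s * sqrt(3) / 2))
  }
  F <- memscaffold:::delaunay_cpp(pts[, 1] + 1e-9 * sin(seq_len(nrow(pts))),
                                  pts[, 2] + 1e-9 * cos(seq_len(nrow(pts))))
  V <- cbind(pts, 0)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  k <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(k)
  bv <- unique(as.integer(unlist(strsplit(names(cnt)[cnt == 1], " "))))
  boundary <- rep(FALSE, nrow(V)); boundary[bv] <- TRUE
  list(V = V, F = F, boundary = boundary, interior = !boundary)
}

# small membrane-mesh-shaped wrapper around a bare fixture so that the
# minimizer can run on it (everything free except a fixed boundary frame)
as_membrane_fixture <- function(m, L = 1) {
  tags <- data.frame(kind = ifelse(m$boundary, "strip", "free"),
                     sc = NA_integer_, xi = NA_real_, eta = NA_real_,
                     sp = 0.1, stringsAsFactors = FALSE)
  structure(list(V = m$V, F = m$F, fixed = m$boundary, tags = tags,
                 boundary = m$boundary, interior = m$interior,
                 placements = list(), shape = NULL, config = NULL,
                 single = TRUE, h = 0.1, L = L, level = 0L,
                 collar_delta = 0, area_ref = NA_real_),
            class = "membrane_mesh")
}

coarse_params <- function(...) model_params(profile = "coarse", ...)
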