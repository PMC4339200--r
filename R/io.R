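# Configuration files, curve/mesh output, and the manifest sidecar.

config_schema <- c("preset", "cb_over_ca", "c_b", "rho_a", "rho_b", "r_a",
                   "r_b", "units", "kappa", "gamma", "L", "h", "profile",
                   "d", "phi", "theta", "d_grid", "d_ref_factor", "n_phi",
                   "n_theta", "theta_window", "refine_levels", "seed")

#' Load a run configuration
#'
#' Reads a YAML config, validates it against the documented key schema
#' (unknown keys are rejected), and fills defaults: `kappa = 20` kT,
#' `gamma = 0`, coarse resolution profile.  Shape parameters may be given
#' either as a named `preset` (with `cb_over_ca` or `c_b`) or explicitly as
#' `rho_a, rho_b, r_a, r_b` with a mandatory `units` tag ("a" or "nm").
#'
#' @param path YAML file path.
#' @return a list of class `run_config` with elements `shape`
#'   ([scaffold_shape()]), `params` ([model_params()]) and the raw fields.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_schema)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$preset)) {
    shape <- if (identical(raw$preset, "shallow_circular")) {
      shape_preset("shallow_circular", cb_over_ca = raw$cb_over_ca %||% 1)
    } else if (identical(raw$preset, "endophilin_nbar")) {
      shape_preset("endophilin_nbar", c_b = raw$c_b %||% 0.2)
    } else stop("unknown preset: ", raw$preset)
  } else {
    for (k in c("rho_a", "rho_b", "r_a", "r_b"))
      if (is.null(raw[[k]])) stop("missing shape key: ", k)
    if (is.null(raw$units))
      stop("explicit shape parameters require a 'units' tag (\"a\" or \"nm\")")
    shape <- scaffold_shape(raw$rho_a, raw$rho_b, raw$r_a, raw$r_b,
                            units = raw$units)
  }
  params <- model_params(
    kappa = raw$kappa %||% 20, gamma = raw$gamma %||% 0,
    L = raw$L, h = raw$h, profile = raw$profile %||% "coarse",
    d_ref_factor = raw$d_ref_factor %||% 20,
    n_phi = raw$n_phi, n_theta = raw$n_theta,
    theta_window = raw$theta_window %||% 4,
    refine_levels = raw$refine_levels %||% 0,
    seed = raw$seed %||% 1L)
  structure(list(shape = shape, params = params, raw = raw),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  print(x$shape)
  cat(sprintf("  kappa = %g kT, gamma = %g, profile = %s\n",
              x$params$kappa, x$params$gamma, x$params$profile))
  invisible(x)
}

# small deterministic polynomial rolling hash of a deparsed R object
config_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  sprintf("%08x", h)
}

#' Write an interaction or free-energy curve to CSV with a manifest
#'
#' Fixed column order, 12 significant digits, plus a `.manifest` sidecar
#' echoing the configuration and its hash.
#'
#' @param curve a data frame (`interaction_curve`, `free_energy_curve`, ...).
#' @param path output CSV path.
#' @param config optional configuration list echoed into the manifest.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, config = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(curve)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 12))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  manifest <- c(
    sprintf("file: %s", basename(path)),
    sprintf("columns: %s", paste(names(df), collapse = ",")),
    sprintf("rows: %d", nrow(df)),
    sprintf("d_ref: %s", format(attr(curve, "d_ref") %||% NA)),
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("config: %s", paste(deparse(config), collapse = " ")))
  writeLines(manifest, paste0(path, ".manifest"))
  invisible(path)
}

#' Read a curve written by [write_curve()]
#' @param path CSV path.
#' @export
read_curve <- function(path) read.csv(path)

#' Write a mesh as ASCII PLY (fixed mask as a vertex property)
#'
#' @param mesh a `membrane_mesh`.
#' @param path output path.
#' @export
write_mesh_ply <- function(mesh, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  n <- nrow(mesh$V); m <- nrow(mesh$F)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           "property uchar fixed",
           sprintf("element face %d", m),
           "property list uchar int vertex_indices", "end_header")
  vtx <- sprintf("%.17g %.17g %.17g %d", mesh$V[, 1], mesh$V[, 2],
                 mesh$V[, 3], as.integer(mesh$fixed))
  fc <- sprintf("3 %d %d %d", mesh$F[, 1] - 1L, mesh$F[, 2] - 1L,
                mesh$F[, 3] - 1L)
  writeLines(c(hdr, vtx, fc), path)
  invisible(path)
}

#' Read an ASCII PLY written by [write_mesh_ply()]
#' @param path PLY path.
#' @return list with `V`, `F` (1-based) and `fixed`.
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vl <- do.call(rbind, strsplit(lines[endh + seq_len(nv)], " "))
  fl <- do.call(rbind, strsplit(lines[endh + nv + seq_len(nf)], " "))
  list(V = matrix(as.numeric(vl[, 1:3]), ncol = 3),
       fixed = as.logical(as.integer(vl[, 4])),
       F = matrix(as.integer(fl[, 2:4]), ncol = 3) + 1L)
}

#' Write a mesh as ASCII OFF
#' @inheritParams write_mesh_ply
#' @export
write_mesh_off <- function(mesh, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(c("OFF",
               sprintf("%d %d 0", nrow(mesh$V), nrow(mesh$F)),
               sprintf("%.17g %.17g %.17g", mesh$V[, 1], mesh$V[, 2], mesh$V[, 3]),
               sprintf("3 %d %d %d", mesh$F[, 1] - 1L, mesh$F[, 2] - 1L,
                       mesh$F[, 3] - 1L)), path)
  invisible(path)
}

#' Read an ASCII OFF file
#' @param path OFF path.
#' @return list with `V` and `F` (1-based).
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "OFF")
  counts <- as.integer(strsplit(lines[2], " ")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vl <- do.call(rbind, strsplit(lines[2 + seq_len(nv)], " "))
  fl <- do.call(rbind, strsplit(lines[2 + nv + seq_len(nf)], " "))
  list(V = matrix(as.numeric(vl), ncol = 3),
       F = matrix(as.integer(fl[, 2:4]), ncol = 3) + 1L)
}
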