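# Axisymmetric spherical-coordinate finite-volume mesh for the shelled cell.
# The grid is a tensor product of a radial partition (with faces placed
# exactly on the material interfaces, and the 10-nm membranes resolved by
# several layers each) and a uniform polar partition of [0, pi]. The far
# boundary is a sphere of radius `outer_radius` carrying the uniform-field
# potential of the electrodes; the lateral insulating walls of a physical
# pulsing chamber are far enough that this is their ideal limit.

# geometric grading from x0 to x1 into n cells, finest at the `at` end
graded_seq <- function(x0, x1, n, ratio = 1.4, at = c("start", "end")) {
  at <- match.arg(at)
  w <- ratio^(0:(n - 1))
  if (at == "start") w <- w else w <- rev(w)
  br <- c(0, cumsum(w) / sum(w))
  x0 + (x1 - x0) * br
}

#' Mesh specification
#'
#' Resolution controls for [build_mesh()]. `refine` scales every count, so
#' `refine = 2` is the "one level finer" mesh of the 2%-change convergence
#' rule.
#'
#' @param n_theta Number of polar cells on `[0, pi]` (even; probe spacing of
#'   15 degrees is interpolated).
#' @param membrane_layers Radial cells across each membrane (>= 2).
#' @param n_extracellular,n_cytoplasm,n_nucleoplasm Radial cells per
#'   electrolyte region.
#' @param outer_radius Radius of the far spherical boundary (m) where the
#'   uniform-field electrode potential is imposed.
#' @param refine Integer refinement multiplier applied to all counts.
#' @return An object of class `mesh_spec`.
#' @export
mesh_spec <- function(n_theta = 60, membrane_layers = 2,
                      n_extracellular = 16, n_cytoplasm = 10,
                      n_nucleoplasm = 8, outer_radius = 50e-6,
                      refine = 1) {
  if (membrane_layers < 2) stop("membrane_layers must be >= 2")
  structure(list(n_theta = as.integer(n_theta * refine),
                 membrane_layers = as.integer(round(membrane_layers * refine)),
                 n_extracellular = as.integer(n_extracellular * refine),
                 n_cytoplasm = as.integer(n_cytoplasm * refine),
                 n_nucleoplasm = as.integer(n_nucleoplasm * refine),
                 outer_radius = outer_radius),
            class = "mesh_spec")
}

#' Build the axisymmetric finite-volume mesh
#'
#' Discretizes the (double-)shelled cell and surrounding medium on a
#' spherical `(r, theta)` tensor grid. Radial faces coincide exactly with
#' the material interfaces; each membrane is resolved by
#' `spec$membrane_layers` cells across its thickness; electrolyte regions
#' are geometrically graded toward the membranes they touch.
#'
#' @param geometry A [cell_geometry()].
#' @param spec A [mesh_spec()].
#' @return An object of class `nspef_mesh` with the radial/polar partitions,
#'   per-radial-band material tags (`"nucleoplasm"`, `"nuclear_membrane"`,
#'   `"cytoplasm"`, `"plasma_membrane"`, `"extracellular"`), and precomputed
#'   face tables used by the solver.
#' @export
build_mesh <- function(geometry, spec = mesh_spec()) {
  stopifnot(inherits(geometry, "cell_geometry"), inherits(spec, "mesh_spec"))
  g <- geometry
  R_pm_i <- g$cell_radius - g$plasma_membrane_thickness
  if (spec$outer_radius <= 2 * g$cell_radius)
    stop("outer_radius must exceed twice the cell radius")
  band <- function(x0, x1, n, mat, grade = NULL, ratio = 1.35) {
    faces <- if (is.null(grade)) seq(x0, x1, length.out = n + 1)
             else graded_seq(x0, x1, n, ratio, grade)
    list(faces = faces, mat = rep(mat, n))
  }
  if (g$has_nucleus) {
    R_nm_o <- g$nuclear_radius + g$nuclear_membrane_thickness
    bands <- list(
      band(0, g$nuclear_radius, spec$n_nucleoplasm, "nucleoplasm", "end"),
      band(g$nuclear_radius, R_nm_o, spec$membrane_layers, "nuclear_membrane"),
      band(R_nm_o, R_pm_i, spec$n_cytoplasm, "cytoplasm"),
      band(R_pm_i, g$cell_radius, spec$membrane_layers, "plasma_membrane"),
      band(g$cell_radius, spec$outer_radius, spec$n_extracellular,
           "extracellular", "start", ratio = 1.45))
  } else {
    bands <- list(
      band(0, R_pm_i, spec$n_cytoplasm + spec$n_nucleoplasm, "cytoplasm"),
      band(R_pm_i, g$cell_radius, spec$membrane_layers, "plasma_membrane"),
      band(g$cell_radius, spec$outer_radius, spec$n_extracellular,
           "extracellular", "start", ratio = 1.45))
  }
  r_faces <- c(0, unlist(lapply(bands, function(b) b$faces[-1])))
  mat_r <- unlist(lapply(bands, `[[`, "mat"))
  if (any(diff(r_faces) <= 0))
    stop("degenerate radial partition; membranes are thinner than representable ",
         "at this resolution -- reduce membrane_layers or refine")
  nr <- length(mat_r)
  nt <- spec$n_theta
  th_faces <- seq(0, pi, length.out = nt + 1)
  r_c <- (r_faces[-1] + r_faces[-(nr + 1)]) / 2
  th_c <- (th_faces[-1] + th_faces[-(nt + 1)]) / 2
  m <- structure(list(
    geometry = g, spec = spec,
    r_faces = r_faces, r_centers = r_c, mat_r = mat_r,
    theta_faces = th_faces, theta_centers = th_c,
    nr = nr, nt = nt, n_cells = nr * nt,
    i_pm = which(mat_r == "plasma_membrane"),
    i_nm = which(mat_r == "nuclear_membrane"),
    subdomains = unique(mat_r)
  ), class = "nspef_mesh")
  m$faces <- mesh_faces(m)
  m
}

# Precompute the face tables. Orientation: cell1 -> cell2 (radially outward
# or in +theta). Areas omit the common 2*pi azimuthal factor.
mesh_faces <- function(m) {
  nr <- m$nr; nt <- m$nt
  cell <- function(i, j) i + (j - 1L) * nr
  dcos <- cos(m$theta_faces[-(nt + 1)]) - cos(m$theta_faces[-1])  # per theta cell
  # radial interior faces between (i, j) and (i+1, j), i = 1..nr-1
  i_idx <- rep(seq_len(nr - 1), nt)
  j_idx <- rep(seq_len(nt), each = nr - 1)
  rf <- list(
    c1 = cell(i_idx, j_idx), c2 = cell(i_idx + 1L, j_idx),
    area = m$r_faces[i_idx + 1L]^2 * dcos[j_idx],
    d1 = m$r_faces[i_idx + 1L] - m$r_centers[i_idx],
    d2 = m$r_centers[i_idx + 1L] - m$r_faces[i_idx + 1L],
    m1 = i_idx, m2 = i_idx + 1L,        # radial band index (material lookup)
    jj = j_idx)
  # polar faces between (i, j) and (i, j+1), j = 1..nt-1
  i2 <- rep(seq_len(nr), nt - 1)
  j2 <- rep(seq_len(nt - 1), each = nr)
  r_in <- m$r_faces[i2]; r_out <- m$r_faces[i2 + 1L]
  tf <- list(
    c1 = cell(i2, j2), c2 = cell(i2, j2 + 1L),
    area = sin(m$theta_faces[j2 + 1L]) * (r_out^2 - r_in^2) / 2,
    d1 = m$r_centers[i2] * (m$theta_faces[j2 + 1L] - m$theta_centers[j2]),
    d2 = m$r_centers[i2] * (m$theta_centers[j2 + 1L] - m$theta_faces[j2 + 1L]),
    m1 = i2, m2 = i2,
    jj = j2)  # theta index of cell1 (sigma of membrane may differ across jj)
  # outer Dirichlet boundary faces at r = outer_radius, one per theta cell
  jb <- seq_len(nt)
  bf <- list(
    c1 = cell(rep(nr, nt), jb),
    area = m$r_faces[nr + 1L]^2 * dcos,
    d1 = m$r_faces[nr + 1L] - m$r_centers[nr],
    m1 = rep(nr, nt),
    jj = jb)
  # polar face material sigma must follow its own theta cell for membrane
  # bands; record the theta of each side (j and j+1) for sigma lookup
  tf$j1 <- j2; tf$j2 <- j2 + 1L
  rf$j1 <- j_idx; rf$j2 <- j_idx
  bf$j1 <- jb
  list(radial = rf, polar = tf, boundary = bf)
}

#' @export
print.nspef_mesh <- function(x, ...) {
  cat(sprintf("Axisymmetric cell mesh: %d radial x %d polar cells (%d unknowns)\n",
              x$nr, x$nt, x$n_cells))
  cat(sprintf("  subdomains: %s\n", paste(x$subdomains, collapse = ", ")))
  cat(sprintf("  outer boundary at %g um\n", x$spec$outer_radius * 1e6))
  invisible(x)
}
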