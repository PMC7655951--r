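#' @keywords internal
"_PACKAGE"

# Vacuum permittivity, F/m. Fixed constant used everywhere a relative
# permittivity is converted to an absolute one.
EPS_VACUUM <- 8.854187817e-12

#' Vacuum permittivity constant
#'
#' @return The vacuum permittivity in F/m used throughout the package.
#' @export
eps_vacuum <- function() EPS_VACUUM

#' Cell geometry
#'
#' Geometry of the double-shelled spherical cell: a cell bounded by a thin
#' plasma membrane, optionally containing a concentric nucleus bounded by its
#' own thin membrane. `cell_radius` is the outer radius of the cell (outer
#' face of the plasma membrane, which occupies
#' `[cell_radius - thickness, cell_radius]`); `nuclear_radius` is the radius
#' of the nucleoplasm (inner face of the nuclear membrane, which occupies
#' `[nuclear_radius, nuclear_radius + thickness]`).
#'
#' @param cell_radius Outer cell radius (m).
#' @param plasma_membrane_thickness Plasma membrane thickness (m).
#' @param nuclear_radius Nucleoplasm radius (m).
#' @param nuclear_membrane_thickness Nuclear membrane thickness (m).
#' @param has_nucleus Logical; `FALSE` reduces the model to a single-shelled
#'   cell (no nucleus).
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(cell_radius = 5e-6,
                          plasma_membrane_thickness = 0.01e-6,
                          nuclear_radius = 2.5e-6,
                          nuclear_membrane_thickness = 0.01e-6,
                          has_nucleus = TRUE) {
  g <- structure(list(
    cell_radius = cell_radius,
    plasma_membrane_thickness = plasma_membrane_thickness,
    nuclear_radius = nuclear_radius,
    nuclear_membrane_thickness = nuclear_membrane_thickness,
    has_nucleus = isTRUE(has_nucleus)
  ), class = "cell_geometry")
  validate_cell_geometry(g)
  g
}

validate_cell_geometry <- function(g) {
  num <- c(g$cell_radius, g$plasma_membrane_thickness,
           g$nuclear_radius, g$nuclear_membrane_thickness)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all radii and thicknesses must be strictly positive and finite")
  if (g$nuclear_radius + g$nuclear_membrane_thickness >=
      g$cell_radius - g$plasma_membrane_thickness)
    stop("nucleus (radius + membrane thickness) must fit strictly inside the cell")
  invisible(g)
}

#' Passive (non-dispersive) material
#'
#' A compartment described by a frequency-independent conductivity and
#' relative permittivity.
#'
#' @param conductivity Conductivity (S/m), non-negative.
#' @param relative_permittivity Relative permittivity, >= 1.
#' @return An object of class `passive_material`.
#' @export
passive_material <- function(conductivity, relative_permittivity) {
  if (!is.finite(conductivity) || conductivity < 0)
    stop("conductivity must be non-negative")
  if (!is.finite(relative_permittivity) || relative_permittivity < 1)
    stop("relative_permittivity must be >= 1")
  structure(list(conductivity = conductivity,
                 relative_permittivity = relative_permittivity),
            class = "passive_material")
}

#' Second-order Debye dispersive material
#'
#' Membrane dielectric described by the second-order Debye relation
#' \deqn{\varepsilon(\omega) = \varepsilon_\infty +
#'   \frac{\Delta\varepsilon_1}{1 + j\omega\tau_1} +
#'   \frac{\Delta\varepsilon_2}{1 + j\omega\tau_2}.}
#' All permittivities are stored as *absolute* permittivities (F/m); the
#' static limit is `eps_inf + delta_eps_1 + delta_eps_2`.
#'
#' @param eps_inf High-frequency permittivity (F/m).
#' @param delta_eps_1,delta_eps_2 Relaxation amplitudes (F/m).
#' @param tau_1,tau_2 Relaxation times (s).
#' @return An object of class `debye_material`.
#' @export
debye_material <- function(eps_inf = 13.9e-12,
                           delta_eps_1 = 2.3e-11,
                           delta_eps_2 = 7.4e-12,
                           tau_1 = 3.0e-9,
                           tau_2 = 4.6e-10) {
  v <- c(eps_inf, delta_eps_1, delta_eps_2, tau_1, tau_2)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all Debye parameters must be strictly positive")
  structure(list(eps_inf = eps_inf,
                 delta_eps_1 = delta_eps_1, delta_eps_2 = delta_eps_2,
                 tau_1 = tau_1, tau_2 = tau_2),
            class = "debye_material")
}

#' Static relative permittivity of a Debye material
#'
#' Zero-frequency limit of the second-order Debye relation,
#' `(eps_inf + delta_eps_1 + delta_eps_2) / eps_vacuum`.
#'
#' @param m A [debye_material()].
#' @return Dimensionless static relative permittivity.
#' @export
static_relative_permittivity <- function(m) {
  stopifnot(inherits(m, "debye_material"))
  (m$eps_inf + m$delta_eps_1 + m$delta_eps_2) / EPS_VACUUM
}

#' Asymptotic electroporation model constants
#'
#' Constants of the asymptotic Smoluchowski pore-density equation
#' \deqn{dN/dt = \alpha e^{(1-q)(V_m/V_{ep})^2}
#'   \left(e^{q (V_m/V_{ep})^2} - N/N_0\right)}
#' and of the pore-mediated membrane conductivity
#' \eqn{\sigma_m = \sigma_{m0} + N \pi r_p^2 \sigma_p K(V_m)}.
#'
#' @param alpha Pore creation rate density (m^-2 s^-1).
#' @param N0 Equilibrium pore density at zero voltage (m^-2).
#' @param V_ep Characteristic electroporation voltage (V).
#' @param q Electroporation exponent (dimensionless, > 1).
#' @param r_p Pore radius (m).
#' @param w0 Dimensionless energy barrier inside the pore.
#' @param sigma_p Conductivity of the aqueous pore interior (S/m).
#' @param n_rel Relative entrance length of the pore (dimensionless, in (0,1)).
#' @param T Temperature (K).
#' @param R_gas Universal gas constant (J/K/mol).
#' @param F_const Faraday constant (C/mol).
#' @param pt_threshold Pore density above which a membrane patch is classified
#'   as electroporated (m^-2). A classification constant, not part of the
#'   dynamics.
#' @return An object of class `ep_model`.
#' @export
ep_model <- function(alpha = 1.0e9,
                     N0 = 1.5e9,
                     V_ep = 0.258,
                     q = 2.46,
                     r_p = 0.76e-9,
                     w0 = 2.65,
                     sigma_p = 1.3,
                     n_rel = 0.15,
                     T = 295,
                     R_gas = 8.314,
                     F_const = 9.65e4,
                     pt_threshold = 1e15) {
  pos <- c(alpha, N0, V_ep, r_p, sigma_p, T, R_gas, F_const, pt_threshold)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("alpha, N0, V_ep, r_p, sigma_p, T, R_gas, F_const, pt_threshold must be > 0")
  if (!is.finite(q) || q <= 1) stop("q must be > 1")
  if (!is.finite(n_rel) || n_rel <= 0 || n_rel >= 1)
    stop("n_rel must lie strictly between 0 and 1")
  if (!is.finite(w0) || w0 <= 0) stop("w0 must be > 0")
  structure(list(alpha = alpha, N0 = N0, V_ep = V_ep, q = q, r_p = r_p,
                 w0 = w0, sigma_p = sigma_p, n_rel = n_rel, T = T,
                 R_gas = R_gas, F_const = F_const,
                 pt_threshold = pt_threshold),
            class = "ep_model")
}

#' Full cell model parameter set
#'
#' Bundles geometry, the passive properties of the five compartments, the
#' shared membrane Debye dispersion, and the electroporation constants. The
#' defaults reproduce the published double-shelled cell parameter table
#' exactly (SI units). Both membranes share one Debye relaxation set; only
#' their static conductivities differ.
#'
#' @param geometry A [cell_geometry()].
#' @param extracellular,cytoplasm,nucleoplasm Passive electrolyte
#'   compartments ([passive_material()]).
#' @param plasma_membrane_static,nuclear_membrane_static Static (low
#'   frequency) membrane properties ([passive_material()]); the conductivity
#'   is always taken from here, the permittivity is used whenever dispersion
#'   is disabled.
#' @param membrane_debye Shared membrane [debye_material()].
#' @param ep An [ep_model()].
#' @return An object of class `cell_model_params`.
#' @export
cell_model_params <- function(geometry = cell_geometry(),
                              extracellular = passive_material(0.55, 67),
                              plasma_membrane_static = passive_material(1.1e-7, 5),
                              cytoplasm = passive_material(0.55, 67),
                              nuclear_membrane_static = passive_material(1.1e-5, 5),
                              nucleoplasm = passive_material(0.55, 67),
                              membrane_debye = debye_material(),
                              ep = ep_model()) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(extracellular, "passive_material"),
            inherits(plasma_membrane_static, "passive_material"),
            inherits(cytoplasm, "passive_material"),
            inherits(nuclear_membrane_static, "passive_material"),
            inherits(nucleoplasm, "passive_material"),
            inherits(membrane_debye, "debye_material"),
            inherits(ep, "ep_model"))
  p <- structure(list(
    geometry = geometry,
    extracellular = extracellular,
    plasma_membrane_static = plasma_membrane_static,
    cytoplasm = cytoplasm,
    nuclear_membrane_static = nuclear_membrane_static,
    nucleoplasm = nucleoplasm,
    membrane_debye = membrane_debye,
    ep = ep,
    eps_vacuum = EPS_VACUUM
  ), class = "cell_model_params")
  validate_cell_model_params(p)
  p
}

validate_cell_model_params <- function(p, tol = 0.02) {
  # the Debye static limit must agree with the declared static relative
  # permittivity of the membranes (consistency of the two descriptions)
  er_static <- static_relative_permittivity(p$membrane_debye)
  er_decl <- p$plasma_membrane_static$relative_permittivity
  if (abs(er_static - er_decl) / er_decl > tol)
    stop(sprintf(paste0("Debye static limit (%.3f) and declared static relative ",
                        "permittivity (%.3f) disagree by more than %.0f%%"),
                 er_static, er_decl, 100 * tol))
  invisible(p)
}

#' Default cell model parameters
#'
#' The full published parameter set of the double-shelled cell in SI units:
#' a 5 um cell with a 10 nm plasma membrane, a 2.5 um nucleus with a 10 nm
#' nuclear membrane, electrolyte compartments at 0.55 S/m and relative
#' permittivity 67, membranes at relative permittivity 5 with conductivities
#' 1.1e-7 S/m (plasma) and 1.1e-5 S/m (nuclear), one shared second-order
#' Debye relaxation set, and the asymptotic electroporation constants.
#'
#' @return A [cell_model_params()] object.
#' @export
default_parameters <- function() cell_model_params()

#' @export
print.cell_model_params <- function(x, ...) {
  g <- x$geometry
  cat("Double-shelled cell model parameters\n")
  cat(sprintf("  cell radius          %g um (membrane %g nm)\n",
              g$cell_radius * 1e6, g$plasma_membrane_thickness * 1e9))
  if (g$has_nucleus)
    cat(sprintf("  nuclear radius       %g um (membrane %g nm)\n",
                g$nuclear_radius * 1e6, g$nuclear_membrane_thickness * 1e9))
  else cat("  nucleus              absent (single-shelled)\n")
  cat(sprintf("  sigma e/c/n          %g / %g / %g S/m\n",
              x$extracellular$conductivity, x$cytoplasm$conductivity,
              x$nucleoplasm$conductivity))
  cat(sprintf("  sigma_m0 pm/nm       %g / %g S/m\n",
              x$plasma_membrane_static$conductivity,
              x$nuclear_membrane_static$conductivity))
  cat(sprintf("  membrane eps_r       %g static, %.2f at f -> Inf\n",
              x$plasma_membrane_static$relative_permittivity,
              x$membrane_debye$eps_inf / EPS_VACUUM))
  cat(sprintf("  EP: alpha %g, N0 %g, V_ep %g V, q %g\n",
              x$ep$alpha, x$ep$N0, x$ep$V_ep, x$ep$q))
  invisible(x)
}

# --- configuration file I/O ---------------------------------------------

#' Write a cell model parameter set to a YAML configuration file
#'
#' The file mirrors the nested structure of [cell_model_params()]; all values
#' are SI. It can be edited by hand and read back with [read_cell_model()].
#'
#' @param params A [cell_model_params()] object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_cell_model <- function(params, path) {
  stopifnot(inherits(params, "cell_model_params"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  obj <- strip(params)
  obj$eps_vacuum <- NULL
  header <- paste(
    "# Cell model parameters (all values SI: m, S/m, F/m, s, V, K).",
    "# geometry: radii/thicknesses in metres; has_nucleus toggles the inner shell.",
    "# *_static compartments: conductivity (S/m), relative_permittivity (-).",
    "# membrane_debye: absolute permittivities (F/m) and relaxation times (s).",
    "# ep: asymptotic electroporation constants (see ?ep_model for units).",
    sep = "\n")
  writeLines(c(header, yaml::as.yaml(obj)), path)
  invisible(path)
}

#' Read a cell model parameter set from a YAML configuration file
#'
#' @param path File written by [write_cell_model()] (or hand-edited in the
#'   same layout). Values are validated against the model invariants.
#' @return A [cell_model_params()] object.
#' @export
read_cell_model <- function(path) {
  obj <- yaml::read_yaml(path)
  pm <- function(x) passive_material(x$conductivity, x$relative_permittivity)
  cell_model_params(
    geometry = do.call(cell_geometry, obj$geometry),
    extracellular = pm(obj$extracellular),
    plasma_membrane_static = pm(obj$plasma_membrane_static),
    cytoplasm = pm(obj$cytoplasm),
    nuclear_membrane_static = pm(obj$nuclear_membrane_static),
    nucleoplasm = pm(obj$nucleoplasm),
    membrane_debye = do.call(debye_material, obj$membrane_debye),
    ep = do.call(ep_model, obj$ep))
}
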