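# Coupled quasi-static field / dispersion / electroporation solver.
#
# Each time step solves the charge-conservation equation
#   div( sigma E + dD/dt ) = 0,   E = -grad phi,
# on the axisymmetric finite-volume mesh, with D = eps0 E + P. In the
# dispersive membranes P carries the two Debye relaxation branches advanced
# by their exact exponential update (field linear over the step); everywhere
# else D = eps E instantaneously. Time discretization of dD/dt is backward
# Euler on the first step and BDF2 afterwards (A-stable, second order).
# Faces between different materials are treated as two half-cells in series,
# which yields the harmonic-mean conductance and keeps each half's
# displacement history on its own side of the interface.
#
# With electroporation enabled, the pore density N(theta) on the plasma
# membrane and the resulting bulk membrane conductivity are updated inside a
# short fixed-point loop per step (pore ODE via exponential integrator with
# the midpoint transmembrane potential).

#' Solver options
#'
#' @param dispersive Apply second-order Debye dispersion to both membranes.
#' @param electroporate Solve the pore-density equation on the plasma
#'   membrane and feed the pore conductivity back into the field problem.
#' @param nuclear_ep Also electroporate the nuclear membrane (off by
#'   default; the reference configuration porates the plasma membrane only).
#' @param include_nucleus Keep the nucleus (double-shelled model); `FALSE`
#'   reduces to the single-shelled cell.
#' @param dt Time step (s). The default resolves the fastest membrane
#'   relaxation time (0.46 ns) more than twentyfold and the 1 ns pulse edges
#'   fiftyfold.
#' @param t_end Simulation horizon (s); default [pulse_horizon()] of the
#'   drive.
#' @param probe_angles Probe angles in degrees from the electrode-facing
#'   pole (default `A1..A7` = 0, 15, ..., 90).
#' @param profile_times Times (s) at which spatial profiles are recorded.
#' @param dispersion_drive Field driving the membrane Debye polarization.
#'   `"applied"` (reference convention): the polarization vector on both
#'   membranes follows the nominal applied field along the field axis and
#'   the membranes carry bare vacuum displacement, so the effective membrane
#'   capacitance during fast transients collapses to `eps0/d`. `"local"`:
#'   each polarization branch is driven by the local in-membrane field
#'   (fully self-consistent; reproduces the phasor solution exactly in the
#'   linear regime). See the methods vignette for why both exist.
#' @param max_sweeps Fixed-point sweeps per step for the nonlinear
#'   electroporation coupling.
#' @param tol Relative TMP tolerance ending the fixed-point loop.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(dispersive = TRUE, electroporate = TRUE,
                           nuclear_ep = FALSE, include_nucleus = TRUE,
                           dt = 0.02e-9, t_end = NULL,
                           probe_angles = seq(0, 90, by = 15),
                           profile_times = NULL,
                           dispersion_drive = c("applied", "local"),
                           max_sweeps = 3L, tol = 1e-6) {
  if (dt <= 0) stop("dt must be > 0")
  structure(list(dispersive = dispersive, electroporate = electroporate,
                 nuclear_ep = nuclear_ep, include_nucleus = include_nucleus,
                 dt = dt, t_end = t_end, probe_angles = probe_angles,
                 profile_times = profile_times,
                 dispersion_drive = match.arg(dispersion_drive),
                 max_sweeps = as.integer(max_sweeps), tol = tol),
            class = "solver_options")
}

# even-symmetric interpolation of per-theta-cell values to arbitrary angles
# (deg); values are even about 0 and 180 degrees
interp_theta <- function(values, theta_centers, target_deg) {
  thd <- theta_centers * 180 / pi
  # extend evenly past both poles so approx() can reach 0 and 180 exactly
  x <- c(-thd[1], thd, 360 - thd[length(thd)])
  y <- c(values[1], values, values[length(values)])
  stats::approx(x, y, xout = target_deg, rule = 2)$y
}

#' Time-domain solve of the coupled cell model
#'
#' Marches the coupled field / dispersion / electroporation system for a
#' trapezoidal pulse train and extracts transmembrane potential (TMP), pore
#' density and membrane conductivity at the probe angles, plus spatial
#' profiles at requested times.
#'
#' @param params A [cell_model_params()].
#' @param pulse A [pulse_train()] (or `NULL` if `field_fun` is given).
#' @param opts A [solver_options()].
#' @param mesh Optional prebuilt [build_mesh()] mesh (must match the
#'   geometry implied by `opts$include_nucleus`).
#' @param spec A [mesh_spec()] used when `mesh` is `NULL`.
#' @param field_fun Optional function `t -> applied field (V/m)` overriding
#'   the pulse train (used for single-tone verification drives).
#' @return An object of class `nspef_run`; see Details.
#' @details The returned list contains `time` (s), `probe_angles` (deg),
#'   matrices `tmp`, `N`, `sigma_m` (time x probe) for the plasma membrane,
#'   `tmp_nuclear` (time x probe), the full per-theta-cell fields
#'   `tmp_theta`, `N_theta`, `sigma_theta`, `P_mem_theta` (physical membrane
#'   polarization, C/m^2), the applied-field polarization diagnostic
#'   `P_applied` (membrane Debye law driven by the nominal applied field),
#'   `N_max_theta` (max-over-time pore density per theta cell), spatial
#'   `profiles`, and the resolved configuration.
#' @export
solve_time_domain <- function(params, pulse, opts = solver_options(),
                              mesh = NULL, spec = mesh_spec(),
                              field_fun = NULL) {
  stopifnot(inherits(params, "cell_model_params"))
  geom <- params$geometry
  geom$has_nucleus <- opts$include_nucleus
  if (is.null(mesh)) mesh <- build_mesh(geom, spec)
  else if (!identical(mesh$geometry$has_nucleus, opts$include_nucleus))
    stop("supplied mesh does not match opts$include_nucleus")
  if (is.null(field_fun)) {
    stopifnot(inherits(pulse, "pulse_train"))
    field_fun <- function(t) pulse_field(pulse, t)
  } else {
    ff <- field_fun
    field_fun <- function(t) {  # tolerate non-vectorized drive functions
      out <- ff(t)
      if (length(out) == length(t)) out else vapply(t, function(x) ff(x)[1], 0)
    }
  }
  t_end <- if (!is.null(opts$t_end)) opts$t_end else pulse_horizon(pulse)
  dt <- opts$dt
  nsteps <- as.integer(ceiling(t_end / dt - 1e-9))
  times <- dt * (0:nsteps)

  e0 <- params$eps_vacuum
  nr <- mesh$nr; nt <- mesh$nt; n <- mesh$n_cells
  mat_r <- mesh$mat_r
  band_cell <- rep(seq_len(nr), nt)
  th_c <- mesh$theta_centers
  cos_bc <- cos(th_c)
  Rout <- mesh$r_faces[nr + 1]

  # per-band static material tables
  sigma_band <- vapply(mat_r, function(m) switch(m,
    extracellular = params$extracellular$conductivity,
    plasma_membrane = params$plasma_membrane_static$conductivity,
    cytoplasm = params$cytoplasm$conductivity,
    nuclear_membrane = params$nuclear_membrane_static$conductivity,
    nucleoplasm = params$nucleoplasm$conductivity), 0)
  eps_band <- vapply(mat_r, function(m) e0 * switch(m,
    extracellular = params$extracellular$relative_permittivity,
    plasma_membrane = params$plasma_membrane_static$relative_permittivity,
    cytoplasm = params$cytoplasm$relative_permittivity,
    nuclear_membrane = params$nuclear_membrane_static$relative_permittivity,
    nucleoplasm = params$nucleoplasm$relative_permittivity), 0)
  is_disp_band <- opts$dispersive & mat_r %in% c("plasma_membrane", "nuclear_membrane")

  md <- params$membrane_debye
  bc1 <- debye_branch_coefs(dt, md$tau_1, md$delta_eps_1)
  bc2 <- debye_branch_coefs(dt, md$tau_2, md$delta_eps_2)
  applied_drive <- opts$dispersive && opts$dispersion_drive == "applied"
  eps_hat_band <- if (applied_drive) ifelse(is_disp_band, e0, eps_band)
                  else ifelse(is_disp_band, md$eps_inf + bc1$a + bc2$a, eps_band)

  # ---- concatenated face tables (interior faces then boundary) ----------
  fr <- mesh$faces$radial; fp <- mesh$faces$polar; fb <- mesh$faces$boundary
  c1 <- c(fr$c1, fp$c1); c2 <- c(fr$c2, fp$c2)
  ar <- c(fr$area, fp$area)
  d1 <- c(fr$d1, fp$d1); d2 <- c(fr$d2, fp$d2)
  nfi <- length(c1)
  b1 <- band_cell[c1]; b2 <- band_cell[c2]
  mem1 <- is_disp_band[b1]; mem2 <- is_disp_band[b2]
  bb1 <- band_cell[fb$c1]
  # component of the field-axis unit vector along each face normal
  # (radial faces: cos theta of the cell row; polar faces: -sin theta_face)
  dirfac <- c(cos(th_c[fr$jj]), -sin(mesh$theta_faces[fp$jj + 1L]))

  # triplet pattern: (c1,c1,+g), (c2,c2,+g), (c2,c1,-g), boundary (c,c,+g)
  trip_i <- c(c1, c2, c2, fb$c1)
  trip_j <- c(c1, c2, c1, fb$c1)

  # radial-face row lookup for membrane interface/midpoint faces
  face_row <- function(i, j) (j - 1L) * (nr - 1L) + i
  i_pm <- mesh$i_pm
  rows_pm_in <- face_row(i_pm[1] - 1L, seq_len(nt))
  rows_pm_out <- face_row(i_pm[length(i_pm)], seq_len(nt))
  rows_pm_mid <- face_row(i_pm[1], seq_len(nt))
  has_nuc <- geom$has_nucleus
  if (has_nuc) {
    i_nm <- mesh$i_nm
    rows_nm_in <- face_row(i_nm[1] - 1L, seq_len(nt))
    rows_nm_out <- face_row(i_nm[length(i_nm)], seq_len(nt))
  }
  pm_cells <- as.vector(outer(i_pm, (seq_len(nt) - 1L) * nr, "+"))
  if (has_nuc) nm_cells <- as.vector(outer(i_nm, (seq_len(nt) - 1L) * nr, "+"))

  # ---- state -------------------------------------------------------------
  phi <- numeric(n)
  E1 <- E2 <- D1 <- D2 <- Dp1 <- Dp2 <- numeric(nfi)
  P11 <- P21 <- P12 <- P22 <- numeric(nfi)   # branch1/2 on side1/2
  Eb <- Db <- Dpb <- numeric(nt)             # boundary halves
  ep <- params$ep
  N_pm <- rep(ep$N0, nt)
  N_nm <- rep(ep$N0, nt)
  sig_geom <- pi * ep$r_p^2 * ep$sigma_p
  sigma_pm0 <- params$plasma_membrane_static$conductivity
  sigma_nm0 <- params$nuclear_membrane_static$conductivity
  tmp_pm <- numeric(nt); tmp_nm <- numeric(nt)
  sigma_pm_theta <- membrane_conductivity(N_pm, tmp_pm, ep, sigma_pm0)
  sigma_nm_theta <- if (opts$nuclear_ep)
    membrane_conductivity(N_nm, tmp_nm, ep, sigma_nm0) else rep(sigma_nm0, nt)

  # ---- recorded series ---------------------------------------------------
  rec_tmp <- matrix(0, nsteps + 1L, nt)
  rec_tmp_nm <- matrix(0, nsteps + 1L, nt)
  rec_N <- matrix(ep$N0, nsteps + 1L, nt)
  rec_sig <- matrix(sigma_pm_theta[1], nsteps + 1L, nt)
  rec_Pmem <- matrix(0, nsteps + 1L, nt)
  N_max <- N_pm
  sweeps_used <- integer(nsteps)

  ep_on <- isTRUE(opts$electroporate)
  refactor_every_step <- ep_on || isTRUE(opts$nuclear_ep)

  sys_build <- function(scheme, sigma_cell) {
    kcell <- sigma_cell + scheme$ct * eps_hat_band[band_cell]
    k1 <- kcell[c1]; k2 <- kcell[c2]; kb <- kcell[fb$c1]
    rho1 <- d1 / k1; rho2 <- d2 / k2; rhob <- fb$d1 / kb
    g <- ar / (rho1 + rho2)
    gb <- fb$area / rhob
    A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = c(g, g, -g, gb),
                              dims = c(n, n), symmetric = TRUE)
    list(k1 = k1, k2 = k2, kb = kb, rho1 = rho1, rho2 = rho2, rhob = rhob,
         g = g, gb = gb, ch = Matrix::Cholesky(A, LDL = FALSE))
  }

  sys_solve <- function(sys, s1, s2, sb, phibc) {
    bsrc <- ar * (sys$rho1 * s1 + sys$rho2 * s2) / (sys$rho1 + sys$rho2)
    bb <- sys$gb * phibc - fb$area * sb
    bvec <- as.vector(Matrix::sparseMatrix(
      i = c(c1, c2, fb$c1), j = rep(1L, 2L * nfi + nt),
      x = c(-bsrc, bsrc, bb), dims = c(n, 1L)))
    phi <- as.vector(Matrix::solve(sys$ch, bvec))
    dphi <- phi[c1] - phi[c2]
    J <- (dphi + sys$rho1 * s1 + sys$rho2 * s2) / (sys$rho1 + sys$rho2)
    Jb <- (phi[fb$c1] - phibc + sys$rhob * sb) / sys$rhob
    list(phi = phi,
         E1 = (J - s1) / sys$k1, E2 = (J - s2) / sys$k2,
         Eb = (Jb - sb) / sys$kb)
  }

  half_hist <- function(scheme, Papp_next) {
    # history source s_h and the part of D^{n+1} not proportional to E^{n+1}
    if (applied_drive) {
      H1 <- ifelse(mem1, Papp_next * dirfac, 0)
      H2 <- ifelse(mem2, Papp_next * dirfac, 0)
    } else {
      H1 <- ifelse(mem1, (bc1$b0 + bc2$b0) * E1 + bc1$ek * P11 + bc2$ek * P21, 0)
      H2 <- ifelse(mem2, (bc1$b0 + bc2$b0) * E2 + bc1$ek * P12 + bc2$ek * P22, 0)
    }
    Hb <- numeric(nt)  # extracellular boundary is never dispersive
    if (scheme$order == 1L) {
      list(s1 = (H1 - D1) / dt, s2 = (H2 - D2) / dt, sb = (Hb - Db) / dt,
           H1 = H1, H2 = H2)
    } else {
      list(s1 = (3 * H1 - 4 * D1 + Dp1) / (2 * dt),
           s2 = (3 * H2 - 4 * D2 + Dp2) / (2 * dt),
           sb = (3 * Hb - 4 * Db + Dpb) / (2 * dt),
           H1 = H1, H2 = H2)
    }
  }

  extract_tmp <- function(sol) {
    phf_out <- sol$phi[c1[rows_pm_out]] - d1[rows_pm_out] * sol$E1[rows_pm_out]
    phf_in <- sol$phi[c1[rows_pm_in]] - d1[rows_pm_in] * sol$E1[rows_pm_in]
    tmp <- phf_out - phf_in
    if (has_nuc) {
      nhf_out <- sol$phi[c1[rows_nm_out]] - d1[rows_nm_out] * sol$E1[rows_nm_out]
      nhf_in <- sol$phi[c1[rows_nm_in]] - d1[rows_nm_in] * sol$E1[rows_nm_in]
      list(pm = tmp, nm = nhf_out - nhf_in)
    } else list(pm = tmp, nm = rep(0, nt))
  }

  sigma_cell_of <- function(spm, snm) {
    s <- sigma_band[band_cell]
    s[pm_cells] <- rep(spm, each = length(i_pm))
    if (has_nuc) s[nm_cells] <- rep(snm, each = length(mesh$i_nm))
    s
  }

  sys <- NULL
  Pa1 <- Pa2 <- 0  # applied-field Debye branches (scalar, shared by all faces)
  for (step in seq_len(nsteps)) {
    scheme <- if (step == 1L) list(order = 1L, ct = 1 / dt)
              else list(order = 2L, ct = 1.5 / dt)
    if (step <= 2L) sys <- NULL  # time-derivative coefficient changes
    Papp_next <- 0
    if (applied_drive) {
      Ea0 <- field_fun(times[step]); Ea1 <- field_fun(times[step + 1L])
      Pa1 <- debye_branch_step(Pa1, Ea0, Ea1, dt, md$tau_1, md$delta_eps_1)
      Pa2 <- debye_branch_step(Pa2, Ea0, Ea1, dt, md$tau_2, md$delta_eps_2)
      Papp_next <- (md$eps_inf - e0) * Ea1 + Pa1 + Pa2
    }
    hist <- half_hist(scheme, Papp_next)
    phibc <- field_fun(times[step + 1L]) * Rout * cos_bc
    tmp_prev <- tmp_pm; tmp_nm_prev <- tmp_nm
    tmp_guess <- tmp_pm; tmp_nm_guess <- tmp_nm
    N_try <- N_pm; Nn_try <- N_nm
    for (sw in seq_len(if (refactor_every_step) opts$max_sweeps else 1L)) {
      if (ep_on) {
        N_try <- step_pore_density(N_pm, (tmp_prev + tmp_guess) / 2, dt, ep)
        sigma_pm_theta <- membrane_conductivity(N_try, tmp_guess, ep, sigma_pm0)
      }
      if (opts$nuclear_ep) {
        Nn_try <- step_pore_density(N_nm, (tmp_nm_prev + tmp_nm_guess) / 2, dt, ep)
        sigma_nm_theta <- membrane_conductivity(Nn_try, tmp_nm_guess, ep, sigma_nm0)
      }
      if (refactor_every_step || is.null(sys))
        sys <- sys_build(scheme, sigma_cell_of(sigma_pm_theta, sigma_nm_theta))
      sol <- sys_solve(sys, hist$s1, hist$s2, hist$sb, phibc)
      tm <- extract_tmp(sol)
      dmax <- max(abs(tm$pm - tmp_guess)) / max(max(abs(tm$pm)), 1e-12)
      tmp_guess <- tm$pm; tmp_nm_guess <- tm$nm
      if (!refactor_every_step || dmax < opts$tol) break
    }
    sweeps_used[step] <- sw
    tmp_pm <- tmp_guess; tmp_nm <- tmp_nm_guess
    N_pm <- N_try; N_nm <- Nn_try
    N_max <- pmax(N_max, N_pm)

    # commit displacement / polarization state
    Dp1 <- D1; Dp2 <- D2; Dpb <- Db
    if (applied_drive) {
      D1 <- ifelse(mem1, e0 * sol$E1 + Papp_next * dirfac, eps_band[b1] * sol$E1)
      D2 <- ifelse(mem2, e0 * sol$E2 + Papp_next * dirfac, eps_band[b2] * sol$E2)
    } else {
      newP11 <- ifelse(mem1, bc1$a * sol$E1 + bc1$b0 * E1 + bc1$ek * P11, 0)
      newP21 <- ifelse(mem1, bc2$a * sol$E1 + bc2$b0 * E1 + bc2$ek * P21, 0)
      newP12 <- ifelse(mem2, bc1$a * sol$E2 + bc1$b0 * E2 + bc1$ek * P12, 0)
      newP22 <- ifelse(mem2, bc2$a * sol$E2 + bc2$b0 * E2 + bc2$ek * P22, 0)
      D1 <- ifelse(mem1, md$eps_inf * sol$E1 + newP11 + newP21,
                   eps_band[b1] * sol$E1)
      D2 <- ifelse(mem2, md$eps_inf * sol$E2 + newP12 + newP22,
                   eps_band[b2] * sol$E2)
      P11 <- newP11; P21 <- newP21; P12 <- newP12; P22 <- newP22
    }
    Db <- eps_band[bb1] * sol$Eb
    E1 <- sol$E1; E2 <- sol$E2; Eb <- sol$Eb
    phi <- sol$phi

    k <- step + 1L
    rec_tmp[k, ] <- tmp_pm
    rec_tmp_nm[k, ] <- tmp_nm
    rec_N[k, ] <- N_pm
    rec_sig[k, ] <- if (ep_on) sigma_pm_theta else rep(sigma_pm0, nt)
    rec_Pmem[k, ] <- if (applied_drive) Papp_next * cos(th_c)
      else if (opts$dispersive)
        (md$eps_inf - e0) * E1[rows_pm_mid] + P11[rows_pm_mid] + P21[rows_pm_mid]
      else (eps_band[b1[rows_pm_mid]] - e0) * E1[rows_pm_mid]
  }

  E_applied <- field_fun(times)
  P_applied <- if (opts$dispersive) polarization_response(E_applied, times, md)
               else (eps_band[mesh$i_pm[1]] - e0) * E_applied

  pa <- opts$probe_angles
  probe_mat <- function(M) {
    out <- matrix(0, nrow(M), length(pa))
    for (r in seq_len(nrow(M))) out[r, ] <- interp_theta(M[r, ], th_c, pa)
    colnames(out) <- sprintf("A%d", seq_along(pa))
    out
  }
  profiles <- NULL
  if (!is.null(opts$profile_times)) {
    profiles <- lapply(opts$profile_times, function(tp) {
      k <- which.min(abs(times - tp))
      data.frame(theta_deg = th_c * 180 / pi, tmp = rec_tmp[k, ],
                 N = rec_N[k, ], sigma_m = rec_sig[k, ],
                 time = times[k])
    })
  }

  structure(list(
    time = times, probe_angles = pa,
    tmp = probe_mat(rec_tmp), tmp_nuclear = probe_mat(rec_tmp_nm),
    N = probe_mat(rec_N), sigma_m = probe_mat(rec_sig),
    P_mem = probe_mat(rec_Pmem),
    tmp_theta = rec_tmp, N_theta = rec_N, sigma_theta = rec_sig,
    P_mem_theta = rec_Pmem, N_max_theta = N_max,
    P_applied = P_applied, E_applied = E_applied,
    theta_centers_deg = th_c * 180 / pi,
    profiles = profiles, sweeps = sweeps_used,
    params = params, pulse = if (is.null(pulse)) NULL else pulse,
    opts = opts, mesh = mesh), class = "nspef_run")
}

#' Static (DC conduction) solve
#'
#' Solves the pure conduction problem (no displacement currents) for a
#' constant applied field; used for mesh verification against the layered
#' sphere solution.
#'
#' @param params A [cell_model_params()].
#' @param E0 Applied field (V/m).
#' @param mesh A [build_mesh()] mesh (or `NULL` to build from `spec`).
#' @param spec A [mesh_spec()].
#' @param include_nucleus Logical.
#' @return List with `tmp_theta` (TMP per theta cell, V), `theta_centers_deg`
#'   and the potential vector `phi`.
#' @export
solve_static_field <- function(params, E0 = 1e5, mesh = NULL,
                               spec = mesh_spec(), include_nucleus = TRUE) {
  opts <- solver_options(dispersive = FALSE, electroporate = FALSE,
                         include_nucleus = include_nucleus,
                         dt = 1, t_end = 2, probe_angles = seq(0, 90, 15))
  # two huge steps of the transient scheme: with dt far beyond every
  # relaxation time the displacement terms vanish and the solve is DC
  run <- solve_time_domain(params, pulse = NULL, opts = opts, mesh = mesh,
                           spec = spec, field_fun = function(t) E0)
  list(tmp_theta = run$tmp_theta[nrow(run$tmp_theta), ],
       theta_centers_deg = run$theta_centers_deg,
       tmp_probes = run$tmp[nrow(run$tmp), ])
}

#' Angular extent of the electroporated cap
#'
#' Largest contiguous angle from the electrode-facing pole over which the
#' maximum-over-time pore density meets the electroporation threshold.
#'
#' @param run An `nspef_run` from [solve_time_domain()] (or a list with
#'   `N_max_theta` and `theta_centers_deg`).
#' @param ep An [ep_model()] supplying `pt_threshold`.
#' @return Extent in degrees (0 if even the pole stays below threshold).
#' @export
classify_electroporated_extent <- function(run, ep) {
  thd <- run$theta_centers_deg
  sel <- thd <= 90 + 1e-9
  above <- run$N_max_theta[sel] >= ep$pt_threshold
  if (!above[1]) return(0)
  k <- which(!above)[1]
  if (is.na(k)) return(90)
  # boundary between last porated and first unporated cell
  (thd[k - 1] + thd[k]) / 2
}

#' Cosine-law misfit of a transmembrane potential profile
#'
#' Least-squares misfit of `TMP(theta)` against `A cos(theta)` over the
#' quarter arc `[0, 90]` degrees, normalized by the fitted amplitude `A`.
#' Small in the linear (unporated) regime; order one once poration flattens
#' the polar cap.
#'
#' @param profile Data frame with columns `theta_deg` and `tmp` (a spatial
#'   profile from [solve_time_domain()]).
#' @return Dimensionless relative root-mean-square misfit.
#' @export
cos_theta_deviation <- function(profile) {
  sel <- profile$theta_deg <= 90 + 1e-9
  th <- profile$theta_deg[sel] * pi / 180
  y <- profile$tmp[sel]
  ct <- cos(th)
  A <- sum(y * ct) / sum(ct^2)
  if (abs(A) < .Machine$double.eps) return(0)
  sqrt(mean((y - A * ct)^2)) / abs(A)
}

#' @export
print.nspef_run <- function(x, ...) {
  cat(sprintf("nsPEF run: %d steps of %.3g ns, %d x %d mesh\n",
              length(x$time) - 1, diff(x$time[1:2]) * 1e9,
              x$mesh$nr, x$mesh$nt))
  cat(sprintf("  modes: dispersion %s, electroporation %s, nucleus %s\n",
              x$opts$dispersive, x$opts$electroporate, x$opts$include_nucleus))
  i1 <- which.max(abs(x$tmp[, 1]))
  cat(sprintf("  peak |TMP| at pole: %.3f V at %.2f ns\n",
              x$tmp[i1, 1], x$time[i1] * 1e9))
  cat(sprintf("  max pore density at pole: %.3g m^-2\n", max(x$N[, 1])))
  invisible(x)
}

#' Write the probe series and profiles of a run to delimited text
#'
#' @param run An `nspef_run`.
#' @param dir Output directory (created if missing). Writes `probes.tsv`
#'   (time series at the probe angles), `profiles.tsv` (stacked spatial
#'   profiles, if any) and `config.yaml` (resolved parameters).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pa <- run$probe_angles
  d <- data.frame(t = run$time,
                  E_applied = run$E_applied, P_applied = run$P_applied)
  add <- function(d, M, nm) {
    colnames(M) <- sprintf("%s_A%d", nm, seq_along(pa)); cbind(d, M)
  }
  d <- add(d, run$tmp, "tmp"); d <- add(d, run$N, "N")
  d <- add(d, run$sigma_m, "sigma")
  utils::write.table(d, file.path(dir, "probes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(run$profiles))
    utils::write.table(do.call(rbind, run$profiles),
                       file.path(dir, "profiles.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  write_cell_model(run$params, file.path(dir, "config.yaml"))
  invisible(dir)
}
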