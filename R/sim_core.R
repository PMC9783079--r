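## sim_core: electrochemical system definitions and the voltammogram simulator.

#' Define an electrochemical system
#'
#' Bundles a mechanism identifier, its kinetic/thermodynamic parameters and the
#' scan protocol into a single system description consumed by [simulate_cv()].
#' The reduction convention A + e- -> B is used throughout; for ECE the second
#' couple must be thermodynamically more facile, `E0_2 >= E0_1 + 0.1` V.
#'
#' @param mechanism One of `"E"`, `"EC"`, `"CE"`, `"ECE"`, `"DISP1"` (or 1..5).
#' @param E0_1 Standard potential of the first couple (V).
#' @param E0_2 Standard potential of the second couple (V, ECE only).
#' @param k0 Standard interfacial rate constant (cm/s).
#' @param alpha Transfer coefficient, in (0, 1).
#' @param kf,kb Forward/backward homogeneous rate constants of the C step (1/s);
#'   `kb = 0` encodes an irreversible C step.
#' @param ki Irreversible C-step rate constant for ECE/DISP1 (1/s).
#' @param kd Disproportionation rate constant, DISP1 only (1/(M s)).
#' @param D Common diffusion coefficient (cm^2/s).
#' @param C_bulk Bulk concentration of the initial species pool (mol/cm^3).
#' @param Cdl Double-layer capacitance (F/cm^2).
#' @param v_list Scan rates (V/s), 1 to 6 strictly increasing values.
#' @param E_start,E_vertex Potential window endpoints (V).
#' @param n_cycles Number of consecutive cycles (>= 2 so the analysis cycle exists).
#' @param T Temperature (K).
#' @param electrode_area Electrode area (cm^2); currents are densities, so this
#'   only matters when scaling to absolute currents.
#'
#' @return An object of class `cv_system`.
#' @export
#' @examples
#' sys <- system_spec("E", k0 = 1, v_list = c(0.1, 0.5))
#' sys$mechanism
system_spec <- function(mechanism, E0_1 = 0, E0_2 = NULL, k0 = 0.01, alpha = 0.5,
                        kf = 0, kb = 0, ki = 0, kd = 0,
                        D = 1e-5, C_bulk = 1e-6, Cdl = 2e-5,
                        v_list = 0.1, E_start = E0_1 + 0.5, E_vertex = E0_1 - 0.5,
                        n_cycles = 3L, T = 298.15, electrode_area = 1) {
  mech <- .mech_id(mechanism)
  stopifnot(k0 >= 0, kf >= 0, kb >= 0, ki >= 0, kd >= 0, D > 0, C_bulk > 0,
            Cdl >= 0, alpha > 0, alpha < 1, n_cycles >= 2, T > 0)
  if (length(v_list) < 1L || length(v_list) > 6L)
    stop("v_list must contain 1 to 6 scan rates")
  if (any(diff(v_list) <= 0)) stop("v_list must be strictly increasing")
  if (any(v_list <= 0)) stop("scan rates must be positive")
  if (E_start == E_vertex) stop("E_start and E_vertex must differ")
  if (mech == 4L) {
    if (is.null(E0_2)) E0_2 <- E0_1 + 0.3
    if (E0_2 - E0_1 < 0.1)
      stop("ECE requires E0_2 >= E0_1 + 0.1 V (second transfer more facile)")
  }
  structure(list(
    mechanism = mechanism_levels()[mech], mech_id = mech,
    params = list(E0_1 = E0_1, E0_2 = E0_2, k0 = k0, alpha = alpha,
                  kf = kf, kb = kb, ki = ki, kd = kd,
                  Keq = if (kb > 0) kf / kb else NA_real_,
                  D = D, C_bulk = C_bulk, Cdl = Cdl),
    protocol = list(v_list = as.numeric(v_list), E_start = E_start,
                    E_vertex = E_vertex, n_cycles = as.integer(n_cycles),
                    T = T, electrode_area = electrode_area)
  ), class = "cv_system")
}

#' @export
print.cv_system <- function(x, ...) {
  cat("<cv_system> mechanism:", x$mechanism, "\n")
  cat("  k0 =", x$params$k0, "cm/s, alpha =", x$params$alpha, "\n")
  if (x$mech_id %in% 2:3) cat("  kf =", x$params$kf, "1/s, kb =", x$params$kb, "1/s\n")
  if (x$mech_id %in% 4:5) cat("  ki =", x$params$ki, "1/s\n")
  if (x$mech_id == 5) cat("  kd =", x$params$kd, "1/(M s)\n")
  cat("  v =", paste(signif(x$protocol$v_list, 3), collapse = ", "), "V/s;",
      x$protocol$n_cycles, "cycles\n")
  invisible(x)
}

#' Solver configuration
#'
#' Discretization settings for the finite-difference voltammogram solver: a
#' geometrically expanding spatial grid whose first interval resolves the
#' thinner of the scan diffusion layer and the kinetic reaction layer, and a
#' theta-scheme in time (Crank-Nicolson by default).
#'
#' @param n_space Number of spatial nodes (>= 50).
#' @param n_time_per_cycle Time steps per cycle (>= 200, made even).
#' @param L_factor Domain length as a multiple of `sqrt(D * t_total)` (>= 6).
#' @param scheme `"crank_nicolson"` or `"implicit_euler"`.
#' @param kd_substeps Sub-iterations for the stiff DISP1 bimolecular term.
#' @return An object of class `cv_solver_config`.
#' @export
solver_config <- function(n_space = 200L, n_time_per_cycle = 1000L, L_factor = 6,
                          scheme = c("crank_nicolson", "implicit_euler"),
                          kd_substeps = 10L) {
  scheme <- match.arg(scheme)
  stopifnot(n_space >= 50, n_time_per_cycle >= 200, L_factor >= 6, kd_substeps >= 1)
  structure(list(n_space = as.integer(n_space),
                 n_time_per_cycle = as.integer(n_time_per_cycle),
                 L_factor = L_factor, scheme = scheme,
                 kd_substeps = as.integer(kd_substeps)),
            class = "cv_solver_config")
}

#' Nicholson's dimensionless interfacial rate parameter
#'
#' `psi = k0 / sqrt(pi * D * F * v / (R * T))`; values above ~7 indicate an
#' electrochemically reversible couple, below ~0.3 a strongly quasireversible one.
#'
#' @param k0 Standard rate constant (cm/s).
#' @param D Diffusion coefficient (cm^2/s).
#' @param v Scan rate (V/s).
#' @param T Temperature (K).
#' @return Dimensionless psi.
#' @export
#' @examples
#' nicholson_psi(0.01, 1e-5, 0.1)
nicholson_psi <- function(k0, D, v, T = 298.15) {
  stopifnot(k0 >= 0, D > 0, v > 0, T > 0)
  k0 / sqrt(pi * D * .FARADAY * v / (.RGAS * T))
}

#' Invert Nicholson's psi for the standard rate constant
#'
#' @param psi Dimensionless interfacial rate parameter.
#' @inheritParams nicholson_psi
#' @return k0 in cm/s.
#' @export
k0_from_psi <- function(psi, D, v, T = 298.15) {
  stopifnot(psi >= 0, D > 0, v > 0, T > 0)
  psi * sqrt(pi * D * .FARADAY * v / (.RGAS * T))
}

#' Saveant's dimensionless homogeneous kinetic parameter
#'
#' `lambda = (R * T / F) * kf / v`, measuring the competition between the
#' homogeneous reaction and diffusion; the abscissa of the kinetic zone diagram.
#'
#' @param kf Homogeneous forward rate constant (1/s).
#' @param v Scan rate (V/s).
#' @param T Temperature (K).
#' @return Dimensionless lambda.
#' @export
#' @examples
#' saveant_lambda(10, 0.1)
saveant_lambda <- function(kf, v, T = 298.15) {
  stopifnot(kf >= 0, v > 0, T > 0)
  (.RGAS * T / .FARADAY) * kf / v
}

#' Homogeneous reaction rate terms for each mechanism
#'
#' Mass-action rates `R_s` for each species of a mechanism, given a vector of
#' concentrations. Species orderings: E `(A, B)`; EC `(A, B, P)`; CE `(Y, A, B)`;
#' ECE `(A, B, C, D)`; DISP1 `(A, B, C, P)`.
#'
#' @param mechanism Mechanism identifier.
#' @param params Named list with any of `kf`, `kb`, `ki`, `kd` (1/s; kd in 1/(M s)).
#' @param concentrations Numeric vector matching the mechanism's species count.
#'   Units mol/cm^3.
#' @return Numeric vector of rates `dC/dt` (mol/cm^3/s) from homogeneous steps.
#' @export
#' @examples
#' mechanism_rate_terms("EC", list(kf = 1, kb = 0), c(0, 2, 0))
mechanism_rate_terms <- function(mechanism, params, concentrations) {
  mech <- .mech_id(mechanism)
  nsp <- c(2L, 3L, 3L, 4L, 4L)[mech]
  if (length(concentrations) != nsp)
    stop("expected ", nsp, " concentrations for ", mechanism_levels()[mech])
  if (any(concentrations < 0)) stop("negative concentrations")
  kf <- params$kf %||% 0; kb <- params$kb %||% 0
  ki <- params$ki %||% 0; kd <- params$kd %||% 0
  x <- concentrations
  switch(mech,
    rep(0, 2),
    { r <- kf * x[2] - kb * x[3]; c(0, -r, r) },                   # EC: B <-> P
    { r <- kf * x[1] - kb * x[2]; c(-r, r, 0) },                   # CE: Y <-> A
    { r <- ki * x[2];             c(0, -r, r, 0) },                # ECE: B -> C
    { r1 <- ki * x[2]                                              # DISP1
      r2 <- (kd * 1000) * x[2] * x[3]                              #  B + C -> A + P
      c(r2, -r1 - r2, r1 - r2, r2) })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one cyclic voltammogram
#'
#' Solves the one-dimensional semi-infinite diffusion-reaction problem for the
#' system's mechanism under a triangular potential sweep and returns the
#' faradaic-plus-capacitive current density. Reductive current is negative.
#'
#' @param system A [system_spec()].
#' @param v Scan rate (V/s). Defaults to the first entry of the system's `v_list`.
#' @param solver A [solver_config()].
#' @param save_conc_every If > 0, store a concentration-profile snapshot every
#'   this many time steps (for diagnostics/conservation checks).
#' @return A `cv_voltammogram`: data.frame with columns `cycle`, `E`, `i`,
#'   `i_far`, `direction`, plus attributes `v`, `min_conc_rel` and (optionally)
#'   `conc`, `conc_t`, `x`.
#' @export
#' @examples
#' sys <- system_spec("E", k0 = 1, Cdl = 0)
#' vg <- simulate_cv(sys, v = 0.1, solver = solver_config(100, 400))
#' range(vg$i)
simulate_cv <- function(system, v = system$protocol$v_list[1],
                        solver = solver_config(), save_conc_every = 0L) {
  stopifnot(inherits(system, "cv_system"), inherits(solver, "cv_solver_config"),
            v > 0)
  res <- simulate_cv_cpp(system$mech_id, system$params, v,
                         system$protocol, unclass(solver),
                         as.integer(save_conc_every))
  df <- data.frame(cycle = res$cycle, E = res$E,
                   i = res$i_far + res$i_cap, i_far = res$i_far,
                   direction = ifelse(res$direction == 1L, "forward", "reverse"),
                   stringsAsFactors = FALSE)
  attr(df, "v") <- v
  attr(df, "min_conc_rel") <- res$min_conc_rel
  if (save_conc_every > 0) {
    attr(df, "conc") <- res$conc
    attr(df, "conc_t") <- res$conc_t
    attr(df, "x") <- res$x
  }
  class(df) <- c("cv_voltammogram", "data.frame")
  df
}

#' Simulate the multi-scan-rate voltammogram set of a system
#'
#' Runs [simulate_cv()] for every scan rate in the system's protocol.
#'
#' @inheritParams simulate_cv
#' @param label Optional true mechanism label to attach.
#' @return A `cv_voltset`: list with `curves` (one `cv_voltammogram` per scan
#'   rate), `v`, `system` and `label`.
#' @export
simulate_set <- function(system, solver = solver_config(), label = system$mechanism) {
  curves <- lapply(system$protocol$v_list, function(v)
    simulate_cv(system, v = v, solver = solver))
  structure(list(curves = curves, v = system$protocol$v_list,
                 system = system, label = label),
            class = "cv_voltset")
}

#' @export
print.cv_voltset <- function(x, ...) {
  cat("<cv_voltset>", length(x$curves), "scan rate(s):",
      paste(signif(x$v, 3), collapse = ", "), "V/s")
  if (!is.null(x$label)) cat("; label:", x$label)
  cat("\n")
  invisible(x)
}

#' Write a voltammogram set to CSV
#'
#' Long format with header columns `cycle`, `scan_rate_V_per_s`, `E_V`,
#' `i_A_per_cm2`, `direction` (the package's voltammogram exchange schema).
#'
#' @param set A `cv_voltset` (or a single `cv_voltammogram`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_voltset_csv <- function(set, path) {
  if (inherits(set, "cv_voltammogram"))
    set <- structure(list(curves = list(set), v = attr(set, "v")),
                     class = "cv_voltset")
  stopifnot(inherits(set, "cv_voltset"))
  rows <- lapply(seq_along(set$curves), function(j) {
    cu <- set$curves[[j]]
    data.frame(cycle = cu$cycle, scan_rate_V_per_s = set$v[j],
               E_V = cu$E, i_A_per_cm2 = cu$i, direction = cu$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize/restore a system and solver configuration through YAML
#'
#' @param system A [system_spec()].
#' @param solver A [solver_config()].
#' @param path Output YAML path.
#' @return For `write_config_yaml`, `path` invisibly; for `read_config_yaml`,
#'   a list with elements `system` and `solver`.
#' @export
write_config_yaml <- function(system, solver, path) {
  stopifnot(inherits(system, "cv_system"), inherits(solver, "cv_solver_config"))
  yaml::write_yaml(list(
    system = list(mechanism = system$mechanism,
                  params = system$params[!vapply(system$params, is.null, TRUE)],
                  protocol = system$protocol),
    solver = unclass(solver)), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- cfg$system$params; pr <- cfg$system$protocol
  sys <- system_spec(cfg$system$mechanism,
                     E0_1 = p$E0_1, E0_2 = p$E0_2, k0 = p$k0, alpha = p$alpha,
                     kf = p$kf, kb = p$kb, ki = p$ki, kd = p$kd,
                     D = p$D, C_bulk = p$C_bulk, Cdl = p$Cdl,
                     v_list = pr$v_list, E_start = pr$E_start,
                     E_vertex = pr$E_vertex, n_cycles = pr$n_cycles, T = pr$T,
                     electrode_area = pr$electrode_area)
  sol <- solver_config(cfg$solver$n_space, cfg$solver$n_time_per_cycle,
                       cfg$solver$L_factor, cfg$solver$scheme,
                       cfg$solver$kd_substeps)
  list(system = sys, solver = sol)
}
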