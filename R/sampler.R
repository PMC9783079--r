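## sampler: random electrochemically plausible systems, noise injection,
## accessibility sanitization, and labeled-pool construction.

#' Parameter domain for random system sampling
#'
#' Sampling ranges spanning each mechanism's kinetic zone diagram from the pure
#' diffusion to the pure kinetic zone. Interfacial reversibility is drawn
#' log-uniformly over Nicholson's `psi` in `[0.3, 10]` (enforced at the median
#' sampled scan rate), homogeneous kinetics over the Saveant parameter `lambda`
#' in `lambda_range`, equilibrium constants over `Keq_range`.
#'
#' @param psi_range Nicholson psi range, fixed default `c(0.3, 10)`.
#' @param v_range Scan-rate range (V/s), log-uniform draws.
#' @param n_range Integer range for the number of scan rates per system.
#' @param lambda_range Range of the dimensionless homogeneous parameter lambda
#'   at the median scan rate (log-uniform); sets kf (EC/CE) or ki (ECE/DISP1).
#' @param Keq_range Equilibrium-constant range for reversible C steps (log-uniform).
#' @param Cdl_range Double-layer capacitance range (F/cm^2), uniform.
#' @param delta_E0_range `E0_2 - E0_1` range for ECE (V), uniform.
#' @param kd_range DISP1 disproportionation rate-constant range (1/(M s)),
#'   log-uniform; the solver realizes the fast-disproportionation limit.
#' @param alpha_range Transfer-coefficient range, uniform.
#' @param C_bulk,D,T,E0_1 Fixed bulk concentration (mol/cm^3), diffusion
#'   coefficient (cm^2/s), temperature (K) and first standard potential (V).
#' @param window_half Half-width of the potential window around `E0_1` (V).
#' @param n_cycles Simulated cycles per voltammogram.
#' @param min_v_ratio Minimum ratio `v[2]/v[1]` enforced when `n = 2` (default 1,
#'   i.e. no constraint beyond ascending order).
#' @return An object of class `cv_domain`.
#' @export
parameter_domain <- function(psi_range = c(0.3, 10), v_range = c(0.05, 2),
                             n_range = c(1L, 6L), lambda_range = c(1e-2, 1e3),
                             Keq_range = c(1e-3, 1e3), Cdl_range = c(1e-5, 5e-5),
                             delta_E0_range = c(0.1, 0.5), kd_range = c(1e8, 1e10),
                             alpha_range = c(0.3, 0.7),
                             C_bulk = 1e-6, D = 1e-5, T = 298.15, E0_1 = 0,
                             window_half = 0.5, n_cycles = 3L, min_v_ratio = 1) {
  stopifnot(length(psi_range) == 2, all(psi_range > 0), diff(psi_range) > 0,
            all(v_range > 0), diff(v_range) >= 0,
            n_range[1] >= 1, n_range[2] <= 6, n_range[1] <= n_range[2],
            all(lambda_range > 0), all(Keq_range > 0), all(Cdl_range >= 0),
            all(delta_E0_range >= 0.1), all(kd_range > 0),
            all(alpha_range > 0), all(alpha_range < 1),
            C_bulk > 0, D > 0, T > 0, window_half > 0, n_cycles >= 2,
            min_v_ratio >= 1)
  if (diff(v_range) == 0 && n_range[2] > 1)
    stop("empty v_range: cannot draw multiple distinct scan rates")
  structure(as.list(environment()), class = "cv_domain")
}

.runif_log <- function(n, range) 10^stats::runif(n, log10(range[1]), log10(range[2]))

#' Sample one electrochemically plausible system
#'
#' Draws a random [system_spec()] for the given mechanism from a
#' [parameter_domain()]. Nicholson's psi is drawn log-uniformly in `psi_range`
#' and converted to `k0` at the median sampled scan rate; homogeneous rate
#' constants are set from a log-uniform draw of the Saveant lambda at the median
#' scan rate. Deterministic under a fixed R random seed.
#'
#' @param mechanism Mechanism identifier (name or 1..5).
#' @param domain A [parameter_domain()].
#' @param n Optionally force the number of scan rates (otherwise drawn from
#'   `domain$n_range`).
#' @return A [system_spec()].
#' @export
#' @examples
#' set.seed(1)
#' sample_system("EC", parameter_domain())
sample_system <- function(mechanism, domain = parameter_domain(), n = NULL) {
  stopifnot(inherits(domain, "cv_domain"))
  mech <- .mech_id(mechanism)
  if (is.null(n)) n <- sample(domain$n_range[1]:domain$n_range[2], 1L)
  stopifnot(n >= 1, n <= 6)
  v <- sort(.runif_log(n, domain$v_range))
  if (n == 2L && domain$min_v_ratio > 1) {
    while (v[2] / v[1] < domain$min_v_ratio) v <- sort(.runif_log(2L, domain$v_range))
  }
  v_med <- stats::median(v)
  psi <- .runif_log(1L, domain$psi_range)
  k0 <- k0_from_psi(psi, domain$D, v_med, domain$T)
  alpha <- stats::runif(1L, domain$alpha_range[1], domain$alpha_range[2])
  lam <- .runif_log(1L, domain$lambda_range)
  rate <- lam * .FARADAY * v_med / (.RGAS * domain$T)  # 1/s at the median v
  kf <- kb <- ki <- kd <- 0
  E0_2 <- NULL
  if (mech %in% 2:3) {
    Keq <- .runif_log(1L, domain$Keq_range)
    kf <- rate
    kb <- kf / Keq
  } else if (mech == 4L) {
    ki <- rate
    E0_2 <- domain$E0_1 + stats::runif(1L, domain$delta_E0_range[1],
                                       domain$delta_E0_range[2])
  } else if (mech == 5L) {
    ki <- rate
    kd <- .runif_log(1L, domain$kd_range)
  }
  Cdl <- stats::runif(1L, domain$Cdl_range[1], domain$Cdl_range[2])
  system_spec(mech, E0_1 = domain$E0_1, E0_2 = E0_2, k0 = k0, alpha = alpha,
              kf = kf, kb = kb, ki = ki, kd = kd,
              D = domain$D, C_bulk = domain$C_bulk, Cdl = Cdl,
              v_list = v,
              E_start = domain$E0_1 + domain$window_half,
              E_vertex = domain$E0_1 - domain$window_half,
              n_cycles = domain$n_cycles, T = domain$T)
}

#' Noise specification
#'
#' @param sigma Standard deviation of additive Gaussian noise relative to the
#'   set's maximal absolute current.
#' @param seed Optional seed applied before drawing.
#' @return An object of class `cv_noise`.
#' @export
noise_spec <- function(sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  structure(list(sigma = sigma, seed = seed), class = "cv_noise")
}

#' Add Gaussian noise to a voltammogram set
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `sigma * max(|i|)` (maximum over every current sample in the set) to every
#' current sample; potentials are untouched. Each call draws fresh noise, which
#' is how training-time augmentation regenerates noise per epoch.
#'
#' @param set A `cv_voltset`.
#' @param noise A [noise_spec()] (or a bare numeric sigma).
#' @return The noisy `cv_voltset`.
#' @export
add_gaussian_noise <- function(set, noise) {
  stopifnot(inherits(set, "cv_voltset"), length(set$curves) >= 1)
  if (is.numeric(noise)) noise <- noise_spec(noise)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  if (noise$sigma == 0) return(set)
  imax <- max(vapply(set$curves, function(cu) max(abs(cu$i)), 0))
  sd <- noise$sigma * imax
  set$curves <- lapply(set$curves, function(cu) {
    cu$i <- cu$i + stats::rnorm(length(cu$i), 0, sd)
    cu
  })
  set
}

#' Test whether a simulated voltammogram set is electrochemically accessible
#'
#' Applies the package's sanitization rules to a noiseless set: (1) a faradaic
#' feature exists (max |i_faradaic| at least `min_faradaic_ratio` times the
#' capacitive plateau `Cdl * v_max`); (2) the forward faradaic peak of the
#' slowest curve lies at least `edge_margin_V` inside both window edges; (3) no
#' concentration went meaningfully negative during simulation; (4) forward peak
#' currents are monotone non-decreasing in scan rate; and, when a `solver` is
#' supplied, (5) the mechanism is actually expressed: the set's analysis-cycle
#' normalized faradaic curves must differ from the same system's reference
#' E-mechanism simulation by at least `min_expression` somewhere (a C step
#' with, say, Keq = 1e-3 and tiny lambda produces voltammograms that are E in
#' all but name; such sets both mislead training and are wrong as labeled
#' test cases). The first failed rule is reported as the rejection reason.
#'
#' @param set A `cv_voltset` from [simulate_set()] (noiseless).
#' @param rules Named list of thresholds and switches; see Details.
#' @param cycle Analysis cycle used for peak-based rules.
#' @param solver Optional [solver_config()] enabling the mechanism-expression
#'   rule (it requires one extra reference simulation).
#' @details `rules` accepts `min_faradaic_ratio` (default 3), `edge_margin_V`
#'   (0.05), `conc_tol_rel` (-1e-3), `min_expression` (0.05), and logical
#'   switches `check_faradaic`, `check_edges`, `check_conc`, `check_monotone`,
#'   `check_expression` (all `TRUE`).
#' @return Logical scalar with attribute `reason` (`"ok"` if accessible).
#' @export
is_accessible <- function(set, rules = list(), cycle = 2L, solver = NULL) {
  stopifnot(inherits(set, "cv_voltset"))
  r <- utils::modifyList(list(min_faradaic_ratio = 3, edge_margin_V = 0.05,
                              conc_tol_rel = -1e-3, min_expression = 0.05,
                              check_faradaic = TRUE, check_edges = TRUE,
                              check_conc = TRUE, check_monotone = TRUE,
                              check_expression = TRUE), rules)
  fail <- function(reason) structure(FALSE, reason = reason)
  Cdl <- set$system$params$Cdl
  if (r$check_faradaic) {
    imax_far <- max(vapply(set$curves, function(cu) max(abs(cu$i_far)), 0))
    if (imax_far < r$min_faradaic_ratio * Cdl * max(set$v) || imax_far == 0)
      return(fail("no faradaic feature"))
  }
  if (r$check_conc) {
    mc <- min(vapply(set$curves, function(cu) attr(cu, "min_conc_rel"), 0))
    if (mc < r$conc_tol_rel) return(fail("negative concentrations"))
  }
  pk <- vapply(set$curves, function(cu) {
    s <- cu$cycle == cycle & cu$direction == "forward"
    max(abs(cu$i_far[s]))
  }, 0)
  if (r$check_edges) {
    cu <- set$curves[[1]]                      # slowest scan rate
    s <- cu$cycle == cycle & cu$direction == "forward"
    Es <- cu$E[s]
    Epk <- Es[which.max(abs(cu$i_far[s]))]
    lo <- min(cu$E) + r$edge_margin_V
    hi <- max(cu$E) - r$edge_margin_V
    if (Epk < lo || Epk > hi) return(fail("peak too close to window edge"))
  }
  if (r$check_monotone && length(pk) > 1) {
    if (any(diff(pk) < -1e-3 * max(pk)))
      return(fail("peak currents not monotone in scan rate"))
  }
  if (r$check_expression && !is.null(solver) && set$system$mech_id != 1L &&
      !is.null(set$system)) {
    # Homogeneous kinetics express most strongly at the slowest scan rate
    # (lambda is proportional to 1/v), so comparing that single curve against
    # the system's reference E simulation decides the rule at minimal cost.
    ref_sys <- set$system
    ref_sys$mech_id <- 1L
    ref_sys$mechanism <- "E"
    ref_sys$params$kf <- ref_sys$params$kb <- 0
    ref_sys$params$ki <- ref_sys$params$kd <- 0
    ref <- simulate_cv(ref_sys, v = set$v[1], solver = solver)
    a <- set$curves[[1]]
    ia <- a$i_far[a$cycle == cycle]
    ib <- ref$i_far[ref$cycle == cycle]
    ma <- max(abs(ia)); mb <- max(abs(ib))
    if (ma > 0 && mb > 0 &&
        max(abs(ia / ma - ib / mb)) < r$min_expression)
      return(fail("mechanism not expressed"))
  }
  structure(TRUE, reason = "ok")
}

#' Build a class-balanced labeled pool of accessible systems
#'
#' Samples systems per mechanism, simulates their voltammogram sets, discards
#' inaccessible ones (resampling until the requested count is reached), and
#' stores the analysis-cycle raw curves in a compact form consumed by the
#' preprocessing and training code. Currents are stored noiseless; noise is
#' always injected downstream so one pool serves every sigma experiment.
#'
#' @param per_mech_count Accessible systems to keep per mechanism.
#' @param domain A [parameter_domain()].
#' @param solver A [solver_config()].
#' @param seed Integer seed; the pool is reproducible bit-for-bit under it.
#' @param n Optionally force the number of scan rates per system (e.g. 6 for
#'   the canonical training protocol).
#' @param rules Sanitization rule overrides for [is_accessible()].
#' @param cycle Analysis cycle stored (default 2).
#' @param verbose Print progress.
#' @return An object of class `cv_pool`: list with `systems`, `raw` (per system:
#'   `v`, `Ef`, `Er`, `If`, `Ir` for the analysis cycle), integer `label`
#'   (canonical mechanism order), and `meta`.
#' @export
build_labeled_pool <- function(per_mech_count, domain = parameter_domain(),
                               solver = solver_config(), seed = 1L, n = NULL,
                               rules = list(), cycle = 2L, verbose = FALSE) {
  stopifnot(per_mech_count >= 1)
  set.seed(seed)
  systems <- list(); raw <- list(); label <- integer(0)
  for (mech in 1:5) {
    kept <- 0L; attempts <- 0L
    while (kept < per_mech_count) {
      attempts <- attempts + 1L
      if (attempts > 40L && kept / attempts < 0.05)
        stop("rejection rate above 95% for mechanism ",
             mechanism_levels()[mech], ": domain misconfiguration")
      sys <- sample_system(mech, domain, n = n)
      set <- simulate_set(sys, solver)
      if (!isTRUE(is_accessible(set, rules, cycle, solver = solver))) next
      kept <- kept + 1L
      systems[[length(systems) + 1L]] <- sys
      raw[[length(raw) + 1L]] <- voltset_raw(set, cycle)
      label <- c(label, mech)
    }
    if (verbose)
      message(mechanism_levels()[mech], ": kept ", kept, "/", attempts,
              " (", round(100 * kept / attempts), "% accepted)")
  }
  structure(list(systems = systems, raw = raw, label = label,
                 meta = list(domain = domain, solver = solver, seed = seed,
                             cycle = cycle, per_mech_count = per_mech_count)),
            class = "cv_pool")
}

#' Extract the compact raw representation of one voltammogram set
#'
#' Pulls the chosen cycle's forward/reverse half-sweeps into aligned arrays:
#' shared potential vectors `Ef`, `Er` and current matrices `If`, `Ir`
#' (samples x scan rates). This is the storage format of [build_labeled_pool()].
#'
#' @param set A `cv_voltset`.
#' @param cycle Cycle to extract.
#' @return List with `v`, `Ef`, `Er`, `If`, `Ir`.
#' @export
voltset_raw <- function(set, cycle = 2L) {
  stopifnot(inherits(set, "cv_voltset"))
  cu1 <- set$curves[[1]]
  if (!any(cu1$cycle == cycle))
    stop("cycle ", cycle, " not simulated; available: ",
         paste(unique(cu1$cycle), collapse = ", "))
  sf <- cu1$cycle == cycle & cu1$direction == "forward"
  sr <- cu1$cycle == cycle & cu1$direction == "reverse"
  Ef <- cu1$E[sf]; Er <- cu1$E[sr]
  If <- vapply(set$curves, function(cu)
    cu$i[cu$cycle == cycle & cu$direction == "forward"], numeric(sum(sf)))
  Ir <- vapply(set$curves, function(cu)
    cu$i[cu$cycle == cycle & cu$direction == "reverse"], numeric(sum(sr)))
  list(v = set$v, Ef = Ef, Er = Er,
       If = matrix(If, ncol = length(set$curves)),
       Ir = matrix(Ir, ncol = length(set$curves)))
}

#' @export
print.cv_pool <- function(x, ...) {
  cat("<cv_pool>", length(x$label), "systems;",
      paste(mechanism_levels(), tabulate(x$label, 5), collapse = ", "), "\n")
  invisible(x)
}
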