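## preprocess: VoltSet -> fixed 6 x 3 x 500 normalized tensor, independent of
## absolute potential and current scale.

.TENSOR_COLS <- 500L
.V_ENC_RANGE <- c(0.05, 2)   # V/s; log10 min-max scaling range of the v channel
.SMOOTH_HALF <- 4L           # moving-average half-width for peak finding
.REV_PEAK_MIN <- 0.05        # normalized magnitude for a return peak to "exist"
.EDGE_SAMPLES <- 5L          # return peak must sit this far from the half-sweep ends

.movavg <- function(x, half = .SMOOTH_HALF) {
  m <- length(x)
  vapply(seq_len(m), function(j)
    mean(x[max(1L, j - half):min(m, j + half)]), 0)
}

#' Restrict a voltammogram set to one cycle
#'
#' @param set A `cv_voltset`.
#' @param cycle Cycle index to keep.
#' @return The `cv_voltset` containing only that cycle's samples.
#' @export
keep_cycle <- function(set, cycle = 2L) {
  stopifnot(inherits(set, "cv_voltset"))
  if (!any(set$curves[[1]]$cycle == cycle))
    stop("cycle ", cycle, " not present; available: ",
         paste(unique(set$curves[[1]]$cycle), collapse = ", "))
  set$curves <- lapply(set$curves, function(cu) {
    out <- cu[cu$cycle == cycle, , drop = FALSE]
    attr(out, "v") <- attr(cu, "v")
    attr(out, "min_conc_rel") <- attr(cu, "min_conc_rel")
    class(out) <- class(cu)
    out
  })
  set
}

#' Normalize a voltammogram set
#'
#' Divides every current by the single set-wide maximum absolute current and
#' flips the global sign if needed so the forward-sweep principal feature is
#' positive (sign of the summed forward-sweep current). Potentials untouched.
#'
#' @param set A `cv_voltset`.
#' @return The normalized `cv_voltset`.
#' @export
normalize_set <- function(set) {
  stopifnot(inherits(set, "cv_voltset"), length(set$curves) >= 1)
  imax <- max(vapply(set$curves, function(cu) max(abs(cu$i)), 0))
  if (imax == 0) stop("degenerate input: all currents are zero")
  fsum <- sum(vapply(set$curves, function(cu)
    sum(cu$i[cu$direction == "forward"]), 0))
  s <- if (fsum >= 0) 1 else -1
  set$curves <- lapply(set$curves, function(cu) {
    cu$i <- s * cu$i / imax
    if (!is.null(cu$i_far)) cu$i_far <- s * cu$i_far / imax
    cu
  })
  set
}

#' Estimate the reference potential of the studied redox couple
#'
#' On the slowest-scan-rate curve of a normalized set: if forward and reverse
#' peaks both exist, the reference is their midpoint; otherwise (irreversible
#' wave, no return peak) it falls back to the potential of the largest slope on
#' the rising flank of the forward wave. Peak finding uses a light moving
#' average so the estimate survives moderate noise.
#'
#' @param set A normalized `cv_voltset` (see [normalize_set()]).
#' @param cycle Analysis cycle.
#' @return List with `E_ref` (V) and `method` (`"midpoint_of_peaks"` or
#'   `"max_slope_fallback"`).
#' @export
estimate_reference_potential <- function(set, cycle = NULL) {
  stopifnot(inherits(set, "cv_voltset"))
  cu <- set$curves[[1]]
  if (!is.null(cycle)) cu <- cu[cu$cycle == cycle, , drop = FALSE]
  fwd <- cu$direction == "forward"
  Ef <- cu$E[fwd]; If <- cu$i[fwd]
  Er <- cu$E[!fwd]; Ir <- cu$i[!fwd]
  if (length(Ef) < 3L || max(abs(If)) == 0)
    stop("featureless curve: cannot estimate a reference potential")
  smf <- .movavg(If)
  smr <- .movavg(Ir)
  fpk <- which.max(smf)
  rpk <- which.min(smr)
  m <- length(smr)
  # noise-adaptive return-peak threshold: MAD of successive differences
  # estimates the per-sample noise; smoothing (9-window mean) divides it by 3
  sigma_hat <- stats::median(abs(diff(Ir))) / (sqrt(2) * 0.6745)
  tau <- max(.REV_PEAK_MIN, 5 * sigma_hat / 3)
  has_return <- smr[rpk] <= -tau &&
    rpk > .EDGE_SAMPLES && rpk <= m - .EDGE_SAMPLES
  if (has_return) {
    return(list(E_ref = (Ef[fpk] + Er[rpk]) / 2, method = "midpoint_of_peaks"))
  }
  hi <- if (fpk >= 3L) fpk else length(smf)
  j <- 2:hi
  slope <- (smf[j] - smf[j - 1L]) / (Ef[j] - Ef[j - 1L])
  jmax <- j[which.max(abs(slope))]
  list(E_ref = Ef[jmax], method = "max_slope_fallback")
}

#' Resample one cycle of a set onto the fixed potential grid
#'
#' Linearly interpolates the forward and reverse half-sweeps of the chosen
#' cycle onto a uniform 500-point grid spanning the scan window recentered at
#' `E_ref`; positions outside a half-sweep's sampled range are imputed as zero.
#' Absolute potentials are not retained downstream.
#'
#' @param set A `cv_voltset`.
#' @param E_ref Reference potential (V) used to recenter the window.
#' @param cycle Cycle to resample (default 2, the analysis cycle).
#' @return List with `grid` (recentred potentials, length 500) and `channels`,
#'   one `list(i_forward, i_reverse)` of length-500 vectors per scan rate.
#' @export
resample_to_grid <- function(set, E_ref, cycle = 2L) {
  stopifnot(inherits(set, "cv_voltset"))
  if (!any(set$curves[[1]]$cycle == cycle))
    stop("cycle ", cycle, " not present; available: ",
         paste(unique(set$curves[[1]]$cycle), collapse = ", "))
  cu1 <- set$curves[[1]]
  sel <- cu1$cycle == cycle
  Emin <- min(cu1$E[sel]); Emax <- max(cu1$E[sel])
  grid <- seq(Emin - E_ref, Emax - E_ref, length.out = .TENSOR_COLS)
  interp0 <- function(E, i) {
    out <- stats::approx(E - E_ref, i, xout = grid, method = "linear",
                         yleft = 0, yright = 0, ties = "ordered")$y
    out[is.na(out)] <- 0
    out
  }
  channels <- lapply(set$curves, function(cu) {
    sf <- cu$cycle == cycle & cu$direction == "forward"
    sr <- cu$cycle == cycle & cu$direction == "reverse"
    of <- order(cu$E[sf]); orv <- order(cu$E[sr])
    list(i_forward = interp0(cu$E[sf][of], cu$i[sf][of]),
         i_reverse = interp0(cu$E[sr][orv], cu$i[sr][orv]))
  })
  list(grid = grid, channels = channels)
}

.encode_v <- function(v) {
  (log10(v) - log10(.V_ENC_RANGE[1])) /
    (log10(.V_ENC_RANGE[2]) - log10(.V_ENC_RANGE[1]))
}

#' Assemble the 6 x 3 x 500 input tensor
#'
#' Row r holds `(i_forward, i_reverse, v)` for the r-th smallest scan rate; the
#' v channel is constant across the 500 columns at `log10(v)` min-max scaled
#' over 0.05-2 V/s (zeroed entirely in ablation mode). Rows beyond the number
#' of populated scan rates are zero, and the populated current channels are
#' rescaled so their largest magnitude is exactly 1.
#'
#' @param channels Per-scan-rate channel list from [resample_to_grid()].
#' @param v_list Ascending scan rates matching `channels`.
#' @param label Optional mechanism label.
#' @param ablate_v Zero the v channel (the "no explicit scan-rate" model input).
#' @return A `cv_tensor`: array `c(6, 3, 500)` with attributes `n_used`,
#'   `label`, `v_list`.
#' @export
assemble_tensor <- function(channels, v_list, label = NULL, ablate_v = FALSE) {
  n <- length(channels)
  if (n < 1L || n > 6L) stop("contract violation: need 1..6 populated scan rates")
  if (length(v_list) != n) stop("v_list length must match channels")
  if (n > 1L && any(diff(v_list) <= 0))
    stop("contract violation: v_list must be ascending")
  x <- array(0, dim = c(6L, 3L, .TENSOR_COLS))
  for (r in seq_len(n)) {
    x[r, 1L, ] <- channels[[r]]$i_forward
    x[r, 2L, ] <- channels[[r]]$i_reverse
    if (!ablate_v) x[r, 3L, ] <- .encode_v(v_list[r])
  }
  m <- max(abs(x[seq_len(n), 1:2, ]))
  if (m > 0) x[, 1:2, ] <- x[, 1:2, ] / m
  structure(x, n_used = n, label = label, v_list = v_list, class = "cv_tensor")
}

#' Full preprocessing pipeline: voltammogram set to input tensor
#'
#' Chains cycle selection, optional noise injection, normalization (set-wide
#' current scale and forward-positive sign), reference-potential alignment,
#' resampling onto the 500-point grid and tensor assembly. The result is
#' invariant to translating all potentials and to scaling all currents.
#'
#' @param set A `cv_voltset`.
#' @param cycle Analysis cycle (default 2).
#' @param sigma Gaussian noise level relative to the set's maximal current
#'   (0 = noiseless).
#' @param n_used Keep only the `n_used` smallest scan rates (default all).
#' @param ablate_v Zero the v channel.
#' @return A `cv_tensor`.
#' @export
#' @examples
#' sys <- system_spec("E", k0 = 0.05, v_list = c(0.1, 0.5))
#' set <- simulate_set(sys, solver_config(100, 400))
#' x <- preprocess_voltset(set)
#' attr(x, "n_used")
preprocess_voltset <- function(set, cycle = 2L, sigma = 0, n_used = NULL,
                               ablate_v = FALSE) {
  stopifnot(inherits(set, "cv_voltset"))
  if (!is.null(n_used)) {
    keep <- seq_len(min(length(set$curves), n_used))
    set$curves <- set$curves[keep]
    set$v <- set$v[keep]
  }
  set <- keep_cycle(set, cycle)
  if (sigma > 0) set <- add_gaussian_noise(set, noise_spec(sigma))
  set <- normalize_set(set)
  al <- estimate_reference_potential(set)
  rs <- resample_to_grid(set, al$E_ref, cycle)
  assemble_tensor(rs$channels, set$v, label = set$label, ablate_v = ablate_v)
}

#' @export
print.cv_tensor <- function(x, ...) {
  cat("<cv_tensor> 6 x 3 x 500; n_used =", attr(x, "n_used"))
  if (!is.null(attr(x, "label"))) cat("; label:", attr(x, "label"))
  cat("\n")
  invisible(x)
}
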