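# Shared fixtures, built lazily once per test run. All data is generated in
# code; solver settings are reduced where physical fidelity is not the point
# of the test.

.fx <- new.env(parent = emptyenv())

fast_solver <- function() solver_config(100L, 400L)

fine_solver <- function() solver_config(300L, 4000L)

# a small class-balanced pool (n = 6 scan rates per system)
tiny_pool <- function() {
  if (is.null(.fx$pool)) {
    .fx$pool <- build_labeled_pool(8L, parameter_domain(), fast_solver(),
                                   seed = 7L, n = 6L)
  }
  .fx$pool
}

# one clean reversible E-mechanism voltammogram set
reversible_set <- function() {
  if (is.null(.fx$rev)) {
    sys <- system_spec("E", k0 = 1, Cdl = 2e-5, v_list = c(0.1, 0.5))
    .fx$rev <- simulate_set(sys, fast_solver())
  }
  .fx$rev
}

# quadratic interpolation of a peak position/height on a uniformly sampled
# signal: refines the discrete argmax beyond the sampling step
peak_interp <- function(E, i) {
  j <- which.max(abs(i))
  if (j == 1L || j == length(i)) return(list(E = E[j], i = i[j]))
  y0 <- i[j - 1L]; y1 <- i[j]; y2 <- i[j + 1L]
  den <- y0 - 2 * y1 + y2
  off <- if (den == 0) 0 else 0.5 * (y0 - y2) / den
  list(E = E[j] + off * (E[j + 1L] - E[j]),
       i = y1 - 0.25 * (y0 - y2) * off)
}

# forward/reverse faradaic peak of one cycle of a voltammogram
cycle_peaks <- function(vg, cycle = 1L) {
  sf <- vg$cycle == cycle & vg$direction == "forward"
  sr <- vg$cycle == cycle & vg$direction == "reverse"
  list(fwd = peak_interp(vg$E[sf], vg$i_far[sf]),
       rev = peak_interp(vg$E[sr], vg$i_far[sr]))
}

# dimensionless peak-current normalization for the reversible wave
randles_norm <- function(C_bulk = 1e-6, D = 1e-5, v = 0.1, T = 298.15) {
  FA <- 96485.33212; RG <- 8.314462618
  FA * C_bulk * sqrt(D * FA * v / (RG * T))
}

# rebuild a cycle-2 cv_voltset from the compact raw-pool representation
raw_to_curves <- function(raw) {
  lapply(seq_along(raw$v), function(j) {
    df <- data.frame(cycle = 2L,
                     E = c(raw$Ef, raw$Er),
                     i = c(raw$If[, j], raw$Ir[, j]),
                     i_far = NA_real_,
                     direction = rep(c("forward", "reverse"),
                                     c(length(raw$Ef), length(raw$Er))),
                     stringsAsFactors = FALSE)
    attr(df, "v") <- raw$v[j]
    attr(df, "min_conc_rel") <- 0
    class(df) <- c("cv_voltammogram", "data.frame")
    df
  })
}
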