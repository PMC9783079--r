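# VoltSet -> 6 x 3 x 500 tensor: normalization, alignment, resampling,
# assembly, and the pipeline's invariances.

test_that("normalization scales to unit maximum with a positive forward wave", {
  set <- normalize_set(reversible_set())
  imax <- max(vapply(set$curves, function(cu) max(abs(cu$i)), 0))
  expect_equal(imax, 1)
  # reductive raw currents (negative forward peak) flip to positive
  cu <- set$curves[[1]]
  sel <- cu$cycle == 2 & cu$direction == "forward"
  expect_gt(max(cu$i[sel]), 0.2)
  # idempotence
  again <- normalize_set(set)
  expect_equal(again$curves[[1]]$i, set$curves[[1]]$i, tolerance = 1e-12)
})

test_that("degenerate all-zero input is rejected", {
  set <- simulate_set(system_spec("E", k0 = 0, Cdl = 0), fast_solver())
  expect_error(normalize_set(set), "degenerate")
})

test_that("reference potential recovers E0 of a symmetric reversible wave", {
  set <- normalize_set(keep_cycle(reversible_set(), 2L))
  al <- estimate_reference_potential(set)
  expect_equal(al$method, "midpoint_of_peaks")
  expect_lt(abs(al$E_ref - 0), 0.005)          # E0 = 0 by construction

  # translation equivariance: shifting all potentials shifts E_ref exactly
  shifted <- set
  shifted$curves <- lapply(set$curves, function(cu) { cu$E <- cu$E + 0.2; cu })
  al2 <- estimate_reference_potential(shifted)
  expect_equal(al2$E_ref, al$E_ref + 0.2, tolerance = 1e-12)
})

test_that("irreversible waves fall back to the max-slope estimate", {
  sys <- system_spec("EC", k0 = 1, kf = 4000, kb = 0, Cdl = 0, v_list = 0.1)
  set <- normalize_set(keep_cycle(simulate_set(sys, fast_solver()), 2L))
  al <- estimate_reference_potential(set)
  expect_equal(al$method, "max_slope_fallback")
  expect_true(al$E_ref > -0.5 && al$E_ref < 0.5)
})

test_that("the resampling grid spans the recentered window and reproduces grid data", {
  set <- normalize_set(keep_cycle(reversible_set(), 2L))
  al <- estimate_reference_potential(set)
  rs <- resample_to_grid(set, al$E_ref, 2L)
  cu <- set$curves[[1]]
  expect_equal(min(rs$grid), min(cu$E) - al$E_ref, tolerance = 1e-12)
  expect_equal(max(rs$grid), max(cu$E) - al$E_ref, tolerance = 1e-12)
  expect_length(rs$grid, 500L)

  # interpolation identity: a curve already sampled at the grid nodes
  synth <- set
  Ef <- sort(rs$grid + al$E_ref, decreasing = TRUE)
  iF <- sin(seq_along(Ef) / 40)
  synth$curves <- list(structure(
    data.frame(cycle = 2L, E = c(Ef, rev(Ef)), i = c(iF, rev(iF)),
               i_far = 0, direction = rep(c("forward", "reverse"),
                                          each = length(Ef))),
    v = 0.1, class = c("cv_voltammogram", "data.frame")))
  synth$v <- 0.1
  rs2 <- resample_to_grid(synth, al$E_ref, 2L)
  expect_equal(rs2$channels[[1]]$i_forward, rev(iF), tolerance = 1e-9)
})

test_that("round-trip through the 500-point grid keeps smooth waves to < 1% of peak", {
  sys <- system_spec("E", k0 = 1, Cdl = 0, v_list = 0.1)
  dense <- simulate_set(sys, solver_config(150L, 5000L))
  set <- normalize_set(keep_cycle(dense, 2L))
  al <- estimate_reference_potential(set)
  rs <- resample_to_grid(set, al$E_ref, 2L)
  # back onto the dense forward potentials
  cu <- set$curves[[1]]
  sf <- cu$cycle == 2 & cu$direction == "forward"
  Ef <- cu$E[sf]; If <- cu$i[sf]
  back <- approx(rs$grid + al$E_ref, rs$channels[[1]]$i_forward, xout = Ef,
                 rule = 2)$y
  inner <- Ef > min(Ef) + 0.01 & Ef < max(Ef) - 0.01
  expect_lt(max(abs(back[inner] - If[inner])), 0.01 * max(abs(If)))
})

test_that("tensor assembly enforces shape, padding and the ablation mask", {
  set <- reversible_set()                       # n = 2 scan rates
  x <- preprocess_voltset(set)
  expect_s3_class(x, "cv_tensor")
  expect_equal(dim(x), c(6L, 3L, 500L))
  expect_equal(attr(x, "n_used"), 2L)
  expect_equal(max(abs(x[1:2, 1:2, ])), 1)      # normalization invariant
  expect_true(all(x[3:6, , ] == 0))             # padding rows exactly zero
  expect_gt(max(x[1, 1, ]), 0)                  # forward principal wave positive

  xa <- preprocess_voltset(set, ablate_v = TRUE)
  expect_true(all(xa[, 3, ] == 0))
  expect_equal(xa[, 1:2, ], x[, 1:2, ], tolerance = 1e-12)

  expect_error(assemble_tensor(list(), numeric(0)), "1..6")
  ch <- list(list(i_forward = rep(0, 500), i_reverse = rep(0, 500)),
             list(i_forward = rep(0, 500), i_reverse = rep(0, 500)))
  expect_error(assemble_tensor(ch, c(0.5, 0.1)), "ascending")
})

test_that("preprocessing is invariant to potential translation and current scale", {
  set <- reversible_set()
  x <- preprocess_voltset(set)

  shifted <- set
  shifted$curves <- lapply(set$curves, function(cu) { cu$E <- cu$E + 0.37; cu })
  xt <- preprocess_voltset(shifted)
  expect_equal(as.numeric(xt), as.numeric(x), tolerance = 1e-10)
  expect_identical(attr(xt, "n_used"), attr(x, "n_used"))

  scaled <- set
  scaled$curves <- lapply(set$curves, function(cu) { cu$i <- cu$i * 123.4; cu })
  xs <- preprocess_voltset(scaled)
  expect_equal(xs[, 1:2, ], x[, 1:2, ], tolerance = 1e-12)
})

test_that("the fused C++ tensor path equals the R pipeline", {
  pool <- tiny_pool()
  for (k in c(1L, 9L, 17L, 25L, 33L)) {     # one system per mechanism
    xr <- tensor_flat(preprocess_voltset(
      structure(list(curves = raw_to_curves(pool$raw[[k]]),
                     v = pool$raw[[k]]$v, label = NULL),
                class = "cv_voltset")))
    xc <- cvmech:::cpp_tensor_from_raw(pool$raw[[k]], 0, 0L, FALSE)
    expect_lt(max(abs(xr - xc)), 1e-12)
  }
})

test_that("n_used truncation keeps the smallest scan rates in both paths", {
  pool <- tiny_pool()
  raw <- pool$raw[[1]]
  set <- structure(list(curves = raw_to_curves(raw), v = raw$v, label = NULL),
                   class = "cv_voltset")
  xr <- tensor_flat(preprocess_voltset(set, n_used = 2L))
  xc <- cvmech:::cpp_tensor_from_raw(raw, 0, 2L, FALSE)
  expect_lt(max(abs(xr - xc)), 1e-12)
  expect_true(all(xr[7:18, ] == 0))
})
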