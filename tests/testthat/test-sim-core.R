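# Dimensionless parameters, rate terms, and basic simulator contracts.

test_that("nicholson psi follows its functional form and inverts exactly", {
  psi <- nicholson_psi(0.01, 1e-5, 0.1)
  # direct scalar arithmetic of k0 / sqrt(pi D F v / (R T))
  expect_equal(psi, 0.01 / sqrt(pi * 1e-5 * 96485.33212 * 0.1 /
                                  (8.314462618 * 298.15)), tolerance = 1e-12)
  expect_equal(nicholson_psi(0.01, 1e-5, 0.2) / psi, 1 / sqrt(2),
               tolerance = 1e-12)
  expect_lt(abs(k0_from_psi(psi, 1e-5, 0.1) - 0.01), 1e-14)
})

test_that("saveant lambda is linear in kf and matches direct arithmetic", {
  expect_identical(saveant_lambda(0, 0.1), 0)
  expect_equal(saveant_lambda(20, 0.1), 2 * saveant_lambda(10, 0.1))
  expect_equal(saveant_lambda(10, 0.1),
               (8.314462618 * 298.15 / 96485.33212) * 10 / 0.1,
               tolerance = 1e-12)
})

test_that("mechanism rate terms follow mass action", {
  expect_equal(mechanism_rate_terms("E", list(), c(1, 2)), c(0, 0))
  expect_equal(mechanism_rate_terms("EC", list(kf = 1, kb = 0), c(0, 2, 0)),
               c(0, -2, 2))
  # DISP1 hand evaluation: ki = 1 and kd = 10 1/(M s) = 1e4 cm^3/(mol s);
  # with [B] = 1, [C] = 0.5 mol/cm^3 the bimolecular rate is 1e4 * 1 * 0.5
  r <- mechanism_rate_terms("DISP1", list(ki = 1, kd = 10), c(0.3, 1, 0.5, 0))
  bimol <- 10 * 1000 * 1 * 0.5
  expect_equal(r, c(bimol, -1 - bimol, 1 - bimol, bimol))
  expect_error(mechanism_rate_terms("EC", list(), c(1, 2)), "3 concentrations")
  expect_error(mechanism_rate_terms("E", list(), c(-1, 2)), "negative")
})

test_that("no charge-transfer pathway and no capacitance gives zero current", {
  sys <- system_spec("E", k0 = 0, Cdl = 0)
  vg <- simulate_cv(sys, v = 0.1, solver = fast_solver())
  expect_true(all(vg$i == 0))
})

test_that("capacitance-only current is the rectangular background Cdl*v", {
  sys <- system_spec("E", k0 = 0, Cdl = 2e-5)
  v <- 0.1
  vg <- simulate_cv(sys, v = v, solver = fast_solver())
  expect_true(all(abs(abs(vg$i) - 2e-5 * v) < 1e-15))
  expect_true(all(vg$i[vg$direction == "forward"] < 0))  # reductive sweep
  expect_true(all(vg$i[vg$direction == "reverse"] > 0))  # sign flips at vertex
})

test_that("voltammogram structure honours the scan protocol", {
  vg <- simulate_cv(system_spec("E", k0 = 0.05, n_cycles = 3), v = 0.2,
                    solver = fast_solver())
  expect_equal(sort(unique(vg$cycle)), 1:3)
  expect_equal(length(vg$E), length(vg$i))
  for (cy in 1:3) {
    sf <- vg$cycle == cy & vg$direction == "forward"
    sr <- vg$cycle == cy & vg$direction == "reverse"
    expect_true(all(diff(vg$E[sf]) < 0))   # E_start -> E_vertex
    expect_true(all(diff(vg$E[sr]) > 0))   # E_vertex -> E_start
    expect_equal(min(vg$E[sf]), -0.5, tolerance = 1e-9)
    expect_equal(max(vg$E[sr]), 0.5, tolerance = 1e-9)
  }
})

test_that("a six-scan-rate protocol yields a six-member set", {
  vlist <- c(0.05, 0.1, 0.2, 0.3, 0.5, 0.7)
  sys <- system_spec("E", k0 = 0.05, v_list = vlist)
  set <- simulate_set(sys, fast_solver())
  expect_length(set$curves, 6L)
  expect_equal(set$v, vlist)
  expect_equal(vapply(set$curves, function(cu) attr(cu, "v"), 0), vlist)
})

test_that("system and solver configs round-trip through YAML", {
  sys <- system_spec("ECE", k0 = 0.02, ki = 30, E0_2 = 0.25,
                     v_list = c(0.1, 0.4))
  sol <- solver_config(150L, 600L, 7, "implicit_euler", 4L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config_yaml(sys, sol, path)
  back <- read_config_yaml(path)
  expect_equal(back$system$params, sys$params)
  expect_equal(back$system$protocol, sys$protocol)
  expect_equal(unclass(back$solver), unclass(sol))
})

test_that("spec validation rejects bad systems", {
  expect_error(system_spec("ECE", E0_2 = 0.05), "more facile")
  expect_error(system_spec("E", v_list = c(0.2, 0.1)), "increasing")
  expect_error(system_spec("E", n_cycles = 1), "n_cycles")
  expect_error(system_spec("E", E_start = 0.2, E_vertex = 0.2), "differ")
  expect_error(system_spec("bogus"), "unknown mechanism")
})
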