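# Random system sampling, noise injection, accessibility rules, pool building.

test_that("sampling is deterministic under a fixed seed", {
  set.seed(123)
  a <- sample_system("ECE", parameter_domain())
  set.seed(123)
  b <- sample_system("ECE", parameter_domain())
  expect_identical(a, b)
})

test_that("sampled psi honours the [0.3, 10] interval at the median scan rate", {
  dom <- parameter_domain()
  set.seed(99)
  psis <- replicate(2000, {
    sys <- sample_system("E", dom)
    nicholson_psi(sys$params$k0, sys$params$D,
                  median(sys$protocol$v_list), sys$protocol$T)
  })
  expect_gte(min(psis), 0.3)
  expect_lte(max(psis), 10)
  # log-uniform draws should populate both halves of the interval
  expect_gt(mean(psis < sqrt(0.3 * 10)), 0.3)
})

test_that("sampled kinetic parameters stay inside their declared ranges", {
  dom <- parameter_domain()
  set.seed(17)
  for (mech in c("EC", "CE", "ECE", "DISP1")) {
    for (k in 1:50) {
      sys <- sample_system(mech, dom)
      v_med <- median(sys$protocol$v_list)
      rate <- if (mech %in% c("EC", "CE")) sys$params$kf else sys$params$ki
      lam <- saveant_lambda(rate, v_med, sys$protocol$T)
      expect_gte(lam, dom$lambda_range[1] * 0.999)
      expect_lte(lam, dom$lambda_range[2] * 1.001)
      expect_true(sys$params$Cdl >= dom$Cdl_range[1] &&
                    sys$params$Cdl <= dom$Cdl_range[2])
      expect_true(length(sys$protocol$v_list) %in% 1:6)
      expect_true(all(diff(sys$protocol$v_list) > 0))
      if (mech == "ECE")
        expect_gte(sys$params$E0_2 - sys$params$E0_1, 0.1)
      if (mech == "DISP1")
        expect_true(sys$params$kd >= 1e8 && sys$params$kd <= 1e10)
    }
  }
})

test_that("gaussian noise has the specified amplitude and leaves potentials alone", {
  set <- reversible_set()
  noisy <- add_gaussian_noise(set, noise_spec(0, seed = 1))
  expect_identical(noisy, set)                      # sigma = 0 is the identity

  imax <- max(vapply(set$curves, function(cu) max(abs(cu$i)), 0))
  set.seed(2)
  diffs <- unlist(lapply(1:45, function(k) {
    ns <- add_gaussian_noise(set, noise_spec(0.3))
    unlist(Map(function(a, b) a$i - b$i, ns$curves, set$curves))
  }))
  expect_gt(length(diffs), 1e5)
  expect_equal(sd(diffs), 0.3 * imax, tolerance = 0.05)
  expect_lt(abs(mean(diffs)), 0.01 * imax)
  ns <- add_gaussian_noise(set, noise_spec(0.3))
  expect_identical(ns$curves[[1]]$E, set$curves[[1]]$E)
})

test_that("accessibility rules reject the pathologies they encode", {
  # pure capacitive set: no faradaic pathway
  cap <- simulate_set(system_spec("E", k0 = 0, Cdl = 2e-5, v_list = c(0.1, 0.3)),
                      fast_solver())
  verdict <- is_accessible(cap)
  expect_false(as.logical(verdict))
  expect_equal(attr(verdict, "reason"), "no faradaic feature")

  # textbook reversible wave centered in the window passes every rule
  expect_true(as.logical(is_accessible(reversible_set())))

  # wave pushed against the window edge fails the margin rule
  edge <- simulate_set(system_spec("E", k0 = 1, E0_1 = 0, Cdl = 0,
                                   E_start = 0.97, E_vertex = -0.03,
                                   v_list = 0.1),
                       fast_solver())
  verdict <- is_accessible(edge)
  expect_false(as.logical(verdict))
  expect_equal(attr(verdict, "reason"), "peak too close to window edge")
})

test_that("acceptance fraction matches an independent re-application of the rules", {
  dom <- parameter_domain()
  solv <- fast_solver()
  set.seed(31)
  sets <- lapply(1:40, function(k) simulate_set(sample_system("E", dom, n = 3),
                                                solv))
  pipeline <- vapply(sets, function(s) as.logical(is_accessible(s)), TRUE)

  # independent oracle: re-state the four rules from scratch
  oracle <- vapply(sets, function(s) {
    Cdl <- s$system$params$Cdl
    imax_far <- max(vapply(s$curves, function(cu) max(abs(cu$i_far)), 0))
    r1 <- imax_far >= 3 * Cdl * max(s$v) && imax_far > 0
    cu <- s$curves[[1]]
    sel <- cu$cycle == 2 & cu$direction == "forward"
    Epk <- cu$E[sel][which.max(abs(cu$i_far[sel]))]
    r2 <- Epk >= min(cu$E) + 0.05 && Epk <= max(cu$E) - 0.05
    r3 <- min(vapply(s$curves, function(cu) attr(cu, "min_conc_rel"), 0)) >= -1e-3
    pk <- vapply(s$curves, function(cu) {
      sel <- cu$cycle == 2 & cu$direction == "forward"
      max(abs(cu$i_far[sel]))
    }, 0)
    r4 <- all(diff(pk) >= -1e-3 * max(pk))
    r1 && r2 && r3 && r4
  }, TRUE)
  expect_identical(pipeline, oracle)
})

test_that("labeled pools are balanced, reproducible, and seed-disjoint", {
  pool <- tiny_pool()
  expect_equal(tabulate(pool$label, 5), rep(8L, 5))
  expect_length(pool$raw, 40L)

  pool2 <- build_labeled_pool(2L, parameter_domain(), fast_solver(),
                              seed = 7L, n = 6L)
  # same seed, smaller count: identical leading draws per mechanism
  expect_identical(pool2$raw[[1]], pool$raw[[1]])
  expect_equal(tabulate(pool2$label, 5), rep(2L, 5))

  pool3 <- build_labeled_pool(2L, parameter_domain(), fast_solver(),
                              seed = 8L, n = 6L)
  # different seeds: no duplicated parameter draws (exhaustive comparison)
  k0a <- vapply(pool2$systems, function(s) s$params$k0, 0)
  k0b <- vapply(pool3$systems, function(s) s$params$k0, 0)
  expect_length(intersect(k0a, k0b), 0L)
})

test_that("stored noiseless currents are bit-identical across rebuilds", {
  pool2 <- build_labeled_pool(2L, parameter_domain(), fast_solver(),
                              seed = 101L, n = 4L)
  pool3 <- build_labeled_pool(2L, parameter_domain(), fast_solver(),
                              seed = 101L, n = 4L)
  expect_identical(pool2$raw, pool3$raw)
  expect_identical(pool2$label, pool3$label)
})
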