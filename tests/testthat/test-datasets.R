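# Dataset lifecycle: split arithmetic, persistence round-trips, CSV import.

test_that("split fractions produce the stratified 400/50/50 layout", {
  pool <- tiny_pool()
  # synthetic 100-per-mechanism label layout, no simulation needed
  fake <- pool
  fake$label <- rep(1:5, each = 100)
  fake$raw <- rep(pool$raw[1:5], 100)
  fake$systems <- rep(pool$systems[1:5], 100)
  sp <- split_pool(fake, c(0.8, 0.1, 0.1), seed = 5)
  expect_length(sp$train, 400L)
  expect_length(sp$validation, 50L)
  expect_length(sp$test, 50L)
  for (mech in 1:5) {
    expect_equal(sum(fake$label[sp$train] == mech), 80L)
    expect_equal(sum(fake$label[sp$test] == mech), 10L)
  }
})

test_that("splits are disjoint and cover the pool", {
  pool <- tiny_pool()
  sp <- split_pool(pool, c(0.6, 0.2, 0.2), seed = 6)
  all_idx <- c(sp$train, sp$validation, sp$test)
  expect_equal(sort(all_idx), seq_along(pool$label))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_length(intersect(sp$validation, sp$test), 0L)
})

test_that("a persisted dataset reloads bit-identically", {
  ds <- make_dataset(2L, parameter_domain(), fast_solver(),
                     fractions = c(0.5, 0.25, 0.25), seed = 71, n = 3L)
  dir <- withr::local_tempdir()
  save_dataset(ds, dir)
  back <- load_dataset(dir)
  expect_identical(back$pool$raw, ds$pool$raw)
  expect_identical(back$pool$label, ds$pool$label)
  expect_identical(back$splits, ds$splits)
  for (k in seq_along(ds$pool$systems)) {
    expect_identical(back$pool$systems[[k]]$params, ds$pool$systems[[k]]$params)
    expect_identical(back$pool$systems[[k]]$protocol,
                     ds$pool$systems[[k]]$protocol)
  }
  expect_equal(back$manifest$seed, ds$manifest$seed)
})

test_that("no system leaks across splits after persistence", {
  ds <- make_dataset(2L, parameter_domain(), fast_solver(),
                     fractions = c(0.5, 0.25, 0.25), seed = 72, n = 2L)
  k0s <- vapply(ds$pool$systems, function(s) s$params$k0, 0)
  expect_length(unique(k0s), length(k0s))      # all draws distinct
  tr <- k0s[ds$splits$train]
  te <- k0s[ds$splits$test]
  va <- k0s[ds$splits$validation]
  expect_length(intersect(tr, te), 0L)
  expect_length(intersect(tr, va), 0L)
})

test_that("voltammogram CSV exports re-import exactly, even after row shuffling", {
  set <- reversible_set()
  f <- withr::local_tempfile(fileext = ".csv")
  write_voltset_csv(set, f)
  back <- import_experimental_csv(f)
  expect_length(back$curves, 2L)
  expect_equal(back$v, set$v)
  for (j in 1:2) {
    expect_equal(back$curves[[j]]$E, set$curves[[j]]$E)
    expect_equal(back$curves[[j]]$i, set$curves[[j]]$i)
  }

  df <- utils::read.csv(f)
  set.seed(8)
  df <- df[sample(nrow(df)), ]
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  back2 <- import_experimental_csv(f2)
  for (j in 1:2)
    expect_equal(back2$curves[[j]]$i, back$curves[[j]]$i)
})

test_that("a six-scan-rate experimental file imports as n = 6", {
  vlist <- c(0.05, 0.1, 0.2, 0.3, 0.5, 0.7)
  sys <- system_spec("E", k0 = 0.05, v_list = vlist)
  set <- simulate_set(sys, fast_solver())
  f <- withr::local_tempfile(fileext = ".csv")
  write_voltset_csv(set, f)
  back <- import_experimental_csv(f)
  expect_length(back$curves, 6L)
  expect_equal(back$v, vlist)
  x <- preprocess_voltset(back)
  expect_equal(attr(x, "n_used"), 6L)
})

test_that("schema violations are reported with actionable messages", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(cycle = 1, E_V = 0.1), f, row.names = FALSE)
  expect_error(import_experimental_csv(f), "missing column")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cycle,scan_rate_V_per_s,E_V,i_A_per_cm2,direction",
               "1,0.1,0.2,1e-5,forward",
               "1,0.1,oops,1e-5,forward"), f2)
  expect_error(import_experimental_csv(f2), "non-numeric")

  # requesting a cycle that is absent names the available ones
  set <- reversible_set()
  expect_error(preprocess_voltset(set, cycle = 9L), "available")
})
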