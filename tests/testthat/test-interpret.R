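# Confusion bookkeeping, robustness sweeps, and gradient importance maps.

test_that("confusion-matrix identities hold exactly", {
  pool <- tiny_pool()
  m <- build_model("resnet18", width = 8, seed = 51)
  ev <- evaluate_ensemble(m, pool, sigma = 0.3, seed = 52)
  expect_equal(sum(ev$confusion), length(pool$label))
  expect_equal(unname(rowSums(ev$confusion)), unname(tabulate(pool$label, 5)))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  # recomputing accuracy from pred/truth agrees with the matrix trace
  expect_equal(mean(ev$pred == ev$truth), ev$accuracy)
})

test_that("a perfect predictor yields a diagonal confusion matrix", {
  # construct the tally directly from truth == pred
  truth <- rep(1:5, each = 4)
  cm <- matrix(0L, 5, 5)
  for (k in seq_along(truth)) cm[truth[k], truth[k]] <- cm[truth[k], truth[k]] + 1L
  expect_true(all(cm[row(cm) != col(cm)] == 0))
  expect_equal(sum(diag(cm)) / sum(cm), 1.0)
})

test_that("evaluation with a fixed seed is reproducible", {
  pool <- tiny_pool()
  m <- build_model("resnet18", width = 8, seed = 53)
  e1 <- evaluate_ensemble(m, pool, sigma = 0.5, seed = 54)
  e2 <- evaluate_ensemble(m, pool, sigma = 0.5, seed = 54)
  expect_identical(e1$probs, e2$probs)
})

test_that("sweeps cover exactly the requested grids", {
  pool <- tiny_pool()
  m <- build_model("resnet18", width = 8, seed = 55)
  ss <- sigma_sweep(m, pool, idx = 1:15, sigmas = c(0, 0.4, 0.8), seed = 56)
  expect_equal(ss$sigma, c(0, 0.4, 0.8))
  expect_true(all(ss$accuracy >= 0 & ss$accuracy <= 1))
  ns <- n_sweep(m, pool, idx = 1:15, ns = c(1, 3, 6), sigma = 0.3, seed = 57)
  expect_equal(ns$n_used, c(1, 3, 6))
})

test_that("importance maps have the input shape, are nonnegative and max-normalized", {
  x <- preprocess_voltset(reversible_set())
  m <- build_model("resnet18", width = 8, seed = 61)
  imp <- importance_map(m, x)
  expect_equal(dim(imp), c(6L, 3L, 500L))
  expect_true(all(imp >= 0))
  expect_equal(max(imp), 1)
  expect_true(attr(imp, "target_class") %in% mechanism_levels())
  # attributing a chosen class works too
  imp2 <- importance_map(m, x, target = "CE")
  expect_equal(attr(imp2, "target_class"), "CE")
})

test_that("input gradients match central finite differences", {
  x <- preprocess_voltset(reversible_set())
  xm <- tensor_flat(x)
  for (kind in c("resnet18", "mlp_attention")) {
    m <- build_model(kind, width = 8, seed = 62)
    res <- cvmech:::nn_input_grad_cpp(m$params, m$kind, m$width, xm, 2L)
    g <- res$grad
    h <- 1e-5
    set.seed(63)
    rows <- sample(1:18, 20, replace = TRUE)
    cols <- sample(1:500, 20, replace = TRUE)
    checked <- 0L
    for (t in 1:20) {
      xp <- xm; xp[rows[t], cols[t]] <- xp[rows[t], cols[t]] + h
      xq <- xm; xq[rows[t], cols[t]] <- xq[rows[t], cols[t]] - h
      lp <- cvmech:::nn_input_grad_cpp(m$params, m$kind, m$width, xp, 2L)$logits[3]
      lq <- cvmech:::nn_input_grad_cpp(m$params, m$kind, m$width, xq, 2L)$logits[3]
      fd <- (lp - lq) / (2 * h)
      ref <- g[rows[t], cols[t]]
      if (abs(ref) > 1e-8) {        # skip entries pinned at a ReLU kink / zero
        expect_lt(abs(fd - ref) / max(abs(ref), abs(fd)), 1e-3)
        checked <- checked + 1L
      }
    }
    expect_gte(checked, 5L)
  }
})

test_that("importance overlays render to a PNG file", {
  x <- preprocess_voltset(reversible_set())
  m <- build_model("resnet18", width = 8, seed = 64)
  imp <- importance_map(m, x)
  f <- withr::local_tempfile(fileext = ".png")
  plot_importance(x, imp, row = 1L, file = f)
  expect_true(file.exists(f))
  expect_gt(file.info(f)$size, 1000)
})
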