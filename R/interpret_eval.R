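## interpret_eval: confusion matrices, sigma/n robustness sweeps, gradient
## importance maps, and the in-silico mechanism-transition analysis.

#' Evaluate an ensemble on a test pool
#'
#' Applies noise at `sigma`, truncates each set to its `n_used` smallest scan
#' rates, optionally zeroes the scan-rate channel, preprocesses, predicts, and
#' tallies the 5 x 5 confusion matrix (rows = true mechanism, columns =
#' predicted, canonical order). Accuracy is trace/total.
#'
#' @param models A `cv_model`, `cv_ensemble`, or list of models.
#' @param pool A `cv_pool` (its test indices must be disjoint from training).
#' @param idx Pool indices to evaluate (default all).
#' @param sigma Test noise level.
#' @param n_used Scan rates kept (`NULL` = all).
#' @param ablate_v Zero the v channel.
#' @param seed Seed for the noise draws.
#' @param noise_stage Where noise is injected; see [preprocess_voltset()].
#' @return A `cv_eval`: list with `confusion`, `accuracy`, `pred`, `truth`,
#'   `probs`.
#' @export
evaluate_ensemble <- function(models, pool, idx = NULL, sigma = 0,
                              n_used = NULL, ablate_v = FALSE, seed = NULL,
                              noise_stage = c("tensor", "raw")) {
  noise_stage <- match.arg(noise_stage)
  stopifnot(inherits(pool, "cv_pool"))
  if (is.null(idx)) idx <- seq_along(pool$label)
  if (length(idx) == 0) stop("empty evaluation pool")
  probs <- predict_pool(models, pool, idx, sigma, n_used, ablate_v, seed,
                        noise_stage = noise_stage)
  pred <- max.col(probs, ties.method = "first")
  truth <- pool$label[idx]
  cm <- matrix(0L, 5, 5, dimnames = list(true = mechanism_levels(),
                                         predicted = mechanism_levels()))
  for (k in seq_along(pred)) cm[truth[k], pred[k]] <- cm[truth[k], pred[k]] + 1L
  structure(list(confusion = cm,
                 accuracy = sum(diag(cm)) / sum(cm),
                 pred = pred, truth = truth, probs = probs),
            class = "cv_eval")
}

#' @export
print.cv_eval <- function(x, ...) {
  cat("<cv_eval> accuracy:", round(100 * x$accuracy, 2), "%\n")
  print(x$confusion)
  invisible(x)
}

#' Accuracy as a function of the test noise level
#'
#' Re-evaluates the same pool with fresh noise injected at each sigma.
#'
#' @inheritParams evaluate_ensemble
#' @param sigmas Noise grid (default 0 to 1).
#' @return data.frame with columns `sigma` and `accuracy`.
#' @export
sigma_sweep <- function(models, pool, idx = NULL, sigmas = seq(0, 1, by = 0.1),
                        n_used = NULL, ablate_v = FALSE, seed = NULL,
                        noise_stage = c("tensor", "raw")) {
  noise_stage <- match.arg(noise_stage)
  if (!is.null(seed)) set.seed(seed)
  acc <- vapply(sigmas, function(s)
    evaluate_ensemble(models, pool, idx, sigma = s, n_used = n_used,
                      ablate_v = ablate_v, noise_stage = noise_stage)$accuracy, 0)
  data.frame(sigma = sigmas, accuracy = acc)
}

#' Accuracy as a function of the number of scan rates used
#'
#' Truncation keeps the `n` smallest scan rates of each set.
#'
#' @inheritParams evaluate_ensemble
#' @param ns Scan-rate counts to test.
#' @return data.frame with columns `n_used` and `accuracy`.
#' @export
n_sweep <- function(models, pool, idx = NULL, ns = 1:6, sigma = 0.3,
                    ablate_v = FALSE, seed = NULL,
                    noise_stage = c("tensor", "raw")) {
  noise_stage <- match.arg(noise_stage)
  if (!is.null(seed)) set.seed(seed)
  acc <- vapply(ns, function(n)
    evaluate_ensemble(models, pool, idx, sigma = sigma, n_used = n,
                      ablate_v = ablate_v, noise_stage = noise_stage)$accuracy, 0)
  data.frame(n_used = ns, accuracy = acc)
}

#' Gradient-based importance map
#'
#' Absolute value of the gradient of the target-class logit with respect to
#' every entry of the input tensor, max-normalized to `[0, 1]`. Batch
#' normalization uses its running (inference) statistics, so the map is the
#' exact gradient of the deterministic prediction function.
#'
#' @param model A single trained `cv_model`.
#' @param x A `cv_tensor`.
#' @param target Mechanism to attribute (default: the predicted class).
#' @return A `cv_importance`: array `c(6, 3, 500)` in `[0, 1]` with attributes
#'   `target_class` and `grad` (the raw signed gradient, same shape).
#' @export
importance_map <- function(model, x, target = NULL) {
  stopifnot(inherits(model, "cv_model"))
  xm <- if (is.matrix(x)) x else tensor_flat(x)
  tc <- if (is.null(target)) -1L else .mech_id(target) - 1L
  res <- nn_input_grad_cpp(model$params, model$kind, model$width, xm, tc)
  g <- res$grad                       # 18 x 500 signed gradient
  arr <- array(0, dim = c(6L, 3L, 500L))
  raw <- array(0, dim = c(6L, 3L, 500L))
  for (r in 1:6) for (c in 1:3) {
    raw[r, c, ] <- g[(r - 1L) * 3L + c, ]
    arr[r, c, ] <- abs(g[(r - 1L) * 3L + c, ])
  }
  mx <- max(arr)
  if (mx > 0) arr <- arr / mx
  structure(arr, target_class = mechanism_levels()[res$class0 + 1L],
            grad = raw, logits = as.numeric(res$logits),
            class = "cv_importance")
}

#' Render an importance overlay for one scan-rate row
#'
#' Draws the forward and reverse half-sweeps with the line shaded by the
#' importance intensity (darker = more important), mirroring the usual
#' darkness-encoded voltammogram overlays.
#'
#' @param x A `cv_tensor`.
#' @param imp The matching `cv_importance`.
#' @param row Scan-rate row to draw (1 = slowest).
#' @param file Optional PNG path; when given the plot is written there.
#' @return The file path (or `NULL` when drawing to the active device),
#'   invisibly.
#' @export
plot_importance <- function(x, imp, row = 1L, file = NULL) {
  stopifnot(inherits(imp, "cv_importance"))
  if (!is.null(file)) grDevices::png(file, width = 800, height = 600)
  grid <- seq_len(500L)
  shade <- function(w) grDevices::gray(1 - pmin(1, 0.15 + 0.85 * w))
  plot(grid, x[row, 1L, ], type = "n", xlab = "potential grid index",
       ylab = "normalized current",
       main = paste0("importance overlay (row ", row, ", target ",
                     attr(imp, "target_class"), ")"))
  segments(grid[-500], x[row, 1L, -500], grid[-1], x[row, 1L, -1],
           col = shade(imp[row, 1L, -500]), lwd = 2)
  segments(grid[-500], x[row, 2L, -500], grid[-1], x[row, 2L, -1],
           col = shade(imp[row, 2L, -500]), lwd = 2)
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}

#' In-silico mechanism-transition sweep along the Saveant parameter
#'
#' Simulates the same EC system across increasing forward rate constants
#' (hence increasing lambda at the median scan rate) and reports the ensemble's
#' y components per point. At `lambda = 0` the system has no C step and is an
#' E system by construction; as lambda grows the EC component should rise to
#' dominance.
#'
#' @param models A `cv_model`, `cv_ensemble`, or list of models.
#' @param base_system An EC [system_spec()] serving as the fixed scaffold.
#'   `kf` is overridden per point; when the scaffold has a finite equilibrium
#'   constant `Keq = kf/kb`, `kb` is scaled along so the C step's
#'   thermodynamics stay fixed while its kinetics sweep.
#' @param lambdas Lambda grid (may include 0).
#' @param solver A [solver_config()].
#' @param cycle Analysis cycle.
#' @return data.frame with `lambda`, `kf`, the five y components and the
#'   designated `mechanism`.
#' @export
transition_sweep <- function(models, base_system,
                             lambdas = c(0, 10^seq(-2, 3, by = 1)),
                             solver = solver_config(), cycle = 2L) {
  stopifnot(inherits(base_system, "cv_system"), base_system$mech_id == 2L)
  v_med <- stats::median(base_system$protocol$v_list)
  T <- base_system$protocol$T
  Keq <- base_system$params$Keq
  rows <- lapply(lambdas, function(lam) {
    sys <- base_system
    sys$params$kf <- lam * .FARADAY * v_med / (.RGAS * T)
    if (is.finite(Keq %||% NA_real_) && (Keq %||% 0) > 0)
      sys$params$kb <- sys$params$kf / Keq
    set <- simulate_set(sys, solver)
    pr <- predict_voltset(models, set, cycle = cycle)
    c(lambda = lam, kf = sys$params$kf, pr$y,
      mechanism = which.max(pr$y))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$mechanism <- mechanism_levels()[out$mechanism]
  out
}

#' Write a confusion matrix or sweep curve to CSV
#'
#' @param x A `cv_eval`, or a data.frame from [sigma_sweep()]/[n_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_csv <- function(x, path) {
  if (inherits(x, "cv_eval")) {
    df <- as.data.frame(x$confusion)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    utils::write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}
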