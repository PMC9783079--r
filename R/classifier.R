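## classifier: residual convolutional networks and baselines over input
## tensors; five-component mechanism-probability vectors; averaging ensembles.

#' Build an untrained classification model
#'
#' `"resnet18"` is the main architecture: a first convolution spanning the full
#' 6 x 3 channel extent with a width-7 kernel along the 500-sample potential
#' axis, four stages of two residual blocks (widths `width`, `2*width`,
#' `4*width`, `8*width`, strides along the potential axis only, 18 weighted
#' layers in total) with batch normalization, global average pooling and a
#' 5-way linear head. Baselines: `"linear"` (flatten to 5 logits), `"mlp"`
#' (two hidden layers), `"mlp_shared"` (shared first layer per scan-rate row),
#' `"mlp_attention"` (shared row encoder with attention pooling over rows).
#'
#' @param kind Model kind.
#' @param width Base channel width of the residual network (the full-scale
#'   reference uses 64; reduced widths train in minutes on one CPU).
#' @param seed Optional seed for the weight initialization.
#' @return A `cv_model`: list with `kind`, `width`, `params`, `history`.
#' @export
#' @examples
#' m <- build_model("linear", seed = 1)
#' length(m$params$l3.W)   # 6*3*500 weights x 5 classes
build_model <- function(kind = c("resnet18", "linear", "mlp", "mlp_attention",
                                 "mlp_shared"),
                        width = 16L, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(width >= 1)
  if (!is.null(seed)) set.seed(seed)
  params <- nn_init_cpp(kind, as.integer(width))
  structure(list(kind = kind, width = as.integer(width), params = params,
                 history = NULL, seed = seed),
            class = "cv_model")
}

#' @export
print.cv_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, 0L))
  cat("<cv_model>", x$kind, "width", x$width, "-", npar, "parameters")
  if (!is.null(x$history)) cat("; trained", length(x$history$loss), "epochs")
  cat("\n")
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: learning rate 1e-3, weight decay
#' 1e-5, fresh Gaussian noise at sigma = 0.3 added to the normalized input
#' tensors every minibatch, and an eight-member ensemble differing only by
#' seed. Epoch count and width are scaled to the problem size at hand (the
#' full-scale protocol uses 1000 epochs).
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 weight decay on convolution/linear weights.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param train_noise_sigma Gaussian noise level (relative to each set's
#'   maximal current) injected during training.
#' @param ensemble_size Number of ensemble members.
#' @param seeds Integer seeds, one per member (defaults to `1:ensemble_size`
#'   offsets of `base_seed`).
#' @param base_seed Base seed used when `seeds` is `NULL`.
#' @param model_kind,width Passed to [build_model()].
#' @param n_used Truncate training sets to this many smallest scan rates
#'   (`NULL` = use all).
#' @param n_mode `"fixed"` trains at the pool's scan-rate counts (truncated by
#'   `n_used`); `"random"` draws a fresh count in 1..6 per sample per epoch,
#'   the protocol for models meant to handle any number of scan rates.
#' @param ablate_v Train without the explicit scan-rate channel.
#' @param noise_stage Where training noise is injected; see
#'   [preprocess_voltset()].
#' @param cosine_lr Cosine learning-rate annealing.
#' @return A `cv_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-5,
                         epochs = 30L, batch_size = 64L,
                         train_noise_sigma = 0.3, ensemble_size = 8L,
                         seeds = NULL, base_seed = 100L,
                         model_kind = "resnet18", width = 16L,
                         n_used = NULL, n_mode = c("fixed", "random"),
                         ablate_v = FALSE, noise_stage = c("tensor", "raw"),
                         cosine_lr = TRUE) {
  n_mode <- match.arg(n_mode)
  noise_stage <- match.arg(noise_stage)
  stopifnot(learning_rate > 0, weight_decay >= 0, epochs >= 0, batch_size >= 1,
            train_noise_sigma >= 0, ensemble_size >= 1)
  if (is.null(seeds)) seeds <- base_seed + seq_len(ensemble_size)
  stopifnot(length(seeds) == ensemble_size)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 train_noise_sigma = train_noise_sigma,
                 ensemble_size = as.integer(ensemble_size), seeds = seeds,
                 model_kind = model_kind, width = as.integer(width),
                 n_used = n_used, n_mode = n_mode,
                 ablate_v = isTRUE(ablate_v), noise_stage = noise_stage,
                 cosine_lr = isTRUE(cosine_lr)),
            class = "cv_train_config")
}

.n_used_int <- function(n_used) if (is.null(n_used)) 0L else as.integer(n_used)
.stage_int <- function(stage) if (identical(stage, "raw")) 0L else 1L

#' Train a classifier on a labeled pool
#'
#' Minimizes multiclass cross-entropy with Adam. Every minibatch draws fresh
#' Gaussian noise at `cfg$train_noise_sigma` on the clean normalized input
#' tensors (on-the-fly augmentation), so no two epochs see identical inputs;
#' with `noise_stage = "raw"` the tensors are instead regenerated from noisy
#' raw curves. Deterministic under `seed`.
#'
#' @param model A `cv_model` from [build_model()].
#' @param pool A `cv_pool` from [build_labeled_pool()].
#' @param idx Pool indices to train on (default: all systems).
#' @param cfg A [train_config()].
#' @param seed Seed controlling shuffling and noise draws.
#' @param verbose Print per-epoch loss/accuracy.
#' @return The trained `cv_model`, with `history` (per-epoch loss and training
#'   accuracy under the injected noise).
#' @export
train_classifier <- function(model, pool, idx = NULL, cfg = train_config(),
                             seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "cv_model"), inherits(pool, "cv_pool"),
            inherits(cfg, "cv_train_config"))
  if (is.null(idx)) idx <- seq_along(pool$label)
  set.seed(seed)
  res <- nn_train_cpp(model$params, model$kind, model$width,
                      pool$raw, as.integer(pool$label), as.integer(idx - 1L),
                      cfg$train_noise_sigma, .n_used_int(cfg$n_used),
                      cfg$ablate_v, cfg$epochs, cfg$batch_size,
                      cfg$learning_rate, cfg$weight_decay, cfg$cosine_lr,
                      verbose, noise_stage = .stage_int(cfg$noise_stage),
                      n_random = identical(cfg$n_mode, "random"))
  model$params <- res$params
  model$history <- list(loss = as.numeric(res$loss), acc = as.numeric(res$acc))
  model$config <- cfg
  model
}

#' Train an ensemble of classifiers
#'
#' Members share the architecture and training protocol and differ only by
#' seed (weight initialization, shuffling and augmentation noise).
#'
#' @inheritParams train_classifier
#' @return A `cv_ensemble`: list of trained `cv_model`s.
#' @export
train_ensemble <- function(pool, idx = NULL, cfg = train_config(),
                           verbose = FALSE) {
  models <- lapply(seq_len(cfg$ensemble_size), function(k) {
    if (verbose) message("training ensemble member ", k, "/", cfg$ensemble_size)
    m <- build_model(cfg$model_kind, cfg$width, seed = cfg$seeds[k])
    train_classifier(m, pool, idx, cfg, seed = cfg$seeds[k], verbose = verbose)
  })
  structure(models, class = "cv_ensemble")
}

.as_model_list <- function(models) {
  if (inherits(models, "cv_model")) return(list(models))
  if (inherits(models, "cv_ensemble")) return(unclass(models))
  stopifnot(is.list(models), all(vapply(models, inherits, TRUE, "cv_model")))
  models
}

#' Flatten a 6 x 3 x 500 tensor to the 18 x 500 network input layout
#'
#' Row-major channel mapping: network channel `(r-1)*3 + c` holds tensor entry
#' `[r, c, ]`.
#'
#' @param x A `cv_tensor`.
#' @return An 18 x 500 numeric matrix.
#' @export
tensor_flat <- function(x) {
  stopifnot(length(dim(x)) == 3, all(dim(x) == c(6L, 3L, 500L)))
  out <- matrix(0, 18L, 500L)
  for (r in 1:6) for (c in 1:3) out[(r - 1L) * 3L + c, ] <- x[r, c, ]
  out
}

.new_prediction <- function(y) {
  y <- as.numeric(y)
  names(y) <- mechanism_levels()
  structure(list(y = y,
                 mechanism = mechanism_levels()[which.max(y)]),
            class = "cv_prediction")
}

#' @export
print.cv_prediction <- function(x, ...) {
  cat("<cv_prediction>", x$mechanism, "\n")
  print(round(x$y, 4))
  invisible(x)
}

#' Predict the mechanism-probability vector for one input tensor
#'
#' Per-model class probabilities (softmax of logits) are averaged over the
#' ensemble members; the designated mechanism is the argmax, ties broken by
#' the canonical order (E, EC, CE, ECE, DISP1).
#'
#' @param models A `cv_model`, `cv_ensemble`, or list of models.
#' @param x A `cv_tensor` (or an 18 x 500 matrix in network layout).
#' @return A `cv_prediction`: list with the five-component `y` (nonnegative,
#'   summing to 1) and the designated `mechanism`.
#' @export
predict_ensemble <- function(models, x) {
  models <- .as_model_list(models)
  xm <- if (is.matrix(x)) x else tensor_flat(x)
  probs <- lapply(models, function(m)
    nn_predict_tensor_cpp(m$params, m$kind, m$width, xm))
  .new_prediction(Reduce(`+`, probs) / length(probs))
}

#' Predict class probabilities for pool systems
#'
#' Regenerates tensors from the stored raw curves (optionally with noise,
#' truncation to the `n_used` smallest scan rates, and v-channel ablation) and
#' returns per-system ensemble-averaged probabilities.
#'
#' @param models A `cv_model`, `cv_ensemble`, or list of models.
#' @param pool A `cv_pool`.
#' @param idx Pool indices (default all).
#' @param sigma Noise level applied before preprocessing.
#' @param n_used Truncate to this many smallest scan rates (`NULL` = all).
#' @param ablate_v Zero the scan-rate channel.
#' @param seed Optional seed for the noise draws.
#' @param noise_stage Where noise is injected; see [preprocess_voltset()].
#' @param per_model Also return the per-member probability matrices.
#' @return Matrix (length(idx) x 5) of ensemble probabilities, with attribute
#'   `per_model` when requested.
#' @export
predict_pool <- function(models, pool, idx = NULL, sigma = 0, n_used = NULL,
                         ablate_v = FALSE, seed = NULL,
                         noise_stage = c("tensor", "raw"), per_model = FALSE) {
  noise_stage <- match.arg(noise_stage)
  models <- .as_model_list(models)
  stopifnot(inherits(pool, "cv_pool"))
  if (is.null(idx)) idx <- seq_along(pool$label)
  if (!is.null(seed)) set.seed(seed)
  pm <- lapply(models, function(m)
    nn_predict_pool_cpp(m$params, m$kind, m$width, pool$raw,
                        as.integer(idx - 1L), sigma, .n_used_int(n_used),
                        isTRUE(ablate_v), 128L, .stage_int(noise_stage)))
  avg <- Reduce(`+`, pm) / length(pm)
  colnames(avg) <- mechanism_levels()
  if (per_model) attr(avg, "per_model") <- pm
  avg
}

#' Predict the mechanism of a voltammogram set
#'
#' Preprocesses a `cv_voltset` (experimental or simulated) and applies the
#' ensemble.
#'
#' @param models A `cv_model`, `cv_ensemble`, or list of models.
#' @param set A `cv_voltset`.
#' @param cycle Analysis cycle (default 2).
#' @param n_used,ablate_v Preprocessing options, see [preprocess_voltset()].
#' @return A `cv_prediction`.
#' @export
predict_voltset <- function(models, set, cycle = 2L, n_used = NULL,
                            ablate_v = FALSE) {
  x <- preprocess_voltset(set, cycle = cycle, sigma = 0, n_used = n_used,
                          ablate_v = ablate_v)
  predict_ensemble(models, x)
}

#' Component-wise ensemble spread of predictions
#'
#' Standard deviation of each y component across ensemble members, a
#' per-mechanism measure of the ensemble's internal variability.
#'
#' @inheritParams predict_pool
#' @return Matrix (length(idx) x 5) of standard deviations.
#' @export
ensemble_spread <- function(models, pool, idx = NULL, sigma = 0, n_used = NULL,
                            ablate_v = FALSE, seed = NULL) {
  models <- .as_model_list(models)
  if (length(models) < 2) stop("need at least two ensemble members")
  avg <- predict_pool(models, pool, idx, sigma, n_used, ablate_v, seed,
                      per_model = TRUE)
  pm <- attr(avg, "per_model")
  out <- sqrt(Reduce(`+`, lapply(pm, function(p) (p - avg)^2)) / (length(pm) - 1))
  colnames(out) <- mechanism_levels()
  out
}
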