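#' Build a network input feature from current and baseline spectral LACs
#'
#' The regressor input has eight elements: the material's four per-bin LACs
#' at the current temperature, followed by the four heating residuals above
#' the baseline scan, each scaled by a factor of exactly 100 to bring the
#' residuals into the numeric range of the baseline LACs.
#'
#' @param current,baseline [spectral_lac()]s (or plain 4-vectors) of the
#'   same material and binning.
#' @return Numeric 8-vector.
#' @export
build_feature <- function(current, baseline) {
  mu_of <- function(x) if (inherits(x, "spectral_lac")) x$mu_per_bin else as.numeric(x)
  mu <- mu_of(current); mu0 <- mu_of(baseline)
  if (length(mu) != length(mu0))
    stop("binning mismatch between current and baseline LACs")
  c(mu, (mu - mu0) * 100)
}

#' Regressor architecture and training hyperparameters
#'
#' A fully connected 8-4-4-1 network with ReLU activation, trained by
#' per-sample stochastic gradient descent on mean squared error at learning
#' rate 1e-5 with an 80/20 train/validation split. The output unit is also
#' rectified by default (`output_relu = TRUE`); temperature targets are
#' positive so the output rectifier is non-binding once training leaves the
#' origin, and it can be disabled.
#'
#' @param layer_sizes Integer vector of layer widths; input must be 8 and
#'   output 1.
#' @param learning_rate SGD learning rate (> 0).
#' @param split Training fraction of the 80/20 split.
#' @param max_epochs Maximum training epochs.
#' @param seed Integer seed governing initialisation, split and shuffling.
#' @param output_relu Apply ReLU to the output unit as well as the hidden
#'   layers.
#' @param patience Optional early-stopping patience (epochs without a new
#'   best validation MAE); `NULL` trains the full `max_epochs`.
#' @param average_tail Fraction of the final epochs whose SGD iterates are
#'   averaged into the returned weights (Polyak-Ruppert tail averaging;
#'   per-sample SGD keeps oscillating around the optimum, and the
#'   averaged iterate is a lower-variance estimate than any single
#'   epoch's weights). Set to 0 to return the final iterate.
#' @param init Weight initialisation: `"he"` (fan-in-scaled Gaussian) or
#'   `"zero"`.
#' @return An object of class `regressor_spec`.
#' @export
regressor_spec <- function(layer_sizes = c(8L, 4L, 4L, 1L),
                           learning_rate = 1e-5,
                           split = 0.8,
                           max_epochs = 1000L,
                           seed = 1L,
                           output_relu = TRUE,
                           patience = NULL,
                           average_tail = 0.2,
                           init = c("he", "zero")) {
  layer_sizes <- as.integer(layer_sizes)
  if (layer_sizes[1] != 8L || layer_sizes[length(layer_sizes)] != 1L)
    stop("input width must be 8 and output width 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (split <= 0 || split >= 1) stop("split must be in (0, 1)")
  if (average_tail < 0 || average_tail > 1) stop("average_tail must be in [0, 1]")
  structure(list(layer_sizes = layer_sizes, activation = "relu",
                 loss = "mse", optimizer = "sgd",
                 learning_rate = learning_rate, split = split,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 output_relu = isTRUE(output_relu), patience = patience,
                 average_tail = average_tail,
                 init = match.arg(init)),
            class = "regressor_spec")
}

#' Generate a training set from base-material thermal series
#'
#' For each base material, `n_per_material` temperatures on a uniform grid
#' over `t_range` are drawn; the series is linearly interpolated at each
#' grid temperature, perturbed with zero-mean Gaussian noise whose SD is
#' `noise_sd_rel` times that material's baseline LAC per bin, and
#' featurised against the noiseless baseline scan.
#'
#' @param bases A [base_material_set()].
#' @param n_per_material Rows generated per base (default 333).
#' @param t_range Temperature range (degC) of the grid.
#' @param noise_sd_rel Relative SD of the Gaussian input noise.
#' @param seed Integer seed; the set is a pure function of it.
#' @return An object of class `training_set`: `features` (n x 8 matrix),
#'   `targets` (degC), `provenance` (data.frame material, temperature_C,
#'   draw).
#' @export
generate_training_set <- function(bases, n_per_material = 333L,
                                  t_range = c(33, 90),
                                  noise_sd_rel = 0.005, seed = 1L) {
  stopifnot(inherits(bases, "base_material_set"))
  for (b in bases$bases) {
    tr <- range(b$temperatures_C)
    if (t_range[1] < tr[1] - 1e-9 || t_range[2] > tr[2] + 1e-9)
      stop(sprintf("t_range exceeds support of base '%s'", b$material))
  }
  set.seed(as.integer(seed))
  grid <- seq(t_range[1], t_range[2], length.out = n_per_material)
  nb <- bases$binning$n_bins
  feats <- list(); targ <- numeric(0); prov <- list()
  for (b in bases$bases) {
    mu0 <- series_lac_at(b, b$baseline_C)$mu_per_bin
    X <- matrix(0, n_per_material, 2L * nb)
    for (i in seq_len(n_per_material)) {
      mu <- series_lac_at(b, grid[i])$mu_per_bin
      mu_noisy <- mu + stats::rnorm(nb, 0, noise_sd_rel * mu0)
      X[i, ] <- build_feature(mu_noisy, mu0)
    }
    feats[[b$material]] <- X
    targ <- c(targ, grid)
    prov[[b$material]] <- data.frame(material = b$material,
                                     temperature_C = grid,
                                     draw = seq_len(n_per_material))
  }
  structure(list(features = do.call(rbind, feats), targets = targ,
                 provenance = do.call(rbind, c(prov, make.row.names = FALSE))),
            class = "training_set")
}

# fan-in-scaled Gaussian initialisation (or zeros) for the weight stack
init_params <- function(spec) {
  ls <- spec$layer_sizes
  params <- list()
  for (l in seq_len(length(ls) - 1L)) {
    n_in <- ls[l]; n_out <- ls[l + 1L]
    if (spec$init == "zero") {
      W <- matrix(0, n_out, n_in); b <- rep(0, n_out)
    } else {
      W <- matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in)
      b <- rep(0.01, n_out)
    }
    params[[l]] <- list(W = W, b = b)
  }
  params
}

# batch forward pass: X is n x 8, returns n-vector of predictions
forward_batch <- function(params, X, output_relu = TRUE) {
  H <- t(X)
  nl <- length(params)
  for (l in seq_len(nl)) {
    H <- params[[l]]$W %*% H + params[[l]]$b
    if (l < nl || output_relu) H <- pmax(H, 0)
  }
  drop(H)
}

#' Train the temperature regressor
#'
#' Per-sample stochastic gradient descent on mean squared error. The
#' train/validation split is random but stratified by material, and the
#' training order is reshuffled every epoch; initialisation, split and
#' shuffling are all driven by `spec$seed`, so training is bitwise
#' reproducible. The full per-epoch history of train/validation MAE and
#' MSE is returned. The returned weights are the Polyak-Ruppert average
#' of the SGD iterates over the final `average_tail` fraction of the
#' epochs (see [regressor_spec()]); the history itself always tracks the
#' raw per-epoch iterates.
#'
#' @param ts A [training_set()][generate_training_set].
#' @param spec A [regressor_spec()].
#' @return An object of class `thermo_regressor`: `params` (weight
#'   stack), `spec`, `history` (data.frame epoch, train_mae, train_mse,
#'   val_mae, val_mse), `best_epoch` (epoch of minimum validation MAE),
#'   `val_index` (validation row indices).
#' @export
train_regressor <- function(ts, spec = regressor_spec()) {
  stopifnot(inherits(ts, "training_set"), inherits(spec, "regressor_spec"))
  n <- nrow(ts$features)
  if (n < 50L) stop("need at least 50 training rows")
  set.seed(spec$seed)
  mats <- ts$provenance$material
  tr_idx <- unlist(lapply(unique(mats), function(m) {
    idx <- which(mats == m)
    sample(idx, round(spec$split * length(idx)))
  }), use.names = FALSE)
  va_idx <- setdiff(seq_len(n), tr_idx)
  Xtr <- ts$features[tr_idx, , drop = FALSE]; ytr <- ts$targets[tr_idx]
  Xva <- ts$features[va_idx, , drop = FALSE]; yva <- ts$targets[va_idx]

  params <- init_params(spec)
  nl <- length(params)
  lr <- spec$learning_rate
  out_relu <- spec$output_relu
  hist <- matrix(NA_real_, spec$max_epochs, 4,
                 dimnames = list(NULL, c("train_mae", "train_mse", "val_mae", "val_mse")))
  best_mae <- Inf; best_epoch <- 0L; stall <- 0L
  avg_start <- if (spec$average_tail > 0)
    floor(spec$max_epochs * (1 - spec$average_tail)) + 1L else Inf
  avg_params <- NULL; n_avg <- 0L
  ntr <- nrow(Xtr)

  for (ep in seq_len(spec$max_epochs)) {
    ord <- sample.int(ntr)
    for (i in ord) {
      x <- Xtr[i, ]
      zs <- vector("list", nl); hs <- vector("list", nl + 1L)
      hs[[1]] <- x
      for (l in seq_len(nl)) {
        z <- drop(params[[l]]$W %*% hs[[l]]) + params[[l]]$b
        zs[[l]] <- z
        hs[[l + 1L]] <- if (l < nl || out_relu) pmax(z, 0) else z
      }
      o <- hs[[nl + 1L]]
      if (!is.finite(o)) stop(sprintf("training failure: non-finite output at epoch %d", ep))
      delta <- 2 * (o - ytr[i])
      if (out_relu) delta <- delta * (zs[[nl]] > 0)
      for (l in rev(seq_len(nl))) {
        gW <- outer(delta, hs[[l]])
        gb <- delta
        if (l > 1L)
          delta <- drop(crossprod(params[[l]]$W, delta)) * (zs[[l - 1L]] > 0)
        params[[l]]$W <- params[[l]]$W - lr * gW
        params[[l]]$b <- params[[l]]$b - lr * gb
      }
    }
    ptr <- forward_batch(params, Xtr, out_relu)
    pva <- forward_batch(params, Xva, out_relu)
    if (any(!is.finite(ptr)))
      stop(sprintf("training failure: non-finite loss at epoch %d", ep))
    hist[ep, ] <- c(mean(abs(ptr - ytr)), mean((ptr - ytr)^2),
                    mean(abs(pva - yva)), mean((pva - yva)^2))
    if (ep >= avg_start) {
      n_avg <- n_avg + 1L
      if (is.null(avg_params)) {
        avg_params <- params
      } else {
        for (l in seq_len(nl)) {
          avg_params[[l]]$W <- avg_params[[l]]$W +
            (params[[l]]$W - avg_params[[l]]$W) / n_avg
          avg_params[[l]]$b <- avg_params[[l]]$b +
            (params[[l]]$b - avg_params[[l]]$b) / n_avg
        }
      }
    }
    if (hist[ep, "val_mae"] < best_mae - 1e-12) {
      best_mae <- hist[ep, "val_mae"]; best_epoch <- ep; stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (!is.null(spec$patience) && stall >= spec$patience) break
  }
  hist <- hist[seq_len(ep), , drop = FALSE]
  if (is.null(avg_params)) avg_params <- params
  structure(list(params = avg_params, spec = spec,
                 history = data.frame(epoch = seq_len(ep), hist),
                 best_epoch = best_epoch, val_index = va_idx),
            class = "thermo_regressor")
}

#' @export
print.thermo_regressor <- function(x, ...) {
  h <- x$history
  cat(sprintf("Temperature regressor %s, %d epochs\n",
              paste(x$spec$layer_sizes, collapse = "-"), nrow(h)))
  cat(sprintf("  validation MAE: %.2f degC (epoch 1) -> %.2f degC (final)\n",
              h$val_mae[1], h$val_mae[nrow(h)]))
  invisible(x)
}

#' Predict temperature from a feature vector
#'
#' @param object A trained [train_regressor()] model.
#' @param feature An 8-vector from [build_feature()], or an n x 8 matrix.
#' @param ... Unused.
#' @return Predicted temperature(s), degC.
#' @export
predict.thermo_regressor <- function(object, feature, ...) {
  X <- if (is.matrix(feature)) feature else matrix(feature, nrow = 1)
  if (ncol(X) != object$spec$layer_sizes[1])
    stop("feature must have 8 elements")
  if (any(!vapply(object$params, function(p) all(is.finite(p$W)), logical(1))))
    stop("model has non-finite weights")
  forward_batch(object$params, X, object$spec$output_relu)
}

#' Predict temperature with a Monte-Carlo confidence interval
#'
#' Propagates attenuation measurement noise into the prediction: the four
#' LAC components of the feature are perturbed with independent Gaussian
#' noise of the supplied per-bin variance (as estimated across 10 adjacent
#' LOIs in the projection), the residual half of the feature is re-derived
#' from each perturbed LAC, and the network is evaluated on every draw. The
#' point estimate is the noiseless prediction; the interval is the
#' 2.5-97.5 percentile range of the draws, widened if needed to contain
#' the point estimate.
#'
#' @param model A trained [train_regressor()] model.
#' @param feature 8-vector from [build_feature()].
#' @param var_per_bin Non-negative 4-vector of LAC variances (mm^-2).
#' @param n_draws Monte-Carlo draws (>= 100).
#' @param seed Integer seed.
#' @return An object of class `temperature_prediction`: `t_hat`, `ci_low`,
#'   `ci_high`, `n_draws`.
#' @export
predict_with_ci <- function(model, feature, var_per_bin, n_draws = 1000L,
                            seed = 1L) {
  stopifnot(inherits(model, "thermo_regressor"))
  var_per_bin <- as.numeric(var_per_bin)
  if (any(var_per_bin < 0)) stop("var_per_bin must be non-negative")
  if (n_draws < 100L) stop("n_draws must be at least 100")
  feature <- as.numeric(feature)
  mu <- feature[1:4]
  mu0 <- mu - feature[5:8] / 100
  t_hat <- as.numeric(predict(model, feature))
  set.seed(as.integer(seed))
  sds <- sqrt(var_per_bin)
  draws <- matrix(stats::rnorm(n_draws * 4L, mean = rep(mu, each = n_draws),
                               sd = rep(sds, each = n_draws)),
                  n_draws, 4L)
  Xd <- cbind(draws, sweep(draws, 2, mu0) * 100)
  preds <- predict(model, Xd)
  qs <- stats::quantile(preds, c(0.025, 0.975), names = FALSE)
  structure(list(t_hat = t_hat,
                 ci_low = min(qs[1], t_hat),
                 ci_high = max(qs[2], t_hat),
                 n_draws = as.integer(n_draws)),
            class = "temperature_prediction")
}

#' @export
print.temperature_prediction <- function(x, ...) {
  cat(sprintf("T = %.2f degC  (95%% CI %.2f - %.2f, %d draws)\n",
              x$t_hat, x$ci_low, x$ci_high, x$n_draws))
  invisible(x)
}

#' Mean absolute error of temperature predictions
#'
#' @param model A trained [train_regressor()] model.
#' @param features n x 8 matrix of feature vectors.
#' @param truth n-vector of true temperatures (degC).
#' @return MAE in degC.
#' @export
evaluate_mae <- function(model, features, truth) {
  features <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (nrow(features) == 0L || length(truth) == 0L) stop("empty test set")
  if (nrow(features) != length(truth)) stop("features and truth must align")
  mean(abs(predict(model, features) - truth))
}

#' Save / load a trained regressor as JSON
#'
#' Persists layer sizes, activation choices, flattened weights and biases,
#' the training seed and the full history, so a saved model reloads to
#' bit-identical predictions.
#'
#' @param model A [train_regressor()] model.
#' @param path Output JSON path.
#' @return `save_model`: the path, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "thermo_regressor"))
  obj <- list(
    layer_sizes = model$spec$layer_sizes,
    activation = model$spec$activation,
    output_relu = model$spec$output_relu,
    learning_rate = model$spec$learning_rate,
    seed = model$spec$seed,
    weights = lapply(model$params, function(p) as.numeric(p$W)),
    biases = lapply(model$params, function(p) as.numeric(p$b)),
    history = model$history,
    best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ls <- as.integer(obj$layer_sizes)
  spec <- regressor_spec(layer_sizes = ls,
                         learning_rate = obj$learning_rate,
                         seed = obj$seed,
                         output_relu = isTRUE(obj$output_relu))
  params <- lapply(seq_len(length(ls) - 1L), function(l) {
    list(W = matrix(as.numeric(obj$weights[[l]]), ls[l + 1L], ls[l]),
         b = as.numeric(obj$biases[[l]]))
  })
  structure(list(params = params, spec = spec,
                 history = as.data.frame(obj$history),
                 best_epoch = obj$best_epoch, val_index = integer(0)),
            class = "thermo_regressor")
}
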