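# Multilayer perceptron mapping feature vectors to discretised spectra.
# Dense tanh layers with a linear output, MSE cost, ADAM updates over
# shuffled minibatches, inverted dropout on the hidden layers.

#' Multilayer-perceptron configuration
#'
#' The default architecture is a funnel of four fully-connected hidden
#' layers: the first has 1200 neurons and each subsequent layer is reduced
#' by 30% (floor rounding), giving hidden sizes 1200, 840, 588, 411. Hidden
#' layers use the hyperbolic tangent activation, which bounds activations in
#' (-1, 1); the output layer is linear because cross-sections are unbounded.
#'
#' @param input_dim length of the feature vector (210 for a 20-atom Coulomb
#'   matrix, grid length for an RDC).
#' @param output_dim length of the discretised target spectrum (default
#'   300).
#' @param first_hidden neurons in the first hidden layer (default 1200).
#' @param shrink per-layer size factor (default 0.70, i.e. a 30% reduction;
#'   sizes are floored).
#' @param n_hidden number of hidden layers (default 4).
#' @param dropout fraction of hidden activations zeroed during training
#'   (default 0.15; inactive at prediction time).
#' @param learning_rate ADAM step size (default 3e-4).
#' @param minibatch samples per gradient estimate (default 100).
#' @param max_epochs training epochs, i.e. forward passes through the
#'   dataset (default 500).
#' @param patience if non-`NULL`, stop early when the monitored MSE has not
#'   improved for this many epochs.
#' @param adam_beta1,adam_beta2,adam_eps ADAM moment decay rates and
#'   stabiliser (standard defaults).
#' @param scale_features standardise each feature column (zero mean, unit
#'   variance, statistics estimated on the training set and stored in the
#'   model) before the first layer (default TRUE). Coulomb-matrix and RDC
#'   entries reach hundreds of charge-squared units, which would saturate
#'   the tanh first layer.
#' @param seed integer seed controlling weight initialisation, minibatch
#'   shuffling, and dropout masks; identical seeds give bit-identical runs.
#' @return an `mlp_config` list with a `hidden_sizes` field.
#' @export
mlp_config <- function(input_dim, output_dim = 300L, first_hidden = 1200L,
                       shrink = 0.70, n_hidden = 4L, dropout = 0.15,
                       learning_rate = 3e-4, minibatch = 100L,
                       max_epochs = 500L, patience = NULL,
                       adam_beta1 = 0.9, adam_beta2 = 0.999,
                       adam_eps = 1e-8, scale_features = TRUE, seed = 1L) {
  stopifnot(input_dim >= 1, output_dim >= 1, first_hidden >= 1,
            n_hidden >= 1, shrink > 0, shrink <= 1,
            dropout >= 0, dropout < 1, learning_rate > 0, minibatch >= 1,
            max_epochs >= 1)
  hidden <- integer(n_hidden)
  hidden[1] <- as.integer(first_hidden)
  for (k in seq_len(n_hidden - 1L)) {
    hidden[k + 1L] <- as.integer(floor(hidden[k] * shrink))
  }
  structure(list(input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 first_hidden = as.integer(first_hidden), shrink = shrink,
                 n_hidden = as.integer(n_hidden), hidden_sizes = hidden,
                 dropout = dropout, learning_rate = learning_rate,
                 minibatch = as.integer(minibatch),
                 max_epochs = as.integer(max_epochs), patience = patience,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, scale_features = isTRUE(scale_features),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Count trainable parameters of a configuration
#'
#' @param config an [mlp_config()].
#' @param include_bias count bias vectors as well as weight matrices
#'   (default TRUE).
#' @return total number of trainable parameters.
#' @export
mlp_n_weights <- function(config, include_bias = TRUE) {
  sizes <- as.double(c(config$input_dim, config$hidden_sizes,
                       config$output_dim))
  w <- sum(sizes[-length(sizes)] * sizes[-1])
  if (include_bias) w <- w + sum(sizes[-1])
  w
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Deterministic derived seed, kept within 32-bit integer range.
derive_seed <- function(seed, ...) {
  offsets <- c(...)
  as.integer((as.double(seed) + sum(offsets * 9973)) %% .Machine$integer.max)
}

#' Build (initialise) an MLP
#'
#' Layers are fully connected: input -> hidden sizes -> output. Weights are
#' initialised from a symmetric uniform fan-in scheme,
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`, biases at zero, using the
#' configuration seed; the same seed reproduces the initial weights exactly.
#'
#' @param config an [mlp_config()].
#' @return an `mlp_model`: list of weight matrices `w` (fan_in x fan_out),
#'   bias vectors `b`, the `config`, an empty training `history`, and an
#'   `init` descriptor.
#' @export
mlp_build <- function(config) {
  stopifnot(inherits(config, "mlp_config"))
  sizes <- c(config$input_dim, config$hidden_sizes, config$output_dim)
  nlayer <- length(sizes) - 1L
  w <- vector("list", nlayer)
  b <- vector("list", nlayer)
  with_rng(derive_seed(config$seed, 1), {
    for (l in seq_len(nlayer)) {
      lim <- 1 / sqrt(sizes[l])
      w[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
  })
  structure(list(w = w, b = b, config = config, feature_scale = NULL,
                 history = data.frame(epoch = integer(0),
                                      train_mse = numeric(0),
                                      val_mse = numeric(0)),
                 init = "uniform fan-in U(-1/sqrt(fan_in), 1/sqrt(fan_in))",
                 format_version = 1L),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  sizes <- c(x$config$input_dim, x$config$hidden_sizes, x$config$output_dim)
  cat(sprintf("<mlp_model> layers %s, %d parameters, %d epochs trained\n",
              paste(sizes, collapse = " -> "),
              mlp_n_weights(x$config), nrow(x$history)))
  invisible(x)
}

# Standardise features with the statistics frozen at training time.
apply_feature_scale <- function(model, x) {
  fs <- model$feature_scale
  if (is.null(fs)) return(x)
  sweep(sweep(x, 2, fs$mean), 2, fs$sd, "/")
}

# Forward pass. Returns output activations and, if keep = TRUE, the
# per-layer activations (input first) and dropout masks for backprop.
# Dropout is inverted (activations rescaled by 1/(1-p)) and applied to
# hidden layers only, never at prediction time.
mlp_forward <- function(model, x, dropout = FALSE, keep = FALSE) {
  nlayer <- length(model$w)
  p <- model$config$dropout
  a <- x
  acts <- if (keep) vector("list", nlayer + 1L) else NULL
  masks <- if (keep) vector("list", nlayer) else NULL
  if (keep) acts[[1L]] <- a
  for (l in seq_len(nlayer)) {
    zl <- a %*% model$w[[l]]
    zl <- sweep(zl, 2, model$b[[l]], "+")
    if (l < nlayer) {
      a <- tanh(zl)
      if (dropout && p > 0) {
        m <- matrix(stats::rbinom(length(a), 1L, 1 - p) / (1 - p),
                    nrow(a), ncol(a))
        a <- a * m
        if (keep) masks[[l]] <- m
      }
    } else {
      a <- zl                                   # linear output
    }
    if (keep) acts[[l + 1L]] <- a
  }
  if (keep) list(output = a, acts = acts, masks = masks) else a
}

# Gradients of the MSE cost (mean over samples and output points) w.r.t.
# every weight and bias, computed by backpropagation. Used by the trainer
# and by finite-difference verification.
mlp_gradients <- function(model, x, y, dropout = FALSE) {
  nlayer <- length(model$w)
  fw <- mlp_forward(model, x, dropout = dropout, keep = TRUE)
  nb <- nrow(x)
  d <- ncol(y)
  delta <- 2 * (fw$output - y) / (nb * d)
  gw <- vector("list", nlayer)
  gb <- vector("list", nlayer)
  for (l in rev(seq_len(nlayer))) {
    gw[[l]] <- crossprod(fw$acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      a_prev <- fw$acts[[l]]                    # post-dropout activation
      delta <- delta %*% t(model$w[[l]])
      if (!is.null(fw$masks) && !is.null(fw$masks[[l - 1L]])) {
        m <- fw$masks[[l - 1L]]
        # undo mask scaling to recover tanh output, then chain rule
        pre_drop <- ifelse(m > 0, a_prev / m, tanh_of_dropped(model, fw, l))
        delta <- delta * m * (1 - pre_drop^2)
      } else {
        delta <- delta * (1 - a_prev^2)
      }
    }
  }
  list(w = gw, b = gb, cost = mean((fw$output - y)^2))
}

# For dropped units the stored activation is 0 and the tanh output is not
# recoverable from it, but the chain rule multiplies by the zero mask anyway,
# so any finite value works here.
tanh_of_dropped <- function(model, fw, l) 0

#' Cost (MSE) of an MLP on a dataset
#'
#' @param model an `mlp_model`.
#' @param x feature matrix (rows = samples).
#' @param y target matrix (rows = samples).
#' @return mean squared error over all samples and output points.
#' @export
mlp_cost <- function(model, x, y) {
  mean((mlp_forward(model, apply_feature_scale(model, x)) - y)^2)
}

#' Train an MLP
#'
#' ADAM updates over shuffled minibatches with inverted dropout on the
#' hidden layers (training only). Given the same data, configuration, and
#' seed, two runs produce identical histories and weights.
#'
#' @param model an `mlp_model` from [mlp_build()].
#' @param x feature matrix, `ncol(x) == input_dim`.
#' @param y target matrix (one discretised spectrum per row),
#'   `ncol(y) == output_dim`.
#' @param epochs number of epochs (default `config$max_epochs`).
#' @param validation optional list `list(x =, y =)` scored after each epoch
#'   and recorded in the history (also the early-stopping monitor when
#'   `config$patience` is set; otherwise the training MSE is monitored).
#' @param verbose print the MSE every `verbose` epochs (0 = silent).
#' @return the trained `mlp_model` with per-epoch `history`
#'   (`epoch`, `train_mse`, `val_mse`).
#' @export
mlp_train <- function(model, x, y, epochs = NULL, validation = NULL,
                      verbose = 0) {
  stopifnot(inherits(model, "mlp_model"))
  x <- as.matrix(x); y <- as.matrix(y)
  cfg <- model$config
  if (ncol(x) != cfg$input_dim) stop("feature dimension != input_dim")
  if (ncol(y) != cfg$output_dim) stop("target dimension != output_dim")
  if (nrow(x) != nrow(y)) stop("feature and target row counts differ")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite inputs")
  if (is.null(epochs)) epochs <- cfg$max_epochs
  if (cfg$scale_features && is.null(model$feature_scale)) {
    sds <- apply(x, 2, stats::sd)
    model$feature_scale <- list(mean = colMeans(x),
                                sd = ifelse(sds > 0, sds, 1))
  }
  x <- apply_feature_scale(model, x)
  if (!is.null(validation)) {
    validation <- list(x = apply_feature_scale(model,
                                               as.matrix(validation$x)),
                       y = as.matrix(validation$y))
  }
  n <- nrow(x)
  nlayer <- length(model$w)
  mw <- lapply(model$w, function(w) w * 0); vw <- mw
  mb <- lapply(model$b, function(b) b * 0); vb <- mb
  t_step <- 0L
  hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
  best <- Inf; wait <- 0L
  with_rng(derive_seed(cfg$seed, 2), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$minibatch)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + cfg$minibatch - 1L, n)]
        g <- mlp_gradients(model, x[idx, , drop = FALSE],
                           y[idx, , drop = FALSE],
                           dropout = cfg$dropout > 0)
        t_step <- t_step + 1L
        bc1 <- 1 - cfg$adam_beta1^t_step
        bc2 <- 1 - cfg$adam_beta2^t_step
        for (l in seq_len(nlayer)) {
          mw[[l]] <- cfg$adam_beta1 * mw[[l]] + (1 - cfg$adam_beta1) * g$w[[l]]
          vw[[l]] <- cfg$adam_beta2 * vw[[l]] + (1 - cfg$adam_beta2) * g$w[[l]]^2
          model$w[[l]] <- model$w[[l]] - cfg$learning_rate * (mw[[l]] / bc1) /
            (sqrt(vw[[l]] / bc2) + cfg$adam_eps)
          mb[[l]] <- cfg$adam_beta1 * mb[[l]] + (1 - cfg$adam_beta1) * g$b[[l]]
          vb[[l]] <- cfg$adam_beta2 * vb[[l]] + (1 - cfg$adam_beta2) * g$b[[l]]^2
          model$b[[l]] <- model$b[[l]] - cfg$learning_rate * (mb[[l]] / bc1) /
            (sqrt(vb[[l]] / bc2) + cfg$adam_eps)
        }
      }
      # x / validation$x are already standardised here
      tr <- mean((mlp_forward(model, x) - y)^2)
      va <- if (!is.null(validation)) {
        mean((mlp_forward(model, validation$x) - validation$y)^2)
      } else NA_real_
      hist_epoch <- c(hist_epoch, ep)
      hist_train <- c(hist_train, tr)
      hist_val <- c(hist_val, va)
      if (verbose > 0 && ep %% verbose == 0) {
        message(sprintf("epoch %d: train MSE %.6g%s", ep, tr,
                        if (is.na(va)) "" else sprintf(", val MSE %.6g", va)))
      }
      if (!is.null(cfg$patience)) {
        monitor <- if (is.na(va)) tr else va
        if (monitor < best - 1e-12) { best <- monitor; wait <- 0L }
        else { wait <- wait + 1L; if (wait >= cfg$patience) break }
      }
    }
  })
  model$history <- rbind(model$history,
                         data.frame(epoch = nrow(model$history) + hist_epoch,
                                    train_mse = hist_train,
                                    val_mse = hist_val))
  model
}

#' Predict spectra for a feature matrix
#'
#' Dropout is disabled: prediction is deterministic and repeat-stable.
#'
#' @param object a trained `mlp_model`.
#' @param x feature matrix, one row per sample.
#' @param ... unused.
#' @return matrix of predicted spectra, one row per input row, input order
#'   preserved.
#' @export
predict.mlp_model <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$config$input_dim) {
    stop("feature dimension != input_dim")
  }
  out <- mlp_forward(object, apply_feature_scale(object, x),
                     dropout = FALSE)
  rownames(out) <- rownames(x)
  out
}

#' Mean-squared-error scores between spectra tables
#'
#' @param predicted,target numeric matrices of identical shape (rows =
#'   samples, columns = energy grid points).
#' @return list with `per_sample` (mean squared pointwise difference per
#'   row) and `mean` (aggregate over all samples).
#' @export
mse_scores <- function(predicted, target) {
  predicted <- as.matrix(predicted); target <- as.matrix(target)
  if (!all(dim(predicted) == dim(target))) {
    stop("predicted and target shapes differ")
  }
  per <- rowMeans((predicted - target)^2)
  list(per_sample = per, mean = mean(per))
}

#' Save / load a trained model
#'
#' The archive stores the configuration, weight tensors, training history,
#' initialisation descriptor and a format version; [load_mlp()] restores a
#' model with bit-identical predictions.
#'
#' @param model an `mlp_model`.
#' @param path archive path.
#' @return `path` invisibly for `save_mlp`; the restored `mlp_model` for
#'   `load_mlp`.
#' @export
save_mlp <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mlp_model")) stop("'", path, "' is not a model archive")
  model
}
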