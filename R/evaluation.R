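# Model evaluation: repeated K-fold cross-validation, learning curves,
# peak-parity statistics, centile ranking, encoded-radius histograms.

#' Cross-validation configuration
#'
#' Five-fold cross-validation (an 80:20 in-sample/out-of-sample split) with
#' five repetitions by default: each repetition draws a fresh random
#' partition and every sample appears out-of-sample exactly once per
#' repetition.
#'
#' @param k number of folds (>= 2, default 5).
#' @param repetitions independent re-partitions (>= 1, default 5).
#' @param seed integer seed for the partitions and fold-model training.
#' @return a `cv_config` list.
#' @export
cv_config <- function(k = 5L, repetitions = 5L, seed = 1L) {
  k <- as.integer(k); repetitions <- as.integer(repetitions)
  stopifnot(k >= 2L, repetitions >= 1L)
  structure(list(k = k, repetitions = repetitions, seed = as.integer(seed)),
            class = "cv_config")
}

# A random partition of n samples into k folds of near-equal size
# (differing by at most one). Returns an integer fold id per sample.
cv_partition <- function(n, k) {
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  sample(rep(seq_len(k), sizes))
}

#' Repeated K-fold cross-validation of an MLP
#'
#' For each repetition the data are randomly partitioned into `k` folds;
#' each fold in turn is held out-of-sample while a fresh model is trained on
#' the remaining `k - 1` folds, giving `k * repetitions` fold evaluations in
#' total. Performance is always assessed on the out-of-sample fold only.
#'
#' @param features feature matrix (rows = samples).
#' @param targets target spectra matrix (rows = samples).
#' @param model_config an [mlp_config()]; its seed is re-derived per fold so
#'   folds are independent but reproducible.
#' @param cv a [cv_config()].
#' @param epochs training epochs per fold (default
#'   `model_config$max_epochs`).
#' @param keep_predictions store each repetition's out-of-sample predictions
#'   (matrix per repetition, rows aligned with the input) (default TRUE).
#' @return an `evaluation_report`: `fold_mse` (data.frame rep/fold/mse),
#'   `mean`, `sd`, `per_sample` (data.frame rep/sample/mse of out-of-sample
#'   per-sample errors), `predictions` (list by repetition, or NULL), and
#'   the configurations used.
#' @export
kfold_evaluate <- function(features, targets, model_config, cv = cv_config(),
                           epochs = NULL, keep_predictions = TRUE) {
  features <- as.matrix(features); targets <- as.matrix(targets)
  n <- nrow(features)
  stopifnot(nrow(targets) == n)
  if (n < cv$k) stop("fewer samples (", n, ") than folds (", cv$k, ")")
  fold_rows <- list(); per_rows <- list()
  predictions <- if (keep_predictions) vector("list", cv$repetitions) else NULL
  for (rep_i in seq_len(cv$repetitions)) {
    folds <- with_rng(derive_seed(cv$seed, 100, rep_i),
                      cv_partition(n, cv$k))
    if (keep_predictions) {
      pred_rep <- matrix(NA_real_, n, ncol(targets))
    }
    for (fold_i in seq_len(cv$k)) {
      test <- which(folds == fold_i)
      train <- which(folds != fold_i)
      cfg <- model_config
      cfg$seed <- derive_seed(model_config$seed, 1000, rep_i, fold_i)
      model <- mlp_build(cfg)
      model <- mlp_train(model, features[train, , drop = FALSE],
                         targets[train, , drop = FALSE], epochs = epochs)
      pred <- predict(model, features[test, , drop = FALSE])
      sc <- mse_scores(pred, targets[test, , drop = FALSE])
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(rep = rep_i, fold = fold_i, mse = sc$mean)
      per_rows[[length(per_rows) + 1L]] <-
        data.frame(rep = rep_i, sample = test, mse = sc$per_sample)
      if (keep_predictions) pred_rep[test, ] <- pred
    }
    if (keep_predictions) predictions[[rep_i]] <- pred_rep
  }
  fold_mse <- do.call(rbind, fold_rows)
  per_sample <- do.call(rbind, per_rows)
  structure(list(fold_mse = fold_mse,
                 mean = mean(fold_mse$mse),
                 sd = stats::sd(fold_mse$mse),
                 per_sample = per_sample,
                 predictions = predictions,
                 cv = cv, model_config = model_config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %d-fold x %d reps: out-of-sample MSE %.6g +/- %.3g\n",
    x$cv$k, x$cv$repetitions, x$mean, x$sd))
  invisible(x)
}

#' Learning curve over in-sample dataset size
#'
#' For each requested size, a seeded subsample (drawn without replacement,
#' fresh per size) is cross-validated with [kfold_evaluate()] and the mean
#' and standard deviation of the fold MSEs recorded.
#'
#' @param features,targets full dataset matrices.
#' @param sizes sample counts to evaluate (each <= available rows).
#' @param model_config an [mlp_config()].
#' @param cv a [cv_config()].
#' @param epochs training epochs per fold.
#' @return data.frame with columns `size`, `mean_mse`, `sd_mse`.
#' @export
learning_curve_samples <- function(features, targets, sizes, model_config,
                                   cv = cv_config(), epochs = NULL) {
  features <- as.matrix(features); targets <- as.matrix(targets)
  n <- nrow(features)
  if (any(sizes > n)) stop("requested size exceeds available samples (", n, ")")
  out <- data.frame(size = as.integer(sizes), mean_mse = NA_real_,
                    sd_mse = NA_real_)
  for (i in seq_along(sizes)) {
    # the full-dataset point degenerates to a plain kfold_evaluate
    idx <- if (sizes[i] == n) seq_len(n) else
      with_rng(derive_seed(cv$seed, 7, i), sample.int(n, sizes[i]))
    rep_i <- kfold_evaluate(features[idx, , drop = FALSE],
                            targets[idx, , drop = FALSE],
                            model_config, cv, epochs = epochs,
                            keep_predictions = FALSE)
    out$mean_mse[i] <- rep_i$mean
    out$sd_mse[i] <- rep_i$sd
  }
  out
}

#' Locate peaks in a spectrum
#'
#' Local maxima whose topographic prominence is at least
#' `prominence_fraction` times the global maximum intensity. The prominence
#' of a peak is its height above the higher of the two valley floors
#' separating it from higher ground (or the grid edge). Intended for
#' convoluted (broadened) spectra, where ripple below the prominence floor
#' is noise.
#'
#' @param spec an [xas_spectrum][spectrum()].
#' @param prominence_fraction prominence threshold as a fraction of the
#'   global maximum (default 0.05).
#' @return data.frame with columns `energy` and `intensity`, sorted by
#'   energy; zero rows if no peak qualifies.
#' @export
find_peaks <- function(spec, prominence_fraction = 0.05) {
  stopifnot(inherits(spec, "xas_spectrum"))
  y <- spec$intensity; e <- spec$energy
  n <- length(y)
  if (n < 3L) return(data.frame(energy = numeric(0), intensity = numeric(0)))
  # candidate maxima: strictly above the previous point, at least as high as
  # the next (first point of a plateau wins)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  cand <- cand[y[cand] > y[cand - 1L]]
  if (length(cand) == 0L) {
    return(data.frame(energy = numeric(0), intensity = numeric(0)))
  }
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left <- if (i > 1L) {
      higher <- which(y[seq_len(i - 1L)] > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(y[lo:(i - 1L)])
    } else h
    right <- if (i < n) {
      higher <- which(y[(i + 1L):n] > h)
      hi <- if (length(higher)) i + min(higher) - 1L else n
      min(y[(i + 1L):hi])
    } else h
    h - max(left, right)
  }, numeric(1))
  keep <- prom >= prominence_fraction * max(y)
  data.frame(energy = e[cand[keep]], intensity = y[cand[keep]])
}

#' Peak parity between target and estimated spectra
#'
#' For each sample, peaks are extracted from the target and estimated
#' spectra and each target peak is greedily matched to the nearest unused
#' estimated peak within `window` eV (targets processed in energy order).
#' The pooled (energy, intensity) pairs over all samples yield coefficients
#' of determination for peak position and peak intensity.
#'
#' @param targets,estimates matrices of matched spectra (rows = samples) on
#'   the shared energy grid `energy`; both should be convoluted the same
#'   way.
#' @param energy shared energy grid (eV).
#' @param window maximum energy mismatch for a pair (eV, default 5).
#' @param prominence_fraction passed to [find_peaks()] (default 0.05).
#' @param r2_method `"pearson"` (squared Pearson correlation of the pooled
#'   pairs, default) or `"identity"` (1 - SS_res/SS_tot about the y = x
#'   line).
#' @return a `peak_parity` list: `pairs` (data.frame sample, e_target,
#'   e_est, i_target, i_est), `r2_energy`, `r2_intensity` (NA when fewer
#'   than two pairs), `n_unmatched_target`, `n_unmatched_estimate`, and the
#'   settings used.
#' @export
peak_parity <- function(targets, estimates, energy, window = 5,
                        prominence_fraction = 0.05,
                        r2_method = c("pearson", "identity")) {
  r2_method <- match.arg(r2_method)
  targets <- as.matrix(targets); estimates <- as.matrix(estimates)
  stopifnot(all(dim(targets) == dim(estimates)),
            ncol(targets) == length(energy))
  pairs <- list(); un_t <- 0L; un_e <- 0L
  for (s in seq_len(nrow(targets))) {
    pt <- find_peaks(spectrum(energy, targets[s, ], convoluted = TRUE),
                     prominence_fraction)
    pe <- find_peaks(spectrum(energy, estimates[s, ], convoluted = TRUE),
                     prominence_fraction)
    used <- logical(nrow(pe))
    for (i in seq_len(nrow(pt))) {
      if (!any(!used)) { un_t <- un_t + 1L; next }
      cand <- which(!used)
      dE <- abs(pe$energy[cand] - pt$energy[i])
      j <- cand[which.min(dE)]
      if (abs(pe$energy[j] - pt$energy[i]) <= window) {
        used[j] <- TRUE
        pairs[[length(pairs) + 1L]] <-
          data.frame(sample = s, e_target = pt$energy[i],
                     e_est = pe$energy[j], i_target = pt$intensity[i],
                     i_est = pe$intensity[j])
      } else {
        un_t <- un_t + 1L
      }
    }
    un_e <- un_e + sum(!used)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(sample = integer(0), e_target = numeric(0),
               e_est = numeric(0), i_target = numeric(0),
               i_est = numeric(0))
  r2 <- function(a, b) {
    if (length(a) < 2L) return(NA_real_)
    if (r2_method == "pearson") {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)^2
    } else {
      tot <- sum((b - mean(b))^2)
      if (tot == 0) return(NA_real_)
      1 - sum((b - a)^2) / tot
    }
  }
  structure(list(pairs = pairs,
                 r2_energy = r2(pairs$e_target, pairs$e_est),
                 r2_intensity = r2(pairs$i_target, pairs$i_est),
                 n_unmatched_target = un_t, n_unmatched_estimate = un_e,
                 window = window, prominence_fraction = prominence_fraction,
                 r2_method = r2_method),
            class = "peak_parity")
}

#' Centile ranking of per-sample scores
#'
#' Samples are ranked by score ascending (stable: ties keep input order) and
#' assigned `centile = ceiling(100 * rank / n)`. The first centile holds the
#' best-scoring (smallest-MSE) samples, the hundredth the worst.
#'
#' @param scores numeric vector of per-sample MSEs (or any scores where
#'   smaller is better).
#' @return integer vector of centiles in 1..100, aligned with `scores`.
#' @export
centile_rank <- function(scores) {
  n <- length(scores)
  if (n == 0L) return(integer(0))
  rk <- rank(scores, ties.method = "first")
  as.integer(ceiling(100 * rk / n))
}

#' Encoded-radius histograms for a cluster population
#'
#' Histogram (a): the maximum radius around each absorber encoded by an
#' N-atom Coulomb matrix ([max_encoded_radius()]). Histogram (b): the CM
#' dimension needed to encode everything within `radius`
#' ([required_cm_dimension()]). Both are normalised to unit area.
#'
#' @param clusters non-empty list of [atomic_cluster()] objects.
#' @param n CM dimension for histogram (a) (default 20).
#' @param radius radius in Angstrom for histogram (b) (default 4.0).
#' @param breaks_radius,breaks_dimension passed to [graphics::hist()]
#'   (default `"Sturges"`).
#' @return list with `radius` and `dimension` histograms (as returned by
#'   `hist(..., plot = FALSE)` with density normalisation), the raw value
#'   vectors `radius_values` / `dimension_values`, and the modal bin
#'   midpoints `radius_mode` / `dimension_mode`.
#' @export
radius_histograms <- function(clusters, n = 20L, radius = 4.0,
                              breaks_radius = "Sturges",
                              breaks_dimension = "Sturges") {
  stopifnot(length(clusters) > 0L)
  rv <- vapply(clusters, max_encoded_radius, numeric(1), n = n)
  dv <- vapply(clusters, required_cm_dimension, integer(1), radius = radius)
  hr <- graphics::hist(rv, breaks = breaks_radius, plot = FALSE)
  hd <- graphics::hist(as.numeric(dv), breaks = breaks_dimension, plot = FALSE)
  list(radius = hr, dimension = hd,
       radius_values = rv, dimension_values = dv,
       radius_mode = hr$mids[which.max(hr$density)],
       dimension_mode = hd$mids[which.max(hd$density)])
}
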