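# Shared small problem for the CV tests (module-level so each block reuses it).
eval_prob <- toy_problem(40, seed = 606, grid_points = 50, energy_points = 30)
eval_cfg <- mlp_config(input_dim = 50, output_dim = 30, first_hidden = 24,
                       minibatch = 10, seed = 5)

test_that("K-fold partitions are disjoint, exhaustive, and near-equal", {
  set.seed(1)
  for (n in c(10, 23, 100)) {
    folds <- nearedge:::cv_partition(n, 5)
    expect_length(folds, n)
    expect_setequal(unique(folds), 1:5)
    sizes <- tabulate(folds, 5)
    expect_lte(diff(range(sizes)), 1L)
  }
})

test_that("repeated K-fold evaluation produces k x reps folds, deterministically", {
  cv <- cv_config(k = 5, repetitions = 5, seed = 17)
  rep1 <- kfold_evaluate(eval_prob$x, eval_prob$y, eval_cfg, cv, epochs = 5)
  expect_identical(nrow(rep1$fold_mse), 25L)
  # per repetition: every sample out-of-sample exactly once
  for (r in 1:5) {
    seen <- rep1$per_sample$sample[rep1$per_sample$rep == r]
    expect_setequal(seen, seq_len(nrow(eval_prob$x)))
    expect_identical(length(seen), nrow(eval_prob$x))
  }
  # reported sd equals the direct formula over fold MSEs
  expect_equal(rep1$sd, sd(rep1$fold_mse$mse), tolerance = 1e-12)
  expect_equal(rep1$mean, mean(rep1$fold_mse$mse), tolerance = 1e-12)
  # determinism: identical partitions and identical per-fold MSEs
  rep2 <- kfold_evaluate(eval_prob$x, eval_prob$y, eval_cfg, cv, epochs = 5)
  expect_identical(rep1$fold_mse, rep2$fold_mse)
  expect_error(kfold_evaluate(eval_prob$x[1:3, ], eval_prob$y[1:3, ],
                              eval_cfg, cv), "fewer samples")
})

test_that("learning curves report one seeded point per requested size", {
  cv <- cv_config(k = 4, repetitions = 1, seed = 3)
  curve <- learning_curve_samples(eval_prob$x, eval_prob$y,
                                  sizes = c(16, 40), eval_cfg, cv,
                                  epochs = 5)
  expect_identical(curve$size, c(16L, 40L))
  expect_true(all(is.finite(curve$mean_mse)))
  expect_true(all(curve$sd_mse >= 0))
  # full-dataset point equals kfold_evaluate run directly
  full <- kfold_evaluate(eval_prob$x, eval_prob$y, eval_cfg, cv, epochs = 5,
                         keep_predictions = FALSE)
  expect_equal(curve$mean_mse[2], full$mean, tolerance = 1e-12)
  expect_error(learning_curve_samples(eval_prob$x, eval_prob$y, 1000,
                                      eval_cfg, cv), "exceeds")
})

test_that("find_peaks keeps prominent maxima only", {
  e <- seq(0, 100, by = 0.25)
  bump <- exp(-(e - 40)^2 / 20)
  pk <- find_peaks(spectrum(e, bump, convoluted = TRUE))
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$energy, 40)

  ramp <- find_peaks(spectrum(e, e / 100, convoluted = TRUE))
  expect_identical(nrow(ramp), 0L)

  # two bumps plus a ripple below the prominence floor
  y <- exp(-(e - 30)^2 / 15) + 0.7 * exp(-(e - 70)^2 / 25) +
    0.02 * sin(e * 2)
  pk2 <- find_peaks(spectrum(e, y, convoluted = TRUE),
                    prominence_fraction = 0.05)
  expect_identical(nrow(pk2), 2L)
  expect_equal(pk2$energy, c(30, 70), tolerance = 0.1)
})

test_that("peak parity is perfect on identical tables and NA with no matches", {
  e <- seq(0, 100, by = 0.25)
  set.seed(10)
  tab <- t(vapply(1:6, function(i) {
    exp(-(e - runif(1, 20, 45))^2 / 12) +
      runif(1, 0.4, 0.9) * exp(-(e - runif(1, 55, 85))^2 / 20)
  }, numeric(length(e))))
  self <- peak_parity(tab, tab, e)
  expect_equal(self$r2_energy, 1.0)
  expect_equal(self$r2_intensity, 1.0)
  expect_identical(self$n_unmatched_target, 0L)

  # shift estimates beyond the window: nothing matches
  shifted <- peak_parity(tab[, ], cbind(tab[, -(1:60)], tab[, 1:60]), e,
                         window = 2)
  expect_true(is.na(shifted$r2_energy))

  # known jitter: R^2 equals a direct correlation on the pair list
  jit <- tab
  for (i in seq_len(nrow(tab))) {
    sh <- sample(0:12, 1)                      # up to 3 eV circular shift
    jit[i, ] <- tab[i, ((seq_along(e) - 1 + sh) %% length(e)) + 1]
  }
  pp <- peak_parity(tab, jit, e, window = 5)
  if (nrow(pp$pairs) >= 2) {
    expect_equal(pp$r2_energy, cor(pp$pairs$e_target, pp$pairs$e_est)^2,
                 tolerance = 1e-12)
    expect_equal(pp$r2_intensity, cor(pp$pairs$i_target, pp$pairs$i_est)^2,
                 tolerance = 1e-12)
  }
})

test_that("centile ranking is exact, stable under ties, and monotone-invariant", {
  set.seed(2)
  s100 <- runif(100)
  c100 <- centile_rank(s100)
  expect_identical(sort(unique(c100)), 1:100)       # one sample per centile
  expect_identical(tabulate(c100, 100), rep(1L, 100))
  expect_identical(c100[which.min(s100)], 1L)
  expect_identical(c100[which.max(s100)], 100L)

  ties <- centile_rank(rep(0.5, 10))
  expect_identical(ties, as.integer(ceiling(100 * 1:10 / 10)))

  # invariance under strictly monotone transforms
  expect_identical(centile_rank(exp(s100)), c100)
  expect_identical(centile_rank(rank(s100)), c100)

  # boundaries match a sort-based oracle
  s <- runif(37)
  want <- integer(37)
  ord <- order(s)
  for (r in seq_along(ord)) want[ord[r]] <- as.integer(ceiling(100 * r / 37))
  expect_identical(centile_rank(s), want)
})

test_that("radius histograms are unit-area with the planted mode", {
  # population whose 20th-nearest distance is 3.5 for most clusters
  set.seed(33)
  make_shell_cluster <- function(r20) {
    repeat {
      dirs <- matrix(rnorm(19 * 3), 19, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      radii <- c(sort(runif(18, 1.5, r20 - 0.05)), r20)
      xyz <- rbind(c(0, 0, 0), dirs * radii)
      if (min(dist(xyz)) >= 0.2) {
        return(atomic_cluster(c(26L, rep(8L, 19)), xyz))
      }
    }
  }
  clusters <- c(lapply(rep(3.5, 40), make_shell_cluster),
                lapply(runif(10, 2.5, 4.4), make_shell_cluster))
  h <- radius_histograms(clusters, n = 20, radius = 4.0,
                         breaks_radius = seq(1, 5, by = 0.25))
  expect_equal(sum(h$radius$density * diff(h$radius$breaks)), 1,
               tolerance = 1e-9)
  expect_equal(sum(h$dimension$density * diff(h$dimension$breaks)), 1,
               tolerance = 1e-9)
  expect_lt(abs(h$radius_mode - 3.5), 0.25)

  # identical clusters collapse to a single occupied bin
  same <- lapply(rep(3.0, 5), make_shell_cluster)
  hs <- radius_histograms(same, n = 20, radius = 4.0)
  expect_identical(sum(hs$radius$counts > 0), 1L)
})
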