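test_that("coulomb_matrix matches the closed form on minimal clusters", {
  h1 <- atomic_cluster(1L, c(0, 0, 0), label = "h")
  expect_equal(coulomb_matrix(h1, cm_config(n = 1))$m, matrix(0.5))

  # 0.5 * 26^2.4 computed independently beforehand
  fe <- atomic_cluster(26L, c(0, 0, 0))
  expect_equal(coulomb_matrix(fe, cm_config(n = 1))$m,
               matrix(1244.2453875152546), tolerance = 1e-12)

  h2 <- atomic_cluster(c(1L, 1L), rbind(c(0, 0, 0), c(1, 0, 0)))
  m <- coulomb_matrix(h2, cm_config(n = 2))$m
  expect_equal(diag(m), c(0.5, 0.5))
  expect_equal(m[1, 2], 1.0)
  expect_equal(m, t(m))
})

test_that("coulomb_matrix matches the naive double-loop oracle and zero-fills", {
  for (seed in c(2, 5, 19)) {
    cl <- random_test_cluster(12, seed = seed)
    cm <- coulomb_matrix(cl, cm_config(n = 20))
    expect_equal(cm$m, naive_cm(cl, 20), tolerance = 1e-12)
    expect_true(all(cm$m[13:20, ] == 0))
    expect_true(all(cm$m[, 13:20] == 0))
  }
})

test_that("sort_cm matches exhaustive permutation search at small N", {
  for (seed in c(1, 4, 9)) {
    cl <- random_test_cluster(6, seed = seed)
    cm <- sort_cm(coulomb_matrix(cl, cm_config(n = 6)))
    norms <- sqrt(rowSums(cm$m^2))
    expect_true(all(diff(norms) <= 1e-12))
    expect_equal(cm$m, t(cm$m))
    # exhaustive: find the permutation of the unsorted matrix whose row
    # norms are non-increasing and compare
    m0 <- coulomb_matrix(cl, cm_config(n = 6))$m
    found <- NULL
    for (p in all_permutations(6)) {
      mp <- m0[p, p]
      if (!is.unsorted(rev(sqrt(rowSums(mp^2))))) { found <- mp; break }
    }
    expect_equal(cm$m, found)
  }
  # already-sorted input is unchanged
  cl <- random_test_cluster(5, seed = 31)
  cm1 <- sort_cm(coulomb_matrix(cl, cm_config(n = 5)))
  expect_equal(sort_cm(cm1)$m, cm1$m)
})

test_that("flatten_cm yields the row-wise upper triangle and inverts", {
  cm <- structure(list(m = matrix(c(1, 2, 2, 3), 2), k = 2L, label = "",
                       config = cm_config(2)), class = "coulomb_matrix")
  expect_equal(as.numeric(flatten_cm(cm)), c(1, 2, 3))

  cl <- random_test_cluster(12, seed = 8)
  v <- flatten_cm(sort_cm(coulomb_matrix(cl, cm_config(n = 20))))
  expect_length(v, 210L)
  expect_true(all(is.finite(v)))
  expect_equal(unflatten_cm(as.numeric(v)),
               sort_cm(coulomb_matrix(cl, cm_config(n = 20)))$m)
})

test_that("rdc matches the closed form and the naive pair-loop oracle", {
  lone <- atomic_cluster(26L, c(0, 0, 0))
  cfg <- rdc_config(alpha = 10, cutoff = 4, grid = seq(0, 8, by = 0.01))
  expect_true(all(rdc(lone, cfg) == 0))

  # single pair of unit charges 2 Angstrom apart: exp(-alpha (2 - R)^2)
  pair <- atomic_cluster(c(1L, 1L), rbind(c(0, 0, 0), c(2, 0, 0)))
  f <- rdc(pair, cfg)
  expect_equal(as.numeric(f), exp(-10 * (2 - cfg$grid)^2), tolerance = 1e-12)
  expect_equal(max(f), 1.0)
  expect_equal(cfg$grid[which.max(f)], 2.0)

  # three atoms: sum over the 3 pairs
  tri <- atomic_cluster(c(26L, 8L, 9L),
                        rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2.5, 0)))
  expect_equal(as.numeric(rdc(tri, cfg)),
               naive_rdc(tri, 10, 4, cfg$grid), tolerance = 1e-12)

  for (seed in c(3, 14)) {
    cl <- random_test_cluster(18, seed = seed)
    expect_equal(as.numeric(rdc(cl, cfg)),
                 naive_rdc(cl, 10, 4, cfg$grid), tolerance = 1e-12)
  }

  # all-ones weights reduce to the unweighted pair-distance kernel density
  cfg1 <- rdc_config(alpha = 10, cutoff = 4, grid = cfg$grid,
                     weight_property = function(z) rep(1, length(z)))
  cl <- random_test_cluster(10, seed = 21)
  expect_equal(as.numeric(rdc(cl, cfg1)),
               naive_rdc(cl, 10, 4, cfg$grid,
                         weight = function(z) rep(1, length(z))),
               tolerance = 1e-12)
})

test_that("sorted-CM and RDC features are invariant to rigid motions and ordering", {
  cfg_rdc <- rdc_config(grid = seq(0, 8, length.out = 200))
  set.seed(77)
  for (seed in c(6, 13)) {
    cl <- random_test_cluster(15, seed = seed)
    v_cm <- as.numeric(flatten_cm(sort_cm(coulomb_matrix(cl))))
    v_rdc <- as.numeric(rdc(cl, cfg_rdc))
    for (i in 1:10) {
      tr <- transform_cluster(cl, rot = random_rotation(),
                              shift = rnorm(3, sd = 5),
                              perm = sample(length(cl$z)))
      expect_equal(as.numeric(flatten_cm(sort_cm(coulomb_matrix(tr)))),
                   v_cm, tolerance = 1e-10)
      expect_equal(as.numeric(rdc(tr, cfg_rdc)), v_rdc, tolerance = 1e-10)
    }
  }
})

test_that("CM off-diagonals scale as 1/s under distance scaling", {
  cl <- random_test_cluster(10, seed = 17)
  s <- 1.7
  scaled <- atomic_cluster(cl$z, cl$xyz * s, absorber = cl$absorber)
  m1 <- sort_cm(coulomb_matrix(cl, cm_config(n = 10)))$m
  m2 <- sort_cm(coulomb_matrix(scaled, cm_config(n = 10)))$m
  off <- upper.tri(m1)
  expect_equal(m2[off], m1[off] / s, tolerance = 1e-10)
  expect_equal(diag(m2), diag(m1))
})

test_that("larger alpha never widens an RDC peak", {
  pair <- atomic_cluster(c(8L, 8L), rbind(c(0, 0, 0), c(2.5, 0, 0)))
  grid <- seq(0, 8, by = 0.002)
  fwhm <- function(alpha) {
    f <- as.numeric(rdc(pair, rdc_config(alpha = alpha, cutoff = 4,
                                         grid = grid)))
    sum(f >= max(f) / 2) * 0.002
  }
  widths <- vapply(c(0.5, 2, 10, 50, 200), fwhm, numeric(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("featurise_batch keeps order, labels rows, and isolates failures", {
  cls <- lapply(1:3, function(i) random_test_cluster(8, seed = 100 + i))
  tab <- featurise_batch(cls, "rdc", rdc_config(grid = seq(0, 8, 0.1)))
  expect_identical(nrow(tab), 3L)
  expect_identical(rownames(tab),
                   vapply(cls, function(cl) cl$label, character(1)))

  expect_warning(empty <- featurise_batch(list(), "cm"), "empty")
  expect_identical(nrow(empty), 0L)

  # one corrupt entry among many: row dropped, failure itemised
  bad <- c(cls, list("not a cluster"))
  tab2 <- featurise_batch(bad, "cm")
  expect_identical(nrow(tab2), 3L)
  expect_length(attr(tab2, "failures"), 1L)

  expect_error(featurise_batch(list("a", "b"), "cm"), "all 2 clusters failed")
})

test_that("feature tables round-trip through delimited text", {
  cls <- lapply(1:4, function(i) random_test_cluster(10, seed = 200 + i))
  tab <- featurise_batch(cls, "cm")
  path <- tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(as.numeric(back), as.numeric(tab), tolerance = 1e-10)
  expect_identical(dim(back), dim(tab))
  expect_identical(rownames(back), rownames(tab))
  expect_identical(attr(back, "representation"), "cm")
})

test_that("max_encoded_radius and required_cm_dimension match distance oracles", {
  # 19 atoms on a 3-Angstrom shell + absorber: N = 20 encodes exactly 3.0
  set.seed(5)
  dirs <- matrix(rnorm(19 * 3), 19, 3)
  dirs <- 3 * dirs / sqrt(rowSums(dirs^2))
  shell <- atomic_cluster(c(26L, rep(8L, 19)), rbind(c(0, 0, 0), dirs))
  expect_equal(max_encoded_radius(shell, 20), 3.0, tolerance = 1e-12)

  lone <- atomic_cluster(26L, c(0, 0, 0))
  expect_equal(max_encoded_radius(lone, 20), 0.0)
  expect_identical(required_cm_dimension(lone, 4.0), 1L)

  cl <- random_test_cluster(30, seed = 44)
  d <- sort(sqrt(colSums((t(cl$xyz) - cl$xyz[cl$absorber, ])^2)))
  expect_equal(max_encoded_radius(cl, 12), d[12])
  expect_identical(required_cm_dimension(cl, 3.0), sum(d <= 3.0))
  # the N-th nearest atom is inside the max encoded radius by construction
  expect_true(max_encoded_radius(cl, 12) >= d[12] - 1e-12)
})
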