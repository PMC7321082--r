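# Independent brute-force oracles and fixture generators. These stay naive
# (explicit double loops, exhaustive enumeration) on purpose: they verify
# the vectorised implementations without sharing code with them.

# Random cluster with an Fe absorber at a random position; atoms are placed
# uniformly in a box and re-drawn until all pairwise separations exceed
# 0.8 Angstrom, so distances are distinct with probability one.
random_test_cluster <- function(n, seed, box = 6) {
  set.seed(seed)
  repeat {
    xyz <- matrix(runif(n * 3, -box / 2, box / 2), n, 3)
    if (n == 1 || min(dist(xyz)) > 0.8) break
  }
  z <- sample(c(1L, 6L, 8L, 9L, 16L, 26L), n, replace = TRUE)
  absorber <- sample.int(n, 1)
  z[absorber] <- 26L
  atomic_cluster(z, xyz, absorber = absorber, label = sprintf("rt_%d", seed))
}

# Uniform random proper rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid transform (rotation + translation) and a site permutation to
# a cluster, keeping track of the absorber.
transform_cluster <- function(cluster, rot = diag(3), shift = c(0, 0, 0),
                              perm = seq_along(cluster$z)) {
  xyz <- cluster$xyz %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  atomic_cluster(cluster$z[perm], xyz[perm, , drop = FALSE],
                 absorber = match(cluster$absorber, perm),
                 label = cluster$label)
}

# Naive Coulomb matrix: explicit double loop over the N nearest sites.
naive_cm <- function(cluster, n) {
  d <- sqrt(colSums((t(cluster$xyz) - cluster$xyz[cluster$absorber, ])^2))
  ord <- order(d)[seq_len(min(n, length(d)))]
  z <- cluster$z[ord]
  xyz <- cluster$xyz[ord, , drop = FALSE]
  k <- length(z)
  m <- matrix(0, n, n)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      m[i, j] <- if (i == j) 0.5 * z[i]^2.4 else
        z[i] * z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    }
  }
  m
}

# Naive RDC: explicit pair loop over the in-cutoff sub-cluster.
naive_rdc <- function(cluster, alpha, cutoff, grid, weight = identity) {
  d <- sqrt(colSums((t(cluster$xyz) - cluster$xyz[cluster$absorber, ])^2))
  keep <- which(d <= cutoff)
  z <- cluster$z[keep]
  xyz <- cluster$xyz[keep, , drop = FALSE]
  w <- weight(z)
  f <- numeric(length(grid))
  if (length(z) >= 2) {
    for (i in seq_len(length(z) - 1)) {
      for (j in (i + 1):length(z)) {
        rij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        f <- f + w[i] * w[j] * exp(-alpha * (rij - grid)^2)
      }
    }
  }
  f
}

# All permutations of 1..n (recursive; for exhaustive sort_cm search, n <= 7).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Write a small XYZ file from raw text lines.
write_xyz_text <- function(lines) {
  path <- tempfile(fileext = ".xyz")
  writeLines(lines, path)
  path
}

# Small default-shaped synthetic problem shared by model/evaluation tests:
# RDC features on a coarse grid, toy spectra on a short energy grid.
toy_problem <- function(n_clusters, seed, grid_points = 120,
                        energy_points = 60) {
  cfg <- synthetic_config(
    n_clusters = n_clusters, atoms_range = c(8L, 16L),
    energy_grid = seq(0, 100, length.out = energy_points), seed = seed)
  clusters <- generate_clusters(cfg)
  feats <- featurise_batch(
    clusters, "rdc",
    rdc_config(grid = seq(0, 8, length.out = grid_points)))
  y <- do.call(rbind, lapply(clusters, function(cl)
    toy_spectrum(cl, cfg)$intensity))
  list(config = cfg, clusters = clusters, x = feats, y = y,
       energy = cfg$energy_grid)
}
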