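# Chemical-space representations: sorted Coulomb matrix and radial
# distribution curve (RDC).

#' Coulomb-matrix configuration
#'
#' @param n matrix dimension N, i.e. the upper limit on the number of atoms
#'   encoded (default 20). Clusters with more atoms are truncated to the N
#'   nearest the absorber; smaller clusters are zero-padded.
#' @param length_unit `"angstrom"` (default) or `"bohr"`. Distances in the
#'   off-diagonal Coulomb terms are expressed in this unit; switching merely
#'   rescales off-diagonal features.
#' @return a `cm_config` list.
#' @export
cm_config <- function(n = 20L, length_unit = c("angstrom", "bohr")) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  length_unit <- match.arg(length_unit)
  structure(list(n = n, length_unit = length_unit), class = "cm_config")
}

BOHR_PER_ANGSTROM <- 1 / 0.529177210903

#' Coulomb matrix of a cluster
#'
#' Builds the N x N Coulomb matrix of the `config$n` sites nearest the
#' absorber: diagonal entries are the free-atom terms `0.5 * Z^2.4`,
#' off-diagonal entries the pairwise repulsion `Z_I * Z_J / |R_I - R_J|`.
#' When the cluster has k < N sites, rows and columns k+1..N are zero-filled.
#'
#' @param cluster an [atomic_cluster()].
#' @param config a [cm_config()].
#' @return a `coulomb_matrix`: list with the symmetric matrix `m`, the number
#'   of encoded sites `k`, the cluster `label`, and the `config`.
#' @export
coulomb_matrix <- function(cluster, config = cm_config()) {
  stopifnot(inherits(cluster, "atomic_cluster"), inherits(config, "cm_config"))
  sub <- nearest_n(cluster, config$n)
  k <- length(sub$z)
  z <- as.numeric(sub$z)
  scale <- if (config$length_unit == "bohr") BOHR_PER_ANGSTROM else 1
  m <- matrix(0, config$n, config$n)
  if (k > 0L) {
    r <- as.matrix(stats::dist(sub$xyz)) * scale
    if (k > 1L && min(r[upper.tri(r)]) <= 0) {
      stop("singular geometry: coincident atoms in cluster")
    }
    zz <- outer(z, z)
    block <- zz / (r + diag(k))          # placeholder diagonal, overwritten
    diag(block) <- 0.5 * z^2.4
    m[seq_len(k), seq_len(k)] <- block
  }
  structure(list(m = m, k = k, label = cluster$label, config = config),
            class = "coulomb_matrix")
}

#' Sort a Coulomb matrix by row norm
#'
#' Applies one permutation simultaneously to rows and columns so that row
#' Euclidean (L2) norms are non-increasing. The sort is stable: rows with
#' equal norms keep their relative order, so symmetric geometries featurise
#' deterministically. Zero-filled padding rows (norm 0) end up trailing.
#'
#' @param cm a `coulomb_matrix` from [coulomb_matrix()].
#' @return the sorted `coulomb_matrix`.
#' @export
sort_cm <- function(cm) {
  stopifnot(inherits(cm, "coulomb_matrix"))
  norms <- sqrt(rowSums(cm$m^2))
  ord <- order(-norms)                  # stable for ties
  cm$m <- cm$m[ord, ord, drop = FALSE]
  cm
}

#' Flatten the upper triangle of a Coulomb matrix
#'
#' Takes the upper triangle (including the diagonal) row-wise, yielding a
#' feature vector of length N(N+1)/2 (210 at N = 20).
#'
#' @param cm a sorted `coulomb_matrix`.
#' @return a `feature_vector`: numeric vector with attributes
#'   `representation = "cm"` and `config`.
#' @export
flatten_cm <- function(cm) {
  stopifnot(inherits(cm, "coulomb_matrix"))
  mt <- t(cm$m)
  v <- mt[lower.tri(mt, diag = TRUE)]   # row-wise upper triangle of m
  structure(v, representation = "cm", config = cm$config,
            class = "feature_vector")
}

#' Rebuild a symmetric Coulomb matrix from its flattened upper triangle
#'
#' Inverse of [flatten_cm()] (up to the dropped `k`/`label` metadata).
#'
#' @param v a numeric vector of length N(N+1)/2.
#' @return the symmetric N x N matrix.
#' @export
unflatten_cm <- function(v) {
  n <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(n - round(n)) > 1e-9) stop("length is not triangular: ", length(v))
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  mt <- t(m)
  mt[lower.tri(mt, diag = TRUE)] <- v
  m <- t(mt)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Radial-distribution-curve configuration
#'
#' @param alpha Gaussian smoothing parameter in 1/Angstrom^2 (default 10).
#'   Larger values sharpen the pair-distance peaks; very large values make
#'   the curve sparse.
#' @param cutoff radius in Angstrom around the absorber defining the local
#'   environment (default 4.0). The grid spans twice this value so every
#'   in-cutoff pair distance is representable.
#' @param grid evaluation distances in Angstrom; default 800 evenly spaced
#'   points from 0 to `2 * cutoff` inclusive.
#' @param weight_property function mapping atomic numbers to per-atom weights
#'   w(Z); the default is the nuclear charge itself. Any scalar atomic
#'   property (electronegativity, van der Waals radius, ...) can be used.
#' @return an `rdc_config` list.
#' @export
rdc_config <- function(alpha = 10.0, cutoff = 4.0,
                       grid = seq(0, 2 * cutoff, length.out = 800L),
                       weight_property = identity) {
  stopifnot(alpha > 0, cutoff > 0, is.function(weight_property))
  grid <- as.numeric(grid)
  if (length(grid) < 1L || any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing")
  }
  structure(list(alpha = alpha, cutoff = cutoff, grid = grid,
                 weight_property = weight_property),
            class = "rdc_config")
}

#' Radial distribution curve of a cluster
#'
#' Encodes the local environment as an intensity distribution over
#' interatomic distance: `f(R) = sum_{I<J} w_I w_J exp(-alpha (r_IJ - R)^2)`
#' evaluated at every grid point. The sum runs over all pairs among the sites
#' within `config$cutoff` of the absorber (the cutoff sub-clustering is
#' applied internally); the absorber participates like any other site. The
#' default weights are the nuclear charges.
#'
#' @param cluster an [atomic_cluster()].
#' @param config an [rdc_config()].
#' @return a `feature_vector` of length `length(config$grid)` with attributes
#'   `representation = "rdc"` and `config`. A single-site environment yields
#'   the all-zero vector.
#' @export
rdc <- function(cluster, config = rdc_config()) {
  stopifnot(inherits(cluster, "atomic_cluster"), inherits(config, "rdc_config"))
  env <- local_environment(cluster, config$cutoff)
  k <- length(env$z)
  f <- numeric(length(config$grid))
  if (k > 1L) {
    r <- as.matrix(stats::dist(env$xyz))
    w <- as.numeric(config$weight_property(env$z))
    pair <- which(upper.tri(r), arr.ind = TRUE)
    rij <- r[pair]
    wij <- w[pair[, 1]] * w[pair[, 2]]
    # grid x pair Gaussian kernel, weighted sum over pairs
    kern <- exp(-config$alpha * (outer(config$grid, rij, "-"))^2)
    f <- as.numeric(kern %*% wij)
  }
  structure(f, representation = "rdc", config = config,
            class = "feature_vector")
}

#' Featurise a batch of clusters
#'
#' @param clusters list of [atomic_cluster()] objects.
#' @param representation `"cm"` (sorted, flattened Coulomb matrix) or
#'   `"rdc"`.
#' @param config a [cm_config()] or [rdc_config()] matching the
#'   representation (defaults are used when omitted).
#' @return numeric matrix, one row per successfully featurised cluster (rows
#'   in input order, rownames = cluster labels). Per-cluster failures are
#'   collected in the `"failures"` attribute (named character vector of
#'   messages); the call errors only if every cluster fails.
#' @export
featurise_batch <- function(clusters, representation = c("cm", "rdc"),
                            config = NULL) {
  representation <- match.arg(representation)
  if (is.null(config)) {
    config <- if (representation == "cm") cm_config() else rdc_config()
  }
  if (representation == "cm") stopifnot(inherits(config, "cm_config"))
  if (representation == "rdc") stopifnot(inherits(config, "rdc_config"))
  p <- if (representation == "cm") config$n * (config$n + 1L) / 2L else
    length(config$grid)
  if (length(clusters) == 0L) {
    warning("featurise_batch: empty cluster list")
    out <- matrix(numeric(0), 0L, p)
    attr(out, "failures") <- character(0)
    return(out)
  }
  rows <- vector("list", length(clusters))
  failures <- character(0)
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    lab <- if (inherits(cl, "atomic_cluster") && nzchar(cl$label)) cl$label
           else sprintf("cluster_%d", i)
    res <- tryCatch({
      if (representation == "cm") {
        as.numeric(flatten_cm(sort_cm(coulomb_matrix(cl, config))))
      } else {
        as.numeric(rdc(cl, config))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[lab] <- conditionMessage(res)
    } else {
      rows[[i]] <- stats::setNames(list(res), lab)
    }
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) {
    stop("featurise_batch: all ", length(clusters), " clusters failed; first: ",
         failures[1])
  }
  out <- do.call(rbind, lapply(rows[ok], function(x) x[[1]]))
  rownames(out) <- vapply(rows[ok], names, character(1))
  attr(out, "failures") <- failures
  attr(out, "representation") <- representation
  out
}

#' Maximum radius encoded by an N-atom Coulomb matrix
#'
#' Distance from the absorber to the N-th nearest atom (the absorber itself
#' counts as the first). If the cluster has fewer than N sites the distance
#' to the farthest site is returned.
#'
#' @param cluster an [atomic_cluster()].
#' @param n CM dimension (default 20).
#' @return radius in Angstrom.
#' @export
max_encoded_radius <- function(cluster, n = 20L) {
  stopifnot(n >= 1L)
  d <- sort(absorber_distances(cluster))
  d[min(n, length(d))]
}

#' CM dimension needed to encode a radius
#'
#' Number of sites within `radius` of the absorber, the absorber included:
#' the Coulomb-matrix dimension N that would capture the whole local
#' environment out to `radius`.
#'
#' @param cluster an [atomic_cluster()].
#' @param radius radius in Angstrom (> 0; default 4.0).
#' @param include_absorber count the absorber itself (default TRUE).
#' @return integer site count.
#' @export
required_cm_dimension <- function(cluster, radius = 4.0,
                                  include_absorber = TRUE) {
  stopifnot(radius > 0)
  d <- absorber_distances(cluster)
  n <- sum(d <= radius)
  if (!include_absorber) n <- n - 1L
  as.integer(n)
}

#' Write a feature table to delimited text
#'
#' One row per cluster; a `#`-prefixed header records the representation and
#' a hash of the configuration so tables from different configurations are
#' not silently mixed. Round-trips through [read_feature_table()].
#'
#' @param features matrix from [featurise_batch()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  rep_tag <- attr(features, "representation")
  if (is.null(rep_tag)) rep_tag <- "unknown"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nearedge feature table representation=%s ncol=%d",
                     rep_tag, ncol(features)), con)
  labs <- rownames(features)
  if (is.null(labs)) labs <- sprintf("cluster_%d", seq_len(nrow(features)))
  for (i in seq_len(nrow(features))) {
    writeLines(paste(c(labs[i], sprintf("%.12g", features[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path path to a feature-table file.
#' @return numeric matrix with rownames and a `representation` attribute.
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rep_tag <- regmatches(hdr[1], regexpr("representation=[^ ]+", hdr[1]))
  rep_tag <- if (length(rep_tag)) sub("representation=", "", rep_tag) else NA
  parts <- strsplit(body, "\t", fixed = TRUE)
  labs <- vapply(parts, `[`, character(1), 1L)
  vals <- lapply(parts, function(p) as.numeric(p[-1L]))
  out <- do.call(rbind, vals)
  rownames(out) <- labs
  attr(out, "representation") <- rep_tag
  out
}
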