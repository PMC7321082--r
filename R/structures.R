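# Atomic clusters: the absorber-centred unit of featurisation.

# Element symbols indexed by atomic number (H = 1 .. Lr = 103).
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr")

#' Map element symbols to atomic numbers
#'
#' @param symbol character vector of element symbols (case-sensitive, e.g.
#'   `"Fe"`).
#' @return integer vector of atomic numbers.
#' @export
element_z <- function(symbol) {
  z <- match(symbol, ELEMENT_SYMBOLS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  }
  as.integer(z)
}

#' Map atomic numbers to element symbols
#'
#' @param z integer vector of atomic numbers (1..103).
#' @return character vector of element symbols.
#' @export
element_symbol <- function(z) {
  if (any(z < 1 | z > length(ELEMENT_SYMBOLS))) {
    stop("atomic number out of range 1..", length(ELEMENT_SYMBOLS))
  }
  ELEMENT_SYMBOLS[z]
}

# Pairwise-separation guard: clusters with two sites closer than this (in
# Angstrom) are rejected as corrupt geometry.
MIN_SEPARATION <- 0.1

#' Construct an atomic cluster
#'
#' An `atomic_cluster` is an ordered set of atom sites (atomic number plus
#' Cartesian position in Angstrom) with one site designated as the X-ray
#' absorber. It is the unit on which the Coulomb-matrix and
#' radial-distribution-curve featurisers operate.
#'
#' @param z integer vector of atomic numbers, one per site (all >= 1).
#' @param xyz numeric matrix with one row per site and columns x, y, z
#'   (Angstrom).
#' @param absorber 1-based index of the absorbing atom in `z`/`xyz`.
#' @param label free-text identifier carried through featurisation.
#' @return an object of class `atomic_cluster` with fields `z`, `xyz`,
#'   `absorber`, `label`.
#' @export
atomic_cluster <- function(z, xyz, absorber = 1L, label = "") {
  z <- as.integer(z)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (length(z) == 0L) stop("cluster must contain at least one site")
  if (nrow(xyz) != length(z)) stop("z and xyz disagree on the number of sites")
  if (any(z < 1L)) stop("atomic numbers must be >= 1")
  if (!all(is.finite(xyz))) stop("positions must be finite")
  absorber <- as.integer(absorber)
  if (length(absorber) != 1L || is.na(absorber) ||
      absorber < 1L || absorber > length(z)) {
    stop("absorber index out of range")
  }
  if (length(z) > 1L) {
    dmin <- min(stats::dist(xyz))
    if (dmin < MIN_SEPARATION) {
      stop(sprintf(
        "degenerate geometry: two sites are %.4f Angstrom apart (< %.1f)",
        dmin, MIN_SEPARATION))
    }
  }
  structure(list(z = z, xyz = xyz, absorber = absorber,
                 label = as.character(label)),
            class = "atomic_cluster")
}

#' @export
print.atomic_cluster <- function(x, ...) {
  cat(sprintf("<atomic_cluster> %d sites, absorber %s at index %d%s\n",
              length(x$z), element_symbol(x$z[x$absorber]), x$absorber,
              if (nzchar(x$label)) paste0(", label '", x$label, "'") else ""))
  invisible(x)
}

#' @export
length.atomic_cluster <- function(x) length(x$z)

#' Distances from every site to the absorber
#'
#' @param cluster an [atomic_cluster()].
#' @return numeric vector of Euclidean distances (Angstrom); the absorber's
#'   own entry is 0.
#' @export
absorber_distances <- function(cluster) {
  d <- sweep(cluster$xyz, 2, cluster$xyz[cluster$absorber, ])
  sqrt(rowSums(d * d))
}

# Order sites by ascending distance to the absorber, ties broken by original
# index (order() is stable). The absorber (distance 0) always comes first.
absorber_order <- function(cluster) order(absorber_distances(cluster))

subset_cluster <- function(cluster, idx) {
  atomic_cluster(cluster$z[idx], cluster$xyz[idx, , drop = FALSE],
                 absorber = match(cluster$absorber, idx),
                 label = cluster$label)
}

#' Read an XYZ file as an atomic cluster
#'
#' Standard XYZ layout: atom count, comment line, then one `symbol x y z`
#' record per atom (coordinates in Angstrom). The absorber may be designated
#' in the comment line with a `absorber=<index>` key, where the index is
#' 0-based (external convention); otherwise the first Fe site is taken as the
#' absorber.
#'
#' @param path path to an XYZ file.
#' @return an [atomic_cluster()]; its `label` is the file name without
#'   extension unless the comment line carries `label=<text>`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("malformed XYZ '", path, "': fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) {
    stop("malformed XYZ '", path, "': line 1 is not a positive atom count")
  }
  comment <- lines[2L]
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop(sprintf(
      "malformed XYZ '%s': header declares %d atoms but %d records follow",
      path, n, length(body)))
  }
  sym <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "[[:space:]]+")[[1L]]
    if (length(tok) < 4L) {
      stop(sprintf("malformed XYZ '%s': line %d has fewer than 4 fields",
                   path, i + 2L))
    }
    coords <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(coords)) {
      stop(sprintf("malformed XYZ '%s': line %d has non-numeric coordinates",
                   path, i + 2L))
    }
    sym[i] <- tok[1L]
    xyz[i, ] <- coords
  }
  z <- element_z(sym)
  tag <- regmatches(comment, regexpr("absorber=[0-9]+", comment))
  if (length(tag) == 1L) {
    absorber <- as.integer(sub("absorber=", "", tag)) + 1L  # 0-based on disk
    if (absorber < 1L || absorber > n) {
      stop("malformed XYZ '", path, "': absorber index out of range")
    }
  } else {
    absorber <- which(z == 26L)[1L]
    if (is.na(absorber)) {
      stop("no absorber in '", path,
           "': no Fe site and no absorber=<i> tag in the comment line")
    }
  }
  lab <- regmatches(comment, regexpr("label=[^[:space:]]+", comment))
  label <- if (length(lab) == 1L) sub("label=", "", lab) else
    tools::file_path_sans_ext(basename(path))
  atomic_cluster(z, xyz, absorber = absorber, label = label)
}

#' Write an atomic cluster to an XYZ file
#'
#' The comment line records the absorber as a 0-based `absorber=<i>` key and
#' the cluster label, so [read_xyz()] round-trips losslessly.
#'
#' @param cluster an [atomic_cluster()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cluster, path) {
  n <- length(cluster$z)
  head <- c(as.character(n),
            sprintf("absorber=%d label=%s", cluster$absorber - 1L,
                    if (nzchar(cluster$label)) cluster$label else "cluster"))
  rows <- sprintf("%-2s %14.8f %14.8f %14.8f",
                  element_symbol(cluster$z),
                  cluster$xyz[, 1], cluster$xyz[, 2], cluster$xyz[, 3])
  writeLines(c(head, rows), path)
  invisible(path)
}

#' Extract the local environment within a cutoff radius
#'
#' Returns the sub-cluster of all sites within `cutoff` Angstrom of the
#' absorber. The absorber is always retained. Retained sites are ordered by
#' ascending distance to the absorber, ties broken by original index, and the
#' absorber index is updated accordingly.
#'
#' @param cluster an [atomic_cluster()].
#' @param cutoff radius in Angstrom (> 0).
#' @return an [atomic_cluster()] (possibly the absorber alone).
#' @export
local_environment <- function(cluster, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  d <- absorber_distances(cluster)
  keep <- which(d <= cutoff)
  keep <- keep[order(d[keep])]
  subset_cluster(cluster, keep)
}

#' The n sites nearest the absorber
#'
#' The absorber (distance 0) is counted among the `n`; if the cluster has
#' fewer than `n` sites, all are returned. Sites are ordered by ascending
#' distance, ties broken by original index.
#'
#' @param cluster an [atomic_cluster()].
#' @param n number of sites to keep (>= 1).
#' @return an [atomic_cluster()] of `min(n, length(cluster))` sites.
#' @export
nearest_n <- function(cluster, n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  ord <- absorber_order(cluster)
  subset_cluster(cluster, ord[seq_len(min(n, length(ord)))])
}
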