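# Spectrum container, I/O, resampling, normalisation, and the
# energy-dependent arctangent lifetime broadening.

#' Construct a spectrum
#'
#' A discretised absorption cross-section on an energy grid. Spectra serve
#' both as training targets (unconvoluted cross-sections) and as model
#' outputs; the `convoluted` flag records whether lifetime broadening has
#' been applied.
#'
#' @param energy strictly increasing numeric vector (eV).
#' @param intensity cross-section values, same length as `energy` (arbitrary
#'   units).
#' @param convoluted logical; has the lifetime broadening been applied?
#' @param meta named list of free-form metadata (normalisation mode, origin).
#' @return an object of class `xas_spectrum`.
#' @export
spectrum <- function(energy, intensity, convoluted = FALSE, meta = list()) {
  energy <- as.numeric(energy)
  intensity <- as.numeric(intensity)
  if (length(energy) != length(intensity)) {
    stop("energy and intensity lengths differ")
  }
  if (length(energy) < 1L) stop("empty spectrum")
  if (any(diff(energy) <= 0)) stop("energy grid must be strictly increasing")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  structure(list(energy = energy, intensity = intensity,
                 convoluted = isTRUE(convoluted), meta = meta),
            class = "xas_spectrum")
}

#' @export
print.xas_spectrum <- function(x, ...) {
  cat(sprintf("<xas_spectrum> %d points, %.6g..%.6g eV, %s\n",
              length(x$energy), min(x$energy), max(x$energy),
              if (x$convoluted) "convoluted" else "unconvoluted"))
  invisible(x)
}

is_uniform_grid <- function(energy, tol = 1e-8) {
  h <- diff(energy)
  length(h) == 0L || max(abs(h - h[1])) <= tol * max(abs(h))
}

#' Broadening parameters for the arctangent convolution
#'
#' The energy-dependent width combines a constant core-level (core-hole)
#' width with a final-state width switched on smoothly above the absorption
#' edge by an arctangent profile. The defaults are configuration
#' placeholders on a relative energy scale; all values are user-settable.
#'
#' @param gamma_i core-level width (eV, >= 0); the width floor below the
#'   edge.
#' @param gamma_f final-state width (eV, >= 0); the additional broadening
#'   reached far above the edge.
#' @param e_c centre of the arctangent profile (eV above the edge, > 0).
#' @param e_w width of the arctangent profile (eV, > 0).
#' @param e_f reference (Fermi/edge) energy on the spectrum's scale (eV).
#' @param kernel `"lorentzian"` (lifetime-broadening convention, default) or
#'   `"gaussian"`; the width formula fixes only the full width at half
#'   maximum, not the kernel shape.
#' @return a `conv_params` list.
#' @export
conv_params <- function(gamma_i = 1.25, gamma_f = 15, e_c = 30, e_w = 30,
                        e_f = 0, kernel = c("lorentzian", "gaussian")) {
  stopifnot(gamma_i >= 0, gamma_f >= 0, e_c > 0, e_w > 0)
  kernel <- match.arg(kernel)
  structure(list(gamma_i = gamma_i, gamma_f = gamma_f, e_c = e_c,
                 e_w = e_w, e_f = e_f, kernel = kernel),
            class = "conv_params")
}

#' Energy-dependent broadening width
#'
#' For `e = E - e_f > 0` the full width is
#' `gamma_i + gamma_f * (1/2 + (1/pi) * atan((pi/3) * (gamma_f/e_w) *
#' (e/e_c - e_c^2/e^2)))`; at and below the edge (`e <= 0`) the arctangent
#' argument diverges to minus infinity and the width takes its limiting
#' value `gamma_i`. The width is therefore bounded between `gamma_i` and
#' `gamma_i + gamma_f` and non-decreasing in energy above the edge.
#'
#' @param energy numeric vector of energies (eV).
#' @param params a [conv_params()].
#' @return numeric vector of full widths (eV).
#' @export
gamma_width <- function(energy, params) {
  stopifnot(inherits(params, "conv_params"))
  e <- as.numeric(energy) - params$e_f
  g <- rep(params$gamma_i, length(e))
  pos <- e > 0
  if (any(pos)) {
    arg <- (pi / 3) * (params$gamma_f / params$e_w) *
      (e[pos] / params$e_c - params$e_c^2 / e[pos]^2)
    g[pos] <- params$gamma_i + params$gamma_f * (0.5 + atan(arg) / pi)
  }
  g
}

# Antiderivatives of x(E') * K(E' - E) for piecewise-linear x and unit-area
# kernel K of full width gamma: A(u) = int K du, B(u) = int u K du.
kernel_antiderivatives <- function(u, gamma, kernel) {
  if (kernel == "lorentzian") {
    hw <- gamma / 2                         # half width at half maximum
    list(A = atan(u / hw) / pi,
         B = (hw / (2 * pi)) * log(u^2 + hw^2))
  } else {                                  # gaussian, FWHM = gamma
    sd <- gamma / (2 * sqrt(2 * log(2)))
    list(A = stats::pnorm(u / sd),
         B = -sd^2 * stats::dnorm(u, sd = sd))
  }
}

#' Arctangent-broadened spectrum
#'
#' Applies the energy-dependent lifetime broadening as a post-processing
#' step: each output point is the integral of the input cross-section
#' against a unit-area kernel (Lorentzian by default) whose full width is
#' [gamma_width()] evaluated at the output energy. The input is treated as
#' piecewise linear and the integral evaluated in closed form per segment;
#' each kernel is normalised to unit area over the spectrum's energy range,
#' so total integrated intensity is preserved whenever the grid contains the
#' broadened support. Training data are never convoluted; this operates on
#' model outputs and targets for comparison.
#'
#' @param spec an unconvoluted [spectrum()] on a uniform energy grid.
#' @param params a [conv_params()].
#' @return the convoluted [spectrum()] (flagged `convoluted = TRUE`).
#' @export
arctan_convolve <- function(spec, params = conv_params()) {
  stopifnot(inherits(spec, "xas_spectrum"), inherits(params, "conv_params"))
  if (spec$convoluted) {
    stop("spectrum is already convoluted; refusing to broaden twice")
  }
  if (!is_uniform_grid(spec$energy)) {
    stop("non-uniform energy grid; resample() onto a uniform grid first")
  }
  e <- spec$energy
  x <- spec$intensity
  n <- length(e)
  if (n < 2L) stop("need at least 2 points to convolve")
  g <- gamma_width(e, params)
  g <- pmax(g, 1e-12)                        # zero-width limit -> identity
  # U[i, j] = e[j] - e[i]; row i uses the width at output energy e[i]
  U <- outer(-e, e, "+")
  ad <- kernel_antiderivatives(U, g, params$kernel)
  A <- ad$A
  B <- ad$B
  hseg <- diff(e)
  s <- diff(x) / hseg                        # segment slopes
  head <- seq_len(n - 1L)
  dA <- A[, head + 1L, drop = FALSE] - A[, head, drop = FALSE]
  dB <- B[, head + 1L, drop = FALSE] - B[, head, drop = FALSE]
  # int over segment k: x_k * dA + s_k * (dB - u_k * dA)
  out <- as.numeric(dA %*% x[head] +
                    (dB - U[, head, drop = FALSE] * dA) %*% s)
  denom <- A[, n] - A[, 1L]                  # kernel mass on the grid
  out <- out / denom
  spectrum(e, out, convoluted = TRUE,
           meta = c(spec$meta, list(conv_params = unclass(params))))
}

#' Resample a spectrum onto a new energy grid
#'
#' Linear interpolation; extrapolation outside the source range is refused.
#'
#' @param spec an [xas_spectrum][spectrum()].
#' @param grid strictly increasing target energies (eV) within the source
#'   range.
#' @return the resampled [spectrum()] (convoluted flag preserved).
#' @export
resample <- function(spec, grid) {
  stopifnot(inherits(spec, "xas_spectrum"))
  grid <- as.numeric(grid)
  tol <- 1e-9 * diff(range(spec$energy))
  if (min(grid) < min(spec$energy) - tol ||
      max(grid) > max(spec$energy) + tol) {
    stop("target grid extends beyond the source energy range (extrapolation)")
  }
  y <- stats::approx(spec$energy, spec$intensity, xout = grid,
                     rule = 2)$y
  spectrum(grid, y, convoluted = spec$convoluted, meta = spec$meta)
}

#' Normalise a spectrum
#'
#' @param spec an [xas_spectrum][spectrum()].
#' @param mode `"max1"` divides by the maximum intensity (peak becomes 1);
#'   `"none"` is the identity. The mode applied is recorded in the
#'   spectrum's metadata.
#' @return the normalised [spectrum()].
#' @export
normalise_spectrum <- function(spec, mode = c("max1", "none")) {
  stopifnot(inherits(spec, "xas_spectrum"))
  mode <- match.arg(mode)
  if (mode == "max1") {
    m <- max(spec$intensity)
    if (m == 0) stop("cannot max-normalise an all-zero spectrum")
    spec$intensity <- spec$intensity / m
  }
  spec$meta$normalisation <- mode
  spec
}

#' Read a two-column spectrum file
#'
#' Whitespace-delimited `energy intensity` pairs; `#`-prefixed lines and a
#' leading block of non-numeric comment lines (as written by
#' multiple-scattering codes) are tolerated.
#'
#' @param path path to a spectrum file.
#' @param convoluted flag to set on the returned spectrum (default FALSE;
#'   overridden by a `# convoluted=TRUE` header if present).
#' @return an [xas_spectrum][spectrum()].
#' @export
read_spectrum <- function(path, convoluted = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("convoluted=TRUE", lines[startsWith(lines, "#")]))) {
    convoluted <- TRUE
  }
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  numeric_row <- vapply(fields, function(f) {
    length(f) >= 2L && !anyNA(suppressWarnings(as.numeric(f[1:2])))
  }, logical(1))
  fields <- fields[numeric_row]            # skip leading free-text headers
  if (length(fields) == 0L) stop("no numeric rows in '", path, "'")
  energy <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
  intensity <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  spectrum(energy, intensity, convoluted = convoluted)
}

#' Write a spectrum as two-column text
#'
#' @param spec an [xas_spectrum][spectrum()].
#' @param path output path.
#' @param header extra `#`-prefixed metadata lines to include.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, header = character(0)) {
  stopifnot(inherits(spec, "xas_spectrum"))
  lines <- c(sprintf("# nearedge spectrum convoluted=%s", spec$convoluted),
             paste0("# ", header),
             sprintf("%.8f %.10g", spec$energy, spec$intensity))
  if (length(header) == 0L) lines <- lines[lines != "# "]
  writeLines(lines, path)
  invisible(path)
}
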