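#' One-dimensional SAXS dataset
#'
#' A reduced 1-D scattering curve: strictly increasing momentum-transfer
#' grid `q`, intensities `I` and 1-sigma uncertainties `sigma`, plus a label
#' and free-form metadata (protein/lipid concentrations etc.).
#'
#' @param q momentum transfer \[1/Angstrom\], strictly increasing, > 0
#' @param I intensities (arbitrary units)
#' @param sigma 1-sigma uncertainties, same units as `I`, > 0
#' @param label sample identifier
#' @param metadata named list of sample metadata
#' @return Object of class `saxs_dataset`.
#' @export
saxs_dataset <- function(q, I, sigma, label = "sample", metadata = list()) {
  if (length(q) != length(I) || length(q) != length(sigma))
    stop("q, I and sigma must have equal length", call. = FALSE)
  if (any(q <= 0)) stop("q must be positive", call. = FALSE)
  if (is.unsorted(q, strictly = TRUE))
    stop("q must be strictly increasing", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  structure(list(q = as.numeric(q), I = as.numeric(I),
                 sigma = as.numeric(sigma),
                 label = label, metadata = metadata),
            class = "saxs_dataset")
}

#' @export
print.saxs_dataset <- function(x, ...) {
  cat(sprintf("SAXS dataset '%s': %d points, q in [%.4g, %.4g] 1/A\n",
              x$label, length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Read a 1-D SAXS curve from ASCII
#'
#' Reads a 3-column (q, I, sigma) file, whitespace- or comma-delimited,
#' ignoring `#` comment lines.
#'
#' @param path file path
#' @param label sample label; defaults to the file name
#' @param metadata named list attached to the dataset
#' @return A [saxs_dataset()].
#' @export
read_saxs <- function(path, label = NULL, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data rows in ", path, call. = FALSE)
  sep <- if (grepl(",", lines[1L])) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           colClasses = "numeric")
  if (ncol(tab) < 3L)
    stop("expected 3 columns (q, I, sigma) in ", path, call. = FALSE)
  saxs_dataset(tab[[1L]], tab[[2L]], tab[[3L]],
               label = if (is.null(label)) basename(path) else label,
               metadata = metadata)
}

#' Write a 1-D SAXS curve to ASCII
#'
#' Emits the same dialect [read_saxs()] accepts: a `#` header line followed
#' by whitespace-delimited q, I, sigma columns. Output is byte-deterministic.
#'
#' @param dataset a [saxs_dataset()]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_saxs <- function(dataset, path) {
  stopifnot(inherits(dataset, "saxs_dataset"))
  hdr <- sprintf("# %s | q [1/A]  I(q)  sigma(I)", dataset$label)
  rows <- sprintf("%.10e %.10e %.10e", dataset$q, dataset$I, dataset$sigma)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Buffer (background) subtraction
#'
#' Subtracts a scaled buffer measurement from a sample measurement with
#' Gaussian error propagation:
#' `I = I_sample - scale * I_buffer`,
#' `sigma = sqrt(sigma_sample^2 + scale^2 sigma_buffer^2)`.
#' The grids must match exactly unless `interpolate = TRUE`, in which case
#' the buffer is linearly interpolated onto the sample grid and the output
#' metadata is flagged.
#'
#' @param sample,buffer [saxs_dataset()] objects
#' @param scale buffer scale factor (transmission ratio); default 1
#' @param interpolate allow interpolating the buffer onto the sample grid?
#' @return A [saxs_dataset()] with the subtracted curve. Note the result may
#'   contain non-positive intensities; `sigma` stays positive.
#' @export
subtract_background <- function(sample, buffer, scale = 1,
                                interpolate = FALSE) {
  stopifnot(inherits(sample, "saxs_dataset"), inherits(buffer, "saxs_dataset"))
  meta <- sample$metadata
  same_grid <- length(sample$q) == length(buffer$q) &&
    isTRUE(all.equal(sample$q, buffer$q, tolerance = 1e-12))
  if (!same_grid) {
    if (!interpolate)
      stop("sample and buffer q grids differ; set interpolate = TRUE",
           call. = FALSE)
    ib <- stats::approx(buffer$q, buffer$I, xout = sample$q, rule = 2)$y
    sb <- stats::approx(buffer$q, buffer$sigma, xout = sample$q, rule = 2)$y
    meta$buffer_interpolated <- TRUE
  } else {
    ib <- buffer$I
    sb <- buffer$sigma
  }
  out <- sample
  out$I <- sample$I - scale * ib
  out$sigma <- sqrt(sample$sigma^2 + scale^2 * sb^2)
  out$metadata <- meta
  out
}

#' Logarithmic re-binning of a SAXS curve
#'
#' Averages a curve into `n_bins` bins with geometric (log-equidistant)
#' edges between the smallest and largest measured q. Within each bin the
#' intensity is the inverse-variance-weighted mean, the uncertainty the
#' standard error of that weighted mean, and the reported q the same
#' weighted mean of the member q values. Empty bins are dropped.
#'
#' @param dataset a [saxs_dataset()]
#' @param n_bins number of bins (>= 2, <= number of points)
#' @return A re-binned [saxs_dataset()].
#' @export
rebin_log <- function(dataset, n_bins) {
  stopifnot(inherits(dataset, "saxs_dataset"))
  n <- length(dataset$q)
  if (n_bins < 2) stop("n_bins must be at least 2", call. = FALSE)
  if (n_bins > n)
    stop("n_bins exceeds the number of data points", call. = FALSE)
  edges <- exp(seq(log(min(dataset$q)), log(max(dataset$q)),
                   length.out = n_bins + 1L))
  idx <- findInterval(dataset$q, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  w <- 1 / dataset$sigma^2
  qb <- Ib <- sb <- numeric(0)
  for (b in sort(unique(idx))) {
    m <- idx == b
    sw <- sum(w[m])
    qb <- c(qb, sum(w[m] * dataset$q[m]) / sw)
    Ib <- c(Ib, sum(w[m] * dataset$I[m]) / sw)
    sb <- c(sb, sqrt(1 / sw))
  }
  o <- order(qb)
  saxs_dataset(qb[o], Ib[o], sb[o], label = dataset$label,
               metadata = c(dataset$metadata, list(rebinned = n_bins)))
}

#' Momentum transfer from scattering angle
#'
#' \eqn{q = 4\pi \sin\theta / \lambda} with \eqn{\theta} half the scattering
#' angle.
#'
#' @param theta half scattering angle [rad], in \[0, pi/2\]
#' @param wavelength X-ray wavelength [Angstrom] (1.54 for Cu K-alpha)
#' @return q \[1/Angstrom\].
#' @examples
#' q_from_angle(0.01, 1.54)
#' @export
q_from_angle <- function(theta, wavelength = 1.54) {
  if (any(wavelength <= 0)) stop("wavelength must be positive", call. = FALSE)
  if (any(theta < 0 | theta > pi / 2))
    stop("theta must lie in [0, pi/2]", call. = FALSE)
  4 * pi * sin(theta) / wavelength
}
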