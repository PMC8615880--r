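#' Connectivity matrix
#'
#' Symmetric region-by-region phase-locking-value matrix for one
#' frequency band. Entries lie in `[0, 1]`; the diagonal is stored as 0
#' by convention and excluded from all downstream features.
#'
#' @param values symmetric numeric `N x N` matrix of PLV.
#' @param region_labels ordered region labels (length `N`).
#' @param band a [band_definition()] or `NULL` for broadband.
#' @return Object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, region_labels, band = NULL) {
  values <- as.matrix(values)
  region_labels <- as.character(region_labels)
  n <- length(region_labels)
  if (!all(dim(values) == n)) stop("values must be ", n, " x ", n)
  if (anyDuplicated(region_labels)) stop("region labels must be unique")
  if (max(abs(values - t(values))) > 1e-9) stop("values must be symmetric")
  diag(values) <- 0
  if (any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("PLV entries must lie in [0, 1]")
  values <- pmin(pmax(values, 0), 1)
  dimnames(values) <- list(region_labels, region_labels)
  structure(list(region_labels = region_labels, band = band,
                 values = values),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, band %s\n",
              length(x$region_labels), length(x$region_labels),
              if (is.null(x$band)) "broadband" else x$band$name))
  invisible(x)
}

# Windowed-sinc FIR band-pass, zero phase (forward-backward) with
# reflective padding. Order scales with the low edge so one octave
# below the band is well into the stop band.
fir_bandpass <- function(x, low, high, fs) {
  n <- length(x)
  ord <- round(6.6 * fs / low)
  ord <- min(ord, n - 1L)
  if (ord %% 2L == 1L) ord <- ord - 1L
  if (ord < 6L) stop("epoch too short to design a band-pass filter")
  b <- as.numeric(signal::fir1(ord, c(low, high) / (fs / 2), type = "pass"))
  # reflect the full epoch on both sides, filter twice (zero phase)
  pad <- c(rev(x[2:n]), x, rev(x[1:(n - 1)]))
  y <- as.numeric(signal::filter(b, 1, pad))
  y <- rev(as.numeric(signal::filter(b, 1, rev(y))))
  y[n:(2 * n - 1)]
}

#' Band-pass filter epoched signals
#'
#' Zero-phase FIR (windowed-sinc, Hamming) band-pass applied per epoch
#' and region with reflective padding, so that no phase distortion is
#' introduced ahead of phase extraction.
#'
#' @param signals an [epoched_parcel_signals()] object.
#' @param band a [band_definition()]. The sampling rate must exceed
#'   `2 * band$high` (Nyquist).
#' @return A band-limited copy of `signals`, same shape.
#' @export
bandpass_epochs <- function(signals, band) {
  stopifnot(inherits(signals, "epoched_parcel_signals"),
            inherits(band, "band_definition"))
  fs <- signals$sampling_rate
  if (fs <= 2 * band$high)
    stop("band '", band$name, "' (", band$low, "-", band$high,
         " Hz) violates Nyquist at sampling rate ", fs, " Hz")
  out <- signals$data
  for (e in seq_len(n_epochs(signals)))
    for (r in seq_len(n_regions(signals)))
      out[e, r, ] <- fir_bandpass(signals$data[e, r, ], band$low, band$high, fs)
  signals$data <- out
  signals
}

# analytic signal via FFT; x real vector
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase via the Hilbert transform
#'
#' Extracts the per-sample analytic-signal phase (radians, in
#' `(-pi, pi]`) of every epoch and region. Intended for band-limited
#' input, for which the instantaneous phase is physically interpretable.
#'
#' @param signals an [epoched_parcel_signals()] object.
#' @return numeric array of phases, same dimensions as `signals$data`.
#' @export
instantaneous_phase <- function(signals) {
  stopifnot(inherits(signals, "epoched_parcel_signals"))
  ph <- signals$data
  for (e in seq_len(n_epochs(signals)))
    for (r in seq_len(n_regions(signals))) {
      x <- signals$data[e, r, ]
      if (all(x == 0))
        stop("all-zero channel (epoch ", e, ", region '",
             signals$region_labels[r], "'): phase undefined")
      ph[e, r, ] <- Arg(analytic_signal(x))
    }
  ph
}

#' Phase-locking value of a phase-difference series
#'
#' The PLV statistic itself: the modulus of the time average of
#' `exp(1i * dphi)` (mean resultant length of the phase differences).
#' Equals 1 for a constant phase difference and is near
#' `sqrt(pi) / (2 sqrt(n))` in expectation for independent uniform
#' phases.
#'
#' @param dphi numeric vector of phase differences (radians).
#' @return scalar in `[0, 1]`.
#' @examples
#' phase_locking_value(rep(0.3, 100))   # 1
#' @export
phase_locking_value <- function(dphi) {
  if (length(dphi) < 1L) stop("empty phase series")
  Mod(mean(exp(1i * dphi)))
}

#' PLV adjacency matrix of epoched signals
#'
#' For each region pair, computes the per-epoch phase-locking value of
#' the Hilbert phase difference, then averages across epochs, yielding a
#' symmetric `N x N` adjacency matrix in `[0, 1]`. When `band` is given,
#' the signals are band-pass filtered first; a fraction of samples at
#' each epoch edge is discarded before averaging to suppress filter and
#' Hilbert edge effects.
#'
#' @param signals an [epoched_parcel_signals()] object.
#' @param band a [band_definition()], or `NULL` to use the signals as
#'   provided (broadband phase).
#' @param edge_trim fraction of samples dropped at each epoch edge
#'   (default 0.1).
#' @return a [connectivity_matrix()].
#' @export
plv_matrix <- function(signals, band = NULL, edge_trim = 0.1) {
  stopifnot(inherits(signals, "epoched_parcel_signals"),
            edge_trim >= 0, edge_trim < 0.5)
  if (n_samples(signals) < 2L) stop("single-sample epochs: PLV undefined")
  if (!is.null(band)) signals <- bandpass_epochs(signals, band)
  ph <- instantaneous_phase(signals)
  ns <- n_samples(signals)
  keep <- seq.int(floor(edge_trim * ns) + 1L, ns - floor(edge_trim * ns))
  nr <- n_regions(signals)
  acc <- matrix(0, nr, nr)
  for (e in seq_len(n_epochs(signals))) {
    z <- exp(1i * ph[e, , keep, drop = TRUE])
    if (is.null(dim(z))) z <- matrix(z, nrow = nr)
    acc <- acc + Mod(z %*% Conj(t(z))) / length(keep)
  }
  connectivity_matrix(acc / n_epochs(signals), signals$region_labels, band)
}

#' Network definition
#'
#' A named set of atlas region labels, e.g. the expectancy
#' implementation, expectancy violation or response implementation
#' network of a task study.
#'
#' @param name network label.
#' @param members character vector of region labels (nonempty unless
#'   `allow_empty`, no duplicates).
#' @param allow_empty permit an empty member list (used by
#'   [intersection_network()] for its degenerate case).
#' @return Object of class `network_definition`.
#' @export
network_definition <- function(name, members, allow_empty = FALSE) {
  members <- as.character(members)
  if (!allow_empty && length(members) == 0L)
    stop("network '", name, "' has no members")
  if (anyDuplicated(members))
    stop("network '", name, "' has duplicate members")
  structure(list(name = as.character(name), members = members),
            class = "network_definition")
}

#' @export
print.network_definition <- function(x, ...) {
  cat(sprintf("<network> %s: %d regions\n", x$name, length(x$members)))
  invisible(x)
}

#' Read a network definition from a label-list file
#'
#' One region label per line; blank lines and `#` comments ignored.
#' The files shipped under `inst/extdata/networks/` are illustrative
#' placeholders (the region sets of a real study are study-specific).
#'
#' @param path file path.
#' @param name network name; default is the file base name.
#' @return a [network_definition()].
#' @export
read_network_labels <- function(path, name = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  network_definition(name, lines)
}

#' Restrict a connectivity matrix to a network
#'
#' Sub-matrix on the network's member regions, in the member order given
#' by the network definition.
#'
#' @param matrix a [connectivity_matrix()].
#' @param net a [network_definition()]; all members must be present
#'   among the matrix labels.
#' @return a [connectivity_matrix()] of size `length(net$members)`.
#' @export
restrict_to_network <- function(matrix, net) {
  stopifnot(inherits(matrix, "connectivity_matrix"),
            inherits(net, "network_definition"))
  missing <- setdiff(net$members, matrix$region_labels)
  if (length(missing))
    stop("network '", net$name, "' members not in matrix: ",
         paste(missing, collapse = ", "))
  idx <- match(net$members, matrix$region_labels)
  connectivity_matrix(matrix$values[idx, idx, drop = FALSE],
                      net$members, matrix$band)
}

#' Intersection network
#'
#' Members of the response-implementation network that also belong to
#' the expectancy-implementation or expectancy-violation network, in
#' response-network order. Used to focus nodal graph analysis on the
#' regions common to the task networks.
#'
#' @param resp,expImpl,expViol [network_definition()] objects.
#' @param name name for the result (default `"intersection"`).
#' @return a [network_definition()] (possibly empty, with a warning).
#' @export
intersection_network <- function(resp, expImpl, expViol,
                                 name = "intersection") {
  stopifnot(inherits(resp, "network_definition"),
            inherits(expImpl, "network_definition"),
            inherits(expViol, "network_definition"))
  members <- resp$members[resp$members %in%
                            union(expImpl$members, expViol$members)]
  if (length(members) == 0L)
    warning("intersection network is empty")
  network_definition(name, members, allow_empty = TRUE)
}
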