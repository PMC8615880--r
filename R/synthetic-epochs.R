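#' Specification for the coupled-oscillator epoch generator
#'
#' Describes a synthetic resting-state recording: how many regions and
#' epochs, which narrowband oscillations each region carries, and which
#' region pairs are phase-coupled in which band. Coupled pairs share a
#' common phase-diffusing sinusoid mixed (by the coupling strength) with
#' an independent same-band process, so the expected downstream PLV
#' increases monotonically with coupling strength: strength 1 with no
#' noise yields a constant phase lag (PLV 1), strength 0 leaves the pair
#' independent.
#'
#' @param n_regions number of regions.
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_length epoch length in seconds (default 2, the usual
#'   resting-state segmentation).
#' @param n_epochs number of epochs (default 60: two minutes of 2-s
#'   epochs).
#' @param band_targets data frame with columns `band` (name) and
#'   `center` (Hz): the narrowband processes present in every region.
#' @param coupling data frame with columns `i`, `j` (region indexes),
#'   `band`, `strength` in `[0,1]`, `lag` (radians): the planted
#'   couplings.
#' @param noise_sd standard deviation of additive white measurement
#'   noise.
#' @param phase_diffusion_sd innovation sd of the phase random walk
#'   (radians per sample); controls how narrowband the oscillations are.
#' @param seed integer seed; the generator is fully reproducible.
#' @return Object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(n_regions,
                            sampling_rate = 250,
                            epoch_length = 2,
                            n_epochs = 60,
                            band_targets = data.frame(
                              band = "alpha", center = 10),
                            coupling = NULL,
                            noise_sd = 1,
                            phase_diffusion_sd = 0.25,
                            seed = 1L) {
  stopifnot(n_regions >= 1, sampling_rate > 0, epoch_length > 0,
            n_epochs >= 1, noise_sd >= 0, phase_diffusion_sd >= 0)
  band_targets <- as.data.frame(band_targets)
  stopifnot(all(c("band", "center") %in% names(band_targets)))
  bands <- canonical_bands()
  for (k in seq_len(nrow(band_targets))) {
    bn <- band_targets$band[k]
    if (bn %in% names(bands)) {
      b <- bands[[bn]]
      cf <- band_targets$center[k]
      if (cf < b$low || cf > b$high)
        stop("center ", cf, " Hz outside band '", bn, "' (",
             b$low, "-", b$high, " Hz)")
    }
  }
  if (!is.null(coupling)) {
    coupling <- as.data.frame(coupling)
    stopifnot(all(c("i", "j", "band", "strength", "lag") %in% names(coupling)))
    if (any(coupling$i == coupling$j))
      stop("coupling edges must join two distinct regions")
    if (any(coupling$strength < 0 | coupling$strength > 1))
      stop("coupling strength must lie in [0, 1]")
    if (any(coupling$i > n_regions | coupling$j > n_regions |
              coupling$i < 1 | coupling$j < 1))
      stop("coupling edge references a region outside 1..n_regions")
    if (!all(coupling$band %in% band_targets$band))
      stop("coupling references a band absent from band_targets")
  }
  structure(list(n_regions = as.integer(n_regions),
                 sampling_rate = sampling_rate,
                 epoch_length = epoch_length,
                 n_epochs = as.integer(n_epochs),
                 band_targets = band_targets,
                 coupling = coupling,
                 noise_sd = noise_sd,
                 phase_diffusion_sd = phase_diffusion_sd,
                 seed = as.integer(seed)),
            class = "oscillator_spec")
}

# one phase-diffusion trajectory: 2*pi*f*t + random start + random walk
diffuse_phase <- function(nsamp, f, fs, pdsd) {
  drift <- 2 * pi * f * seq(0, by = 1 / fs, length.out = nsamp)
  drift + stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(nsamp, 0, pdsd))
}

#' Simulate coupled oscillatory epochs
#'
#' Generates one subject's [epoched_parcel_signals()] according to an
#' [oscillator_spec()]. Every region carries, per band target, a
#' phase-diffusing sinusoid at the band's center frequency; for each
#' coupling edge `(i, j, band, strength s, lag)`, region `j`'s band
#' component is `s * cos(phase_i - lag) + (1 - s) * cos(phase_j)` with
#' `phase_j` independent. White noise of sd `noise_sd` is added to all
#' regions.
#'
#' @param spec an [oscillator_spec()].
#' @param subject_id subject label.
#' @return an [epoched_parcel_signals()] object.
#' @export
simulate_coupled_epochs <- function(spec, subject_id = "S01") {
  stopifnot(inherits(spec, "oscillator_spec"))
  nsamp <- round(spec$epoch_length * spec$sampling_rate)
  f_lo <- min(spec$band_targets$center)
  lo_name <- spec$band_targets$band[which.min(spec$band_targets$center)]
  if (nsamp < 3 * spec$sampling_rate / f_lo)
    stop("epoch (", nsamp, " samples) shorter than 3 cycles of band '",
         lo_name, "' (center ", f_lo, " Hz)")
  set.seed(spec$seed)
  dat <- array(0, dim = c(spec$n_epochs, spec$n_regions, nsamp))
  for (e in seq_len(spec$n_epochs)) {
    for (k in seq_len(nrow(spec$band_targets))) {
      bn <- spec$band_targets$band[k]
      f <- spec$band_targets$center[k]
      # independent band phase for every region first
      ph <- lapply(seq_len(spec$n_regions), function(r)
        diffuse_phase(nsamp, f, spec$sampling_rate, spec$phase_diffusion_sd))
      comp <- lapply(ph, cos)
      if (!is.null(spec$coupling)) {
        ce <- spec$coupling[spec$coupling$band == bn, , drop = FALSE]
        for (m in seq_len(nrow(ce))) {
          i <- ce$i[m]; j <- ce$j[m]
          s <- ce$strength[m]; lag <- ce$lag[m]
          comp[[j]] <- s * cos(ph[[i]] - lag) + (1 - s) * cos(ph[[j]])
        }
      }
      for (r in seq_len(spec$n_regions))
        dat[e, r, ] <- dat[e, r, ] + comp[[r]]
    }
    if (spec$noise_sd > 0)
      dat[e, , ] <- dat[e, , ] +
        matrix(stats::rnorm(spec$n_regions * nsamp, 0, spec$noise_sd),
               spec$n_regions, nsamp)
  }
  epoched_parcel_signals(dat,
                         region_labels = sprintf("R%03d", seq_len(spec$n_regions)),
                         sampling_rate = spec$sampling_rate,
                         subject_id = subject_id)
}
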