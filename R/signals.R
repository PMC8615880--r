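#' Epoched parcel signals
#'
#' Container for one subject's epoched, parcellated time series: a
#' numeric array of `epochs x regions x samples`, the ordered region
#' labels and the sampling rate. This is the shape in which
#' source-projected resting-state EEG enters the connectivity stage
#' (e.g. 2-s epochs over the 148 regions of a cortical parcellation).
#'
#' @param data numeric array, dimensions `epochs x regions x samples`.
#' @param region_labels character vector, one unique label per region.
#' @param sampling_rate sampling rate in Hz.
#' @param subject_id subject label.
#' @return Object of class `epoched_parcel_signals`.
#' @export
epoched_parcel_signals <- function(data, region_labels, sampling_rate,
                                   subject_id = "S01") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-d array (epochs x regions x samples)")
  if (dim(data)[1] < 1L) stop("need at least one epoch")
  if (anyNA(data)) stop("data contains missing samples")
  region_labels <- as.character(region_labels)
  if (length(region_labels) != dim(data)[2])
    stop("region_labels length (", length(region_labels),
         ") does not match region dimension (", dim(data)[2], ")")
  if (anyDuplicated(region_labels))
    stop("region labels must be unique")
  stopifnot(is.numeric(sampling_rate), sampling_rate > 0)
  structure(list(subject_id = as.character(subject_id),
                 region_labels = region_labels,
                 sampling_rate = as.numeric(sampling_rate),
                 data = data),
            class = "epoched_parcel_signals")
}

#' @export
print.epoched_parcel_signals <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_parcel_signals> subject %s: %d epochs x %d regions x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$sampling_rate))
  invisible(x)
}

n_epochs  <- function(x) dim(x$data)[1]
n_regions <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]
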