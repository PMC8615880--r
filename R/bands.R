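#' Frequency band definition
#'
#' A band is a named frequency interval used for band-limited
#' connectivity. The canonical EEG set used throughout the package is
#' Delta (2-4 Hz), Theta (4-7 Hz), Alpha (8-12 Hz), Beta (13-30 Hz) and
#' Gamma (30-45 Hz); see [canonical_bands()].
#'
#' @param name band label, e.g. `"alpha"`.
#' @param low,high band limits in Hz; `0 < low < high` required.
#' @return An object of class `band_definition` with fields `name`,
#'   `low`, `high`.
#' @examples
#' band_definition("alpha", 8, 12)
#' @export
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  low <- as.numeric(low); high <- as.numeric(high)
  if (!(is.finite(low) && is.finite(high) && 0 < low && low < high))
    stop("band '", name, "': need 0 < low < high (got ", low, ", ", high, ")")
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Canonical EEG frequency bands
#'
#' @return Named list of five [band_definition()] objects:
#'   delta (2-4), theta (4-7), alpha (8-12), beta (13-30),
#'   gamma (30-45 Hz).
#' @export
canonical_bands <- function() {
  list(
    delta = band_definition("delta", 2, 4),
    theta = band_definition("theta", 4, 7),
    alpha = band_definition("alpha", 8, 12),
    beta  = band_definition("beta", 13, 30),
    gamma = band_definition("gamma", 30, 45)
  )
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}
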