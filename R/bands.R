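#' Define a frequency band
#'
#' @param name Band label (e.g. "alpha").
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz`.
#' @return A `band_definition` object.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  stopifnot(is.character(name), length(name) == 1L)
  check_scalar_num(low_hz, "low_hz", positive = TRUE)
  check_scalar_num(high_hz, "high_hz", positive = TRUE)
  if (low_hz >= high_hz) stop_invalid("band `%s`: low_hz must be < high_hz", name)
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

#' Default EEG frequency bands
#'
#' The conventional theta/alpha/beta/gamma split used throughout the package:
#' theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz.
#'
#' @return A named list of four [band_definition()] objects.
#' @export
default_bands <- function() {
  list(theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 13),
       beta  = band_definition("beta", 13, 30),
       gamma = band_definition("gamma", 30, 45))
}

check_bands_for_fs <- function(bands, fs) {
  for (b in bands) {
    if (b$high_hz >= fs / 2)
      stop_invalid("band `%s` upper edge %.1f Hz is at or above Nyquist (fs = %.1f Hz)",
                   b$name, b$high_hz, fs)
  }
  invisible(TRUE)
}

band_names <- function(bands) vapply(bands, `[[`, "", "name")
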