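#' Acoustic medium
#'
#' Physical constants of the still atmosphere shared by every acoustic
#' computation: the speed of sound \eqn{a_o}, the air density \eqn{\rho_o},
#' and the gravitational acceleration \eqn{g} (used to convert body mass to
#' the weight the wings must support in hover).
#'
#' @param speed_of_sound speed of sound \eqn{a_o} (m/s)
#' @param density air density \eqn{\rho_o} (kg/m^3)
#' @param gravity gravitational acceleration \eqn{g} (m/s^2)
#'
#' @return An object of class `"hum_medium"`.
#' @examples
#' air <- medium()
#' air$speed_of_sound
#' @export
medium <- function(speed_of_sound = 343, density = 1.23, gravity = 9.81) {
  vals <- c(speed_of_sound, density, gravity)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("medium constants must be finite and strictly positive")
  structure(list(speed_of_sound = speed_of_sound,
                 density = density,
                 gravity = gravity),
            class = "hum_medium")
}

#' @export
print.hum_medium <- function(x, ...) {
  cat(sprintf("<hum_medium> ao = %g m/s, rho_o = %g kg/m^3, g = %g m/s^2\n",
              x$speed_of_sound, x$density, x$gravity))
  invisible(x)
}

#' Acoustic wavelength of a wingbeat harmonic
#'
#' @param freq wingbeat (flapping) frequency \eqn{f_w} (Hz)
#' @param harmonic harmonic index (1 = fundamental)
#' @param med a [medium()]
#' @return Wavelength \eqn{\lambda_k = a_o / (k f_w)} in metres.
#' @examples
#' wavelength(44.2)        # ~7.8 m
#' wavelength(44.2, 10)    # ~0.78 m
#' @export
wavelength <- function(freq, harmonic = 1, med = medium()) {
  stopifnot(freq > 0, harmonic >= 1)
  med$speed_of_sound / (harmonic * freq)
}

#' Acoustic compactness of a flapping wing
#'
#' Ratio of wing length to the wavelength of the first wingbeat harmonic,
#' \eqn{R/\lambda_1 = R f_w / a_o}. Values well below 1 mean the wing can be
#' collapsed to a single equivalent point force per wing half.
#'
#' @param wing_length wing length R (m)
#' @param freq flapping frequency (Hz)
#' @param med a [medium()]
#' @return Dimensionless compactness ratio.
#' @examples
#' compactness(0.058, 44.2)  # ~0.007: hummingbird wings are compact sources
#' @export
compactness <- function(wing_length, freq, med = medium()) {
  stopifnot(wing_length >= 0, freq > 0)
  wing_length * freq / med$speed_of_sound
}
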