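#' Quasi-uniform (Fibonacci) spherical lattice
#'
#' Golden-angle lattice on the unit sphere: `n` nodes of equal solid angle,
#' so spherical quadrature reduces to an unweighted mean.
#'
#' @param n number of nodes
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  az <- pi * (3 - sqrt(5)) * i
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(az), s * sin(az), z)
}

# Per-node harmonic band rms and broadband rms at one observer position.
# Exploits exact periodicity: with a one-period rectangular window every
# spectral bin is a wingbeat harmonic, so the +/-2.5 Hz band around harmonic
# k contains exactly bin k.
.node_band_rms <- function(model, pos, n_harmonics, broadband,
                           method = c("eq1", "eq3")) {
  method <- match.arg(method)
  tr <- if (method == "eq3") pressure_eq3(model, pos, n_periods = 1)
        else pressure_eq1(model, pos, n_periods = 1)
  n <- tr$samples_per_period
  X <- stats::fft(tr$p[seq_len(n)]) / n
  half <- floor(n / 2)
  ms <- c(Mod(X[1])^2, 2 * Mod(X[2:half])^2, Mod(X[half + 1])^2)
  freqs <- (0:half) * tr$freq
  kmax <- min(n_harmonics, half - 1)
  band <- sqrt(ms[1 + seq_len(kmax)])
  if (kmax < n_harmonics) band <- c(band, rep(0, n_harmonics - kmax))
  bb <- freqs >= broadband[1] & freqs <= broadband[2]
  bb[1] <- FALSE                        # never count the DC offset
  list(band_rms = band, rms = sqrt(sum(ms[bb])),
       near_rms = {
         Xn <- stats::fft(tr$nearfield[seq_len(n)]) / n
         msn <- c(Mod(Xn[1])^2, 2 * Mod(Xn[2:half])^2, Mod(Xn[half + 1])^2)
         sqrt(sum(msn[bb]))
       },
       far_rms = {
         Xf <- stats::fft(tr$farfield[seq_len(n)]) / n
         msf <- c(Mod(Xf[1])^2, 2 * Mod(Xf[2:half])^2, Mod(Xf[half + 1])^2)
         sqrt(sum(msf[bb]))
       })
}

#' Sample the pressure field on a sphere
#'
#' Evaluates the model pressure at quasi-uniform spherical nodes and
#' summarises each node by its broadband rms (default 3-500 Hz, excluding
#' the static offset) and per-harmonic band rms pressures.
#'
#' @param model a [hum_model()] or [static_point_force()]
#' @param radius sphere radius (m); must exceed the source excursion R3
#' @param n_nodes number of equal-area nodes
#' @param n_harmonics harmonics to band-resolve
#' @param broadband broadband limits (Hz)
#' @param method `"eq1"` (full equation) or `"eq3"` (simplified)
#' @return A `"field_map"` data frame: `node`, `x`, `y`, `z`, `rms`,
#'   `near_rms`, `far_rms` and `band<k>_rms` columns, with the radius and
#'   node solid angle as attributes.
#' @export
sample_sphere <- function(model, radius, n_nodes = 512, n_harmonics = 10,
                          broadband = c(3, 500), method = c("eq1", "eq3")) {
  method <- match.arg(method)
  excur <- if (inherits(model, "hum_model"))
    model$spec$r3_frac * model$spec$wing_length else 0
  if (radius <= excur) stop("radius must exceed the source excursion (R3)")
  nodes <- fibonacci_sphere(n_nodes) * radius
  rows <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    nb <- .node_band_rms(model, nodes[i, ], n_harmonics, broadband, method)
    rows[[i]] <- c(nodes[i, ], nb$rms, nb$near_rms, nb$far_rms, nb$band_rms)
  }
  m <- do.call(rbind, rows)
  out <- data.frame(node = seq_len(n_nodes), x = m[, 1], y = m[, 2], z = m[, 3],
                    rms = m[, 4], near_rms = m[, 5], far_rms = m[, 6])
  for (k in seq_len(n_harmonics)) out[[sprintf("band%d_rms", k)]] <- m[, 6 + k]
  structure(out, radius = radius, n_nodes = n_nodes,
            node_area = 4 * pi * radius^2 / n_nodes, method = method,
            med = .hum_med(model),
            class = c("field_map", "data.frame"))
}

#' Directivity cross section in an anatomical plane
#'
#' Band (or broadband) rms pressure versus polar angle on a ring of
#' observers in the sagittal (x-z, side view) or coronal (y-z, front view)
#' plane. Angles follow the waistline-axis convention: 0 deg points along
#' +x (anterior) in the sagittal plane or +y (the animal's left) in the
#' coronal plane, 90 deg is vertical (+z), angles beyond 90 deg tilt aft in
#' the sagittal plane.
#'
#' @param model a [hum_model()] or [static_point_force()]
#' @param plane `"sagittal"` or `"coronal"`
#' @param radius ring radius (m)
#' @param band harmonic index, or `"broadband"`
#' @param n_angles observers around the ring
#' @param broadband broadband limits (Hz) when `band = "broadband"`
#' @param method `"eq1"` or `"eq3"`
#' @return A `"directivity_section"` data frame with `angle` (deg) and
#'   `rms` (Pa).
#' @export
directivity_section <- function(model, plane = c("sagittal", "coronal"),
                                radius, band = "broadband", n_angles = 360,
                                broadband = c(3, 500),
                                method = c("eq1", "eq3")) {
  if (!is.character(plane) || !(plane[1] %in% c("sagittal", "coronal")))
    stop("unknown plane: use \"sagittal\" (x-z) or \"coronal\" (y-z)")
  plane <- plane[1]
  method <- match.arg(method)
  stopifnot(n_angles >= 8, radius > 0)
  kband <- if (identical(band, "broadband")) 0L else as.integer(band)
  ang <- (seq_len(n_angles) - 1) * 360 / n_angles
  rad <- ang * pi / 180
  dirs <- if (plane == "sagittal") cbind(cos(rad), 0, sin(rad))
          else cbind(0, cos(rad), sin(rad))
  nh <- max(kband, 1)
  rms <- vapply(seq_len(n_angles), function(i) {
    nb <- .node_band_rms(model, radius * dirs[i, ], nh, broadband, method)
    if (kband == 0) nb$rms else nb$band_rms[kband]
  }, numeric(1))
  structure(data.frame(angle = ang, rms = rms),
            plane = plane, radius = radius, band = band,
            class = c("directivity_section", "data.frame"))
}

#' Principal directivity axis by the waistline method
#'
#' Locates the two angular minima (the "waist") of a lobed polar pressure
#' pattern on the 3-point moving-average smoothed curve, forms the waistline
#' through them, and returns the axis perpendicular to it, folded into
#' [0, 180) degrees (90 deg = vertical; > 90 deg = tilted aft in the
#' sagittal plane). Ties are broken toward the smaller angle.
#'
#' @param section a [directivity_section()]
#' @return Principal axis angle in degrees.
#' @export
principal_axis <- function(section) {
  stopifnot(inherits(section, "directivity_section"))
  r <- section$rms
  n <- length(r)
  sm <- (r + r[c(n, 1:(n - 1))] + r[c(2:n, 1)]) / 3
  prv <- sm[c(n, 1:(n - 1))]
  nxt <- sm[c(2:n, 1)]
  is_min <- sm < prv & sm <= nxt       # left-strict: ties go to smaller angle
  idx <- which(is_min)
  if (length(idx) < 2) {
    rng <- diff(range(sm))
    if (rng < 1e-12 * max(abs(sm), 1e-300))
      stop("axisymmetric pattern: no waist minima to define an axis")
    stop("fewer than two local minima: pattern is not lobed")
  }
  idx <- idx[order(sm[idx], section$angle[idx])][1:2]
  a <- section$angle[idx] * pi / 180
  # axial (mod 180 deg) mean of the two minima directions = waistline
  w <- 0.5 * atan2(sum(sin(2 * a)), sum(cos(2 * a))) * 180 / pi
  axis <- (w + 90) %% 180
  if (abs(axis - 180) < 1e-9) axis <- 0
  axis
}

#' Total radiated acoustic power
#'
#' Integrates the broadband mean-square pressure over a sphere:
#' \eqn{P = \oint p_{rms}^2 / (\rho_o a_o)\, dA}, using the equal-area
#' Fibonacci quadrature of [sample_sphere()]. In the farfield the result is
#' radius-invariant; a warning is issued when the radius is inside one
#' wavelength of the first harmonic, where the nearfield term inflates the
#' surface integral.
#'
#' @param model a [hum_model()] or [static_point_force()]
#' @param radius sphere radius (m)
#' @param n_nodes quadrature nodes
#' @param method `"eq1"` or `"eq3"`
#' @param broadband band limits (Hz) for the rms
#' @param fieldmap optionally, a precomputed [sample_sphere()] map to
#'   integrate instead of re-sampling
#' @return Radiated power (W).
#' @export
radiated_power <- function(model, radius, n_nodes = 512,
                           method = c("eq1", "eq3"), broadband = c(3, 500),
                           fieldmap = NULL) {
  method <- match.arg(method)
  if (is.null(fieldmap)) {
    lam1 <- .hum_med(model)$speed_of_sound / .hum_freq(model)
    if (radius < lam1)
      warning(sprintf(paste0("radius %.3g m is inside the first-harmonic ",
                             "wavelength %.3g m: power is not radius-invariant ",
                             "in the nearfield"), radius, lam1))
    fieldmap <- sample_sphere(model, radius, n_nodes, n_harmonics = 1,
                              broadband = broadband, method = method)
  }
  med <- attr(fieldmap, "med")
  sum(fieldmap$rms^2) * attr(fieldmap, "node_area") /
    (med$density * med$speed_of_sound)
}
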