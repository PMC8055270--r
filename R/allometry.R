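#' Prefactor of the radiated-power scaling law
#'
#' The constant \eqn{4 g^2 / (\pi \rho_o a_o^3)} relating radiated acoustic
#' power to \eqn{\Phi_o^2 m^2 f_w^2}; about 2.5e-6 per kg per s with the
#' standard constants.
#'
#' @param med a [medium()]
#' @return Prefactor (kg^-1 s^-1).
#' @export
scaling_prefactor <- function(med = medium()) {
  4 * med$gravity^2 / (pi * med$density * med$speed_of_sound^3)
}

#' Radiated-power scaling law
#'
#' Order-of-magnitude farfield radiated acoustic power of a hovering flapper
#' supporting its weight \eqn{F_o = m g}:
#' \deqn{P_o = \frac{4 F_o^2 \Phi_o^2 f_w^2}{\pi \rho_o a_o^3}
#'       \approx 2.5\times10^{-6}\, \Phi_o^2 m^2 f_w^2.}
#'
#' @param mass body mass (kg), vectorised
#' @param stroke_amplitude stroke amplitude \eqn{\Phi_o} (rad)
#' @param freq flapping frequency (Hz)
#' @param med a [medium()]
#' @return Power (W), with the prefactor as attribute `"prefactor"`.
#' @examples
#' power_law(0.4, 1, 7)   # ~2e-5 W for a pigeon
#' @export
power_law <- function(mass, stroke_amplitude, freq, med = medium()) {
  if (any(mass <= 0) || any(stroke_amplitude <= 0) || any(freq <= 0))
    stop("mass, stroke_amplitude and freq must be positive")
  pref <- scaling_prefactor(med)
  structure(pref * (mass * stroke_amplitude * freq)^2, prefactor = pref)
}

#' Read or validate a species table
#'
#' Schema: columns `name, group, mass_kg, wing_length_m, flap_freq_hz` and
#' optional `stroke_amp_rad`. Groups must map to registered paradigm
#' profiles ([paradigm_groups()]).
#'
#' @param path CSV file path
#' @return Validated data frame.
#' @export
read_species_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty species table")
  need <- c("name", "group", "mass_kg", "wing_length_m", "flap_freq_hz")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop(sprintf("species table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  bad <- setdiff(unique(tab$group), paradigm_groups())
  if (length(bad) > 0)
    stop(sprintf("unmapped group(s): %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(paradigm_groups(), collapse = ", ")))
  tab
}

#' Synthetic isometric species grid
#'
#' A geometric-similarity ladder for validating the scaling machinery: wing
#' length grows as \eqn{m^{1/3}} and flapping frequency falls as
#' \eqn{m^{-1/3}}, anchored to a paradigm animal, with fixed stroke
#' amplitude and profile. Under these assumptions the simulated power scales
#' exactly as the scaling-law predictor (log-log slope 1) and as
#' \eqn{m^{4/3}} against mass.
#'
#' @param n number of species
#' @param group anchoring paradigm group
#' @param mass_range mass span (kg), log-spaced
#' @return Species data frame in the [read_species_table()] schema.
#' @export
synthetic_species_grid <- function(n = 8, group = "hummingbird",
                                   mass_range = c(2e-3, 2e-1)) {
  anchor <- .paradigm[[group]]
  if (is.null(anchor)) stop(sprintf("unknown group '%s'", group))
  m <- exp(seq(log(mass_range[1]), log(mass_range[2]), length.out = n))
  sc <- (m / anchor$mass)^(1 / 3)
  data.frame(name = sprintf("%s_iso_%02d", group, seq_len(n)),
             group = group, mass_kg = m,
             wing_length_m = anchor$wing_length * sc,
             flap_freq_hz = anchor$freq / sc,
             stroke_amp_rad = anchor$stroke_amplitude)
}

# Per-group default stroke amplitudes used when a record omits one: order-one
# radians, with the shallow-stroke override for elongated flies.
.default_stroke_amp <- function(group) {
  vapply(group, function(g) .paradigm[[g]]$stroke_amplitude, numeric(1))
}

#' Model sweep over a species table
#'
#' For each species: builds the paradigm kinematics at the species'
#' morphology, normalises the group weight-support profile to the species'
#' weight, runs the acoustic model, and integrates the radiated power on a
#' farfield sphere (radius `radius_wavelengths` first-harmonic wavelengths,
#' so the geometry is acoustically similar across species). Also evaluates
#' the scaling law and its predictor for each species.
#'
#' @param species data frame in the [read_species_table()] schema
#' @param method `"eq1"` or `"eq3"`
#' @param n_nodes quadrature nodes per species
#' @param samples_per_period simulation resolution
#' @param radius_wavelengths farfield radius in units of \eqn{\lambda_1}
#' @param med a [medium()]
#' @return A `"scaling_result"` data frame with `p_sim`, `p_law` and
#'   `predictor` columns appended.
#' @export
species_sweep <- function(species, method = c("eq1", "eq3"), n_nodes = 128,
                          samples_per_period = 256, radius_wavelengths = 2,
                          med = medium()) {
  method <- match.arg(method)
  if (nrow(species) == 0)
    return(structure(cbind(species, p_sim = numeric(0), p_law = numeric(0),
                           predictor = numeric(0)),
                     class = c("scaling_result", "data.frame")))
  bad <- setdiff(unique(species$group), paradigm_groups())
  if (length(bad) > 0)
    stop(sprintf("unmapped group(s): %s", paste(bad, collapse = ", ")))
  if (is.null(species$stroke_amp_rad))
    species$stroke_amp_rad <- NA_real_
  species$stroke_amp_rad <- ifelse(is.na(species$stroke_amp_rad),
                                   .default_stroke_amp(species$group),
                                   species$stroke_amp_rad)
  p_sim <- numeric(nrow(species))
  for (i in seq_len(nrow(species))) {
    rec <- species[i, ]
    preset <- make_preset(rec$group, mass = rec$mass_kg,
                          wing_length = rec$wing_length_m,
                          freq = rec$flap_freq_hz,
                          stroke_amplitude = rec$stroke_amp_rad)
    mod <- hum_model(preset$spec, med = med, weight_support = preset$profile,
                     lift_drag_ratio = preset$lift_drag_ratio,
                     samples_per_period = samples_per_period)
    radius <- radius_wavelengths * med$speed_of_sound / rec$flap_freq_hz
    p_sim[i] <- radiated_power(mod, radius, n_nodes = n_nodes, method = method)
  }
  p_law <- as.numeric(power_law(species$mass_kg, species$stroke_amp_rad,
                                species$flap_freq_hz, med))
  structure(cbind(species, p_sim = p_sim, p_law = p_law, predictor = p_law),
            method = method, class = c("scaling_result", "data.frame"))
}

#' Allometric log-log slope fits
#'
#' Ordinary least squares of log10 simulated power on log10 of either body
#' mass or the scaling-law predictor, per group (with at least 3 species)
#' and pooled. A slope of 1 against the predictor means the scaling law
#' collapses the simulations.
#'
#' @param result a [species_sweep()] result
#' @param x `"predictor"` or `"mass"`
#' @param level confidence level for the slope interval
#' @return Data frame with `group` (including `"all"`), `slope`, `ci_lo`,
#'   `ci_hi`, `n`.
#' @export
fit_allometry <- function(result, x = c("predictor", "mass"), level = 0.95) {
  x <- match.arg(x)
  stopifnot(inherits(result, "scaling_result"))
  xv <- if (x == "mass") result$mass_kg else result$predictor
  if (any(xv <= 0) || any(result$p_sim <= 0))
    stop("non-positive values cannot be log-fitted")
  fit1 <- function(lx, ly) {
    m <- stats::lm(ly ~ lx)
    ci <- stats::confint(m, "lx", level = level)
    c(slope = unname(stats::coef(m)["lx"]), ci_lo = ci[1], ci_hi = ci[2])
  }
  lx <- log10(xv); ly <- log10(result$p_sim)
  rows <- list(c(group = "all", as.list(fit1(lx, ly)), n = nrow(result)))
  for (g in unique(result$group)) {
    sel <- result$group == g
    if (sum(sel) >= 3)
      rows[[length(rows) + 1]] <- c(group = g, as.list(fit1(lx[sel], ly[sel])),
                                    n = sum(sel))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(group = r$group, slope = r$slope, ci_lo = r$ci_lo,
               ci_hi = r$ci_hi, n = r$n)))
  rownames(out) <- NULL
  out
}
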