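# Configuration, table I/O and the programmatic CLI entry points. All output
# tables are delimited text: angles in degrees, positions in metres,
# pressures in Pa, SPL in dB re the configured reference (20 uPa default).

.coord_header <- paste("# coordinates: x anterior, y left, z up, origin at",
                       "the shoulder pivot; angles deg, positions m,",
                       "pressure Pa")

#' Read a run configuration
#'
#' Configurations are YAML (or JSON) mappings with optional blocks `medium`
#' (ao, rho, g), `animal` (`preset` name plus field overrides `mass`,
#' `wing_length`, `freq`, `stroke_amplitude`), `simulation`
#' (`samples_per_period`, `n_periods`, `harmonic_cutoff`, `method`),
#' `analysis` (`n_harmonics`, `half_width`, `broadband`, `spl_reference`),
#' `observers` (list of `[x, y, z]` or a `file` with columns
#' `label,x,y,z`), `directivity` (`plane`, `radius`, `bands`, `n_angles`),
#' and `output` (`dir`, `wav`, `wav_scale`). Any omitted field takes the
#' documented default, so a run is reproducible from its config alone.
#'
#' @param path YAML or JSON file
#' @return A `"run_config"` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping")
  structure(cfg, class = "run_config", source = normalizePath(path))
}

.cfg_get <- function(cfg, path, default) {
  node <- cfg
  for (key in path) {
    if (is.null(node[[key]])) return(default)
    node <- node[[key]]
  }
  node
}

.cfg_medium <- function(cfg) {
  medium(speed_of_sound = .cfg_get(cfg, c("medium", "speed_of_sound"), 343),
         density = .cfg_get(cfg, c("medium", "density"), 1.23),
         gravity = .cfg_get(cfg, c("medium", "gravity"), 9.81))
}

.cfg_model <- function(cfg) {
  med <- .cfg_medium(cfg)
  preset <- make_preset(
    .cfg_get(cfg, c("animal", "preset"), "hummingbird"),
    mass = .cfg_get(cfg, c("animal", "mass"), NULL),
    wing_length = .cfg_get(cfg, c("animal", "wing_length"), NULL),
    freq = .cfg_get(cfg, c("animal", "freq"), NULL),
    stroke_amplitude = .cfg_get(cfg, c("animal", "stroke_amplitude"), NULL))
  hum_model(preset$spec, med = med, weight_support = preset$profile,
            lift_drag_ratio = preset$lift_drag_ratio,
            harmonic_cutoff = .cfg_get(cfg, c("simulation", "harmonic_cutoff"),
                                       NULL),
            samples_per_period = .cfg_get(cfg, c("simulation",
                                                 "samples_per_period"), 1024))
}

.cfg_observers <- function(cfg) {
  obs <- .cfg_get(cfg, "observers", list(c(0, 0, 1)))
  if (is.list(obs) && !is.null(obs$file)) {
    tab <- utils::read.csv(obs$file, stringsAsFactors = FALSE)
    need <- c("label", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stop("observer file needs columns label, x, y, z")
    return(lapply(seq_len(nrow(tab)), function(i)
      observer(c(tab$x[i], tab$y[i], tab$z[i]), tab$label[i])))
  }
  if (is.matrix(obs)) obs <- lapply(seq_len(nrow(obs)), function(i) obs[i, ])
  lapply(seq_along(obs), function(i)
    observer(as.numeric(obs[[i]]), sprintf("obs%02d", i)))
}

.write_manifest <- function(cfg, outdir, files) {
  cfgfile <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), cfgfile, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "flaphum",
    version = as.character(utils::packageVersion("flaphum")),
    config_hash = unname(tools::md5sum(cfgfile)),
    config = unclass(cfg),
    files = files)
  unlink(cfgfile)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.out_dir <- function(cfg) {
  dir <- .cfg_get(cfg, c("output", "dir"), ".")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create output directory: %s", dir))
  dir
}

.write_table <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.coord_header, con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Run a simulation from a configuration: traces, spectra, harmonic tables
#'
#' Computes the pressure trace at every configured observer, writes per-
#' observer trace CSVs (time, total, nearfield, farfield channels), the
#' summed-array spectrum, a per-observer harmonic SPL table, optional WAV
#' renderings, and a JSON run manifest with the package version and config
#' hash. Fully deterministic: identical configs give bit-identical numeric
#' output.
#'
#' @param config a [read_run_config()] object or path
#' @param quiet suppress progress messages
#' @return Invisibly, a list with the output file paths, the traces and the
#'   harmonic tables.
#' @export
cli_simulate <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  model <- .cfg_model(config)
  obs <- .cfg_observers(config)
  outdir <- .out_dir(config)
  n_periods <- .cfg_get(config, c("simulation", "n_periods"), 18)
  method <- .cfg_get(config, c("simulation", "method"), "eq1")
  n_harm <- .cfg_get(config, c("analysis", "n_harmonics"), 10)
  hw <- .cfg_get(config, c("analysis", "half_width"), 2.5)
  p_ref <- .cfg_get(config, c("analysis", "spl_reference"), 20e-6)
  wav <- isTRUE(.cfg_get(config, c("output", "wav"), FALSE))
  note <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)
  traces <- list()
  tables <- list()
  for (i in seq_along(obs)) {
    note("simulating observer %d/%d (%s)", i, length(obs), obs[[i]]$label)
    tr <- if (method == "eq3") pressure_eq3(model, obs[[i]], n_periods)
          else pressure_eq1(model, obs[[i]], n_periods)
    traces[[i]] <- tr
    f <- file.path(outdir, sprintf("trace_%s.csv", obs[[i]]$label))
    .write_table(data.frame(time_s = tr$times, p_pa = tr$p,
                            nearfield_pa = tr$nearfield,
                            farfield_pa = tr$farfield), f)
    files <- c(files, f)
    sp <- spl_spectrum(tr, p_ref = p_ref)
    ht <- harmonic_bands(sp, n_harmonics = n_harm, half_width = hw)
    tables[[i]] <- ht
    f <- file.path(outdir, sprintf("harmonics_%s.csv", obs[[i]]$label))
    .write_table(as.data.frame(ht), f)
    files <- c(files, f)
    if (wav) {
      f <- file.path(outdir, sprintf("trace_%s.wav", obs[[i]]$label))
      write_wav(tr, f, scale = .cfg_get(config, c("output", "wav_scale"), 1e3))
      files <- c(files, f)
    }
  }
  sp_sum <- summed_array_spectrum(traces, p_ref = p_ref)
  f <- file.path(outdir, "spectrum_summed.csv")
  .write_table(data.frame(frequency_hz = sp_sum$frequency, spl_db = sp_sum$spl,
                          mean_square_pa2 = sp_sum$mean_square), f)
  files <- c(files, f)
  .write_manifest(config, outdir, basename(files))
  note("wrote %d files to %s", length(files) + 1, outdir)
  invisible(list(files = files, traces = traces, harmonics = tables))
}

#' Directivity sections and principal-axis report from a configuration
#'
#' Computes sagittal and/or coronal band directivity sections at the
#' configured radii, writes one CSV per section and a principal-axis report
#' with one row per (plane, radius, band), analogous to the model rows of a
#' near/farfield directivity-angle table. With `directivity$radius_ladder`
#' set, also fits and reports the farfield decay exponent of band rms
#' versus radius.
#'
#' @inheritParams cli_simulate
#' @return Invisibly, a list with the report data frame and file paths.
#' @export
cli_directivity <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  model <- .cfg_model(config)
  outdir <- .out_dir(config)
  planes <- .cfg_get(config, c("directivity", "planes"),
                     c("sagittal", "coronal"))
  radii <- .cfg_get(config, c("directivity", "radii"), c(1, 10))
  bands <- .cfg_get(config, c("directivity", "bands"), 1:4)
  n_angles <- .cfg_get(config, c("directivity", "n_angles"), 360)
  method <- .cfg_get(config, c("simulation", "method"), "eq1")
  note <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)
  rows <- list()
  for (plane in planes) for (radius in radii) for (b in bands) {
    note("section %s r=%g band=%s", plane, radius, as.character(b))
    sec <- directivity_section(model, plane, radius, band = b,
                               n_angles = n_angles, method = method)
    f <- file.path(outdir, sprintf("section_%s_r%g_band%s.csv", plane, radius,
                                   as.character(b)))
    .write_table(as.data.frame(sec), f)
    files <- c(files, f)
    ax <- tryCatch(principal_axis(sec), error = function(e) NA_real_)
    rows[[length(rows) + 1]] <- data.frame(plane = plane, radius_m = radius,
                                           band = as.character(b),
                                           axis_deg = ax)
  }
  report <- do.call(rbind, rows)
  if (!is.null(.cfg_get(config, c("directivity", "radius_ladder"), NULL))) {
    ladder <- as.numeric(.cfg_get(config, c("directivity", "radius_ladder"),
                                  NULL))
    rms <- vapply(ladder, function(r) {
      .node_band_rms(model, c(0, 0, r), 1, c(3, 500), method)$far_rms
    }, numeric(1))
    ex <- stats::coef(stats::lm(log(rms) ~ log(ladder)))[2]
    note("farfield decay exponent on ladder: %.3f", ex)
    report <- rbind(report, data.frame(plane = "ladder", radius_m = NA,
                                       band = "farfield_exponent",
                                       axis_deg = unname(ex)))
  }
  f <- file.path(outdir, "principal_axes.csv")
  .write_table(report, f)
  files <- c(files, f)
  .write_manifest(config, outdir, basename(files))
  invisible(list(report = report, files = files))
}

#' Species sweep and allometric fits from the command line
#'
#' @param species_csv path to a species table ([read_species_table()] schema)
#' @inheritParams cli_simulate
#' @return Invisibly, a list with the sweep result and slope table.
#' @export
cli_sweep <- function(species_csv, config = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config)) config <- structure(list(), class = "run_config")
  species <- read_species_table(species_csv)
  outdir <- .out_dir(config)
  res <- species_sweep(
    species,
    method = .cfg_get(config, c("simulation", "method"), "eq1"),
    n_nodes = .cfg_get(config, c("sweep", "n_nodes"), 128),
    samples_per_period = .cfg_get(config, c("simulation",
                                            "samples_per_period"), 256),
    med = .cfg_medium(config))
  slopes <- rbind(
    cbind(x = "predictor", fit_allometry(res, "predictor")),
    cbind(x = "mass", fit_allometry(res, "mass")))
  f1 <- .write_table(as.data.frame(res), file.path(outdir, "sweep_results.csv"))
  f2 <- .write_table(slopes, file.path(outdir, "sweep_slopes.csv"))
  .write_manifest(config, outdir, basename(c(f1, f2)))
  if (!quiet) message(sprintf("swept %d species", nrow(res)))
  invisible(list(result = res, slopes = slopes, files = c(f1, f2)))
}

# In vivo table ingestion -----------------------------------------------------

.read_delim_table <- function(path, need) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s) %s (expected %s)", basename(path),
                 paste(miss, collapse = ", "), paste(need, collapse = ", ")))
  tab
}

.check_phase_coverage <- function(phase, what) {
  phase <- sort(phase %% 1)
  gaps <- diff(c(phase, phase[1] + 1))
  if (max(gaps) > 0.2)
    stop(sprintf("%s: phase coverage has a gap of %.2f wingbeats (need dense coverage of [0,1))",
                 what, max(gaps)))
}

#' Ingest measured kinematics and force tables
#'
#' Reads delimited tables of wingbeat-resolved kinematics
#' (`phase, stroke_rad, deviation_rad`) and per-wing forces
#' (`phase, lift_N, drag_N`, or `phase, weight_support_bw`), optionally
#' lowpass-filters them with the zero-phase Butterworth settings used for
#' measured data (forces: order 8 at 180 Hz; kinematics: order 4 at 400 Hz),
#' fits periodic Fourier representations, and returns objects ready for the
#' acoustic pipeline. This is the path for externally deposited in vivo
#' recordings.
#'
#' @param kinematics_file kinematics table path
#' @param forces_file forces table path (optional)
#' @param mass,wing_length,freq,r3_frac morphology of the recorded animal
#' @param n_harmonics Fourier truncation order for the fits
#' @param filter_kinematics,filter_forces lists `list(order =, cutoff =)`
#'   applied at the implied sample rate `freq * samples`, or NULL to skip
#' @return List with `spec` (a [flapping_spec()]) and, when a forces file is
#'   given, `lift`/`drag` [fourier_series()] or `profile`
#'   ([weight_support_profile()]).
#' @export
read_in_vivo_tables <- function(kinematics_file, forces_file = NULL,
                                mass, wing_length, freq, r3_frac = 0.55,
                                n_harmonics = 5,
                                filter_kinematics = NULL,
                                filter_forces = NULL) {
  kin <- .read_delim_table(kinematics_file,
                           c("phase", "stroke_rad", "deviation_rad"))
  if (nrow(kin) < 2 * (2 * n_harmonics + 1))
    stop("kinematics table too short for the requested harmonic order")
  .check_phase_coverage(kin$phase, "kinematics")
  ord <- order(kin$phase %% 1)
  kin <- kin[ord, ]
  # filter on three tiled copies of the (periodic) wingbeat record and keep
  # the middle one, so filtfilt edge transients never touch the kept data
  maybe_filter <- function(y, fl, n) {
    if (is.null(fl)) return(y)
    y3 <- lowpass_forces(rep(y, 3), order = fl$order, cutoff = fl$cutoff,
                         sample_rate = freq * n)
    y3[(n + 1):(2 * n)]
  }
  kin$stroke_rad <- maybe_filter(kin$stroke_rad, filter_kinematics, nrow(kin))
  kin$deviation_rad <- maybe_filter(kin$deviation_rad, filter_kinematics,
                                    nrow(kin))
  stroke <- fit_fourier_series(kin$phase, kin$stroke_rad, n_harmonics)
  deviation <- fit_fourier_series(kin$phase, kin$deviation_rad, n_harmonics)
  ptp <- diff(range(eval_fourier(stroke, seq(0, 1, length.out = 1025)[-1025])))
  spec <- flapping_spec(mass = mass, wing_length = wing_length,
                        r3_frac = r3_frac, freq = freq,
                        stroke_amplitude = ptp, stroke = stroke,
                        deviation = deviation)
  out <- list(spec = spec)
  if (!is.null(forces_file)) {
    head1 <- utils::read.csv(forces_file, nrows = 1, comment.char = "#")
    if ("weight_support_bw" %in% names(head1)) {
      frc <- .read_delim_table(forces_file, c("phase", "weight_support_bw"))
      .check_phase_coverage(frc$phase, "forces")
      w <- maybe_filter(frc$weight_support_bw, filter_forces, nrow(frc))
      out$profile <- weight_support_profile(
        fit_fourier_series(frc$phase, w, n_harmonics), group = "ingested")
    } else {
      frc <- .read_delim_table(forces_file, c("phase", "lift_N", "drag_N"))
      .check_phase_coverage(frc$phase, "forces")
      lift <- maybe_filter(frc$lift_N, filter_forces, nrow(frc))
      drag <- maybe_filter(frc$drag_N, filter_forces, nrow(frc))
      out$lift <- fit_fourier_series(frc$phase, lift, n_harmonics)
      out$drag <- fit_fourier_series(frc$phase, drag, n_harmonics)
    }
  }
  out
}

#' Write kinematics / force tables for a spec or model
#'
#' Round-trip companions to [read_in_vivo_tables()].
#'
#' @param spec a [flapping_spec()]
#' @param path output CSV path
#' @param n samples over the wingbeat
#' @return `path`, invisibly.
#' @export
write_kinematics_table <- function(spec, path, n = 256) {
  tau <- seq(0, 1, length.out = n + 1)[-(n + 1)]
  kin <- eval_kinematics(spec, tau)
  utils::write.csv(data.frame(phase = kin$phase, stroke_rad = kin$stroke,
                              deviation_rad = kin$deviation),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinematics_table
#' @param model a [hum_model()] whose left-wing lift/drag series are written
#' @export
write_forces_table <- function(model, path, n = 256) {
  stopifnot(inherits(model, "hum_model"))
  np <- model$samples_per_period
  idx <- floor(seq(0, np, length.out = n + 1))[-(n + 1)] + 1
  utils::write.csv(data.frame(phase = (idx - 1) / np,
                              lift_N = model$forces$left$lift[idx],
                              drag_N = model$forces$left$drag[idx]),
                   path, row.names = FALSE)
  invisible(path)
}
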