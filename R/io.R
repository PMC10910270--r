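# TSV readers/writers, YAML configuration and fixture generation.
#
# Interchange dialect: UTF-8 TSV with a header row, '.' decimal, values at 17
# significant digits (lossless for doubles). Recordings carry the sampling
# rate in a leading '# fs=<Hz>' comment line.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read sensor geometry TSV
#'
#' Columns `name, x, y, z, ox, oy, oz, sensor_id`, tab-separated, one row per
#' channel. Reading validates orientations: deviations from unit norm above
#' 1e-6 trigger a warning and the orientation is re-normalised; missing
#' columns or non-finite values are rejected.
#'
#' @param array A [sensor_array()].
#' @param path File path.
#' @param axes_per_sensor Axis multiplicity to assume on read (inferred from
#'   the sensor ids by default).
#' @return `write_geometry` returns `path` invisibly; `read_geometry` a
#'   [sensor_array()].
#' @export
write_geometry <- function(array, path) {
  df <- data.frame(
    name = array$names,
    x = fmt17(array$positions[, 1]), y = fmt17(array$positions[, 2]),
    z = fmt17(array$positions[, 3]),
    ox = fmt17(array$orientations[, 1]), oy = fmt17(array$orientations[, 2]),
    oz = fmt17(array$orientations[, 3]),
    sensor_id = array$sensor_index)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path, axes_per_sensor = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(name = "character"))
  need <- c("name", "x", "y", "z", "ox", "oy", "oz", "sensor_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("geometry file missing column(s): ",
                         paste(miss, collapse = ", "))
  pos <- as.matrix(df[, c("x", "y", "z")])
  ori <- as.matrix(df[, c("ox", "oy", "oz")])
  if (any(!is.finite(pos)) || any(!is.finite(ori))) {
    bad <- which(!stats::complete.cases(cbind(pos, ori)))[1]
    stop("non-finite geometry value at data line ", bad)
  }
  nrm <- sqrt(rowSums(ori^2))
  if (any(abs(nrm - 1) > 1e-6))
    warning(sum(abs(nrm - 1) > 1e-6),
            " orientation(s) deviate from unit norm by more than 1e-6; re-normalised")
  fix <- abs(nrm - 1) > 1e-12 # leave bit-exact rows untouched (lossless round-trip)
  ori[fix, ] <- ori[fix, , drop = FALSE] / nrm[fix]
  dimnames(pos) <- dimnames(ori) <- NULL
  if (is.null(axes_per_sensor))
    axes_per_sensor <- max(table(df$sensor_id))
  sensor_array(df$name, pos, ori, axes_per_sensor, df$sensor_id)
}

#' Write / read a multichannel recording TSV
#'
#' First line `# fs=<Hz>`, then a header `name\tt000001...` and one row per
#' channel at 17 significant digits (lossless round-trip).
#'
#' @param rec A [recording()].
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `read_recording` a
#'   [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "opm_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g", rec$fs), con)
  writeLines(paste(c("name", sprintf("t%06d", seq_len(ncol(rec$data)))),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(rec$data)))
    writeLines(paste(c(rec$names[i], fmt17(rec$data[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  if (!grepl("^# fs=", first)) stop("missing '# fs=' header line in ", path)
  fs <- as.numeric(sub("^# fs=", "", first))
  df <- utils::read.delim(path, skip = 1, check.names = FALSE,
                          colClasses = "character")
  dat <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[, -1, drop = FALSE])), nrow = nrow(df)))
  if (any(!is.finite(dat))) {
    bad <- which(apply(dat, 1, function(r) any(!is.finite(r))))[1]
    stop("non-finite sample value at data line ", bad, " of ", path)
  }
  recording(dat, fs, df[[1]])
}

default_config <- function() {
  list(
    basis = list(family = "spheroidal", external_family = "spherical",
                 L_in = 9L, L_out = 2L, grad_step = NA_real_),
    spheroid = list(centre = c(0, 0, 0), axis = c(0, 1, 0),
                    a = 0.08, b = 0.07),
    temporal = list(limit = 0.98, window_s = 0),
    simulate = list(seed = 1L, reps = 50L)
  )
}

#' Read / write a YAML configuration
#'
#' Unknown keys are rejected; missing keys take the documented defaults. The
#' parsed configuration round-trips to an identical normalised form.
#'
#' @param path YAML file path.
#' @param config A configuration list (as returned by `read_config`).
#' @return `read_config` returns the normalised configuration list.
#' @export
read_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  def <- default_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown)) stop("unknown config section(s): ",
                            paste(unknown, collapse = ", "))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(def[[sec]]))
    if (length(bad)) stop("unknown key(s) in [", sec, "]: ",
                          paste(bad, collapse = ", "))
    for (k in names(raw[[sec]])) def[[sec]][[k]] <- raw[[sec]][[k]]
  }
  def$basis$L_in <- as.integer(def$basis$L_in)
  def$basis$L_out <- as.integer(def$basis$L_out)
  def$simulate$seed <- as.integer(def$simulate$seed)
  def$simulate$reps <- as.integer(def$simulate$reps)
  def
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Generate a small deterministic fixture scenario
#'
#' A 60-sensor triaxial array on the default head spheroid, three cortical
#' sources driven by smooth random time courses, one interference topography
#' with a sinusoidal driver and white noise. Files written: `array.tsv`,
#' `recording.tsv`, `leadfields.tsv`, `config.yaml`. Byte-stable for a given
#' seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sph <- reference_spheroid()
  arr <- generate_scalp_array(sph, spacing = 0.025, axes = 3, seed = seed) # ~60 sensors
  lf <- simulate_leadfields(arr, sph, n_src = 3, seed = seed)
  fs <- 200; n_t <- 400
  sim <- with_seed(seed + 1, {
    tt <- seq_len(n_t) / fs
    J <- rbind(sin(2 * pi * 7 * tt), sin(2 * pi * 11 * tt + 1),
               sin(2 * pi * 17 * tt + 2)) * 1e-8
    topo <- random_interference(arr)
    interf <- topo %o% (5e-12 * sin(2 * pi * 3 * tt))
    noise <- matrix(stats::rnorm(n_channels(arr) * n_t, sd = 1e-13),
                    n_channels(arr), n_t)
    lf$matrix %*% J + interf + noise
  })
  rec <- recording(sim, fs, arr$names)
  paths <- list(array = file.path(dir, "array.tsv"),
                recording = file.path(dir, "recording.tsv"),
                config = file.path(dir, "config.yaml"))
  write_geometry(arr, paths$array)
  write_recording(rec, paths$recording)
  write_config(default_config(), paths$config)
  invisible(list(array = arr, recording = rec, leadfields = lf,
                 spheroid = sph, paths = paths))
}
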