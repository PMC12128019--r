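#' Write / read one window's energy series as TSV
#'
#' The on-disk series format is plain tab-separated text: a single comment
#' header line `# lambda=<l> temperature=<T> seed=<s>` followed by a column
#' header and the per-frame rows `step`, `e_singlet`, `e_triplet`, `e_mix`.
#' Values are written with full double precision so a round trip reproduces
#' the series exactly.
#'
#' @param series An [energy_series()].
#' @param path Output file path.
#' @return `path` invisibly (write); an [energy_series()] (read).
#' @export
write_energy_series <- function(series, path) {
  stopifnot(inherits(series, "energy_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lambda=%s temperature=%s seed=%s",
                     format(series_lambda(series), digits = 17),
                     format(series_temperature(series), digits = 17),
                     series_seed(series)), con)
  writeLines(paste(c("step", "e_singlet", "e_triplet", "e_mix"),
                   collapse = "\t"), con)
  writeLines(sprintf("%d\t%s\t%s\t%s", series$step,
                     format(series$e_singlet, digits = 17),
                     format(series$e_triplet, digits = 17),
                     format(series$e_mix, digits = 17)), con)
  invisible(path)
}

#' @rdname write_energy_series
#' @export
read_energy_series <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec(
    "^#\\s*lambda=([^ ]+)\\s+temperature=([^ ]+)\\s+seed=([^ ]+)", header))[[1]]
  if (length(m) != 4) {
    abort(sprintf("'%s' is not an energy-series file (bad header).", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          colClasses = c("integer", rep("numeric", 3)))
  energy_series(df, lambda = as.numeric(m[2]), temperature = as.numeric(m[3]),
                seed = suppressWarnings(as.integer(m[4])))
}

#' Write / read a two-state system definition as YAML
#'
#' Versioned schema (`format: spinfep-system/1`) with a `[system]` block
#' carrying the backend name, particle layout and backend parameter arrays.
#'
#' @param system A [two_state_system()].
#' @param path File path.
#' @return `path` invisibly (write); a [two_state_system()] (read).
#' @export
write_system_yaml <- function(system, path) {
  stopifnot(inherits(system, "two_state_system"))
  yaml::write_yaml(list(
    format = "spinfep-system/1",
    system = list(
      backend = system$backend,
      n_particles = system$n_particles,
      dim = system$dim,
      masses = as.numeric(system$masses),
      frozen = as.logical(system$frozen),
      params = system$params)), path)
  invisible(path)
}

#' @rdname write_system_yaml
#' @export
read_system_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$format) || !identical(doc$format, "spinfep-system/1")) {
    abort(sprintf("'%s': unsupported or missing system format key.", path))
  }
  s <- doc$system
  for (req in c("backend", "n_particles", "dim", "params")) {
    if (is.null(s[[req]])) {
      abort(sprintf("'%s': system block is missing '%s'.", path, req))
    }
  }
  p <- s$params
  # yaml scalarizes length-1 arrays; the constructors re-validate shapes
  if (s$backend == "noisy_environment") p$solute <- lapply(p$solute, unlist)
  two_state_system(s$backend, params = lapply(p, function(v) {
    if (is.list(v)) v else unlist(v)
  }), n_particles = s$n_particles, dim = s$dim,
  masses = s$masses %||% 1, frozen = s$frozen %||% FALSE)
}

# 32-bit FNV-1a hash of a string; provenance fingerprint for manifests.
# Arithmetic kept in doubles below 2^41 so no precision is lost.
config_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 2^32
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Run all lambda windows of a schedule and write series + manifest
#'
#' Samples every window of `schedule` (by Langevin MD, or by exact canonical
#' draws for harmonic-family backends when `sampler = "exact"`), writes one
#' TSV series file per lambda into `out_dir`, and writes a `manifest.json`
#' recording the schedule, per-window seeds, sampler, package version and a
#' config hash. A rerun from the same manifest inputs is bit-identical.
#' Per-window seeds are derived from the master seed and the window index, so
#' windows are reproducible independently.
#'
#' @param system A [two_state_system()] (or path to a system YAML file).
#' @param schedule Strictly increasing lambda schedule from 0 to 1; default
#'   `c(0, 0.2, 0.4, 0.6, 0.8, 1)` -- four alchemical intermediates between
#'   the pure singlet and pure triplet.
#' @param config An [md_config()]; its `seed` acts as the master seed. For
#'   `sampler = "exact"`, `n_steps - n_equil` frames are drawn per window at
#'   `config$temperature`.
#' @param out_dir Output directory (created if needed).
#' @param sampler `"md"` ([run_window()]) or `"exact"`
#'   ([direct_canonical_sample()]).
#' @return Invisibly, the list of written series file paths.
#' @export
run_simulate <- function(system, config, out_dir,
                         schedule = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                         sampler = c("md", "exact")) {
  sampler <- match.arg(sampler)
  if (is.character(system)) system <- read_system_yaml(system)
  check_schedule(schedule)
  stopifnot(inherits(config, "md_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(schedule))
  seeds <- integer(length(schedule))
  for (i in seq_along(schedule)) {
    seeds[i] <- window_seed(config$seed, i)
    series <- if (sampler == "md") {
      cfg_i <- config
      cfg_i$seed <- seeds[i]
      run_window(system, schedule[i], cfg_i)
    } else {
      direct_canonical_sample(system, schedule[i], config$temperature,
                              n = config$n_steps - config$n_equil,
                              seed = seeds[i])
    }
    paths[i] <- file.path(out_dir,
                          sprintf("window_lambda_%s.tsv",
                                  gsub("\\.", "p", format(schedule[i]))))
    write_energy_series(series, paths[i])
  }
  cfg_string <- paste(
    sampler, paste(schedule, collapse = ","), config$n_steps, config$n_equil,
    config$dt, config$temperature, config$friction, config$record_stride,
    sep = "|")
  jsonlite::write_json(list(
    format = "spinfep-manifest/1",
    version = as.character(utils::packageVersion("spinfep")),
    sampler = sampler,
    schedule = schedule,
    master_seed = config$seed,
    window_seeds = seeds,
    temperature = config$temperature,
    config_hash = config_hash(cfg_string),
    files = basename(paths)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

check_schedule <- function(schedule) {
  if (length(schedule) < 2 || any(diff(schedule) <= 0) ||
      schedule[1] != 0 || schedule[length(schedule)] != 1) {
    abort("`schedule` must increase strictly from 0 to 1.",
          class = "spinfep_schedule_error")
  }
  invisible(schedule)
}

#' FEP estimate from series files on disk
#'
#' Estimation-only mode: reads a directory of energy-series TSV files (or an
#' explicit file list), checks that their lambdas form a contiguous schedule
#' from 0 to 1 and share one temperature, and runs [fep_estimate()].
#'
#' @param paths A directory containing `*.tsv` series files, or a character
#'   vector of file paths.
#' @param ... Passed to [fep_estimate()].
#' @return A `fep_result`.
#' @export
fep_estimate_files <- function(paths, ...) {
  manifest_path <- NULL
  if (length(paths) == 1 && dir.exists(paths)) {
    manifest_path <- file.path(paths, "manifest.json")
    paths <- list.files(paths, pattern = "\\.tsv$", full.names = TRUE)
  }
  if (length(paths) < 2) {
    abort("Need at least two series files for an estimate.")
  }
  series <- lapply(paths, read_energy_series)
  lams <- sort(vapply(series, series_lambda, numeric(1)))
  if (!is.null(manifest_path) && file.exists(manifest_path)) {
    declared <- unlist(jsonlite::read_json(manifest_path)$schedule)
    missing <- setdiff(declared, lams)
    if (length(missing)) {
      abort(sprintf(
        "Missing lambda window(s) declared by the manifest: %s.",
        paste(missing, collapse = ", ")),
        class = "spinfep_schedule_error")
    }
  }
  if (lams[1] != 0 || lams[length(lams)] != 1) {
    abort(sprintf(
      "Series schedule {%s} does not span lambda 0 to 1.",
      paste(lams, collapse = ", ")), class = "spinfep_schedule_error")
  }
  fep_estimate(series, ...)
}

#' Write a FEP result document as JSON
#'
#' Emits per-window `dg`, `eps`, `r1`, `sampling_ratio`, `n` plus the totals,
#' the schedule and (optionally) provenance fields.
#'
#' @param result A `fep_result`.
#' @param path Output file path.
#' @param provenance Optional named list merged into the document (e.g.
#'   master seed, config hash).
#' @return `path`, invisibly.
#' @export
write_fep_json <- function(result, path, provenance = NULL) {
  stopifnot(inherits(result, "fep_result"))
  doc <- list(
    format = "spinfep-result/1",
    lambda_schedule = result$lambda_schedule,
    temperature = result$temperature,
    windows = result$windows,
    total_dg = result$total_dg,
    total_eps = result$total_eps)
  if (!is.null(provenance)) doc <- c(doc, provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Plain-text summary table of Delta-U and Delta-G estimates
#'
#' A small fixed-width report in the layout of spin-state free-energy tables:
#' one row per method, columns `dU +/- SD` and `dG +/- eps`.
#'
#' @param fep A `fep_result`, or `NULL`.
#' @param du A `delta_u_result` from [delta_u()], or `NULL`.
#' @param method Row label.
#' @return A character vector of report lines (also printed invisibly
#'   usable via `cat`).
#' @export
fep_summary_table <- function(fep = NULL, du = NULL, method = "model") {
  fmt <- function(v, e) if (is.null(v)) "" else sprintf("%.1f +/- %.1f", v, e)
  lines <- c(
    sprintf("%-16s %-22s %-22s", "method", "dU (kJ/mol)", "dG (kJ/mol)"),
    sprintf("%-16s %-22s %-22s", method,
            if (is.null(du)) "" else fmt(du$du, du$sd),
            if (is.null(fep)) "" else
              sprintf("%.1f +/- %.2f", fep$total_dg, fep$total_eps)))
  lines
}
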