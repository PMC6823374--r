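# Trajectory CSV writers/readers, JSON manifests, fixture generator.

.fmt12 <- function(x) sprintf("%.12g", x)

# Solver configuration of a trajectory as a plain list (JSON-ready).
.traj_config <- function(traj) {
  cfg <- list(
    type = if (inherits(traj, "fhr_coupled_trajectory")) "coupled" else
      "single",
    alpha = traj$alpha, dt = traj$dt, n_steps = traj$n_steps,
    perturbation_scale = traj$perturbation_scale,
    engine = traj$engine,
    init = as.numeric(traj$init),
    params = c(unclass(traj$params)),
    label = attr(traj$params, "label"),
    package_version = as.character(packageVersion("fracFHR")))
  if (cfg$type == "coupled") {
    cfg$g_e <- traj$g_e
    cfg$seeds <- traj$seeds
  } else {
    cfg$seed <- traj$seed
  }
  cfg
}

#' Write a trajectory to CSV (with a JSON sidecar)
#'
#' Columns `t, v, w, y` (or `t, v1, w1, y1, v2, w2, y2` for a coupled run),
#' 12 significant digits. The full solver configuration (alpha, dt, seeds,
#' parameters, package version) goes to `<path>.json`, so any output can be
#' regenerated bit-for-bit.
#'
#' @param traj an `fhr_trajectory` or `fhr_coupled_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, c("fhr_trajectory", "fhr_coupled_trajectory")))
  df <- as.data.frame(traj)
  out <- as.data.frame(lapply(df, .fmt12), stringsAsFactors = FALSE)
  names(out) <- names(df)
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(.traj_config(traj), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Restores the trajectory object, including its configuration from the
#' JSON sidecar when present (without a sidecar a bare object with the data
#' columns is returned).
#'
#' @param path CSV path.
#' @return An `fhr_trajectory` or `fhr_coupled_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  side <- paste0(path, ".json")
  cfg <- if (file.exists(side)) jsonlite::read_json(side,
                                                    simplifyVector = TRUE)
  else NULL
  states <- as.matrix(df[, -1, drop = FALSE])
  coupled <- ncol(states) == 6L
  params <- if (!is.null(cfg))
    do.call(fhr_params, c(as.list(cfg$params),
                          list(label = cfg$label)))
  else NULL
  base <- list(times = df$t, states = states, params = params,
               alpha = if (!is.null(cfg)) cfg$alpha else NA_real_,
               dt = if (!is.null(cfg)) cfg$dt else
                 stats::median(diff(df$t)),
               n_steps = nrow(states) - 1L,
               perturbation_scale = cfg$perturbation_scale,
               init = states[1L, ],
               engine = cfg$engine)
  if (coupled) {
    base$g_e <- cfg$g_e
    base$seeds <- as.integer(cfg$seeds)
    structure(base, class = "fhr_coupled_trajectory")
  } else {
    base$seed <- if (!is.null(cfg)) as.integer(cfg$seed) else NA_integer_
    structure(base, class = "fhr_trajectory")
  }
}

#' Write a run manifest
#'
#' Every CLI run drops a `manifest.json` naming the subcommand, the full
#' configuration (including seeds and alpha), the package version and a
#' timestamp: enough to reproduce the outputs bit-for-bit with the same
#' build.
#'
#' @param dir output directory.
#' @param subcommand the CLI subcommand (or any run label).
#' @param config named list echoing the full configuration.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, subcommand, config) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(subcommand = subcommand, config = config,
         package_version = as.character(packageVersion("fracFHR")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Generate seeded fixtures
#'
#' Writes the five canonical parameter sets as flat YAML configs plus three
#' seeded initial-condition files (perturbed preset-I equilibria, seeds
#' `seed`, `seed+1`, `seed+2`) and a manifest.
#'
#' @param dir output directory (created if needed).
#' @param seed base integer seed.
#' @return Character vector of the files written, invisibly.
#' @export
fhr_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (lab in c("I", "II", "III", "IV", "V")) {
    f <- file.path(dir, sprintf("preset-%s.yaml", lab))
    write_params_config(fhr_preset(lab), f)
    files <- c(files, f)
  }
  p1 <- fhr_preset("I")
  for (i in 1:3) {
    s <- as.integer(seed) + i - 1L
    x0 <- perturbed_init(p1, s)
    f <- file.path(dir, sprintf("init-%d.csv", i))
    writeLines(c("seed,v,w,y",
                 paste(s, .fmt12(x0[1]), .fmt12(x0[2]), .fmt12(x0[3]),
                       sep = ",")), f)
    files <- c(files, f)
  }
  write_manifest(dir, "fixtures", list(seed = as.integer(seed)))
  invisible(c(files, file.path(dir, "manifest.json")))
}
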