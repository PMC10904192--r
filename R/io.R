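# error helper for config validation: unknown keys are rejected with the
# offending field path so typos never silently fall back to defaults.
.check_keys <- function(x, allowed, path) {
  if (is.null(x)) return(invisible(TRUE))
  if (!is.list(x)) stop("config block '", path, "' must be a mapping",
                        call. = FALSE)
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste0(path, ".", unknown), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Write a time series as delimited text
#'
#' CSV with header `t,y1..yn[,u1..up]`, one sample per line, rendered at
#' full double precision (17 significant digits) so that a read-back
#' reproduces every value exactly. Provenance is written to a JSON
#' sidecar `<path>.meta.json`.
#'
#' @param ts a [time_series()].
#' @param path output file path.
#' @param meta write the sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, meta = TRUE) {
  stopifnot(inherits(ts, "time_series"))
  M <- cbind(t = ts$t, ts$Y)
  if (!is.null(ts$U) && ncol(ts$U) > 0) M <- cbind(M, ts$U)
  header <- paste(colnames(M), collapse = ",")
  body <- apply(M, 1, function(row)
    paste(sprintf("%.17g", row), collapse = ","))
  writeLines(c(header, body), path)
  if (meta && length(ts$meta))
    jsonlite::write_json(ts$meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a time series from delimited text
#'
#' Expects the format written by [write_timeseries()]: a `t` column,
#' state columns `y1..yn`, optional input columns `u1..up`. Timestamps
#' must be strictly increasing and uniform to 1e-9 relative; violations
#' are reported with the offending row.
#'
#' @param path input file path.
#' @return a [time_series()]; the sidecar meta is attached when present.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cn <- names(df)
  if (!"t" %in% cn) stop("missing 't' column in ", path, call. = FALSE)
  ycols <- grep("^y[0-9]+$", cn, value = TRUE)
  ucols <- grep("^u[0-9]+$", cn, value = TRUE)
  if (length(ycols) == 0) stop("no state columns y1..yn in ", path, call. = FALSE)
  extra <- setdiff(cn, c("t", ycols, ucols))
  if (length(extra))
    stop("unrecognised column(s): ", paste(extra, collapse = ", "), call. = FALSE)
  ycols <- ycols[order(as.integer(sub("^y", "", ycols)))]
  ucols <- ucols[order(as.integer(sub("^u", "", ucols)))]
  for (cc in c("t", ycols, ucols))
    if (!is.numeric(df[[cc]]))
      stop("non-numeric values in column '", cc, "'", call. = FALSE)
  meta <- list()
  side <- paste0(path, ".meta.json")
  if (file.exists(side))
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  time_series(df$t, as.matrix(df[ycols]),
              if (length(ucols)) as.matrix(df[ucols]) else NULL,
              meta = meta, tol = 1e-9)
}

#' Export a discovered model as JSON
#'
#' Schema-versioned structured text: states, per-equation term and
#' coefficient lists, `dt`, `threshold`, a hash of the library labels,
#' plus a human-readable rendering of each equation.
#'
#' @param model a `discovered_model`.
#' @param path output path.
#' @param lib optional `odisco_library` used to record the library hash.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, lib = NULL) {
  stopifnot(inherits(model, "discovered_model"))
  render <- vapply(seq_len(model$n_states), function(j) {
    eq <- model$equations[[j]]
    rhs <- if (nrow(eq) == 0) "0" else
      paste(sprintf("%+.6g*%s", eq$coefficient, eq$label), collapse = " ")
    paste0("dx", j, "/dt = ", rhs)
  }, character(1))
  obj <- list(schema_version = "1.0",
              n_states = model$n_states,
              dt = model$dt, threshold = model$threshold,
              library_hash = if (is.null(lib)) NULL else .library_hash(lib),
              equations = lapply(seq_len(model$n_states), function(j) {
                eq <- model$equations[[j]]
                list(state = j,
                     terms = if (nrow(eq)) eq else list())
              }),
              rendering = render)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}

.library_hash <- function(lib) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(c(lib$n_states, lib$n_inputs, lib$mode,
               paste(lib$row, lib$labels, sep = ":")), tf)
  unname(tools::md5sum(tf))
}

#' Export a parameter-estimate trajectory as CSV
#'
#' Columns `k,t,theta_1..theta_r` at full precision.
#'
#' @param traj an `estimate_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(traj, path) {
  stopifnot(inherits(traj, "estimate_trajectory"))
  r <- ncol(traj$theta_path)
  header <- paste(c("k", "t", paste0("theta_", seq_len(r))), collapse = ",")
  M <- cbind(seq_len(nrow(traj$theta_path)), traj$t, traj$theta_path)
  body <- apply(M, 1, function(row) paste(sprintf("%.17g", row), collapse = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration with blocks `system`, `library`,
#' `observer`, `pipeline`, `output`, `seed`. Missing observer entries
#' fall back to the benchmark defaults (`lambda_x` 0.995,
#' `lambda_theta` 0.999, `Rx = Rtheta = I`, `Px0 = Ptheta0 = 0.1 I`,
#' zero initial sensitivity and parameters); unknown keys are rejected
#' with their field path.
#'
#' @param path configuration file path.
#' @return an object of class `run_config` with parsed `system` (list),
#'   `library` (`odisco_library` or NULL), `observer`
#'   ([observer_config()]), `pipeline` (threshold, level, window),
#'   `output`, `seed`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  .check_keys(raw, c("system", "library", "observer", "pipeline", "output",
                     "seed"), "config")
  obs <- raw$observer %||% list()
  .check_keys(obs, c("lambda_x", "lambda_theta", "rx_scale", "rtheta_scale",
                     "px0_scale", "ptheta0_scale", "x0_policy", "x0",
                     "theta0"), "observer")
  cfg <- observer_config(
    lambda_x = obs$lambda_x %||% 0.995,
    lambda_theta = obs$lambda_theta %||% 0.999,
    Rx = obs$rx_scale %||% 1,
    Rtheta = obs$rtheta_scale %||% 1,
    Px0 = obs$px0_scale %||% 0.1,
    Ptheta0 = obs$ptheta0_scale %||% 0.1,
    x0_policy = obs$x0_policy %||% "first_measurement",
    x0 = obs$x0,
    theta0 = if (is.null(obs$theta0)) NULL else as.numeric(obs$theta0))
  sys <- raw$system
  .check_keys(sys, c("name", "params", "x0", "dt", "n_steps", "integrator",
                     "input", "noise"), "system")
  if (!is.null(sys)) {
    if (is.null(sys$name)) stop("config error at system.name: missing",
                                call. = FALSE)
    .check_keys(sys$input, c("kind", "amplitude", "frequency", "offset",
                             "phase"), "system.input")
    .check_keys(sys$noise, c("sd", "seed"), "system.noise")
  }
  pl <- raw$pipeline %||% list()
  .check_keys(pl, c("threshold", "level", "window"), "pipeline")
  lib <- if (is.null(raw$library)) NULL else library_from_config(raw$library)
  structure(list(system = sys, library = lib, observer = cfg,
                 pipeline = list(threshold = pl$threshold %||% 5e-4,
                                 level = pl$level %||% 0.8,
                                 window = pl$window %||% 200),
                 output = raw$output, seed = raw$seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> system=", x$system$name %||% "<none>",
      " seed=", x$seed %||% "<none>", "\n", sep = "")
  print(x$observer)
  invisible(x)
}
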