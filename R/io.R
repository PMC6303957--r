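#' Resolve a run configuration from a file and/or overrides
#'
#' Reads a YAML or JSON configuration for one of the pipeline commands
#' (`simulate`, `fit`, `analyze`, `grid`) and fills unset fields from the
#' documented defaults: 4 chains, 2000 iterations, 1000 burn-in, 100
#' replicates, n = 1000. Unknown keys are rejected so that typos cannot
#' silently fall back to defaults.
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON config file, or
#'   `NULL` to use `overrides` alone.
#' @param overrides Named list of fields that take precedence over the
#'   file (command-line flags).
#' @return An object of class `run_config`: the fully resolved settings.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    command = "grid", data = NULL, scenarios = "table1",
    beta_yx = 0, beta_yz = 1, beta_xz = 1, beta_yu = 0, beta_xu = 0,
    beta_zu = 0, n = 1000L,
    prior_mean = NULL, tau_yz = NULL, tau_yx = 0.001, sigma_upper = 100,
    n_chains = 4L, n_iter = 2000L, n_burn = 1000L,
    reps = 100L, seed = 1L, out = NULL, verbose = FALSE, intercept = FALSE)

  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(cfg)) cfg <- list()
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]

  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  resolved <- utils::modifyList(defaults, cfg, keep.null = TRUE)

  if (!resolved$command %in% c("simulate", "fit", "analyze", "grid"))
    stop("unknown command: ", resolved$command, call. = FALSE)
  for (nm in c("n", "n_chains", "n_iter", "n_burn", "reps", "seed")) {
    v <- resolved[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v != round(v))
      stop("config field '", nm, "' must be a single integer", call. = FALSE)
    resolved[[nm]] <- as.integer(v)
  }
  if (resolved$n_burn >= resolved$n_iter)
    stop("n_burn must be < n_iter", call. = FALSE)
  if (!is.null(resolved$tau_yz) && any(resolved$tau_yz <= 0))
    stop("tau_yz must be strictly positive", call. = FALSE)
  structure(resolved, class = "run_config")
}

#' Expand the configured priors into prior_spec objects
#'
#' `tau_yz` in a config may be a vector (e.g. `c(1000, 100, 10)`), in
#' which case one [prior_spec()] is built per precision, all sharing the
#' configured prior mean.
#'
#' @param config A `run_config` from [load_config()].
#' @return Named list of [prior_spec()] objects.
#' @export
config_priors <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$tau_yz) || is.null(config$prior_mean))
    stop("config must set 'prior_mean' and 'tau_yz' to build priors",
         call. = FALSE)
  taus <- config$tau_yz
  out <- lapply(taus, function(t)
    prior_spec(mu_yz = config$prior_mean, tau_yz = t,
               tau_yx = config$tau_yx, sigma_upper = config$sigma_upper))
  names(out) <- paste0("tau", format(taus, trim = TRUE, scientific = FALSE))
  out
}

#' Write pipeline results with an embedded provenance header
#'
#' Tables (`scenario_metrics` collections, data.frames) are written as CSV
#' with `#`-prefixed header lines embedding the package version, the master
#' seed and the resolved configuration as JSON; single fits are written as
#' JSON. Bodies are deterministic for a given config and seed; the wall
#' clock goes to a `.meta` sidecar so repeated runs are byte-identical.
#'
#' @param x A data.frame (written as CSV) or a `posterior_summary` /
#'   `fit_result` / list (written as JSON).
#' @param path Output file path.
#' @param config Optional `run_config` to embed.
#' @param seed Optional master seed to embed.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, config = NULL, seed = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  meta <- list(package = "priorconf",
               version = as.character(utils::packageVersion("priorconf")),
               seed = seed,
               config = if (!is.null(config)) unclass(config))
  ok <- tryCatch({
    if (is.data.frame(x)) {
      con <- file(path, "w")
      on.exit(close(con), add = TRUE)
      writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                               null = "null")), con)
      utils::write.csv(x, con, row.names = FALSE)
    } else {
      payload <- list(meta = meta, result = unclass_deep(x))
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
    }
    TRUE
  }, error = function(e) {
    stop("failed writing results to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  writeLines(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
             paste0(path, ".meta"))
  invisible(path)
}

# strip classes/draws so fits serialize as plain JSON
unclass_deep <- function(x) {
  if (inherits(x, "posterior_summary"))
    return(list(mean = as.list(x$mean), sd = as.list(x$sd),
                rhat = as.list(x$rhat), n_retained = x$n_retained))
  if (inherits(x, "fit_result"))
    return(list(method = x$method, estimate = as.list(x$estimate),
                se = as.list(x$se), sigma = x$sigma))
  if (is.list(x)) return(lapply(x, unclass_deep))
  x
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return The data.frame, with the embedded provenance header parsed into
#'   the `"meta"` attribute.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  out <- utils::read.csv(text = paste(lines[!hdr], collapse = "\n"),
                         check.names = FALSE)
  if (any(hdr))
    attr(out, "meta") <- jsonlite::fromJSON(sub("^# ", "", lines[hdr][1]))
  out
}

#' Write or read a dataset as headed CSV
#'
#' Datasets travel as plain CSV with a one-line header naming the columns
#' (`y`, `x`, `z` and optionally `u`).
#'
#' @param data Data frame to write.
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   validated data.frame.
#' @export
write_dataset <- function(data, path) {
  validate_dataset(data, intersect(c("y", "x", "z"), names(data)))
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  validate_dataset(d, intersect(c("y", "x", "z"), names(d)))
  d
}
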