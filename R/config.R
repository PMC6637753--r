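#' Run configuration
#'
#' Bundles the solver, classification and analysis settings shared by all
#' stages. `run_config()` builds a validated configuration from defaults;
#' [load_config()] reads one from a flat `key: value` YAML file.
#'
#' @param rtol,atol Solver tolerances.
#' @param delta_rel,delta_abs Oscillation-amplitude thresholds
#'   (see [classify_regime()]).
#' @param cpi_threshold,ntsi_threshold Index classification thresholds
#'   (see [classify_cell()]).
#' @param horizon Default simulation horizon (h).
#' @param population_horizon Horizon for population runs (h).
#' @param window_fraction Final fraction of the horizon analyzed.
#' @param output_step Trajectory sampling step (h).
#' @param seed Default random seed.
#' @param src_pulse Src level of the transforming pulse (a.u.).
#' @param gene_map_path Optional path to a gene-name mapping TSV (must
#'   exist if given; empty string means the packaged default).
#' @return Object of class `grn_config` (a named list).
#' @export
run_config <- function(rtol = 1e-8, atol = 1e-10, delta_rel = 0.05,
                       delta_abs = 0.01, cpi_threshold = 1,
                       ntsi_threshold = 10, horizon = 600,
                       population_horizon = 1000, window_fraction = 0.4,
                       output_step = 0.5, seed = 1, src_pulse = 0.5,
                       gene_map_path = "") {
  cfg <- list(rtol = rtol, atol = atol, delta_rel = delta_rel,
              delta_abs = delta_abs, cpi_threshold = cpi_threshold,
              ntsi_threshold = ntsi_threshold, horizon = horizon,
              population_horizon = population_horizon,
              window_fraction = window_fraction, output_step = output_step,
              seed = as.integer(seed), src_pulse = src_pulse,
              gene_map_path = gene_map_path)
  num <- setdiff(names(cfg), "gene_map_path")
  if (!all(vapply(cfg[num], function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v), TRUE)))
    stop("all numeric config entries must be finite scalars", call. = FALSE)
  if (any(unlist(cfg[c("rtol", "atol", "delta_rel", "delta_abs",
                       "cpi_threshold", "ntsi_threshold", "horizon",
                       "population_horizon", "output_step")]) <= 0))
    stop("tolerances, thresholds and horizons must be > 0", call. = FALSE)
  if (cfg$window_fraction <= 0 || cfg$window_fraction > 1)
    stop("window_fraction must be in (0, 1]", call. = FALSE)
  if (nzchar(cfg$gene_map_path) && !file.exists(cfg$gene_map_path))
    stop("gene_map_path does not exist: ", cfg$gene_map_path, call. = FALSE)
  class(cfg) <- "grn_config"
  cfg
}

#' Load / write a run configuration
#'
#' The file is flat YAML (`key: value`); unknown keys are rejected, missing
#' keys take their defaults, and `load_config(write_config(cfg))` returns
#' an identical configuration.
#'
#' @param path Config file path.
#' @return `load_config`: a `grn_config`; `write_config`: invisibly `path`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed config file: ", conditionMessage(e), call. = FALSE))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("malformed config file: expected key: value pairs",
                          call. = FALSE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

#' @rdname load_config
#' @param config A `grn_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "grn_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Short reproducibility hash of an R object
#'
#' MD5 of the serialized object; used by [run_log()] to record effective
#' parameters.
#'
#' @param x Any R object.
#' @return Character scalar (32 hex digits).
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Structured run log line
#'
#' Emits (and invisibly returns) one structured log line recording the
#' stage, the hash of the effective parameters / config, the seed, and any
#' extra fields - enough to reproduce a deterministic stage byte-for-byte
#' and a stochastic stage distributionally.
#'
#' @param stage Character stage name (e.g. "simulate", "population").
#' @param params Effective parameters / settings object (hashed).
#' @param seed Seed in effect (NA for deterministic stages).
#' @param ... Further `name = value` fields appended to the line.
#' @param file Connection or path passed to [cat()] (default: stdout).
#' @return Invisibly, the log line.
#' @export
run_log <- function(stage, params = NULL, seed = NA, ..., file = "") {
  extra <- list(...)
  fields <- c(
    sprintf("time=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("stage=%s", stage),
    sprintf("params_hash=%s", if (is.null(params)) "none" else config_hash(params)),
    sprintf("seed=%s", ifelse(is.na(seed), "NA", as.character(seed))),
    if (length(extra)) sprintf("%s=%s", names(extra),
                               vapply(extra, function(v) paste(format(v), collapse = ";"), "")))
  line <- paste(fields, collapse = " ")
  cat(line, "\n", sep = "", file = file)
  invisible(line)
}

#' Figure-protocol presets
#'
#' Each preset bundles the parameter overrides, perturbation events and
#' run settings of one of the canonical simulation protocols (temporal
#' panels, switch and rescue protocols, population scatters). Presets are
#' shipped as YAML files under `inst/extdata/presets/` and loaded by name.
#'
#' @param name Preset name (see `list_presets()`), e.g. `"fig3a"`.
#' @return List with elements `description`, `overrides` (named numeric),
#'   `events` (list, possibly empty), `initial` (`"bootstrap"`, `"NT"` or
#'   `"T"`), `t_end`, and for population presets `n_cells`,
#'   `jitter_fraction`, `start`.
#' @export
load_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "let7cycle")
  if (!nzchar(path)) stop("unknown preset: ", name, call. = FALSE)
  pre <- yaml::read_yaml(path)
  stopifnot(is.list(pre), !is.null(pre$initial), !is.null(pre$t_end))
  if (length(pre$overrides)) apply_overrides(default_parameters(), pre$overrides)
  if (length(pre$events)) {
    pre$events <- lapply(pre$events, function(e) {
      list(t_start = e$t_start,
           t_end = if (is.character(e$t_end) && e$t_end == "Inf") Inf else e$t_end,
           overrides = unlist(e$overrides))
    })
    perturbation_schedule(default_parameters(), pre$events)  # validates
  } else pre$events <- list()
  pre
}

#' @rdname load_preset
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "let7cycle")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' Run a figure-protocol preset
#'
#' Resolves the preset's initial state (bootstrap, NT fixture or T
#' fixture), applies its overrides and events, and integrates.
#'
#' @param name Preset name.
#' @param fixtures Optional precomputed [make_fixtures()] result.
#' @param output_step Sampling step (h).
#' @return A `grn_trajectory`.
#' @export
run_preset <- function(name, fixtures = NULL, output_step = 1) {
  pre <- load_preset(name)
  base <- apply_overrides(default_parameters(), pre$overrides)
  init <- if (pre$initial == "bootstrap") {
    initial_state(base)
  } else {
    if (is.null(fixtures)) fixtures <- make_fixtures(default_parameters())
    fixtures[[pre$initial]]
  }
  sch <- perturbation_schedule(base, pre$events)
  integrate_model(sch, initial = init, t_end = pre$t_end,
                  output_step = output_step)
}
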