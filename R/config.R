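# Configuration schema, seeding and the YAML surface tying the pipeline
# together.

config_defaults <- function() {
  list(
    paradigm = "ALIGNED_FIXED", width = 20L, height = 20L,
    barrier_size = 4L, size_range = c(3L, 6L), attempts = 20L, buffer = 1L,
    density = 0.2,
    H = 2L, variant = "FULL",
    gamma_a = 0.95, gamma_e = 0.95, gamma_q = 0.95,
    alpha_a = 0.05, alpha_e = 0.05,
    eta = 0.005, beta1 = 0.9, beta2 = 0.999, eps_adam = 1e-8,
    epsilon = 0.1, tau = 0.2, step_cap = 10000L, adam_no_sqrt = FALSE,
    episodes_per_world = 1000L, n_worlds = 5L, n_tasks = 30L,
    seed = 1L)
}

#' Load (and validate) a run configuration
#'
#' Reads a YAML file, fills defaults for missing keys, rejects unknown keys
#' and validates ranges. An empty file yields all defaults. The resolved
#' configuration round-trips losslessly through [save_config()].
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated named list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, user)
  for (nm in c("width", "height", "barrier_size", "attempts", "buffer", "H",
               "step_cap", "episodes_per_world", "n_worlds", "n_tasks",
               "seed"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  cfg$size_range <- as.integer(cfg$size_range)
  validate_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

validate_config <- function(cfg) {
  chk <- function(ok, field, what)
    if (!ok) abort(sprintf("config field `%s` %s", field, what))
  for (nm in c("gamma_a", "gamma_e", "gamma_q"))
    chk(cfg[[nm]] > 0 && cfg[[nm]] < 1, nm, "must be in (0, 1)")
  for (nm in c("alpha_a", "alpha_e", "eta"))
    chk(cfg[[nm]] >= 0, nm, "must be >= 0")
  chk(cfg$epsilon >= 0 && cfg$epsilon <= 1, "epsilon", "must be in [0, 1]")
  chk(cfg$tau > 0, "tau", "must be > 0")
  chk(cfg$density >= 0 && cfg$density < 1, "density", "must be in [0, 1)")
  chk(cfg$H >= 1, "H", "must be >= 1")
  chk(cfg$paradigm %in% c("ALIGNED_FIXED", "ALIGNED_VARSIZE",
                          "RANDOM_ORIENT_VARSIZE", "FULLY_RANDOM"),
      "paradigm", "is not a known paradigm")
  chk(cfg$variant %in% LESION_VARIANTS, "variant", "is not a known variant")
  invisible(cfg)
}

#' Save a configuration to YAML
#' @param config A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Split config into generator and agent pieces
#' @param config A `run_config`.
#' @return List with `params` ([generator_params()]) and `agent`
#'   ([agent_config()]).
#' @export
config_objects <- function(config) {
  list(params = generator_params(
    paradigm = config$paradigm, width = config$width, height = config$height,
    barrier_size = config$barrier_size, size_range = config$size_range,
    attempts = config$attempts, buffer = config$buffer,
    density = config$density),
    agent = agent_config(
      gamma_a = config$gamma_a, gamma_e = config$gamma_e,
      gamma_q = config$gamma_q, alpha_a = config$alpha_a,
      alpha_e = config$alpha_e, eta = config$eta, beta1 = config$beta1,
      beta2 = config$beta2, eps_adam = config$eps_adam,
      epsilon = config$epsilon, tau = config$tau,
      step_cap = config$step_cap, adam_no_sqrt = config$adam_no_sqrt))
}

#' Derive named independent RNG stream seeds from a master seed
#'
#' Deterministic integer seeds for the package's named randomness sources
#' (world generation, start states/policy draws, permutation tests). Distinct
#' stream names map to distinct seed offsets; per-task seeds are formed by
#' adding the task index.
#'
#' @param master_seed Integer master seed.
#' @return Named list of integer seeds.
#' @export
seed_streams <- function(master_seed) {
  master_seed <- as.integer(master_seed)
  derive <- function(name) {
    h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
    as.integer((as.numeric(master_seed) * 48271 + h) %% 2147483563)
  }
  list(worldgen = derive("worldgen"), policy = derive("policy"),
       permutation = derive("permutation"), analysis = derive("analysis"))
}
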