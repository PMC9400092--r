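#' Run configuration
#'
#' A nested list of every tunable in one place, round-tripping losslessly
#' through YAML. Sections: `physical` (kT, zeta, dt, sigma2), `priors`,
#' `kernel` (h2, ell, m, margin), `sampler` (sweeps, burnin, thin, proposal
#' scales), `scenario` (name and generator settings for the built-in
#' benchmarks), and `seed`.
#'
#' @param ... Named overrides of the defaults, e.g.
#'   `skipper_config(sampler = list(sweeps = 100))` (partial lists are merged
#'   into the defaults).
#' @return An object of class `skipper_config`.
#' @examples
#' cfg <- skipper_config(seed = 7, sampler = list(sweeps = 200))
#' cfg$sampler$sweeps
#' @export
skipper_config <- function(...) {
  defaults <- list(
    physical = list(kT = 1, zeta = 2e-3, dt = 0.01, sigma2 = 25),
    priors = list(alpha_zeta = 2, beta_zeta = 1000,
                  alpha_sigma2 = 2, beta_sigma2 = 25, Theta2 = 1e4),
    kernel = list(h2 = 25, ell = 10, m = NULL, margin = 30),
    sampler = list(sweeps = 5000, burnin = 2000, thin = 5,
                   prop_sd_x = NULL, prop_sd_zeta = 0.1, n_zeta_steps = 5,
                   target_accept = 0.35, store_x = FALSE, adapt = TRUE),
    scenario = list(name = "harmonic", n_steps = 50000, stiffness = 0.005,
                    barrier_height = 10, half_separation = 75,
                    n_traj = 100, len_traj = 500, x0 = 0,
                    bin_width = 2),
    seed = 1L
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) abort(paste("Unknown config section(s):", paste(bad, collapse = ", ")))
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      bad2 <- setdiff(names(overrides[[nm]]), names(defaults[[nm]]))
      if (length(bad2))
        abort(paste0("Unknown key(s) in `", nm, "`: ", paste(bad2, collapse = ", ")))
      defaults[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else defaults[[nm]] <- overrides[[nm]]
  }
  structure(defaults, class = "skipper_config")
}

#' @export
print.skipper_config <- function(x, ...) {
  cat("<skipper_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Read / write a run configuration
#'
#' @param config A [skipper_config()].
#' @param path YAML file path.
#' @return `read_skipper_config()` returns a validated `skipper_config`.
#' @export
write_skipper_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' @rdname write_skipper_config
#' @export
read_skipper_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  raw <- yaml::read_yaml(path)
  do.call(skipper_config, raw)
}

# helpers mapping config sections onto the constructors
config_params <- function(cfg) do.call(skipper_params, cfg$physical)
config_priors <- function(cfg) do.call(skipper_priors, cfg$priors)
config_hyper <- function(cfg) kernel_hyper(h2 = cfg$kernel$h2, ell = cfg$kernel$ell)
config_control <- function(cfg) do.call(skipper_control, cfg$sampler)
config_potential <- function(cfg) {
  sc <- cfg$scenario
  switch(sc$name,
    "harmonic" = make_harmonic(stiffness = sc$stiffness),
    "double-well" = ,
    "rolloff" = make_double_well(barrier_height = sc$barrier_height,
                                 half_separation = sc$half_separation),
    "winky-face" = make_winky_face(),
    abort(sprintf("Unknown scenario '%s'.", sc$name))
  )
}
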