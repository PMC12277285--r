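#' Simulation configuration
#'
#' A configuration is a flat named list (class `hsp_config`) holding every
#' tunable of the model: neuron and coupling parameters, the calcium trace
#' and growth rule of the homeostatic structural plasticity (HSP) controller,
#' phase durations of the experimental protocol, and recording settings.
#'
#' Three profiles are shipped:
#' \describe{
#'   \item{`"paper"`}{Full scale: 10000 excitatory (E) + 2500 inhibitory (I)
#'     neurons, 750 s growth, 150 s learning and DC phases, readouts at
#'     1200 s.}
#'   \item{`"desk"`}{Scale 0.2 (2000 E + 500 I) with an accelerated growth
#'     profile (larger element growth rate, shorter phases) whose equilibrium
#'     reproduces the full-scale firing rate and connectivity on a single
#'     CPU in minutes.}
#'   \item{`"test"`}{Scale 0.05 (500 E + 125 I), strongly accelerated; used
#'     for property checks over many seeds.}
#' }
#'
#' The background rate `nu_ext_hz` is calibrated per profile (one-dimensional
#' search on the grown equilibrium) so that the network settles at the 8 Hz
#' setpoint with an E-E connection probability near 9%; the calibrated values
#' are stored in the profile defaults and remain user-overridable.
#'
#' @param profile One of `"paper"`, `"desk"`, `"test"`.
#' @param ... Named overrides for any configuration key.
#' @return An `hsp_config` list.
#' @examples
#' cfg <- default_config("test")
#' config_sizes(cfg)
#' @export
default_config <- function(profile = c("desk", "paper", "test"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile        = profile,
    scale          = 1,
    # neuron (Brunel-family values; membrane constant fixed by the printed
    # identity mu = nu * tau_m * J = 1.50 mV at nu = 1.5 kHz, J = 0.1 mV)
    tau_m_ms       = 10,
    v_theta_mv     = 20,
    v_reset_mv     = 10,
    t_ref_ms       = 2,
    delay_ms       = 1,
    # coupling
    j_mv           = 0.1,
    g              = 8,
    nu_ext_hz      = 29100,
    p_static       = 0.1,
    # calcium trace and linear growth rule (identical for boutons/spines);
    # beta = 1/tau_ca makes the mean calcium numerically equal the firing
    # rate in Hz, so the setpoint eps equals the 8 Hz target rate
    tau_ca_s       = 10,
    beta_ca        = 0.1,
    nu_g           = 2,
    target_rate_hz = 8,
    dt_struct_s    = 0.1,
    # integration
    dt_ms          = 0.1,
    # protocol
    growth_s       = 750,
    learn_s        = 150,
    dc_s           = 150,
    learn_rate_hz  = 1500,
    learn_j_mv     = 0.1,
    engram_fraction = 0.10,
    unfocused_overlap = 0.5,
    relax_end_s    = 1200,
    dvm_max_mv     = 0.6,
    allow_strong   = FALSE,
    # recording
    window_s       = 5,
    gamma_stride_s = 5
  )
  if (profile == "desk") {
    cfg$scale     <- 0.2
    cfg$nu_ext_hz <- 19500
    cfg$nu_g      <- 4
    cfg$tau_ca_s  <- 5
    cfg$beta_ca   <- 0.2
    cfg$growth_s  <- 250
    cfg$learn_s   <- 50
    cfg$dc_s      <- 50
    cfg$relax_end_s <- 400
  } else if (profile == "test") {
    cfg$scale     <- 0.05
    cfg$nu_ext_hz <- 18300
    cfg$nu_g      <- 0.7
    cfg$dt_ms     <- 0.2
    cfg$tau_ca_s  <- 5
    cfg$beta_ca   <- 0.2
    cfg$growth_s  <- 500
    cfg$learn_s   <- 20
    cfg$dc_s      <- 20
    cfg$relax_end_s <- 660
    cfg$window_s  <- 2.5
    cfg$gamma_stride_s <- 2.5
  }
  cfg <- utils::modifyList(cfg, resolve_linked_defaults(list(...), cfg))
  class(cfg) <- "hsp_config"
  validate_config(cfg)
}

# If tau_ca is overridden without beta, keep beta = 1/tau_ca so that the mean
# calcium equals the firing rate in Hz and eps stays the 8 Hz setpoint.
resolve_linked_defaults <- function(over, cfg) {
  if (!is.null(over$tau_ca_s) && is.null(over$beta_ca)) {
    over$beta_ca <- 1 / over$tau_ca_s
  }
  over
}

#' @rdname default_config
#' @param cfg An `hsp_config`.
#' @return `config_sizes()`: list with `n_E`, `n_I`, `n`, `n_engram`.
#' @export
config_sizes <- function(cfg) {
  n_E <- as.integer(round(10000 * cfg$scale))
  n_I <- as.integer(round(2500 * cfg$scale))
  n_engram <- cfg$engram_fraction * n_E
  if (abs(n_engram - round(n_engram)) > 1e-9) {
    stop("engram_fraction * n_E must be an integer (got ", n_engram, ")")
  }
  list(n_E = n_E, n_I = n_I, n = n_E + n_I, n_engram = as.integer(round(n_engram)))
}

config_keys <- function() names(unclass(default_config("paper")))

#' @rdname default_config
#' @export
validate_config <- function(cfg) {
  num_pos <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("config key '", key, "' must be a positive number", call. = FALSE)
    }
  }
  for (key in c("scale", "tau_m_ms", "v_theta_mv", "j_mv", "g", "tau_ca_s",
                "beta_ca", "nu_g", "target_rate_hz", "dt_struct_s", "dt_ms",
                "learn_rate_hz", "learn_j_mv", "engram_fraction", "window_s",
                "gamma_stride_s", "dvm_max_mv")) {
    num_pos(key)
  }
  if (cfg$v_theta_mv <= cfg$v_reset_mv || cfg$v_reset_mv < 0) {
    stop("require V_theta > V_reset >= 0", call. = FALSE)
  }
  if (cfg$t_ref_ms < 0 || cfg$nu_ext_hz < 0) {
    stop("t_ref and nu_ext must be non-negative", call. = FALSE)
  }
  if (cfg$delay_ms + 1e-9 < cfg$dt_ms) {
    stop("synaptic delay must be at least one integration step (dt <= delay)",
         call. = FALSE)
  }
  if (cfg$engram_fraction > 1) stop("engram_fraction must be <= 1", call. = FALSE)
  if (cfg$unfocused_overlap <= 0 || cfg$unfocused_overlap > 1) {
    stop("unfocused_overlap must be in (0, 1]", call. = FALSE)
  }
  for (key in c("growth_s", "learn_s", "dc_s", "relax_end_s")) {
    if (cfg[[key]] < 0) stop("config key '", key, "' must be non-negative",
                             call. = FALSE)
  }
  config_sizes(cfg)  # validates integrality of the engram
  cfg
}

# Calcium setpoint in trace units: eps = beta * tau_ca * target rate, so with
# beta = 1/tau_ca it equals the target rate in Hz.
config_eps_ca <- function(cfg) cfg$beta_ca * cfg$tau_ca_s * cfg$target_rate_hz

config_params <- function(cfg) {
  list(dt_ms = cfg$dt_ms, tau_m_ms = cfg$tau_m_ms, v_theta_mv = cfg$v_theta_mv,
       v_reset_mv = cfg$v_reset_mv, t_ref_ms = cfg$t_ref_ms,
       delay_ms = cfg$delay_ms, j_mv = cfg$j_mv, g = cfg$g,
       nu_ext_hz = cfg$nu_ext_hz, tau_ca_s = cfg$tau_ca_s,
       beta_ca = cfg$beta_ca, nu_g = cfg$nu_g, eps_ca = config_eps_ca(cfg),
       dt_struct_s = cfg$dt_struct_s)
}

#' Read and write configuration files
#'
#' Configurations are stored as flat YAML key/value files. Unknown keys are
#' rejected; omitted keys fall back to the profile defaults (an empty file
#' yields the full default configuration). `delta_vm` amplitudes beyond
#' `dvm_max_mv` (the weak-stimulation range) are rejected at plan
#' construction unless `allow_strong` is set.
#'
#' @param path File path.
#' @param profile Base profile whose defaults fill unspecified keys; a
#'   `profile:` key inside the file takes precedence.
#' @return An `hsp_config`.
#' @export
load_config <- function(path, profile = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a YAML mapping")
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  prof <- raw$profile %||% profile %||% "desk"
  raw$profile <- NULL
  do.call(default_config, c(list(profile = prof), raw))
}

#' @rdname load_config
#' @param cfg An `hsp_config` to serialize.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
#' @method print hsp_config
print.hsp_config <- function(x, ...) {
  sz <- config_sizes(x)
  cat("hspsim configuration (profile '", x$profile, "')\n", sep = "")
  cat(sprintf("  network: %d E + %d I neurons, engram %d\n",
              sz$n_E, sz$n_I, sz$n_engram))
  for (key in setdiff(names(unclass(x)), "profile")) {
    cat(sprintf("  %-18s %s\n", key, paste(format(x[[key]]), collapse = " ")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
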