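#' Linear gradient of deme optima
#'
#' Builds the baseline optimum phenotype of each deme: an affine function of
#' deme index, centered on zero, with adjacent demes differing by `steepness`.
#' The defaults elsewhere in the package (50 demes, steepness 0.4) give
#' endpoints of -9.8 and +9.8 trait units.
#'
#' @param n_demes number of demes (>= 1).
#' @param steepness change in the optimum between adjacent demes (trait units
#'   per deme, >= 0).
#' @return Numeric vector of baseline optima, length `n_demes`.
#' @examples
#' range(build_gradient(50, 0.4))  # -9.8  9.8
#' @export
build_gradient <- function(n_demes, steepness) {
  if (n_demes < 1L) stop("n_demes must be at least 1")
  if (steepness < 0) stop("steepness must be non-negative")
  (seq_len(n_demes) - (n_demes + 1) / 2) * steepness
}

#' Initialize the environment state
#'
#' The optimum of deme `i` in generation `t` is
#' `theta_it = O_i + tau * x_it`, where `O_i` is the baseline gradient and
#' `x_it` a stationary AR(1) process with unit marginal variance:
#' `x_it = rho * x_{i,t-1} + sqrt(1 - rho^2) * z_it`, `z_it ~ Normal(0, 1)`.
#' The latent state is initialized with a stationary draw so there is no
#' burn-in transient. When `synchronized`, one shared process drives every
#' deme (the optimum shifts by the same amount everywhere); otherwise each
#' deme runs an independent process.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `"environment_state"` with fields `baseline`,
#'   `current`, `latent`, `tau`, `rho`, `synchronized`, `generation`.
#' @export
init_environment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  baseline <- build_gradient(cfg$n_demes, cfg$gradient_steepness)
  tau <- tau_from_spec(cfg$tau_mode, cfg$tau_value, cfg)
  latent <- if (cfg$synchronized) {
    rep(stats::rnorm(1L), cfg$n_demes)
  } else {
    stats::rnorm(cfg$n_demes)
  }
  structure(
    list(baseline = baseline, current = baseline + tau * latent,
         latent = latent, tau = tau, rho = cfg$rho,
         synchronized = cfg$synchronized, generation = 0L),
    class = "environment_state"
  )
}

#' @export
print.environment_state <- function(x, ...) {
  cat("<environment_state> ", length(x$baseline), " demes, generation ",
      x$generation, "\n  tau = ", format(x$tau), ", rho = ", format(x$rho),
      if (x$synchronized) ", synchronized" else ", independent",
      "\n", sep = "")
  invisible(x)
}

#' Advance the environment by one generation
#'
#' Applies one AR(1) step to the latent state (one shared innovation when
#' synchronized, independent innovations per deme otherwise), recomputes the
#' current optima `baseline + tau * latent`, and increments the generation
#' counter. With `tau = 0` the current optima always equal the baseline.
#'
#' @param env an `"environment_state"`.
#' @return The updated state.
#' @export
advance_environment <- function(env) {
  stopifnot(inherits(env, "environment_state"))
  n <- length(env$baseline)
  z <- if (env$synchronized) rep(stats::rnorm(1L), n) else stats::rnorm(n)
  env$latent <- env$rho * env$latent + sqrt(1 - env$rho^2) * z
  env$current <- env$baseline + env$tau * env$latent
  env$generation <- env$generation + 1L
  env
}

#' Resolve the temporal-noise standard deviation tau
#'
#' Tau can be given in three scalings: `"absolute"` trait units;
#' `"percent"` of the gradient range (the difference between the optima at
#' the two gradient ends, 19.6 units for the default 50-deme gradient); or
#' `"width"`, a multiple of the survival-function width
#' `width_multiplier * sigma` (2 trait units at the defaults).
#'
#' @param mode one of `"absolute"`, `"percent"`, `"width"`.
#' @param value magnitude in the chosen scaling (percent mode takes the
#'   percentage number, e.g. 25 for 25%).
#' @param cfg a [sim_config()] supplying the gradient and selection width.
#' @return Tau in trait units (>= 0).
#' @examples
#' cfg <- sim_config()
#' tau_from_spec("percent", 25, cfg)  # 4.9
#' @export
tau_from_spec <- function(mode, value, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (value < 0) stop("tau magnitude must be non-negative")
  switch(match.arg(mode, c("absolute", "percent", "width")),
    absolute = value,
    percent = value / 100 * (cfg$n_demes - 1L) * cfg$gradient_steepness,
    width = value * selection_width(cfg)
  )
}
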