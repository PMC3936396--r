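#' Dispersal specification
#'
#' Two movement patterns are supported. Under `"stepping_stone"`, each
#' individual draws a `Normal(0, kernel_scale)` displacement which is
#' truncated toward zero to an integer number of demes, so the probability of
#' moving at all (`|draw| >= 1`) and the distance moved rise together with
#' the kernel scale; the scale is calibrated so the realized movement
#' probability equals `nominal_rate`. Under `"island"`, each individual
#' moves with probability `nominal_rate`, and a mover picks a destination
#' uniformly among all other demes. Individuals that would step beyond the
#' gradient are clamped to the terminal demes; dispersal itself is cost-free.
#'
#' @param pattern `"stepping_stone"` or `"island"`.
#' @param nominal_rate probability of moving, in `[0, 1]` (`< 1` for
#'   stepping stone, where 1 is unattainable under the truncated kernel).
#' @return An object of class `"dispersal_spec"` with the calibrated
#'   `kernel_scale` (stepping stone) attached.
#' @export
dispersal_spec <- function(pattern = c("stepping_stone", "island"),
                           nominal_rate = 0) {
  pattern <- match.arg(pattern)
  if (nominal_rate < 0 || nominal_rate > 1) {
    stop("nominal_rate must lie in [0, 1]")
  }
  scale <- if (pattern == "stepping_stone") {
    calibrate_stepping_stone(nominal_rate)
  } else {
    NA_real_
  }
  structure(
    list(pattern = pattern, nominal_rate = nominal_rate,
         kernel_scale = scale),
    class = "dispersal_spec"
  )
}

#' @export
print.dispersal_spec <- function(x, ...) {
  cat("<dispersal_spec> ", x$pattern, ", rate ", format(x$nominal_rate),
      if (x$pattern == "stepping_stone")
        paste0(", kernel scale ", format(x$kernel_scale, digits = 4)),
      "\n", sep = "")
  invisible(x)
}

#' Calibrate the stepping-stone kernel scale
#'
#' Finds the Gaussian scale `s` at which the probability of moving —
#' `P(|Normal(0, s)| >= 1)`, since displacements are truncated toward zero —
#' equals the nominal dispersal rate: `s = 1 / qnorm(1 - rate / 2)`.
#'
#' @param nominal_rate movement probability in `[0, 1)`.
#' @return Kernel scale in demes (`0` when the rate is 0).
#' @examples
#' calibrate_stepping_stone(0.32)  # ~1.006
#' @export
calibrate_stepping_stone <- function(nominal_rate) {
  if (nominal_rate < 0 || nominal_rate >= 1) {
    stop("stepping-stone rate must lie in [0, 1); a rate of 1 is unattainable")
  }
  if (nominal_rate == 0) return(0)
  1 / stats::qnorm(1 - nominal_rate / 2)
}

#' Draw stepping-stone displacements
#'
#' @param spec a stepping-stone [dispersal_spec()].
#' @param n number of draws.
#' @return Integer vector of signed displacements (0 = no movement).
#' @export
draw_displacement <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "dispersal_spec"))
  if (spec$pattern != "stepping_stone") {
    stop("draw_displacement applies only to stepping-stone dispersal")
  }
  if (spec$kernel_scale == 0) return(integer(n))
  as.integer(trunc(stats::rnorm(n, 0, spec$kernel_scale)))
}

#' Draw island-migration destinations
#'
#' A mover relocates to a deme chosen uniformly among all demes except its
#' origin.
#'
#' @param origin integer vector of origin demes.
#' @param n_demes total number of demes (>= 2).
#' @return Integer vector of destination demes, same length as `origin`.
#' @export
draw_island_destination <- function(origin, n_demes) {
  if (n_demes < 2L) stop("island migration requires at least 2 demes")
  k <- length(origin)
  dest <- floor(stats::runif(k) * (n_demes - 1L)) + 1L
  as.integer(dest + (dest >= origin))
}

#' Disperse a metapopulation
#'
#' Relocates every individual according to the dispersal pattern.
#' Stepping-stone targets beyond the gradient ends are clamped to deme 1 or
#' deme `n_demes`. Dispersal never changes the total population size and
#' incurs no mortality.
#'
#' @param pop a `"metapopulation"`.
#' @param spec a [dispersal_spec()].
#' @return The metapopulation with updated deme indices.
#' @export
disperse <- function(pop, spec) {
  stopifnot(inherits(pop, "metapopulation"), inherits(spec, "dispersal_spec"))
  n <- pop_size(pop)
  if (n == 0L || spec$nominal_rate == 0) return(pop)
  if (spec$pattern == "stepping_stone") {
    d <- draw_displacement(spec, n)
    pop$deme <- pmin(pmax(pop$deme + d, 1L), pop$n_demes)
  } else {
    moves <- which(stats::runif(n) < spec$nominal_rate)
    if (length(moves)) {
      pop$deme[moves] <- draw_island_destination(pop$deme[moves], pop$n_demes)
    }
  }
  pop
}
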