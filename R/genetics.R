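#' Construct a genotype
#'
#' A genotype carries two classes of diploid loci: deterministic loci, whose
#' allelic values sum to the genetically determined trait value, and
#' instability loci, whose (non-negative) allelic values sum to the standard
#' deviation of a random developmental deviate added to the trait at
#' development. Alleles are stored flat: locus `k` occupies positions
#' `2k - 1` and `2k`.
#'
#' @param det numeric vector of deterministic allelic values (length
#'   `2 * n_det_loci`; unbounded).
#' @param inst numeric vector of instability allelic values (same length
#'   convention; every value must be `>= 0`).
#' @return An object of class `"genotype"`.
#' @examples
#' g <- genotype(det = rep(1, 10), inst = rep(0, 10))
#' deterministic_value(g)
#' @export
genotype <- function(det, inst) {
  det <- as.numeric(det)
  inst <- as.numeric(inst)
  if (length(det) %% 2L != 0L || length(inst) %% 2L != 0L) {
    stop("allele vectors must have even length (two alleles per locus)")
  }
  if (anyNA(det) || anyNA(inst)) stop("allelic values must not be NA")
  if (any(inst < 0)) {
    stop("instability allelic values must be non-negative")
  }
  structure(list(det = det, inst = inst), class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype> ", length(x$det) / 2L, " deterministic + ",
      length(x$inst) / 2L, " instability loci\n", sep = "")
  cat("  deterministic value: ", format(deterministic_value(x)),
      " | instability sd: ", format(instability_sd(x)), "\n", sep = "")
  invisible(x)
}

#' Genetically determined trait value
#'
#' The deterministic loci act additively: the trait value encoded by a
#' genotype is the plain sum of all deterministic allelic values.
#'
#' @param g a [genotype()].
#' @return Scalar trait value.
#' @export
deterministic_value <- function(g) {
  stopifnot(inherits(g, "genotype"))
  sum(g$det)
}

#' Developmental-instability standard deviation
#'
#' The instability loci also act additively: their allelic values sum to the
#' standard deviation of the Gaussian developmental deviate drawn at
#' development. Because every instability allele is floored at zero, the sum
#' is always non-negative; zero means fully canalized development.
#'
#' @param g a [genotype()].
#' @return Non-negative scalar standard deviation (trait units).
#' @export
instability_sd <- function(g) {
  stopifnot(inherits(g, "genotype"))
  if (any(g$inst < 0)) stop("instability allelic values must be non-negative")
  sum(g$inst)
}

#' Develop an individual from a genotype
#'
#' Development draws the individual's (permanent) developmental deviate
#' `noise ~ Normal(0, instability_sd(g))` and freezes the phenotype at
#' `deterministic_value(g) + noise`. The phenotype is assigned exactly once:
#' an individual is never re-developed.
#'
#' @param g a [genotype()].
#' @param deme integer deme index the individual is born into.
#' @return An object of class `"individual"` with fields `genotype`,
#'   `phenotype`, `noise`, `deme`.
#' @export
develop <- function(g, deme = 1L) {
  stopifnot(inherits(g, "genotype"))
  s <- instability_sd(g)
  noise <- if (s > 0) stats::rnorm(1L, 0, s) else 0
  structure(
    list(genotype = g, phenotype = deterministic_value(g) + noise,
         noise = noise, deme = as.integer(deme)),
    class = "individual"
  )
}

#' @export
print.individual <- function(x, ...) {
  cat("<individual> deme ", x$deme,
      " phenotype ", format(x$phenotype),
      " (noise ", format(x$noise), ")\n", sep = "")
  invisible(x)
}

#' Mendelian inheritance with free recombination
#'
#' At every locus (deterministic and instability alike) the offspring receives
#' one uniformly chosen allele from each parent's pair at that locus; loci
#' segregate independently.
#'
#' @param a,b parental [genotype()]s with matching locus counts.
#' @return Offspring `"genotype"`.
#' @export
inherit <- function(a, b) {
  stopifnot(inherits(a, "genotype"), inherits(b, "genotype"))
  if (length(a$det) != length(b$det) || length(a$inst) != length(b$inst)) {
    stop("parental genotypes must have matching locus counts")
  }
  genotype(
    det = transmit_gametes(a$det, b$det),
    inst = transmit_gametes(a$inst, b$inst)
  )
}

# One allele per locus from each parent; offspring keeps the paired layout
# (parent a's contribution at 2k-1, parent b's at 2k).
transmit_gametes <- function(av, bv) {
  L <- length(av) %/% 2L
  first <- 2L * seq_len(L) - 1L
  pick_a <- first + (stats::runif(L) < 0.5)
  pick_b <- first + (stats::runif(L) < 0.5)
  out <- numeric(2L * L)
  out[first] <- av[pick_a]
  out[first + 1L] <- bv[pick_b]
  out
}

#' Mutate a genotype
#'
#' Each allele independently mutates with probability `rate`; a mutation adds
#' a `Normal(0, mut_sd)` deviate to the current allelic value (an
#' infinite-alleles model). Deterministic alleles are unbounded; mutated
#' instability alleles that would become negative are set to zero.
#'
#' @param g a [genotype()].
#' @param rate per-allele mutation probability in `[0, 1]`.
#' @param mut_sd standard deviation of the mutational deviate (trait units).
#' @return Mutated `"genotype"`.
#' @export
mutate_genotype <- function(g, rate = 0.1, mut_sd = 0.1) {
  stopifnot(inherits(g, "genotype"))
  if (rate < 0 || rate > 1) stop("mutation rate must lie in [0, 1]")
  if (mut_sd < 0) stop("mutational sd must be non-negative")
  if (rate == 0) return(g)
  det <- g$det
  hit <- which(stats::runif(length(det)) < rate)
  if (length(hit)) det[hit] <- det[hit] + stats::rnorm(length(hit), 0, mut_sd)
  inst <- g$inst
  hit <- which(stats::runif(length(inst)) < rate)
  if (length(hit)) {
    inst[hit] <- pmax(0, inst[hit] + stats::rnorm(length(hit), 0, mut_sd))
  }
  genotype(det, inst)
}

# ---- vectorized population representation -----------------------------------
# The simulation engine stores a whole metapopulation column-wise: one row per
# individual in two allele matrices plus per-individual vectors. The scalar
# genotype/individual API above defines the contracts; these routines are the
# same operations applied to all rows at once.

new_metapopulation <- function(det, inst, deme, phenotype, noise, n_demes) {
  structure(
    list(det = det, inst = inst, deme = as.integer(deme),
         phenotype = phenotype, noise = noise, n_demes = as.integer(n_demes)),
    class = "metapopulation"
  )
}

#' Number of individuals in a metapopulation
#' @param pop a `"metapopulation"`.
#' @return Integer count.
#' @export
pop_size <- function(pop) {
  stopifnot(inherits(pop, "metapopulation"))
  length(pop$deme)
}

#' @export
print.metapopulation <- function(x, ...) {
  occ <- tabulate(x$deme, x$n_demes)
  cat("<metapopulation> ", pop_size(x), " individuals in ",
      sum(occ > 0L), "/", x$n_demes, " demes\n", sep = "")
  if (pop_size(x) > 0L) {
    cat("  mean phenotype ", format(mean(x$phenotype), digits = 4),
        " | mean instability sd ", format(mean(rowSums(x$inst)), digits = 4),
        "\n", sep = "")
  }
  invisible(x)
}

pop_subset <- function(pop, idx) {
  new_metapopulation(pop$det[idx, , drop = FALSE], pop$inst[idx, , drop = FALSE],
                     pop$deme[idx], pop$phenotype[idx], pop$noise[idx],
                     pop$n_demes)
}

#' Extract one individual's genotype from a metapopulation
#' @param pop a `"metapopulation"`.
#' @param i row index.
#' @return A [genotype()].
#' @export
pop_genotype <- function(pop, i) {
  stopifnot(inherits(pop, "metapopulation"))
  genotype(pop$det[i, ], pop$inst[i, ])
}

# Draw developmental deviates and freeze phenotypes for a newborn cohort.
develop_cohort <- function(det, inst, deme, n_demes) {
  n <- nrow(det)
  s <- rowSums(inst)
  noise <- numeric(n)
  pos <- s > 0
  if (any(pos)) noise[pos] <- stats::rnorm(sum(pos), 0, s[pos])
  new_metapopulation(det, inst, deme, rowSums(det) + noise, noise, n_demes)
}

#' Found the initial metapopulation
#'
#' Every deme is founded at carrying capacity with newborns whose
#' deterministic allelic values are drawn i.i.d. uniformly from
#' `{-2, -1, 0, 1, 2}` and whose instability alleles all start at zero
#' (canalized founders). Each founder is developed immediately.
#'
#' @param cfg a [sim_config()].
#' @return A `"metapopulation"` of `n_demes * carrying_capacity` individuals.
#' @export
init_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_demes * cfg$carrying_capacity
  det <- matrix(
    sample(c(-2, -1, 0, 1, 2), n * 2L * cfg$n_det_loci, replace = TRUE),
    nrow = n
  )
  inst <- matrix(0, nrow = n, ncol = 2L * cfg$n_inst_loci)
  deme <- rep(seq_len(cfg$n_demes), each = cfg$carrying_capacity)
  develop_cohort(det, inst, deme, cfg$n_demes)
}
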