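#' Mean developmental instability of a population
#'
#' The population-level instability statistic is the mean, over individuals,
#' of the individual-level instability standard deviation (the sum of the
#' instability allelic values). It is the quantity reported at
#' selection-mutation balance (about 0.93 under the default parameters with
#' no environmental heterogeneity).
#'
#' @param pop a `"metapopulation"`.
#' @return Non-negative mean instability sd; `NA` (flagged missing) for an
#'   empty population.
#' @export
mean_instability <- function(pop) {
  stopifnot(inherits(pop, "metapopulation"))
  if (pop_size(pop) == 0L) return(NA_real_)
  mean(rowSums(pop$inst))
}

#' Local-adaptation index
#'
#' Measures how closely deme mean phenotypes track the baseline optima:
#' the ordinary least-squares slope of the deme-mean deterministic phenotype
#' (the genetic trait value, excluding developmental noise) on the baseline
#' optimum. The index is 1 when every deme mean equals its optimum, 0 when
#' all deme means are equal (no genetic differentiation), and scales
#' linearly in between. `method = "correlation"` instead returns the Pearson
#' correlation between deme means and optima (an alternative 0/1-anchored
#' index).
#'
#' @param pop a `"metapopulation"`.
#' @param baseline numeric vector of baseline optima per deme.
#' @param method `"slope"` (default) or `"correlation"`.
#' @return Scalar index.
#' @export
local_adaptation_index <- function(pop, baseline,
                                   method = c("slope", "correlation")) {
  stopifnot(inherits(pop, "metapopulation"))
  method <- match.arg(method)
  if (pop_size(pop) == 0L) stop("population is empty")
  genetic <- rowSums(pop$det)
  means <- rowsum(genetic, pop$deme) / tabulate(pop$deme, pop$n_demes)[
    sort(unique(pop$deme))]
  occ <- as.integer(rownames(means))
  if (length(occ) < 2L) stop("local adaptation needs >= 2 occupied demes")
  x <- baseline[occ]
  if (stats::var(x) == 0) stop("occupied demes must have distinct optima")
  y <- means[, 1L]
  if (method == "slope") {
    stats::cov(x, y) / stats::var(x)
  } else {
    if (stats::var(y) == 0) 0 else stats::cor(x, y)
  }
}

#' Equilibrium summary of one replicate
#'
#' Averages the recorded statistics over the equilibrium window: the final
#' `tail_frac` of the run's horizon (by recorded generation).
#'
#' @param result a `"replicate_result"`.
#' @param tail_frac fraction of the horizon treated as equilibrium.
#' @return One-row data.frame with `mean_instability`, `mean_phenotype`,
#'   `mean_fitness`, `local_adaptation`, `mean_size`.
#' @export
equilibrium_summary <- function(result, tail_frac = 0.1) {
  stopifnot(inherits(result, "replicate_result"))
  if (tail_frac <= 0 || tail_frac > 1) stop("tail_frac must lie in (0, 1]")
  rec <- result$records
  cutoff <- (1 - tail_frac) * result$config$generations
  win <- rec[rec$generation > cutoff, , drop = FALSE]
  if (nrow(win) == 0L) win <- rec[nrow(rec), , drop = FALSE]
  data.frame(
    mean_instability = mean(win$mean_instability, na.rm = TRUE),
    mean_phenotype = mean(win$mean_phenotype, na.rm = TRUE),
    mean_fitness = mean(win$mean_fitness, na.rm = TRUE),
    local_adaptation = if (all(is.na(win$local_adaptation))) NA_real_
                       else mean(win$local_adaptation, na.rm = TRUE),
    mean_size = mean(win$deme_size, na.rm = TRUE)
  )
}

#' Aggregate equilibrium statistics across replicates
#'
#' For each statistic column, computes the cross-replicate mean, sample
#' (n-1) standard deviation, and coefficient of variation in percent.
#'
#' @param df data.frame with one row per completed replicate and one numeric
#'   column per statistic.
#' @return Long data.frame with columns `statistic`, `n`, `mean`, `sd`,
#'   `cv_percent`.
#' @export
aggregate_replicates <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1L))
  df <- df[, num, drop = FALSE]
  if (ncol(df) == 0L || nrow(df) == 0L) stop("need at least one replicate")
  out <- lapply(names(df), function(nm) {
    v <- df[[nm]][!is.na(df[[nm]])]
    m <- mean(v)
    s <- if (length(v) > 1L) stats::sd(v) else NA_real_
    data.frame(statistic = nm, n = length(v), mean = m, sd = s,
               cv_percent = if (!is.na(s) && m != 0) 100 * s / abs(m)
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-deme summary of a metapopulation snapshot
#'
#' @param pop a `"metapopulation"`.
#' @param baseline optional baseline optima to attach.
#' @return Data.frame with one row per occupied deme: `deme`, `n`,
#'   `mean_instability`, `mean_phenotype`, and `optimum` when `baseline` is
#'   given.
#' @export
deme_summary <- function(pop, baseline = NULL) {
  stopifnot(inherits(pop, "metapopulation"))
  if (pop_size(pop) == 0L) {
    return(data.frame(deme = integer(0), n = integer(0),
                      mean_instability = numeric(0),
                      mean_phenotype = numeric(0)))
  }
  occ <- sort(unique(pop$deme))
  n <- tabulate(pop$deme, pop$n_demes)[occ]
  out <- data.frame(
    deme = occ, n = n,
    mean_instability = rowsum(rowSums(pop$inst), pop$deme)[, 1L] / n,
    mean_phenotype = rowsum(pop$phenotype, pop$deme)[, 1L] / n
  )
  if (!is.null(baseline)) out$optimum <- baseline[occ]
  rownames(out) <- NULL
  out
}
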