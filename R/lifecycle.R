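#' Simulation configuration
#'
#' Collects every model parameter with the study's defaults: a 50-deme linear
#' gradient whose optima step by 0.4 trait units per deme (endpoints -9.8 and
#' +9.8), carrying capacity 100 per deme, 5 deterministic + 5 instability
#' diploid loci, selection strength `sigma = 2` (effective width
#' survival-function width `width_multiplier * sigma = 2` trait units),
#' per-allele mutation rate 0.1 with mutational sd
#' 0.1, a 10,000-generation horizon, and 20 replicates with up to 60 attempts
#' per cell when metapopulations go extinct.
#'
#' @param n_demes number of demes on the gradient.
#' @param carrying_capacity individuals per deme after reproduction.
#' @param n_det_loci,n_inst_loci diploid locus counts for the two classes.
#' @param gradient_steepness change in optimum between adjacent demes.
#' @param sigma strength-of-selection parameter.
#' @param width_multiplier converts sigma to the effective selection width.
#' @param dispersal_pattern `"stepping_stone"` or `"island"`.
#' @param dispersal_rate nominal movement probability.
#' @param tau_mode,tau_value temporal-noise scaling and magnitude (see
#'   [tau_from_spec()]).
#' @param rho temporal autocorrelation in `(-1, 1)`.
#' @param synchronized share one temporal process across all demes?
#' @param life_history `"move_first"` (birth, development, dispersal,
#'   selection, reproduction) or `"select_first"` (selection before
#'   dispersal).
#' @param generations horizon in generations.
#' @param replicates completed replicates required per parameter cell.
#' @param mutation_rate,mutation_sd per-allele mutation probability and
#'   mutational deviate sd.
#' @param base_seed integer seed anchoring the replicate seed policy.
#' @param max_attempts attempt cap per cell when runs go extinct.
#' @param record_every record summary statistics every this many generations.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_demes = 50L,
                       carrying_capacity = 100L,
                       n_det_loci = 5L,
                       n_inst_loci = 5L,
                       gradient_steepness = 0.4,
                       sigma = 2,
                       width_multiplier = 1,
                       dispersal_pattern = c("stepping_stone", "island"),
                       dispersal_rate = 0,
                       tau_mode = c("absolute", "percent", "width"),
                       tau_value = 0,
                       rho = 0,
                       synchronized = FALSE,
                       life_history = c("move_first", "select_first"),
                       generations = 10000L,
                       replicates = 20L,
                       mutation_rate = 0.1,
                       mutation_sd = 0.1,
                       base_seed = 1L,
                       max_attempts = 60L,
                       record_every = 1L) {
  cfg <- structure(
    list(n_demes = as.integer(n_demes),
         carrying_capacity = as.integer(carrying_capacity),
         n_det_loci = as.integer(n_det_loci),
         n_inst_loci = as.integer(n_inst_loci),
         gradient_steepness = gradient_steepness,
         sigma = sigma,
         width_multiplier = width_multiplier,
         dispersal_pattern = match.arg(dispersal_pattern),
         dispersal_rate = dispersal_rate,
         tau_mode = match.arg(tau_mode),
         tau_value = tau_value,
         rho = rho,
         synchronized = isTRUE(synchronized),
         life_history = match.arg(life_history),
         generations = as.integer(generations),
         replicates = as.integer(replicates),
         mutation_rate = mutation_rate,
         mutation_sd = mutation_sd,
         base_seed = as.integer(base_seed),
         max_attempts = as.integer(max_attempts),
         record_every = as.integer(record_every)),
    class = "sim_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_demes < 1L) stop("n_demes must be at least 1")
    if (carrying_capacity < 1L) stop("carrying_capacity must be at least 1")
    if (n_det_loci < 1L || n_inst_loci < 1L) stop("locus counts must be >= 1")
    if (gradient_steepness < 0) stop("gradient_steepness must be >= 0")
    if (sigma <= 0) stop("sigma must be positive")
    if (dispersal_rate < 0 || dispersal_rate > 1) {
      stop("dispersal_rate must lie in [0, 1]")
    }
    if (tau_value < 0) stop("tau_value must be >= 0")
    if (abs(rho) >= 1) stop("rho must lie strictly inside (-1, 1)")
    if (generations < 1L) stop("generations must be >= 1")
    if (mutation_rate < 0 || mutation_rate > 1) {
      stop("mutation_rate must lie in [0, 1]")
    }
    if (mutation_sd < 0) stop("mutation_sd must be >= 0")
    if (record_every < 1L) stop("record_every must be >= 1")
    if (dispersal_pattern == "island" && dispersal_rate > 0 && n_demes < 2L) {
      stop("island migration requires at least 2 demes")
    }
    if (dispersal_pattern == "stepping_stone" && dispersal_rate >= 1) {
      stop("stepping-stone dispersal rate must be below 1")
    }
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  demes: ", x$n_demes, " x K = ", x$carrying_capacity,
      ", gradient step ", x$gradient_steepness, "\n", sep = "")
  cat("  loci: ", x$n_det_loci, " deterministic + ", x$n_inst_loci,
      " instability (diploid)\n", sep = "")
  cat("  selection: sigma ", x$sigma, " (survival width ",
      x$sigma * x$width_multiplier, ")\n", sep = "")
  cat("  dispersal: ", x$dispersal_pattern, " at rate ", x$dispersal_rate,
      ", life history ", x$life_history, "\n", sep = "")
  cat("  temporal noise: tau ", x$tau_value, " (", x$tau_mode, "), rho ",
      x$rho, if (x$synchronized) ", synchronized" else "", "\n", sep = "")
  cat("  run: ", x$generations, " generations, ", x$replicates,
      " replicates, mutation ", x$mutation_rate, " / sd ", x$mutation_sd,
      "\n", sep = "")
  invisible(x)
}

# ---- reproduction -----------------------------------------------------------

# Uniform Mendelian transmission for a whole cohort: one allele per locus from
# each parent. `pa`/`pb` are row indices into the parental allele matrix.
make_offspring_alleles <- function(mat, pa, pb) {
  m <- length(pa)
  L <- ncol(mat) %/% 2L
  out <- matrix(0, m, 2L * L)
  for (k in seq_len(L)) {
    c1 <- 2L * k - 1L
    out[, c1] <- mat[cbind(pa, c1 + (stats::runif(m) < 0.5))]
    out[, c1 + 1L] <- mat[cbind(pb, c1 + (stats::runif(m) < 0.5))]
  }
  out
}

# Per-allele mutation over a cohort matrix; instability alleles are floored
# at zero after mutation (infinite-alleles model otherwise).
mutate_alleles <- function(mat, rate, mut_sd, floor_zero = FALSE) {
  if (rate == 0) return(mat)
  hit <- which(stats::runif(length(mat)) < rate)
  if (length(hit)) {
    mat[hit] <- mat[hit] + stats::rnorm(length(hit), 0, mut_sd)
    if (floor_zero) mat[hit] <- pmax(0, mat[hit])
  }
  mat
}

#' Soft-selection reproduction within one deme
#'
#' Mates are drawn uniformly with replacement from the breeding pool
#' (self-fertilization allowed); each pair yields one offspring, repeated
#' until exactly `K` newborns exist — regardless of how many breeders
#' survived selection (soft selection). Offspring are formed by Mendelian
#' inheritance, then mutation, then development. An empty pool yields no
#' newborns and leaves the deme vacant for the generation.
#'
#' @param pool a `"metapopulation"` whose individuals all occupy one deme.
#' @param K carrying capacity (newborn count).
#' @param mutation_rate,mutation_sd per-allele mutation parameters.
#' @return A `"metapopulation"` of `K` developed newborns (0 if the pool is
#'   empty).
#' @export
reproduce_deme <- function(pool, K, mutation_rate = 0.1, mutation_sd = 0.1) {
  stopifnot(inherits(pool, "metapopulation"))
  if (K < 1L) stop("K must be at least 1")
  n <- pop_size(pool)
  if (n == 0L) return(pop_subset(pool, integer(0)))
  if (length(unique(pool$deme)) > 1L) {
    stop("breeding pool must occupy a single deme")
  }
  pa <- floor(stats::runif(K) * n) + 1L
  pb <- floor(stats::runif(K) * n) + 1L
  det <- mutate_alleles(make_offspring_alleles(pool$det, pa, pb),
                        mutation_rate, mutation_sd, FALSE)
  inst <- mutate_alleles(make_offspring_alleles(pool$inst, pa, pb),
                         mutation_rate, mutation_sd, TRUE)
  develop_cohort(det, inst, rep(pool$deme[1L], K), pool$n_demes)
}

# Reproduction across all demes at once. Survivors are grouped by deme;
# every occupied deme is refilled to exactly K newborns, vacant demes stay
# empty this generation (they can be recolonized by dispersal later).
reproduce_all <- function(pop, cfg) {
  counts <- tabulate(pop$deme, pop$n_demes)
  occ <- which(counts > 0L)
  if (!length(occ)) return(pop_subset(pop, integer(0)))
  ord <- order(pop$deme)
  start <- cumsum(c(0L, counts))
  K <- cfg$carrying_capacity
  off_deme <- rep(occ, each = K)
  m <- length(off_deme)
  nd <- counts[off_deme]
  pa <- ord[start[off_deme] + floor(stats::runif(m) * nd) + 1L]
  pb <- ord[start[off_deme] + floor(stats::runif(m) * nd) + 1L]
  det <- mutate_alleles(make_offspring_alleles(pop$det, pa, pb),
                        cfg$mutation_rate, cfg$mutation_sd, FALSE)
  inst <- mutate_alleles(make_offspring_alleles(pop$inst, pa, pb),
                         cfg$mutation_rate, cfg$mutation_sd, TRUE)
  develop_cohort(det, inst, off_deme, pop$n_demes)
}

# ---- generation scheduling --------------------------------------------------

#' Initialize a simulation state
#'
#' Founds the population, draws the initial environment, and caches the
#' selection and dispersal specifications. Randomness comes from R's global
#' RNG stream; seed it (or use [run_replicate()]) for reproducible runs.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `"sim_state"` with fields `pop`, `env`,
#'   `mean_fitness` (of the most recent selection event).
#' @export
init_state <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  structure(
    list(pop = init_population(cfg),
         env = init_environment(cfg),
         sspec = selection_spec(cfg$sigma, cfg$width_multiplier),
         dspec = dispersal_spec(cfg$dispersal_pattern, cfg$dispersal_rate),
         mean_fitness = NA_real_),
    class = "sim_state"
  )
}

#' Advance the simulation by one generation
#'
#' The environment steps once at the start of the generation. The developed
#' cohort then passes through one of two life-history orders —
#' `"move_first"`: dispersal, selection, reproduction; `"select_first"`:
#' selection, dispersal, reproduction — and reproduction yields the next
#' generation's developed newborn cohort (every occupied breeding deme
#' refilled to carrying capacity).
#'
#' @param state a `"sim_state"`.
#' @param cfg the [sim_config()] used to build the state.
#' @return The updated state; `state$mean_fitness` holds the mean survival
#'   probability of the cohort that entered selection.
#' @export
generation_step <- function(state, cfg) {
  stopifnot(inherits(state, "sim_state"))
  env <- advance_environment(state$env)
  pop <- state$pop
  if (cfg$life_history == "move_first") {
    pop <- disperse(pop, state$dspec)
    sel <- apply_selection(pop, env$current, state$sspec)
    surv <- sel$pop
  } else {
    sel <- apply_selection(pop, env$current, state$sspec)
    surv <- disperse(sel$pop, state$dspec)
  }
  state$pop <- reproduce_all(surv, cfg)
  state$env <- env
  state$mean_fitness <- sel$mean_fitness
  state
}

#' Run one replicate
#'
#' Seeds the RNG, founds the metapopulation, and iterates [generation_step()]
#' until the horizon or total extinction (extinction is absorbing: once every
#' deme is empty the run stops and is flagged). Per-generation summary
#' statistics are recorded (thinned by `cfg$record_every`): mean fitness is
#' measured on the cohort entering selection; mean instability, mean
#' phenotype, and local adaptation on the newborn cohort it produced.
#' The same config and seed always reproduce the run bit for bit.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed for this replicate.
#' @return An object of class `"replicate_result"`: `status`
#'   (`"completed"`/`"extinct"`), `records` (a data.frame of per-generation
#'   summary rows: generation, deme, mean_instability, mean_phenotype,
#'   mean_fitness, deme_size, local_adaptation), `final` (metapopulation
#'   snapshot), `env`, `config`, `seed`.
#' @export
run_replicate <- function(cfg, seed = cfg$base_seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  state <- init_state(cfg)
  gens <- cfg$generations
  keep <- seq(cfg$record_every, gens, by = cfg$record_every)
  nrec <- length(keep)
  rec <- list(generation = integer(nrec), size = integer(nrec),
              fitness = rep(NA_real_, nrec), inst = rep(NA_real_, nrec),
              phen = rep(NA_real_, nrec), adapt = rep(NA_real_, nrec))
  baseline <- state$env$baseline
  do_adapt <- cfg$n_demes >= 2L && cfg$gradient_steepness > 0
  i <- 0L
  status <- "completed"
  for (g in seq_len(gens)) {
    state <- generation_step(state, cfg)
    if (i < nrec && g == keep[i + 1L]) {
      i <- i + 1L
      rec$generation[i] <- g
      rec$size[i] <- pop_size(state$pop)
      rec$fitness[i] <- state$mean_fitness
      if (pop_size(state$pop) > 0L) {
        rec$inst[i] <- mean(rowSums(state$pop$inst))
        rec$phen[i] <- mean(state$pop$phenotype)
        if (do_adapt) {
          rec$adapt[i] <- tryCatch(
            local_adaptation_index(state$pop, baseline),
            error = function(e) NA_real_
          )
        }
      }
    }
    if (pop_size(state$pop) == 0L) {
      status <- "extinct"
      break
    }
  }
  if (status == "extinct" && i < nrec) {
    # ensure the terminal (empty) generation is on record
    i <- i + 1L
    rec$generation[i] <- g
    rec$size[i] <- 0L
  }
  records <- data.frame(
    generation = rec$generation[seq_len(i)],
    deme = "all",
    mean_instability = rec$inst[seq_len(i)],
    mean_phenotype = rec$phen[seq_len(i)],
    mean_fitness = rec$fitness[seq_len(i)],
    deme_size = rec$size[seq_len(i)],
    local_adaptation = rec$adapt[seq_len(i)],
    stringsAsFactors = FALSE
  )
  structure(
    list(status = status, records = records, final = state$pop,
         env = state$env, config = cfg, seed = as.integer(seed)),
    class = "replicate_result"
  )
}

#' @export
print.replicate_result <- function(x, ...) {
  cat("<replicate_result> seed ", x$seed, ", ", x$status, " after ",
      max(x$records$generation, 0L), " generations\n", sep = "")
  if (x$status == "completed") {
    eq <- equilibrium_summary(x)
    cat("  equilibrium mean instability ", format(eq$mean_instability, digits = 4),
        ", mean fitness ", format(eq$mean_fitness, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

# Seed policy: replicate attempt `attempt` of cell `cell` runs under
# (base_seed + cell * 10007 + attempt) mod (2^31 - 1).
replicate_seed <- function(base_seed, cell, attempt) {
  as.integer((as.double(base_seed) + as.double(cell) * 10007 + attempt) %%
               (2^31 - 1))
}

#' Run a parameter-sweep experiment
#'
#' Each row of `grid` overrides fields of `base_cfg` and defines one cell.
#' For every cell, replicates are attempted (seed policy:
#' `base_seed + cell * 10007 + attempt`, modulo 2^31-1) until the target
#' number of completed (non-extinct) runs is reached or `max_attempts` total
#' attempts have been made. Equilibrium statistics — means over the final
#' `tail_frac` of recorded generations — are averaged over completed
#' replicates only; a cell with no completion is flagged missing with
#' extinction fraction 1.
#'
#' @param base_cfg a [sim_config()] supplying every non-swept parameter.
#' @param grid data.frame of parameter overrides, one row per cell (may be
#'   `NULL` for a single cell).
#' @param replicates completed replicates required per cell (defaults to
#'   `base_cfg$replicates`).
#' @param base_seed seed anchor (defaults to `base_cfg$base_seed`).
#' @param max_attempts attempt cap per cell.
#' @param tail_frac fraction of the horizon treated as the equilibrium
#'   window.
#' @param verbose print per-cell progress?
#' @return An object of class `"experiment_result"`: `cells` (per-cell
#'   aggregate data.frame), `replicates` (per-completed-replicate equilibrium
#'   statistics), `attempts` (attempt log with extinction outcomes).
#' @export
run_experiment <- function(base_cfg, grid = NULL,
                           replicates = base_cfg$replicates,
                           base_seed = base_cfg$base_seed,
                           max_attempts = base_cfg$max_attempts,
                           tail_frac = 0.1,
                           verbose = FALSE) {
  stopifnot(inherits(base_cfg, "sim_config"))
  if (is.null(grid)) grid <- data.frame(.cell = 1L)[, 0, drop = FALSE]
  n_cells <- max(nrow(grid), 1L)
  rep_rows <- list()
  att_rows <- list()
  cell_rows <- list()
  for (cell in seq_len(n_cells)) {
    cfg <- base_cfg
    if (ncol(grid) > 0L) {
      ov <- unclass(cfg)[setdiff(names(unclass(cfg)), "record_every")]
      for (nm in names(grid)) ov[[nm]] <- grid[[nm]][cell]
      ov$record_every <- cfg$record_every
      cfg <- do.call(sim_config, ov)
    }
    completed <- 0L
    attempt <- 0L
    eqs <- list()
    while (completed < replicates && attempt < max_attempts) {
      attempt <- attempt + 1L
      seed <- replicate_seed(base_seed, cell, attempt)
      res <- run_replicate(cfg, seed)
      att_rows[[length(att_rows) + 1L]] <- data.frame(
        cell = cell, attempt = attempt, seed = seed,
        status = res$status, stringsAsFactors = FALSE
      )
      if (res$status == "completed") {
        completed <- completed + 1L
        eq <- equilibrium_summary(res, tail_frac = tail_frac)
        eqs[[completed]] <- cbind(
          data.frame(cell = cell, replicate = completed, seed = seed),
          eq
        )
      }
    }
    if (verbose) {
      message(sprintf("cell %d/%d: %d completed in %d attempts",
                      cell, n_cells, completed, attempt))
    }
    cell_eq <- if (completed > 0L) do.call(rbind, eqs) else NULL
    if (!is.null(cell_eq)) rep_rows[[length(rep_rows) + 1L]] <- cell_eq
    agg <- if (completed > 0L) {
      aggregate_replicates(cell_eq[, setdiff(names(cell_eq),
                                             c("cell", "replicate", "seed"))])
    } else {
      NULL
    }
    row <- data.frame(cell = cell)
    if (ncol(grid) > 0L) row <- cbind(row, grid[cell, , drop = FALSE])
    row$n_attempts <- attempt
    row$n_completed <- completed
    row$extinction_fraction <- (attempt - completed) / attempt
    row$missing <- completed == 0L
    if (!is.null(agg)) {
      for (j in seq_len(nrow(agg))) {
        st <- agg$statistic[j]
        row[[paste0(st, "_mean")]] <- agg$mean[j]
        row[[paste0(st, "_cv")]] <- agg$cv_percent[j]
      }
    }
    rownames(row) <- NULL
    cell_rows[[cell]] <- row
  }
  cells <- rbind_fill(cell_rows)
  structure(
    list(cells = cells,
         replicates = if (length(rep_rows)) do.call(rbind, rep_rows) else NULL,
         attempts = do.call(rbind, att_rows),
         base_config = base_cfg, grid = grid),
    class = "experiment_result"
  )
}

# rbind data.frames whose columns may differ (missing cells lack stat columns)
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA
    d[, cols, drop = FALSE]
  }))
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", nrow(x$cells), " cell(s), ",
      sum(x$cells$n_completed), " completed replicates\n", sep = "")
  print(x$cells)
  invisible(x)
}
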