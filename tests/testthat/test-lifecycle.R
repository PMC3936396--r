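test_that("soft selection refills a deme to carrying capacity from any pool size", {
  set.seed(51)
  lone <- make_pop(4, 1, 3L, n_demes = 5)
  kids <- reproduce_deme(lone, K = 100, mutation_rate = 0)
  expect_equal(pop_size(kids), 100)
  expect_true(all(kids$deme == 3L))
  # selfing a homozygote with no mutation clones the genotype
  expect_true(all(kids$det == lone$det[rep(1, 100), ]))

  pool50 <- make_pop(rnorm(50), runif(50, 0, 0.2), rep(2L, 50), n_demes = 5)
  expect_equal(pop_size(reproduce_deme(pool50, K = 100)), 100)

  empty <- hedgesim:::pop_subset(pool50, integer(0))
  expect_equal(pop_size(reproduce_deme(empty, K = 100)), 0)
  expect_error(reproduce_deme(pool50, K = 0))
})

test_that("offspring alleles come from the parental pool at every locus", {
  set.seed(52)
  pool <- make_pop(c(-3, 7), c(0.4, 1.2), c(1L, 1L), n_demes = 1)
  kids <- reproduce_deme(pool, K = 500, mutation_rate = 0)
  parental_det <- unique(as.vector(pool$det))
  parental_inst <- unique(as.vector(pool$inst))
  expect_true(all(kids$det %in% parental_det))
  expect_true(all(kids$inst %in% parental_inst))
  expect_true(all(kids$inst >= 0))
})

test_that("a generation step runs the configured life-history order and refills demes", {
  for (lh in c("move_first", "select_first")) {
    cfg <- sim_config(n_demes = 5, carrying_capacity = 40,
                      dispersal_rate = 0.32, life_history = lh,
                      generations = 10)
    set.seed(53)
    st <- init_state(cfg)
    for (i in 1:10) {
      st <- generation_step(st, cfg)
      occ <- tabulate(st$pop$deme, 5)
      expect_true(all(occ %in% c(0L, 40L)))
      expect_lte(pop_size(st$pop), 5 * 40)
      expect_true(st$mean_fitness > 0 && st$mean_fitness <= 1)
    }
    expect_equal(st$env$generation, 10L)
  }
})

test_that("a replicate is bit-for-bit reproducible under its seed", {
  cfg <- sim_config(n_demes = 4, carrying_capacity = 30,
                    dispersal_rate = 0.32, tau_mode = "absolute",
                    tau_value = 1, generations = 120)
  r1 <- run_replicate(cfg, seed = 77)
  r2 <- run_replicate(cfg, seed = 77)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$final, r2$final)
  r3 <- run_replicate(cfg, seed = 78)
  expect_false(identical(r1$records, r3$records))
})

test_that("extinction is absorbing and flagged", {
  # an absurdly large optimum shift wipes out a small deme almost at once
  cfg <- sim_config(n_demes = 1, carrying_capacity = 30,
                    tau_mode = "absolute", tau_value = 200,
                    generations = 400)
  res <- run_replicate(cfg, seed = 54)
  expect_equal(res$status, "extinct")
  expect_equal(pop_size(res$final), 0)
  last <- res$records[nrow(res$records), ]
  expect_equal(last$deme_size, 0L)
  expect_lt(last$generation, 400)
})

test_that("experiments retry extinct attempts and aggregate completed replicates", {
  cfg <- sim_config(n_demes = 2, carrying_capacity = 25,
                    dispersal_rate = 0.32, generations = 60,
                    replicates = 3, max_attempts = 10, base_seed = 5)
  ex <- run_experiment(cfg)
  expect_equal(ex$cells$n_completed, 3)
  expect_equal(ex$cells$extinction_fraction, 0)
  expect_false(ex$cells$missing)
  expect_equal(nrow(ex$replicates), 3)
  expect_true(all(c("mean_instability_mean", "mean_instability_cv") %in%
                    names(ex$cells)))
  # the seed policy makes the whole experiment reproducible
  ex2 <- run_experiment(cfg)
  expect_identical(ex$cells, ex2$cells)

  # a hopeless cell exhausts its attempts and is flagged missing
  doomed <- sim_config(n_demes = 1, carrying_capacity = 20,
                       tau_mode = "absolute", tau_value = 500,
                       generations = 60, replicates = 3, max_attempts = 6,
                       base_seed = 5)
  exd <- run_experiment(doomed)
  expect_equal(exd$cells$n_completed, 0)
  expect_equal(exd$cells$extinction_fraction, 1)
  expect_true(exd$cells$missing)
})

test_that("a grid sweep produces one aggregated row per cell", {
  base <- sim_config(n_demes = 2, carrying_capacity = 20, generations = 40,
                     replicates = 2, max_attempts = 6, base_seed = 3)
  grid <- data.frame(dispersal_rate = c(0, 0.32),
                     life_history = c("move_first", "select_first"),
                     stringsAsFactors = FALSE)
  ex <- run_experiment(base, grid)
  expect_equal(nrow(ex$cells), 2)
  expect_equal(ex$cells$dispersal_rate, c(0, 0.32))
  expect_equal(ex$cells$life_history, c("move_first", "select_first"))
  expect_true(all(ex$cells$n_completed == 2))
})
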