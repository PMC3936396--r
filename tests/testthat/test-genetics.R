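test_that("deterministic trait value is the plain sum of allelic values", {
  expect_equal(deterministic_value(genotype(rep(0, 10), rep(0, 10))), 0)
  expect_equal(deterministic_value(genotype(rep(1, 10), rep(0, 10))), 10)
  # the extreme initial genotype (all alleles at 2) spans the whole gradient
  expect_equal(deterministic_value(genotype(rep(2, 10), rep(0, 10))), 20)
  expect_gte(20, 9.8)
  v <- c(-2, 1, 0, 2, -1, 1, 1, -2, 0, 2)
  expect_equal(deterministic_value(genotype(v, rep(0, 10))), sum(v))
})

test_that("instability sd sums the allelic values and rejects negatives", {
  expect_equal(instability_sd(genotype(rep(0, 10), rep(0, 10))), 0)
  expect_equal(instability_sd(genotype(rep(0, 10), rep(0.1, 10))), 1.0)
  expect_error(genotype(rep(0, 10), c(rep(0, 9), -0.01)), "non-negative")
  g <- genotype(rep(0, 10), rep(0.1, 10))
  g$inst[1] <- -1  # tampering past the constructor still gets caught
  expect_error(instability_sd(g), "non-negative")
})

test_that("development freezes phenotype = deterministic value + Gaussian noise", {
  g0 <- genotype(rep(0, 10), rep(0, 10))
  ind <- develop(g0)
  expect_identical(ind$phenotype, 0)
  expect_identical(ind$noise, 0)
  g10 <- genotype(rep(1, 10), rep(0, 10))
  expect_identical(develop(g10)$phenotype, 10)

  # Monte-Carlo oracle: noise sd must match the summed instability alleles
  g <- genotype(rep(0.5, 10), rep(0.2, 10))  # det sum 5, inst sum 2
  set.seed(42)
  ph <- replicate(2e4, develop(g)$phenotype)
  se_sd <- 2 / sqrt(2 * 2e4)
  expect_lt(abs(sd(ph) - 2), 3 * se_sd)
  expect_lt(abs(mean(ph) - 5), 3 * 2 / sqrt(2e4))

  # engine path draws from the same law
  set.seed(43)
  pop <- make_pop(rep(5, 1e5), rep(2, 1e5), rep(1L, 1e5))
  expect_lt(abs(sd(pop$noise) - 2), 3 * 2 / sqrt(2 * 1e5))
  expect_equal(pop$phenotype, 5 + pop$noise)
})

test_that("inheritance is fair Mendelian transmission with free recombination", {
  set.seed(7)
  hom <- genotype(rep(3, 10), rep(0.2, 10))
  off <- inherit(hom, hom)
  expect_identical(off$det, hom$det)
  expect_identical(off$inst, hom$inst)

  a <- genotype(rep(1, 10), rep(0.1, 10))
  b <- genotype(rep(5, 10), rep(0.4, 10))
  off <- inherit(a, b)
  for (k in 1:5) {
    expect_setequal(off$det[c(2 * k - 1, 2 * k)], c(1, 5))
    expect_setequal(off$inst[c(2 * k - 1, 2 * k)], c(0.1, 0.4))
  }
  expect_length(off$det, 10)

  # heterozygous parent transmits each allele with probability 1/2
  het <- genotype(c(10, 20, rep(0, 8)), rep(0, 10))
  set.seed(8)
  sent <- replicate(1e4, inherit(het, hom)$det[1])
  n10 <- sum(sent == 10)
  expect_true(all(sent %in% c(10, 20)))
  expect_gt(stats::binom.test(n10, 1e4, 0.5)$p.value, 0.001)
})

test_that("mutation hits each allele at the nominal rate and floors instability at zero", {
  g <- genotype(rep(1, 10), rep(5, 10))
  expect_identical(mutate_genotype(g, rate = 0), g)

  # realized per-allele mutation fraction matches the rate (binomial oracle)
  set.seed(9)
  big <- genotype(rep(0, 1e5), rep(5, 1e5))
  mut <- mutate_genotype(big, rate = 0.1, mut_sd = 0.1)
  frac <- mean(mut$det != big$det)
  se <- sqrt(0.1 * 0.9 / 1e5)
  expect_lt(abs(frac - 0.1), 3 * se)

  # instability alleles near zero with large downward deviates get floored
  set.seed(10)
  small <- genotype(rep(0, 1000), rep(0.05, 1000))
  out <- mutate_genotype(small, rate = 1, mut_sd = 10)
  expect_true(all(out$inst >= 0))
  expect_true(any(out$inst == 0))   # many deviates were below -0.05
  expect_false(any(is.na(out$det)))
})

test_that("founding populations have the stated size and allele distribution", {
  cfg <- sim_config(n_demes = 50, carrying_capacity = 100)
  set.seed(11)
  pop <- init_population(cfg)
  expect_equal(pop_size(pop), 5000)
  expect_equal(tabulate(pop$deme, 50), rep(100L, 50))

  cfg1 <- sim_config(n_demes = 1, carrying_capacity = 1000)
  expect_equal(pop_size(init_population(cfg1)), 1000)

  # founder alleles: discrete uniform on {-2,...,2} has mean 0, variance 2
  set.seed(12)
  big <- init_population(sim_config(n_demes = 100, carrying_capacity = 100))
  al <- as.vector(big$det)[seq_len(1e5)]
  expect_true(all(al %in% c(-2, -1, 0, 1, 2)))
  expect_lt(abs(mean(al)), 3 * sqrt(2 / 1e5))
  expect_lt(abs(var(al) - 2), 3 * sqrt(2.8 / 1e5))
  expect_true(all(big$inst == 0))
  expect_equal(big$phenotype, rowSums(big$det))
})

test_that("instability alleles stay non-negative through any operation sequence", {
  set.seed(13)
  g <- genotype(rep(0, 10), rep(0, 10))
  h <- genotype(sample(-2:2, 10, TRUE), runif(10, 0, 0.3))
  for (i in 1:200) {
    g <- mutate_genotype(inherit(g, h), rate = 0.5, mut_sd = 0.5)
    expect_true(all(g$inst >= 0))
    h <- mutate_genotype(h, rate = 0.5, mut_sd = 0.5)
  }
})

test_that("inheritance and development are reproducible under a fixed seed", {
  a <- genotype(runif(10, -2, 2), runif(10, 0, 0.5))
  b <- genotype(runif(10, -2, 2), runif(10, 0, 0.5))
  set.seed(99)
  o1 <- develop(mutate_genotype(inherit(a, b), rate = 0.1))
  set.seed(99)
  o2 <- develop(mutate_genotype(inherit(a, b), rate = 0.1))
  expect_identical(o1, o2)
})
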