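# Synthetic climate pairs and virtual species.

test_that("zero shift and zero noise reproduce period 1 exactly", {
  cfg <- synthetic_climate_config(20, 20, 3, shift = 0, noise_sd = 0, seed = 2)
  pair <- generate_climate_pair(cfg)
  expect_identical(pair$T1$variables, setNames(pair$T2$variables,
                                               names(pair$T1$variables)))
  expect_equal(pair$T1$period, "T1")
  expect_equal(pair$T2$period, "T2")
})

test_that("generation is reproducible and rejects bad configs", {
  cfg <- synthetic_climate_config(15, 15, 2, shift = 1, noise_sd = 0.2, seed = 9)
  expect_identical(generate_climate_pair(cfg), generate_climate_pair(cfg))
  expect_error(synthetic_climate_config(0, 10), "positive")
  expect_error(synthetic_climate_config(variable_correlation = 1), "correlation")
})

test_that("the configured shift moves the period-2 mean by the right amount", {
  cfg <- synthetic_climate_config(200, 200, 2, shift = c(2, 0), noise_sd = 0,
                                  seed = 4)
  pair <- generate_climate_pair(cfg)
  d1 <- mean(pair$T2$variables[[1]]) - mean(pair$T1$variables[[1]])
  expect_equal(d1, 2 * sd(pair$T1$variables[[1]]), tolerance = 0.05)
  expect_equal(mean(pair$T2$variables[[2]]), mean(pair$T1$variables[[2]]),
               tolerance = 1e-12)
})

test_that("variables are inter-correlated at the configured level", {
  cfg <- synthetic_climate_config(150, 150, 3, variable_correlation = 0.6,
                                  seed = 1)
  pair <- generate_climate_pair(cfg)
  v <- sapply(pair$T1$variables, as.vector)
  cm <- cor(v)
  off <- cm[upper.tri(cm)]
  expect_true(all(off > 0.3 & off < 0.85))
})

test_that("true suitability has its closed forms", {
  sp <- virtual_species(mu = c(0, 1), sigma = c(1, 2))
  suit <- function(x) retroniche:::true_suitability(sp, matrix(x, 1))
  expect_equal(suit(c(0, 1)), 1)
  expect_equal(suit(c(1, 1)), exp(-0.5))
  expect_lt(suit(c(10, 1)), 1e-20)
  expect_error(virtual_species(mu = c(0, 0), sigma = c(1, -1)), "positive")
  expect_error(virtual_species(mu = c(0, 0), sigma = c(1)), "lengths")

  box <- virtual_species(mu = c(0, 0), sigma = c(1, 1), shape = "box")
  bs <- function(x) retroniche:::true_suitability(box, matrix(x, 1))
  expect_equal(bs(c(0.99, -0.99)), 1)
  expect_equal(bs(c(1.01, 0)), 0)
})

test_that("suitability maps put the maximum at the niche centre", {
  cfg <- synthetic_climate_config(30, 30, 2, seed = 6)
  pair <- generate_climate_pair(cfg)
  sp <- virtual_species(mu = c(0, 0), sigma = c(0.5, 0.5))
  m <- virtual_species_suitability(sp, pair$T1)
  expect_true(all(m$grid >= 0 & m$grid <= 1, na.rm = TRUE))
  sp3 <- virtual_species(mu = rep(0, 3), sigma = rep(1, 3))
  expect_error(virtual_species_suitability(sp3, pair$T1), "fewer variables")
})

test_that("occurrence sampling concentrates in high-suitability patches", {
  # one high patch vs low background, ratio >= 100:1
  high <- matrix(0.005, 30, 30)
  high[8:17, 8:17] <- 1
  s <- env_stack(list(w = high), "T1")
  sp_flat <- virtual_species(mu = 0, sigma = 1e6)   # uniform true suitability
  inside <- replicate(60, {
    occ <- sample_virtual_occurrences(sp_flat, s, 25, bias_map = high,
                                      seed = sample.int(1e6, 1))
    mean(high[cbind(occ$records$row, occ$records$col)] == 1)
  })
  expect_gte(mean(inside), 0.9)
})

test_that("uniform weights give uniform cell frequencies", {
  s <- env_stack(list(w = matrix(1, 10, 10)), "T1")
  sp_flat <- virtual_species(mu = 0, sigma = 1e6)
  counts <- integer(100)
  set.seed(77)
  for (i in 1:2000) {
    occ <- sample_virtual_occurrences(sp_flat, s, 10, seed = i)
    counts[occ$records$cell] <- counts[occ$records$cell] + 1L
  }
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("degenerate sampling weights are rejected", {
  s <- env_stack(list(w = matrix(0, 5, 5)), "T1")
  sp <- virtual_species(mu = 50, sigma = 1e-4)   # suitability underflows to 0
  expect_error(sample_virtual_occurrences(sp, s, 3, seed = 1), "zero")
  s2 <- env_stack(list(w = matrix(c(1, rep(0, 24)), 5, 5)), "T1")
  sp2 <- virtual_species(mu = 1, sigma = 1e-3)
  expect_error(sample_virtual_occurrences(sp2, s2, 5, seed = 1), "capacity")
})

test_that("sampling is seed-reproducible and duplicate-free", {
  cfg <- synthetic_climate_config(25, 25, 2, seed = 8)
  pair <- generate_climate_pair(cfg)
  sp <- virtual_species(mu = c(0, 0), sigma = c(1, 1))
  o1 <- sample_virtual_occurrences(sp, pair$T1, 40, seed = 5)
  o2 <- sample_virtual_occurrences(sp, pair$T1, 40, seed = 5)
  expect_identical(o1$records, o2$records)
  expect_equal(anyDuplicated(o1$records$cell), 0)
})

test_that("the synthetic compilation reproduces the published margins", {
  cfg <- synthetic_climate_config(40, 40, 2, seed = 1)
  stack <- generate_climate_pair(cfg)$T1
  tab <- synthetic_supp_occurrences(stack, seed = 3)
  out <- load_and_deduplicate(tab, stack)
  rep_ <- classify_species_sufficiency(out$sets)
  expect_equal(nrow(rep_), 117)
  tallied <- table(rep_$status)
  expect_equal(unname(tallied["sufficient"]), 44L)
  expect_equal(unname(tallied["underrepresented_one_period"]), 14L)
  expect_equal(unname(tallied["insufficient_both"]), 59L)
  expect_equal(max(rep_$n_T1 + rep_$n_T2), 504)
  expect_gt(unname(out$dropped["duplicate"]), 0)
  expect_gt(unname(out$dropped["off_grid"]), 0)
})
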