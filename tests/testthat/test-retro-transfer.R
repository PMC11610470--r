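# The auto/cross quadruple, the 70% control gate, transfer evaluation and
# the run_all orchestration. Bioclim and GLM carry most cases: they are
# cheap and deterministic, and the algorithm-facing contracts are shared.

test_that("full-identity construction gives pair similarities of exactly 1", {
  w <- toy_world(n = 30)
  stacks <- list(T1 = w$pair$T1, T2 = w$pair$T1)     # identical climates
  occ2 <- w$occ_T1; occ2$period <- "T2"              # identical occurrences
  for (alg in c("bioclim", "glm")) {
    q <- build_quadruple(w$occ_T1, occ2, stacks, w$area,
                         model_spec(alg), seed = 5)
    expect_equal(q$similarity_pair1, 1.0)
    expect_equal(q$similarity_pair2, 1.0)
    expect_equal(control_gate(q)$status, "control")
  }
})

test_that("independent same-size samples on identical climates pass the gate", {
  w <- toy_world(n = 100)
  stacks <- list(T1 = w$pair$T1, T2 = w$pair$T1)
  occ2 <- sample_virtual_occurrences(w$species, w$pair$T1, 100, seed = 999)
  occ2$period <- "T2"
  q <- build_quadruple(w$occ_T1, occ2, stacks, w$area, model_spec("bioclim"),
                       seed = 5)
  expect_gte(q$similarity_pair1, 0.70)
  expect_gte(q$similarity_pair2, 0.70)
})

test_that("the gate applies the minimum rule with an inclusive boundary", {
  mk <- function(s1, s2) structure(list(similarity_pair1 = s1,
                                        similarity_pair2 = s2,
                                        species = "v", algorithm = "glm"),
                                   class = "quadruple_result")
  expect_equal(control_gate(mk(1.0, 1.0))$status, "control")
  expect_equal(control_gate(mk(0.95, 0.69))$status, "without_control")
  expect_equal(control_gate(mk(0.70, 0.70))$status, "control")
  # monotonicity: lowering the threshold never removes control status
  sims <- cbind(runif(20), runif(20))
  for (i in seq_len(nrow(sims))) {
    hi <- control_gate(mk(sims[i, 1], sims[i, 2]), threshold = 0.8)$status
    lo <- control_gate(mk(sims[i, 1], sims[i, 2]), threshold = 0.5)$status
    expect_false(hi == "control" && lo == "without_control")
  }
})

test_that("missing-period data is a precondition error", {
  w <- toy_world(n = 30)
  stacks <- list(T1 = w$pair$T1, T2 = w$pair$T2)
  expect_error(build_quadruple(w$occ_T1, NULL, stacks, w$area,
                               model_spec("glm"), 1), "precondition")
  few <- w$occ_T2
  few$records <- few$records[1:5, ]
  expect_error(build_quadruple(w$occ_T1, few, stacks, w$area,
                               model_spec("glm"), 1), "precondition")
})

test_that("a failed gate refuses the transfer with a status echo", {
  w <- toy_world(n = 30)
  ctrl <- structure(list(species = "v", algorithm = "glm",
                         status = "without_control", gate_similarity = 0.61,
                         threshold = 0.7), class = "control_status")
  expect_error(run_transfer_experiment(w$occ_T1, w$occ_T2,
                                       list(T1 = w$pair$T1, T2 = w$pair$T2),
                                       w$area, model_spec("glm"),
                                       "forecast", 1, control = ctrl),
               "refused.*without_control")
})

test_that("swapping period labels mirrors forecast and hindcast exactly", {
  w <- toy_world(n = 60)
  stacks <- list(T1 = w$pair$T1, T2 = w$pair$T2)
  swapped <- list(T1 = w$pair$T2, T2 = w$pair$T1)
  for (alg in c("bioclim", "rf")) {
    spec <- model_spec(alg)
    ctrl <- structure(list(species = "virtual", algorithm = alg,
                           status = "control", gate_similarity = 1,
                           threshold = 0.7), class = "control_status")
    fore <- run_transfer_experiment(w$occ_T1, w$occ_T2, stacks, w$area, spec,
                                    "forecast", seed = 3, control = ctrl)
    hind_sw <- run_transfer_experiment(w$occ_T2, w$occ_T1, swapped, w$area,
                                       spec, "hindcast", seed = 3,
                                       control = ctrl)
    expect_equal(fore$metrics, hind_sw$metrics)
    expect_equal(fore$counts, hind_sw$counts)
  }
})

test_that("transfer recovers the niche when climates are identical", {
  w <- toy_world(nrow = 40, ncol = 40, n = 200)
  stacks <- list(T1 = w$pair$T1, T2 = w$pair$T1)
  occ2 <- sample_virtual_occurrences(w$species, w$pair$T1, 200, seed = 321)
  occ2$period <- "T2"
  tr <- run_transfer_experiment(w$occ_T1, occ2, stacks, w$area,
                                model_spec("bioclim"), "forecast", seed = 2)
  expect_gte(tr$metrics$tss, 0.7)
  expect_lt(tr$validation$p_value, 0.05)
})

test_that("transfer TSS degrades on average as the climate shift grows", {
  mean_tss <- function(shift) {
    vals <- vapply(1:8, function(seed) {
      w <- toy_world(nrow = 30, ncol = 30, n = 60, shift = shift, seed = seed)
      stacks <- list(T1 = w$pair$T1, T2 = w$pair$T2)
      ctrl <- structure(list(species = "virtual", algorithm = "bioclim",
                             status = "control", gate_similarity = 1,
                             threshold = 0.7), class = "control_status")
      run_transfer_experiment(w$occ_T1, w$occ_T2, stacks, w$area,
                              model_spec("bioclim"), "forecast", seed = 1,
                              control = ctrl)$metrics$tss
    }, numeric(1))
    mean(vals)
  }
  t0 <- mean_tss(0); t2 <- mean_tss(2); t4 <- mean_tss(4)
  expect_gt(t0, t2)
  expect_gt(t2, t4)
})

test_that("run_all books results per species, algorithm and direction", {
  w1 <- toy_world(n = 60, seed = 5)
  w2 <- toy_world(n = 60, seed = 6)
  stacks <- list(T1 = w1$pair$T1, T2 = w1$pair$T2)
  sp_data <- list(
    sp_a = list(occ_T1 = w1$occ_T1, occ_T2 = w1$occ_T2),
    sp_b = list(occ_T1 = w2$occ_T1, occ_T2 = w2$occ_T2),
    sp_thin = list(occ_T1 = occ_at_cells(w1$pair$T1, 1:5),
                   occ_T2 = occ_at_cells(w1$pair$T1, 1:12, period = "T2")))
  res <- run_all(sp_data, stacks, algorithms = c("bioclim", "glm"), seed = 4)
  expect_equal(nrow(res$sufficiency), 3)
  expect_equal(res$sufficiency$status[res$sufficiency$species == "sp_thin"],
               "underrepresented_one_period")
  # 2 sufficient species x 2 algorithms x 2 directions
  expect_equal(nrow(res$control_status), 8)
  n_control <- sum(res$control_status$status == "control")
  expect_equal(nrow(res$metrics), n_control)
  expect_false(any(res$metrics$species == "sp_thin"))
  # deterministic rerun
  res2 <- run_all(sp_data, stacks, algorithms = c("bioclim", "glm"), seed = 4)
  expect_identical(res, res2)
})
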