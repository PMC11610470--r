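# retro_transfer module: the retrospective cross-temporal procedure — the
# auto/cross model quadruple, the 70% map-similarity control gate, and
# forecast/hindcast transfer evaluation.
#
# Seeding is content-based: every stochastic step of a model build derives
# its seed from (experiment seed, species, algorithm, the occurrence cells
# used), never from period labels or role names. Identical inputs therefore
# give bit-identical models (so the full-identity quadruple has pair
# similarities of exactly 1), and swapping period labels on identical inputs
# makes forecast and hindcast exactly mirror each other.

occ_tag <- function(occ) paste(occ$records$cell, collapse = ",")

# Fit one model on (occurrences x environment), binarize at its own
# ten-percentile threshold. Returns model, threshold, binary map and the
# calibration/validation partitions.
fit_binary_model <- function(occ, env, area, spec, seed) {
  base <- derive_seed(seed, occ$species, spec$algorithm, occ_tag(occ))
  pseudo <- generate_pseudoabsences(occ, area, derive_seed(base, "pa"), env)
  part_p <- partition_calibration_validation(occ, 0.7, derive_seed(base, "sp"))
  part_a <- partition_calibration_validation(pseudo, 0.7, derive_seed(base, "sa"))
  pres_vals <- cell_values(env, part_p$calibration$records$cell)
  abs_vals <- cell_values(env, part_a$calibration$records$cell)
  mspec <- model_spec(spec$algorithm, spec$hyperparameters,
                      seed = derive_seed(base, "fit"))
  model <- fit_enm(mspec, pres_vals, abs_vals)
  # suitability at the calibration presences, for the ten-percentile
  # threshold; for RF the out-of-bag votes replace resubstitution votes
  # (training points are memorized by the trees, which would push the
  # threshold far above the honest vote level of suitable cells)
  pres_suit <- attr(model$fit, "oob_presence") %||%
    predict_values(model, pres_vals)
  thr <- ten_percentile_threshold(pres_suit)
  suit <- predict_enm(model, env, area)
  list(model = model, threshold = thr, suitability = suit,
       binary = binarize(suit, thr),
       presences = part_p, pseudoabsences = part_a)
}

#' Build the auto/cross model quadruple for one species and algorithm
#'
#' Fits the four models of the cross-temporal scheme — auto1 (occurrences T1
#' x environment T1), cross1 (occ T2 x env T1), auto2 (occ T2 x env T2),
#' cross2 (occ T1 x env T2) — each binarized at its own ten-percentile
#' threshold, and computes the two pair similarities (auto1 vs cross1,
#' auto2 vs cross2) used by the control gate.
#'
#' @param occ_T1,occ_T2 `occurrence_set`s for the two periods.
#' @param stacks list with `env_stack`s `T1` and `T2` (shared geometry).
#' @param area the species' `accessible_area`.
#' @param spec a [model_spec()].
#' @param seed experiment seed.
#' @param min_records minimum unique localities per period (default 10).
#' @return object of class `quadruple_result`: the four `binary_map`s plus
#'   `similarity_pair1`, `similarity_pair2`.
#' @export
build_quadruple <- function(occ_T1, occ_T2, stacks, area, spec, seed,
                            min_records = 10) {
  if (is.null(occ_T1) || is.null(occ_T2) ||
      nrow(occ_T1$records) < min_records || nrow(occ_T2$records) < min_records)
    stop_arg("precondition error: both periods need at least ", min_records,
             " unique localities")
  if (!same_geometry(stacks$T1, stacks$T2))
    stop_arg("alignment error: period stacks differ in geometry")
  auto1 <- fit_binary_model(occ_T1, stacks$T1, area, spec, seed)
  cross1 <- fit_binary_model(occ_T2, stacks$T1, area, spec, seed)
  auto2 <- fit_binary_model(occ_T2, stacks$T2, area, spec, seed)
  cross2 <- fit_binary_model(occ_T1, stacks$T2, area, spec, seed)
  # simple agreement; computed directly so the gate also handles saturated
  # maps (all-presence or all-absence), which the full index set rejects
  sim <- function(a, b) {
    cc <- confusion_counts(a$binary, b$binary, area)
    (cc$a + cc$d) / (cc$a + cc$b + cc$c + cc$d)
  }
  structure(list(auto1 = auto1$binary, cross1 = cross1$binary,
                 auto2 = auto2$binary, cross2 = cross2$binary,
                 similarity_pair1 = sim(auto1, cross1),
                 similarity_pair2 = sim(auto2, cross2),
                 species = occ_T1$species, algorithm = spec$algorithm),
            class = "quadruple_result")
}

#' Apply the control gate to a quadruple
#'
#' A species/algorithm combination is a "control" case when both pair
#' similarities reach the gate threshold (the conservative minimum rule):
#' its occurrence data structure is comparable across periods, so transfer
#' failures can be attributed to the algorithm rather than the data.
#'
#' @param quad a `quadruple_result`.
#' @param threshold gate threshold (default 0.70); the boundary is inclusive.
#' @return object of class `control_status` with `status` (`"control"` /
#'   `"without_control"`) and `gate_similarity` (the minimum pair
#'   similarity).
#' @export
control_gate <- function(quad, threshold = 0.70) {
  g <- min(quad$similarity_pair1, quad$similarity_pair2)
  structure(list(species = quad$species, algorithm = quad$algorithm,
                 status = if (g >= threshold) "control" else "without_control",
                 gate_similarity = g, threshold = threshold),
            class = "control_status")
}

#' Run one forecast or hindcast transfer experiment
#'
#' Forecast: the model calibrated on (occurrences T1 x environment T1) is
#' projected onto environment T2, binarized at its calibration-period
#' ten-percentile threshold (no re-thresholding in the target period), and
#' compared pixel-by-pixel against the auto model of the target period
#' (auto2) as reference. Hindcast mirrors the construction with the periods
#' swapped. The calibration-period model is additionally validated with an
#' exact binomial test on its held-out 30% presences.
#'
#' @param occ_T1,occ_T2 `occurrence_set`s for the two periods.
#' @param stacks list with `env_stack`s `T1` and `T2`.
#' @param area the species' `accessible_area`.
#' @param spec a [model_spec()].
#' @param direction `"forecast"` (T1 to T2) or `"hindcast"` (T2 to T1).
#' @param seed experiment seed.
#' @param control optional precomputed `control_status`; when `NULL` the
#'   quadruple and gate are evaluated first. A gate failure is a refusal
#'   echoing the status.
#' @param gate_threshold control-gate threshold (default 0.70).
#' @return object of class `transfer_result`: `metrics`
#'   (`transfer_metrics`), `counts`, `validation` (`binomial_validation` of
#'   the calibration model), `n_records_T1`, `n_records_T2`, `direction`.
#' @export
run_transfer_experiment <- function(occ_T1, occ_T2, stacks, area, spec,
                                    direction = c("forecast", "hindcast"),
                                    seed = 1L, control = NULL,
                                    gate_threshold = 0.70) {
  direction <- match.arg(direction)
  if (is.null(control)) {
    quad <- build_quadruple(occ_T1, occ_T2, stacks, area, spec, seed)
    control <- control_gate(quad, gate_threshold)
  }
  if (control$status != "control")
    stop_arg("refused: control gate not passed (status ", control$status,
             ", gate similarity ", signif(control$gate_similarity, 4), ")")
  if (direction == "forecast") {
    occ_cal <- occ_T1; env_cal <- stacks$T1; env_tgt <- stacks$T2; occ_tgt <- occ_T2
  } else {
    occ_cal <- occ_T2; env_cal <- stacks$T2; env_tgt <- stacks$T1; occ_tgt <- occ_T1
  }
  cal <- fit_binary_model(occ_cal, env_cal, area, spec, seed)
  ref <- fit_binary_model(occ_tgt, env_tgt, area, spec, seed)
  transferred <- binarize(predict_enm(cal$model, env_tgt, area), cal$threshold)
  counts <- confusion_counts(ref$binary, transferred, area)
  metrics <- transfer_metrics(counts)
  validation <- binomial_validation(cal$binary, cal$presences$validation, area)
  structure(list(species = occ_T1$species, algorithm = spec$algorithm,
                 direction = direction, metrics = metrics, counts = counts,
                 validation = validation,
                 n_records_T1 = nrow(occ_T1$records),
                 n_records_T2 = nrow(occ_T2$records),
                 control = control),
            class = "transfer_result")
}

#' Run the full experiment over species, algorithms and directions
#'
#' For every species passing the sufficiency rule and every algorithm, the
#' quadruple and gate are evaluated once; for every control case both
#' requested transfer directions are run. Per-species failures are recorded
#' in `failures` and do not abort the run. Results are independent of
#' iteration order (content-based seeding).
#'
#' @param species_data named list; each element a list with `occ_T1`,
#'   `occ_T2` (`occurrence_set` or `NULL`) and optionally `area`.
#' @param stacks list with `env_stack`s `T1` and `T2`.
#' @param algorithms character vector of algorithm names.
#' @param area default `accessible_area` for species without their own.
#' @param directions subset of `c("forecast", "hindcast")`.
#' @param seed experiment seed.
#' @param min_records sufficiency minimum (default 10).
#' @param gate_threshold control-gate threshold (default 0.70).
#' @param hyperparameters named list (by algorithm) of hyperparameter
#'   overrides.
#' @return list of data.frames: `sufficiency`, `control_status`, `metrics`,
#'   `failures`.
#' @export
run_all <- function(species_data, stacks, algorithms, area = NULL,
                    directions = c("forecast", "hindcast"), seed = 1L,
                    min_records = 10, gate_threshold = 0.70,
                    hyperparameters = list()) {
  suff <- do.call(rbind, lapply(names(species_data), function(sp) {
    d <- species_data[[sp]]
    data.frame(species = sp,
               n_T1 = if (is.null(d$occ_T1)) 0L else nrow(d$occ_T1$records),
               n_T2 = if (is.null(d$occ_T2)) 0L else nrow(d$occ_T2$records))
  }))
  sufficiency <- classify_species_sufficiency(suff, minimum = min_records)
  control_rows <- list(); metric_rows <- list(); failure_rows <- list()
  for (sp in names(species_data)) {
    if (sufficiency$status[sufficiency$species == sp] != "sufficient") next
    d <- species_data[[sp]]
    sp_area <- d$area %||% area %||% full_area(stacks$T1)
    for (alg in algorithms) {
      spec <- model_spec(alg, hyperparameters[[alg]] %||% list())
      res <- tryCatch({
        quad <- build_quadruple(d$occ_T1, d$occ_T2, stacks, sp_area, spec,
                                seed, min_records)
        ctrl <- control_gate(quad, gate_threshold)
        for (dir in directions) {
          control_rows[[length(control_rows) + 1L]] <- data.frame(
            species = sp, algorithm = alg, direction = dir,
            status = ctrl$status, gate_similarity = ctrl$gate_similarity)
          if (ctrl$status == "control") {
            tr <- run_transfer_experiment(d$occ_T1, d$occ_T2, stacks, sp_area,
                                          spec, dir, seed, control = ctrl)
            m <- tr$metrics
            metric_rows[[length(metric_rows) + 1L]] <- data.frame(
              species = sp, algorithm = alg, direction = dir,
              a = tr$counts$a, b = tr$counts$b, c = tr$counts$c,
              d = tr$counts$d, tss = m$tss, oi = m$oi,
              eq3_rate = m$eq3_rate, eq4_rate = m$eq4_rate,
              similarity = m$similarity, p_value = tr$validation$p_value,
              n_records_T1 = tr$n_records_T1, n_records_T2 = tr$n_records_T2)
          }
        }
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res))
        failure_rows[[length(failure_rows) + 1L]] <- data.frame(
          species = sp, algorithm = alg, error = res)
    }
  }
  bind <- function(rows, proto) if (length(rows)) do.call(rbind, rows) else proto
  list(sufficiency = sufficiency,
       control_status = bind(control_rows,
         data.frame(species = character(), algorithm = character(),
                    direction = character(), status = character(),
                    gate_similarity = numeric())),
       metrics = bind(metric_rows,
         data.frame(species = character(), algorithm = character(),
                    direction = character(), a = integer(), b = integer(),
                    c = integer(), d = integer(), tss = numeric(),
                    oi = numeric(), eq3_rate = numeric(), eq4_rate = numeric(),
                    similarity = numeric(), p_value = numeric(),
                    n_records_T1 = integer(), n_records_T2 = integer())),
       failures = bind(failure_rows,
         data.frame(species = character(), algorithm = character(),
                    error = character())))
}
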