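# niche_models module: uniform fit/project interface over the seven
# algorithms. Bioclim is native (bioclim.R); the Maxent-style penalized
# logistic is in maxent_like.R; GLM performs the quadratic-term stepwise-AIC
# procedure; GAM/BRT/RF/SVM delegate to established estimators configured
# with the study defaults.

ALGORITHMS <- c("bioclim", "glm", "gam", "brt", "maxent", "rf", "svm")

#' Build a model specification
#'
#' Hyperparameter defaults follow the study protocol: BRT with learning rate
#' 0.005, tree complexity (max depth) 5 and bag fraction 0.5; RF with 500
#' trees; GLM binomial/logit with quadratic terms and stepwise AIC selection;
#' Maxent-style models tuned over regularization multipliers
#' \{0.5, 1, 1.5, 2\} crossed with the nested feature ladder L, LQ, LQP,
#' LQPT, LQPTH and selected by AICc.
#'
#' @param algorithm one of `"bioclim"`, `"glm"`, `"gam"`, `"brt"`,
#'   `"maxent"`, `"rf"`, `"svm"`.
#' @param hyperparameters named list overriding algorithm defaults.
#' @param seed integer seed for stochastic learners.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(algorithm, hyperparameters = list(), seed = 1L) {
  if (!is.character(algorithm) || length(algorithm) != 1L ||
      !(algorithm %in% ALGORITHMS))
    stop_arg("unknown algorithm: ", paste(algorithm, collapse = ", "),
             " (expected one of ", paste(ALGORITHMS, collapse = ", "), ")")
  defaults <- switch(algorithm,
    bioclim = list(),
    glm = list(stepwise = TRUE),
    gam = list(k = NULL),                       # basis dim: library default,
                                                # shrunk only if data demand it
    brt = list(learning_rate = 0.005, tree_complexity = 5,
               bag_fraction = 0.5, n_trees = 1000),
    maxent = list(rm_grid = c(0.5, 1, 1.5, 2),
                  feature_ladder = list("l", c("l", "q"), c("l", "q", "p"),
                                        c("l", "q", "p", "t"),
                                        c("l", "q", "p", "t", "h")),
                  n_knots = 5),
    rf = list(n_trees = 500),
    svm = list(kernel = "radial", cost = 1))
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown))
    stop_arg("unknown hyperparameter(s) for ", algorithm, ": ",
             paste(unknown, collapse = ", "))
  hp <- defaults
  hp[names(hyperparameters)] <- hyperparameters  # whole-value replacement
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit a niche model under a uniform interface
#'
#' Presence-only (bioclim) and presence/background (maxent) algorithms accept
#' `absence_values` as optional background; the presence-absence algorithms
#' (glm, gam, brt, rf, svm) require both classes.
#'
#' @param spec a [model_spec()].
#' @param presence_values data.frame/matrix of variable values at presence
#'   records.
#' @param absence_values data.frame/matrix of variable values at
#'   pseudoabsence (or background) records.
#' @return object of class `enm_model` with a [predict_enm()] /
#'   [predict_values()] interface.
#' @export
fit_enm <- function(spec, presence_values, absence_values = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  pv <- as.matrix(presence_values)
  vars <- colnames(pv)
  if (is.null(vars)) stop_arg("presence values must have variable names")
  alg <- spec$algorithm
  if (alg == "bioclim") {
    fit <- fit_bioclim(pv)
  } else {
    if (is.null(absence_values))
      stop_arg(alg, " requires absence/background values")
    av <- as.matrix(absence_values)[, vars, drop = FALSE]
    if (nrow(av) == 0L)
      stop_arg("single-class input: ", alg, " needs both classes")
    x <- rbind(pv, av)
    y <- c(rep(1L, nrow(pv)), rep(0L, nrow(av)))
    fit <- switch(alg,
      glm = fit_glm_quadratic(x, y, spec),
      gam = fit_gam_adapter(x, y, spec),
      brt = fit_brt_adapter(x, y, spec),
      rf = fit_rf_adapter(x, y, spec),
      svm = fit_svm_adapter(x, y, spec),
      maxent = fit_maxent_like(pv, av, spec))
  }
  structure(list(algorithm = alg, spec = spec, fit = fit, variables = vars),
            class = "enm_model")
}

#' Predict suitability for a matrix of variable values
#'
#' @param model an `enm_model`.
#' @param values data.frame/matrix (rows = points, columns = variables).
#' @return numeric vector of suitabilities in \[0, 1\].
#' @export
predict_values <- function(model, values) {
  values <- as.matrix(values)
  miss <- setdiff(model$variables, colnames(values))
  if (length(miss))
    stop_arg("missing variable(s): ", paste(miss, collapse = ", "))
  x <- values[, model$variables, drop = FALSE]
  p <- switch(model$algorithm,
    bioclim = bioclim_suitability(model$fit, x),
    glm = as.numeric(stats::predict(model$fit, newdata = as.data.frame(x),
                                    type = "response")),
    gam = as.numeric(mgcv::predict.gam(model$fit, newdata = as.data.frame(x),
                                       type = "response")),
    brt = stats::predict(model$fit,
                         xgboost::xgb.DMatrix(x)),
    rf = stats::predict(model$fit, newdata = x),
    svm = attr(stats::predict(model$fit, newdata = x, probability = TRUE),
               "probabilities")[, "1"],
    maxent = predict_maxent_like(model$fit, x))
  pmin(1, pmax(0, as.numeric(p)))
}

#' Project a fitted model onto a stack
#'
#' @param model an `enm_model`.
#' @param stack an `env_stack` holding all model variables.
#' @param area `accessible_area` restriction (default: full valid grid).
#' @return a `suitability_map`.
#' @export
predict_enm <- function(model, stack, area = full_area(stack)) {
  if (model$algorithm == "bioclim")
    return(predict_bioclim(model$fit, stack, area))
  cells <- mask_cells(area$mask)
  vals <- cell_values(stack, cells)
  suitability_map_from_cells(stack, cells, predict_values(model, vals),
                             model$algorithm)
}

# --- individual adapters -----------------------------------------------------

# GLM: binomial/logit with linear + quadratic terms, stepwise AIC in both
# directions from the full model.
fit_glm_quadratic <- function(x, y, spec) {
  d <- as.data.frame(x)
  d$.y <- y
  terms <- c(colnames(x), sprintf("I(%s^2)", colnames(x)))
  full <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(full, family = stats::binomial("logit"),
                                     data = d))
  if (isTRUE(spec$hyperparameters$stepwise))
    fit <- suppressWarnings(stats::step(fit, direction = "both", trace = 0))
  fit
}

# GAM: binomial/logit with one smooth per variable. The basis dimension
# defaults to the library default; it is reduced automatically when the data
# cannot support it (few calibration records), the standard small-sample
# adjustment.
fit_gam_adapter <- function(x, y, spec) {
  d <- as.data.frame(x)
  d$.y <- y
  k <- spec$hyperparameters$k
  if (is.null(k)) {
    k_max <- floor((nrow(x) - 1) / ncol(x))
    k <- if (k_max >= 10) -1 else max(3, k_max)
  }
  sm <- if (identical(k, -1)) sprintf("s(%s)", colnames(x))
        else sprintf("s(%s, k = %d)", colnames(x), as.integer(k))
  f <- stats::as.formula(paste(".y ~", paste(sm, collapse = " + ")))
  # REML first; on numerical failure (e.g. complete separation) fall back to
  # the extended Fellner-Schall optimizer, then to GCV
  fit <- tryCatch(
    suppressWarnings(mgcv::gam(f, family = stats::binomial("logit"),
                               data = d, method = "REML")),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      suppressWarnings(mgcv::gam(f, family = stats::binomial("logit"),
                                 data = d, method = "REML",
                                 optimizer = "efs")),
      error = function(e) NULL)
  if (is.null(fit))
    fit <- suppressWarnings(mgcv::gam(f, family = stats::binomial("logit"),
                                      data = d, method = "GCV.Cp"))
  fit
}

# BRT: gradient-boosted trees, learning rate 0.005, depth 5, bag fraction 0.5.
fit_brt_adapter <- function(x, y, spec) {
  hp <- spec$hyperparameters
  dm <- xgboost::xgb.DMatrix(x, label = y)
  with_seed(spec$seed,
    xgboost::xgb.train(params = list(objective = "binary:logistic",
                                     eta = hp$learning_rate,
                                     max_depth = hp$tree_complexity,
                                     subsample = hp$bag_fraction,
                                     nthread = 1,
                                     seed = spec$seed),
                       data = dm, nrounds = hp$n_trees, verbose = 0))
}

# RF: 500 regression trees on the 0/1 response, suitability = ensemble mean
# (the standard "probability forest" formulation for presence/absence data,
# smoother and more stable than classification votes). Out-of-bag
# predictions for the training presences are kept alongside the fit:
# resubstitution predictions at training points are memorized by the trees,
# so the ten-percentile threshold must come from the OOB values to be honest.
fit_rf_adapter <- function(x, y, spec) {
  fit <- with_seed(spec$seed,
    suppressWarnings(randomForest::randomForest(
      x, as.numeric(y), ntree = spec$hyperparameters$n_trees)))
  attr(fit, "oob_presence") <- pmin(1, pmax(0, unname(fit$predicted[y == 1L])))
  fit
}

# SVM: radial-kernel C-classification with probability outputs.
fit_svm_adapter <- function(x, y, spec) {
  with_seed(spec$seed,
    e1071::svm(x, factor(y, levels = c("0", "1")),
               kernel = spec$hyperparameters$kernel,
               cost = spec$hyperparameters$cost,
               probability = TRUE))
}
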