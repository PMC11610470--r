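# Maxent-style adapter: a penalized presence/background logistic regression
# ("maxnet-style") over the classical feature classes — linear (l),
# quadratic (q), product (p), threshold (t) and hinge (h). Candidate models
# cross the regularization multipliers {0.5, 1, 1.5, 2} with the nested
# feature ladder L, LQ, LQP, LQPT, LQPTH; the winner minimizes AICc with
# k = number of nonzero coefficients and n = number of presences. Features
# are evaluated as-is beyond the calibration range (no clamping), so
# projection into novel conditions extrapolates the fitted curves.

# Feature template: knots and ranges computed once from the training data so
# the identical expansion can be applied to projection data.
maxent_feature_template <- function(x, classes, n_knots) {
  vars <- colnames(x)
  probs <- seq(0, 1, length.out = n_knots + 2L)[2:(n_knots + 1L)]
  tpl <- list(classes = classes, vars = vars,
              knots = lapply(vars, function(v)
                unique(stats::quantile(x[, v], probs, names = FALSE))),
              min = apply(x, 2L, min), max = apply(x, 2L, max))
  names(tpl$knots) <- vars
  tpl
}

maxent_design <- function(tpl, x) {
  x <- as.matrix(x)[, tpl$vars, drop = FALSE]
  cols <- list()
  if ("l" %in% tpl$classes)
    for (v in tpl$vars) cols[[paste0("l_", v)]] <- x[, v]
  if ("q" %in% tpl$classes)
    for (v in tpl$vars) cols[[paste0("q_", v)]] <- x[, v]^2
  if ("p" %in% tpl$classes && length(tpl$vars) >= 2L)
    for (i in seq_len(length(tpl$vars) - 1L))
      for (j in (i + 1L):length(tpl$vars))
        cols[[paste0("p_", tpl$vars[i], "_", tpl$vars[j])]] <-
          x[, tpl$vars[i]] * x[, tpl$vars[j]]
  if ("t" %in% tpl$classes)
    for (v in tpl$vars)
      for (k in seq_along(tpl$knots[[v]]))
        cols[[paste0("t_", v, "_", k)]] <-
          as.numeric(x[, v] > tpl$knots[[v]][k])
  if ("h" %in% tpl$classes)
    for (v in tpl$vars) {
      rng <- tpl$max[v] - tpl$min[v]
      if (rng <= 0) next
      for (k in seq_along(tpl$knots[[v]])) {
        kn <- tpl$knots[[v]][k]
        cols[[paste0("hf_", v, "_", k)]] <- pmax(0, (x[, v] - kn) / rng)
        cols[[paste0("hr_", v, "_", k)]] <- pmax(0, (kn - x[, v]) / rng)
      }
    }
  do.call(cbind, cols)
}

# Fit one candidate (feature set, regularization multiplier); returns NULL on
# failure. Lambda is rm-scaled off the top of the glmnet path.
maxent_candidate <- function(X, y, rm) {
  if (ncol(X) < 2L) return(NULL)
  keep <- apply(X, 2L, function(col) stats::sd(col) > 0)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2L) return(NULL)
  path <- tryCatch(suppressWarnings(glmnet::glmnet(X, y, family = "binomial",
                                                   standardize = TRUE)),
                   error = function(e) NULL)
  if (is.null(path)) return(NULL)
  lam_max <- path$lambda[1L]
  target <- rm * 0.01 * lam_max
  lam_seq <- exp(seq(log(lam_max), log(target), length.out = 30L))
  fit <- tryCatch(suppressWarnings(glmnet::glmnet(X, y, family = "binomial",
                                                  standardize = TRUE,
                                                  lambda = lam_seq)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- as.numeric(stats::predict(fit, newx = X, s = target,
                                 type = "response"))
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  beta <- as.numeric(stats::coef(fit, s = target))
  k <- sum(beta[-1L] != 0) + 1L
  list(fit = fit, s = target, loglik = ll, k = k, kept = keep)
}

fit_maxent_like <- function(presence_values, background_values, spec) {
  hp <- spec$hyperparameters
  x_all <- rbind(presence_values, background_values)
  y <- c(rep(1, nrow(presence_values)), rep(0, nrow(background_values)))
  n_pres <- nrow(presence_values)
  best <- NULL
  for (fc in hp$feature_ladder) {
    tpl <- maxent_feature_template(x_all, fc, hp$n_knots)
    X <- maxent_design(tpl, x_all)
    for (rm in hp$rm_grid) {
      cand <- maxent_candidate(X, y, rm)
      if (is.null(cand)) next
      aicc <- if (n_pres - cand$k - 1 > 0)
        -2 * cand$loglik + 2 * cand$k +
          2 * cand$k * (cand$k + 1) / (n_pres - cand$k - 1)
      else Inf
      aic <- -2 * cand$loglik + 2 * cand$k
      score <- c(aicc = aicc, aic = aic)
      if (is.null(best) ||
          (is.finite(score["aicc"]) && score["aicc"] < best$score["aicc"]) ||
          (!is.finite(best$score["aicc"]) && !is.finite(score["aicc"]) &&
           score["aic"] < best$score["aic"])) {
        best <- list(template = tpl, candidate = cand, rm = rm,
                     classes = fc, score = score)
      }
    }
  }
  if (is.null(best))
    stop_arg("no Maxent-style candidate model could be fitted")
  best
}

predict_maxent_like <- function(model, values) {
  X <- maxent_design(model$template, values)
  X <- X[, model$candidate$kept, drop = FALSE]
  as.numeric(stats::predict(model$candidate$fit, newx = X,
                            s = model$candidate$s, type = "response"))
}
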