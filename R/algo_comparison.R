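# algo_comparison module: nonparametric cross-algorithm statistics on the
# transfer-metric table — direction comparisons (Mann-Whitney-Wilcoxon),
# algorithm comparisons (Kruskal-Wallis with a Nemenyi post hoc on mean
# ranks), and sample-size vs performance Pearson correlations.

#' Assemble a tidy metric table from run_all output
#'
#' @param metrics the `metrics` data.frame emitted by [run_all()].
#' @param metric_names which metric columns to gather (default the four
#'   indices).
#' @return data.frame with `species`, `algorithm`, `direction`, `metric`,
#'   `value`, `n_records` (total unique localities across both periods).
#' @export
metric_table <- function(metrics,
                         metric_names = c("tss", "oi", "eq3_rate", "eq4_rate")) {
  rows <- lapply(metric_names, function(m)
    data.frame(species = metrics$species, algorithm = metrics$algorithm,
               direction = metrics$direction, metric = m,
               value = metrics[[m]],
               n_records = metrics$n_records_T1 + metrics$n_records_T2))
  out <- do.call(rbind, rows)
  key <- paste(out$species, out$algorithm, out$direction, out$metric)
  if (anyDuplicated(key)) stop_arg("duplicated (species, algorithm, direction, metric) rows")
  out
}

#' Compare forecast vs hindcast for one algorithm and metric
#'
#' Two-sided Mann-Whitney-Wilcoxon rank-sum test (midranks, tie-corrected
#' normal approximation when ties are present).
#'
#' @param table a [metric_table()].
#' @param algorithm,metric which slice to test.
#' @return list with `W`, `p_value`, `n_forecast`, `n_hindcast`.
#' @export
compare_directions <- function(table, algorithm, metric) {
  sub <- table[table$algorithm == algorithm & table$metric == metric, ]
  x <- sub$value[sub$direction == "forecast"]
  y <- sub$value[sub$direction == "hindcast"]
  if (length(x) < 2L || length(y) < 2L)
    stop_arg("need at least 2 values per direction")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(W = unname(wt$statistic), p_value = wt$p.value,
       n_forecast = length(x), n_hindcast = length(y))
}

# Kruskal-Wallis with the all-ties degenerate case defined as H = 0
# (stats::kruskal.test returns NaN there because the tie correction is 0/0).
kruskal_safe <- function(values, groups) {
  if (length(unique(values)) == 1L)
    return(list(H = 0, p_value = 1))
  kt <- stats::kruskal.test(values, factor(groups))
  list(H = unname(kt$statistic), p_value = kt$p.value)
}

#' Nemenyi all-pairs post-hoc test on mean ranks
#'
#' Pairwise comparison of group mean ranks after a significant
#' Kruskal-Wallis omnibus: the statistic for groups i, j is
#' `|Ri - Rj| / sqrt(C * N(N+1)/12 * (1/ni + 1/nj))` (C the tie correction),
#' referred to the studentized range distribution with k groups and infinite
#' degrees of freedom (divided by sqrt(2)). Midranks handle ties.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return list with `p_values` (symmetric k x k matrix) and `mean_ranks`.
#' @export
nemenyi_test <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop_arg("need at least 2 groups")
  N <- length(values)
  r <- rank(values)  # midranks
  mr <- tapply(r, groups, mean)
  n <- tabulate(groups)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) C <- 1e-12
  p <- matrix(NA_real_, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    se <- sqrt(C * N * (N + 1) / 12 * (1 / n[i] + 1 / n[j]))
    q <- abs(mr[i] - mr[j]) / se * sqrt(2)
    p[i, j] <- p[j, i] <- stats::ptukey(q, k, Inf, lower.tail = FALSE)
  }
  diag(p) <- 1
  list(p_values = p, mean_ranks = mr)
}

#' Compare algorithms within one direction and metric
#'
#' Kruskal-Wallis omnibus across algorithms; when the omnibus p-value falls
#' below `alpha` the Nemenyi all-pairs matrix is computed, otherwise it is
#' `NULL`.
#'
#' @param table a [metric_table()].
#' @param direction,metric which slice to test.
#' @param alpha gate for the post hoc (default 0.05).
#' @return list with `H`, `p_value`, `nemenyi` (or `NULL`), `groups`.
#' @export
compare_algorithms <- function(table, direction, metric, alpha = 0.05) {
  sub <- table[table$direction == direction & table$metric == metric, ]
  counts <- table(sub$algorithm)
  counts <- counts[counts > 0]
  if (length(counts) < 3L || any(counts < 2L))
    stop_arg("need at least 3 algorithm groups with at least 2 values each")
  kw <- kruskal_safe(sub$value, sub$algorithm)
  nem <- if (kw$p_value < alpha) nemenyi_test(sub$value, sub$algorithm) else NULL
  list(H = kw$H, p_value = kw$p_value, nemenyi = nem,
       groups = as.data.frame(counts))
}

#' Correlate sample size with performance
#'
#' Two-sided Pearson correlation between the number of occurrence records
#' and the metric (TSS by default) for one algorithm and direction.
#'
#' @param table a [metric_table()].
#' @param algorithm,direction which slice to test.
#' @param metric metric name (default `"tss"`).
#' @return list with `r`, `r_squared`, `p_value`, `n`.
#' @export
correlate_sample_size <- function(table, algorithm, direction,
                                  metric = "tss") {
  sub <- table[table$algorithm == algorithm & table$direction == direction &
                 table$metric == metric, ]
  if (nrow(sub) < 3L) stop_arg("need at least 3 points")
  if (stats::sd(sub$value) == 0 || stats::sd(sub$n_records) == 0)
    stop_arg("undefined-correlation error: zero variance")
  ct <- stats::cor.test(sub$n_records, sub$value, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = nrow(sub))
}
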