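# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a base seed and string tags
#'
#' Streams of randomness inside one experiment (pseudoabsence draws, data
#' splits, stochastic learners) each get their own seed derived from the
#' experiment seed plus a role tag, so that re-running any component in
#' isolation reproduces it exactly.
#'
#' @param seed integer base seed.
#' @param ... character or numeric tags identifying the role.
#' @return an integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                       character(1)), collapse = "::")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(tags)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so library code cannot perturb downstream draws.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_arg <- function(...) stop(..., call. = FALSE)
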