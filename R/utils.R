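# Internal helpers: condition classes, seeded evaluation, linear algebra.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
fsda_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fsdacam_error"),
                      call = call))
}

stop_validation <- function(msg) fsda_stop(msg, "fsdacam_validation_error")
stop_dimension  <- function(msg) fsda_stop(msg, "fsdacam_dimension_error")
stop_degenerate <- function(msg) fsda_stop(msg, "fsdacam_degenerate_class_error")
stop_illcond    <- function(msg) fsda_stop(msg, "fsdacam_ill_conditioned_error")
stop_nodirection <- function(msg) fsda_stop(msg, "fsdacam_no_direction_error")

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x)))
    stop_validation(sprintf("%s contains non-finite values", what))
  invisible(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never perturb the
#' caller's random stream. All randomness in the package flows through this.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic sub-stream seeds (kept < 2^31) so each generator draws from
# an independently reproducible stream derived from one master seed.
sub_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + id) %% 2147483647)
}

# Solve A x = b for symmetric positive definite A via Cholesky; never forms
# an explicit inverse.
chol_solve <- function(R, b) {
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop_validation("cannot normalize a zero vector")
  v / n
}

# Rank-based AUC of `scores` for the positive class (Mann-Whitney form).
auc_from_scores <- function(scores, is_positive) {
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  if (n1 == 0L || n0 == 0L)
    stop_validation("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
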