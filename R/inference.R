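# Permutation-based significance for CPM predictions and for simple
# measure-measure correlations.

new_perm_result <- function(observed, null_r, m, p, seed, estimator) {
  structure(list(observed_r = observed, null_r = null_r,
                 m = as.integer(m), p = p, seed = as.integer(seed),
                 estimator = estimator),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed r = %.4f, m = %d permutations, p = %.4g\n",
    x$observed_r, x$m, x$p))
  invisible(x)
}

#' Permutation test for CPM predictive accuracy
#'
#' Re-runs the complete CPM pipeline (fold construction, family-aware
#' exclusion, edge selection, model fitting, out-of-fold prediction) after
#' permuting the target, and locates the observed `r_eval` in the null
#' distribution. The p-value is the plain proportion of permutations with
#' `r >= observed` (one-sided, matching the directional question "does the
#' model predict better than chance").
#'
#' All permutation orders are pre-drawn from the master seed before any
#' replicate runs, so results are identical for every `workers` setting.
#'
#' @param data A [subject_dataset()].
#' @param m Number of permutations (the reference analyses used 10,000 for
#'   task-based and 2,000 for resting-state data; desk-scale runs use far
#'   fewer).
#' @param seed Integer master seed (also used for the fold plan of every
#'   replicate and the observed run).
#' @param workers Parallel workers via [parallel::mclapply()]; results are
#'   invariant to this setting.
#' @param scope `"global"` permutes the target over the whole sample
#'   (default); `"within_fold"` permutes only within each test fold of the
#'   fold plan, i.e. within the test populations.
#' @param estimator `"proportion"` (default) uses `p = b/m`;
#'   `"add_one"` uses `(b + 1)/(m + 1)`, which cannot return 0.
#' @param ... Passed to [run_cpm()] (`k`, `alpha`, `exclude_related`, ...).
#' @return A `perm_result`: `observed_r`, `null_r`, `m`, `p`, `seed`.
#' @export
permutation_test_cpm <- function(data, m = 1000L, seed = 1L, workers = 1L,
                                 scope = c("global", "within_fold"),
                                 estimator = c("proportion", "add_one"),
                                 ...) {
  stopifnot(inherits(data, "subject_dataset"), m >= 1L)
  scope <- match.arg(scope)
  estimator <- match.arg(estimator)
  N <- nrow(data$edges)
  observed <- run_cpm(data, seed = seed, keep_folds = FALSE, ...)
  perms <- with_seed(seed, {
    if (scope == "global") {
      lapply(seq_len(m), function(b) sample.int(N))
    } else {
      assignment <- observed$fold_plan$assignment
      lapply(seq_len(m), function(b) {
        idx <- seq_len(N)
        for (f in seq_len(observed$fold_plan$k)) {
          members <- which(assignment == f)
          idx[members] <- members[sample.int(length(members))]
        }
        idx
      })
    }
  })
  one_rep <- function(perm) {
    d <- data
    d$target <- data$target[perm]
    tryCatch(run_cpm(d, seed = seed, keep_folds = FALSE, ...)$r_eval,
             error = function(e) NA_real_)
  }
  null_r <- if (workers > 1L) {
    unlist(parallel::mclapply(perms, one_rep, mc.cores = workers))
  } else {
    vapply(perms, one_rep, numeric(1))
  }
  if (anyNA(null_r)) {
    warning(sum(is.na(null_r)), " permutation replicate(s) failed; ",
            "excluded with m adjusted")
    null_r <- null_r[!is.na(null_r)]
  }
  m_eff <- length(null_r)
  b <- sum(null_r >= observed$r_eval)
  p <- if (estimator == "proportion") b / m_eff else (b + 1) / (m_eff + 1)
  new_perm_result(observed$r_eval, null_r, m_eff, p, seed, estimator)
}

#' Permutation test for a Pearson correlation
#'
#' Two-sided permutation test of `cor(x, y)`, building the null by
#' shuffling `y`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param m Number of permutations.
#' @param seed Integer seed.
#' @param estimator See [permutation_test_cpm()].
#' @return A `perm_result` with two-sided `p`.
#' @export
permutation_corr_test <- function(x, y, m = 1000L, seed = 1L,
                                  estimator = c("proportion", "add_one")) {
  estimator <- match.arg(estimator)
  stopifnot(length(x) == length(y), length(x) >= 3L, m >= 1L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_cerebcpm("correlation undefined for constant input",
                  "cerebcpm_degenerate_input")
  observed <- stats::cor(x, y)
  null_r <- with_seed(seed, vapply(seq_len(m), function(b)
    stats::cor(x, y[sample.int(length(y))]), numeric(1)))
  b <- sum(abs(null_r) >= abs(observed))
  p <- if (estimator == "proportion") b / m else (b + 1) / (m + 1)
  new_perm_result(observed, null_r, m, p, seed, estimator)
}

#' Bonferroni correction
#'
#' `min(1, p * n_tests)` element-wise.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param n_tests Number of tests corrected for; must be at least
#'   `length(p_values)` (defaults to it).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, n_tests = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (n_tests < length(p_values))
    stop("n_tests must be >= length(p_values)")
  pmin(1, p_values * n_tests)
}
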