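# The CPM engine: fold construction, family-aware exclusion, nuisance
# regression, edge selection, network-strength models, out-of-fold
# prediction and evaluation.

#' Assemble a subject dataset for CPM
#'
#' Binds the per-subject COI edge vectors to the prediction target (e.g.
#' BMI in kg/m^2), the encoded confounds and the family labels used for
#' relative exclusion.
#'
#' @param edges N x E numeric matrix: one row per subject, one column per
#'   COI edge (canonical order).
#' @param target Length-N numeric target.
#' @param confounds N x q numeric design matrix of encoded confounds
#'   (see [encode_confounds()]), or `NULL` for none.
#' @param family_id Length-N family labels, or `NULL` for all-singleton
#'   families.
#' @param subject_ids Optional subject identifiers.
#' @param edge_mask Optional `edge_mask` the columns of `edges` were taken
#'   from; carried along so networks can be mapped back to parcels.
#' @return A `subject_dataset`.
#' @export
subject_dataset <- function(edges, target, confounds = NULL,
                            family_id = NULL, subject_ids = NULL,
                            edge_mask = NULL) {
  edges <- as.matrix(edges)
  N <- nrow(edges)
  if (N < 3L) stop("need at least 3 subjects")
  if (ncol(edges) < 1L) stop("need at least 1 edge")
  if (length(target) != N) stop("target length must match subjects")
  if (!is_finite_num(edges) || !is_finite_num(as.numeric(target)))
    stop("edges/target contain non-finite values")
  if (is.null(confounds)) {
    confounds <- matrix(numeric(0), N, 0L)
  } else {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != N) stop("confound rows must match subjects")
    if (!is_finite_num(confounds)) stop("confounds contain non-finite values")
  }
  if (is.null(family_id)) family_id <- seq_len(N)
  if (length(family_id) != N) stop("family_id length must match subjects")
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%04d", seq_len(N))
  structure(list(subject_ids = as.character(subject_ids), edges = edges,
                 target = as.numeric(target), confounds = confounds,
                 family_id = as.character(family_id), edge_mask = edge_mask),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf(
    "Subject dataset: %d subjects, %d edges, %d confound column(s), %d families\n",
    nrow(x$edges), ncol(x$edges), ncol(x$confounds),
    length(unique(x$family_id))))
  invisible(x)
}

#' Encode a confound data frame as a numeric design matrix
#'
#' Numeric columns are kept as-is; two-level factors/characters become one
#' binary indicator; factors with more levels are one-hot encoded with the
#' first level dropped. No intercept column is produced (model fits add
#' their own).
#'
#' @param df Data frame of confounds (e.g. gender, age, ethnicity).
#' @return Numeric matrix with one row per subject.
#' @export
encode_confounds <- function(df) {
  if (is.null(df) || ncol(df) == 0L)
    return(matrix(numeric(0), nrow(df) %||% 0L, 0L))
  df <- as.data.frame(df)
  for (nm in names(df)) if (is.character(df[[nm]]) || is.logical(df[[nm]]))
    df[[nm]] <- factor(df[[nm]])
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1L, drop = FALSE]  # drop the intercept
}

#' Balanced random fold assignment
#'
#' Uniformly random partition of N subjects into k folds whose sizes
#' differ by at most one; reproducible from `seed`.
#'
#' @param N Number of subjects.
#' @param k Number of folds, `2 <= k <= N` (`k = N` is leave-one-out).
#' @param seed Integer seed.
#' @return A `fold_plan`: `k`, length-N `assignment` in 1..k, `seed`.
#' @export
make_folds <- function(N, k, seed) {
  N <- as.integer(N); k <- as.integer(k)
  if (k < 2L || k > N)
    stop_cerebcpm("k must satisfy 2 <= k <= N", "cerebcpm_config_error")
  assignment <- with_seed(seed, sample(rep_len(seq_len(k), N)))
  structure(list(k = k, assignment = assignment, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Remove training subjects related to test subjects
#'
#' Drops from the training indices every subject sharing a family label
#' with any test subject, so that relatives never predict each other. The
#' test set is left untouched to preserve out-of-fold coverage.
#'
#' @param train_idx,test_idx Disjoint integer subject indices.
#' @param family_id Family labels for all subjects.
#' @return Filtered training indices.
#' @export
exclude_relatives <- function(train_idx, test_idx, family_id) {
  if (length(intersect(train_idx, test_idx)) > 0L)
    stop("train and test sets overlap")
  keep <- !(family_id[train_idx] %in% family_id[test_idx])
  out <- train_idx[keep]
  if (length(out) == 0L)
    stop_cerebcpm(
      "no training subjects left after excluding relatives; use fewer folds",
      "cerebcpm_config_error")
  out
}

#' Residualize a vector on confounds
#'
#' Ordinary least-squares residuals of `y` on `[1 | X]`; with an empty
#' design this is mean-centering.
#'
#' @param y Numeric vector.
#' @param X Numeric confound matrix (may have zero columns), or `NULL`.
#' @return Residual vector, orthogonal to the intercept and every column
#'   of `X`.
#' @export
residualize <- function(y, X = NULL) {
  as.numeric(residualize_matrix(matrix(as.numeric(y), ncol = 1L), X))
}

# Residualize every column of M on [1 | X] with a single QR decomposition.
residualize_matrix <- function(M, X = NULL) {
  M <- as.matrix(M)
  if (is.null(X) || NCOL(X) == 0L)
    return(sweep(M, 2L, colMeans(M)))
  Xaug <- cbind(`(Intercept)` = 1, as.matrix(X))
  qrx <- qr(Xaug)
  if (qrx$rank < ncol(Xaug)) {
    dropped <- colnames(Xaug)[qrx$pivot[(qrx$rank + 1L):ncol(Xaug)]]
    stop_cerebcpm(paste0("confound design is rank deficient; collinear: ",
                         paste(dropped, collapse = ", ")),
                  "cerebcpm_rank_error")
  }
  qr.resid(qrx, M)
}

#' Edge-wise association of connectivity with the target
#'
#' For every edge, correlates edge strength with the target across
#' training subjects after regressing the confounds out of both (a partial
#' correlation). Two-sided p-values come from
#' `t = r * sqrt(df / (1 - r^2))` with `df = N - 2 - q`. Edges with
#' positive (negative) `r` and `p <= alpha` form the positive (negative)
#' network of the fold.
#'
#' @param edges N_train x E matrix of edge strengths.
#' @param target Length-N_train target.
#' @param confounds Confound design matrix or `NULL`.
#' @param alpha Selection threshold on the p-value (default 0.05).
#' @param residualize_edges If `FALSE`, only the target is residualized on
#'   the confounds (edges are merely centered) and `df = N - 2`.
#' @return An `edge_selection`: vectors `r`, `p` and logical `pos_mask`,
#'   `neg_mask`.
#' @export
edgewise_association <- function(edges, target, confounds = NULL,
                                 alpha = 0.05, residualize_edges = TRUE) {
  edges <- as.matrix(edges)
  N <- nrow(edges)
  q <- if (is.null(confounds)) 0L else NCOL(confounds)
  if (N <= q + 3L)
    stop_cerebcpm("too few training subjects for the confound design",
                  "cerebcpm_config_error")
  ry <- residualize(target, confounds)
  RE <- if (residualize_edges) residualize_matrix(edges, confounds)
        else sweep(edges, 2L, colMeans(edges))
  df <- N - 2L - if (residualize_edges) q else 0L
  sy <- sqrt(sum(ry^2))
  se <- sqrt(colSums(RE^2))
  denom <- se * sy
  degenerate <- denom <= .Machine$double.eps * N
  r <- numeric(ncol(edges))
  r[!degenerate] <- as.numeric(crossprod(RE[, !degenerate, drop = FALSE],
                                         ry)) / denom[!degenerate]
  r <- pmin(1, pmax(-1, r))
  p <- rep(1, ncol(edges))
  ok <- !degenerate & abs(r) < 1
  tt <- r[ok] * sqrt(df / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df)
  p[!degenerate & abs(r) >= 1] <- 0
  if (any(degenerate))
    warning(sum(degenerate), " constant edge(s): r set to 0, p to 1")
  structure(list(r = r, p = p,
                 pos_mask = r > 0 & p <= alpha & !degenerate,
                 neg_mask = r < 0 & p <= alpha & !degenerate,
                 alpha = alpha, df = df),
            class = "edge_selection")
}

#' Network strength of a subject
#'
#' Sum of a subject's edge values over a selected edge set; the summary
#' score that CPM regresses the target on. Vectorized over subjects.
#'
#' @param edge_values Length-E vector, or N x E matrix (one row per
#'   subject).
#' @param mask Logical length-E edge mask.
#' @return Scalar, or length-N vector for matrix input; 0 for an empty
#'   mask.
#' @export
network_strength <- function(edge_values, mask) {
  mask <- as.logical(mask)
  if (is.matrix(edge_values)) {
    stopifnot(ncol(edge_values) == length(mask))
    return(rowSums(edge_values[, mask, drop = FALSE]))
  }
  stopifnot(length(edge_values) == length(mask))
  sum(edge_values[mask])
}

#' Fit the combined positive/negative network model
#'
#' Ordinary least squares of the target on
#' `[1, S_pos, S_neg]`, the positive and negative network strengths. A
#' regressor whose mask is empty is dropped and its coefficient recorded
#' as 0; with both masks empty the model is flagged and prediction falls
#' back to the training mean.
#'
#' @param S_pos,S_neg Length-N training network strengths.
#' @param target Length-N training target.
#' @param pos_empty,neg_empty Whether the corresponding mask is empty.
#' @return A `cpm_model` with `beta0`, `beta_pos`, `beta_neg`, `flag`.
#' @export
fit_combined_glm <- function(S_pos, S_neg, target,
                             pos_empty = FALSE, neg_empty = FALSE) {
  n <- length(target)
  stopifnot(n >= 3L)
  flag <- "ok"
  beta0 <- mean(target); bpos <- 0; bneg <- 0
  if (pos_empty && neg_empty) {
    flag <- "no model"
  } else {
    X <- cbind(intercept = rep(1, n),
               if (!pos_empty) S_pos,
               if (!neg_empty) S_neg)
    fit <- stats::lm.fit(X, target)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0  # collinear/constant strength: coefficient dropped
    if (anyNA(fit$coefficients)) flag <- "collinear"
    beta0 <- cf[[1L]]
    j <- 2L
    if (!pos_empty) { bpos <- cf[[j]]; j <- j + 1L }
    if (!neg_empty) bneg <- cf[[j]]
  }
  structure(list(beta0 = beta0, beta_pos = bpos, beta_neg = bneg,
                 flag = flag),
            class = "cpm_model")
}

predict_cpm_model <- function(model, S_pos, S_neg) {
  model$beta0 + model$beta_pos * S_pos + model$beta_neg * S_neg
}

#' Pearson correlation of predicted with observed values
#'
#' The population-level evaluation statistic of a CPM run.
#'
#' @param pred,obs Numeric vectors of equal length >= 3.
#' @return Pearson r.
#' @export
evaluate <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 3L)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop_cerebcpm("correlation undefined for constant input",
                  "cerebcpm_degenerate_input")
  stats::cor(pred, obs)
}

#' Run connectome-based predictive modeling
#'
#' The full k-fold CPM protocol: subjects are partitioned into k random
#' folds; for each fold, training relatives of test subjects are excluded,
#' edges are correlated with the target (confound-adjusted) and selected
#' at `p <= alpha` into positive and negative networks, a linear model is
#' fitted on the two network strengths, and the held-out fold is
#' predicted. Every subject is predicted exactly once; the run is
#' evaluated by the Pearson correlation of out-of-fold predictions with
#' observed targets.
#'
#' @param data A [subject_dataset()].
#' @param k Number of folds (default 128, capped at N with a warning).
#' @param alpha Edge-selection p threshold (default 0.05).
#' @param seed Integer seed governing the fold assignment.
#' @param exclude_related Apply family-aware exclusion (default `TRUE`).
#' @param residualize_edges Residualize edges as well as the target on the
#'   confounds (default `TRUE`).
#' @param keep_folds Keep per-fold models and selections (default `TRUE`;
#'   disable to save memory in permutation loops).
#' @return A `cpm_result`: out-of-fold `predictions`, `observed`,
#'   `r_eval`, `fold_plan`, per-fold details in `folds`, configuration in
#'   `params`.
#' @export
run_cpm <- function(data, k = 128L, alpha = 0.05, seed = 1L,
                    exclude_related = TRUE, residualize_edges = TRUE,
                    keep_folds = TRUE) {
  stopifnot(inherits(data, "subject_dataset"))
  N <- nrow(data$edges)
  if (k > N) {
    warning("k = ", k, " exceeds N = ", N, "; capped at N (leave-one-out)")
    k <- N
  }
  plan <- make_folds(N, k, seed)
  predictions <- rep(NA_real_, N)
  folds <- vector("list", plan$k)
  n_failed <- 0L
  for (f in seq_len(plan$k)) {
    test_idx <- which(plan$assignment == f)
    train_idx <- which(plan$assignment != f)
    res <- tryCatch({
      excluded <- integer(0)
      if (exclude_related) {
        kept <- exclude_relatives(train_idx, test_idx, data$family_id)
        excluded <- setdiff(train_idx, kept)
        train_idx <- kept
      }
      sel <- edgewise_association(
        data$edges[train_idx, , drop = FALSE], data$target[train_idx],
        if (ncol(data$confounds)) data$confounds[train_idx, , drop = FALSE],
        alpha = alpha, residualize_edges = residualize_edges)
      pos_empty <- !any(sel$pos_mask); neg_empty <- !any(sel$neg_mask)
      Sp_tr <- network_strength(data$edges[train_idx, , drop = FALSE],
                                sel$pos_mask)
      Sn_tr <- network_strength(data$edges[train_idx, , drop = FALSE],
                                sel$neg_mask)
      model <- fit_combined_glm(Sp_tr, Sn_tr, data$target[train_idx],
                                pos_empty, neg_empty)
      Sp_te <- network_strength(data$edges[test_idx, , drop = FALSE],
                                sel$pos_mask)
      Sn_te <- network_strength(data$edges[test_idx, , drop = FALSE],
                                sel$neg_mask)
      list(pred = predict_cpm_model(model, Sp_te, Sn_te),
           model = model, selection = sel,
           excluded_train_ids = data$subject_ids[excluded])
    }, cerebcpm_error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      folds[[f]] <- list(error = conditionMessage(res))
      next
    }
    predictions[test_idx] <- res$pred
    if (keep_folds)
      folds[[f]] <- res[c("model", "selection", "excluded_train_ids")]
  }
  if (n_failed > 0.1 * plan$k)
    stop_cerebcpm(sprintf("%d of %d folds failed; run aborted",
                          n_failed, plan$k),
                  "cerebcpm_run_error")
  ok <- !is.na(predictions)
  r_eval <- evaluate(predictions[ok], data$target[ok])
  structure(list(
    predictions = predictions, observed = data$target,
    subject_ids = data$subject_ids, fold_plan = plan,
    folds = if (keep_folds) folds, r_eval = r_eval,
    edge_mask = data$edge_mask,
    n_failed_folds = n_failed,
    params = list(k = plan$k, alpha = alpha, seed = as.integer(seed),
                  exclude_related = exclude_related,
                  residualize_edges = residualize_edges,
                  n_subjects = N, n_edges = ncol(data$edges))),
    class = "cpm_result")
}

#' @export
print.cpm_result <- function(x, ...) {
  cat(sprintf("CPM result: %d subjects, %d edges, k = %d folds\n",
              x$params$n_subjects, x$params$n_edges, x$params$k))
  cat(sprintf("  out-of-fold Pearson r(predicted, observed) = %.4f\n",
              x$r_eval))
  if (x$n_failed_folds > 0L)
    cat(sprintf("  %d fold(s) failed\n", x$n_failed_folds))
  invisible(x)
}
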