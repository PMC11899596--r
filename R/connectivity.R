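# Subject-level connectivity estimation from parcellated time series, and
# combination of matrices across task conditions.

CONN_KINDS <- c("correlation", "partial", "covariance", "tangent",
                "average", "contrast")

#' Construct a connectivity matrix object
#'
#' Thin container tying a symmetric parcel x parcel matrix to its subject
#' and estimation kind. Most package functions accept either a
#' `conn_matrix` or a plain matrix.
#'
#' @param values Symmetric numeric P x P matrix.
#' @param subject_id Subject identifier.
#' @param kind One of `"correlation"`, `"partial"`, `"covariance"`,
#'   `"tangent"`, `"average"`, `"contrast"`.
#' @return A `conn_matrix` object.
#' @export
conn_matrix <- function(values, subject_id = NA_character_,
                        kind = "correlation") {
  values <- as.matrix(values)
  kind <- match.arg(kind, CONN_KINDS)
  if (nrow(values) != ncol(values))
    stop("connectivity matrix must be square")
  if (!is_finite_num(values))
    stop("connectivity matrix contains non-finite values")
  if (max(abs(values - t(values))) > 1e-10)
    stop("connectivity matrix is not symmetric (tolerance 1e-10)")
  values <- (values + t(values)) / 2
  structure(list(subject_id = as.character(subject_id), kind = kind,
                 values = values),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("Connectivity matrix (%s), subject %s: %d x %d\n",
              x$kind, x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Accept a conn_matrix or a plain matrix.
conn_values <- function(x) {
  if (inherits(x, "conn_matrix")) x$values else as.matrix(x)
}

conn_subject <- function(x) {
  if (inherits(x, "conn_matrix")) x$subject_id else NA_character_
}

check_timeseries <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L || ncol(ts) < 2L)
    stop("time series needs >= 2 timepoints and >= 2 parcels")
  if (!is_finite_num(ts))
    stop("time series contains non-finite values")
  ts
}

#' Pearson correlation connectivity
#'
#' Full (marginal) correlation between every pair of parcel time series;
#' the default connectivity kind for resting-state data.
#'
#' @param ts T x P numeric matrix, timepoints by parcels.
#' @param subject_id Subject identifier carried into the result.
#' @return A [conn_matrix()] of kind `"correlation"`: unit diagonal,
#'   entries in \[-1, 1\].
#' @export
pearson_connectivity <- function(ts, subject_id = NA_character_) {
  ts <- check_timeseries(ts)
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0))
    stop_cerebcpm(paste0("zero-variance parcel(s): ",
                         paste(which(sds == 0), collapse = ", ")),
                  "cerebcpm_degenerate_input")
  r <- stats::cor(ts)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  conn_matrix(r, subject_id, "correlation")
}

#' Ledoit-Wolf shrinkage covariance
#'
#' Empirical covariance shrunk toward a scaled identity,
#' `(1 - alpha) * S + alpha * mu * I` with `mu = tr(S)/P`, using the
#' analytically optimal shrinkage intensity `alpha` in \[0, 1\]. The
#' empirical covariance uses the 1/T normalization of the original
#' estimator. The result is symmetric positive definite whenever the data
#' are not all-constant, which is what makes downstream tangent-space
#' embedding well defined.
#'
#' @inheritParams pearson_connectivity
#' @return A [conn_matrix()] of kind `"covariance"` with attribute
#'   `"shrinkage"` holding alpha.
#' @export
ledoit_wolf_covariance <- function(ts, subject_id = NA_character_) {
  ts <- check_timeseries(ts)
  n <- nrow(ts); P <- ncol(ts)
  X <- sweep(ts, 2L, colMeans(ts))
  S <- crossprod(X) / n
  mu <- sum(diag(S)) / P
  if (mu <= 0)
    stop_cerebcpm("all-constant time series: covariance is zero",
                  "cerebcpm_degenerate_input")
  d2 <- sum((S - diag(mu, P))^2)
  if (d2 == 0) {
    alpha <- 0  # S already equals the shrinkage target
  } else {
    # sum_t ||x_t x_t' - S||_F^2 = sum_t ||x_t||^4 - n ||S||_F^2
    b2bar <- (sum(rowSums(X^2)^2) - n * sum(S^2)) / n^2
    alpha <- min(1, max(0, min(b2bar, d2) / d2))
  }
  out <- (1 - alpha) * S + diag(alpha * mu, P)
  cm <- conn_matrix(out, subject_id, "covariance")
  attr(cm, "shrinkage") <- alpha
  cm
}

#' Partial correlation from a covariance matrix
#'
#' `rho_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)` with `Theta` the
#' precision matrix (inverse covariance); the conditional correlation of
#' each parcel pair given all others.
#'
#' @param cov A symmetric positive definite covariance
#'   ([conn_matrix()] of kind `"covariance"` or plain matrix).
#' @return A [conn_matrix()] of kind `"partial"` with unit diagonal.
#' @export
partial_correlation <- function(cov) {
  V <- conn_values(cov)
  theta <- tryCatch(chol2inv(chol(V)),
                    error = function(e)
                      stop_cerebcpm("covariance is not invertible (not SPD?)",
                                    "cerebcpm_inversion_error"))
  d <- sqrt(diag(theta))
  rho <- -theta / tcrossprod(d)
  diag(rho) <- 1
  conn_matrix(rho, conn_subject(cov), "partial")
}

## ---- SPD matrix helpers (symmetric eigendecomposition route) -------------

# Validate symmetry and positive definiteness; eigenvalues below
# 1e-10 * lambda_max are floored (with a warning) rather than failing.
check_spd <- function(m, label = "matrix") {
  m <- conn_values(m)
  if (max(abs(m - t(m))) > 1e-10)
    stop_cerebcpm(paste(label, "is not symmetric"), "cerebcpm_spd_error")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lmax <- max(e$values)
  if (lmax <= 0)
    stop_cerebcpm(paste(label, "is not positive definite"),
                  "cerebcpm_spd_error")
  floor_val <- 1e-10 * lmax
  if (min(e$values) < floor_val) {
    if (min(e$values) < -1e-8 * lmax)
      stop_cerebcpm(paste(label, "has substantially negative eigenvalues"),
                    "cerebcpm_spd_error")
    warning(label, ": near-zero eigenvalues floored at 1e-10 * lambda_max")
    e$values <- pmax(e$values, floor_val)
  }
  e
}

sym_from_eigen <- function(e, f) {
  v <- e$vectors
  out <- v %*% (f(e$values) * t(v))
  (out + t(out)) / 2
}

spd_sqrt <- function(m) sym_from_eigen(check_spd(m), sqrt)
spd_inv_sqrt <- function(m) sym_from_eigen(check_spd(m), function(x) 1 / sqrt(x))
spd_logm <- function(m) sym_from_eigen(check_spd(m), log)

# Matrix exponential of a symmetric matrix.
sym_expm <- function(m) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  sym_from_eigen(e, exp)
}

#' Affine-invariant geometric mean of SPD matrices
#'
#' Fixed-point iteration
#' `G <- G^(1/2) expm(mean_i logm(G^(-1/2) C_i G^(-1/2))) G^(1/2)`,
#' initialized at the arithmetic mean and stopped when the Frobenius norm
#' of the mean log falls below `tol`. This is the Riemannian (Karcher) mean
#' used as the reference point of tangent-space connectivity.
#'
#' @param mats List of SPD matrices (or [conn_matrix()] objects), same P.
#' @param tol Convergence tolerance on the Frobenius norm of the mean log.
#' @param max_iter Maximum fixed-point iterations.
#' @return SPD matrix; attribute `"converged"` is `FALSE` (with a warning)
#'   if `max_iter` was reached.
#' @export
geometric_mean <- function(mats, tol = 1e-7, max_iter = 50L) {
  stopifnot(length(mats) >= 1L)
  vals <- lapply(mats, conn_values)
  P <- nrow(vals[[1L]])
  if (!all(vapply(vals, function(v) all(dim(v) == P), logical(1))))
    stop("all matrices must share the same dimension")
  for (v in vals) check_spd(v, "geometric_mean input")
  if (length(vals) == 1L) {
    out <- vals[[1L]]
    attr(out, "converged") <- TRUE
    return(out)
  }
  G <- Reduce(`+`, vals) / length(vals)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    W <- spd_inv_sqrt(G)
    L <- Reduce(`+`, lapply(vals, function(v) spd_logm(W %*% v %*% W))) /
      length(vals)
    L <- (L + t(L)) / 2
    if (sqrt(sum(L^2)) < tol) { converged <- TRUE; break }
    Gh <- spd_sqrt(G)
    G <- Gh %*% sym_expm(L) %*% Gh
    G <- (G + t(G)) / 2
  }
  if (!converged)
    warning("geometric_mean did not converge in ", max_iter, " iterations")
  attr(G, "converged") <- converged
  G
}

#' Fit a tangent-space reference
#'
#' Computes the group geometric mean `G` of subject covariances and its
#' whitener `G^(-1/2)`. By default the reference is fitted on all supplied
#' subjects; for a leakage-safe cross-validation, fit on training-fold
#' covariances only and reuse the reference for test subjects.
#'
#' @param covs List of SPD covariance matrices ([conn_matrix()] or plain).
#' @param tol,max_iter Passed to [geometric_mean()].
#' @return A `tangent_reference`: `G`, `whitener`, `fitted_on` subject ids.
#' @export
tangent_reference <- function(covs, tol = 1e-7, max_iter = 50L) {
  G <- geometric_mean(covs, tol = tol, max_iter = max_iter)
  structure(list(G = G, whitener = spd_inv_sqrt(G),
                 fitted_on = vapply(covs, conn_subject, character(1))),
            class = "tangent_reference")
}

#' @export
print.tangent_reference <- function(x, ...) {
  cat(sprintf("Tangent-space reference: %d x %d, fitted on %d matrices\n",
              nrow(x$G), ncol(x$G), length(x$fitted_on)))
  invisible(x)
}

#' Project a covariance into tangent space
#'
#' Returns `logm(G^(-1/2) cov G^(-1/2))`: the whitened matrix logarithm of
#' the subject covariance around the group reference. The reference itself
#' maps to the zero matrix; the embedding is inverted by
#' `G^(1/2) expm(.) G^(1/2)`.
#'
#' @param cov SPD covariance ([conn_matrix()] or plain matrix).
#' @param ref A [tangent_reference()].
#' @return A [conn_matrix()] of kind `"tangent"` (symmetric, diagonal
#'   unconstrained).
#' @export
tangent_embed <- function(cov, ref) {
  stopifnot(inherits(ref, "tangent_reference"))
  V <- conn_values(cov)
  if (!all(dim(V) == dim(ref$G)))
    stop("covariance and tangent reference dimensions differ")
  W <- ref$whitener
  conn_matrix(spd_logm(W %*% V %*% W), conn_subject(cov), "tangent")
}

#' Invert a tangent-space embedding
#' @param tan Tangent matrix ([conn_matrix()] of kind `"tangent"` or plain).
#' @param ref The [tangent_reference()] used for embedding.
#' @return The reconstructed SPD covariance matrix.
#' @export
tangent_invert <- function(tan, ref) {
  stopifnot(inherits(ref, "tangent_reference"))
  Gh <- spd_sqrt(ref$G)
  Gh %*% sym_expm(conn_values(tan)) %*% Gh
}

## ---- Condition / task combination ----------------------------------------

#' Average connectivity matrices of one subject
#'
#' Element-wise arithmetic mean, used to collapse task conditions into a
#' per-task matrix and task matrices into a task-general matrix.
#'
#' @param mats Non-empty list of matrices ([conn_matrix()] or plain), all
#'   from the same subject and of identical shape.
#' @return A [conn_matrix()] of kind `"average"`.
#' @export
average_matrices <- function(mats) {
  if (length(mats) == 0L) stop("cannot average an empty list of matrices")
  subj <- unique(stats::na.omit(vapply(mats, conn_subject, character(1))))
  if (length(subj) > 1L)
    stop("matrices from different subjects: ", paste(subj, collapse = ", "))
  vals <- lapply(mats, conn_values)
  d <- dim(vals[[1L]])
  if (!all(vapply(vals, function(v) all(dim(v) == d), logical(1))))
    stop("matrices have mismatched shapes")
  conn_matrix(Reduce(`+`, vals) / length(vals),
              if (length(subj)) subj else NA_character_, "average")
}

#' Contrast two condition matrices of one subject
#'
#' Element-wise `specific - general`, e.g. 2-back minus 0-back.
#'
#' @param specific,general Matrices ([conn_matrix()] or plain) of the same
#'   subject and shape.
#' @return A [conn_matrix()] of kind `"contrast"`.
#' @export
contrast_matrices <- function(specific, general) {
  ss <- conn_subject(specific); gs <- conn_subject(general)
  if (!is.na(ss) && !is.na(gs) && ss != gs)
    stop("matrices from different subjects: ", ss, " vs ", gs)
  a <- conn_values(specific); b <- conn_values(general)
  if (!all(dim(a) == dim(b))) stop("matrices have mismatched shapes")
  conn_matrix(a - b, if (!is.na(ss)) ss else gs, "contrast")
}
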