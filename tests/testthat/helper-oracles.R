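# Fixtures and independent oracles used across the suite. Every oracle is
# a deliberately naive, loop-based computation kept independent of the
# package's vectorized code paths.

random_spd <- function(p, jitter = 0.5) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(jitter, p)
}

frob <- function(m) sqrt(sum(m^2))

# Textbook Pearson correlation from raw sums.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Ledoit-Wolf 2004 single-target shrinkage, written as explicit loops over
# timepoints.
lw_oracle <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- matrix(0, p, p)
  for (t in seq_len(n)) S <- S + tcrossprod(Xc[t, ])
  S <- S / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2)
  b2bar <- 0
  for (t in seq_len(n)) b2bar <- b2bar + sum((tcrossprod(Xc[t, ]) - S)^2)
  b2bar <- b2bar / n^2
  alpha <- min(b2bar, d2) / d2
  list(sigma = (1 - alpha) * S + diag(alpha * mu, p), alpha = alpha)
}

# Per-edge association via lm() residuals: the regress-out-then-correlate
# route, one edge at a time.
edgewise_oracle <- function(edges, target, confounds = NULL) {
  N <- nrow(edges); E <- ncol(edges)
  q <- if (is.null(confounds)) 0L else ncol(confounds)
  rt <- if (q > 0) residuals(lm(target ~ confounds)) else target - mean(target)
  r <- p <- numeric(E)
  df <- N - 2L - q
  for (e in seq_len(E)) {
    re <- if (q > 0) residuals(lm(edges[, e] ~ confounds))
          else edges[, e] - mean(edges[, e])
    r[e] <- pearson_oracle(re, rt)
    tt <- r[e] * sqrt(df / (1 - r[e]^2))
    p[e] <- 2 * pt(-abs(tt), df)
  }
  list(r = r, p = p)
}

# OLS through the normal equations.
ols_oracle <- function(X, y) as.numeric(solve(crossprod(X), crossprod(X, y)))

# Hypergeometric upper-tail by exhaustive enumeration of every placement
# of the second edge set (universe <= 15).
hyper_enum_oracle <- function(a_mask, b_size, obs) {
  U <- length(a_mask)
  placements <- combn(U, b_size)
  hits <- 0
  for (col in seq_len(ncol(placements))) {
    b <- logical(U); b[placements[, col]] <- TRUE
    if (sum(a_mask & b) >= obs) hits <- hits + 1
  }
  hits / ncol(placements)
}

# Small labelled parcellation: 2 cerebellar, 2 cortical, 1 subcortical.
toy_parcels <- function() {
  parcel_table(label = c("CbL", "CbR", "CtxL", "CtxR", "Thal"),
               group = c("cerebellar", "cerebellar", "cortical",
                         "cortical", "subcortical"),
               hemisphere = c("left", "right", "left", "right", "midline"))
}

# Hand-built edge_selection over E edges.
make_selection <- function(E, pos, neg, r = NULL) {
  if (is.null(r)) {
    r <- numeric(E)
    r[pos] <- 0.5
    r[neg] <- -0.5
  }
  structure(list(r = r, p = rep(1, E),
                 pos_mask = seq_len(E) %in% pos,
                 neg_mask = seq_len(E) %in% neg),
            class = "edge_selection")
}

# Small, quick synthetic spec for unit tests.
quick_spec <- function(seed, ...) {
  args <- list(n_subjects = 60L,
               parcels = c(cerebellar = 4L, cortical = 8L, subcortical = 2L),
               n_timepoints = 60L, n_pos_edges = 5L, n_neg_edges = 5L,
               n_families = 20L, seed = seed)
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}
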