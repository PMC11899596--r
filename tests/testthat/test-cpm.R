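test_that("fold plans are balanced, covering and reproducible", {
  plan <- make_folds(8, 4, seed = 3)
  sizes <- tabulate(plan$assignment, 4)
  expect_identical(sizes, rep(2L, 4))
  expect_identical(sort(unique(plan$assignment)), 1:4)
  # leave-one-out when k = N
  loo <- make_folds(5, 5, seed = 1)
  expect_identical(sort(tabulate(loo$assignment, 5)), rep(1L, 5))
  expect_identical(make_folds(20, 7, seed = 9)$assignment,
                   make_folds(20, 7, seed = 9)$assignment)
  expect_false(identical(make_folds(20, 7, seed = 9)$assignment,
                         make_folds(20, 7, seed = 10)$assignment))
  expect_error(make_folds(5, 6, seed = 1), class = "cerebcpm_config_error")
  # sizes differ by at most one for awkward N/k
  plan2 <- make_folds(23, 5, seed = 2)
  expect_lte(diff(range(tabulate(plan2$assignment, 5))), 1)
})

test_that("relative exclusion removes exactly the train-side family members", {
  fam <- c(A = "f1", B = "f2", C = "f3", D = "f2")
  expect_identical(exclude_relatives(1:3, 4L, fam), c(1L, 3L))
  # no shared families: no-op
  expect_identical(exclude_relatives(1:3, 4L, c("a", "b", "c", "d")), 1:3)
  expect_error(exclude_relatives(1:3, 3L, fam), "overlap")
  expect_error(exclude_relatives(2L, 4L, fam), class = "cerebcpm_config_error")
  # property: matches a brute-force pairwise scan on random family layouts
  set.seed(71)
  for (rep in 1:10) {
    N <- 40
    fam <- sample(sprintf("f%d", 1:12), N, replace = TRUE)
    test_idx <- sample.int(N, 6)
    train_idx <- setdiff(seq_len(N), test_idx)
    got <- exclude_relatives(train_idx, test_idx, fam)
    keep <- vapply(train_idx, function(tr)
      !any(vapply(test_idx, function(te) fam[tr] == fam[te], logical(1))),
      logical(1))
    expect_identical(got, train_idx[keep])
  }
})

test_that("residualization is an orthogonal projection", {
  set.seed(72)
  X <- cbind(rnorm(50), rnorm(50))
  y <- rnorm(50)
  r <- residualize(y, X)
  expect_lt(abs(sum(r)), 1e-10)                 # orthogonal to intercept
  expect_lt(max(abs(crossprod(X, r))), 1e-10)   # and to each confound
  expect_lt(max(abs(residualize(X[, 1], X))), 1e-10)  # confound maps to 0
  expect_equal(residualize(y, NULL), y - mean(y))
  expect_error(residualize(y, cbind(X, X[, 1])),
               class = "cerebcpm_rank_error")
})

test_that("edgewise association matches a per-edge lm() oracle", {
  set.seed(73)
  for (rep in 1:3) {
    N <- 50; E <- 40
    edges <- matrix(rnorm(N * E), N, E)
    conf <- cbind(rnorm(N), rbinom(N, 1, 0.5))
    target <- rnorm(N) + 0.5 * edges[, 1] - 0.5 * edges[, 2]
    sel <- edgewise_association(edges, target, conf)
    oracle <- edgewise_oracle(edges, target, conf)
    expect_lt(max(abs(sel$r - oracle$r)), 1e-10)
    expect_lt(max(abs(sel$p - oracle$p)), 1e-10)
    expect_true(all(!(sel$pos_mask & sel$neg_mask)))
    expect_true(all(sel$r[sel$pos_mask] > 0))
    expect_true(all(sel$r[sel$neg_mask] < 0))
    expect_true(all(sel$p[sel$pos_mask | sel$neg_mask] <= 0.05))
  }
})

test_that("edgewise association handles exact and degenerate edges", {
  set.seed(74)
  target <- rnorm(30)
  edges <- cbind(target, -target, rep(1, 30), rnorm(30))
  expect_warning(sel <- edgewise_association(edges, target), "constant")
  expect_equal(sel$r[1], 1)
  expect_equal(sel$r[2], -1)
  expect_true(sel$pos_mask[1])
  expect_true(sel$neg_mask[2])
  expect_equal(sel$r[3], 0)
  expect_equal(sel$p[3], 1)
  expect_false(sel$pos_mask[3] || sel$neg_mask[3])
})

test_that("network strength is the masked sum", {
  expect_equal(network_strength(c(0.5, -0.2, 0.3), c(TRUE, FALSE, TRUE)), 0.8)
  expect_equal(network_strength(c(0.5, -0.2), c(FALSE, FALSE)), 0)
  set.seed(75)
  v <- rnorm(30); m <- runif(30) < 0.4
  brute <- 0
  for (i in seq_along(v)) if (m[i]) brute <- brute + v[i]
  expect_equal(network_strength(v, m), brute)
  M <- matrix(rnorm(150), 5, 30)
  expect_equal(network_strength(M, m),
               apply(M, 1, function(row) network_strength(row, m)))
})

test_that("the combined GLM recovers exact and noisy coefficients", {
  set.seed(76)
  Sp <- rnorm(40); Sn <- rnorm(40)
  y <- 2 + 3 * Sp - 1 * Sn
  fit <- fit_combined_glm(Sp, Sn, y)
  expect_equal(c(fit$beta0, fit$beta_pos, fit$beta_neg), c(2, 3, -1))
  # constant target
  fit0 <- fit_combined_glm(Sp, Sn, rep(7, 40))
  expect_equal(c(fit0$beta0, fit0$beta_pos, fit0$beta_neg), c(7, 0, 0))
  # noisy fit equals the normal-equations oracle
  yn <- y + rnorm(40)
  fitn <- fit_combined_glm(Sp, Sn, yn)
  beta <- ols_oracle(cbind(1, Sp, Sn), yn)
  expect_equal(c(fitn$beta0, fitn$beta_pos, fitn$beta_neg), beta,
               tolerance = 1e-8)
  # one empty mask: regressor dropped, coefficient 0
  fitp <- fit_combined_glm(Sp, rep(0, 40), yn, neg_empty = TRUE)
  expect_equal(fitp$beta_neg, 0)
  expect_equal(c(fitp$beta0, fitp$beta_pos), ols_oracle(cbind(1, Sp), yn),
               tolerance = 1e-8)
  # both empty: flagged, falls back to the training mean
  fit2 <- fit_combined_glm(rep(0, 40), rep(0, 40), yn,
                           pos_empty = TRUE, neg_empty = TRUE)
  expect_identical(fit2$flag, "no model")
  expect_equal(fit2$beta0, mean(yn))
})

test_that("evaluation is plain Pearson correlation with guards", {
  expect_equal(evaluate(1:5, 1:5), 1)
  expect_equal(evaluate(1:5, 5:1), -1)
  expect_equal(evaluate(c(1, 2, 3, 4), c(2, 1, 4, 3)),
               pearson_oracle(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  expect_error(evaluate(rep(1, 5), 1:5), class = "cerebcpm_degenerate_input")
})

test_that("run_cpm predicts every subject exactly once and keeps families apart", {
  gen <- generate_dataset(quick_spec(81, family_trait_icc = 0.4))
  res <- run_cpm(gen$dataset, k = 10, seed = 81)
  expect_false(anyNA(res$predictions))
  expect_identical(sort(unique(res$fold_plan$assignment)), 1:10)
  fam <- gen$dataset$family_id
  for (f in seq_len(res$fold_plan$k)) {
    test_idx <- which(res$fold_plan$assignment == f)
    excluded <- res$folds[[f]]$excluded_train_ids
    train_ids <- setdiff(gen$dataset$subject_ids[-test_idx], excluded)
    train_fams <- fam[match(train_ids, gen$dataset$subject_ids)]
    expect_length(intersect(train_fams, fam[test_idx]), 0)
    sel <- res$folds[[f]]$selection
    expect_true(all(!(sel$pos_mask & sel$neg_mask)))
    expect_true(all(sel$p[sel$pos_mask | sel$neg_mask] <= 0.05))
  }
})

test_that("run_cpm is deterministic and caps k at N", {
  gen <- generate_dataset(quick_spec(82))
  r1 <- run_cpm(gen$dataset, k = 8, seed = 5)
  r2 <- run_cpm(gen$dataset, k = 8, seed = 5)
  expect_identical(r1, r2)
  expect_false(identical(r1$fold_plan$assignment,
                         run_cpm(gen$dataset, k = 8, seed = 6)$fold_plan$assignment))
  expect_warning(rl <- run_cpm(gen$dataset, k = 1000, seed = 5), "capped")
  expect_identical(rl$params$k, nrow(gen$dataset$edges))
})

test_that("run_cpm recovers a strong planted signal", {
  gen <- generate_dataset(quick_spec(83, n_subjects = 120))
  res <- run_cpm(gen$dataset, k = 10, seed = 83)
  expect_gt(res$r_eval, 0.3)
  sel_union_pos <- Reduce(`|`, lapply(res$folds, function(f) f$selection$pos_mask))
  expect_gt(sum(sel_union_pos[gen$truth$pos_edges]),
            0.8 * length(gen$truth$pos_edges))
})

test_that("null datasets give r_eval centred near zero", {
  rs <- vapply(1:20, function(s) {
    gen <- generate_dataset(quick_spec(100 + s, effect_size = 0))
    run_cpm(gen$dataset, k = 5, seed = s, keep_folds = FALSE)$r_eval
  }, numeric(1))
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se + 0.05)
})
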