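test_that("consensus networks tally selection frequencies correctly", {
  E <- 6
  sels <- list(make_selection(E, pos = c(1, 2), neg = 5),
               make_selection(E, pos = 1, neg = 5),
               make_selection(E, pos = c(1, 3), neg = numeric(0)))
  net_all <- consensus_network(sels, "positive", freq_threshold = 1)
  expect_identical(which(net_all$mask), 1L)          # only edge 1 in all folds
  net_half <- consensus_network(sels, "positive", freq_threshold = 0.5)
  expect_identical(which(net_half$mask), 1L)         # edge 2,3 at 1/3 < 0.5
  expect_equal(net_half$edge_freq, c(1, 1 / 3, 1 / 3, 0, 0, 0))
  neg <- consensus_network(sels, "negative", freq_threshold = 0.5)
  expect_identical(which(neg$mask), 5L)
  expect_equal(neg$edge_freq[5], 2 / 3)
  expect_equal(neg$edge_weight[5], -0.5)             # mean r over selecting folds
  expect_warning(consensus_network(sels, "negative", freq_threshold = 1),
                 "empty consensus")
})

test_that("consensus frequency matches a brute-force tally and nests by threshold", {
  set.seed(101)
  E <- 30
  sels <- lapply(1:12, function(f)
    make_selection(E, pos = sample.int(E, 6), neg = numeric(0),
                   r = runif(E, -1, 1)))
  net <- suppressWarnings(consensus_network(sels, "positive", 0.4))
  brute <- numeric(E)
  for (s in sels) for (e in seq_len(E)) if (s$pos_mask[e])
    brute[e] <- brute[e] + 1 / 12
  expect_equal(net$edge_freq, brute)
  m_low <- suppressWarnings(consensus_network(sels, "positive", 0.25))$mask
  m_high <- suppressWarnings(consensus_network(sels, "positive", 0.75))$mask
  expect_true(all(m_high <= m_low))                  # nesting t1 <= t2
})

test_that("weighted degree sums incident edge weights (handshake lemma)", {
  pt <- toy_parcels()
  E <- choose(5, 2)
  pairs <- edge_pairs(5)
  sels <- list(make_selection(E, pos = c(edge_index(1, 2, 5),
                                         edge_index(1, 3, 5)),
                              neg = numeric(0),
                              r = rep(c(0.5, 0.25), c(1, E - 1))))
  net <- consensus_network(sels, "positive", 1, pairs = pairs)
  deg <- weighted_degree(net, pt)
  expect_equal(deg$degree[1], 0.75)
  expect_equal(deg$degree[2], 0.5)
  expect_equal(deg$degree[3], 0.25)
  expect_equal(deg$degree[4:5], c(0, 0))
  expect_identical(deg$rank[1], 1L)
  # handshake: sum of degrees = 2 * sum of masked weights
  expect_equal(sum(deg$degree), 2 * sum(abs(net$edge_weight[net$mask])),
               tolerance = 1e-10)
  # adjacency row-sum oracle on a random network
  set.seed(102)
  sels2 <- lapply(1:5, function(f)
    make_selection(E, pos = sample.int(E, 4), neg = sample.int(E, 2),
                   r = runif(E, -1, 1)))
  net2 <- suppressWarnings(consensus_network(sels2, "positive", 0.2,
                                             pairs = pairs))
  deg2 <- weighted_degree(net2, pt)
  adj <- matrix(0, 5, 5)
  for (e in which(net2$mask)) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    adj[i, j] <- adj[j, i] <- abs(net2$edge_weight[e])
  }
  expect_equal(deg2$degree, rowSums(adj), tolerance = 1e-12)
  # unit mode counts edges
  degu <- weighted_degree(net2, pt, weight_mode = "unit")
  expect_equal(degu$degree, rowSums(adj > 0))
})

test_that("top_nodes takes the ceiling fraction with deterministic ties", {
  pt <- parcel_table(sprintf("p%03d", 1:454),
                     rep(c("cerebellar", "cortical", "subcortical"),
                         times = c(40, 380, 34)))
  deg <- data.frame(parcel_id = pt$parcel_id, label = pt$label,
                    group = pt$group, hemisphere = pt$hemisphere,
                    degree = rep(1, 454))
  # 414 cerebral nodes at 5% -> ceil(20.7) = 21
  expect_identical(nrow(top_nodes(deg, "cerebral", 0.05)), 21L)
  # 40 cerebellar nodes at 5% -> ceil(2.0) = 2
  expect_identical(nrow(top_nodes(deg, "cerebellar", 0.05)), 2L)
  expect_identical(nrow(top_nodes(deg, "cerebellar", 1.0)), 40L)
  # all-tied degrees: selection falls back to ascending parcel id
  expect_identical(top_nodes(deg, "cerebellar", 0.05)$parcel_id, 1:2)
  expect_error(top_nodes(deg[deg$group == "cortical", ], "cerebellar", 0.05),
               class = "cerebcpm_config_error")
})

test_that("degree thresholding filters and sorts", {
  deg <- data.frame(parcel_id = 1:4, label = letters[1:4],
                    group = rep("cerebellar", 4),
                    hemisphere = rep("left", 4),
                    degree = c(0.2, 0.9, 0, 0.5))
  got <- degree_threshold_nodes(deg, "cerebellar", 0.4)
  expect_identical(got$parcel_id, c(2L, 4L))
  expect_identical(nrow(degree_threshold_nodes(deg, "cerebellar", 2)), 0L)
  expect_identical(nrow(degree_threshold_nodes(deg, "cerebellar", 0)), 4L)
})

test_that("overlap is mask multiplication: commutative, idempotent, monotone", {
  a <- c(TRUE, TRUE, FALSE); b <- c(TRUE, FALSE, FALSE)
  ov <- overlap_network(a, b)
  expect_identical(ov$mask, c(TRUE, FALSE, FALSE))
  expect_identical(ov$count, 1L)
  expect_identical(overlap_network(b, a)$mask, ov$mask)       # commutative
  expect_identical(overlap_network(a, a)$mask, a)             # idempotent
  expect_identical(overlap_network(a, !a)$count, 0L)          # disjoint
  set.seed(103)
  for (rep in 1:5) {
    x <- runif(20) < 0.5; y <- runif(20) < 0.5; z <- x & (runif(20) < 0.5)
    expect_identical(overlap_network(overlap_network(x, y)$mask, z)$mask,
                     overlap_network(x, overlap_network(y, z)$mask)$mask)
    expect_lte(overlap_network(z, y)$count, overlap_network(x, y)$count)
  }
  expect_error(overlap_network(a, c(TRUE, FALSE)),
               class = "cerebcpm_config_error")
})

test_that("hypergeometric overlap p matches exhaustive enumeration", {
  # single-draw sanity: |a| = |b| = 1 over universe 100
  a <- logical(100); a[7] <- TRUE
  expect_equal(overlap_significance(a, a)$p, 1 / 100)
  # certainty: both masks fill the universe
  full <- rep(TRUE, 8)
  expect_equal(overlap_significance(full, full)$p, 1)
  # enumeration oracle on small universes
  set.seed(104)
  for (rep in 1:6) {
    U <- sample(8:13, 1)
    am <- logical(U); am[sample.int(U, sample(2:4, 1))] <- TRUE
    bm <- logical(U); bm[sample.int(U, sample(2:5, 1))] <- TRUE
    got <- overlap_significance(am, bm)
    expect_equal(got$p, hyper_enum_oracle(am, sum(bm), got$overlap),
                 tolerance = 1e-12)
  }
  expect_error(overlap_significance(logical(5), full[1:5]),
               class = "cerebcpm_config_error")
  # permutation mode agrees roughly with the analytic tail
  am <- logical(40); am[1:10] <- TRUE
  bm <- logical(40); bm[5:16] <- TRUE
  ph <- overlap_significance(am, bm)$p
  pp <- overlap_significance(am, bm, m = 4000, seed = 9,
                             method = "permutation")$p
  expect_lt(abs(ph - pp), 0.05)
})

test_that("node ranking averages degrees over overlap networks", {
  pt <- toy_parcels()
  base <- data.frame(parcel_id = 1:5, label = pt$label, group = pt$group,
                     hemisphere = pt$hemisphere, degree = c(1, 2, 3, 4, 5))
  other <- base; other$degree <- c(5, 4, 3, 2, 1)
  single <- rank_nodes_over_overlaps(list(base))
  expect_equal(single$degree[order(single$parcel_id)], base$degree)
  dup <- rank_nodes_over_overlaps(list(base, base))
  expect_equal(dup$degree[order(dup$parcel_id)], base$degree)   # no-op
  avg <- rank_nodes_over_overlaps(list(base, other))
  expect_equal(avg$degree, rep(3, 5))
  expect_identical(avg$parcel_id, 1:5)          # tie-break by parcel id
  expect_error(rank_nodes_over_overlaps(list()))
})
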