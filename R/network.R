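# Consensus predictive networks, weighted-degree node ranking and overlap
# analysis between predictive networks.

#' Aggregate per-fold edge selections into a consensus network
#'
#' Computes, for every edge, the fraction of folds that selected it into
#' the network of the requested sign and the mean confound-adjusted `r`
#' over the folds that selected it; the consensus mask keeps edges whose
#' selection frequency reaches `freq_threshold`.
#'
#' @param x A `cpm_result` (its per-fold selections are used), or a list
#'   of `edge_selection` objects.
#' @param sign `"positive"` or `"negative"`.
#' @param freq_threshold Consensus threshold in (0, 1\]; 1 (default) keeps
#'   only edges selected in every fold.
#' @param pairs Optional E x 2 matrix of parcel endpoints per edge
#'   (taken from the dataset's edge mask when `x` is a `cpm_result` that
#'   carries one).
#' @return A `predictive_network`: `sign`, `edge_freq`, `edge_weight`,
#'   logical `mask`, and `pairs` if available.
#' @export
consensus_network <- function(x, sign = c("positive", "negative"),
                              freq_threshold = 1, pairs = NULL) {
  sign <- match.arg(sign)
  stopifnot(freq_threshold > 0, freq_threshold <= 1)
  if (inherits(x, "cpm_result")) {
    if (is.null(x$folds))
      stop("cpm_result was run with keep_folds = FALSE; no selections kept")
    selections <- lapply(Filter(function(f) is.null(f$error), x$folds),
                         `[[`, "selection")
    if (is.null(pairs) && !is.null(x$edge_mask))
      pairs <- masked_edge_pairs(x$edge_mask)
  } else {
    selections <- x
  }
  if (length(selections) == 0L) stop("no fold selections available")
  field <- if (sign == "positive") "pos_mask" else "neg_mask"
  sel_mat <- vapply(selections, `[[`, logical(length(selections[[1L]]$r)),
                    field)
  r_mat <- vapply(selections, `[[`, numeric(nrow(sel_mat)), "r")
  n_sel <- rowSums(sel_mat)
  edge_freq <- n_sel / ncol(sel_mat)
  edge_weight <- ifelse(n_sel > 0, rowSums(r_mat * sel_mat) / pmax(n_sel, 1), 0)
  mask <- edge_freq >= freq_threshold
  if (!any(mask))
    warning("empty consensus ", sign, " network at threshold ",
            freq_threshold)
  structure(list(sign = sign, edge_freq = edge_freq,
                 edge_weight = edge_weight, mask = mask,
                 freq_threshold = freq_threshold, pairs = pairs),
            class = "predictive_network")
}

#' @export
print.predictive_network <- function(x, ...) {
  cat(sprintf(
    "%s predictive network: %d of %d edges (consensus threshold %.2f)\n",
    x$sign, sum(x$mask), length(x$mask), x$freq_threshold))
  invisible(x)
}

net_pairs <- function(net, pairs = NULL) {
  pairs <- pairs %||% net$pairs
  if (is.null(pairs))
    stop("edge endpoints unknown; supply `pairs` (E x 2 matrix)")
  stopifnot(nrow(pairs) == length(net$mask))
  pairs
}

#' Weighted degree of every parcel in a predictive network
#'
#' The weighted degree of a node is the sum of the weights of all masked
#' edges incident to it. By default the weight is `|mean r|` so that
#' positive and negative networks are on a comparable scale;
#' `"freq"` uses the selection frequency and `"unit"` counts edges.
#'
#' @param net A [consensus_network()] result.
#' @param parcels The owning [parcel_table()].
#' @param weight_mode `"abs_r"` (default), `"freq"` or `"unit"`.
#' @param pairs Optional E x 2 endpoint matrix if `net` does not carry one.
#' @return A `node_degree_table` data frame: `parcel_id`, `label`,
#'   `group`, `hemisphere`, `degree`, `rank` (1 = highest degree, ties
#'   broken by parcel id).
#' @export
weighted_degree <- function(net, parcels,
                            weight_mode = c("abs_r", "freq", "unit"),
                            pairs = NULL) {
  weight_mode <- match.arg(weight_mode)
  pairs <- net_pairs(net, pairs)
  w <- switch(weight_mode,
              abs_r = abs(net$edge_weight),
              freq = net$edge_freq,
              unit = rep(1, length(net$mask)))
  w <- w * net$mask
  P <- nrow(parcels)
  degree <- numeric(P)
  on <- net$mask
  if (any(on)) {
    di <- tapply(w[on], pairs[on, 1L], sum)
    dj <- tapply(w[on], pairs[on, 2L], sum)
    degree[as.integer(names(di))] <- degree[as.integer(names(di))] + di
    degree[as.integer(names(dj))] <- degree[as.integer(names(dj))] + dj
  }
  out <- data.frame(parcel_id = parcels$parcel_id, label = parcels$label,
                    group = parcels$group, hemisphere = parcels$hemisphere,
                    degree = degree, stringsAsFactors = FALSE)
  out$rank <- rank_by_degree(out$degree, out$parcel_id)
  class(out) <- c("node_degree_table", "data.frame")
  out
}

# Dense ranks: highest degree first, ties broken by ascending parcel id.
rank_by_degree <- function(degree, parcel_id) {
  ord <- order(-degree, parcel_id)
  rk <- integer(length(degree))
  rk[ord] <- seq_along(degree)
  rk
}

# "cerebral" = everything non-cerebellar (cortical + subcortical).
filter_group <- function(df, group_filter) {
  group_filter <- match.arg(group_filter,
                            c("all", "cerebral", PARCEL_GROUPS))
  switch(group_filter,
         all = df,
         cerebral = df[df$group != "cerebellar", , drop = FALSE],
         df[df$group == group_filter, , drop = FALSE])
}

#' Top nodes of a group by weighted degree
#'
#' Ranks the nodes of a parcel group by weighted degree (descending, ties
#' broken by parcel id) and keeps the top `ceiling(fraction * group
#' size)`, e.g. the most relevant 5% of cerebral nodes.
#'
#' @param degrees A [weighted_degree()] table.
#' @param group_filter `"cerebral"` (non-cerebellar), `"cerebellar"`,
#'   `"cortical"`, `"subcortical"` or `"all"`.
#' @param fraction Fraction of the group to keep, in (0, 1\].
#' @return The selected rows, ranked.
#' @export
top_nodes <- function(degrees, group_filter = "cerebral", fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  sub <- filter_group(degrees, group_filter)
  if (nrow(sub) == 0L)
    stop_cerebcpm(paste("no parcels in group", group_filter),
                  "cerebcpm_config_error")
  sub <- sub[order(-sub$degree, sub$parcel_id), , drop = FALSE]
  utils::head(sub, ceiling(fraction * nrow(sub)))
}

#' Nodes of a group above a degree threshold
#'
#' Companion to [top_nodes()] for groups whose node count is chosen by
#' inspecting the degree distribution (e.g. cerebellar nodes): keeps all
#' nodes with `degree >= threshold`, sorted descending.
#'
#' @inheritParams top_nodes
#' @param threshold Non-negative degree cutoff.
#' @return The selected rows, sorted by degree descending.
#' @export
degree_threshold_nodes <- function(degrees, group_filter = "cerebellar",
                                   threshold = 0) {
  stopifnot(threshold >= 0)
  sub <- filter_group(degrees, group_filter)
  sub <- sub[sub$degree >= threshold, , drop = FALSE]
  sub[order(-sub$degree, sub$parcel_id), , drop = FALSE]
}

#' Overlap of two predictive networks
#'
#' Element-wise AND (mask multiplication) of two edge masks over the same
#' edge universe.
#'
#' @param a,b `predictive_network` objects or logical edge masks.
#' @return List with the logical `mask`, the overlap `count`, and `pairs`
#'   when available.
#' @export
overlap_network <- function(a, b) {
  ma <- if (inherits(a, "predictive_network")) a$mask else as.logical(a)
  mb <- if (inherits(b, "predictive_network")) b$mask else as.logical(b)
  if (length(ma) != length(mb))
    stop_cerebcpm("edge universes differ in size", "cerebcpm_config_error")
  pairs <- if (inherits(a, "predictive_network")) a$pairs
           else if (inherits(b, "predictive_network")) b$pairs
  mask <- ma & mb
  list(mask = mask, count = sum(mask), pairs = pairs)
}

#' Significance of a network overlap
#'
#' Probability of an overlap at least as large as observed if the two
#' edge sets were placed independently in the edge universe. The default
#' is the hypergeometric upper tail; `method = "permutation"` instead
#' shuffles one mask's edge positions `m` times.
#'
#' @param a_mask,b_mask Logical edge masks (or `predictive_network`s) over
#'   the same universe.
#' @param m Permutations for `method = "permutation"`.
#' @param seed Seed for the permutation mode.
#' @param method `"hypergeometric"` (default) or `"permutation"`.
#' @return List: `p`, `overlap`, `method`, sizes of both masks and of the
#'   universe.
#' @export
overlap_significance <- function(a_mask, b_mask, m = 1000L, seed = 1L,
                                 method = c("hypergeometric",
                                            "permutation")) {
  method <- match.arg(method)
  ma <- if (inherits(a_mask, "predictive_network")) a_mask$mask
        else as.logical(a_mask)
  mb <- if (inherits(b_mask, "predictive_network")) b_mask$mask
        else as.logical(b_mask)
  if (length(ma) != length(mb))
    stop_cerebcpm("edge universes differ in size", "cerebcpm_config_error")
  U <- length(ma); na <- sum(ma); nb <- sum(mb)
  if (na == 0L || nb == 0L)
    stop_cerebcpm("overlap significance undefined for an empty mask",
                  "cerebcpm_config_error")
  obs <- sum(ma & mb)
  p <- if (method == "hypergeometric") {
    stats::phyper(obs - 1L, na, U - na, nb, lower.tail = FALSE)
  } else {
    null_overlap <- with_seed(seed, vapply(seq_len(m), function(b)
      sum(ma & mb[sample.int(U)]), numeric(1)))
    sum(null_overlap >= obs) / m
  }
  list(p = p, overlap = obs, method = method,
       n_a = na, n_b = nb, universe = U)
}

#' Rank nodes by degree averaged over overlap networks
#'
#' Averages per-node weighted degrees across several networks (typically
#' the overlap networks of one measure with several related measures) and
#' re-ranks.
#'
#' @param degree_tables Non-empty list of [weighted_degree()] tables over
#'   the same parcellation.
#' @return A `node_degree_table` with the mean `degree` and fresh `rank`.
#' @export
rank_nodes_over_overlaps <- function(degree_tables) {
  if (length(degree_tables) == 0L)
    stop("need at least one degree table")
  ids <- degree_tables[[1L]]$parcel_id
  for (dt in degree_tables)
    if (!identical(dt$parcel_id, ids))
      stop("degree tables are not over the same parcellation")
  out <- degree_tables[[1L]]
  out$degree <- rowMeans(vapply(degree_tables, `[[`, numeric(length(ids)),
                                "degree"))
  out$rank <- rank_by_degree(out$degree, out$parcel_id)
  out[order(out$rank), , drop = FALSE]
}

#' Export a predictive network as an edge list
#'
#' @param net A [consensus_network()] result (must carry edge endpoints).
#' @param parcels The owning [parcel_table()].
#' @param path Optional TSV output path.
#' @return Data frame `parcel_i`, `parcel_j`, `label_i`, `label_j`,
#'   `weight`, `freq` for the masked edges; written to `path` if given.
#' @export
network_edge_list <- function(net, parcels, path = NULL) {
  pairs <- net_pairs(net)
  on <- which(net$mask)
  df <- data.frame(parcel_i = pairs[on, 1L], parcel_j = pairs[on, 2L],
                   label_i = parcels$label[pairs[on, 1L]],
                   label_j = parcels$label[pairs[on, 2L]],
                   weight = net$edge_weight[on], freq = net$edge_freq[on],
                   stringsAsFactors = FALSE)
  df <- df[order(-abs(df$weight)), , drop = FALSE]
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  df
}
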