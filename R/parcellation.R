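# Grouped whole-brain parcellation and the connection-of-interest (COI)
# edge universe.
#
# Parcels are graph nodes; an edge is the connectivity value of an unordered
# parcel pair. All edge vectors in the package share one canonical order:
# the row-major upper triangle of the parcel x parcel matrix, diagonal
# excluded. Parcel ids and edge positions are 1-based.

PARCEL_GROUPS <- c("cerebellar", "cortical", "subcortical")
HEMISPHERES <- c("left", "right", "midline", "unknown")

#' Construct a parcellation table
#'
#' Defines the node universe of all analyses: one row per parcel, with a
#' group label (`cerebellar`, `cortical`, `subcortical`) used to build the
#' connection-of-interest mask, and an optional hemisphere and MNI
#' coordinates used only for reporting.
#'
#' @param label Character vector of parcel names.
#' @param group Character vector; one of `"cerebellar"`, `"cortical"`,
#'   `"subcortical"` per parcel.
#' @param hemisphere Optional character vector (`"left"`, `"right"`,
#'   `"midline"`, `"unknown"`); defaults to `"unknown"`.
#' @param mni Optional numeric matrix (P x 3) of MNI millimetre coordinates.
#' @return A `parcel_table` data frame with columns `parcel_id` (1..P),
#'   `label`, `group`, `hemisphere`, `mni_x`, `mni_y`, `mni_z`.
#' @examples
#' parcel_table(label = c("CbL1", "CtxL1", "ScL1"),
#'              group = c("cerebellar", "cortical", "subcortical"))
#' @export
parcel_table <- function(label, group, hemisphere = NULL, mni = NULL) {
  P <- length(label)
  if (P < 2L) stop("a parcellation needs at least two parcels")
  if (length(group) != P) stop("`group` must match `label` in length")
  group <- as.character(group)
  bad <- setdiff(unique(group), PARCEL_GROUPS)
  if (length(bad) > 0L)
    stop("unknown parcel group(s): ", paste(bad, collapse = ", "))
  if (is.null(hemisphere)) hemisphere <- rep("unknown", P)
  hemisphere <- as.character(hemisphere)
  if (!all(hemisphere %in% HEMISPHERES))
    stop("hemisphere must be one of: ", paste(HEMISPHERES, collapse = ", "))
  if (is.null(mni)) {
    mni <- matrix(NA_real_, P, 3L)
  } else {
    mni <- as.matrix(mni)
    stopifnot(nrow(mni) == P, ncol(mni) == 3L)
  }
  out <- data.frame(
    parcel_id = seq_len(P),
    label = as.character(label),
    group = group,
    hemisphere = hemisphere,
    mni_x = mni[, 1L], mni_y = mni[, 2L], mni_z = mni[, 3L],
    stringsAsFactors = FALSE
  )
  class(out) <- c("parcel_table", "data.frame")
  out
}

#' @export
print.parcel_table <- function(x, ...) {
  cat(sprintf("Parcellation: %d parcels (%s)\n", nrow(x),
              paste(sprintf("%d %s", table(factor(x$group, PARCEL_GROUPS)),
                            PARCEL_GROUPS), collapse = ", ")))
  NextMethod()
}

#' Read a parcellation table from a delimited file
#'
#' Expects columns `id`, `label`, `group`, `hemisphere` and optionally
#' `mni_x`, `mni_y`, `mni_z`. Tab- or comma-separated, inferred from the
#' file extension.
#'
#' @param path Path to a TSV/CSV file.
#' @param zero_based If `TRUE`, ids in the file run 0..P-1 and are shifted
#'   to the package's 1-based convention.
#' @return A [parcel_table()].
#' @export
read_parcellation <- function(path, zero_based = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("id", "label", "group")
  if (!all(need %in% names(df)))
    stop("parcellation file must have columns: ", paste(need, collapse = ", "))
  ids <- df$id + if (zero_based) 1L else 0L
  df <- df[order(ids), , drop = FALSE]
  ids <- sort(ids)
  if (!identical(as.integer(ids), seq_len(nrow(df))))
    stop("parcel ids must be contiguous and unique (use zero_based = TRUE ",
         "for 0-based tables)")
  mni <- if (all(c("mni_x", "mni_y", "mni_z") %in% names(df)))
    cbind(as.numeric(df$mni_x), as.numeric(df$mni_y), as.numeric(df$mni_z))
  parcel_table(df$label, df$group,
               hemisphere = if ("hemisphere" %in% names(df)) df$hemisphere,
               mni = mni)
}

#' Write a parcellation table to TSV
#' @param parcels A [parcel_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parcels, path) {
  df <- as.data.frame(parcels)
  names(df)[names(df) == "parcel_id"] <- "id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fingerprint of the node universe, stamped into exported masks/results so
# that edge vectors are never combined across different parcellations.
parcellation_hash <- function(parcels) {
  fnv1a_hash(paste(parcels$parcel_id, parcels$label, parcels$group,
                   collapse = ";"))
}

#' Canonical edge position of a parcel pair
#'
#' Maps an unordered parcel pair to its position in the canonical edge
#' order: row-major upper triangle of the P x P matrix, diagonal excluded,
#' positions 1..P(P-1)/2. Vectorized over `i` and `j`.
#'
#' @param i,j Parcel ids in 1..P; `i != j`. Order is irrelevant.
#' @param P Number of parcels.
#' @return Integer edge position(s).
#' @examples
#' edge_index(1, 2, P = 4)  # 1, the first upper-triangle entry
#' edge_index(3, 4, P = 4)  # 6 = choose(4, 2), the last entry
#' @export
edge_index <- function(i, j, P) {
  i <- as.integer(i); j <- as.integer(j); P <- as.integer(P)
  if (any(i < 1L | i > P | j < 1L | j > P))
    stop_cerebcpm("parcel id out of range 1..P", "cerebcpm_index_error")
  if (any(i == j))
    stop_cerebcpm("self-edges (i == j) are not part of the edge universe",
                  "cerebcpm_invalid_edge")
  lo <- pmin(i, j); hi <- pmax(i, j)
  # entries before row `lo`: sum_{r < lo} (P - r), rows 1-based
  before <- (lo - 1L) * P - (lo - 1L) * lo / 2
  as.integer(before + (hi - lo))
}

#' All parcel pairs in canonical edge order
#'
#' @param P Number of parcels.
#' @return Integer matrix with P(P-1)/2 rows and columns `i`, `j` (`i < j`),
#'   row `k` being the endpoints of edge position `k`.
#' @export
edge_pairs <- function(P) {
  P <- as.integer(P)
  stopifnot(P >= 2L)
  i <- rep.int(seq_len(P - 1L), times = (P - 1L):1L)
  j <- sequence((P - 1L):1L, from = 2:P)
  cbind(i = i, j = j)
}

#' Recover the parcel pair of an edge position
#' @param k Edge position(s) in 1..P(P-1)/2.
#' @param P Number of parcels.
#' @return Integer matrix with columns `i`, `j`.
#' @export
edge_pair <- function(k, P) {
  pairs <- edge_pairs(P)
  k <- as.integer(k)
  if (any(k < 1L | k > nrow(pairs)))
    stop_cerebcpm("edge position out of range", "cerebcpm_index_error")
  pairs[k, , drop = FALSE]
}

new_edge_mask <- function(bits, parcels, kind) {
  structure(list(bits = as.logical(bits), P = nrow(parcels), kind = kind,
                 parcellation = parcellation_hash(parcels)),
            class = "edge_mask")
}

#' Build the connection-of-interest (COI) edge mask
#'
#' Restricts the edge universe to cerebellocerebral edges (one cerebellar
#' endpoint) and, by default, cerebellocerebellar edges (both endpoints
#' cerebellar). Edges between two non-cerebellar parcels are never of
#' interest.
#'
#' @param parcels A [parcel_table()] with at least one cerebellar and one
#'   non-cerebellar parcel.
#' @param include_intracerebellar Keep edges with two cerebellar endpoints
#'   (default `TRUE`).
#' @return An `edge_mask`: logical `bits` over the canonical edge order plus
#'   the owning parcel count `P`.
#' @examples
#' pt <- parcel_table(paste0("p", 1:5),
#'                    c("cerebellar", "cerebellar", rep("cortical", 3)))
#' sum(build_coi_mask(pt)$bits)                                   # 7
#' sum(build_coi_mask(pt, include_intracerebellar = FALSE)$bits)  # 6
#' @export
build_coi_mask <- function(parcels, include_intracerebellar = TRUE) {
  is_cb <- parcels$group == "cerebellar"
  if (!any(is_cb))
    stop_cerebcpm("COI mask needs at least one cerebellar parcel",
                  "cerebcpm_config_error")
  if (all(is_cb))
    stop_cerebcpm("COI mask needs at least one non-cerebellar parcel",
                  "cerebcpm_config_error")
  pr <- edge_pairs(nrow(parcels))
  n_cb <- is_cb[pr[, "i"]] + is_cb[pr[, "j"]]
  bits <- if (include_intracerebellar) n_cb >= 1L else n_cb == 1L
  new_edge_mask(bits, parcels, "coi")
}

#' Build the whole-brain edge mask
#'
#' All P(P-1)/2 edges, for whole-brain (unrestricted) analyses.
#'
#' @inheritParams build_coi_mask
#' @return An `edge_mask` with every bit set.
#' @export
build_full_mask <- function(parcels) {
  new_edge_mask(rep(TRUE, nrow(parcels) * (nrow(parcels) - 1L) / 2),
                parcels, "full")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("Edge mask (%s): %d of %d edges over %d parcels\n",
              x$kind, sum(x$bits), length(x$bits), x$P))
  invisible(x)
}

#' Vectorize a symmetric matrix in canonical edge order
#'
#' Extracts the row-major upper triangle (diagonal excluded), optionally
#' restricted to a mask's edges.
#'
#' @param mat Symmetric P x P matrix (or a [conn_matrix()]).
#' @param mask Optional `edge_mask`; keep only its edges.
#' @return Numeric vector of edge values.
#' @export
vectorize_edges <- function(mat, mask = NULL) {
  m <- conn_values(mat)
  v <- t(m)[lower.tri(m)]  # row-major upper triangle
  if (!is.null(mask)) {
    if (length(mask$bits) != length(v))
      stop("mask and matrix edge universes differ")
    v <- v[mask$bits]
  }
  v
}

#' Endpoints of the edges retained by a mask
#' @param mask An `edge_mask`.
#' @return Integer matrix, columns `i`, `j`: one row per retained edge, in
#'   canonical order.
#' @export
masked_edge_pairs <- function(mask) {
  edge_pairs(mask$P)[mask$bits, , drop = FALSE]
}
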