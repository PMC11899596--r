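# Synthetic connectome generator: subject covariances with planted
# positive/negative predictive COI edges, confound structure and family
# clustering, plus recovery metrics against the planted ground truth.

#' Specification of a synthetic connectome study
#'
#' Defines the conditions under which the pipeline is exercised. The
#' defaults describe a desk-scale study: 300 subjects, a 44-parcel
#' parcellation (10 cerebellar, 30 cortical, 4 subcortical), 200
#' timepoints, 15 positive and 15 negative planted COI edges, and 60
#' families.
#'
#' Each subject's covariance is
#' `Sigma_i = Sigma_0 + effect_size * y_i * (sum_pos Delta_e - sum_neg Delta_e)`
#' with `y_i` the standardized latent trait and `Delta_e` the symmetric
#' unit indicator of edge `e`; time series are drawn from
#' `N(0, Sigma_i)`. The observed target adds a confound channel and
#' measurement noise to `y`. Families cluster both the trait
#' (`family_trait_icc`) and, via shared offsets on measured edge values,
#' the connectome (`family_edge_sd`); together these two make the
#' relative-exclusion step consequential, since spurious family-level
#' edge-trait associations then genuinely transfer between relatives.
#'
#' @param n_subjects Number of subjects.
#' @param parcels Named integer vector: counts of `cerebellar`,
#'   `cortical`, `subcortical` parcels.
#' @param n_timepoints Timepoints per subject.
#' @param n_pos_edges,n_neg_edges Planted COI edge counts per sign.
#' @param effect_size Covariance shift per unit standardized trait on each
#'   planted edge (default 0.1, a strong effect at the default scale:
#'   planted edge-target correlations around 0.6, and small enough that
#'   subject covariances stay SPD without material eigenvalue flooring
#'   even for traits several SDs from the mean).
#' @param noise_sd SD of target measurement noise (target scale; trait is
#'   standardized).
#' @param confound_strength Correlation of the latent confound score with
#'   the trait, and its coefficient in the observed target.
#' @param n_families Number of families (members assigned round-robin).
#' @param family_trait_icc Between-family share of trait variance, in
#'   \[0, 1).
#' @param family_edge_sd SD of family-shared offsets added to measured COI
#'   edge values (0 disables the family connectome channel).
#' @param include_intracerebellar Plant and analyse intracerebellar edges
#'   too (default `TRUE`).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 300L,
                           parcels = c(cerebellar = 10L, cortical = 30L,
                                       subcortical = 4L),
                           n_timepoints = 200L,
                           n_pos_edges = 15L, n_neg_edges = 15L,
                           effect_size = 0.1, noise_sd = 0.3,
                           confound_strength = 0.2,
                           n_families = 60L, family_trait_icc = 0,
                           family_edge_sd = 0.1,
                           include_intracerebellar = TRUE,
                           seed = 1L) {
  stopifnot(n_subjects >= 6L, n_timepoints >= 2L,
            all(parcels >= c(1L, 1L, 0L)),
            n_pos_edges >= 0L, n_neg_edges >= 0L,
            effect_size >= 0, noise_sd >= 0,
            family_trait_icc >= 0, family_trait_icc < 1,
            family_edge_sd >= 0, n_families >= 1L)
  structure(list(n_subjects = as.integer(n_subjects),
                 parcels = parcels, n_timepoints = as.integer(n_timepoints),
                 n_pos_edges = as.integer(n_pos_edges),
                 n_neg_edges = as.integer(n_neg_edges),
                 effect_size = effect_size, noise_sd = noise_sd,
                 confound_strength = confound_strength,
                 n_families = as.integer(n_families),
                 family_trait_icc = family_trait_icc,
                 family_edge_sd = family_edge_sd,
                 include_intracerebellar = isTRUE(include_intracerebellar),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

synthetic_parcels <- function(spec) {
  counts <- spec$parcels
  label <- c(sprintf("Cb%02d", seq_len(counts[["cerebellar"]])),
             sprintf("Ctx%02d", seq_len(counts[["cortical"]])),
             if (counts[["subcortical"]] > 0L)
               sprintf("Sc%02d", seq_len(counts[["subcortical"]])))
  group <- rep(PARCEL_GROUPS, times = counts[PARCEL_GROUPS])
  hemi <- rep_len(c("left", "right"), length(label))
  parcel_table(label, group, hemisphere = hemi)
}

#' Generate a synthetic connectome dataset
#'
#' Draws family-clustered latent traits, plants the trait linearly into
#' randomly chosen COI edges of each subject's covariance (projected back
#' to SPD by eigenvalue flooring where needed), simulates Gaussian time
#' series, measures edge vectors as empirical covariances over the COI
#' universe, adds family-shared edge offsets, and builds the observed
#' target and confound table.
#'
#' @param spec A [synthetic_spec()].
#' @param keep_timeseries Also return the per-subject time-series matrices
#'   (default `FALSE`; they are large).
#' @return List with components
#'   \describe{
#'     \item{dataset}{a [subject_dataset()] ready for [run_cpm()];}
#'     \item{truth}{a `ground_truth`: `pos_edges`, `neg_edges` (COI edge
#'       positions), latent `trait`, `family_id`;}
#'     \item{parcels}{the [parcel_table()];}
#'     \item{coi_mask}{the COI `edge_mask`;}
#'     \item{confound_table}{the raw (un-encoded) confound data frame;}
#'     \item{timeseries}{list of T x P matrices if requested.}
#'   }
#' @export
generate_dataset <- function(spec, keep_timeseries = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  parcels <- synthetic_parcels(spec)
  P <- nrow(parcels)
  coi <- build_coi_mask(parcels, spec$include_intracerebellar)
  coi_pos <- which(coi$bits)        # full-universe indices of COI edges
  E <- length(coi_pos)
  if (spec$n_pos_edges + spec$n_neg_edges > E)
    stop("more planted edges than COI edges")
  pairs_all <- edge_pairs(P)
  N <- spec$n_subjects
  with_seed(spec$seed, {
    planted <- sample.int(E, spec$n_pos_edges + spec$n_neg_edges)
    pos_edges <- sort(planted[seq_len(spec$n_pos_edges)])
    neg_edges <- sort(planted[spec$n_pos_edges + seq_len(spec$n_neg_edges)])

    family_id <- sprintf("fam%03d", rep_len(seq_len(spec$n_families), N))
    fam_idx <- rep_len(seq_len(spec$n_families), N)
    f <- stats::rnorm(spec$n_families)
    y <- sqrt(spec$family_trait_icc) * f[fam_idx] +
      sqrt(1 - spec$family_trait_icc) * stats::rnorm(N)

    # confounds: latent score c correlated with the trait; observed as one
    # binary, one continuous and one 3-level categorical column
    rho <- spec$confound_strength
    cscore <- rho * y + sqrt(max(0, 1 - rho^2)) * stats::rnorm(N)
    gender <- ifelse(cscore + stats::rnorm(N) > 0, "F", "M")
    age <- 28 + 3 * (0.5 * cscore + stats::rnorm(N))
    ethnicity <- c("A", "B", "C")[1L +
      findInterval(0.3 * cscore + stats::rnorm(N),
                   stats::qnorm(c(1 / 3, 2 / 3), sd = sqrt(1.09)))]
    target <- y + rho * cscore + spec$noise_sd * stats::rnorm(N)

    # base covariance: unit variances, mild uniform background coupling
    Sigma0 <- matrix(0.1, P, P); diag(Sigma0) <- 1
    delta <- matrix(0, P, P)  # signed planted-edge indicator
    for (e in coi_pos[pos_edges]) {
      i <- pairs_all[e, 1L]; j <- pairs_all[e, 2L]
      delta[i, j] <- delta[i, j] + 1; delta[j, i] <- delta[i, j]
    }
    for (e in coi_pos[neg_edges]) {
      i <- pairs_all[e, 1L]; j <- pairs_all[e, 2L]
      delta[i, j] <- delta[i, j] - 1; delta[j, i] <- delta[i, j]
    }

    edges <- matrix(NA_real_, N, E)
    ts_list <- if (keep_timeseries) vector("list", N)
    for (s in seq_len(N)) {
      Sig <- Sigma0 + spec$effect_size * y[s] * delta
      ev <- eigen(Sig, symmetric = TRUE)
      lmax <- max(ev$values)
      floor_val <- 1e-6 * lmax
      if (min(ev$values) < floor_val) {
        lift <- floor_val - min(ev$values)
        if (lift > 0.1 * lmax)
          stop_cerebcpm(
            "SPD projection would alter eigenvalues by > 10% of lambda_max; lower effect_size",
            "cerebcpm_config_error")
        Sig <- sym_from_eigen(ev, function(v) pmax(v, floor_val))
      }
      ts <- matrix(stats::rnorm(spec$n_timepoints * P),
                   spec$n_timepoints, P) %*% chol(Sig)
      edges[s, ] <- vectorize_edges(stats::cov(ts), coi)
      if (keep_timeseries) ts_list[[s]] <- ts
    }
    if (spec$family_edge_sd > 0) {
      fam_offsets <- matrix(stats::rnorm(spec$n_families * E,
                                         sd = spec$family_edge_sd),
                            spec$n_families, E)
      edges <- edges + fam_offsets[fam_idx, , drop = FALSE]
    }

    confound_table <- data.frame(gender = gender, age = age,
                                 ethnicity = ethnicity,
                                 stringsAsFactors = FALSE)
    dataset <- subject_dataset(edges, target,
                               confounds = encode_confounds(confound_table),
                               family_id = family_id, edge_mask = coi)
    truth <- structure(list(pos_edges = pos_edges, neg_edges = neg_edges,
                            trait = y, family_id = family_id),
                       class = "ground_truth")
    list(dataset = dataset, truth = truth, parcels = parcels,
         coi_mask = coi, confound_table = confound_table,
         timeseries = if (keep_timeseries) ts_list)
  })
}

set_metrics <- function(selected, truth_set) {
  inter <- length(intersect(selected, truth_set))
  union <- length(union(selected, truth_set))
  c(precision = if (length(selected)) inter / length(selected) else 0,
    recall = inter / length(truth_set),
    jaccard = if (union) inter / union else 0)
}

#' Recovery of planted edges by a consensus selection
#'
#' Standard set-overlap metrics (precision, recall, Jaccard) of selected
#' versus planted edge sets, per sign.
#'
#' @param pos_selected,neg_selected Selected edges: logical masks over the
#'   COI universe or integer COI edge positions (e.g. the masks of
#'   [consensus_network()] results).
#' @param truth The `ground_truth` from [generate_dataset()].
#' @return Data frame with rows `positive`, `negative` and columns
#'   `precision`, `recall`, `jaccard`.
#' @export
recovery_report <- function(pos_selected, neg_selected, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(truth$pos_edges) == 0L && length(truth$neg_edges) == 0L)
    stop("ground truth contains no planted edges")
  as_idx <- function(x) if (is.logical(x)) which(x) else as.integer(x)
  out <- rbind(positive = set_metrics(as_idx(pos_selected), truth$pos_edges),
               negative = set_metrics(as_idx(neg_selected), truth$neg_edges))
  as.data.frame(out)
}
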