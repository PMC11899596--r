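# Delimited-text round-tripping for time series, phenotypes, masks and
# CPM results.

#' Read a parcellated time-series table
#'
#' Delimited numeric table, timepoints x parcels, tab- or comma-separated
#' (inferred from the extension), header optional.
#'
#' @param path File path.
#' @return Numeric matrix (T x P).
#' @export
read_timeseries <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  header <- anyNA(suppressWarnings(as.numeric(first)))
  m <- as.matrix(utils::read.table(path, header = header, sep = sep))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (!is_finite_num(m)) stop("time series file contains non-finite values")
  m
}

#' Write a parcellated time-series table as TSV
#' @param ts T x P numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(format(ts, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with one row per subject: a subject id column, the target measure,
#' the declared confound columns and a family column.
#'
#' @param path CSV path.
#' @param target Name of the target column.
#' @param confounds Character vector of confound column names (may be
#'   empty).
#' @param family Name of the family column, or `NULL` for singleton
#'   families.
#' @param subject Name of the subject id column.
#' @return Data frame with standardized columns `subject`, `target`,
#'   `family` plus the confound columns.
#' @export
read_phenotype <- function(path, target = "target",
                           confounds = c("gender", "age", "ethnicity"),
                           family = "family", subject = "subject") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(subject, target, confounds, family)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("phenotype file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(subject = as.character(df[[subject]]),
                    target = as.numeric(df[[target]]),
                    stringsAsFactors = FALSE)
  for (cc in confounds) out[[cc]] <- df[[cc]]
  out$family <- if (is.null(family)) out$subject else as.character(df[[family]])
  attr(out, "confound_cols") <- confounds
  out
}

#' Write predictions of a CPM run as TSV
#'
#' Columns: subject, observed, predicted, fold.
#'
#' @param result A `cpm_result`.
#' @param path Output path.
#' @return The data frame written, invisibly.
#' @export
write_predictions <- function(result, path) {
  df <- data.frame(subject = result$subject_ids,
                   observed = result$observed,
                   predicted = result$predictions,
                   fold = result$fold_plan$assignment,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# Serializable summary of a cpm_result: parameters, evaluation, per-fold
# models and selections (as COI edge-position lists with their r values),
# and the COI universe (full-universe edge indices) when known.
cpm_result_to_list <- function(result) {
  folds <- NULL
  if (!is.null(result$folds)) {
    folds <- lapply(result$folds, function(f) {
      if (!is.null(f$error)) return(list(error = f$error))
      sel <- f$selection
      pos <- which(sel$pos_mask); neg <- which(sel$neg_mask)
      list(beta0 = f$model$beta0, beta_pos = f$model$beta_pos,
           beta_neg = f$model$beta_neg, flag = f$model$flag,
           pos_edges = pos, pos_r = sel$r[pos],
           neg_edges = neg, neg_r = sel$r[neg],
           excluded_train_ids = f$excluded_train_ids)
    })
  }
  list(r_eval = result$r_eval, params = result$params,
       n_failed_folds = result$n_failed_folds,
       fold_assignment = result$fold_plan$assignment,
       coi_edges = if (!is.null(result$edge_mask)) which(result$edge_mask$bits),
       n_parcels = if (!is.null(result$edge_mask)) result$edge_mask$P,
       folds = folds)
}

#' Serialize a CPM result to JSON
#' @param result A `cpm_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpm_result <- function(result, path) {
  jsonlite::write_json(cpm_result_to_list(result), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Rebuild per-fold edge selections from a serialized CPM result
#'
#' Returns objects usable by [consensus_network()]; `r` is zero outside
#' the selected edges (consensus weights only average over selecting
#' folds, so this is lossless).
#'
#' @param path Path to a JSON written by [write_cpm_result()].
#' @return List with `selections`, `n_edges`, `pairs` (endpoints of the
#'   COI edges, or `NULL`), `r_eval`, `params`.
#' @export
read_cpm_selections <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  n_edges <- js$params$n_edges
  folds <- js$folds
  if (is.null(folds)) stop("serialized result contains no fold selections")
  n_folds <- if (is.data.frame(folds)) nrow(folds) else length(folds)
  selections <- lapply(seq_len(n_folds), function(f) {
    fd <- if (is.data.frame(folds)) lapply(folds, `[[`, f) else folds[[f]]
    if (!is.null(fd$error) && !is.na(fd$error %||% NA)) return(NULL)
    r <- numeric(n_edges)
    pos <- as.integer(unlist(fd$pos_edges))
    neg <- as.integer(unlist(fd$neg_edges))
    r[pos] <- unlist(fd$pos_r); r[neg] <- unlist(fd$neg_r)
    structure(list(r = r, p = NULL,
                   pos_mask = seq_len(n_edges) %in% pos,
                   neg_mask = seq_len(n_edges) %in% neg),
              class = "edge_selection")
  })
  selections <- Filter(Negate(is.null), selections)
  pairs <- NULL
  if (!is.null(js$coi_edges) && !is.null(js$n_parcels))
    pairs <- edge_pairs(js$n_parcels)[as.integer(js$coi_edges), ,
                                      drop = FALSE]
  list(selections = selections, n_edges = n_edges, pairs = pairs,
       r_eval = js$r_eval, params = js$params)
}

#' Write an edge mask as a 0/1 text vector
#'
#' One value per line, in canonical edge order (or consensus-network mask
#' order), with a `#`-comment header carrying the parcellation hash when
#' known.
#'
#' @param mask Logical vector, `edge_mask` or `predictive_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  hash <- NULL
  bits <- if (inherits(mask, "edge_mask")) {
    hash <- mask$parcellation
    mask$bits
  } else if (inherits(mask, "predictive_network")) mask$mask
  else as.logical(mask)
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# parcellation: ", hash), con)
  writeLines(as.character(as.integer(bits)), con)
  invisible(path)
}

#' Read a 0/1 edge-mask vector written by [write_mask()]
#' @param path File path.
#' @return Logical vector.
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  as.integer(lines) > 0L
}

#' Write a null distribution as a single-column TSV
#' @param perm A `perm_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_null_distribution <- function(perm, path) {
  utils::write.table(data.frame(null_r = perm$null_r), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a permutation-test summary to JSON
#' @param perm A `perm_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_perm_summary <- function(perm, path) {
  jsonlite::write_json(list(observed_r = perm$observed_r, m = perm$m,
                            p = perm$p, seed = perm$seed,
                            estimator = perm$estimator),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
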