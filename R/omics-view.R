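#' Construct an omics view
#'
#' An omics view holds one modality's sample-by-feature numeric matrix
#' together with its sample and feature identifiers and a flag recording
#' whether the matrix has been normalized.
#'
#' @param matrix Numeric matrix, samples in rows. Row names are taken as
#'   sample identifiers and column names as feature identifiers; both are
#'   required and must be unique.
#' @param modality One of `"mrna"`, `"methylation"`, `"mirna"`, or any other
#'   short modality label.
#' @param normalized Logical; `TRUE` once the view has been z-scored.
#' @return An object of class `omics_view`.
#' @export
omics_view <- function(matrix, modality, normalized = FALSE) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix")
  }
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) {
    stop("empty omics matrix (", nrow(matrix), " x ", ncol(matrix), ")")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("omics matrix requires row names (samples) and column names (features)")
  }
  if (anyDuplicated(rownames(matrix))) stop("duplicate sample ids in omics matrix")
  if (anyDuplicated(colnames(matrix))) stop("duplicate feature ids in omics matrix")
  if (normalized && !all(is.finite(matrix))) {
    stop("normalized omics matrix contains non-finite values")
  }
  structure(
    list(
      modality = as.character(modality)[1],
      matrix = matrix,
      normalized = isTRUE(normalized)
    ),
    class = "omics_view"
  )
}

#' @export
print.omics_view <- function(x, ...) {
  cat(sprintf(
    "<omics_view> modality=%s  %d samples x %d features  normalized=%s\n",
    x$modality, nrow(x$matrix), ncol(x$matrix), x$normalized
  ))
  invisible(x)
}

sample_ids <- function(view) rownames(view$matrix)
feature_names <- function(view) colnames(view$matrix)

# population (1/n) column variances; the ranking is invariant to the
# 1/n vs 1/(n-1) choice but the z-score contract fixes 1/n
col_pop_var <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  colMeans(m * m) - mu * mu
}

#' Normalize an omics view
#'
#' Applies an optional `log2(x + 1)` transform (expression modalities)
#' followed by per-feature z-scoring across samples,
#' `(x - mu) / (sigma + epsilon)`, with `sigma` the population (1/n)
#' standard deviation. Constant features map to all-zero columns because of
#' the epsilon guard. DNA methylation beta-values are normalized with
#' `log_transform = FALSE`.
#'
#' @param view An [omics_view()].
#' @param log_transform Apply `log2(x + 1)` before standardization.
#' @param epsilon Small positive constant added to the standard deviation.
#' @param stats Optional `norm_stats` from a previous call; when supplied the
#'   stored transform is replayed (e.g. on test samples) instead of being
#'   re-estimated, so no information leaks from the new samples.
#' @return A list with elements `view` (normalized [omics_view()]) and
#'   `stats` (a `norm_stats` object with `mu`, `sigma`, `epsilon`,
#'   `log_transform`).
#' @export
normalize_view <- function(view, log_transform = FALSE, epsilon = 1e-8,
                           stats = NULL) {
  stopifnot(inherits(view, "omics_view"))
  x <- view$matrix
  if (is.null(stats)) {
    if (nrow(x) < 2L) stop("normalization requires at least 2 samples")
    if (!(epsilon > 0)) stop("`epsilon` must be > 0")
  } else {
    stopifnot(inherits(stats, "norm_stats"))
    log_transform <- stats$log_transform
    epsilon <- stats$epsilon
    if (!identical(names(stats$mu), colnames(x))) {
      stop("feature names do not match the stored normalization stats")
    }
  }
  if (log_transform) {
    if (any(x < 0)) stop("negative values are incompatible with log transform")
    x <- log2(x + 1)
  }
  if (is.null(stats)) {
    mu <- colMeans(x)
    sigma <- sqrt(pmax(col_pop_var(x), 0))
    names(sigma) <- names(mu)
    stats <- structure(
      list(mu = mu, sigma = sigma, epsilon = epsilon,
           log_transform = log_transform),
      class = "norm_stats"
    )
  }
  z <- sweep(sweep(x, 2L, stats$mu, `-`), 2L, stats$sigma + stats$epsilon, `/`)
  list(view = omics_view(z, view$modality, normalized = TRUE), stats = stats)
}

#' Select the most variable features within one dataset
#'
#' Tumor-specific feature selection: zero-variance features are removed, the
#' remainder are ranked by descending sample variance (ties broken by the
#' original column index), and the top `n_keep` are kept in rank order.
#'
#' @param view An [omics_view()].
#' @param n_keep Number of features to retain.
#' @param exclude Optional feature identifiers to skip (used to keep the
#'   tumor-specific block disjoint from an already-chosen common block).
#' @return An [omics_view()] with `n_keep` columns, ordered by variance rank.
#' @export
select_specific_features <- function(view, n_keep, exclude = character()) {
  stopifnot(inherits(view, "omics_view"))
  v <- col_pop_var(view$matrix)
  eligible <- which(v > 0 & !(colnames(view$matrix) %in% exclude))
  if (n_keep > length(eligible)) {
    stop(sprintf(
      "requested %d features but only %d non-constant features are available",
      n_keep, length(eligible)
    ))
  }
  ord <- eligible[order(-v[eligible], eligible)]
  keep <- ord[seq_len(n_keep)]
  omics_view(view$matrix[, keep, drop = FALSE], view$modality, view$normalized)
}

#' Select common features across several datasets
#'
#' Common features are those measured with non-zero variance in every
#' dataset, ranked by the mean of their per-dataset variance ranks
#' (rank 1 = most variable within a dataset). The top `n_keep` identifiers
#' are returned in rank order.
#'
#' @param views A list of [omics_view()] objects for the same modality, one
#'   per dataset, sharing a feature namespace.
#' @param n_keep Number of common feature identifiers to return.
#' @return Character vector of `n_keep` feature identifiers.
#' @export
select_common_features <- function(views, n_keep) {
  if (length(views) < 2L) stop("common-feature selection needs >= 2 datasets")
  lapply(views, function(v) stopifnot(inherits(v, "omics_view")))
  vars <- lapply(views, function(v) col_pop_var(v$matrix))
  present <- Reduce(intersect, lapply(vars, function(x) names(x)[x > 0]))
  # keep the first dataset's column order as the canonical tie-break order
  present <- intersect(feature_names(views[[1]]), present)
  if (length(present) < n_keep) {
    stop(sprintf(
      "only %d features are present (non-constant) in all datasets; %d requested",
      length(present), n_keep
    ))
  }
  mean_rank <- rowMeans(vapply(
    vars,
    function(x) rank(-x[present], ties.method = "first"),
    numeric(length(present))
  ))
  present[order(mean_rank, seq_along(present))][seq_len(n_keep)]
}

#' Feature-selection dimensions per modality
#'
#' Fixed model-input widths: common features shared across pretraining
#' datasets plus tumor-specific features per dataset. Defaults follow the
#' standard configuration of 200/200/100 common and 800/800/400 specific
#' features for mRNA/methylation/miRNA, i.e. totals of 1000/1000/500.
#'
#' @param common_dims,specific_dims Named integer vectors
#'   (`mrna`, `methylation`, `mirna`).
#' @return A `feature_selection_spec` with `common_dims`, `specific_dims`
#'   and `target_dims`.
#' @export
feature_selection_spec <- function(
    common_dims = c(mrna = 200L, methylation = 200L, mirna = 100L),
    specific_dims = c(mrna = 800L, methylation = 800L, mirna = 400L)) {
  if (!identical(sort(names(common_dims)), sort(names(specific_dims)))) {
    stop("common_dims and specific_dims must cover the same modalities")
  }
  specific_dims <- specific_dims[names(common_dims)]
  if (any(common_dims < 0) || any(specific_dims < 0)) stop("negative dims")
  target <- common_dims + specific_dims
  if (any(target <= 0)) stop("target dims must be positive")
  structure(
    list(common_dims = common_dims, specific_dims = specific_dims,
         target_dims = target),
    class = "feature_selection_spec"
  )
}

#' Assemble a fixed-width pretraining view
#'
#' Places the shared common features in the first columns (in the shared
#' order, which downstream shared-biomarker ranking relies on) and fills the
#' remaining width with the dataset's top-variance tumor-specific features,
#' excluding any feature already in the common block.
#'
#' @param view An [omics_view()] for one dataset.
#' @param common_ids Ordered common feature identifiers for this modality
#'   (may be empty for evaluation datasets, which use tumor-specific
#'   features only).
#' @param n_specific Number of tumor-specific features to append.
#' @return An [omics_view()] of width `length(common_ids) + n_specific`.
#' @export
assemble_pretraining_view <- function(view, common_ids, n_specific) {
  stopifnot(inherits(view, "omics_view"))
  if (!all(common_ids %in% feature_names(view))) {
    stop("dataset is missing ", sum(!(common_ids %in% feature_names(view))),
         " of the common features")
  }
  parts <- list()
  if (length(common_ids)) {
    parts$common <- view$matrix[, common_ids, drop = FALSE]
  }
  if (n_specific > 0) {
    spec_view <- select_specific_features(view, n_specific, exclude = common_ids)
    parts$specific <- spec_view$matrix
  }
  omics_view(do.call(cbind, unname(parts)), view$modality, view$normalized)
}
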