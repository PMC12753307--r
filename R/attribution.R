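#' Input-times-gradient feature attribution
#'
#' Runs one modality's encoder and single-omics head with an identity
#' adjacency (so every sample is scored on its own signal, without graph
#' smoothing), takes the model's own prediction as a pseudo-label
#' `y*_i = argmax_c f_ic`, sets the per-sample loss to the cross-entropy at
#' `y*_i`, and scores each feature as the sample-mean absolute
#' input-times-gradient `s_g = (1/N) sum_i |X_ig * d l_i / d X_ig|`.
#' The fusion network is not involved; attribution follows the single-omics
#' head path. Model parameters are never mutated.
#'
#' @param model A `mogedn_model` (any trained encoder/head pair works,
#'   including toy dimensions).
#' @param view Normalized [omics_view()] or numeric matrix
#'   (samples x input width). An unnormalized view triggers a warning.
#' @param modality Which encoder/head pair to use.
#' @return Named numeric vector of per-feature scores `s_g` (>= 0).
#' @export
attribute <- function(model, view, modality) {
  if (inherits(view, "omics_view") && !view$normalized) {
    warning("attributing on an unnormalized view; scores assume the ",
            "training normalization")
  }
  x <- check_view_matrix(view, NULL, model$input_dims[[modality]], modality)
  if (nrow(x) == 0L) stop("empty sample set")
  eye <- Matrix::Diagonal(nrow(x))
  enc <- encoder_forward(model$params, paste0("enc.", modality), x, eye,
                         latent_norm = isTRUE(model$latent_norm))
  logits <- linear_forward(enc$z, model$params, paste0("head.", modality))
  probs <- softmax_rows(logits)
  y_star <- max.col(logits, ties.method = "first")
  # per-sample CE gradient at the pseudo-label (no 1/N: l_i is per sample)
  dlogits <- probs
  idx <- cbind(seq_len(nrow(x)), y_star)
  dlogits[idx] <- dlogits[idx] - 1
  dz <- dlogits %*% t(model$params[[paste0("head.", modality, ".W")]])
  dx <- encoder_backward(dz, enc$cache, model$params,
                         paste0("enc.", modality), eye)$dx
  s <- colMeans(abs(x * dx))
  names(s) <- colnames(x)
  s
}

new_attribution_result <- function(scores, modality, provenance, k_top) {
  ranking <- order(-scores, seq_along(scores))
  k_top <- min(k_top, length(scores))
  top_idx <- ranking[seq_len(k_top)]
  structure(
    list(
      modality = modality,
      scores = scores,
      feature_names = names(scores),
      ranking = ranking,
      provenance = provenance,
      k_top = k_top,
      top = data.frame(
        rank = seq_len(k_top),
        index = top_idx,
        feature = if (is.null(names(scores))) as.character(top_idx) else
          names(scores)[top_idx],
        score = unname(scores[top_idx])
      )
    ),
    class = "attribution_result"
  )
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> %s (%s), top %d of %d features\n",
              x$modality, x$provenance, x$k_top, length(x$scores)))
  print(utils::head(x$top, 5))
  invisible(x)
}

#' Shared biomarkers from the pretrained bundle
#'
#' For every pretraining dataset, computes input-times-gradient scores with
#' the shared encoders and that dataset's own heads, averages the scores
#' across datasets, restricts to the first `d_shared` columns per modality
#' (the common-feature block, which pretraining views place first), and
#' ranks within that shared subset.
#'
#' @param state A trained `mogedn_pretrain_state` with datasets attached.
#' @param d_shared Named per-modality width of the common block (defaults
#'   200/200/100 for mrna/methylation/mirna; missing modalities fall back
#'   to the full width).
#' @param k Named top-k to report per modality (defaults 100/100/50).
#' @return Named list of `attribution_result` per modality
#'   (provenance `"shared"`).
#' @export
shared_biomarkers <- function(state,
                              d_shared = c(mrna = 200L, methylation = 200L,
                                           mirna = 100L),
                              k = c(mrna = 100L, methylation = 100L,
                                    mirna = 50L)) {
  stopifnot(inherits(state, "mogedn_pretrain_state"))
  if (is.null(state$datasets[[1]]$matrices)) {
    stop("pretraining datasets (with matrices) must be attached to the state")
  }
  mods <- state$modalities
  res <- list()
  for (m in mods) {
    acc <- NULL
    for (i in seq_along(state$datasets)) {
      model <- make_ds_model(state, i)
      s <- attribute(model, state$datasets[[i]]$matrices[[m]], m)
      acc <- if (is.null(acc)) s else acc + s
    }
    s_bar <- acc / length(state$datasets)
    d <- min(d_shared[[m]] %||% length(s_bar), length(s_bar))
    s_shared <- s_bar[seq_len(d)]
    res[[m]] <- new_attribution_result(
      s_shared, m, "shared",
      k[[m]] %||% min(100L, d)
    )
  }
  res
}

#' Tumor-specific biomarkers from a finetuned model
#'
#' Computes input-times-gradient scores over the full tumor-specific feature
#' width of each modality using the finetuned encoders and heads on the
#' cohort's training matrix, and returns the descending ranking (ties broken
#' by ascending feature index).
#'
#' @param ft A `mogedn_finetuned`, or any `mogedn_model` together with
#'   `matrices`.
#' @param k Top-k to retain (default 300).
#' @param matrices Optional named list of normalized training matrices (only
#'   needed when `ft` is a bare model).
#' @return Named list of `attribution_result` per modality
#'   (provenance `"tumor_specific"`).
#' @export
tumor_specific_biomarkers <- function(ft, k = 300L, matrices = NULL) {
  if (inherits(ft, "mogedn_finetuned")) {
    model <- ft$model
    matrices <- ft$train_matrices
  } else {
    model <- ft
    if (is.null(matrices)) stop("supply `matrices` with a bare model")
  }
  res <- list()
  for (m in model$modalities) {
    s <- attribute(model, matrices[[m]], m)
    if (k > length(s)) {
      stop(sprintf("k = %d exceeds the %d features of modality %s",
                   k, length(s), m))
    }
    res[[m]] <- new_attribution_result(s, m, "tumor_specific", k)
  }
  res
}

#' Write ranked biomarkers as TSV
#'
#' @param result An `attribution_result`.
#' @param path Output TSV (columns `rank`, `feature_id`, `score`).
#' @return The path, invisibly.
#' @export
write_biomarkers <- function(result, path) {
  dt <- data.table::data.table(
    rank = seq_along(result$ranking),
    feature_id = result$feature_names[result$ranking],
    score = unname(result$scores[result$ranking])
  )
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
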