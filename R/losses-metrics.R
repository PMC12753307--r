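LOG_CLAMP <- 1e-12

check_simplex <- function(p, tol = 1e-6) {
  if (any(p < -tol) || any(abs(rowSums(p) - 1) > tol)) {
    stop("probability rows must lie on the simplex")
  }
}

one_hot <- function(labels, n_classes) {
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), as.integer(labels))] <- 1
  y
}

#' Class-weighted, sample-weighted focal loss
#'
#' `L = -(1/N) sum_i w_i sum_c alpha_c y_ic (1 - p_ic)^gamma log p_ic`.
#' With `gamma = 0` and unit weights this is the mean cross-entropy. The log
#' is clamped at 1e-12 for numerical safety.
#'
#' @param probs N x C matrix of predicted probabilities (rows on the
#'   simplex).
#' @param y_onehot N x C one-hot label matrix.
#' @param gamma Focusing exponent (>= 0); larger values down-weight easy,
#'   confidently classified samples.
#' @param alpha Per-class weights (length C), default 1.
#' @param sample_weights Per-sample weights (length N), default 1.
#' @return Scalar loss.
#' @export
focal_loss <- function(probs, y_onehot, gamma = 2, alpha = NULL,
                       sample_weights = NULL) {
  stopifnot(identical(dim(probs), dim(y_onehot)), gamma >= 0)
  check_simplex(probs)
  n <- nrow(probs)
  if (is.null(alpha)) alpha <- rep(1, ncol(probs))
  if (is.null(sample_weights)) sample_weights <- rep(1, n)
  term <- y_onehot * (1 - probs)^gamma * log(pmax(probs, LOG_CLAMP))
  term <- sweep(term, 2L, alpha, `*`)
  -sum(sample_weights * rowSums(term)) / n
}

# gradient of the focal loss w.r.t. the logits producing `probs` by softmax;
# y one-hot so only the true-class column of the outer dL/dp survives
focal_loss_grad_logits <- function(probs, labels, gamma, alpha, sample_weights) {
  n <- nrow(probs)
  c_idx <- as.integer(labels)
  p_y <- pmax(probs[cbind(seq_len(n), c_idx)], LOG_CLAMP)
  a_y <- alpha[c_idx]
  one_m <- 1 - p_y
  # dL_i/dp_y before the 1/N; (1-p)^(gamma-1) is clamped away from 0^negative
  focus_term <- if (gamma > 0) {
    gamma * pmax(one_m, LOG_CLAMP)^(gamma - 1) * log(p_y)
  } else {
    0
  }
  g <- -sample_weights * a_y * (one_m^gamma / p_y - focus_term)
  dz <- -(g * p_y / n) * probs
  dz[cbind(seq_len(n), c_idx)] <- dz[cbind(seq_len(n), c_idx)] + g * p_y / n
  # dz_ic = (g_i * p_y / n) * (1[c==y] - p_ic); sign folded above
  dz
}

#' Balanced class weights and per-sample weights
#'
#' `alpha_c = N / (C * n_c)` (the "balanced" inverse-frequency heuristic);
#' sample weights are each sample's own class weight rescaled to mean 1.
#'
#' @param labels Factor (or coercible) of class labels; every class level
#'   present must have at least one sample.
#' @return List with `alpha` (named per-class weights, in level order) and
#'   `sample_weights` (length N, mean 1).
#' @export
balanced_class_weights <- function(labels) {
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  n_c <- table(labels)
  if (length(n_c) < 2L) stop("need at least two classes with samples")
  if (any(n_c == 0L)) stop("empty class in labels")
  alpha <- length(labels) / (length(n_c) * as.numeric(n_c))
  names(alpha) <- names(n_c)
  w <- alpha[as.integer(labels)]
  w <- as.numeric(w / mean(w))
  list(alpha = alpha, sample_weights = w)
}

#' Latent reconstruction loss and similarity monitor
#'
#' `recon_loss` is the mean squared error over all entries of the
#' reconstructed vs. true latent matrices; `similarity` maps an MSE to the
#' monitoring score `Sim = 1 / (1 + MSE)`, which is 1 for a perfect
#' reconstruction and decreases monotonically with the error.
#'
#' @param z_hat,z Matrices of identical shape.
#' @return Scalar MSE.
#' @export
recon_loss <- function(z_hat, z) {
  if (!identical(dim(z_hat), dim(z))) stop("latent shape mismatch")
  mean((z_hat - z)^2)
}

#' @rdname recon_loss
#' @param mse A mean squared error (>= 0).
#' @export
similarity <- function(mse) {
  stopifnot(all(mse >= 0))
  1 / (1 + mse)
}

#' Joint classification + reconstruction loss
#'
#' `L_total = L_cls + lambda * L_recon`.
#'
#' @param cls Classification loss.
#' @param recon Reconstruction loss.
#' @param lambda Non-negative balance weight.
#' @return Scalar.
#' @export
joint_loss <- function(cls, recon, lambda) {
  stopifnot(lambda >= 0)
  cls + lambda * recon
}

#' Weighted cross-entropy
#'
#' `L = (1/N) sum_i w_i (-log p_{i, y_i})`, the finetuning objective with
#' weights derived from balanced class weights.
#'
#' @param probs N x C probability matrix.
#' @param labels Integer/factor labels indexing the columns of `probs`.
#' @param sample_weights Per-sample weights, default 1.
#' @return Scalar loss.
#' @export
weighted_ce <- function(probs, labels, sample_weights = NULL) {
  check_simplex(probs)
  n <- nrow(probs)
  if (is.null(sample_weights)) sample_weights <- rep(1, n)
  p_y <- pmax(probs[cbind(seq_len(n), as.integer(labels))], LOG_CLAMP)
  mean(sample_weights * (-log(p_y)))
}

weighted_ce_grad_logits <- function(probs, labels, sample_weights) {
  n <- nrow(probs)
  dz <- sample_weights * probs / n
  idx <- cbind(seq_len(n), as.integer(labels))
  dz[idx] <- dz[idx] - sample_weights / n
  dz
}

#' Classification metrics and composite model-selection score
#'
#' Computes accuracy, per-class precision/recall/F1, weighted F1 (class-size
#' weights `n_c / N` from the true labels), macro F1 (unweighted mean over
#' the class set), and the composite epoch-selection score
#' `0.2 * ACC + 0.2 * F1_weighted + 0.6 * F1_macro`. A class with no
#' predicted positives or no true positives contributes F1 = 0; classes
#' absent from the true labels but present in the class set likewise
#' contribute 0 to the macro average.
#'
#' @param pred,truth Label vectors of equal length.
#' @param classes The class set; defaults to the union of factor levels /
#'   values seen in `pred` and `truth`.
#' @return A `metric_report` list: `acc`, `f1_weighted`, `f1_macro`,
#'   `composite`, `per_class` (data.frame with precision/recall/f1/n), `n`.
#' @export
metrics <- function(pred, truth, classes = NULL) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (is.null(classes)) {
    classes <- if (is.factor(truth)) {
      union(levels(truth), levels(as.factor(pred)))
    } else {
      sort(unique(c(as.character(pred), as.character(truth))))
    }
  }
  pred <- factor(as.character(pred), levels = classes)
  truth <- factor(as.character(truth), levels = classes)
  n <- length(truth)
  cm <- table(truth, pred)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  n_c <- as.numeric(rowSums(cm))
  acc <- sum(tp) / n
  f1w <- sum(n_c / n * f1)
  f1m <- mean(f1)
  structure(
    list(
      acc = acc,
      f1_weighted = f1w,
      f1_macro = f1m,
      composite = composite_score(acc, f1w, f1m),
      per_class = data.frame(
        class = classes, n = n_c,
        precision = as.numeric(precision),
        recall = as.numeric(recall),
        f1 = as.numeric(f1)
      ),
      n = n
    ),
    class = "metric_report"
  )
}

#' @rdname metrics
#' @param acc,f1_weighted,f1_macro Metric values in `[0, 1]`.
#' @export
composite_score <- function(acc, f1_weighted, f1_macro) {
  0.2 * acc + 0.2 * f1_weighted + 0.6 * f1_macro
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> n=%d  ACC=%.4f  F1w=%.4f  F1m=%.4f  composite=%.4f\n",
    x$n, x$acc, x$f1_weighted, x$f1_macro, x$composite
  ))
  invisible(x)
}

#' Serialize a metric report to a JSON string
#' @param report A `metric_report`.
#' @return Length-1 character (one JSON object, suitable for a JSONL log).
#' @export
metric_report_json <- function(report) {
  jsonlite::toJSON(
    list(
      acc = report$acc, f1_weighted = report$f1_weighted,
      f1_macro = report$f1_macro, composite = report$composite,
      n = report$n
    ),
    auto_unbox = TRUE, digits = NA
  )
}
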