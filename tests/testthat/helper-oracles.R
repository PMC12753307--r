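# Brute-force reference implementations and small fixture builders shared by
# the unit and acceptance tests. Everything here is written as naively as
# possible (explicit loops, no shared code with the package) so the tests
# compare two independent derivations.

# naive focal loss: per-sample, per-class double loop
oracle_focal_loss <- function(probs, y_onehot, gamma, alpha = NULL,
                              sample_weights = NULL) {
  n <- nrow(probs)
  c_tot <- ncol(probs)
  if (is.null(alpha)) alpha <- rep(1, c_tot)
  if (is.null(sample_weights)) sample_weights <- rep(1, n)
  total <- 0
  for (i in seq_len(n)) {
    for (c in seq_len(c_tot)) {
      if (y_onehot[i, c] == 1) {
        p <- max(probs[i, c], 1e-12)
        total <- total + sample_weights[i] * alpha[c] *
          (1 - probs[i, c])^gamma * log(p)
      }
    }
  }
  -total / n
}

# naive weighted cross-entropy
oracle_weighted_ce <- function(probs, labels, w = NULL) {
  n <- nrow(probs)
  if (is.null(w)) w <- rep(1, n)
  total <- 0
  for (i in seq_len(n)) {
    total <- total + w[i] * (-log(max(probs[i, as.integer(labels)[i]], 1e-12)))
  }
  total / n
}

# naive metrics from an explicitly built confusion matrix
oracle_metrics <- function(pred, truth, classes) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  n <- length(truth)
  f1 <- prec <- rec <- n_c <- numeric(length(classes))
  acc <- sum(pred == truth) / n
  for (k in seq_along(classes)) {
    cl <- classes[k]
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    n_c[k] <- sum(truth == cl)
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(
    acc = acc,
    f1_weighted = sum(n_c / n * f1),
    f1_macro = mean(f1),
    precision = prec, recall = rec, f1 = f1
  )
}

# random probability rows on the simplex
random_probs <- function(n, c_tot) {
  p <- matrix(stats::rexp(n * c_tot), n, c_tot)
  p / rowSums(p)
}

# O(N^2) brute-force graph builder mirroring the printed construction rules,
# with dense arithmetic and explicit loops
oracle_graph <- function(x, k) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        d[i, j] <- 1 - sum(x[i, ] * x[j, ]) /
          (sqrt(sum(x[i, ]^2)) * sqrt(sum(x[j, ]^2)))
      }
    }
  }
  d <- (d + t(d)) / 2
  off <- sort(d[row(d) != col(d)])
  thr <- off[round(k * n)]
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && d[i, j] <= thr) a[i, j] <- max(0, 1 - d[i, j])
    }
    a[i, i] <- 1
  }
  a / rowSums(a)
}

# central-difference numeric gradient of f w.r.t. the flat parameter list
numeric_grad <- function(f, params, names_to_check, h = 1e-5) {
  grads <- list()
  for (nm in names_to_check) {
    g <- params[[nm]] * 0
    for (i in seq_along(params[[nm]])) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + h
      up <- f(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h
      dn <- f(pp)
      g[i] <- (up - dn) / (2 * h)
    }
    grads[[nm]] <- g
  }
  grads
}

# named random matrix with sample/feature ids
named_matrix <- function(n, d, prefix = "f", sd = 1) {
  m <- matrix(stats::rnorm(n * d, sd = sd), n, d)
  rownames(m) <- sprintf("S%03d", seq_len(n))
  colnames(m) <- sprintf("%s%03d", prefix, seq_len(d))
  m
}

# a tiny trained-free mogedn model for structural tests
tiny_model <- function(seed = 1L, n_classes = 3L) {
  mogedn_model(
    c(mrna = 12L, methylation = 10L, mirna = 8L), n_classes,
    hidden_dims = c(6L), latent_dim = 4L, core_width = 5L, seed = seed
  )
}

# matching tiny normalized views + graphs for tiny_model
tiny_inputs <- function(seed = 2L, n = 25L) {
  set.seed(seed)
  dims <- c(mrna = 12L, methylation = 10L, mirna = 8L)
  views <- lapply(names(dims), function(m) named_matrix(n, dims[[m]], m))
  names(views) <- names(dims)
  graphs <- lapply(views, build_graph, edge_per_node = 4)
  list(views = views, graphs = graphs)
}

# a small synthetic cohort prepared end to end (fast path for training tests)
small_corpus <- function(seed = 1L, n = 90L, n_datasets = 1L, rho = 0.9) {
  spec <- synth_spec(
    n_samples = n, dims = c(mrna = 40L, methylation = 40L, mirna = 20L),
    latent_dim = 6L, cross_modal_strength = rho
  )
  synth_corpus(replicate(n_datasets, spec, simplify = FALSE), seed = seed)
}

small_config <- function(seed = 1L, ...) {
  train_config(
    seed = seed,
    max_epochs = list(phase1 = 25, phase2 = 25, phase3 = 15, finetune = 25),
    early_stop_patience = 10, edge_per_node = 6,
    ...
  )
}
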