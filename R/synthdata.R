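#' Specification for a synthetic multi-omics cohort
#'
#' The generator emulates the statistical structure the model assumes:
#' matched samples across modalities, subtype labels with class imbalance,
#' a fraction of informative features per modality, and tunable cross-omics
#' dependence so that one modality's signal is (or is not) predictable from
#' the others.
#'
#' Construction: each sample draws a shared latent factor
#' `u_i ~ N(mu_{y_i}, I)` whose class means are separated by `class_sep`,
#' plus per-modality private factors `v_{oi} ~ N(0, I)` that carry no class
#' or cross-omics information. A modality's informative columns are
#' `rho * (u_i L_o) + (1 - rho) * (v_{oi} M_o) + noise`, so
#' `cross_modal_strength = rho` is the single knob moving the informative
#' signal between the shared (class-bearing, cross-modality predictable)
#' factor and the private one. Remaining columns are pure noise.
#'
#' @param n_samples Cohort size (default 200).
#' @param n_classes Number of subtypes (default 3).
#' @param class_proportions Class mixing proportions (default 0.5/0.3/0.2,
#'   exercising the imbalance weighting).
#' @param dims Named per-modality feature counts (default 100/100/50 for
#'   mrna/methylation/mirna).
#' @param latent_dim Shared latent dimension (default 10).
#' @param cross_modal_strength `rho` in `[0, 1]` (default 0.9).
#' @param informative_fraction Fraction of columns per modality that carry
#'   signal (default 0.1).
#' @param noise_sd Additive feature noise SD (default 0.5).
#' @param class_sep Separation of class means in latent space (default 6,
#'   i.e. cleanly separable subtypes relative to the unit within-class SD).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_samples = 200L, n_classes = 3L,
                       class_proportions = c(0.5, 0.3, 0.2),
                       dims = c(mrna = 100L, methylation = 100L, mirna = 50L),
                       latent_dim = 10L, cross_modal_strength = 0.9,
                       informative_fraction = 0.1, noise_sd = 0.5,
                       class_sep = 6) {
  if (length(class_proportions) != n_classes) {
    stop("class_proportions has length ", length(class_proportions),
         " but n_classes is ", n_classes)
  }
  stopifnot(
    abs(sum(class_proportions) - 1) < 1e-8,
    all(dims > 0), !is.null(names(dims)),
    cross_modal_strength >= 0, cross_modal_strength <= 1,
    informative_fraction >= 0, informative_fraction <= 1,
    noise_sd >= 0
  )
  if (any(n_samples * class_proportions < 1)) {
    stop("a class has expected count below 1; increase n_samples or proportions")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_classes = as.integer(n_classes),
      class_proportions = class_proportions, dims = dims,
      latent_dim = as.integer(latent_dim),
      cross_modal_strength = cross_modal_strength,
      informative_fraction = informative_fraction,
      noise_sd = noise_sd, class_sep = class_sep
    ),
    class = "synth_spec"
  )
}

#' Draw the feature loading matrices for a synthetic design
#'
#' The loadings map latent factors to informative feature columns. Drawing
#' them once and passing them to several [synth_generate()] calls makes the
#' cross-omics dependency structure consistent across cohorts — the analogue
#' of molecular features co-varying the same way across cancer types, which
#' is what lets a decoder pretrained on some cohorts recover missing
#' modalities in a new one. Cohorts still differ in their class sets, class
#' means and samples.
#'
#' With three or more modalities the shared loadings are made
#' *complementary* by default: each latent dimension loads onto all but one
#' modality (round-robin). Every modality therefore observes only a subset
#' of the latent factors — the omics layers capture overlapping but
#' different aspects of the underlying biology — while any missing
#' modality's view remains fully recoverable from the union of the others
#' (every dimension it sees is seen by at least one other modality).
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @param complementary Assign each latent dimension to all but one modality
#'   (default when >= 3 modalities; ignored otherwise).
#' @return Named list per modality with `shared` and `private` loading
#'   matrices (`latent_dim` x number of informative columns).
#' @export
synth_loadings <- function(spec, seed = 1L,
                           complementary = length(spec$dims) >= 3L) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(seed)
  k <- spec$latent_dim
  mods <- names(spec$dims)
  # latent dim j is hidden from modality ((j - 1) mod M) + 1
  hidden_from <- rep_len(seq_along(mods), k)
  out <- list()
  for (mi in seq_along(mods)) {
    m <- mods[mi]
    n_inf <- max(1L, round(spec$informative_fraction * spec$dims[[m]]))
    shared <- matrix(stats::rnorm(k * n_inf), k, n_inf) / sqrt(k)
    if (complementary && length(mods) >= 3L) {
      shared[hidden_from == mi, ] <- 0
      shared <- shared * sqrt(k / max(sum(hidden_from != mi), 1L))
    }
    out[[m]] <- list(
      shared = shared,
      private = matrix(stats::rnorm(k * n_inf), k, n_inf) / sqrt(k)
    )
  }
  out
}

#' Generate a synthetic multi-omics cohort
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed; the same seed reproduces the cohort bit for
#'   bit.
#' @param label_prefix Prefix for class labels (lets corpus cohorts carry
#'   distinct label sets).
#' @param sample_prefix Prefix for sample identifiers.
#' @param loadings Optional loadings from [synth_loadings()]; when shared
#'   across cohorts the cross-omics dependency transfers between them.
#'   `NULL` draws cohort-specific loadings.
#' @param class_means Optional `n_classes x latent_dim` matrix of latent
#'   class means. Sharing it across cohorts yields i.i.d. cohorts of the
#'   same disease family (same subtype geometry, fresh samples); `NULL`
#'   draws cohort-specific means (distinct subtype geometry).
#' @return List with `views` (named [omics_view()] list, raw scale),
#'   `labels` (named factor), `informative` (named list of planted column
#'   indices per modality), `latent` (the shared factors `u`),
#'   `class_means`, `spec`.
#' @export
synth_generate <- function(spec, seed = 1L, label_prefix = "C",
                           sample_prefix = "S", loadings = NULL,
                           class_means = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  # force before seeding: a lazily supplied `loadings`/`class_means`
  # expression that seeds the RNG itself (e.g. a synth_loadings() call)
  # must not interrupt this cohort's stream mid-generation
  force(loadings); force(class_means)
  set.seed(seed)
  n <- spec$n_samples
  k <- spec$latent_dim
  rho <- spec$cross_modal_strength
  # labels: deterministic counts from proportions (largest remainder), then
  # shuffled, so empirical proportions track the spec tightly
  counts <- floor(n * spec$class_proportions)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * spec$class_proportions - counts
    counts[order(-frac)[seq_len(rem)]] <- counts[order(-frac)[seq_len(rem)]] + 1
  }
  y <- sample(rep(seq_len(spec$n_classes), counts))
  class_names <- paste0(label_prefix, seq_len(spec$n_classes))
  # class means: random directions scaled to pairwise separation class_sep
  if (is.null(class_means)) {
    mu <- matrix(stats::rnorm(spec$n_classes * k), spec$n_classes, k)
    mu <- mu / sqrt(rowSums(mu^2)) * spec$class_sep / sqrt(2)
  } else {
    stopifnot(all(dim(class_means) == c(spec$n_classes, k)))
    mu <- class_means
  }
  u <- mu[y, , drop = FALSE] + matrix(stats::rnorm(n * k), n, k)
  sample_names <- sprintf("%s%04d", sample_prefix, seq_len(n))
  views <- list()
  informative <- list()
  for (m in names(spec$dims)) {
    d <- spec$dims[[m]]
    n_inf <- max(1L, round(spec$informative_fraction * d))
    inf_idx <- seq_len(n_inf)  # planted columns first; selection is tested
                               # against the recorded indices, not position
    if (is.null(loadings)) {
      load_shared <- matrix(stats::rnorm(k * n_inf), k, n_inf) / sqrt(k)
      load_priv <- matrix(stats::rnorm(k * n_inf), k, n_inf) / sqrt(k)
    } else {
      load_shared <- loadings[[m]]$shared
      load_priv <- loadings[[m]]$private
      stopifnot(all(dim(load_shared) == c(k, n_inf)))
    }
    v_priv <- matrix(stats::rnorm(n * k), n, k)
    x <- matrix(stats::rnorm(n * d, sd = max(spec$noise_sd, 1e-12)), n, d)
    x[, inf_idx] <- x[, inf_idx] * (spec$noise_sd > 0) +
      rho * (u %*% load_shared) + (1 - rho) * (v_priv %*% load_priv)
    if (spec$noise_sd == 0) {
      # keep non-informative columns non-constant but label-free
      x[, -inf_idx] <- matrix(stats::rnorm(n * (d - n_inf), sd = 1e-6),
                              n, d - n_inf)
    }
    rownames(x) <- sample_names
    colnames(x) <- sprintf("%s_f%04d", m, seq_len(d))
    views[[m]] <- omics_view(x, m)
    informative[[m]] <- inf_idx
  }
  list(
    views = views,
    labels = stats::setNames(factor(class_names[y], levels = class_names),
                             sample_names),
    informative = informative,
    latent = u,
    class_means = mu,
    spec = spec
  )
}

#' Build a pretraining corpus of synthetic cohorts
#'
#' Cohorts are generated independently with distinct class label sets
#' (mirroring different cancer types) but a shared feature namespace, so
#' the common-feature selection path applies across them. Each cohort gets
#' a stratified train/validation split.
#'
#' @param specs List of [synth_spec()] (all with identical `dims`).
#' @param seed Base seed; cohort `i` uses `seed + i - 1`.
#' @param val_frac Validation fraction (default 0.3).
#' @param loadings Loadings shared by all cohorts; defaults to
#'   [synth_loadings()] drawn from `seed`, so the cross-omics structure is
#'   consistent across the corpus (pass the same object when generating an
#'   external evaluation cohort for the corpus).
#' @param class_means Optional latent class-mean matrix shared by all
#'   cohorts (see [synth_generate()]); `NULL` (default) draws distinct
#'   subtype geometry per cohort.
#' @return List of cohorts, each with `views`, `labels`, `informative`,
#'   `train_idx`, `val_idx`, `name`; the shared loadings are attached as
#'   `attr(, "loadings")`.
#' @export
synth_corpus <- function(specs, seed = 1L, val_frac = 0.3,
                         loadings = synth_loadings(specs[[1]],
                                                   seed + 5000L),
                         class_means = NULL) {
  stopifnot(length(specs) >= 1L)
  force(loadings) # resolve the default before any cohort generation starts
  out <- lapply(seq_along(specs), function(i) {
    g <- synth_generate(specs[[i]], seed = seed + i - 1L,
                        label_prefix = sprintf("D%d.C", i),
                        sample_prefix = sprintf("D%dS", i),
                        loadings = loadings, class_means = class_means)
    split <- stratified_split(g$labels, val_frac, seed = seed + 1000L + i)
    c(g[c("views", "labels", "informative")],
      list(train_idx = split$train, val_idx = split$val,
           name = sprintf("synth%02d", i)))
  })
  attr(out, "loadings") <- loadings
  out
}

#' Stratified two-way split
#'
#' @param labels Factor of class labels.
#' @param frac Fraction assigned to the second (validation/test) part,
#'   within each class (rounded; at least one sample stays in train per
#'   class).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
stratified_split <- function(labels, frac, seed = 1L) {
  force(labels); force(frac)
  set.seed(seed)
  val <- integer()
  for (cl in levels(as.factor(labels))) {
    idx <- which(labels == cl)
    n_val <- min(length(idx) - 1L, round(length(idx) * frac))
    if (n_val > 0) val <- c(val, sample(idx, n_val))
  }
  val <- sort(val)
  list(train = setdiff(seq_along(labels), val), val = val)
}
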