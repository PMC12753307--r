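#' Construct a MOGEDN model
#'
#' Creates and initializes the four network components:
#' \itemize{
#'   \item per-modality GCN encoders `E_o` with widths
#'     `input -> hidden_dims -> latent_dim` (default `[200, 100] -> 100`),
#'     LeakyReLU(0.25) between layers, linear latent layer;
#'   \item a shared multi-head decoder `D`: the concatenated latents of the
#'     available modalities pass through a fully connected core
#'     (`core_width`, LeakyReLU) and a per-modality output head that emits
#'     the missing modality's latent;
#'   \item per-modality linear classifier heads `C_o` (`latent -> logits`);
#'   \item a VCDN fusion classifier `C` over the flattened outer product of
#'     the per-head class probabilities (one hidden layer of width
#'     `n_classes ^ n_modalities`).
#' }
#'
#' @param input_dims Named integer vector of per-modality input widths, in
#'   the fixed modality order used everywhere concatenation order matters
#'   (canonically `mrna`, `methylation`, `mirna`).
#' @param n_classes Number of subtype classes.
#' @param classes Optional class labels (length `n_classes`).
#' @param hidden_dims Encoder hidden widths.
#' @param latent_dim Latent width shared by all modalities.
#' @param core_width Decoder core width.
#' @param latent_norm Standardize each latent unit over the forward batch
#'   (no learnable affine). Keeps the latent scale O(1) so reconstruction
#'   MSE and the Sim monitor are comparable across modalities and runs.
#' @param seed Integer seed for parameter initialization.
#' @return A `mogedn_model` list: `params` (flat named list), `modalities`,
#'   `input_dims`, `n_classes`, `classes`, `hidden_dims`, `latent_dim`,
#'   `core_width`, `schema`.
#' @export
mogedn_model <- function(input_dims, n_classes, classes = NULL,
                         hidden_dims = c(200L, 100L), latent_dim = 100L,
                         core_width = 256L, latent_norm = TRUE, seed = 1L) {
  stopifnot(length(input_dims) >= 2L, !is.null(names(input_dims)),
            n_classes >= 2L)
  modalities <- names(input_dims)
  if (is.null(classes)) classes <- paste0("class", seq_len(n_classes))
  stopifnot(length(classes) == n_classes)
  force(hidden_dims); force(latent_dim); force(core_width); force(latent_norm)
  set.seed(seed)
  params <- list()
  for (m in modalities) {
    widths <- c(input_dims[[m]], hidden_dims, latent_dim)
    params <- init_encoder(params, paste0("enc.", m), widths)
  }
  params <- init_decoder(params, modalities, latent_dim, core_width)
  for (m in modalities) {
    params <- add_linear_params(params, paste0("head.", m),
                                latent_dim, n_classes)
  }
  params <- init_vcdn(params, n_classes, length(modalities))
  structure(
    list(
      params = params,
      modalities = modalities,
      input_dims = input_dims,
      n_classes = as.integer(n_classes),
      classes = as.character(classes),
      hidden_dims = as.integer(hidden_dims),
      latent_dim = as.integer(latent_dim),
      core_width = as.integer(core_width),
      latent_norm = isTRUE(latent_norm),
      schema = "mogedn-checkpoint-v1"
    ),
    class = "mogedn_model"
  )
}

#' @export
print.mogedn_model <- function(x, ...) {
  cat(sprintf(
    "<mogedn_model> modalities: %s | inputs: %s | latent %d | %d classes\n",
    paste(x$modalities, collapse = ", "),
    paste(x$input_dims, collapse = "/"),
    x$latent_dim, x$n_classes
  ))
  invisible(x)
}

check_view_matrix <- function(x, graph = NULL, expected_width = NULL,
                              modality = "") {
  if (inherits(x, "omics_view")) x <- x$matrix
  if (!is.null(expected_width) && ncol(x) != expected_width) {
    stop(sprintf("modality %s: expected %d input features, got %d",
                 modality, expected_width, ncol(x)))
  }
  if (!is.null(graph)) {
    adj <- if (inherits(graph, "sample_graph")) graph$adjacency else graph
    if (nrow(adj) != nrow(x)) {
      stop(sprintf("modality %s: graph has %d nodes but view has %d samples",
                   modality, nrow(adj), nrow(x)))
    }
  }
  x
}

get_adj <- function(graph) {
  if (inherits(graph, "sample_graph")) graph$adjacency else graph
}

#' Encode one omics view into its latent representation
#'
#' Runs the modality's GCN encoder: each layer computes
#' `activation(A %*% H %*% W + b)` with `A` the row-stochastic adjacency.
#'
#' @param model A `mogedn_model`.
#' @param view [omics_view()] or numeric matrix (samples x input width).
#' @param graph `sample_graph` (or adjacency matrix) over the same samples.
#' @param modality Which encoder to use.
#' @return Latent matrix (samples x `latent_dim`).
#' @export
encode <- function(model, view, graph, modality) {
  x <- check_view_matrix(view, graph, model$input_dims[[modality]], modality)
  encoder_forward(model$params, paste0("enc.", modality), x,
                  get_adj(graph), latent_norm = isTRUE(model$latent_norm))$z
}

#' Reconstruct a missing modality's latent with the shared decoder
#'
#' @param model A `mogedn_model`.
#' @param latents Named list of latent matrices for the available
#'   modalities (all modalities except `target` must be present).
#' @param target The missing modality to reconstruct.
#' @return Reconstructed latent matrix (samples x `latent_dim`).
#' @export
decode_missing <- function(model, latents, target) {
  others <- setdiff(model$modalities, target)
  if (!(target %in% model$modalities)) stop("unknown modality: ", target)
  missing_in <- setdiff(others, names(latents))
  if (length(missing_in)) {
    stop("decoder needs all non-target latents; missing: ",
         paste(missing_in, collapse = ", "))
  }
  u <- do.call(cbind, latents[others])
  decoder_forward(model$params, u, target)$z_hat
}

#' Per-modality classifier head
#'
#' @param model A `mogedn_model`.
#' @param latent Latent matrix (samples x `latent_dim`).
#' @param modality Which head to use.
#' @return Logit matrix (samples x `n_classes`).
#' @export
classify_head <- function(model, latent, modality) {
  if (ncol(latent) != model$latent_dim) {
    stop(sprintf("latent width %d does not match model latent_dim %d",
                 ncol(latent), model$latent_dim))
  }
  linear_forward(latent, model$params, paste0("head.", modality))
}

#' VCDN fusion over per-head logits
#'
#' Per-head logits are softmax-normalized into class-confidence vectors, the
#' per-sample outer product across modalities is flattened (length
#' `n_classes ^ n_modalities`, first modality's index varying slowest) and
#' passed through the fusion MLP.
#'
#' @param model A `mogedn_model`.
#' @param logits_list List of per-modality logit matrices, in modality order.
#' @return Fused logit matrix (samples x `n_classes`).
#' @export
vcdn_fuse <- function(model, logits_list) {
  ncls <- vapply(logits_list, ncol, integer(1))
  if (length(unique(ncls)) != 1L || ncls[1] != model$n_classes) {
    stop("inconsistent class counts across heads")
  }
  probs <- lapply(logits_list, softmax_rows)
  vcdn_forward(model$params, probs)$logits
}

#' Full forward pass
#'
#' Encodes every available modality, substitutes the missing modality's
#' latent (decoder reconstruction when `use_decoder = TRUE`, otherwise a
#' zero matrix), applies the per-modality heads and fuses with the VCDN.
#'
#' @param model A `mogedn_model`.
#' @param views Named list of views/matrices. The entry for a missing
#'   modality may be absent; if supplied it is ignored with a warning (the
#'   mask wins).
#' @param graphs Named list of `sample_graph`s (the missing modality's entry
#'   is not used).
#' @param missing Optional name of at most one missing modality.
#' @param use_decoder Reconstruct the missing latent with the decoder
#'   (`TRUE`) or zero-fill it (`FALSE`).
#' @param dropout,training Input-dropout rate and training-mode flag.
#' @return List with `fused_logits`, `head_logits` (named list), `latents`
#'   (named list), `provenance` (named character:
#'   encoded/reconstructed/zero_filled), and `caches` for backpropagation.
#' @export
mogedn_forward <- function(model, views, graphs, missing = NULL,
                           use_decoder = TRUE, dropout = 0,
                           training = FALSE) {
  if (length(missing) > 1L) stop("at most one modality may be missing")
  if (!is.null(missing) && !(missing %in% model$modalities)) {
    stop("unknown missing modality: ", missing)
  }
  if (!is.null(missing) && missing %in% names(views) &&
      !is.null(views[[missing]])) {
    warning("view supplied for masked modality '", missing,
            "' is ignored (mask wins)")
    views[[missing]] <- NULL
  }
  available <- setdiff(model$modalities, missing)
  latents <- list()
  enc_caches <- list()
  n <- NULL
  for (m in available) {
    x <- check_view_matrix(views[[m]], graphs[[m]],
                           model$input_dims[[m]], m)
    out <- encoder_forward(model$params, paste0("enc.", m), x,
                           get_adj(graphs[[m]]), dropout, training,
                           latent_norm = isTRUE(model$latent_norm))
    latents[[m]] <- out$z
    enc_caches[[m]] <- out$cache
    n <- nrow(out$z)
  }
  provenance <- stats::setNames(rep("encoded", length(available)), available)
  dec_cache <- NULL
  if (!is.null(missing)) {
    if (use_decoder) {
      u <- do.call(cbind, latents[setdiff(model$modalities, missing)])
      dec <- decoder_forward(model$params, u, missing)
      latents[[missing]] <- dec$z_hat
      dec_cache <- dec$cache
      provenance[missing] <- "reconstructed"
    } else {
      latents[[missing]] <- matrix(0, n, model$latent_dim)
      provenance[missing] <- "zero_filled"
    }
  }
  latents <- latents[model$modalities]
  head_logits <- lapply(model$modalities, function(m) {
    linear_forward(latents[[m]], model$params, paste0("head.", m))
  })
  names(head_logits) <- model$modalities
  probs <- lapply(head_logits, softmax_rows)
  fus <- vcdn_forward(model$params, probs)
  list(
    fused_logits = fus$logits,
    head_logits = head_logits,
    head_probs = probs,
    latents = latents,
    provenance = provenance[model$modalities],
    caches = list(enc = enc_caches, dec = dec_cache, fusion = fus$cache,
                  missing = missing, use_decoder = use_decoder)
  )
}

# Backward pass for the classification path (fused + per-head losses),
# optionally including a reconstruction term on the masked modality.
#
# dfused: dL/d(fused logits); dheads: named list dL/d(head logits) from the
# per-head losses (may be NULL); recon: optional list(dz_hat, dz_target,
# target) for the lambda * MSE term in Phase 3.
# graphs are needed to push gradients back through the encoders.
#
# Returns a flat named grads list (canonical parameter names).
mogedn_backward <- function(model, fwd, graphs, dfused,
                            dheads = NULL, recon = NULL) {
  grads <- list()
  vb <- vcdn_backward(dfused, fwd$caches$fusion, model$params)
  grads <- accumulate_grads(grads, vb$grads)
  dlatents <- stats::setNames(vector("list", length(model$modalities)),
                              model$modalities)
  for (i in seq_along(model$modalities)) {
    m <- model$modalities[i]
    dlogit <- softmax_backward(vb$dprobs[[i]], fwd$head_probs[[m]])
    if (!is.null(dheads[[m]])) dlogit <- dlogit + dheads[[m]]
    hname <- paste0("head.", m)
    grads[[paste0(hname, ".W")]] <- crossprod(fwd$latents[[m]], dlogit)
    grads[[paste0(hname, ".b")]] <- colSums(dlogit)
    dlatents[[m]] <- dlogit %*% t(model$params[[paste0(hname, ".W")]])
  }
  missing <- fwd$caches$missing
  if (!is.null(recon)) {
    # L_recon gradient flows into the reconstruction and into the target
    # encoder latent
    dlatents[[missing]] <- dlatents[[missing]] + recon$dz_hat
  }
  if (!is.null(missing) && fwd$caches$use_decoder) {
    db <- decoder_backward(dlatents[[missing]], fwd$caches$dec, model$params)
    grads <- accumulate_grads(grads, db$grads)
    others <- setdiff(model$modalities, missing)
    lat <- model$latent_dim
    for (i in seq_along(others)) {
      cols <- ((i - 1L) * lat + 1L):(i * lat)
      dlatents[[others[i]]] <- dlatents[[others[i]]] + db$du[, cols, drop = FALSE]
    }
    dlatents[[missing]] <- NULL
  } else if (!is.null(missing)) {
    dlatents[[missing]] <- NULL  # zero-filled latent: no path back
  }
  if (!is.null(recon)) {
    # target-side gradient of MSE(z_hat, z_target) w.r.t. z_target
    dlatents[[recon$target]] <- if (is.null(dlatents[[recon$target]])) {
      recon$dz_target
    } else {
      dlatents[[recon$target]] + recon$dz_target
    }
  }
  for (m in names(dlatents)) {
    if (is.null(dlatents[[m]]) || is.null(fwd$caches$enc[[m]])) next
    eb <- encoder_backward(dlatents[[m]], fwd$caches$enc[[m]], model$params,
                           paste0("enc.", m), get_adj(graphs[[m]]))
    grads <- accumulate_grads(grads, eb$grads)
  }
  grads
}

param_names_matching <- function(params, patterns) {
  unique(unlist(lapply(patterns, grep, x = names(params), value = TRUE)))
}
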