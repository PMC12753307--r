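#' Training configuration
#'
#' Collects every hyperparameter of the three-phase pretraining and the
#' finetuning stage. The Adam learning-rate scheduler (multiply by
#' `scheduler_factor` after `scheduler_patience` epochs without improvement
#' of the validation statistic) is applied in all phases.
#'
#' @param lr Named list of per-phase learning rates.
#' @param scheduler_factor LR decay factor in (0, 1).
#' @param scheduler_patience Epochs without improvement before decaying.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param max_epochs Named list of per-phase epoch caps.
#' @param seed Master seed; each phase derives its own stream from it, so a
#'   phase re-run from a checkpoint boundary reproduces the original run.
#' @param mask_prob Phase-3 masking probability `P`; `NULL` means
#'   `1 / n_modalities`.
#' @param lambda_recon Weight of the reconstruction term in Phase 3.
#' @param gamma Focal-loss exponent.
#' @param dropout Input dropout on the encoders during training.
#' @param edge_per_node Target mean degree `k` of the sample graphs. The
#'   default (12) smooths each sample over enough neighbors that latents are
#'   driven by shared structure rather than per-sample noise.
#' @param weight_decay L2 penalty applied through the optimizer in every
#'   phase; regularizes both encoders and decoder on small cohorts.
#' @param min_lr Floor for the scheduled learning rate.
#' @param val_frac Validation fraction carved from finetuning training data.
#' @return A `train_config` list.
#' @export
train_config <- function(
    lr = list(phase1 = 5e-3, phase2 = 1e-3, phase3 = 1e-3, finetune = 5e-3),
    scheduler_factor = 0.7, scheduler_patience = 10,
    early_stop_patience = 30,
    max_epochs = list(phase1 = 500, phase2 = 300, phase3 = 300,
                      finetune = 300),
    seed = 1L, mask_prob = NULL, lambda_recon = 1, gamma = 2,
    dropout = 0.5, edge_per_node = 12, weight_decay = 0.02,
    min_lr = 1e-5, val_frac = 0.2) {
  stopifnot(scheduler_factor > 0, scheduler_factor < 1,
            scheduler_patience >= 1, early_stop_patience >= 1,
            lambda_recon >= 0, gamma >= 0, dropout >= 0, dropout < 1,
            weight_decay >= 0)
  if (!is.null(mask_prob)) stopifnot(mask_prob >= 0, mask_prob <= 1)
  structure(
    list(lr = lr, scheduler_factor = scheduler_factor,
         scheduler_patience = scheduler_patience,
         early_stop_patience = early_stop_patience,
         max_epochs = max_epochs, seed = as.integer(seed),
         mask_prob = mask_prob, lambda_recon = lambda_recon, gamma = gamma,
         dropout = dropout, edge_per_node = edge_per_node,
         weight_decay = weight_decay, min_lr = min_lr,
         val_frac = val_frac),
    class = "train_config"
  )
}

#' Prepare a cohort for training
#'
#' Normalizes every modality (z-score with statistics estimated on the
#' training rows only, replayed on the validation rows) and builds one
#' transductive sample graph per modality over all rows. Optional feature
#' assembly (common + tumor-specific blocks) happens before normalization,
#' since variance ranking operates on the raw (post-log) scale.
#'
#' @param cohort List with `views` (raw [omics_view()]s), `labels`,
#'   `train_idx`, `val_idx`, `name` (e.g. from [synth_corpus()]).
#' @param config A [train_config()] (for `edge_per_node`).
#' @param common_ids Optional named list of common feature identifiers per
#'   modality (pretraining mode).
#' @param n_specific Optional named vector of tumor-specific feature counts.
#' @param log_transform Named logical per modality (default all `FALSE`;
#'   set `TRUE` for raw expression counts).
#' @return A prepared dataset: `name`, `matrices`, `graphs`, `labels`,
#'   `classes`, `train_idx`, `val_idx`, `stats`, `weights`.
#' @export
prepare_dataset <- function(cohort, config = train_config(),
                            common_ids = NULL, n_specific = NULL,
                            log_transform = NULL) {
  views <- cohort$views
  modalities <- names(views)
  if (is.null(log_transform)) {
    log_transform <- stats::setNames(rep(FALSE, length(modalities)), modalities)
  }
  matrices <- list()
  norm_stats <- list()
  for (m in modalities) {
    v <- views[[m]]
    if (!is.null(common_ids) || !is.null(n_specific)) {
      v <- assemble_pretraining_view(
        v, common_ids[[m]] %||% character(),
        if (is.null(n_specific)) 0L else n_specific[[m]]
      )
    }
    train_v <- omics_view(v$matrix[cohort$train_idx, , drop = FALSE],
                          v$modality)
    fit <- normalize_view(train_v, log_transform = isTRUE(log_transform[[m]]))
    all_norm <- normalize_view(v, stats = fit$stats)
    matrices[[m]] <- all_norm$view$matrix
    norm_stats[[m]] <- fit$stats
  }
  graphs <- lapply(matrices, build_graph, edge_per_node = config$edge_per_node)
  labels <- droplevels(as.factor(cohort$labels))
  if (nlevels(droplevels(labels[cohort$train_idx])) < 2L) {
    stop("dataset '", cohort$name, "' has fewer than two classes in training")
  }
  list(
    name = cohort$name,
    matrices = matrices,
    graphs = graphs,
    labels = labels,
    classes = levels(labels),
    train_idx = cohort$train_idx,
    val_idx = cohort$val_idx,
    stats = norm_stats,
    weights = balanced_class_weights(labels[cohort$train_idx])
  )
}

# ---- internal pretraining machinery ----------------------------------------

# one flat parameter store: shared "enc.*" / "dec.*" plus per-dataset
# "ds<i>.head.*" / "ds<i>.fusion.*"
init_pretrain_params <- function(input_dims, datasets, hidden_dims,
                                 latent_dim, core_width, seed) {
  force(hidden_dims); force(latent_dim); force(core_width)
  set.seed(seed)
  params <- list()
  modalities <- names(input_dims)
  for (m in modalities) {
    params <- init_encoder(params, paste0("enc.", m),
                           c(input_dims[[m]], hidden_dims, latent_dim))
  }
  params <- init_decoder(params, modalities, latent_dim, core_width)
  for (i in seq_along(datasets)) {
    ncls <- length(datasets[[i]]$classes)
    for (m in modalities) {
      params <- add_linear_params(params, sprintf("ds%d.head.%s", i, m),
                                  latent_dim, ncls)
    }
    k <- ncls^length(modalities)
    params <- add_linear_params(params, sprintf("ds%d.fusion.l1", i), k, k)
    params <- add_linear_params(params, sprintf("ds%d.fusion.l2", i),
                                k, ncls)
  }
  params
}

ds_prefix <- function(i) sprintf("ds%d.", i)

# view of the flat store as a canonical per-dataset mogedn_model
make_ds_model <- function(state, i) {
  pre <- ds_prefix(i)
  local_names <- grep(paste0("^", pre), names(state$params), value = TRUE)
  local <- state$params[local_names]
  names(local) <- sub(paste0("^", pre), "", local_names)
  shared <- state$params[grep("^(enc|dec)\\.", names(state$params))]
  structure(
    list(params = c(shared, local),
         modalities = state$modalities,
         input_dims = state$input_dims,
         n_classes = length(state$datasets[[i]]$classes),
         classes = state$datasets[[i]]$classes,
         hidden_dims = state$hidden_dims,
         latent_dim = state$latent_dim,
         core_width = state$core_width,
         latent_norm = isTRUE(state$latent_norm),
         schema = "mogedn-checkpoint-v1"),
    class = "mogedn_model"
  )
}

# map canonical grad names back to the flat store
store_grad_names <- function(grads, i) {
  nm <- names(grads)
  local <- grepl("^(head|fusion)\\.", nm)
  names(grads)[local] <- paste0(ds_prefix(i), nm[local])
  grads
}

scheduler_init <- function(lr) list(lr = lr, best = -Inf, wait = 0L)

scheduler_update <- function(sched, metric, factor, patience, min_lr) {
  if (metric > sched$best + 1e-10) {
    sched$best <- metric
    sched$wait <- 0L
  } else {
    sched$wait <- sched$wait + 1L
    if (sched$wait >= patience) {
      sched$lr <- max(sched$lr * factor, min_lr)
      sched$wait <- 0L
    }
  }
  sched
}

# gradient of the phase-1/phase-3 classification objective (focal on fused
# logits plus focal on each head), restricted to the training rows
cls_loss_and_grads <- function(fwd, ds, gamma) {
  tr <- ds$train_idx
  y <- ds$labels[tr]
  alpha <- ds$weights$alpha
  w <- ds$weights$sample_weights
  n_all <- nrow(fwd$fused_logits)
  fused_p <- softmax_rows(fwd$fused_logits[tr, , drop = FALSE])
  y1h <- one_hot(y, ncol(fused_p))
  loss <- focal_loss(fused_p, y1h, gamma, alpha, w)
  dfused <- matrix(0, n_all, ncol(fused_p))
  dfused[tr, ] <- focal_loss_grad_logits(fused_p, y, gamma, alpha, w)
  dheads <- list()
  for (m in names(fwd$head_logits)) {
    hp <- softmax_rows(fwd$head_logits[[m]][tr, , drop = FALSE])
    loss <- loss + focal_loss(hp, y1h, gamma, alpha, w)
    dh <- matrix(0, n_all, ncol(hp))
    dh[tr, ] <- focal_loss_grad_logits(hp, y, gamma, alpha, w)
    dheads[[m]] <- dh
  }
  list(loss = loss, dfused = dfused, dheads = dheads)
}

val_f1_macro <- function(model, ds) {
  fwd <- mogedn_forward(model, ds$matrices, ds$graphs)
  pred <- ds$classes[max.col(fwd$fused_logits[ds$val_idx, , drop = FALSE],
                             ties.method = "first")]
  metrics(pred, ds$labels[ds$val_idx], classes = ds$classes)$f1_macro
}

#' Phase 1: supervised encoder and classifier pretraining
#'
#' Trains the shared encoders together with per-dataset classifier heads and
#' VCDN fusion modules, using the class- and sample-weighted focal loss on
#' the fused logits plus the same focal loss on every per-modality head.
#' Datasets are visited round-robin in a seed-shuffled order each epoch; the
#' decoder is untouched. Early stopping and checkpoint selection use the
#' mean validation macro-F1 across datasets.
#'
#' @param state A pretraining state from [init_pretrain_state()].
#' @param config A [train_config()].
#' @return The state with updated parameters and a `history` data.frame
#'   (`epoch`, `train_loss`, `val_f1_macro`, `lr`), plus `best_epoch`.
#' @export
phase1 <- function(state, config) {
  run_supervised_phase(state, config, phase = "phase1", use_masking = FALSE)
}

#' Phase 3: joint training under simulated modality missingness
#'
#' With the decoder frozen, encoders, heads and fusion modules are trained
#' on a hybrid objective: with probability `P` (per epoch) one uniformly
#' chosen modality is masked and its latent replaced by the decoder
#' reconstruction, and the loss adds `lambda * MSE` between the
#' reconstruction and the encoder latent of the masked view to the focal
#' classification loss. Early stopping on mean validation macro-F1.
#'
#' @inheritParams phase1
#' @return Updated state; the decoder parameter hash is verified unchanged.
#' @export
phase3 <- function(state, config) {
  dec_hash <- param_hash(state$params, "^dec\\.")
  state <- run_supervised_phase(state, config, phase = "phase3",
                                use_masking = TRUE)
  if (!identical(param_hash(state$params, "^dec\\."), dec_hash)) {
    stop("internal error: decoder parameters drifted during phase 3")
  }
  state
}

run_supervised_phase <- function(state, config, phase, use_masking) {
  # force lazy arguments before seeding: a promise that itself calls
  # set.seed (e.g. a nested init_pretrain_state()) would otherwise clobber
  # this phase's RNG stream when first used below
  force(state)
  set.seed(config$seed + if (phase == "phase1") 101L else 303L)
  n_ds <- length(state$datasets)
  mods <- state$modalities
  p_mask <- config$mask_prob %||% (1 / length(mods))
  trainable_shared <- grep("^enc\\.", names(state$params), value = TRUE)
  adam <- adam_init()
  sched <- scheduler_init(config$lr[[phase]])
  best <- list(metric = -Inf, params = state$params, epoch = 0L)
  wait <- 0L
  hist <- list()
  max_ep <- config$max_epochs[[phase]]
  epoch <- 0L
  while (epoch < max_ep) {
    epoch <- epoch + 1L
    masked <- NULL
    if (use_masking && stats::runif(1) < p_mask) masked <- sample(mods, 1L)
    losses <- numeric(n_ds)
    for (i in sample.int(n_ds)) {
      ds <- state$datasets[[i]]
      model <- make_ds_model(state, i)
      views_in <- ds$matrices
      if (!is.null(masked)) views_in[[masked]] <- NULL
      fwd <- mogedn_forward(model, views_in, ds$graphs, missing = masked,
                            use_decoder = TRUE, dropout = config$dropout,
                            training = TRUE)
      recon <- NULL
      if (!is.null(masked)) {
        # encoder latent of the masked view is the reconstruction target
        enc <- encoder_forward(model$params, paste0("enc.", masked),
                               ds$matrices[[masked]],
                               get_adj(ds$graphs[[masked]]),
                               latent_norm = isTRUE(model$latent_norm))
        fwd$caches$enc[[masked]] <- enc$cache
        tr <- ds$train_idx
        diff <- fwd$latents[[masked]][tr, , drop = FALSE] -
          enc$z[tr, , drop = FALSE]
        mse <- mean(diff^2)
        dz <- matrix(0, nrow(enc$z), ncol(enc$z))
        dz[tr, ] <- config$lambda_recon * 2 * diff / length(diff)
        recon <- list(dz_hat = dz, dz_target = -dz, target = masked,
                      mse = mse)
      }
      cls <- cls_loss_and_grads(fwd, ds, config$gamma)
      losses[i] <- joint_loss(cls$loss,
                              if (is.null(recon)) 0 else recon$mse,
                              config$lambda_recon)
      if (!is.finite(losses[i])) stop("non-finite training loss in ", phase)
      grads <- mogedn_backward(model, fwd, ds$graphs, cls$dfused,
                               cls$dheads, recon)
      grads <- store_grad_names(grads, i)
      trainable <- c(trainable_shared,
                     grep(paste0("^", ds_prefix(i), "(head|fusion)"),
                          names(state$params), value = TRUE))
      upd <- adam_step(state$params, grads, adam, sched$lr, trainable,
                       weight_decay = config$weight_decay)
      state$params <- upd$params
      adam <- upd$state
    }
    val <- mean(vapply(seq_len(n_ds), function(i) {
      val_f1_macro(make_ds_model(state, i), state$datasets[[i]])
    }, numeric(1)))
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                val_f1_macro = val, lr = sched$lr)
    if (val > best$metric + 1e-10) {
      best <- list(metric = val, params = state$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
    sched <- scheduler_update(sched, val, config$scheduler_factor,
                              config$scheduler_patience, config$min_lr)
  }
  state$params <- best$params
  state$history[[phase]] <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(), train_loss = numeric(),
               val_f1_macro = numeric(), lr = numeric())
  state$best_epoch[[phase]] <- best$epoch
  state
}

#' Phase 2: decoder pretraining on latent reconstruction
#'
#' Freezes the encoders (their latents are precomputed once and verified
#' unchanged by parameter hash), then trains the shared decoder: for every
#' dataset, each modality takes a turn as the masked one and the decoder
#' minimizes the MSE between its reconstruction and the frozen encoder
#' latent on the training rows. The validation statistic is the average
#' similarity `Sim = 1/(1 + MSE)` across modalities and datasets on the
#' validation rows; early stopping maximizes it.
#'
#' @inheritParams phase1
#' @return Updated state with `history$phase2` (`epoch`, `train_mse`,
#'   `val_sim`, `lr`).
#' @export
phase2 <- function(state, config) {
  force(state) # see run_supervised_phase: force before seeding
  set.seed(config$seed + 202L)
  enc_hash <- param_hash(state$params, "^enc\\.")
  mods <- state$modalities
  latents <- lapply(seq_along(state$datasets), function(i) {
    model <- make_ds_model(state, i)
    ds <- state$datasets[[i]]
    stats::setNames(
      lapply(mods, function(m) encode(model, ds$matrices[[m]],
                                      ds$graphs[[m]], m)),
      mods
    )
  })
  dec_names <- grep("^dec\\.", names(state$params), value = TRUE)
  adam <- adam_init()
  sched <- scheduler_init(config$lr$phase2)
  best <- list(metric = -Inf, params = state$params, epoch = 0L)
  wait <- 0L
  hist <- list()
  epoch <- 0L
  while (epoch < config$max_epochs$phase2) {
    epoch <- epoch + 1L
    mse_acc <- c()
    for (i in sample.int(length(state$datasets))) {
      ds <- state$datasets[[i]]
      tr <- ds$train_idx
      for (target in mods) {
        u <- do.call(cbind, latents[[i]][setdiff(mods, target)])
        dec <- decoder_forward(state$params, u[tr, , drop = FALSE], target)
        diff <- dec$z_hat - latents[[i]][[target]][tr, , drop = FALSE]
        mse_acc <- c(mse_acc, mean(diff^2))
        db <- decoder_backward(2 * diff / length(diff), dec$cache,
                               state$params)
        upd <- adam_step(state$params, db$grads, adam, sched$lr, dec_names,
                         weight_decay = config$weight_decay)
        state$params <- upd$params
        adam <- upd$state
      }
    }
    val_sim <- validation_sim(state, latents)
    hist[[epoch]] <- data.frame(epoch = epoch, train_mse = mean(mse_acc),
                                val_sim = val_sim, lr = sched$lr)
    if (!all(is.finite(mse_acc))) stop("non-finite reconstruction loss")
    if (val_sim > best$metric + 1e-10) {
      best <- list(metric = val_sim, params = state$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
    sched <- scheduler_update(sched, val_sim, config$scheduler_factor,
                              config$scheduler_patience, config$min_lr)
  }
  state$params <- best$params
  if (!identical(param_hash(state$params, "^enc\\."), enc_hash)) {
    stop("internal error: encoder parameters drifted during phase 2")
  }
  state$history$phase2 <- do.call(rbind, hist)
  state$best_epoch$phase2 <- best$epoch
  state
}

validation_sim <- function(state, latents) {
  mods <- state$modalities
  sims <- c()
  for (i in seq_along(state$datasets)) {
    va <- state$datasets[[i]]$val_idx
    for (target in mods) {
      u <- do.call(cbind, latents[[i]][setdiff(mods, target)])
      z_hat <- decoder_forward(state$params, u[va, , drop = FALSE], target)$z_hat
      sims <- c(sims, similarity(recon_loss(
        z_hat, latents[[i]][[target]][va, , drop = FALSE]
      )))
    }
  }
  mean(sims)
}

#' Mean-prediction baseline similarity
#'
#' The Sim score achieved by predicting, for every validation sample, the
#' per-unit training mean of the target latent. Phase 2 is only informative
#' where the decoder beats this baseline.
#'
#' @param state A pretraining state with phase-1 encoders.
#' @return Mean baseline Sim across datasets and modalities.
#' @export
baseline_latent_sim <- function(state) {
  mods <- state$modalities
  sims <- c()
  for (i in seq_along(state$datasets)) {
    model <- make_ds_model(state, i)
    ds <- state$datasets[[i]]
    for (target in mods) {
      z <- encode(model, ds$matrices[[target]], ds$graphs[[target]], target)
      mu <- colMeans(z[ds$train_idx, , drop = FALSE])
      z_val <- z[ds$val_idx, , drop = FALSE]
      mse <- mean(sweep(z_val, 2L, mu, `-`)^2)
      sims <- c(sims, similarity(mse))
    }
  }
  mean(sims)
}

#' Initialize a pretraining state
#'
#' @param datasets List of prepared datasets from [prepare_dataset()]; all
#'   must share modality names and per-modality input widths.
#' @param config A [train_config()].
#' @param hidden_dims,latent_dim,core_width Network dimensions.
#' @return A `mogedn_pretrain_state` holding the flat parameter store
#'   (shared encoders and decoder plus per-dataset heads and fusion), the
#'   datasets, and empty history.
#' @export
init_pretrain_state <- function(datasets, config,
                                hidden_dims = c(200L, 100L),
                                latent_dim = 100L, core_width = 256L,
                                latent_norm = TRUE) {
  stopifnot(length(datasets) >= 1L)
  input_dims <- vapply(datasets[[1]]$matrices, ncol, integer(1))
  for (ds in datasets) {
    stopifnot(identical(vapply(ds$matrices, ncol, integer(1)), input_dims))
  }
  params <- init_pretrain_params(input_dims, datasets, hidden_dims,
                                 latent_dim, core_width, config$seed)
  structure(
    list(params = params,
         datasets = datasets,
         modalities = names(input_dims),
         input_dims = input_dims,
         hidden_dims = as.integer(hidden_dims),
         latent_dim = as.integer(latent_dim),
         core_width = as.integer(core_width),
         latent_norm = isTRUE(latent_norm),
         history = list(), best_epoch = list(),
         seed = config$seed,
         schema = "mogedn-checkpoint-v1"),
    class = "mogedn_pretrain_state"
  )
}

#' Run the full three-phase pretraining
#'
#' Executes Phases 1-3 in order and returns the final bundle. When `out_dir`
#' is given, the best checkpoint after each phase and the final bundle are
#' persisted there (directory checkpoints with JSON manifests).
#'
#' @param datasets Prepared datasets ([prepare_dataset()]).
#' @param config A [train_config()].
#' @param out_dir Optional output directory.
#' @inheritParams init_pretrain_state
#' @return The trained `mogedn_pretrain_state` (the "bundle").
#' @export
run_pretraining <- function(datasets, config, out_dir = NULL,
                            hidden_dims = c(200L, 100L), latent_dim = 100L,
                            core_width = 256L, latent_norm = TRUE) {
  state <- init_pretrain_state(datasets, config, hidden_dims, latent_dim,
                               core_width, latent_norm)
  state <- phase1(state, config)
  if (!is.null(out_dir)) save_pretrain_state(state, file.path(out_dir, "phase1"))
  state <- phase2(state, config)
  if (!is.null(out_dir)) save_pretrain_state(state, file.path(out_dir, "phase2"))
  state <- phase3(state, config)
  if (!is.null(out_dir)) save_pretrain_state(state, file.path(out_dir, "final"))
  state
}

#' Persist / restore a pretraining state
#'
#' The datasets themselves are not stored, only parameters, dimensions,
#' per-dataset class sets, histories and the seed; pass the prepared
#' datasets again when loading.
#'
#' @param state A `mogedn_pretrain_state`.
#' @param dir Checkpoint directory.
#' @return `dir` (save) or the restored state (load).
#' @export
save_pretrain_state <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slim <- state
  slim$datasets <- lapply(state$datasets, function(d) {
    list(name = d$name, classes = d$classes)
  })
  manifest <- list(
    schema = state$schema,
    modalities = state$modalities,
    input_dims = as.list(state$input_dims),
    hidden_dims = state$hidden_dims,
    latent_dim = state$latent_dim,
    core_width = state$core_width,
    seed = state$seed,
    datasets = lapply(slim$datasets, function(d) d),
    param_hash = param_hash(state$params)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(slim, file.path(dir, "state.rds"))
  invisible(dir)
}

#' @rdname save_pretrain_state
#' @param datasets Prepared datasets to reattach (optional).
#' @export
load_pretrain_state <- function(dir, datasets = NULL) {
  state <- readRDS(file.path(dir, "state.rds"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(param_hash(state$params), manifest$param_hash)) {
    stop("pretraining checkpoint hash mismatch in ", dir)
  }
  if (!is.null(datasets)) state$datasets <- datasets
  state
}
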