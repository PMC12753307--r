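#' Evaluation scenario
#'
#' @param missing Optional name of the single missing modality.
#' @param use_decoder Reconstruct the missing latent with the decoder
#'   (`TRUE`) or replace it with a zero vector (`FALSE`).
#' @param seed Seed recorded with the scenario.
#' @return An `eval_scenario` list.
#' @export
eval_scenario <- function(missing = NULL, use_decoder = TRUE, seed = 1L) {
  structure(list(missing = missing, use_decoder = isTRUE(use_decoder),
                 seed = as.integer(seed)),
            class = "eval_scenario")
}

#' Finetune a pretrained bundle on a new cohort
#'
#' Initializes fresh single-omics heads and a VCDN fusion classifier for the
#' cohort's class set and finetunes with the pretrained encoders and the
#' frozen pretrained decoder. Encoder layers are frozen except the final
#' (latent) layer; when a pretraining dataset has the same class count the
#' fusion module is warm-started from it and only its last linear layer
#' remains trainable, otherwise the fresh fusion is fully trainable. The
#' loss is the weighted cross-entropy (fused logits plus each head), the
#' optimizer Adam with the factor-0.7 / patience-10 scheduler, and the best
#' epoch is chosen by the composite score `0.2*ACC + 0.2*F1w + 0.6*F1m` on a
#' stratified validation split carved from the training partition.
#'
#' Like Phase 3, finetuning keeps the model exposed to simulated
#' missing-omics conditions: at each epoch, with probability `mask_prob` one
#' uniformly chosen modality is masked and its latent replaced by the frozen
#' decoder's reconstruction, so the new heads and fusion stay calibrated to
#' reconstructed inputs. Set `mask_prob = 0` for a plain complete-omics
#' finetune (the configuration used for tumor-specific attribution). When a
#' modality is genuinely absent from the cohort, name it in `missing`: it is
#' then masked in every epoch and handled per `use_decoder`.
#'
#' @param bundle A trained `mogedn_pretrain_state`.
#' @param cohort List with raw `views` (training partition), `labels`,
#'   `test_views`, `test_labels`.
#' @param config A [train_config()].
#' @param mask_prob Per-epoch masking probability during finetuning;
#'   `NULL` uses `config$mask_prob` (default `1 / n_modalities`).
#' @param missing Optional modality genuinely missing from the whole cohort.
#' @param use_decoder How a masked modality's latent is filled during
#'   finetuning: decoder reconstruction (`TRUE`) or zeros (`FALSE`).
#' @param n_specific Optional named tumor-specific feature counts (applied
#'   before normalization; evaluation cohorts use tumor-specific features
#'   only, so no common block).
#' @param log_transform Optional named logical per modality.
#' @param freeze_encoders `FALSE` (default) leaves the final (latent) GCN
#'   layer trainable; `TRUE` freezes the encoders completely, keeping the
#'   latents exactly in the space the pretrained decoder was calibrated on.
#' @return A `mogedn_finetuned` list: `model`, `history`, `best_epoch`,
#'   `val_report`, `scenario`, `stats`, `train_matrices`, `test_matrices`,
#'   `labels`, `test_labels`, `train_idx`, `val_idx`, `config`.
#' @export
finetune <- function(bundle, cohort, config = train_config(),
                     mask_prob = NULL, missing = NULL, use_decoder = TRUE,
                     n_specific = NULL, log_transform = NULL,
                     freeze_encoders = FALSE) {
  stopifnot(inherits(bundle, "mogedn_pretrain_state"))
  # force lazy arguments up front so promise side effects (in particular a
  # set.seed in a nested call) cannot interrupt the seeded streams below
  force(cohort); force(mask_prob); force(use_decoder); force(freeze_encoders)
  mods <- bundle$modalities
  if (!is.null(missing) && !(missing %in% mods)) {
    stop("unknown missing modality: ", missing)
  }
  if (is.null(mask_prob)) mask_prob <- config$mask_prob %||% (1 / length(mods))
  labels <- droplevels(as.factor(cohort$labels))
  split <- stratified_split(labels, config$val_frac,
                            seed = config$seed + 77L)
  prep <- prepare_dataset(
    list(views = cohort$views, labels = labels,
         train_idx = split$train, val_idx = split$val, name = "finetune"),
    config, n_specific = n_specific, log_transform = log_transform
  )
  for (m in mods) {
    if (ncol(prep$matrices[[m]]) != bundle$input_dims[[m]]) {
      stop(sprintf(
        "modality %s: cohort width %d != pretrained encoder input %d",
        m, ncol(prep$matrices[[m]]), bundle$input_dims[[m]]
      ))
    }
  }
  classes <- prep$classes
  set.seed(config$seed + 404L)
  model <- mogedn_model(bundle$input_dims, length(classes), classes,
                        hidden_dims = bundle$hidden_dims,
                        latent_dim = bundle$latent_dim,
                        core_width = bundle$core_width,
                        latent_norm = isTRUE(bundle$latent_norm),
                        seed = config$seed + 404L)
  shared <- grep("^(enc|dec)\\.", names(bundle$params), value = TRUE)
  model$params[shared] <- bundle$params[shared]
  # warm start the fusion from a pretraining dataset with a matching class
  # count; its earlier layer is then frozen and only fusion.l2 adapts
  fusion_trainable <- c("fusion.l1.W", "fusion.l1.b",
                        "fusion.l2.W", "fusion.l2.b")
  match_ds <- which(vapply(bundle$datasets,
                           function(d) length(d$classes) == length(classes),
                           logical(1)))
  if (length(match_ds)) {
    i <- match_ds[1]
    for (nm in fusion_trainable) {
      model$params[[nm]] <- bundle$params[[paste0(ds_prefix(i), nm)]]
    }
    fusion_trainable <- c("fusion.l2.W", "fusion.l2.b")
  }
  n_enc_layers <- length(bundle$hidden_dims) + 1L
  trainable <- c(
    if (!freeze_encoders) {
      paste0("enc.", rep(mods, each = 2), ".", c("W", "b"), n_enc_layers)
    },
    grep("^head\\.", names(model$params), value = TRUE),
    fusion_trainable
  )
  dec_hash <- param_hash(model$params, "^dec\\.")
  frozen_enc <- setdiff(grep("^enc\\.", names(model$params), value = TRUE),
                        trainable)
  frozen_enc_hash <- param_hash(model$params[frozen_enc])

  test_only <- setdiff(levels(as.factor(cohort$test_labels)), classes)
  if (length(test_only)) {
    warning("test classes absent from training: ",
            paste(test_only, collapse = ", "),
            "; they contribute 0 to macro-F1")
  }

  ds <- prep
  views_in <- ds$matrices
  graphs_in <- ds$graphs
  if (!is.null(missing)) {
    views_in[[missing]] <- NULL
    graphs_in[[missing]] <- NULL
  }
  w <- ds$weights$sample_weights
  tr <- ds$train_idx
  y_tr <- ds$labels[tr]
  adam <- adam_init()
  sched <- scheduler_init(config$lr$finetune)
  best <- list(metric = -Inf, params = model$params, epoch = 0L,
               report = NULL)
  wait <- 0L
  hist <- list()
  set.seed(config$seed + 505L)
  epoch <- 0L
  while (epoch < config$max_epochs$finetune) {
    epoch <- epoch + 1L
    masked <- missing
    if (is.null(masked) && mask_prob > 0 && stats::runif(1) < mask_prob) {
      masked <- sample(mods, 1L)
    }
    views_ep <- views_in
    if (!is.null(masked)) views_ep[[masked]] <- NULL
    fwd <- mogedn_forward(model, views_ep, graphs_in, missing = masked,
                          use_decoder = use_decoder,
                          dropout = config$dropout, training = TRUE)
    n_all <- nrow(fwd$fused_logits)
    fused_p <- softmax_rows(fwd$fused_logits[tr, , drop = FALSE])
    loss <- weighted_ce(fused_p, y_tr, w)
    dfused <- matrix(0, n_all, length(classes))
    dfused[tr, ] <- weighted_ce_grad_logits(fused_p, y_tr, w)
    dheads <- list()
    for (m in mods) {
      hp <- softmax_rows(fwd$head_logits[[m]][tr, , drop = FALSE])
      loss <- loss + weighted_ce(hp, y_tr, w)
      dh <- matrix(0, n_all, length(classes))
      dh[tr, ] <- weighted_ce_grad_logits(hp, y_tr, w)
      dheads[[m]] <- dh
    }
    if (!is.finite(loss)) stop("non-finite finetuning loss")
    grads <- mogedn_backward(model, fwd, graphs_in, dfused, dheads)
    upd <- adam_step(model$params, grads, adam, sched$lr, trainable,
                     weight_decay = config$weight_decay)
    model$params <- upd$params
    adam <- upd$state
    # composite score on the held-out validation split, under the cohort's
    # hard missingness (if any) but without simulated masking
    fwd_val <- mogedn_forward(model, views_in, graphs_in, missing = missing,
                              use_decoder = use_decoder)
    pred_val <- classes[max.col(fwd_val$fused_logits[ds$val_idx, , drop = FALSE],
                                ties.method = "first")]
    rep_val <- metrics(pred_val, ds$labels[ds$val_idx], classes = classes)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = loss,
                                val_composite = rep_val$composite,
                                lr = sched$lr)
    if (rep_val$composite > best$metric + 1e-10) {
      best <- list(metric = rep_val$composite, params = model$params,
                   epoch = epoch, report = rep_val)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
    sched <- scheduler_update(sched, rep_val$composite,
                              config$scheduler_factor,
                              config$scheduler_patience, config$min_lr)
  }
  model$params <- best$params
  stopifnot(identical(param_hash(model$params, "^dec\\."), dec_hash),
            identical(param_hash(model$params[frozen_enc]), frozen_enc_hash))

  test_matrices <- NULL
  test_labels <- NULL
  if (!is.null(cohort$test_views)) {
    test_matrices <- lapply(mods, function(m) {
      v <- cohort$test_views[[m]]
      if (!is.null(n_specific)) {
        v <- omics_view(
          v$matrix[, colnames(ds$matrices[[m]]), drop = FALSE], m
        )
      }
      normalize_view(v, stats = ds$stats[[m]])$view$matrix
    })
    names(test_matrices) <- mods
    # keep test-only classes as levels: they contribute 0 to macro-F1
    test_labels <- factor(
      as.character(cohort$test_labels),
      levels = union(classes, sort(unique(as.character(cohort$test_labels))))
    )
  }
  structure(
    list(model = model,
         history = do.call(rbind, hist),
         best_epoch = best$epoch,
         val_report = best$report,
         scenario = eval_scenario(missing, use_decoder, config$seed),
         stats = ds$stats,
         train_matrices = ds$matrices,
         test_matrices = test_matrices,
         labels = ds$labels,
         test_labels = test_labels,
         train_idx = ds$train_idx,
         val_idx = ds$val_idx,
         config = config),
    class = "mogedn_finetuned"
  )
}

#' Assess a finetuned model under an evaluation scenario
#'
#' Builds per-modality transductive graphs over the union of the training
#' partition and the test samples, runs the forward pass with the scenario's
#' masking and decoder flags, and reports metrics on the test rows only.
#' By default the scenario the model was finetuned under is used.
#'
#' @param ft A `mogedn_finetuned` (with test data attached).
#' @param scenario An [eval_scenario()]; `NULL` uses `ft$scenario`.
#' @return A `metric_report` on the test samples.
#' @export
assess <- function(ft, scenario = NULL) {
  stopifnot(inherits(ft, "mogedn_finetuned"))
  if (is.null(scenario)) scenario <- ft$scenario
  if (is.null(ft$test_matrices)) stop("no test data attached to this model")
  model <- ft$model
  if (!is.null(scenario$missing) &&
      !(scenario$missing %in% model$modalities)) {
    stop("unknown missing modality in scenario: ", scenario$missing)
  }
  mods <- model$modalities
  n_train <- nrow(ft$train_matrices[[1]])
  n_test <- nrow(ft$test_matrices[[1]])
  union_views <- list()
  graphs <- list()
  for (m in setdiff(mods, scenario$missing)) {
    x <- rbind(ft$train_matrices[[m]], ft$test_matrices[[m]])
    union_views[[m]] <- x
    graphs[[m]] <- build_graph(x, ft$config$edge_per_node)
  }
  fwd <- mogedn_forward(model, union_views, graphs,
                        missing = scenario$missing,
                        use_decoder = scenario$use_decoder)
  test_idx <- n_train + seq_len(n_test)
  pred <- model$classes[max.col(fwd$fused_logits[test_idx, , drop = FALSE],
                                ties.method = "first")]
  metrics(pred, ft$test_labels,
          classes = union(model$classes, levels(ft$test_labels)))
}

#' Sweep all missing-omics scenarios
#'
#' Assesses one finetuned model under the complete-omics condition plus
#' every single-modality-missing condition with the decoder on and off — the
#' decoder-off rows are the inference-time ablation where the missing
#' latent is zero-filled instead of reconstructed.
#'
#' @param ft A `mogedn_finetuned` (with test data attached).
#' @return data.frame with columns `scenario`, `use_decoder`, `acc`,
#'   `f1_weighted`, `f1_macro` (`2 * n_modalities + 1` rows).
#' @export
scenario_sweep <- function(ft) {
  stopifnot(inherits(ft, "mogedn_finetuned"))
  rows <- list(cbind(
    data.frame(scenario = "complete", use_decoder = NA),
    sweep_row(ft, eval_scenario())
  ))
  for (m in ft$model$modalities) {
    for (ud in c(TRUE, FALSE)) {
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scenario = paste0("missing_", m), use_decoder = ud),
        sweep_row(ft, eval_scenario(m, ud))
      )
    }
  }
  do.call(rbind, rows)
}

sweep_row <- function(ft, sc) {
  r <- assess(ft, sc)
  data.frame(acc = r$acc, f1_weighted = r$f1_weighted, f1_macro = r$f1_macro)
}

#' Write a scenario sweep as TSV
#' @param sweep Output of [scenario_sweep()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_scenario_sweep <- function(sweep, path) {
  data.table::fwrite(sweep, path, sep = "\t")
  invisible(path)
}
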