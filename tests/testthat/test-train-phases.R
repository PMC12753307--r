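# Training-phase contract tests at deliberately tiny sizes; the heavier
# behavioral benchmarks live in test-acceptance.R.

make_state <- function(seed = 1L, n_datasets = 1L, rho = 0.9, n = 90L,
                       config = small_config(seed)) {
  corpus <- small_corpus(seed = seed, n = n, n_datasets = n_datasets,
                         rho = rho)
  datasets <- lapply(corpus, prepare_dataset, config = config)
  init_pretrain_state(datasets, config, hidden_dims = c(16L),
                      latent_dim = 8L, core_width = 12L)
}

test_that("prepare_dataset normalizes on train stats and builds graphs", {
  corpus <- small_corpus(seed = 2)
  cfg <- small_config()
  ds <- prepare_dataset(corpus[[1]], cfg)
  tr <- ds$train_idx
  # training rows of each modality are centered/scaled by construction
  for (m in names(ds$matrices)) {
    expect_equal(unname(colMeans(ds$matrices[[m]][tr, ])),
                 rep(0, ncol(ds$matrices[[m]])), tolerance = 1e-6)
    expect_equal(nrow(ds$graphs[[m]]$adjacency), length(ds$labels))
  }
  # single-class training data is rejected
  bad <- corpus[[1]]
  bad$labels[] <- bad$labels[1]
  expect_error(prepare_dataset(bad, cfg), "fewer than two classes")
})

test_that("zero max_epochs returns the initial parameters and empty history", {
  cfg <- small_config()
  cfg$max_epochs$phase1 <- 0
  st <- make_state(config = cfg)
  before <- param_hash(st$params)
  st1 <- phase1(st, cfg)
  expect_equal(param_hash(st1$params), before)
  expect_equal(nrow(st1$history$phase1), 0)
})

# a denser-signal corpus (half the columns informative) that the tiny
# architecture can fit within a short run; the default 10% informative
# columns need benchmark-scale capacity and epochs to learn
learnable_fixture <- function(seed) {
  spec <- synth_spec(n_samples = 90,
                     dims = c(mrna = 40L, methylation = 40L, mirna = 20L),
                     latent_dim = 6L, informative_fraction = 0.5)
  corpus <- synth_corpus(list(spec), seed = seed)
  cfg <- train_config(seed = seed,
                      max_epochs = list(phase1 = 80, phase2 = 60,
                                        phase3 = 15, finetune = 25),
                      early_stop_patience = 20, edge_per_node = 6)
  datasets <- lapply(corpus, prepare_dataset, config = cfg)
  st <- init_pretrain_state(datasets, cfg, hidden_dims = c(16L),
                            latent_dim = 8L, core_width = 12L)
  list(st = st, cfg = cfg)
}

test_that("phase 1 learns a separable corpus and leaves the decoder untouched", {
  fx <- learnable_fixture(seed = 3)
  st <- fx$st
  cfg <- fx$cfg
  dec_before <- param_hash(st$params, "^dec\\.")
  st <- phase1(st, cfg)
  expect_identical(param_hash(st$params, "^dec\\."), dec_before)
  h <- st$history$phase1
  expect_lte(nrow(h), cfg$max_epochs$phase1)
  expect_true(all(is.finite(h$train_loss)))
  expect_gt(max(h$val_f1_macro), 0.8)
  expect_gte(st$best_epoch$phase1, 1)
})

test_that("phase 2 freezes encoders/heads and improves validation Sim", {
  fx <- learnable_fixture(seed = 3)
  cfg <- fx$cfg
  st <- phase1(fx$st, cfg)
  enc_before <- param_hash(st$params, "^enc\\.")
  head_before <- param_hash(st$params, "^ds1\\.")
  base <- baseline_latent_sim(st)
  st2 <- phase2(st, cfg)
  expect_identical(param_hash(st2$params, "^enc\\."), enc_before)
  expect_identical(param_hash(st2$params, "^ds1\\."), head_before)
  expect_false(identical(param_hash(st2$params, "^dec\\."),
                         param_hash(st$params, "^dec\\.")))
  expect_gt(max(st2$history$phase2$val_sim), base)
})

test_that("a decoder trained on exactly dependent latents reaches Sim near 1", {
  # construct a state whose modalities carry identical inputs and identical
  # encoder weights, so every latent is an exact (identity) linear function
  # of the others and the decoder can drive the validation MSE toward zero
  cfg <- small_config(seed = 5)
  cfg$max_epochs$phase2 <- 120
  cfg$lr$phase2 <- 5e-3
  cfg$weight_decay <- 0
  corpus <- small_corpus(seed = 5, n = 80)
  d <- corpus[[1]]
  base_mat <- d$views$mrna$matrix[, 1:20]
  for (m in names(d$views)) {
    mat <- base_mat
    colnames(mat) <- sprintf("%s_f%03d", m, 1:20)
    d$views[[m]] <- omics_view(mat, m)
  }
  ds <- prepare_dataset(d, cfg)
  st <- init_pretrain_state(list(ds), cfg, hidden_dims = c(16L),
                            latent_dim = 8L, core_width = 24L)
  for (m in c("methylation", "mirna")) {
    for (l in 1:2) {
      st$params[[sprintf("enc.%s.W%d", m, l)]] <- st$params[[sprintf("enc.mrna.W%d", l)]]
      st$params[[sprintf("enc.%s.b%d", m, l)]] <- st$params[[sprintf("enc.mrna.b%d", l)]]
    }
  }
  st <- phase2(st, cfg)
  expect_gt(max(st$history$phase2$val_sim), 0.95)
})

test_that("phase 3 freezes the decoder and stays finite", {
  cfg <- small_config(seed = 6)
  st <- make_state(seed = 6, config = cfg)
  st <- phase1(st, cfg)
  st <- phase2(st, cfg)
  dec_before <- param_hash(st$params, "^dec\\.")
  st3 <- phase3(st, cfg)
  expect_identical(param_hash(st3$params, "^dec\\."), dec_before)
  expect_true(all(is.finite(st3$history$phase3$train_loss)))
  expect_lte(nrow(st3$history$phase3), cfg$max_epochs$phase3)
})

test_that("pretraining is bit-reproducible and persists checkpoints", {
  cfg <- small_config(seed = 7)
  cfg$max_epochs <- list(phase1 = 8, phase2 = 8, phase3 = 5, finetune = 5)
  corpus <- small_corpus(seed = 7)
  datasets <- lapply(corpus, prepare_dataset, config = cfg)
  dir <- tempfile("pre")
  st_a <- run_pretraining(datasets, cfg, out_dir = dir, hidden_dims = c(16L),
                          latent_dim = 8L, core_width = 12L)
  st_b <- run_pretraining(datasets, cfg, hidden_dims = c(16L),
                          latent_dim = 8L, core_width = 12L)
  expect_equal(st_a$params, st_b$params)
  expect_equal(st_a$history, st_b$history)
  for (p in c("phase1", "phase2", "final")) {
    expect_true(file.exists(file.path(dir, p, "manifest.json")))
  }
  back <- load_pretrain_state(file.path(dir, "final"), datasets)
  expect_equal(back$params, st_a$params)
})

test_that("the LR scheduler decays by factor after patience and respects min_lr", {
  s <- mogedn:::scheduler_init(1e-2)
  s <- mogedn:::scheduler_update(s, 0.5, 0.7, 2, 1e-5)  # improvement
  expect_equal(s$lr, 1e-2)
  s <- mogedn:::scheduler_update(s, 0.4, 0.7, 2, 1e-5)  # wait 1
  s <- mogedn:::scheduler_update(s, 0.4, 0.7, 2, 1e-5)  # wait 2 -> decay
  expect_equal(s$lr, 7e-3)
  for (i in 1:100) s <- mogedn:::scheduler_update(s, 0.1, 0.7, 1, 1e-5)
  expect_gte(s$lr, 1e-5)
})

test_that("Adam with weight decay shrinks unused parameters toward zero", {
  set.seed(61)
  params <- list(w = matrix(1, 2, 2))
  grads <- list(w = matrix(0, 2, 2))
  st <- mogedn:::adam_init()
  for (i in 1:50) {
    upd <- mogedn:::adam_step(params, grads, st, lr = 1e-2,
                              trainable = "w", weight_decay = 0.1)
    params <- upd$params
    st <- upd$state
  }
  expect_lt(max(abs(params$w)), 1)
  # parameters outside `trainable` are never touched
  params2 <- list(a = 1, b = 2)
  upd <- mogedn:::adam_step(params2, list(a = 0.5, b = 0.5),
                            mogedn:::adam_init(), 0.1, trainable = "a")
  expect_equal(upd$params$b, 2)
  expect_false(upd$params$a == 1)
})
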