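test_that("attribution scores are zero for zero inputs and dead paths", {
  model <- tiny_model()
  x0 <- named_matrix(10, 12)
  x0[] <- 0  # X = 0 -> every a_ig = X_ig * grad = 0
  s <- suppressWarnings(attribute(model, x0, "mrna"))
  expect_equal(unname(s), rep(0, 12))
  # a feature whose first-layer weights are all zero gets s_g = 0
  model$params$enc.mrna.W1[3, ] <- 0
  s2 <- suppressWarnings(attribute(model, named_matrix(10, 12), "mrna"))
  expect_equal(unname(s2[3]), 0)
  expect_true(all(s2 >= 0))
  expect_error(attribute(model, x0[0, , drop = FALSE], "mrna"), "empty")
})

test_that("the linear-toy gradient matches the closed form to 1e-6", {
  # 1-layer linear encoder (identity adjacency, no latent norm) + linear
  # head on 2 features, 1 sample: l = -log softmax(x W E)_{y*}, so
  # dl/dx = (p - e_{y*}) E^T W^T and s_g = |x_g * (dl/dx)_g|
  model <- mogedn_model(c(a = 2L, b = 2L), 2L, hidden_dims = integer(),
                        latent_dim = 2L, core_width = 2L,
                        latent_norm = FALSE, seed = 3)
  w <- matrix(c(0.7, -0.2, 0.4, 1.1), 2, 2)
  e <- matrix(c(0.5, 0.3, -0.6, 0.9), 2, 2)
  model$params$enc.a.W1 <- w
  model$params$enc.a.b1 <- c(0, 0)
  model$params$head.a.W <- e
  model$params$head.a.b <- c(0, 0)
  x <- matrix(c(1.2, -0.8), 1, 2,
              dimnames = list("s1", c("f1", "f2")))
  s <- suppressWarnings(attribute(model, x, "a"))
  logits <- x %*% w %*% e
  p <- exp(logits) / sum(exp(logits))
  y_star <- which.max(logits)
  dlogit <- p
  dlogit[y_star] <- dlogit[y_star] - 1
  dx <- dlogit %*% t(e) %*% t(w)
  expect_equal(unname(s), abs(as.vector(x * dx)), tolerance = 1e-6)
  # scaling a feature column rescales the toy score analytically
  x2 <- x
  x2[, 1] <- 3 * x[, 1]
  s2 <- suppressWarnings(attribute(model, x2, "a"))
  logits2 <- x2 %*% w %*% e
  p2 <- exp(logits2) / sum(exp(logits2))
  d2 <- p2
  d2[which.max(logits2)] <- d2[which.max(logits2)] - 1
  expect_equal(unname(s2), abs(as.vector(x2 * (d2 %*% t(e) %*% t(w)))),
               tolerance = 1e-6)
})

test_that("attribution is sample-order invariant and never mutates parameters", {
  model <- tiny_model(seed = 9)
  x <- named_matrix(20, 12)
  before <- param_hash(model$params)
  s <- suppressWarnings(attribute(model, x, "mrna"))
  perm <- sample(20)
  s_perm <- suppressWarnings(attribute(model, x[perm, , drop = FALSE], "mrna"))
  expect_equal(s, s_perm, tolerance = 1e-12)
  expect_identical(param_hash(model$params), before)
})

test_that("rankings break ties by ascending feature index", {
  # duplicated columns give identical scores; ranking must be stable
  model <- mogedn_model(c(a = 4L, b = 4L), 2L, hidden_dims = integer(),
                        latent_dim = 3L, core_width = 2L,
                        latent_norm = FALSE, seed = 4)
  set.seed(71)
  x <- named_matrix(15, 4)
  x[, 3] <- x[, 1]
  model$params$enc.a.W1[3, ] <- model$params$enc.a.W1[1, ]
  s <- suppressWarnings(attribute(model, x, "a"))
  expect_equal(unname(s[1]), unname(s[3]), tolerance = 1e-12)
  res <- mogedn:::new_attribution_result(s, "a", "tumor_specific", 4)
  expect_lt(which(res$ranking == 1), which(res$ranking == 3))
  expect_equal(sort(res$ranking), 1:4)  # a permutation
})

test_that("tumor-specific biomarkers validate k and expose the full ranking", {
  model <- tiny_model(seed = 10)
  mats <- tiny_inputs(seed = 12)$views
  res <- tumor_specific_biomarkers(model, k = 8, matrices = mats)
  expect_named(res, model$modalities)
  expect_equal(res$mrna$provenance, "tumor_specific")
  expect_equal(nrow(res$mrna$top), 8)
  # k = feature count gives the full ranking
  full <- tumor_specific_biomarkers(model, k = 8, matrices = mats)$mirna
  expect_equal(sort(full$ranking), 1:8)
  expect_error(tumor_specific_biomarkers(model, k = 100, matrices = mats),
               "exceeds")
  expect_error(tumor_specific_biomarkers(model), "matrices")
})

test_that("shared biomarkers truncate to the common block per modality", {
  cfg <- small_config(seed = 13)
  cfg$max_epochs <- list(phase1 = 5, phase2 = 2, phase3 = 2, finetune = 2)
  corpus <- small_corpus(seed = 13, n_datasets = 2)
  datasets <- lapply(corpus, prepare_dataset, config = cfg)
  st <- run_pretraining(datasets, cfg, hidden_dims = c(16L),
                        latent_dim = 8L, core_width = 12L)
  d_shared <- c(mrna = 15L, methylation = 15L, mirna = 8L)
  res <- shared_biomarkers(st, d_shared = d_shared,
                           k = c(mrna = 10L, methylation = 10L, mirna = 5L))
  for (m in names(res)) {
    expect_lte(max(res[[m]]$ranking), d_shared[[m]])
    expect_equal(length(res[[m]]$scores), d_shared[[m]])
    expect_equal(res[[m]]$provenance, "shared")
  }
  # single-dataset corpus: averaged scores equal the per-dataset scores
  st1 <- run_pretraining(datasets[1], cfg, hidden_dims = c(16L),
                         latent_dim = 8L, core_width = 12L)
  res1 <- shared_biomarkers(st1, d_shared = d_shared)
  model1 <- mogedn:::make_ds_model(st1, 1)
  direct <- attribute(model1, st1$datasets[[1]]$matrices$mrna, "mrna")
  expect_equal(res1$mrna$scores, direct[1:15], tolerance = 1e-12)
})

test_that("biomarker TSV export preserves the ranking", {
  model <- tiny_model(seed = 14)
  mats <- tiny_inputs(seed = 15)$views
  res <- tumor_specific_biomarkers(model, k = 5, matrices = mats)$mrna
  path <- tempfile(fileext = ".tsv")
  write_biomarkers(res, path)
  tab <- data.table::fread(path)
  expect_equal(nrow(tab), 12)
  expect_equal(tab$feature_id, res$feature_names[res$ranking])
  expect_true(all(diff(tab$score) <= 1e-12))
})
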