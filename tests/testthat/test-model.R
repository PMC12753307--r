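test_that("model construction lays out all components in the flat store", {
  model <- tiny_model()
  nms <- names(model$params)
  for (m in model$modalities) {
    expect_true(all(paste0("enc.", m, ".W", 1:2) %in% nms))
    expect_true(paste0("dec.head.", m, ".W") %in% nms)
    expect_true(paste0("head.", m, ".W") %in% nms)
  }
  expect_true(all(c("dec.core.W", "fusion.l1.W", "fusion.l2.W") %in% nms))
  # decoder input is the concatenation of the other modalities' latents
  expect_equal(dim(model$params$dec.core.W), c(2 * 4, 5))
  # fusion joint width is C^M
  expect_equal(dim(model$params$fusion.l1.W), c(27, 27))
  # same seed, same initialization
  expect_equal(tiny_model(seed = 7)$params, tiny_model(seed = 7)$params)
})

test_that("VCDN joint tensor equals the per-sample outer product", {
  set.seed(41)
  probs <- lapply(1:3, function(i) random_probs(6, 3))
  j <- mogedn:::vcdn_joint(probs)
  expect_equal(dim(j), c(6, 27))
  for (i in c(1, 4)) {
    outer3 <- outer(outer(probs[[1]][i, ], probs[[2]][i, ]), probs[[3]][i, ])
    # first modality's class index varies slowest in the flattened layout
    flat <- as.vector(aperm(outer3, c(3, 2, 1)))
    expect_equal(unname(j[i, ]), flat, tolerance = 1e-12)
  }
  # joint rows still sum to 1 (product of simplex rows)
  expect_equal(unname(rowSums(j)), rep(1, 6), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences through the full model", {
  set.seed(42)
  model <- tiny_model()
  inp <- tiny_inputs(n = 15)
  lab <- sample(3, 15, replace = TRUE)
  loss_fn <- function(params) {
    m2 <- model
    m2$params <- params
    fwd <- suppressWarnings(
      mogedn_forward(m2, inp$views, inp$graphs, missing = "mirna",
                     use_decoder = TRUE)
    )
    p <- mogedn:::softmax_rows(fwd$fused_logits)
    loss <- weighted_ce(p, lab)
    for (mm in m2$modalities) {
      loss <- loss + weighted_ce(mogedn:::softmax_rows(fwd$head_logits[[mm]]), lab)
    }
    loss
  }
  fwd <- suppressWarnings(
    mogedn_forward(model, inp$views, inp$graphs, missing = "mirna",
                   use_decoder = TRUE)
  )
  p <- mogedn:::softmax_rows(fwd$fused_logits)
  dfused <- mogedn:::weighted_ce_grad_logits(p, lab, rep(1, 15))
  dheads <- lapply(fwd$head_logits, function(z) {
    mogedn:::weighted_ce_grad_logits(mogedn:::softmax_rows(z), lab, rep(1, 15))
  })
  grads <- mogedn:::mogedn_backward(model, fwd, inp$graphs, dfused, dheads)
  check <- c("enc.mrna.W1", "enc.methylation.W2", "dec.core.W",
             "dec.head.mirna.W", "head.mirna.W", "fusion.l1.W", "fusion.l2.b")
  num <- numeric_grad(loss_fn, model$params, check)
  for (nm in check) {
    denom <- max(abs(num[[nm]]), 1e-4)
    expect_lt(max(abs(grads[[nm]] - num[[nm]])) / denom, 1e-4)
  }
})

test_that("forward provenance tracks encoded / reconstructed / zero-filled", {
  model <- tiny_model()
  inp <- tiny_inputs()
  fwd <- mogedn_forward(model, inp$views, inp$graphs)
  expect_equal(unname(fwd$provenance), rep("encoded", 3))
  fwd_dec <- mogedn_forward(model, inp$views[c("mrna", "methylation")],
                            inp$graphs, missing = "mirna", use_decoder = TRUE)
  expect_equal(unname(fwd_dec$provenance["mirna"]), "reconstructed")
  fwd_zero <- mogedn_forward(model, inp$views[c("mrna", "methylation")],
                             inp$graphs, missing = "mirna", use_decoder = FALSE)
  expect_equal(unname(fwd_zero$provenance["mirna"]), "zero_filled")
  expect_equal(fwd_zero$latents$mirna, matrix(0, 25, model$latent_dim))
  # the two fill strategies give different fused logits
  expect_false(isTRUE(all.equal(fwd_dec$fused_logits, fwd_zero$fused_logits)))
  # mask wins over a supplied view
  expect_warning(
    mogedn_forward(model, inp$views, inp$graphs, missing = "mirna"),
    "mask wins"
  )
  expect_error(mogedn_forward(model, inp$views, inp$graphs, missing = "cnv"),
               "unknown missing")
})

test_that("encode/decode_missing/classify_head/vcdn_fuse compose into the forward", {
  model <- tiny_model()
  inp <- tiny_inputs()
  latents <- lapply(model$modalities, function(m) {
    encode(model, inp$views[[m]], inp$graphs[[m]], m)
  })
  names(latents) <- model$modalities
  z_hat <- decode_missing(model, latents[c("mrna", "methylation")], "mirna")
  expect_equal(dim(z_hat), c(25, 4))
  logits <- lapply(model$modalities, function(m) {
    classify_head(model, latents[[m]], m)
  })
  fused <- vcdn_fuse(model, logits)
  fwd <- mogedn_forward(model, inp$views, inp$graphs)
  expect_equal(fused, fwd$fused_logits, tolerance = 1e-12)
  expect_error(decode_missing(model, latents["mrna"], "mirna"), "missing")
})

test_that("latent standardization yields unit-scale latents per unit", {
  model <- tiny_model()
  inp <- tiny_inputs(n = 40)
  z <- encode(model, inp$views$mrna, inp$graphs$mrna, "mrna")
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-8)
  expect_equal(unname(apply(z, 2, stats::sd)) * sqrt(39 / 40), rep(1, 4),
               tolerance = 1e-3)
})

test_that("checkpoints round-trip with hash verification", {
  model <- tiny_model(seed = 5)
  dir <- tempfile("ckpt")
  save_checkpoint(model, dir, extra = list(note = "unit-test"))
  back <- load_checkpoint(dir)
  expect_equal(back$params, model$params)
  expect_equal(param_hash(back$params), param_hash(model$params))
  # tampering with the stored parameters is detected
  bad <- back
  bad$params$fusion.l2.b <- bad$params$fusion.l2.b + 1
  saveRDS(bad, file.path(dir, "model.rds"))
  expect_error(load_checkpoint(dir), "hash mismatch")
})
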