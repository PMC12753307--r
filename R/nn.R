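# Dense-layer primitives for the GCN encoders, decoder, heads and VCDN.
# Parameters live in a flat named list of matrices/vectors; every forward
# returns the caches its matching backward consumes. All shapes are small
# (hundreds of samples, <= 1000 features), so plain BLAS matrix products
# are the right tool.

LEAKY_SLOPE <- 0.25

leaky_relu <- function(x, slope = LEAKY_SLOPE) {
  ifelse(x > 0, x, slope * x)
}

leaky_relu_grad <- function(pre, slope = LEAKY_SLOPE) {
  ifelse(pre > 0, 1, slope)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# VJP of row-wise softmax: given dL/dp and p, return dL/dz
softmax_backward <- function(dp, p) {
  p * (dp - rowSums(dp * p))
}

# Glorot-uniform initialization
init_linear <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(
    W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
    b = rep(0, n_out)
  )
}

add_linear_params <- function(params, name, n_in, n_out) {
  p <- init_linear(n_in, n_out)
  params[[paste0(name, ".W")]] <- p$W
  params[[paste0(name, ".b")]] <- p$b
  params
}

linear_forward <- function(x, params, name) {
  sweep(x %*% params[[paste0(name, ".W")]], 2L,
        params[[paste0(name, ".b")]], `+`)
}

# --- GCN encoder -----------------------------------------------------------
# widths = c(input, hidden..., latent); each layer computes A %*% H %*% W + b
# with LeakyReLU between layers and a linear final (latent) layer. Dropout is
# applied to the encoder input only, during training.

encoder_param_names <- function(prefix, widths) {
  l <- seq_len(length(widths) - 1L)
  c(paste0(prefix, ".W", l), paste0(prefix, ".b", l))
}

init_encoder <- function(params, prefix, widths) {
  for (l in seq_len(length(widths) - 1L)) {
    p <- init_linear(widths[l], widths[l + 1L])
    params[[paste0(prefix, ".W", l)]] <- p$W
    params[[paste0(prefix, ".b", l)]] <- p$b
  }
  params
}

BN_EPS <- 1e-5

encoder_forward <- function(params, prefix, x, adj, dropout = 0,
                            training = FALSE, latent_norm = FALSE) {
  n_layers <- length(grep(paste0("^", prefix, "\\.W"), names(params)))
  drop_mask <- NULL
  h <- x
  if (training && dropout > 0) {
    drop_mask <- matrix(
      stats::rbinom(length(x), 1L, 1 - dropout) / (1 - dropout),
      nrow(x), ncol(x)
    )
    h <- h * drop_mask
  }
  inputs <- vector("list", n_layers)   # A %*% H fed to each linear
  pres <- vector("list", n_layers)     # pre-activations
  for (l in seq_len(n_layers)) {
    ah <- as.matrix(adj %*% h)
    inputs[[l]] <- ah
    pre <- sweep(ah %*% params[[paste0(prefix, ".W", l)]], 2L,
                 params[[paste0(prefix, ".b", l)]], `+`)
    pres[[l]] <- pre
    h <- if (l < n_layers) leaky_relu(pre) else pre
  }
  bn <- NULL
  if (latent_norm && nrow(h) > 1L) {
    # standardize each latent unit over the forward batch (all graph nodes
    # in the transductive full-batch setting), without learnable affine:
    # keeps the latent scale O(1) so reconstruction MSE and the Sim monitor
    # are comparable across modalities and runs
    mu <- colMeans(h)
    v <- colMeans(h * h) - mu * mu
    inv_sd <- 1 / sqrt(v + BN_EPS)
    z <- sweep(sweep(h, 2L, mu, `-`), 2L, inv_sd, `*`)
    bn <- list(z_hat = z, inv_sd = inv_sd)
    h <- z
  }
  list(z = h, cache = list(inputs = inputs, pres = pres,
                           drop_mask = drop_mask, n_layers = n_layers,
                           bn = bn))
}

# returns list(grads = named list for this encoder, dx = gradient w.r.t. the
# (pre-dropout) input)
encoder_backward <- function(dz, cache, params, prefix, adj) {
  grads <- list()
  dh <- dz
  if (!is.null(cache$bn)) {
    zh <- cache$bn$z_hat
    n <- nrow(dz)
    dh <- sweep(
      dz - rep(colMeans(dz), each = n) - zh * rep(colMeans(dz * zh), each = n),
      2L, cache$bn$inv_sd, `*`
    )
  }
  for (l in rev(seq_len(cache$n_layers))) {
    dpre <- if (l < cache$n_layers) dh * leaky_relu_grad(cache$pres[[l]]) else dh
    w_name <- paste0(prefix, ".W", l)
    grads[[w_name]] <- crossprod(cache$inputs[[l]], dpre)
    grads[[paste0(prefix, ".b", l)]] <- colSums(dpre)
    dah <- dpre %*% t(params[[w_name]])
    dh <- as.matrix(Matrix::crossprod(adj, dah))
  }
  if (!is.null(cache$drop_mask)) dh <- dh * cache$drop_mask
  list(grads = grads, dx = dh)
}

# --- shared multi-head decoder --------------------------------------------
# concat of the available latents -> core (one hidden layer, LeakyReLU) ->
# per-modality output head producing that modality's latent width.

init_decoder <- function(params, modalities, latent_dim, core_width) {
  n_in <- (length(modalities) - 1L) * latent_dim
  params <- add_linear_params(params, "dec.core", n_in, core_width)
  for (m in modalities) {
    params <- add_linear_params(params, paste0("dec.head.", m),
                                core_width, latent_dim)
  }
  params
}

decoder_forward <- function(params, u, target) {
  pre1 <- linear_forward(u, params, "dec.core")
  h <- leaky_relu(pre1)
  z_hat <- linear_forward(h, params, paste0("dec.head.", target))
  list(z_hat = z_hat, cache = list(u = u, pre1 = pre1, h = h, target = target))
}

decoder_backward <- function(dz_hat, cache, params) {
  head <- paste0("dec.head.", cache$target)
  grads <- list()
  grads[[paste0(head, ".W")]] <- crossprod(cache$h, dz_hat)
  grads[[paste0(head, ".b")]] <- colSums(dz_hat)
  dh <- dz_hat %*% t(params[[paste0(head, ".W")]])
  dpre1 <- dh * leaky_relu_grad(cache$pre1)
  grads[["dec.core.W"]] <- crossprod(cache$u, dpre1)
  grads[["dec.core.b"]] <- colSums(dpre1)
  du <- dpre1 %*% t(params[["dec.core.W"]])
  list(grads = grads, du = du)
}

# --- VCDN fusion -----------------------------------------------------------
# Per-sample joint tensor = outer product of the per-modality class
# probability vectors, flattened so the first modality's class index varies
# slowest (iterated Kronecker product), then a one-hidden-layer MLP.

# class index of each modality at each joint position: K x M matrix
vcdn_digits <- function(n_classes, n_modalities) {
  k <- n_classes^n_modalities
  d <- matrix(0L, k, n_modalities)
  for (m in seq_len(n_modalities)) {
    block <- n_classes^(n_modalities - m)
    d[, m] <- ((seq_len(k) - 1L) %/% block) %% n_classes + 1L
  }
  d
}

vcdn_joint <- function(probs_list) {
  n <- nrow(probs_list[[1]])
  c_classes <- ncol(probs_list[[1]])
  digits <- vcdn_digits(c_classes, length(probs_list))
  j <- matrix(1, n, nrow(digits))
  for (m in seq_along(probs_list)) {
    j <- j * probs_list[[m]][, digits[, m], drop = FALSE]
  }
  j
}

# dL/dJ -> list of dL/dP_o
vcdn_joint_backward <- function(dj, probs_list) {
  c_classes <- ncol(probs_list[[1]])
  m_total <- length(probs_list)
  digits <- vcdn_digits(c_classes, m_total)
  lapply(seq_len(m_total), function(o) {
    other <- matrix(1, nrow(dj), nrow(digits))
    for (m in seq_len(m_total)) {
      if (m != o) other <- other * probs_list[[m]][, digits[, m], drop = FALSE]
    }
    contrib <- dj * other
    dp <- matrix(0, nrow(dj), c_classes)
    for (c in seq_len(c_classes)) {
      cols <- which(digits[, o] == c)
      dp[, c] <- rowSums(contrib[, cols, drop = FALSE])
    }
    dp
  })
}

init_vcdn <- function(params, n_classes, n_modalities) {
  k <- n_classes^n_modalities
  params <- add_linear_params(params, "fusion.l1", k, k)
  add_linear_params(params, "fusion.l2", k, n_classes)
}

vcdn_forward <- function(params, probs_list) {
  j <- vcdn_joint(probs_list)
  pre1 <- linear_forward(j, params, "fusion.l1")
  h <- leaky_relu(pre1)
  logits <- linear_forward(h, params, "fusion.l2")
  list(logits = logits,
       cache = list(j = j, pre1 = pre1, h = h, probs_list = probs_list))
}

vcdn_backward <- function(dlogits, cache, params) {
  grads <- list()
  grads[["fusion.l2.W"]] <- crossprod(cache$h, dlogits)
  grads[["fusion.l2.b"]] <- colSums(dlogits)
  dh <- dlogits %*% t(params[["fusion.l2.W"]])
  dpre1 <- dh * leaky_relu_grad(cache$pre1)
  grads[["fusion.l1.W"]] <- crossprod(cache$j, dpre1)
  grads[["fusion.l1.b"]] <- colSums(dpre1)
  dj <- dpre1 %*% t(params[["fusion.l1.W"]])
  list(grads = grads, dprobs = vcdn_joint_backward(dj, cache$probs_list))
}

# --- Adam ------------------------------------------------------------------

adam_init <- function() {
  list(m = list(), v = list(), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr, trainable = names(grads),
                      weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in intersect(trainable, names(grads))) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

accumulate_grads <- function(total, add) {
  for (nm in names(add)) {
    total[[nm]] <- if (is.null(total[[nm]])) add[[nm]] else total[[nm]] + add[[nm]]
  }
  total
}

#' Hash of a parameter set
#'
#' Used to verify freeze contracts (encoders untouched in Phase 2, decoder
#' untouched in Phase 3 and finetuning) and checkpoint round-trips.
#'
#' @param params Named list of numeric arrays.
#' @param prefix Optional regex; only parameters whose name matches are
#'   hashed (e.g. `"^enc\\."` or `"^dec\\."`).
#' @return Character hash.
#' @export
param_hash <- function(params, prefix = NULL) {
  nms <- sort(names(params))
  if (!is.null(prefix)) nms <- grep(prefix, nms, value = TRUE)
  rlang::hash(params[nms])
}
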