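test_that("focal loss matches the brute-force oracle on random fixtures", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(2:50, 1)
    c_tot <- sample(2:5, 1)
    p <- random_probs(n, c_tot)
    y <- mogedn:::one_hot(sample(c_tot, n, replace = TRUE), c_tot)
    gamma <- sample(c(0, 0.5, 1, 2, 3), 1)
    alpha <- stats::rexp(c_tot) + 0.1
    w <- stats::rexp(n) + 0.1
    expect_equal(focal_loss(p, y, gamma, alpha, w),
                 oracle_focal_loss(p, y, gamma, alpha, w), tolerance = 1e-10)
  }
})

test_that("focal loss with gamma=0 and unit weights is mean cross-entropy", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(2:40, 1)
    c_tot <- sample(2:5, 1)
    p <- random_probs(n, c_tot)
    lab <- sample(c_tot, n, replace = TRUE)
    y <- mogedn:::one_hot(lab, c_tot)
    ce <- mean(-log(p[cbind(seq_len(n), lab)]))
    expect_equal(focal_loss(p, y, gamma = 0), ce, tolerance = 1e-10)
  }
})

test_that("focal loss rejects off-simplex rows and negative gamma", {
  p <- matrix(c(0.5, 0.6, 0.3, 0.7), 2, 2)  # first row sums to 1.1
  y <- mogedn:::one_hot(c(1L, 2L), 2L)
  expect_error(focal_loss(p, y, 2), "simplex")
  expect_error(focal_loss(random_probs(2, 2), y, gamma = -1))
})

test_that("focal loss logit gradient matches finite differences", {
  set.seed(13)
  n <- 7; c_tot <- 4
  z <- matrix(rnorm(n * c_tot), n, c_tot)
  lab <- sample(c_tot, n, replace = TRUE)
  alpha <- stats::rexp(c_tot) + 0.5
  w <- stats::rexp(n) + 0.5
  for (gamma in c(0, 2)) {
    f <- function(zz) {
      focal_loss(mogedn:::softmax_rows(zz), mogedn:::one_hot(lab, c_tot),
                 gamma, alpha, w)
    }
    g <- mogedn:::focal_loss_grad_logits(mogedn:::softmax_rows(z), lab,
                                         gamma, alpha, w)
    num <- z * 0
    h <- 1e-6
    for (i in seq_along(z)) {
      zp <- z; zp[i] <- zp[i] + h
      zm <- z; zm[i] <- zm[i] - h
      num[i] <- (f(zp) - f(zm)) / (2 * h)
    }
    expect_equal(g, num, tolerance = 1e-6)
  }
})

test_that("weighted CE matches its oracle and known closed forms", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    c_tot <- sample(2:5, 1)
    p <- random_probs(n, c_tot)
    lab <- sample(c_tot, n, replace = TRUE)
    w <- stats::rexp(n) + 0.1
    expect_equal(weighted_ce(p, lab, w), oracle_weighted_ce(p, lab, w),
                 tolerance = 1e-10)
  }
  # perfect probabilities -> 0; uniform probabilities -> log C
  perfect <- mogedn:::one_hot(c(1L, 2L), 2L)
  expect_equal(weighted_ce(perfect, c(1L, 2L)), 0, tolerance = 1e-9)
  unif <- matrix(1 / 4, 3, 4)
  expect_equal(weighted_ce(unif, c(1L, 3L, 4L)), log(4), tolerance = 1e-10)
})

test_that("balanced class weights follow N / (C * n_c) with mean-1 samples", {
  lab <- factor(c(rep("a", 6), rep("b", 3), rep("c", 1)))
  bw <- balanced_class_weights(lab)
  expect_equal(unname(bw$alpha), 10 / (3 * c(6, 3, 1)))
  expect_equal(mean(bw$sample_weights), 1, tolerance = 1e-12)
  expect_error(balanced_class_weights(factor(rep("a", 5))), "two classes")
})

test_that("recon loss, similarity and joint loss follow their formulas", {
  z <- matrix(0, 2, 2)
  z_hat <- matrix(1, 2, 2)
  expect_equal(recon_loss(z_hat, z), 1)
  expect_error(recon_loss(matrix(0, 2, 3), z), "shape")
  expect_equal(similarity(0), 1)
  expect_equal(similarity(1), 0.5)
  # strictly decreasing, in (0, 1]
  mses <- sort(stats::rexp(20))
  sims <- similarity(mses)
  expect_true(all(diff(sims) < 0))
  expect_true(all(sims > 0 & sims <= 1))
  expect_equal(joint_loss(0.3, 0.2, 1), 0.5)
  expect_equal(joint_loss(0.3, 0.2, 0), 0.3)
  expect_error(joint_loss(1, 1, -0.5))
})

test_that("metrics match the hand confusion-matrix oracle", {
  set.seed(15)
  for (rep in 1:100) {
    n <- sample(2:50, 1)
    c_tot <- sample(2:5, 1)
    classes <- paste0("k", seq_len(c_tot))
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    got <- metrics(pred, truth, classes = classes)
    want <- oracle_metrics(pred, truth, classes)
    expect_equal(got$acc, want$acc)
    expect_equal(got$f1_weighted, want$f1_weighted)
    expect_equal(got$f1_macro, want$f1_macro)
    expect_equal(got$per_class$precision, want$precision)
    expect_equal(got$per_class$recall, want$recall)
    expect_equal(got$per_class$f1, want$f1)
    expect_equal(got$composite,
                 0.2 * want$acc + 0.2 * want$f1_weighted + 0.6 * want$f1_macro)
  }
})

test_that("metrics handle the spec fixtures and degenerate cases", {
  # perfect predictions
  r <- metrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(c(r$acc, r$f1_weighted, r$f1_macro, r$composite), rep(1, 4))
  # confusion matrix [[5,1],[2,2]] textbook check
  truth <- c(rep("pos", 6), rep("neg", 4))
  pred <- c(rep("pos", 5), "neg", rep("pos", 2), rep("neg", 2))
  r <- metrics(pred, truth, classes = c("pos", "neg"))
  expect_equal(r$per_class$precision, c(5 / 7, 2 / 3))
  expect_equal(r$per_class$recall, c(5 / 6, 2 / 4))
  expect_equal(r$per_class$f1,
               c(2 * (5 / 7) * (5 / 6) / (5 / 7 + 5 / 6),
                 2 * (2 / 3) * 0.5 / (2 / 3 + 0.5)))
  # class in the class set but absent from truth and pred contributes F1 = 0
  r <- metrics(c("a", "a"), c("a", "a"), classes = c("a", "b"))
  expect_equal(r$f1_macro, 0.5)
  # composite is a convex combination
  expect_true(r$composite >= min(r$acc, r$f1_weighted, r$f1_macro))
  expect_true(r$composite <= max(r$acc, r$f1_weighted, r$f1_macro))
  expect_error(metrics(c("a", "b"), c("a")), "length")
})

test_that("metric reports serialize to single-line JSON", {
  r <- metrics(c("a", "b"), c("a", "a"))
  j <- jsonlite::fromJSON(metric_report_json(r))
  expect_equal(j$acc, r$acc)
  expect_equal(j$f1_macro, r$f1_macro)
  expect_equal(j$n, 2L)
})
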