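# The network layers are hand-implemented; their backward passes are checked
# against central finite differences here.

fd_probe <- function(net, inputs, y, n_probe = 2, h = 1e-5) {
  sx <- ecgmff:::nn_softmax_xent
  s0 <- sx(net$forward(inputs, train = TRUE), y)
  net$backward(s0$dlogits)
  worst <- 0
  for (ly in net$param_layers) for (nm in names(ly$params)) {
    g <- ly$grads[[nm]]
    for (t in seq_len(n_probe)) {
      i <- sample(length(ly$params[[nm]]), 1)
      orig <- ly$params[[nm]][i]
      ly$params[[nm]][i] <- orig + h
      lp <- sx(net$forward(inputs, train = TRUE), y)$loss
      ly$params[[nm]][i] <- orig - h
      lm <- sx(net$forward(inputs, train = TRUE), y)$loss
      ly$params[[nm]][i] <- orig
      num <- (lp - lm) / (2 * h)
      worst <- max(worst, abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])))
    }
  }
  worst
}

test_that("backpropagation matches finite differences through the fused model", {
  set.seed(42)
  net <- build_mff(3, c("beat", "gaf", "st"), width_multiplier = 1 / 16,
                   image_size = 8, dropout_rate = 0)
  B <- 3
  inputs <- list(beat = array(rnorm(12 * 48 * B), c(12, 48, B)),
                 gaf = array(rnorm(8 * 8 * B), c(1, 8, 8, B)),
                 st = array(rnorm(8 * 8 * B), c(1, 8, 8, B)))
  y <- sample(1:3, B, replace = TRUE)
  expect_lt(fd_probe(net, inputs, y), 1e-4)
})

test_that("branches produce finite 512/width-scaled feature vectors", {
  set.seed(1)
  b1 <- build_branch(branch_spec("1d", width_multiplier = 1 / 8))
  f1 <- b1$fwd(array(rnorm(12 * 651 * 2), c(12, 651, 2)))
  expect_equal(dim(f1), c(64, 2))            # 512/8
  expect_true(all(is.finite(f1)))

  b2 <- build_branch(branch_spec("2d", width_multiplier = 1 / 8))
  f2 <- b2$fwd(array(rnorm(32 * 32 * 2), c(1, 32, 32, 2)))
  expect_equal(dim(f2), c(64, 2))
  expect_true(all(is.finite(f2)))

  # full-scale spec: 512-wide features, kernel sizes per the architecture
  spec1 <- branch_spec("1d")
  expect_equal(spec1$widths, c(64, 128, 256, 512))
  expect_equal(spec1$first_kernel, 15)
  expect_equal(spec1$block_kernel, 7)
  expect_equal(spec1$se_reduction, c(4, 8, 16, 32))
  expect_true(spec1$use_se)
  expect_equal(spec1$dropout_rate, 0.2)
  spec2 <- branch_spec("2d")
  expect_equal(spec2$first_kernel, 7)
  expect_equal(spec2$block_kernel, 3)
  expect_false(spec2$use_se)

  expect_error(b1$fwd(array(0, c(5, 64, 1))), "channels")
})

test_that("SE excitation weights lie strictly in (0, 1)", {
  set.seed(2)
  se <- ecgmff:::nn_se(8, reduction = 4)
  x <- array(rnorm(8 * 20 * 3), c(8, 20, 3))
  out <- se$fwd(x, train = TRUE)
  w <- se$last_weights()
  expect_true(all(w > 0 & w < 1))
  expect_equal(dim(out), dim(x))
  # output is input rescaled channelwise
  expect_equal(out[3, 5, 2], x[3, 5, 2] * w[3, 2])
})

test_that("fused model emits normalized probabilities for any class count", {
  set.seed(3)
  for (k in c(2, 12)) {
    net <- build_mff(k, width_multiplier = 1 / 16, image_size = 8)
    B <- 4
    inputs <- list(beat = array(rnorm(12 * 64 * B), c(12, 64, B)),
                   gaf = array(rnorm(8 * 8 * B), c(1, 8, 8, B)),
                   st = array(rnorm(8 * 8 * B), c(1, 8, 8, B)))
    p <- net$predict_probs(inputs)
    expect_equal(dim(p), c(k, B))
    expect_equal(colSums(p), rep(1, B), tolerance = 1e-5)
    expect_true(all(p >= 0))
  }
  expect_error(build_mff(2, character(0)), "at least one")
})

test_that("all three branches influence the output and receive gradient", {
  set.seed(4)
  net <- build_mff(2, width_multiplier = 1 / 16, image_size = 8)
  B <- 4
  inputs <- list(beat = array(rnorm(12 * 64 * B), c(12, 64, B)),
                 gaf = array(rnorm(8 * 8 * B), c(1, 8, 8, B)),
                 st = array(rnorm(8 * 8 * B), c(1, 8, 8, B)))
  base <- net$predict_probs(inputs)
  for (b in c("beat", "gaf", "st")) {
    mod <- inputs
    perm <- sample(B)
    while (all(perm == seq_len(B))) perm <- sample(B)
    if (b == "beat") mod$beat <- mod$beat[, , perm, drop = FALSE]
    else mod[[b]] <- mod[[b]][, , , perm, drop = FALSE]
    expect_gt(max(abs(net$predict_probs(mod) - base)), 1e-8)
  }
  # gradient flows into every branch
  sx <- ecgmff:::nn_softmax_xent(net$forward(inputs, train = TRUE), c(1, 2, 1, 2))
  net$backward(sx$dlogits)
  for (b in c("beat", "gaf", "st")) {
    layers <- ecgmff:::nn_collect(net$branches[[b]])
    gn <- sum(vapply(layers, function(ly) sum(vapply(ly$grads, function(g) sum(g^2), 0)), 0))
    expect_gt(gn, 0)
  }
  # mismatched batch sizes across the triple are rejected
  bad <- inputs
  bad$gaf <- bad$gaf[, , , 1:2, drop = FALSE]
  expect_error(net$forward(bad), "batch sizes")
})

test_that("a width-reduced model fits a small separable set to 100% within 200 steps", {
  set.seed(7)
  n <- 64
  y <- rep(1:2, each = n / 2)
  beat <- array(rnorm(12 * 64 * n, sd = 0.3), c(12, 64, n))
  beat[, 20:30, y == 2] <- beat[, 20:30, y == 2] + 2      # separable bump
  gaf <- array(rnorm(8 * 8 * n, sd = 0.3), c(1, 8, 8, n))
  gaf[, 3:5, 3:5, y == 2] <- gaf[, 3:5, 3:5, y == 2] + 2
  st <- array(rnorm(8 * 8 * n, sd = 0.3), c(1, 8, 8, n))
  st[, 6:8, 6:8, y == 2] <- st[, 6:8, 6:8, y == 2] + 2
  net <- build_mff(2, width_multiplier = 1 / 8, image_size = 8)
  inputs <- list(beat = beat, gaf = gaf, st = st)
  acc <- 0
  for (step in 1:200) {
    sx <- ecgmff:::nn_softmax_xent(net$forward(inputs, train = TRUE), y)
    net$backward(sx$dlogits)
    ecgmff:::nn_sgd_step(net$param_layers, lr = 0.01, momentum = 0.9)
    if (step %% 10 == 0) {
      acc <- mean(max.col(t(net$predict_probs(inputs))) == y)
      if (acc == 1) break
    }
  }
  expect_equal(acc, 1)
})
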