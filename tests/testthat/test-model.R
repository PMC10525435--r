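test_that("positional encoding matches the sinusoidal definition", {
  pe <- positional_encoding(8, 2)
  expect_equal(dim(pe), c(8, 2))
  expect_equal(pe[1, 1], 0)             # sin(0)
  expect_equal(pe[1, 2], 1)             # cos(0)
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  pe4 <- positional_encoding(10, 4)
  expect_equal(pe4[3, 3], sin(2 / 10000^(2 / 4)), tolerance = 1e-12)
  expect_equal(pe4[3, 4], cos(2 / 10000^(2 / 4)), tolerance = 1e-12)
})

test_that("the default model maps a batch to one finite prediction per example", {
  m <- build_model(model_config(seed = 4))
  X <- matrix(rnorm(6 * 500), 6, 500)
  y <- forward(m, X)
  expect_length(y, 6)
  expect_true(all(is.finite(y)))
  expect_true(all(is.finite(forward(m, matrix(0, 2, 500)))))
  expect_error(forward(m, matrix(0, 2, 100)), "input_len",
               class = "transrr_contract_error")
})

test_that("two builds from the same seed share parameters; eval mode is bit-reproducible", {
  cfg <- model_config(seed = 123)
  expect_identical(build_model(cfg)$params, build_model(cfg)$params)
  m <- build_model(cfg)
  X <- matrix(rnorm(3 * 500), 3, 500)
  expect_identical(forward(m, X), forward(m, X))
  # dropout only acts in training mode, and is itself seed-reproducible
  tr1 <- forward(m, X, training = TRUE, dropout_seed = 9)
  tr2 <- forward(m, X, training = TRUE, dropout_seed = 9)
  tr3 <- forward(m, X, training = TRUE, dropout_seed = 10)
  expect_identical(tr1, tr2)
  expect_false(identical(tr1, tr3))
})

test_that("trainable parameter count equals explicit per-layer bookkeeping", {
  count_params <- function(cfg) {
    W <- cfg$module_width; D <- cfg$n_heads * cfg$head_size
    n <- if (W != cfg$input_channels) cfg$input_channels * W + W else 0
    kout <- if (cfg$use_kernel_inception)
      length(cfg$kernel_sizes) * cfg$branch_channels else W
    dout <- if (cfg$use_dilated_inception)
      length(cfg$dilation_rates) * cfg$branch_channels else kout
    per_block <- 3 * (W * D + D) + (D * W + W) + 2 * W +
      (if (cfg$use_kernel_inception)
        sum(cfg$kernel_sizes * W * cfg$branch_channels + cfg$branch_channels) else 0) +
      (if (cfg$use_dilated_inception)
        length(cfg$dilation_rates) *
          (cfg$dilation_kernel * kout * cfg$branch_channels + cfg$branch_channels) else 0) +
      (dout * W + W) + 2 * W
    fc_in <- c(cfg$input_len * W, head(cfg$fc_sizes, -1))
    n + cfg$n_blocks * per_block + sum(fc_in * cfg$fc_sizes + cfg$fc_sizes)
  }
  default <- model_config()
  expect_equal(n_params(build_model(default)), count_params(default))
  expect_equal(n_params(build_model(default)), 179601)   # frozen regression value
  for (cfg in list(model_config(use_kernel_inception = FALSE),
                   model_config(use_dilated_inception = FALSE),
                   model_config(module_width = 4, n_blocks = 2),
                   tiny_model_config()))
    expect_equal(n_params(build_model(cfg)), count_params(cfg))
})

test_that("analytic gradients agree with finite differences of the loss", {
  cfg <- tiny_model_config(n_blocks = 2, dropout_rate = 0.2)
  m <- build_model(cfg)
  set.seed(42)
  # jitter away from the exact ReLU kinks of zero-initialized biases
  p0 <- m$params + rnorm(n_params(m), 0, 0.02)
  X <- matrix(rnorm(4 * 32), 4, 32)
  y <- rnorm(4, 15, 3)
  lg <- transrr:::cpp_loss_grad(cfg, p0, X, y)
  expect_true(is.finite(lg$loss))
  # directional derivatives (aggregate check, robust to single-precision
  # noise in the attention kernels)
  for (rep in 1:5) {
    d <- rnorm(length(p0)); d <- d / sqrt(sum(d^2))
    eps <- 1e-3
    fd <- (transrr:::cpp_loss_grad(cfg, p0 + eps * d, X, y)$loss -
           transrr:::cpp_loss_grad(cfg, p0 - eps * d, X, y)$loss) / (2 * eps)
    an <- sum(lg$grad * d)
    expect_lt(abs(an - fd) / (abs(an) + abs(fd)), 0.02)
  }
  # coordinate-wise on the largest-gradient parameters
  idx <- order(-abs(lg$grad))[1:40]
  eps <- 1e-4
  for (i in idx) {
    p1 <- p0; p1[i] <- p1[i] + eps
    p2 <- p0; p2[i] <- p2[i] - eps
    fd <- (transrr:::cpp_loss_grad(cfg, p1, X, y)$loss -
           transrr:::cpp_loss_grad(cfg, p2, X, y)$loss) / (2 * eps)
    expect_lt(abs(fd - lg$grad[i]) / (abs(fd) + abs(lg$grad[i])), 0.01)
  }
})

test_that("every block preserves sequence length for L in {50, 250}", {
  for (L in c(50, 250)) {
    m <- build_model(model_config(input_len = L, n_blocks = 2, seed = 2))
    act <- transrr:::block_activation(m, matrix(rnorm(2 * L), 1))
    expect_equal(dim(act), c(L, m$config$module_width))
  }
})

test_that("attention gives every position a global receptive field", {
  L <- 50
  m <- build_model(model_config(input_len = L, n_blocks = 1, seed = 6))
  x <- matrix(rnorm(2 * L), 1)
  base <- transrr:::block_activation(m, x)
  x2 <- x
  x2[1, 5] <- x2[1, 5] + 1     # perturb one early ECG sample
  diff <- abs(transrr:::block_activation(m, x2) - base)
  # positions far from the perturbation must still react
  expect_true(all(rowSums(diff)[seq(L - 10, L)] > 0))
})

test_that("layer normalization is per-example: predictions are batch-invariant", {
  m <- build_model(model_config(seed = 8))
  X <- matrix(rnorm(8 * 500), 8, 500)
  alone <- forward(m, X[3, , drop = FALSE])
  in_batch <- forward(m, X)[3]
  expect_identical(alone, in_batch)
})

test_that("checkpoints round-trip parameters, config, and predictions", {
  m <- build_model(tiny_model_config())
  m$data_fingerprint <- "train-fp-1"
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_identical(back$data_fingerprint, "train-fp-1")
  X <- matrix(rnorm(2 * 32), 2, 32)
  expect_identical(forward(back, X), forward(m, X))
  # wrong architecture on load is a versioning error
  expect_error(load_checkpoint(path, config = tiny_model_config(input_len = 50)),
               class = "transrr_version_error")
  expect_silent(load_checkpoint(path, config = tiny_model_config()))
})

test_that("degenerate configurations are rejected at construction", {
  expect_error(model_config(module_width = 0), class = "transrr_construction_error")
  expect_error(model_config(fc_sizes = c(64, 2)), class = "transrr_construction_error")
  expect_error(model_config(kernel_sizes = c(3, 4)), class = "transrr_construction_error")
})
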