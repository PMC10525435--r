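#' TransRR architecture configuration
#'
#' Hyperparameters of the network: an input module adding sinusoidal
#' positional encoding to the two 250-sample channels, `n_blocks` stacked
#' Transformer modules (multi-head self-attention, residual + layer
#' normalization, kernel-inception convolutions over `kernel_sizes`, dropout,
#' dilation-inception convolutions at `dilation_rates` with kernel
#' `dilation_kernel`, a pointwise channel-adjusting convolution, and a second
#' residual + layer normalization), and a fully connected regression head of
#' widths `fc_sizes` ending in the scalar RR prediction. All convolutions are
#' same-padded so every block maps an L x W activation to L x W.
#'
#' @param input_len Window length L in samples (250 at the pipeline defaults).
#' @param input_channels Number of input channels (ECG + PPG = 2).
#' @param n_blocks Number of stacked Transformer modules.
#' @param n_heads,head_size Attention heads and per-head projection width;
#'   the attention inner width is their product.
#' @param kernel_sizes Kernel-inception branch kernel sizes (odd).
#' @param dilation_rates Dilation-inception branch dilation rates.
#' @param dilation_kernel Kernel size shared by the dilation branches (odd).
#' @param branch_channels Output channels of each inception branch.
#' @param module_width Channel count W carried between blocks; the residual
#'   topology ties the default to `input_channels`. When it differs, a
#'   learned pointwise input projection maps the channels to W.
#' @param dropout_rate Dropout fraction (after kernel inception and after
#'   each hidden FC layer; active only in training mode).
#' @param fc_sizes Fully connected head widths; last must be 1.
#' @param use_kernel_inception,use_dilated_inception Ablation switches; when
#'   a block is disabled its input feeds the next stage directly.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_len = 250, input_channels = 2, n_blocks = 4,
                         n_heads = 8, head_size = 32,
                         kernel_sizes = c(3, 5, 7, 9),
                         dilation_rates = c(1, 4, 8, 16), dilation_kernel = 5,
                         branch_channels = 8, module_width = 2,
                         dropout_rate = 0.2, fc_sizes = c(256, 64, 16, 1),
                         use_kernel_inception = TRUE,
                         use_dilated_inception = TRUE, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "model_config")
  ints <- c("input_len", "input_channels", "n_blocks", "n_heads", "head_size",
            "dilation_kernel", "branch_channels", "module_width", "seed")
  for (f in ints) cfg[[f]] <- as.integer(cfg[[f]])
  cfg$kernel_sizes <- as.integer(cfg$kernel_sizes)
  cfg$dilation_rates <- as.integer(cfg$dilation_rates)
  cfg$fc_sizes <- as.integer(cfg$fc_sizes)
  with(cfg, {
    if (module_width <= 0 || n_blocks < 1 || n_heads < 1 || head_size < 1 ||
        branch_channels < 1 || input_len < 1)
      transrr_error("transrr_construction_error", "all widths/counts must be positive")
    if (any(kernel_sizes %% 2 == 0) || dilation_kernel %% 2 == 0)
      transrr_error("transrr_construction_error",
                    "convolution kernels must be odd for same-padding")
    if (utils::tail(fc_sizes, 1) != 1)
      transrr_error("transrr_construction_error", "last fc size must be 1")
    if (dropout_rate < 0 || dropout_rate >= 1)
      transrr_error("transrr_construction_error", "dropout_rate must be in [0, 1)")
  })
  cfg
}

#' Sinusoidal positional encoding
#'
#' `PE[pos, 2i] = sin(pos / 10000^(2i/d))`,
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/d))` for 0-based positions and
#' columns. With d = 2 (the TransRR input), column 1 is added to the ECG
#' channel and column 2 to the PPG channel before concatenation into the
#' L x 2 input matrix.
#'
#' @param L Sequence length.
#' @param d Encoding dimension.
#' @return An L x d numeric matrix.
#' @export
positional_encoding <- function(L, d) {
  stopifnot(L >= 1, d >= 1)
  cpp_positional_encoding(as.integer(L), as.integer(d))
}

#' Build a TransRR model
#'
#' Constructs the parameter container with seeded (Glorot-uniform)
#' initialization. The forward pass in evaluation mode is a deterministic
#' function of (parameters, input).
#'
#' @param config A [model_config()].
#' @return An object of class `transrr_model` holding the flat parameter
#'   vector, its configuration, and (optionally) the fingerprint of the data
#'   it was trained on.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  structure(list(config = config,
                 params = cpp_init_params(config, config$seed),
                 data_fingerprint = NULL, trained = FALSE),
            class = "transrr_model")
}

#' Number of trainable parameters
#' @param model A [transrr_model][build_model()].
#' @return Integer parameter count.
#' @export
n_params <- function(model) length(model$params)

#' @export
print.transrr_model <- function(x, ...) {
  cat(sprintf("<transrr_model> %d blocks, width %d, %d parameters%s\n",
              x$config$n_blocks, x$config$module_width, n_params(x),
              if (isTRUE(x$trained)) " (trained)" else " (untrained)"))
  invisible(x)
}

# Assemble the n x (L*C) input matrix the compiled core expects:
# row i = c(ecg window, ppg window).
model_input_matrix <- function(batch, config) {
  if (inherits(batch, "segment_set")) {
    X <- cbind(batch$ecg, batch$ppg)
  } else if (is.matrix(batch)) {
    X <- batch
  } else if (is.array(batch) && length(dim(batch)) == 3) {
    X <- cbind(batch[, , 1], batch[, , 2])
  } else {
    transrr_error("transrr_contract_error",
                  "batch must be a segment_set, matrix, or n x L x 2 array")
  }
  expected <- config$input_len * config$input_channels
  if (ncol(X) != expected)
    transrr_error("transrr_contract_error",
                  "input has %d samples per example; model expects input_len %d x %d channels",
                  ncol(X), config$input_len, config$input_channels)
  if (any(!is.finite(X)))
    transrr_error("transrr_data_error", "batch contains non-finite values")
  X
}

#' Run the model forward
#'
#' @param model A [transrr_model][build_model()].
#' @param batch A [segment_set()], an `n x (L*2)` matrix (ECG columns then
#'   PPG columns), or an `n x L x 2` array.
#' @param training Logical; when `TRUE` dropout is active (stochastic,
#'   controlled by `dropout_seed`). In evaluation mode repeated calls are
#'   bit-identical.
#' @param dropout_seed Seed for the dropout masks when `training = TRUE`.
#' @return Numeric vector of RR predictions (breaths/min), one per example.
#' @export
forward <- function(model, batch, training = FALSE, dropout_seed = 0L) {
  stopifnot(inherits(model, "transrr_model"))
  X <- model_input_matrix(batch, model$config)
  as.numeric(cpp_forward(model$config, model$params, X, training,
                         as.integer(dropout_seed)))
}

#' @export
predict.transrr_model <- function(object, newdata, ...) forward(object, newdata)

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS container holding the flat parameter
#' vector, the full architecture configuration, and the fingerprint of the
#' preprocessing parameters of the training data (surfaced on load).
#'
#' @param model A [transrr_model][build_model()].
#' @param path Checkpoint file path.
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "transrr_model"))
  saveRDS(list(format = "transrr-checkpoint-1", config = unclass(model$config),
               params = model$params, data_fingerprint = model$data_fingerprint,
               trained = isTRUE(model$trained),
               package_version = as.character(utils::packageVersion("transrr"))),
          path)
  invisible(path)
}

#' @param config Optional [model_config()]; if supplied, a mismatch with the
#'   stored architecture raises a versioning error.
#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, config = NULL) {
  if (!file.exists(path))
    transrr_error("transrr_io_error", "checkpoint not found: %s", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "transrr-checkpoint-1"))
    transrr_error("transrr_version_error", "unrecognized checkpoint format")
  stored <- do.call(model_config, ck$config)
  if (!is.null(config)) {
    stopifnot(inherits(config, "model_config"))
    cmp <- setdiff(names(unclass(config)), "seed")
    if (!identical(unclass(config)[cmp], unclass(stored)[cmp]))
      transrr_error("transrr_version_error",
                    "checkpoint architecture does not match the supplied config")
  }
  structure(list(config = stored, params = ck$params,
                 data_fingerprint = ck$data_fingerprint,
                 trained = isTRUE(ck$trained)),
            class = "transrr_model")
}

# Final pre-flatten activation (L x W) for one example; used by the
# invariant tests (length preservation, attention receptive field).
block_activation <- function(model, example) {
  X <- model_input_matrix(example, model$config)
  cpp_block_activation(model$config, model$params, X[1, ])
}
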