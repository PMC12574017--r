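#' Configuration of the convolutional-LSTM decoder
#'
#' The network consumes sliding windows of `window_len` feature frames
#' (10 frames at 30 Hz = 333 ms of context) and regresses the kinematics of
#' the window's final frame (causal decoding). Architecture: a convolution
#' with `conv1_filters` filters of length `conv1_kernel` along the feature
#' axis (kernel (32, 1) over (feature, time)), batch normalization and ReLU;
#' a second convolution with stride-based dimensionality reduction, batch
#' normalization and ReLU; one LSTM layer over the window's time axis;
#' fully connected ReLU layers; and a linear d-dimensional output. Trained
#' with SGD + momentum on mean squared error with patience-based early
#' stopping on a validation set.
#'
#' @param p feature dimension (default 528).
#' @param d output DOFs (default 3).
#' @param window_len window length in frames (default 10).
#' @param conv1_filters,conv1_kernel,conv1_stride first convolution
#'   (defaults 10 filters, kernel 32, stride 1).
#' @param conv2_filters,conv2_kernel,conv2_stride reduction convolution
#'   (defaults 10 filters, kernel 16, stride 4).
#' @param lstm_hidden LSTM hidden units (default 40).
#' @param fc_sizes integer vector of fully connected layer sizes
#'   (default 64).
#' @param lr initial SGD learning rate (default 2e-4).
#' @param momentum SGD momentum (default 0.9).
#' @param max_epochs epoch cap (default 1000).
#' @param patience early-stopping patience in epochs (default 5).
#' @param batch_size minibatch size (default 64).
#' @param window_stride stride between training-window end frames
#'   (default 1; larger values subsample the training windows).
#' @param seed seed for parameter initialization and batch shuffling.
#' @return an object of class `clstm_config`.
#' @export
clstm_config <- function(p = 528, d = 3, window_len = 10,
                         conv1_filters = 10, conv1_kernel = 32,
                         conv1_stride = 1,
                         conv2_filters = 10, conv2_kernel = 16,
                         conv2_stride = 4,
                         lstm_hidden = 40, fc_sizes = 64,
                         lr = 2e-4, momentum = 0.9,
                         max_epochs = 1000, patience = 5,
                         batch_size = 64, window_stride = 1, seed = 1) {
  cfg <- list(p = as.integer(p), d = as.integer(d),
              window_len = as.integer(window_len),
              conv1_filters = as.integer(conv1_filters),
              conv1_kernel = as.integer(conv1_kernel),
              conv1_stride = as.integer(conv1_stride),
              conv2_filters = as.integer(conv2_filters),
              conv2_kernel = as.integer(conv2_kernel),
              conv2_stride = as.integer(conv2_stride),
              lstm_hidden = as.integer(lstm_hidden),
              fc_sizes = as.integer(fc_sizes),
              lr = lr, momentum = momentum,
              bn_eps = 1e-5, bn_momentum = 0.1,
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              batch_size = as.integer(batch_size),
              window_stride = as.integer(window_stride),
              seed = as.integer(seed))
  sizes <- unlist(cfg[c("window_len", "conv1_filters", "conv1_kernel",
                        "conv1_stride", "conv2_filters", "conv2_kernel",
                        "conv2_stride", "lstm_hidden", "batch_size",
                        "window_stride")])
  if (any(sizes < 1)) stop("all sizes and strides must be positive")
  if (cfg$conv1_kernel > cfg$p) {
    stop("conv1 kernel (", cfg$conv1_kernel,
         ") is larger than the feature axis (", cfg$p, ")")
  }
  P1 <- (cfg$p - cfg$conv1_kernel) %/% cfg$conv1_stride + 1L
  if (cfg$conv2_kernel > P1) {
    stop("conv2 kernel (", cfg$conv2_kernel,
         ") is larger than its input axis (", P1, ")")
  }
  class(cfg) <- "clstm_config"
  cfg
}

#' Build an untrained C-LSTM model
#'
#' Initializes all parameters (seeded, so the same seed gives bit-identical
#' initial weights): He-scaled Gaussian weights for the convolutional and
#' fully connected layers, 1/sqrt(fan-in) Gaussians for the LSTM, unit
#' batch-norm scale, and a forget-gate bias of 1.
#'
#' @param cfg a [clstm_config()].
#' @return object of class `clstm_model` with `params` and `cfg`.
#' @export
build_clstm <- function(cfg = clstm_config()) {
  stopifnot(inherits(cfg, "clstm_config"))
  params <- cpp_clstm_init(unclass(cfg), cfg$seed)
  out <- list(params = params, cfg = cfg, history = NULL, trained = FALSE)
  class(out) <- "clstm_model"
  out
}

#' @export
print.clstm_model <- function(x, ...) {
  cat(sprintf("<clstm_model: %d features -> %d DOFs, window %d frames%s>\n",
              x$cfg$p, x$cfg$d, x$cfg$window_len,
              if (isTRUE(x$trained)) sprintf(", trained %d epochs",
                                             x$history$epochs) else ", untrained"))
  invisible(x)
}

# Valid window end-frames: t >= L and the whole window inside one block.
clstm_window_ends <- function(T_, L, blocks = NULL, stride = 1L,
                              subset = NULL) {
  ends <- seq(from = L, to = T_, by = stride)
  if (!is.null(blocks)) {
    ok <- blocks[ends] == blocks[ends - L + 1L]
    ok[is.na(ok)] <- FALSE
    ends <- ends[ok]
  }
  if (!is.null(subset)) ends <- ends[blocks[ends] %in% subset]
  ends
}

#' Train a C-LSTM decoder
#'
#' Builds sliding windows of `window_len` frames labelled with the final
#' frame's kinematics, and minimizes mean squared error with SGD. Stops
#' early when the validation loss fails to improve for `patience`
#' consecutive epochs; the returned model carries the best-validation
#' parameters and a per-epoch train/validation loss history.
#'
#' @param model a [build_clstm()] model.
#' @param Z frames x p feature matrix.
#' @param X frames x d kinematic matrix.
#' @param val validation specification: either a numeric fraction in (0, 1)
#'   of training windows held out from the end, or (with `blocks`) a vector
#'   of block ids reserved for validation.
#' @param blocks optional per-frame block ids; windows never straddle block
#'   seams and validation can be specified per block.
#' @return the trained `clstm_model` (parameters at the best validation
#'   epoch, `history` with per-epoch losses).
#' @export
train_clstm <- function(model, Z, X, val = 0.15, blocks = NULL) {
  stopifnot(inherits(model, "clstm_model"))
  cfg <- model$cfg
  Z <- as.matrix(Z); X <- as.matrix(X)
  stopifnot(nrow(Z) == nrow(X), ncol(Z) == cfg$p, ncol(X) == cfg$d)
  T_ <- nrow(Z)
  if (T_ < cfg$window_len) stop("need at least window_len frames")

  if (length(val) == 1 && is.numeric(val) && val > 0 && val < 1) {
    ends <- clstm_window_ends(T_, cfg$window_len, blocks, cfg$window_stride)
    n_val <- floor(length(ends) * val)
    if (cfg$patience > 0 && n_val < 1) {
      stop("empty validation set but early-stopping patience is active")
    }
    val_ends <- if (n_val >= 1) ends[(length(ends) - n_val + 1L):length(ends)] else integer(0)
    train_ends <- setdiff(ends, val_ends)
  } else {
    if (is.null(blocks)) stop("block-based validation requires `blocks`")
    train_ends <- clstm_window_ends(T_, cfg$window_len, blocks,
                                    cfg$window_stride,
                                    subset = setdiff(unique(blocks), val))
    val_ends <- clstm_window_ends(T_, cfg$window_len, blocks,
                                  cfg$window_stride, subset = val)
    if (cfg$patience > 0 && length(val_ends) < 1) {
      stop("empty validation set but early-stopping patience is active")
    }
  }
  if (length(train_ends) < 1) stop("no training windows")

  fit <- cpp_clstm_train(model$params, Z, X,
                         as.integer(train_ends), as.integer(val_ends),
                         unclass(cfg), cfg$max_epochs, cfg$patience, cfg$seed)
  model$params <- fit$params
  model$history <- fit[c("train_loss", "val_loss", "epochs", "stopped_early",
                         "best_val_loss")]
  model$trained <- TRUE
  model
}

#' Predict kinematics with a C-LSTM decoder
#'
#' One prediction per frame from frame `window_len` onward; earlier frames
#' are back-filled with the first prediction so the output length equals the
#' input frame count.
#'
#' @param model a trained `clstm_model`.
#' @param Z frames x p feature matrix (at least `window_len` frames).
#' @return frames x d matrix of predicted kinematics.
#' @export
predict_clstm <- function(model, Z) {
  stopifnot(inherits(model, "clstm_model"))
  Z <- as.matrix(Z)
  if (nrow(Z) < model$cfg$window_len) {
    stop("need at least window_len (", model$cfg$window_len, ") frames, got ",
         nrow(Z))
  }
  preds <- cpp_clstm_predict(model$params, Z, unclass(model$cfg))
  L <- model$cfg$window_len
  rbind(matrix(rep(preds[1, ], L - 1), nrow = L - 1, byrow = TRUE), preds)
}
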