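#' Configuration of the supervised convolutional autoencoder
#'
#' The encoder is a stack of 1-D convolutions (`encoder_spec`, one
#' `c(kernel, filters, stride)` triple per layer) with batch normalization
#' after each convolution; every stride-2 layer halves the temporal length.
#' A single dropout layer sits at the bottleneck. The decoder mirrors the
#' encoder with transposed 1-D convolutions restoring the input length, and
#' a final 1-channel convolution with a logistic (sigmoid) output yields a
#' per-sample R-wave probability trace.
#'
#' The default architecture uses large kernels (9) in the outer encoder
#' layers to capture wide signal context and a smaller kernel (5) at depth
#' for precise R-wave localization, with stride-2 downsampling in place of
#' pooling: `(9,16,2), (9,32,2), (5,64,2)`, giving a bottleneck of length
#' `window_len / 8` (200 for 1600-sample windows).
#'
#' Training minimizes per-sample binary cross-entropy between the output
#' trace and the binary label mask; with `loss = "weighted_bce"` the
#' positive (R-wave) class is up-weighted by `pos_weight` to counter its
#' ~1-2% prevalence.
#'
#' @param encoder_spec List of `c(kernel, filters, stride)` triples. Kernels
#'   must be odd; strides 1 or 2; the product of strides must divide the
#'   window length.
#' @param decoder_spec Optional list mirroring the encoder; `NULL` derives
#'   the mirror automatically.
#' @param final_kernel Kernel of the output convolution (odd).
#' @param dropout_rate Bottleneck dropout fraction in `[0, 1)`.
#' @param batchnorm Apply batch normalization after encoder convolutions.
#' @param loss `"bce"` or `"weighted_bce"`.
#' @param pos_weight Positive-class weight (>= 1) for `"weighted_bce"`.
#' @param learning_rate,batch_size,max_epochs,early_stop_patience Adam
#'   optimizer settings and early-stopping policy (patience in epochs on the
#'   validation loss).
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(encoder_spec = list(c(9, 16, 2), c(9, 32, 2),
                                             c(5, 64, 2)),
                         decoder_spec = NULL, final_kernel = 9,
                         dropout_rate = 0.3, batchnorm = TRUE,
                         loss = c("weighted_bce", "bce"), pos_weight = 10,
                         learning_rate = 1e-3, batch_size = 32,
                         max_epochs = 200, early_stop_patience = 20,
                         seed = 42L) {
  loss <- match.arg(loss)
  cfg <- list(
    encoder_spec = lapply(encoder_spec, as.numeric),
    decoder_spec = decoder_spec, final_kernel = final_kernel,
    dropout_rate = dropout_rate, batchnorm = isTRUE(batchnorm),
    loss = loss, pos_weight = if (loss == "bce") 1 else pos_weight,
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    early_stop_patience = as.integer(early_stop_patience),
    seed = as.integer(seed)
  )
  kernels <- vapply(cfg$encoder_spec, `[`, numeric(1), 1)
  strides <- vapply(cfg$encoder_spec, `[`, numeric(1), 3)
  if (any(kernels %% 2 != 1) || final_kernel %% 2 != 1) {
    stop("All kernel sizes must be odd.", call. = FALSE)
  }
  if (!all(strides %in% c(1, 2))) {
    stop("Strides must be 1 or 2.", call. = FALSE)
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("`dropout_rate` must lie in [0, 1).", call. = FALSE)
  }
  if (cfg$pos_weight < 1) stop("`pos_weight` must be >= 1.", call. = FALSE)
  structure(cfg, class = "model_config")
}

MODEL_FORMAT_VERSION <- 1L

#' Build an (untrained) R-wave detector from a model configuration
#'
#' Instantiates the encoder/decoder parameter tensors with He-normal
#' initialization, deterministically under `config$seed`. The configuration
#' is validated against `window_len`: the product of encoder strides must
#' divide it, so the mirrored decoder reconstructs the input length exactly.
#'
#' @param config A [model_config()].
#' @param window_len Input window length in samples (default 1600).
#' @return A `trained_detector` object with `trained = FALSE`.
#' @export
build_detector <- function(config, window_len = 1600) {
  stopifnot(inherits(config, "model_config"))
  strides <- vapply(config$encoder_spec, `[`, numeric(1), 3)
  total_stride <- prod(strides)
  lens <- window_len
  L <- window_len
  for (s in strides) {
    if (L %% s != 0) {
      stop(sprintf(
        "Encoder strides (total %d) do not reconstruct window length %d.",
        total_stride, window_len
      ), call. = FALSE)
    }
    L <- L / s
    lens <- c(lens, L)
  }
  enc_filters <- vapply(config$encoder_spec, `[`, numeric(1), 2)
  dec_spec <- config$decoder_spec
  if (is.null(dec_spec)) {
    # mirror: reversed kernels/strides; filter counts walk back up the
    # encoder, the last decoder layer keeping the first encoder width
    kernels <- rev(vapply(config$encoder_spec, `[`, numeric(1), 1))
    dstrides <- rev(strides)
    dfilters <- c(rev(enc_filters)[-1], enc_filters[1])
    dec_spec <- Map(function(k, f, s) c(k, f, s), kernels, dfilters,
                    dstrides)
  }
  withr_seed(derive_seed(config$seed, "init"))
  layers <- list()
  c_in <- 1
  for (i in seq_along(config$encoder_spec)) {
    sp <- config$encoder_spec[[i]]
    k <- sp[1]; f <- sp[2]; s <- sp[3]
    lay <- list(
      type = "conv", k = k, stride = s, pad = (k - 1) / 2,
      W = matrix(rnorm(k * c_in * f, sd = sqrt(2 / (k * c_in))),
                 k * c_in, f),
      b = numeric(f), activation = "relu",
      dropout_after = (i == length(config$encoder_spec))
    )
    if (config$batchnorm) {
      lay$gamma <- rep(1, f); lay$beta <- numeric(f)
      lay$run_mean <- numeric(f); lay$run_var <- rep(1, f)
    }
    layers[[length(layers) + 1]] <- lay
    c_in <- f
  }
  for (sp in dec_spec) {
    k <- sp[1]; f <- sp[2]; s <- sp[3]
    layers[[length(layers) + 1]] <- list(
      type = "tconv", k = k, stride = s, pad = (k - 1) / 2,
      W = matrix(rnorm(c_in * k * f, sd = sqrt(2 / (c_in * k))),
                 c_in, k * f),
      b = numeric(f), activation = "relu", dropout_after = FALSE
    )
    c_in <- f
  }
  kf <- config$final_kernel
  layers[[length(layers) + 1]] <- list(
    type = "conv", k = kf, stride = 1, pad = (kf - 1) / 2,
    W = matrix(rnorm(kf * c_in, sd = sqrt(2 / (kf * c_in))), kf * c_in, 1),
    b = numeric(1), activation = "sigmoid", dropout_after = FALSE
  )
  structure(
    list(config = config, window_len = window_len,
         bottleneck_len = window_len / total_stride,
         params = list(layers = layers), trained = FALSE,
         training_log = tibble::tibble(epoch = integer(),
                                       train_loss = numeric(),
                                       val_loss = numeric())),
    class = "trained_detector"
  )
}

#' @export
print.trained_detector <- function(x, ...) {
  n_par <- sum(vapply(x$params$layers, function(l) {
    length(l$W) + length(l$b) + length(l$gamma %||% numeric(0)) +
      length(l$beta %||% numeric(0))
  }, numeric(1)))
  cat(sprintf(
    "<trained_detector> %d layers, %d parameters, window %d -> bottleneck %d; %s\n",
    length(x$params$layers), n_par, x$window_len, x$bottleneck_len,
    if (x$trained) sprintf("trained (%d epochs logged)",
                           nrow(x$training_log))
    else "untrained"
  ))
  invisible(x)
}

ws_to_cube <- function(ws, what = c("values", "masks")) {
  what <- match.arg(what)
  m <- ws[[what]]
  array(t(m), dim = c(ncol(m), 1, nrow(m)))
}

#' Train the detector on labeled window sets
#'
#' Minimizes (optionally positive-weighted) binary cross-entropy between the
#' output trace and the binary R-wave mask with the Adam optimizer, batch
#' shuffling and bottleneck dropout, monitoring the validation loss for
#' early stopping (`early_stop_patience` epochs without improvement). The
#' weights achieving the best validation loss are restored at the end.
#' Deterministic given `config$seed` and single-threaded numerics; tests
#' treat run-to-run equality as a tolerance contract, not bit-equality.
#'
#' @param detector A [build_detector()] result.
#' @param train_set,val_set Disjoint labeled [window_set()]s.
#' @param verbose Print per-epoch losses.
#' @return A new `trained_detector` with `trained = TRUE` and a populated
#'   `training_log`.
#' @export
train_detector <- function(detector, train_set, val_set, verbose = FALSE) {
  stopifnot(inherits(detector, "trained_detector"),
            inherits(train_set, "window_set"),
            inherits(val_set, "window_set"))
  if (n_windows(train_set) == 0) {
    stop("Training set is empty.", call. = FALSE)
  }
  if (sum(train_set$masks) == 0) {
    warning("All training masks are zero: nothing to detect (degenerate task).")
  }
  cfg <- detector$config
  x_tr <- ws_to_cube(train_set, "values")
  y_tr <- ws_to_cube(train_set, "masks")
  x_va <- ws_to_cube(val_set, "values")
  y_va <- ws_to_cube(val_set, "masks")
  params <- detector$params
  opt <- list()
  n <- n_windows(train_set)
  withr_seed(derive_seed(cfg$seed, "train"))
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  log_rows <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(n)
    batch_starts <- seq(1, n, by = cfg$batch_size)
    tr_loss <- 0
    for (bs in batch_starts) {
      bi <- idx[bs:min(bs + cfg$batch_size - 1, n)]
      xb <- x_tr[, , bi, drop = FALSE]
      yb <- y_tr[, , bi, drop = FALSE]
      res <- nn_loss_and_grads(params, xb, yb, cfg$pos_weight,
                               cfg$dropout_rate)
      params <- res$params   # batch-norm running stats
      for (li in seq_along(params$layers)) {
        g <- res$grads[[li]]
        for (nm in c("W", "b", "gamma", "beta")) {
          gname <- paste0("d", nm)
          if (is.null(g[[gname]])) next
          key <- paste0(li, ".", nm)
          st <- adam_step(params$layers[[li]][[nm]], g[[gname]],
                          opt[[key]], cfg$learning_rate)
          params$layers[[li]][[nm]] <- st$param
          opt[[key]] <- st$state
        }
      }
      tr_loss <- tr_loss + res$loss * length(bi)
    }
    tr_loss <- tr_loss / n
    val_out <- nn_forward(params, x_va, training = FALSE)$out
    val_loss <- bce_loss(val_out, y_va, cfg$pos_weight)$loss
    log_rows[[epoch]] <- tibble::tibble(epoch = epoch,
                                        train_loss = tr_loss,
                                        val_loss = val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, tr_loss,
                      val_loss))
    }
    if (val_loss < best_val - 1e-7) {
      best_val <- val_loss
      best_params <- params
      best_epoch <- epoch
    } else if (epoch - best_epoch >= cfg$early_stop_patience) {
      break
    }
  }
  detector$params <- best_params
  detector$trained <- TRUE
  detector$training_log <- dplyr::bind_rows(log_rows)
  detector$best_epoch <- best_epoch
  detector
}

#' Apply the detector to windows
#'
#' Produces one per-sample R-wave probability trace (values in `[0, 1]`,
#' length equal to the window length) per window. Inference is a pure
#' function of the weights and inputs (no dropout; batch norm uses running
#' statistics).
#'
#' @param object A `trained_detector`.
#' @param windows A [window_set()] or an `n x window_len` numeric matrix.
#' @param allow_untrained Permit inference through an untrained (freshly
#'   built) model; default `FALSE` raises a state error.
#' @param ... Unused.
#' @return Numeric matrix, `n x window_len`, of probabilities.
#' @export
predict.trained_detector <- function(object, windows,
                                     allow_untrained = FALSE, ...) {
  if (!object$trained && !allow_untrained) {
    stop("Model is untrained; train it or pass `allow_untrained = TRUE`.",
         call. = FALSE)
  }
  m <- if (inherits(windows, "window_set")) windows$values else
    as.matrix(windows)
  if (ncol(m) != object$window_len) {
    stop(sprintf("Windows have %d samples; the model expects %d.",
                 ncol(m), object$window_len), call. = FALSE)
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (bs in seq(1, nrow(m), by = 128)) {
    bi <- bs:min(bs + 127, nrow(m))
    x <- array(t(m[bi, , drop = FALSE]), dim = c(ncol(m), 1, length(bi)))
    p <- nn_forward(object$params, x, training = FALSE)$out
    out[bi, ] <- t(matrix(p, ncol(m), length(bi)))
  }
  out
}

#' Save / load a detector
#'
#' The file is a self-describing container (format version, configuration
#' echo, weights, training log); `load_detector(save_detector(m))` yields
#' bit-identical predictions.
#'
#' @param detector A `trained_detector`.
#' @param path File path.
#' @return `path` invisibly (save); a `trained_detector` (load).
#' @export
save_detector <- function(detector, path) {
  stopifnot(inherits(detector, "trained_detector"))
  payload <- unclass(detector)
  payload$format_version <- MODEL_FORMAT_VERSION
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("Cannot read model file %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.list(payload) || is.null(payload$format_version)) {
    stop("File is not a detector container.", call. = FALSE)
  }
  if (payload$format_version != MODEL_FORMAT_VERSION) {
    stop(sprintf(
      "Incompatible model format version %s (this build reads version %d).",
      payload$format_version, MODEL_FORMAT_VERSION
    ), call. = FALSE)
  }
  payload$format_version <- NULL
  structure(payload, class = "trained_detector")
}

#' @method tidy trained_detector
#' @export
tidy.trained_detector <- function(x, ...) x$training_log

#' @method glance trained_detector
#' @export
glance.trained_detector <- function(x, ...) {
  tibble::tibble(
    trained = x$trained,
    n_layers = length(x$params$layers),
    window_len = x$window_len,
    bottleneck_len = x$bottleneck_len,
    epochs_run = nrow(x$training_log),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_loss = if (nrow(x$training_log)) min(x$training_log$val_loss)
                    else NA_real_
  )
}
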