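# The network itself is the package's own code, so its correctness oracles
# are independent re-computations: brute-force convolution arithmetic and
# central finite differences through the full forward pass.

conv_reference <- function(x, W, b, s, p) {
  L <- dim(x)[1]; C <- dim(x)[2]; B <- dim(x)[3]
  k <- nrow(W) / C; nf <- ncol(W)
  Lo <- (L + 2 * p - k) / s + 1
  y <- array(0, c(Lo, nf, B))
  for (bb in 1:B) for (f in 1:nf) for (o in 1:Lo) {
    acc <- b[f]
    for (j in 0:(k - 1)) for (c in 1:C) {
      i <- (o - 1) * s + j - p + 1
      if (i >= 1 && i <= L) acc <- acc + x[i, c, bb] * W[c + C * j, f]
    }
    y[o, f, bb] <- acc
  }
  y
}

tconv_reference <- function(x, W, b, s, p) {
  Li <- dim(x)[1]; B <- dim(x)[3]
  cout <- length(b); k <- ncol(W) / cout
  Lo <- Li * s
  y <- array(0, c(Lo, cout, B))
  for (bb in 1:B) for (i in 1:Li) for (j in 0:(k - 1)) for (f in 1:cout) {
    o <- (i - 1) * s + j - p + 1
    if (o >= 1 && o <= Lo) {
      y[o, f, bb] <- y[o, f, bb] + sum(x[i, , bb] * W[, f + cout * j])
    }
  }
  for (f in 1:cout) y[, f, ] <- y[, f, ] + b[f]
  y
}

test_that("compiled convolutions agree with brute-force arithmetic", {
  set.seed(3)
  for (i in 1:5) {
    C <- sample(1:3, 1); nf <- sample(1:4, 1); k <- sample(c(3, 5, 9), 1)
    s <- sample(1:2, 1); p <- (k - 1) / 2
    L <- s * sample(6:15, 1)
    x <- array(rnorm(L * C * 2), c(L, C, 2))
    W <- matrix(rnorm(k * C * nf), k * C, nf)
    b <- rnorm(nf)
    expect_equal(rwavenet:::nn_conv1d_fw(x, W, b, s, p),
                 conv_reference(x, W, b, s, p), tolerance = 1e-12)
    Wt <- matrix(rnorm(C * k * nf), C, k * nf)
    expect_equal(rwavenet:::nn_tconv1d_fw(x, Wt, b, s, p),
                 tconv_reference(x, Wt, b, s, p), tolerance = 1e-12)
  }
})

test_that("backpropagated gradients match central finite differences", {
  cfg <- model_config(encoder_spec = list(c(3, 2, 2), c(3, 3, 2)),
                      final_kernel = 3, dropout_rate = 0, seed = 7)
  det <- build_detector(cfg, window_len = 16)
  params <- det$params
  # shift biases off zero so no ReLU pre-activation sits exactly on the kink
  set.seed(8)
  for (li in seq_along(params$layers)) {
    params$layers[[li]]$b <- rnorm(length(params$layers[[li]]$b), sd = 0.3)
    if (!is.null(params$layers[[li]]$beta)) {
      params$layers[[li]]$beta <-
        rnorm(length(params$layers[[li]]$beta), sd = 0.3)
    }
  }
  xb <- array(rnorm(16 * 2), c(16, 1, 2))
  yb <- array(rbinom(32, 1, 0.2), c(16, 1, 2))
  res <- rwavenet:::nn_loss_and_grads(params, xb, yb, pos_weight = 3)
  eps <- 1e-6
  worst <- 0
  for (li in seq_along(params$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      if (is.null(params$layers[[li]][[nm]])) next
      g <- res$grads[[li]][[paste0("d", nm)]]
      pv <- params$layers[[li]][[nm]]
      for (ii in seq_along(pv)) {
        pp <- params; pp$layers[[li]][[nm]][ii] <- pv[ii] + eps
        pm <- params; pm$layers[[li]][[nm]][ii] <- pv[ii] - eps
        fd <- (rwavenet:::nn_loss_only(pp, xb, yb, 3) -
                 rwavenet:::nn_loss_only(pm, xb, yb, 3)) / (2 * eps)
        worst <- max(worst, abs(fd - g[ii]) /
                       max(1e-6, abs(fd) + abs(g[ii])))
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the default architecture maps 1600 samples to 1600 probabilities", {
  det <- build_detector(model_config())
  expect_equal(det$bottleneck_len, 200)   # 1600 / 2^3
  p <- predict(det, matrix(rnorm(1600), 1), allow_untrained = TRUE)
  expect_equal(dim(p), c(1L, 1600L))
  expect_true(all(is.finite(p)) && all(p >= 0) && all(p <= 1))
})

test_that("builds are deterministic in the seed and strides are validated", {
  cfg <- tiny_model_config()
  d1 <- build_detector(cfg, 128)
  d2 <- build_detector(cfg, 128)
  expect_identical(d1$params, d2$params)
  d3 <- build_detector(tiny_model_config(seed = 12), 128)
  expect_false(identical(d1$params$layers[[1]]$W,
                         d3$params$layers[[1]]$W))
  expect_error(build_detector(cfg, 130), "reconstruct")
  expect_error(model_config(encoder_spec = list(c(8, 4, 2))), "odd")
  expect_error(model_config(encoder_spec = list(c(9, 4, 3))), "Strides")
})

test_that("training reduces validation loss on a separable task", {
  det <- tiny_trained_detector()
  log <- tidy(det)
  expect_gt(nrow(log), 3)
  expect_lt(min(log$val_loss), log$val_loss[1])
  expect_true(glance(det)$trained)
})

test_that("prediction is a pure function and untrained use is gated", {
  det <- tiny_trained_detector()
  ws <- tiny_windows(seed = 31)
  p1 <- predict(det, ws)
  p2 <- predict(det, ws)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(ncol(p1), 128)
  raw <- build_detector(tiny_model_config(), 128)
  expect_error(predict(raw, ws), "untrained")
  expect_silent(predict(raw, ws, allow_untrained = TRUE))
})

test_that("models round-trip through save/load with identical predictions", {
  dir <- withr::local_tempdir()
  det <- tiny_trained_detector()
  ws <- tiny_windows(seed = 32)
  path <- file.path(dir, "model.rds")
  save_detector(det, path)
  back <- load_detector(path)
  expect_identical(predict(back, ws), predict(det, ws))
  # corrupt and incompatible files are rejected explicitly
  writeLines("", file.path(dir, "empty.rds"))
  expect_error(load_detector(file.path(dir, "empty.rds")), "Cannot read")
  payload <- readRDS(path)
  payload$format_version <- 99L
  saveRDS(payload, file.path(dir, "future.rds"))
  expect_error(load_detector(file.path(dir, "future.rds")),
               "format version")
})

test_that("an empty or degenerate training set is refused or flagged", {
  ws <- tiny_windows(seed = 33)
  det <- build_detector(tiny_model_config(max_epochs = 1), 128)
  expect_error(train_detector(det, ws[integer(0)], ws), "empty")
  blank <- ws
  blank$masks[] <- 0L
  expect_warning(train_detector(det, blank[1:4], blank[5:6]),
                 "degenerate")
})
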