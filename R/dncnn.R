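#' DnCNN configuration
#'
#' Architecture and training hyperparameters for the residual denoising CNN.
#' The network predicts the noise map; the denoised image is input minus the
#' predicted residual. The layer stack is `Conv+ReLU`, then `depth - 2` blocks
#' of `Conv+BN+ReLU`, then a final `Conv`, all 3x3 unit-stride with reflective
#' border padding so shape is preserved.
#'
#' @param depth Number of convolutional layers (>= 3). Default 17, the
#'   original DnCNN depth.
#' @param filters Feature maps per hidden layer. Default 64.
#' @param kernel Spatial kernel size (odd). Only 3 is implemented.
#' @param noise_sigma_train Training noise standard deviation on the `[0, 1]`
#'   intensity scale. Default 15/255 (additive white Gaussian).
#' @param seed Integer seed for deterministic weight initialization.
#' @return A list of class `dncnn_config`.
#' @export
dncnn_config <- function(depth = 17L, filters = 64L, kernel = 3L,
                         noise_sigma_train = 15 / 255, seed = 0L) {
  if (depth < 3L) stop("`depth` must be at least 3", call. = FALSE)
  if (filters < 1L) stop("`filters` must be positive", call. = FALSE)
  if (kernel %% 2L != 1L) stop("`kernel` must be odd", call. = FALSE)
  if (kernel != 3L) stop("only 3x3 kernels are implemented", call. = FALSE)
  stopifnot(noise_sigma_train > 0)
  structure(list(depth = as.integer(depth), filters = as.integer(filters),
                 kernel = as.integer(kernel),
                 noise_sigma_train = noise_sigma_train,
                 seed = as.integer(seed)),
            class = "dncnn_config")
}

#' Build an (untrained) DnCNN model
#'
#' Weights are He-initialized deterministically from the config seed; batch
#' normalization runs with per-channel scale/shift and running moments. The
#' final layer starts near zero so the untrained network is close to the
#' identity denoiser.
#'
#' @param config A [dncnn_config()].
#' @return A list of class `dncnn_model` with fields `config`, `layers`
#'   (each: `W` of shape filters x 9*C_in, `b`, optional `bn`, `relu`) and a
#'   `trained` flag.
#' @export
build_dncnn <- function(config = dncnn_config()) {
  stopifnot(inherits(config, "dncnn_config"))
  set.seed(config$seed)
  L <- config$depth
  f <- config$filters
  c_in <- c(1L, rep(f, L - 1L))
  c_out <- c(rep(f, L - 1L), 1L)
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- 9L * c_in[l]
    sd <- if (l == L) 1e-2 else sqrt(2 / fan_in)
    W <- matrix(stats::rnorm(c_out[l] * fan_in, sd = sd), c_out[l], fan_in)
    bn <- NULL
    if (l > 1L && l < L) {
      bn <- list(gamma = rep(1, c_out[l]), beta = rep(0, c_out[l]),
                 rmean = rep(0, c_out[l]), rvar = rep(1, c_out[l]))
    }
    layers[[l]] <- list(W = W, b = rep(0, c_out[l]), bn = bn,
                        relu = l < L, c_in = c_in[l], c_out = c_out[l])
  }
  structure(list(config = config, layers = layers, trained = FALSE),
            class = "dncnn_model")
}

#' @export
print.dncnn_model <- function(x, ...) {
  n_bn <- sum(vapply(x$layers, function(l) !is.null(l$bn), logical(1)))
  cat(sprintf("<dncnn_model> depth %d, %d filters, %d BN layers, %s\n",
              x$config$depth, x$config$filters, n_bn,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- internal tensor plumbing -------------------------------------------
# Activations are matrices (channels x H*W*N); columns ordered (h, w, n)
# with h fastest. Arrays are (H, W, C, N).

mat_to_arr <- function(M, H, W, N) {
  aperm(array(M, c(nrow(M), H, W, N)), c(2, 3, 1, 4))
}

arr_to_mat <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(3, 1, 2, 4)), nrow = d[3])
}

pad_reflect <- function(A) {
  d <- dim(A)
  A[c(2L, seq_len(d[1]), d[1] - 1L), c(2L, seq_len(d[2]), d[2] - 1L), , ,
    drop = FALSE]
}

conv_offsets <- rbind(
  c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
  c(0L, -1L), c(0L, 0L), c(0L, 1L),
  c(1L, -1L), c(1L, 0L), c(1L, 1L)
)

# im2col on a reflect-padded array; K is (9*C_in x H*W*N), offset-major rows.
im2col3 <- function(Ap, H, W) {
  blocks <- vector("list", 9L)
  for (o in seq_len(9L)) {
    dy <- conv_offsets[o, 1L]
    dx <- conv_offsets[o, 2L]
    S <- Ap[seq_len(H) + 1L + dy, seq_len(W) + 1L + dx, , , drop = FALSE]
    blocks[[o]] <- arr_to_mat(S)
  }
  do.call(rbind, blocks)
}

conv_forward <- function(X, layer, H, W, N) {
  A <- mat_to_arr(X, H, W, N)
  K <- im2col3(pad_reflect(A), H, W)
  Y <- layer$W %*% K + layer$b
  list(Y = Y, K = K)
}

conv_backward <- function(dY, layer, K, H, W, N, need_dx = TRUE) {
  dW <- dY %*% t(K)
  db <- rowSums(dY)
  dX <- NULL
  if (need_dx) {
    dK <- crossprod(layer$W, dY)
    c_in <- layer$c_in
    dAp <- array(0, c(H + 2L, W + 2L, c_in, N))
    for (o in seq_len(9L)) {
      dy <- conv_offsets[o, 1L]
      dx <- conv_offsets[o, 2L]
      blk <- mat_to_arr(dK[(o - 1L) * c_in + seq_len(c_in), , drop = FALSE],
                        H, W, N)
      rr <- seq_len(H) + 1L + dy
      cc <- seq_len(W) + 1L + dx
      dAp[rr, cc, , ] <- dAp[rr, cc, , , drop = FALSE] + blk
    }
    tmp <- dAp[seq_len(H) + 1L, , , , drop = FALSE]
    tmp[2L, , , ] <- tmp[2L, , , , drop = FALSE] + dAp[1L, , , , drop = FALSE]
    tmp[H - 1L, , , ] <- tmp[H - 1L, , , , drop = FALSE] +
      dAp[H + 2L, , , , drop = FALSE]
    dA <- tmp[, seq_len(W) + 1L, , , drop = FALSE]
    dA[, 2L, , ] <- dA[, 2L, , , drop = FALSE] + tmp[, 1L, , , drop = FALSE]
    dA[, W - 1L, , ] <- dA[, W - 1L, , , drop = FALSE] +
      tmp[, W + 2L, , , drop = FALSE]
    dX <- arr_to_mat(dA)
  }
  list(dW = dW, db = db, dX = dX)
}

bn_eps <- 1e-5
bn_momentum <- 0.9

bn_forward_train <- function(X, bn) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + bn_eps)
  xhat <- xc * inv
  Y <- bn$gamma * xhat + bn$beta
  bn$rmean <- bn_momentum * bn$rmean + (1 - bn_momentum) * mu
  bn$rvar <- bn_momentum * bn$rvar + (1 - bn_momentum) * v
  list(Y = Y, xhat = xhat, inv = inv, bn = bn)
}

bn_forward_infer <- function(X, bn) {
  bn$gamma * ((X - bn$rmean) / sqrt(bn$rvar + bn_eps)) + bn$beta
}

bn_backward <- function(dY, bn, xhat, inv) {
  m <- ncol(dY)
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * bn$gamma
  dX <- (inv / m) * (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Full forward pass; X is (1 x H*W*N). Returns residual prediction and,
# when training, the caches needed for backprop (and updated BN moments).
dncnn_forward <- function(model, X, H, W, N, training = FALSE) {
  caches <- if (training) vector("list", length(model$layers)) else NULL
  A <- X
  for (l in seq_along(model$layers)) {
    layer <- model$layers[[l]]
    cf <- conv_forward(A, layer, H, W, N)
    Y <- cf$Y
    cache <- list(K = if (training) cf$K else NULL, X_in = NULL)
    if (!is.null(layer$bn)) {
      if (training) {
        bf <- bn_forward_train(Y, layer$bn)
        model$layers[[l]]$bn <- bf$bn
        cache$xhat <- bf$xhat
        cache$inv <- bf$inv
        Y <- bf$Y
      } else {
        Y <- bn_forward_infer(Y, layer$bn)
      }
    }
    if (layer$relu) {
      if (training) cache$relu_mask <- Y > 0
      Y <- pmax(Y, 0)
    }
    if (training) caches[[l]] <- cache
    A <- Y
  }
  list(out = A, caches = caches, model = model)
}

dncnn_backward <- function(model, dOut, caches, H, W, N) {
  L <- length(model$layers)
  grads <- vector("list", L)
  d <- dOut
  for (l in rev(seq_len(L))) {
    layer <- model$layers[[l]]
    cache <- caches[[l]]
    if (layer$relu) d <- d * cache$relu_mask
    g <- list()
    if (!is.null(layer$bn)) {
      bb <- bn_backward(d, layer$bn, cache$xhat, cache$inv)
      g$dgamma <- bb$dgamma
      g$dbeta <- bb$dbeta
      d <- bb$dX
    }
    cb <- conv_backward(d, layer, cache$K, H, W, N, need_dx = l > 1L)
    g$dW <- cb$dW
    g$db <- cb$db
    grads[[l]] <- g
    d <- cb$dX
  }
  grads
}

adam_init <- function(model) {
  lapply(model$layers, function(layer) {
    s <- list(mW = layer$W * 0, vW = layer$W * 0,
              mb = layer$b * 0, vb = layer$b * 0)
    if (!is.null(layer$bn)) {
      s$mg <- layer$bn$gamma * 0; s$vg <- s$mg
      s$mbeta <- s$mg; s$vbeta <- s$mg
    }
    s
  })
}

adam_step <- function(x, g, m, v, t, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(x = x - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

as_patch_array <- function(clean_patches) {
  if (is.list(clean_patches)) {
    d <- dim(clean_patches[[1]])
    if (!all(vapply(clean_patches, function(p) identical(dim(p), d), logical(1)))) {
      stop("all patches must share one shape", call. = FALSE)
    }
    clean_patches <- array(unlist(clean_patches), c(d, length(clean_patches)))
  }
  stopifnot(length(dim(clean_patches)) == 3L)
  if (min(clean_patches) < 0 || max(clean_patches) > 1) {
    stop("patch intensities must be normalized to [0, 1]", call. = FALSE)
  }
  clean_patches
}

#' Train a DnCNN on clean patches with synthetic Gaussian noise
#'
#' Desk-scale residual training: at each step a mini-batch of clean patches
#' is corrupted with fresh additive white Gaussian noise of standard
#' deviation `sigma`, and Adam minimizes the mean squared error between the
#' predicted residual and the injected noise. A held-out subset of patches
#' (never trained on) is used to report the PSNR of the noisy versus the
#' denoised reconstruction. Fully seeded and repeatable: identical seeds and
#' inputs give identical final weights.
#'
#' @param model A [build_dncnn()] model.
#' @param clean_patches A list of equal-shape matrices, or an `H x W x n`
#'   array, with intensities in `[0, 1]`. At least 8 patches.
#' @param sigma Noise standard deviation on the `[0, 1]` scale.
#' @param steps Number of optimizer steps (0 leaves weights untouched but
#'   still evaluates).
#' @param seed Integer seed driving batching and noise draws.
#' @param batch_size Patches per step. Default 8.
#' @param lr Adam learning rate. Default 0.005.
#' @param holdout_fraction Fraction of patches held out for evaluation.
#' @return A list with the trained `model` and a `report` (class
#'   `denoise_report`: `psnr_noisy`, `psnr_denoised`, `n_eval_patches`).
#' @export
train_dncnn <- function(model, clean_patches, sigma = model$config$noise_sigma_train,
                        steps = 200L, seed = 0L, batch_size = 8L, lr = 0.005,
                        holdout_fraction = 0.25) {
  stopifnot(inherits(model, "dncnn_model"))
  P <- as_patch_array(clean_patches)
  n <- dim(P)[3]
  if (n < 8L) stop("need at least 8 patches", call. = FALSE)
  H <- dim(P)[1]; W <- dim(P)[2]
  set.seed(seed)
  n_hold <- max(1L, floor(holdout_fraction * n))
  hold_idx <- sample.int(n, n_hold)
  train_idx <- setdiff(seq_len(n), hold_idx)
  opt <- adam_init(model)
  t <- 0L
  for (step in seq_len(steps)) {
    bi <- sample(train_idx, min(batch_size, length(train_idx)), replace = FALSE)
    N <- length(bi)
    clean <- matrix(P[, , bi, drop = FALSE], nrow = 1)
    noise <- matrix(stats::rnorm(H * W * N, sd = sigma), nrow = 1)
    X <- clean + noise
    fw <- dncnn_forward(model, X, H, W, N, training = TRUE)
    model <- fw$model
    resid <- fw$out
    err <- resid - noise
    loss <- mean(err * err)
    if (!is.finite(loss)) stop("non-finite training loss", call. = FALSE)
    dOut <- 2 * err / length(err)
    grads <- dncnn_backward(model, dOut, fw$caches, H, W, N)
    t <- t + 1L
    for (l in seq_along(model$layers)) {
      g <- grads[[l]]
      u <- adam_step(model$layers[[l]]$W, g$dW, opt[[l]]$mW, opt[[l]]$vW, t, lr)
      model$layers[[l]]$W <- u$x; opt[[l]]$mW <- u$m; opt[[l]]$vW <- u$v
      u <- adam_step(model$layers[[l]]$b, g$db, opt[[l]]$mb, opt[[l]]$vb, t, lr)
      model$layers[[l]]$b <- u$x; opt[[l]]$mb <- u$m; opt[[l]]$vb <- u$v
      if (!is.null(model$layers[[l]]$bn)) {
        u <- adam_step(model$layers[[l]]$bn$gamma, g$dgamma,
                       opt[[l]]$mg, opt[[l]]$vg, t, lr)
        model$layers[[l]]$bn$gamma <- u$x; opt[[l]]$mg <- u$m; opt[[l]]$vg <- u$v
        u <- adam_step(model$layers[[l]]$bn$beta, g$dbeta,
                       opt[[l]]$mbeta, opt[[l]]$vbeta, t, lr)
        model$layers[[l]]$bn$beta <- u$x; opt[[l]]$mbeta <- u$m; opt[[l]]$vbeta <- u$v
      }
    }
  }
  model$trained <- TRUE
  # held-out evaluation with a fixed noise draw
  N <- length(hold_idx)
  clean <- matrix(P[, , hold_idx, drop = FALSE], nrow = 1)
  noise <- matrix(stats::rnorm(H * W * N, sd = sigma), nrow = 1)
  X <- clean + noise
  resid <- dncnn_forward(model, X, H, W, N, training = FALSE)$out
  den <- pmin(pmax(X - resid, 0), 1)
  noisy_cl <- pmin(pmax(X, 0), 1)
  report <- structure(list(psnr_noisy = psnr(noisy_cl, clean),
                           psnr_denoised = psnr(den, clean),
                           n_eval_patches = N),
                      class = "denoise_report")
  list(model = model, report = report)
}

#' @export
print.denoise_report <- function(x, ...) {
  cat(sprintf("<denoise_report> PSNR noisy %.2f dB -> denoised %.2f dB (gain %+.2f dB, %d patches)\n",
              x$psnr_noisy, x$psnr_denoised, x$psnr_denoised - x$psnr_noisy,
              x$n_eval_patches))
  invisible(x)
}

#' Peak signal-to-noise ratio
#'
#' @param x,ref Numeric arrays of equal shape.
#' @param peak Signal peak (1 for normalized intensities).
#' @return PSNR in dB (`Inf` for identical inputs).
#' @export
psnr <- function(x, ref, peak = 1) {
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Denoise a channel with a trained DnCNN
#'
#' Intensities are normalized to `[0, 1]`, the predicted noise residual is
#' subtracted, and the result is clipped back to the valid intensity range
#' and rescaled. Shape, bit depth and calibration are preserved; the input is
#' never modified. Only the PGP9.5 channel needs denoising for
#' quantification; other channels may be passed through untouched.
#'
#' @param model A trained [dncnn_model] (from [train_dncnn()] or
#'   [load_dncnn_weights()]).
#' @param channel A [channel_image()].
#' @return A denoised [channel_image()].
#' @export
denoise <- function(model, channel) {
  stopifnot(inherits(model, "dncnn_model"), inherits(channel, "channel_image"))
  if (!isTRUE(model$trained)) {
    stop("model is untrained; train it or load weights first", call. = FALSE)
  }
  hi <- 2^channel$bit_depth - 1
  H <- nrow(channel$pixels); W <- ncol(channel$pixels)
  X <- matrix(channel$pixels / hi, nrow = 1)
  resid <- dncnn_forward(model, X, H, W, 1L, training = FALSE)$out
  out <- pmin(pmax(X - resid, 0), 1)
  res <- channel
  res$pixels <- matrix(out * hi, H, W)
  res
}

#' Conventional threshold denoiser (baseline)
#'
#' Zeroes every pixel strictly below the cutoff and leaves the rest
#' untouched. This is the classical background-suppression baseline; it
#' cannot distinguish dim neurite pixels from noise, which is why it tends to
#' underestimate fiber density on dim sections. Idempotent.
#'
#' @param channel A [channel_image()].
#' @param cutoff Intensity cutoff within the channel's valid range.
#' @return A [channel_image()].
#' @export
threshold_denoise <- function(channel, cutoff) {
  stopifnot(inherits(channel, "channel_image"))
  hi <- 2^channel$bit_depth - 1
  if (cutoff < 0 || cutoff > hi) {
    stop(sprintf("`cutoff` must lie in [0, %d]", hi), call. = FALSE)
  }
  out <- channel
  out$pixels <- ifelse(channel$pixels < cutoff, 0, channel$pixels)
  out
}

#' Compare the threshold baseline against the DnCNN path
#'
#' Runs the full quantification twice on a synthetic section — once after
#' [threshold_denoise()] at `cutoff`, once after [denoise()] with the given
#' model — and returns both sets of density records together with the
#' ground-truth densities computed from the generator's fiber mask.
#'
#' @param fixture A [generate_section()] result.
#' @param model A trained [dncnn_model].
#' @param cutoff Intensity cutoff for the baseline, on the channel's native
#'   scale.
#' @param params A [quant_params()] list.
#' @return A tibble of density records with a `method` column
#'   (`"threshold"`, `"dncnn"`, `"truth"`).
#' @export
compare_denoisers <- function(fixture, model, cutoff, params = quant_params()) {
  stopifnot(inherits(fixture, "synthetic_section"))
  red <- get_channel(fixture$image, "pgp95_red")
  th <- quantify_image(replace_channel(fixture$image, threshold_denoise(red, cutoff)),
                       fixture$region_map, params)
  dn <- quantify_image(replace_channel(fixture$image, denoise(model, red)),
                       fixture$region_map, params)
  tr <- true_density_records(fixture)
  dplyr::bind_rows(
    dplyr::mutate(th, method = "threshold"),
    dplyr::mutate(dn, method = "dncnn"),
    dplyr::mutate(tr, method = "truth")
  )
}

replace_channel <- function(image, channel) {
  roles <- vapply(image$channels, `[[`, character(1), "channel_role")
  image$channels[[which(roles == channel$channel_role)[1]]] <- channel
  image
}

#' Save / load DnCNN weights as a flat text container
#'
#' The container is a plain-text file: a one-line JSON manifest describing
#' the architecture and the shape of every parameter array, followed by one
#' line of full-precision numbers per array in layer order. This lets
#' externally trained weights be substituted without changing the pipeline.
#'
#' @param model A [dncnn_model].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_dncnn_weights <- function(model, path) {
  stopifnot(inherits(model, "dncnn_model"))
  arrays <- list()
  shapes <- list()
  for (l in seq_along(model$layers)) {
    layer <- model$layers[[l]]
    nm <- sprintf("layer%02d", l)
    arrays[[paste0(nm, ".W")]] <- as.vector(layer$W)
    shapes[[paste0(nm, ".W")]] <- dim(layer$W)
    arrays[[paste0(nm, ".b")]] <- layer$b
    shapes[[paste0(nm, ".b")]] <- length(layer$b)
    if (!is.null(layer$bn)) {
      for (p in c("gamma", "beta", "rmean", "rvar")) {
        arrays[[paste0(nm, ".", p)]] <- layer$bn[[p]]
        shapes[[paste0(nm, ".", p)]] <- length(layer$bn[[p]])
      }
    }
  }
  manifest <- jsonlite::toJSON(
    list(format = "innervaquant-dncnn-1",
         depth = model$config$depth, filters = model$config$filters,
         kernel = model$config$kernel,
         noise_sigma_train = model$config$noise_sigma_train,
         seed = model$config$seed, trained = isTRUE(model$trained),
         arrays = names(arrays), shapes = shapes),
    auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(manifest), con)
  for (a in arrays) {
    writeLines(paste(sprintf("%.17g", a), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname save_dncnn_weights
#' @return For `load_dncnn_weights`, a [dncnn_model] marked trained.
#' @export
load_dncnn_weights <- function(path) {
  lines <- readLines(path)
  manifest <- jsonlite::fromJSON(lines[1])
  if (!identical(manifest$format, "innervaquant-dncnn-1")) {
    stop("not an innervaquant DnCNN weights file", call. = FALSE)
  }
  cfg <- dncnn_config(depth = manifest$depth, filters = manifest$filters,
                      kernel = manifest$kernel,
                      noise_sigma_train = manifest$noise_sigma_train,
                      seed = manifest$seed)
  model <- build_dncnn(cfg)
  vals <- lapply(lines[-1], function(x) as.numeric(strsplit(x, " ", fixed = TRUE)[[1]]))
  names(vals) <- manifest$arrays
  for (l in seq_along(model$layers)) {
    nm <- sprintf("layer%02d", l)
    model$layers[[l]]$W <- matrix(vals[[paste0(nm, ".W")]],
                                  nrow = model$layers[[l]]$c_out)
    model$layers[[l]]$b <- vals[[paste0(nm, ".b")]]
    if (!is.null(model$layers[[l]]$bn)) {
      for (p in c("gamma", "beta", "rmean", "rvar")) {
        model$layers[[l]]$bn[[p]] <- vals[[paste0(nm, ".", p)]]
      }
    }
  }
  model$trained <- isTRUE(manifest$trained)
  model
}
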