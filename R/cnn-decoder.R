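#' CNN configuration for binary key extraction
#'
#' The `"full"` profile is the reference recipe for a 648 x 692 input:
#' three convolutional layers (16 filters 32x32 stride 2; 32 filters
#' 16x16 stride 1; 64 filters 8x8 stride 1), each followed by batch
#' normalization, ReLU and max-pooling (windows 32x32/16x16/8x8, all
#' strides 2), then two fully connected layers (400 nodes with batch
#' normalization + ReLU; n^2 linear output nodes). Training minimizes
#' mean squared error against 0/1 target keys with ADAM (learning rate
#' 2e-4, mini-batch 100) for at most 15 epochs.
#'
#' The `"desk"` profile keeps the layer structure but scales the
#' geometry to 96 x 96 inputs for CPU-only runs: kernel/pool sides
#' 4/2/2 (preserving the full-scale kernel-to-cell-pitch ratio) and
#' pooling strides 2/1/1 (preserving the output-grid resolution of
#' about 3 spatial units per code cell); its learning rate is raised to
#' 3e-3 to compensate for the smaller number of optimizer steps.
#'
#' Convolutions use "same" zero padding (the stated stride/kernel sizes
#' leave padding unspecified); pooling windows are "valid". Outputs are
#' linear scores trained against 0/1 targets and binarized at
#' `decision_threshold`.
#'
#' @param profile `"full"` or `"desk"`.
#' @param n grid side; output width is n^2.
#' @param input_shape `(rows, cols)`; defaults to the profile's canvas.
#' @param filters,kernels,strides,pools,pool_strides per-conv-layer
#'   integer vectors.
#' @param fc_nodes width of the first fully connected layer.
#' @param learning_rate,batch_size,epochs ADAM training hyperparameters.
#' @param decision_threshold score cutoff for binarization.
#' @param seed seed for weight initialization and data order.
#' @return A `cnn_config`.
#' @export
cnn_config <- function(profile = c("full", "desk"), n = 7L,
                       input_shape = NULL,
                       filters = c(16L, 32L, 64L),
                       kernels = NULL, strides = c(2L, 1L, 1L),
                       pools = NULL, pool_strides = NULL,
                       fc_nodes = 400L, learning_rate = NULL,
                       batch_size = 100L, epochs = 15L,
                       decision_threshold = 0.5, seed = 7L) {
  profile <- match.arg(profile)
  preset <- switch(profile,
    full = list(input_shape = c(648L, 692L), kernels = c(32L, 16L, 8L),
                pools = c(32L, 16L, 8L), pool_strides = c(2L, 2L, 2L),
                learning_rate = 2e-4),
    desk = list(input_shape = c(96L, 96L), kernels = c(4L, 2L, 2L),
                pools = c(4L, 2L, 2L), pool_strides = c(2L, 1L, 1L),
                learning_rate = 3e-3))
  cfg <- list(profile = profile, n = as.integer(n),
              input_shape = as.integer(input_shape %||% preset$input_shape),
              filters = as.integer(filters),
              kernels = as.integer(kernels %||% preset$kernels),
              strides = as.integer(strides),
              pools = as.integer(pools %||% preset$pools),
              pool_strides = as.integer(pool_strides %||% preset$pool_strides),
              fc_nodes = as.integer(fc_nodes),
              n_out = as.integer(n)^2,
              learning_rate = learning_rate %||% preset$learning_rate,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              decision_threshold = decision_threshold,
              seed = as.integer(seed))
  stopifnot(length(cfg$filters) == length(cfg$kernels),
            length(cfg$filters) == length(cfg$strides),
            length(cfg$filters) == length(cfg$pools))
  structure(cfg, class = "cnn_config")
}

# ---- layer geometry -------------------------------------------------------

conv_out_dim <- function(d, stride) as.integer(ceiling(d / stride))  # same pad
pool_out_dim <- function(d, k, stride) as.integer(floor((d - k) / stride) + 1L)

#' Feature-map geometry of a CNN configuration
#'
#' @param config a `cnn_config`.
#' @return List of per-layer dims; errors (naming the layer) if any
#'   convolution or pooling would produce a non-positive spatial size.
#' @export
cnn_geometry <- function(config) {
  H <- config$input_shape[1]; W <- config$input_shape[2]; C <- 1L
  layers <- list()
  for (l in seq_along(config$filters)) {
    k <- config$kernels[l]; s <- config$strides[l]
    Ho <- conv_out_dim(H, s); Wo <- conv_out_dim(W, s)
    if (Ho <= 0 || Wo <= 0)
      stop("conv layer ", l, ": output size ", Ho, " x ", Wo, " underflows")
    kp <- config$pools[l]; sp <- config$pool_strides[l]
    Hp <- pool_out_dim(Ho, kp, sp); Wp <- pool_out_dim(Wo, kp, sp)
    if (Hp <= 0 || Wp <= 0)
      stop("max-pool after conv layer ", l, ": window ", kp,
           " does not fit the ", Ho, " x ", Wo, " feature map")
    layers[[l]] <- list(Hin = H, Win = W, Cin = C, F = config$filters[l],
                        k = k, stride = s, Hc = Ho, Wc = Wo,
                        pool = kp, pool_stride = sp, Hp = Hp, Wp = Wp)
    H <- Hp; W <- Wp; C <- config$filters[l]
  }
  flat <- H * W * C
  list(conv = layers, flat = flat,
       fc = c(config$fc_nodes, config$n_out))
}

# gather-index plan for same-padded convolution (column-major spatial,
# channel-major stacking: index = h + (w-1)*H + (c-1)*H*W)
conv_plan <- function(L) {
  with(L, {
    pad_h <- max((Hc - 1L) * stride + k - Hin, 0L)
    pad_w <- max((Wc - 1L) * stride + k - Win, 0L)
    pt <- pad_h %/% 2L; pl <- pad_w %/% 2L
    Hpad <- Hin + pad_h; Wpad <- Win + pad_w
    # destination rows of the unpadded pixels inside the padded block
    hh <- rep(seq_len(Hin), times = Win * Cin)
    ww <- rep(rep(seq_len(Win), each = Hin), times = Cin)
    cc <- rep(seq_len(Cin), each = Hin * Win)
    fill_idx <- (hh + pt) + (ww + pl - 1L) * Hpad + (cc - 1L) * Hpad * Wpad
    # patch-element offsets (dr fastest, then dc, then channel)
    dr <- rep(seq_len(k), times = k * Cin) - 1L
    dc <- rep(rep(seq_len(k), each = k), times = Cin) - 1L
    ch <- rep(seq_len(Cin), each = k * k) - 1L
    off <- dr + dc * Hpad + ch * Hpad * Wpad
    # top-left padded index of each output position (ho fastest)
    ho <- rep(seq_len(Hc), times = Wc); wo <- rep(seq_len(Wc), each = Hc)
    tl <- ((ho - 1L) * stride + 1L) + ((wo - 1L) * stride) * Hpad
    idx <- outer(off, tl, `+`)          # (K, P)
    list(K = k * k * Cin, P = Hc * Wc, Npad = Hpad * Wpad * Cin,
         fill_idx = fill_idx, idx = idx)
  })
}

# Overlapping max-pool (window `pool`, stride `pool_stride`) decomposed,
# when pool %% pool_stride == 0, into a disjoint pool_stride-block max
# followed by a (pool/pool_stride)^2 stride-1 max on the reduced grid.
# The reference pooling windows overlap heavily (e.g. 32x32 stride 2);
# the decomposition avoids materializing the (window^2 x positions)
# gather.
pool_plan <- function(L) {
  with(L, {
    stopifnot(pool %% pool_stride == 0L)
    sp <- pool_stride
    Ha <- Hc %/% sp; Wa <- Wc %/% sp
    # stage A: disjoint sp x sp blocks over the (Hc, Wc) grid
    dr <- rep(seq_len(sp), times = sp) - 1L
    dc <- rep(seq_len(sp), each = sp) - 1L
    offA <- dr + dc * Hc
    ha <- rep(seq_len(Ha), times = Wa); wa <- rep(seq_len(Wa), each = Ha)
    tlA <- ((ha - 1L) * sp + 1L) + ((wa - 1L) * sp) * Hc
    idxA <- outer(offA, tlA, `+`)       # (sp^2, Ha*Wa)
    # stage B: q x q stride-1 window on the (Ha, Wa) grid
    q <- pool %/% sp
    stopifnot(Hp == Ha - q + 1L, Wp == Wa - q + 1L)
    drb <- rep(seq_len(q), times = q) - 1L
    dcb <- rep(seq_len(q), each = q) - 1L
    offB <- drb + dcb * Ha
    hb <- rep(seq_len(Hp), times = Wp); wb <- rep(seq_len(Wp), each = Hp)
    tlB <- hb + (wb - 1L) * Ha
    idxB <- outer(offB, tlB, `+`)       # (q^2, Hp*Wp)
    list(Pp = Hp * Wp, PA = Ha * Wa, idxA = idxA, idxB = idxB,
         KA = sp * sp, KB = q * q)
  })
}


#' Build an untrained CNN decoder
#'
#' Allocates seeded (He-initialized) weights for the configured layer
#' stack and reports the parameter count. Fails fast, naming the layer,
#' if the geometry underflows.
#'
#' @param config a `cnn_config`.
#' @return A `cnn_decoder` (untrained).
#' @export
build_decoder <- function(config) {
  geom <- cnn_geometry(config)
  set.seed(config$seed)
  params <- list()
  for (l in seq_along(geom$conv)) {
    L <- geom$conv[[l]]
    K <- L$k * L$k * L$Cin
    params[[paste0("conv", l)]] <- list(
      W = matrix(stats::rnorm(K * L$F, 0, sqrt(2 / K)), K, L$F),
      b = numeric(L$F),
      gamma = rep(1, L$F), beta = numeric(L$F),
      run_mean = numeric(L$F), run_var = rep(1, L$F))
  }
  D <- geom$flat
  params$fc1 <- list(
    W = matrix(stats::rnorm(config$fc_nodes * D, 0, sqrt(2 / D)),
               config$fc_nodes, D),
    b = numeric(config$fc_nodes),
    gamma = rep(1, config$fc_nodes), beta = numeric(config$fc_nodes),
    run_mean = numeric(config$fc_nodes), run_var = rep(1, config$fc_nodes))
  params$fc2 <- list(
    W = matrix(stats::rnorm(config$n_out * config$fc_nodes, 0,
                            sqrt(2 / config$fc_nodes)),
               config$n_out, config$fc_nodes),
    b = numeric(config$n_out))
  n_par <- sum(vapply(unlist(params, recursive = FALSE),
                      function(p) if (is.numeric(p)) length(p) else 0L, 0))
  structure(list(config = config, geometry = geom, params = params,
                 n_parameters = n_par, trained = FALSE,
                 decision_threshold = config$decision_threshold,
                 training_manifest = NULL, loss_history = NULL,
                 plans = new.env(parent = emptyenv())),
            class = "cnn_decoder")
}

#' @export
print.cnn_decoder <- function(x, ...) {
  g <- x$geometry
  cat("cnn_decoder (", x$config$profile, " profile, ",
      if (x$trained) "trained" else "untrained", ")\n", sep = "")
  cat("  input ", paste(x$config$input_shape, collapse = " x "), " -> ", sep = "")
  for (L in g$conv)
    cat("[conv ", L$F, "@", L$k, "x", L$k, "/s", L$stride, " bn relu pool ",
        L$pool, "/s", L$pool_stride, " -> ", L$Hp, "x", L$Wp, "] ", sep = "")
  cat("flat ", g$flat, " -> fc ", g$fc[1], " (bn relu) -> fc ", g$fc[2],
      " (linear)\n  parameters: ", format(x$n_parameters, big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

get_plans <- function(model) {
  env <- model$plans
  if (is.null(env$conv)) {
    env$conv <- lapply(model$geometry$conv, conv_plan)
    env$pool <- lapply(model$geometry$conv, pool_plan)
  }
  env
}

.bn_eps <- 1e-5
.bn_momentum <- 0.9

# Forward pass over a batch X (H*W rows, B columns). When `train = TRUE`
# returns the caches needed for backprop and batch statistics; otherwise
# uses running batch-norm statistics.
cnn_forward <- function(model, X, train = FALSE) {
  plans <- get_plans(model)
  B <- ncol(X)
  cache <- list(B = B)
  # per-image median subtraction: codes are mostly background, so the
  # median tracks the background level and the zero padding of the
  # convolutions then blends into it (and decoding becomes invariant to
  # global intensity offsets)
  A <- X - rep(apply(X, 2, stats::median), each = nrow(X))
  for (l in seq_along(model$geometry$conv)) {
    L <- model$geometry$conv[[l]]; cp <- plans$conv[[l]]; pp <- plans$pool[[l]]
    P <- model$params[[paste0("conv", l)]]
    Xp <- matrix(0, cp$Npad, B)
    Xp[cp$fill_idx, ] <- A
    cols <- cpp_im2col(Xp, cp$idx)                  # (K, P*B)
    Z <- crossprod(P$W, cols) + P$b                 # (F, P*B)
    if (train) {
      mv <- cpp_row_meanvar(Z); m <- mv$mean; v <- mv$var
    } else { m <- P$run_mean; v <- P$run_var }
    bn <- cpp_bn_relu_fwd(Z, m, v, P$gamma, P$beta, .bn_eps)
    mp <- cpp_maxpool(bn$A, L$F, cp$P, B, pp$idxA, pp$idxB)
    pooled <- mp$val                   # (Pp*F, B) spatial-then-channel
    if (train)
      cache[[paste0("conv", l)]] <- list(cols = cols, xhat = bn$xhat, v = v,
                                         m = m, relu = bn$mask, src = mp$src)
    A <- pooled
  }
  cache$flat <- A
  P <- model$params$fc1
  Z1 <- P$W %*% A + P$b
  if (train) {
    m1 <- rowMeans(Z1); v1 <- pmax(rowMeans(Z1 * Z1) - m1 * m1, 0)
  } else { m1 <- P$run_mean; v1 <- P$run_var }
  xhat1 <- (Z1 - m1) / sqrt(v1 + .bn_eps)
  A1 <- P$gamma * xhat1 + P$beta
  relu1 <- A1 > 0
  A1[!relu1] <- 0
  Y <- model$params$fc2$W %*% A1 + model$params$fc2$b
  if (train) {
    cache$fc1 <- list(xhat = xhat1, v = v1, m = m1, relu = relu1, A = A1)
    cache$batch_stats <- TRUE
  }
  list(Y = Y, cache = cache)
}

# Backward pass; returns gradients in the same structure as params.
cnn_backward <- function(model, cache, dY) {
  plans <- get_plans(model)
  grads <- list()
  B <- cache$B
  fc2 <- model$params$fc2; fc1c <- cache$fc1
  grads$fc2 <- list(W = tcrossprod(dY, fc1c$A), b = rowSums(dY))
  dA1 <- crossprod(fc2$W, dY)
  dA1 <- dA1 * fc1c$relu
  bb <- cpp_bn_bwd(dA1, fc1c$xhat, model$params$fc1$gamma, fc1c$v, .bn_eps)
  grads$fc1 <- list(W = tcrossprod(bb$dx, cache$flat), b = rowSums(bb$dx),
                    gamma = bb$dgamma, beta = bb$dbeta)
  dA <- crossprod(model$params$fc1$W, bb$dx)  # (flat, B)
  nconv <- length(model$geometry$conv)
  for (l in rev(seq_len(nconv))) {
    L <- model$geometry$conv[[l]]; cp <- plans$conv[[l]]; pp <- plans$pool[[l]]
    cc <- cache[[paste0("conv", l)]]
    # pool backward: dA is (Pp*F, B) -> scatter to (F, P*B)
    g <- dA
    dim(g) <- c(pp$Pp * L$F, B)
    dZc <- cpp_maxpool_bwd(g, cc$src, L$F, cp$P)
    dZc <- dZc * cc$relu
    bb <- cpp_bn_bwd(dZc, cc$xhat, model$params[[paste0("conv", l)]]$gamma,
                     cc$v, .bn_eps)
    dZ <- bb$dx                                # (F, P*B)
    grads[[paste0("conv", l)]] <- list(
      W = tcrossprod(cc$cols, dZ), b = rowSums(dZ),
      gamma = bb$dgamma, beta = bb$dbeta)
    if (l > 1L) {
      Wl <- model$params[[paste0("conv", l)]]$W
      dcols <- Wl %*% dZ                       # (K, P*B)
      dXp <- cpp_col2im(dcols, cp$idx, cp$Npad)
      dA <- dXp[cp$fill_idx, , drop = FALSE]
    }
  }
  grads
}


set_as_matrices <- function(train_set, input_shape, n_out) {
  stopifnot(inherits(train_set, "labeled_set"), train_set$mode == "channel")
  N <- length(train_set$items)
  D <- prod(input_shape)
  r1 <- train_set$items[[1]]$raster
  if (nrow(r1) != input_shape[1] || ncol(r1) != input_shape[2])
    stop("raster size ", nrow(r1), " x ", ncol(r1),
         " does not match decoder input ",
         paste(input_shape, collapse = " x "))
  X <- matrix(0, D, N); TT <- matrix(0, n_out, N)
  for (i in seq_len(N)) {
    X[, i] <- as.vector(train_set$items[[i]]$raster)
    TT[, i] <- train_set$items[[i]]$key$bits
  }
  list(X = X, T = TT)
}

#' Train the CNN decoder on a labelled synthetic set
#'
#' Minimizes the mean squared error between the linear output scores and
#' the 0/1 target keys with ADAM, for at most `config$epochs` epochs at
#' the configured mini-batch size and learning rate. Weight
#' initialization and data order are seeded, so a (config, data) pair
#' reproduces the same trained weights. Batch-norm running statistics
#' are accumulated for inference.
#'
#' @param model an (untrained) `cnn_decoder` from [build_decoder()].
#' @param train_set a `labeled_set` in `"channel"` mode.
#' @param verbose print per-epoch loss.
#' @return The trained `cnn_decoder` with `loss_history` and a training
#'   manifest recording the dataset fingerprint.
#' @export
train_decoder <- function(model, train_set, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_decoder"))
  if (length(train_set$items) == 0) stop("empty training set")
  cfg <- model$config
  dat <- set_as_matrices(train_set, cfg$input_shape, cfg$n_out)
  N <- ncol(dat$X)
  set.seed(cfg$seed)
  # deep-copy the parameters: the ADAM kernel updates them in place
  params <- lapply(model$params, function(l) lapply(l, function(x) x + 0))
  opt_m <- list(); opt_v <- list()
  t_step <- 0L
  loss_hist <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    losses <- numeric(0)
    for (start in seq(1L, N, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, N)]
      Xb <- dat$X[, idx, drop = FALSE]
      Tb <- dat$T[, idx, drop = FALSE]
      model$params <- params
      fw <- cnn_forward(model, Xb, train = TRUE)
      diff <- fw$Y - Tb
      losses <- c(losses, mean(diff * diff))
      dY <- 2 * diff / length(diff)
      grads <- cnn_backward(model, fw$cache, dY)
      t_step <- t_step + 1L
      c1 <- 1 / (1 - 0.9^t_step); c2 <- 1 / (1 - 0.999^t_step)
      for (layer in names(grads)) {
        for (pn in names(grads[[layer]])) {
          key <- paste0(layer, ".", pn)
          g <- grads[[layer]][[pn]]
          if (is.null(opt_m[[key]])) { opt_m[[key]] <- g * 0; opt_v[[key]] <- g * 0 }
          cpp_adam_step(params[[layer]][[pn]], g, opt_m[[key]], opt_v[[key]],
                        cfg$learning_rate, 0.9, 0.999, 1e-8, c1, c2)
        }
      }
      # running batch-norm statistics
      for (l in seq_along(model$geometry$conv)) {
        nm <- paste0("conv", l); cc <- fw$cache[[nm]]
        params[[nm]]$run_mean <- .bn_momentum * params[[nm]]$run_mean +
          (1 - .bn_momentum) * cc$m
        params[[nm]]$run_var <- .bn_momentum * params[[nm]]$run_var +
          (1 - .bn_momentum) * cc$v
      }
      params$fc1$run_mean <- .bn_momentum * params$fc1$run_mean +
        (1 - .bn_momentum) * fw$cache$fc1$m
      params$fc1$run_var <- .bn_momentum * params$fc1$run_var +
        (1 - .bn_momentum) * fw$cache$fc1$v
    }
    loss_hist <- c(loss_hist, mean(losses))
    if (verbose)
      message(sprintf("epoch %2d/%d  mse %.6f", epoch, cfg$epochs,
                      loss_hist[epoch]))
  }
  model$params <- params
  model$trained <- TRUE
  model$loss_history <- loss_hist
  model$training_manifest <- list(
    dataset = train_set$manifest, epochs_run = cfg$epochs,
    final_loss = loss_hist[length(loss_hist)])
  model
}

#' Raw CNN output scores for a batch of rasters
#'
#' @param decoder a trained `cnn_decoder`.
#' @param rasters a single raster matrix or list of rasters.
#' @param batch_size inference batch size.
#' @return Matrix (n_out x n_rasters) of linear scores.
#' @export
predict_scores <- function(decoder, rasters, batch_size = 200L) {
  if (is.matrix(rasters)) rasters <- list(rasters)
  cfg <- decoder$config
  for (r in rasters)
    if (nrow(r) != cfg$input_shape[1] || ncol(r) != cfg$input_shape[2])
      stop("raster is ", nrow(r), " x ", ncol(r), " but decoder expects ",
           paste(cfg$input_shape, collapse = " x "))
  N <- length(rasters)
  out <- matrix(0, cfg$n_out, N)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    X <- vapply(rasters[idx], as.vector, numeric(prod(cfg$input_shape)))
    out[, idx] <- cnn_forward(decoder, X, train = FALSE)$Y
  }
  out
}

#' Extract the binary channel key from one raster
#'
#' Scores above `decision_threshold` become 1-bits: the network is
#' trained to score filled square units near 1 and empty areas near 0.
#'
#' @param decoder a trained `cnn_decoder`.
#' @param raster grayscale matrix matching the decoder input size.
#' @param channel channel label attached to the key.
#' @return A `channel_key`; raw scores in attribute `"scores"`.
#' @export
predict_channel_key <- function(decoder, raster, channel = "ECFP") {
  if (!decoder$trained) warning("decoder has not been trained")
  sc <- predict_scores(decoder, raster)[, 1]
  key <- channel_key(channel, as.integer(sc > decoder$decision_threshold))
  attr(key, "scores") <- sc
  key
}

#' Bit error ratio of a decoder on a labelled evaluation set
#'
#' Compares decoded keys against ground truth over the whole set:
#' `ber = mismatched bits / total bits`. Accepts a trained `cnn_decoder`
#' or a `grid_layout` (classical baseline reader). In strict mode an
#' evaluation set whose manifest fingerprint matches the decoder's
#' training set is rejected (train/eval overlap).
#'
#' @param decoder `cnn_decoder` or `grid_layout`.
#' @param eval_set a `labeled_set` in `"channel"` mode.
#' @param strict escalate train/eval overlap from warning to error.
#' @param batch_size CNN inference batch size.
#' @return A `ber_report`.
#' @export
evaluate_ber <- function(decoder, eval_set, strict = TRUE, batch_size = 200L) {
  stopifnot(inherits(eval_set, "labeled_set"), eval_set$mode == "channel")
  is_cnn <- inherits(decoder, "cnn_decoder")
  if (is_cnn && !is.null(decoder$training_manifest)) {
    tm <- decoder$training_manifest$dataset
    em <- eval_set$manifest
    if (identical(tm$seed, em$seed) && identical(tm$config_hash, em$config_hash) &&
        identical(tm$n_images, em$n_images)) {
      msg <- "evaluation set has the same manifest as the training set"
      if (strict) stop(msg) else warning(msg)
    }
  }
  items <- eval_set$items
  N <- length(items)
  n_bits_cell <- eval_set$n^2
  if (is_cnn) {
    scores <- predict_scores(decoder, lapply(items, `[[`, "raster"),
                             batch_size = batch_size)
    bits <- (scores > decoder$decision_threshold) * 1L
  } else {
    bits <- vapply(items, function(it)
      baseline_decode(it$raster, decoder, channel = it$channel)$bits,
      integer(n_bits_cell))
  }
  truth <- vapply(items, function(it) it$key$bits, integer(n_bits_cell))
  errs <- bits != truth
  chans <- vapply(items, `[[`, "", "channel")
  per_channel <- vapply(channel_order, function(ch) {
    sel <- chans == ch
    if (!any(sel)) return(c(bits = 0, errors = 0, ber = NA_real_))
    e <- sum(errs[, sel]); b <- sum(sel) * n_bits_cell
    c(bits = b, errors = e, ber = e / b)
  }, numeric(3))
  n_err <- sum(errs)
  n_tot <- N * n_bits_cell
  structure(list(n_images = N, n_bits_total = n_tot, n_bit_errors = n_err,
                 ber = n_err / n_tot, per_channel = t(per_channel),
                 decoder = if (is_cnn) "cnn" else "baseline",
                 eval_manifest = eval_set$manifest),
            class = "ber_report")
}

#' @export
print.ber_report <- function(x, ...) {
  cat("BER report (", x$decoder, " decoder): ", x$n_bit_errors, " / ",
      x$n_bits_total, " bits wrong over ", x$n_images, " images\n",
      "  bit error ratio = ", format(x$ber, digits = 4), "\n", sep = "")
  invisible(x)
}
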