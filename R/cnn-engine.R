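## Internal neural-network engine for the log-mel CNN.
##
## Feature maps are stored as dense matrices of shape C x (H*W*B): channels
## as rows, spatial positions (column-major H x W) then batch along the
## columns. In this layout batch normalisation is a rowMeans, convolutions
## are an im2col gather followed by one BLAS GEMM per layer per batch with
## no re-permutation, and pooling is a column gather. Gather index vectors
## depend only on (layer, batch size) and are cached. Backpropagation
## mirrors each forward step; correctness is pinned down by a
## finite-difference gradient check in the test suite.

## ---- geometry -----------------------------------------------------------

conv_geometry <- function(H, W, C_in, C_out, kernel = 5L, stride = 1L) {
  pad <- kernel %/% 2
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- (H + 2L * pad - kernel) %/% stride + 1L
  Wo <- (W + 2L * pad - kernel) %/% stride + 1L
  K <- kernel * kernel * C_in

  ## per-sample padded column of each original pixel (column-major H x W)
  ww <- rep(seq_len(W), each = H)
  hh <- rep(seq_len(H), times = W)
  pad_cols <- (ww + pad - 1L) * Hp + (hh + pad)

  ## kernel taps: channel fastest, then dh, then dw
  kc <- rep(seq_len(C_in), times = kernel * kernel)
  kh <- rep(rep(seq_len(kernel), each = C_in), times = kernel)
  kw <- rep(seq_len(kernel), each = C_in * kernel)
  ## output pixels (column-major Ho x Wo)
  pw <- rep(seq_len(Wo), each = Ho)
  ph <- rep(seq_len(Ho), times = Wo)

  ## base[k, p]: linear index (c + C*(q-1)) into one sample's padded map
  q <- outer((kw - 1L) * Hp + kh, ((pw - 1L) * stride) * Hp + (ph - 1L) * stride, `+`)
  base <- matrix(rep(kc, ncol(q)), nrow(q)) + C_in * (q - 1L)

  list(H = H, W = W, C_in = C_in, C_out = C_out, K = K, stride = stride,
       Ho = Ho, Wo = Wo, HW = H * W, HWo = Ho * Wo, HpWp = Hp * Wp,
       pad_cols = pad_cols, base_vec = as.integer(base),
       base_groups = sort(unique(as.integer(base))),
       cache = new.env(parent = emptyenv()))
}

## batch-size dependent index vectors, cached per (geometry, B)
conv_batch_index <- function(g, B) {
  key <- paste0("B", B)
  if (is.null(g$cache[[key]])) {
    g$cache[[key]] <- list(
      pad_cols = rep(g$pad_cols, B) +
        rep.int((seq_len(B) - 1L) * g$HpWp, rep.int(g$HW, B)),
      idx = rep(g$base_vec, B) +
        rep.int((seq_len(B) - 1L) * g$C_in * g$HpWp,
                rep.int(g$K * g$HWo, B))
    )
  }
  g$cache[[key]]
}

pool_geometry <- function(H, W, C, ph, pw) {
  Ho <- H %/% ph
  Wo <- W %/% pw
  ow <- rep(seq_len(Wo), each = Ho)
  oh <- rep(seq_len(Ho), times = Wo)
  offsets <- vector("list", ph * pw)
  o <- 0L
  for (dw in seq_len(pw)) {
    for (dh in seq_len(ph)) {
      o <- o + 1L
      offsets[[o]] <- ((ow - 1L) * pw + dw - 1L) * H + ((oh - 1L) * ph + dh)
    }
  }
  list(H = H, W = W, C = C, Ho = Ho, Wo = Wo, HW = H * W, HWo = Ho * Wo,
       offsets = offsets, cache = new.env(parent = emptyenv()))
}

pool_batch_index <- function(g, B) {
  key <- paste0("B", B)
  if (is.null(g$cache[[key]])) {
    shift <- rep.int((seq_len(B) - 1L) * g$HW, rep.int(g$HWo, B))
    g$cache[[key]] <- lapply(g$offsets, function(q) rep(q, B) + shift)
  }
  g$cache[[key]]
}

## ---- layers -------------------------------------------------------------

conv_forward <- function(M, Wt, b, g, B) {
  ix <- conv_batch_index(g, B)
  Mpad <- matrix(0, g$C_in, g$HpWp * B)
  Mpad[, ix$pad_cols] <- M
  colK <- Mpad[ix$idx]
  dim(colK) <- c(g$K, g$HWo * B)
  list(y = Wt %*% colK + b, colK = colK)
}

conv_backward <- function(dY, Wt, g, colK, B) {
  ix <- conv_batch_index(g, B)
  dW <- tcrossprod(dY, colK)
  db <- rowSums(dY)
  dcol <- crossprod(Wt, dY) # K x (HWo*B)
  dim(dcol) <- c(g$K * g$HWo, B)
  rs <- rowsum(dcol, group = g$base_vec)
  dMpad <- matrix(0, g$C_in * g$HpWp, B)
  dMpad[g$base_groups, ] <- rs
  dim(dMpad) <- c(g$C_in, g$HpWp * B)
  list(dX = dMpad[, ix$pad_cols, drop = FALSE], dW = dW, db = db)
}

pool_forward <- function(M, g, B) {
  ix <- pool_batch_index(g, B)
  best <- M[, ix[[1]], drop = FALSE]
  arg <- matrix(1L, nrow(best), ncol(best))
  for (o in seq_along(ix)[-1]) {
    cand <- M[, ix[[o]], drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- o
  }
  list(y = best, arg = arg)
}

pool_backward <- function(dY, arg, g, B) {
  ix <- pool_batch_index(g, B)
  dM <- matrix(0, nrow(dY), g$HW * B)
  for (o in seq_along(ix)) {
    dM[, ix[[o]]] <- dM[, ix[[o]], drop = FALSE] + dY * (arg == o)
  }
  dM
}

BN_EPS <- 1e-5

bn_forward <- function(M, gamma, beta, train, run_mean, run_var) {
  if (train) {
    mean_c <- rowMeans(M)
    var_c <- pmax(rowMeans(M^2) - mean_c^2, 0)
  } else {
    mean_c <- run_mean
    var_c <- run_var
  }
  inv_sd <- 1 / sqrt(var_c + BN_EPS)
  xhat <- (M - mean_c) * inv_sd
  list(y = gamma * xhat + beta, xhat = xhat, inv_sd = inv_sd,
       batch_mean = mean_c, batch_var = var_c)
}

bn_backward <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  n <- ncol(dY)
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  dX <- (cache$inv_sd / n) * (n * dxhat - rowSums(dxhat) - xhat * dgamma)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- network ------------------------------------------------------------

nn_init <- function(input_shape = c(96L, 101L), conv_channels = c(24L, 48L, 96L),
                    kernel = 5L, conv_strides = c(2L, 1L, 1L),
                    pool_sizes = list(c(4L, 4L), c(2L, 2L)),
                    dense_units = 112L, n_classes = 4L, seed = 1L) {
  if (length(conv_channels) != 3L) {
    abort(sprintf("The network has exactly 3 convolutional layers; got %d channel widths.",
                  length(conv_channels)))
  }
  if (length(pool_sizes) != 2L) abort("The network has exactly 2 max-pooling stages.")

  H0 <- input_shape[1]; W0 <- input_shape[2]
  c1 <- conv_channels[1]; c2 <- conv_channels[2]; c3 <- conv_channels[3]
  g1 <- conv_geometry(H0, W0, 1L, c1, kernel, conv_strides[1])
  p1 <- pool_geometry(g1$Ho, g1$Wo, c1, pool_sizes[[1]][1], pool_sizes[[1]][2])
  g2 <- conv_geometry(p1$Ho, p1$Wo, c1, c2, kernel, conv_strides[2])
  p2 <- pool_geometry(g2$Ho, g2$Wo, c2, pool_sizes[[2]][1], pool_sizes[[2]][2])
  g3 <- conv_geometry(p2$Ho, p2$Wo, c2, c3, kernel, conv_strides[3])
  n_flat <- g3$HWo * c3

  params <- with_seed(seed, list(
    gamma0 = rep(1, 1), beta0 = rep(0, 1),
    W1 = matrix(rnorm(c1 * g1$K, sd = sqrt(2 / g1$K)), c1, g1$K), b1 = rep(0, c1),
    gamma1 = rep(1, c1), beta1 = rep(0, c1),
    W2 = matrix(rnorm(c2 * g2$K, sd = sqrt(2 / g2$K)), c2, g2$K), b2 = rep(0, c2),
    gamma2 = rep(1, c2), beta2 = rep(0, c2),
    W3 = matrix(rnorm(c3 * g3$K, sd = sqrt(2 / g3$K)), c3, g3$K), b3 = rep(0, c3),
    Wd1 = matrix(rnorm(dense_units * n_flat, sd = sqrt(2 / n_flat)),
                 dense_units, n_flat), bd1 = rep(0, dense_units),
    Wd2 = matrix(rnorm(n_classes * dense_units, sd = sqrt(2 / dense_units)),
                 n_classes, dense_units), bd2 = rep(0, n_classes)
  ))

  list(
    geom = list(g1 = g1, p1 = p1, g2 = g2, p2 = p2, g3 = g3, n_flat = n_flat,
                input_dim = H0 * W0),
    params = params,
    running = list(mean0 = 0, var0 = 1, mean1 = rep(0, c1), var1 = rep(1, c1),
                   mean2 = rep(0, c2), var2 = rep(1, c2)),
    input_shape = input_shape, n_classes = n_classes
  )
}

nn_param_count <- function(net) sum(vapply(net$params, length, numeric(1)))

relu <- function(x) pmax(x, 0)

## X: (H*W) x B matrix of patches
nn_forward <- function(net, X, train = TRUE) {
  p <- net$params; g <- net$geom; r <- net$running
  B <- ncol(X)
  M0 <- matrix(X, 1L, g$input_dim * B)

  bn0 <- bn_forward(M0, p$gamma0, p$beta0, train, r$mean0, r$var0)
  a0 <- relu(bn0$y)
  cv1 <- conv_forward(a0, p$W1, p$b1, g$g1, B)
  pl1 <- pool_forward(cv1$y, g$p1, B)

  bn1 <- bn_forward(pl1$y, p$gamma1, p$beta1, train, r$mean1, r$var1)
  a1 <- relu(bn1$y)
  cv2 <- conv_forward(a1, p$W2, p$b2, g$g2, B)
  pl2 <- pool_forward(cv2$y, g$p2, B)

  bn2 <- bn_forward(pl2$y, p$gamma2, p$beta2, train, r$mean2, r$var2)
  a2 <- relu(bn2$y)
  cv3 <- conv_forward(a2, p$W3, p$b3, g$g3, B)
  h <- relu(cv3$y) # c3 x (HWo3*B)
  hf <- matrix(h, g$n_flat, B)

  z1 <- p$Wd1 %*% hf + p$bd1
  d1 <- relu(z1)
  z2 <- p$Wd2 %*% d1 + p$bd2

  zmax <- apply(z2, 2, max)
  ez <- exp(sweep(z2, 2, zmax))
  probs <- sweep(ez, 2, colSums(ez), `/`)

  list(probs = probs, B = B,
       cache = list(bn0 = bn0, cv1 = cv1, pl1 = pl1,
                    bn1 = bn1, cv2 = cv2, pl2 = pl2,
                    bn2 = bn2, cv3 = cv3, h = h, hf = hf,
                    z1 = z1, d1 = d1))
}

## y: integer class ids 1..n_classes; returns loss and gradients
nn_backward <- function(net, fwd, y) {
  p <- net$params; g <- net$geom; cc <- fwd$cache
  B <- fwd$B
  probs <- fwd$probs
  loss <- -mean(log(pmax(probs[cbind(y, seq_len(B))], 1e-12)))

  dz2 <- probs
  dz2[cbind(y, seq_len(B))] <- dz2[cbind(y, seq_len(B))] - 1
  dz2 <- dz2 / B

  gr <- list()
  gr$Wd2 <- tcrossprod(dz2, cc$d1); gr$bd2 <- rowSums(dz2)
  dd1 <- crossprod(p$Wd2, dz2) * (cc$z1 > 0)
  gr$Wd1 <- tcrossprod(dd1, cc$hf); gr$bd1 <- rowSums(dd1)

  dhf <- crossprod(p$Wd1, dd1)
  dh <- matrix(dhf, nrow(cc$h), ncol(cc$h)) * (cc$cv3$y > 0)
  cb3 <- conv_backward(dh, p$W3, g$g3, cc$cv3$colK, B)
  gr$W3 <- cb3$dW; gr$b3 <- cb3$db
  da2 <- cb3$dX * (cc$bn2$y > 0)
  bb2 <- bn_backward(da2, cc$bn2, p$gamma2)
  gr$gamma2 <- bb2$dgamma; gr$beta2 <- bb2$dbeta

  dpl2 <- pool_backward(bb2$dX, cc$pl2$arg, g$p2, B)
  cb2 <- conv_backward(dpl2, p$W2, g$g2, cc$cv2$colK, B)
  gr$W2 <- cb2$dW; gr$b2 <- cb2$db
  da1 <- cb2$dX * (cc$bn1$y > 0)
  bb1 <- bn_backward(da1, cc$bn1, p$gamma1)
  gr$gamma1 <- bb1$dgamma; gr$beta1 <- bb1$dbeta

  dpl1 <- pool_backward(bb1$dX, cc$pl1$arg, g$p1, B)
  cb1 <- conv_backward(dpl1, p$W1, g$g1, cc$cv1$colK, B)
  gr$W1 <- cb1$dW; gr$b1 <- cb1$db
  da0 <- cb1$dX * (cc$bn0$y > 0)
  bb0 <- bn_backward(da0, cc$bn0, p$gamma0)
  gr$gamma0 <- bb0$dgamma; gr$beta0 <- bb0$dbeta

  list(loss = loss, grads = gr)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.001,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## update running BN statistics from the batch statistics of a forward pass;
## the first update copies the batch statistics outright so inference-mode
## normalisation is sane from the very first epoch
nn_update_running <- function(net, fwd, momentum = 0.8) {
  cc <- fwd$cache
  first <- is.null(net$running$n_updates) || net$running$n_updates == 0L
  net$running$n_updates <- (net$running$n_updates %||% 0L) + 1L
  mix <- function(old, new) if (first) new else momentum * old + (1 - momentum) * new
  net$running$mean0 <- mix(net$running$mean0, cc$bn0$batch_mean)
  net$running$var0 <- mix(net$running$var0, cc$bn0$batch_var)
  net$running$mean1 <- mix(net$running$mean1, cc$bn1$batch_mean)
  net$running$var1 <- mix(net$running$var1, cc$bn1$batch_var)
  net$running$mean2 <- mix(net$running$mean2, cc$bn2$batch_mean)
  net$running$var2 <- mix(net$running$var2, cc$bn2$batch_var)
  net
}

## inference-mode class probabilities, chunked to bound memory
nn_predict_probs <- function(net, X, chunk = 128L) {
  n <- ncol(X)
  out <- matrix(0, net$n_classes, n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[, idx] <- nn_forward(net, X[, idx, drop = FALSE], train = FALSE)$probs
  }
  out
}
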