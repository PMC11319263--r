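#' CNN engine settings
#'
#' A 1D convolutional network over the ordered marker sequence: five
#' convolution layers with kernel sizes 11, 11, 9, 13, 9 and strides 1, 3,
#' 5, 5, 5 under 'same' padding, a 32-unit dense layer, and a sigmoid
#' output head of size equal to the target count (8 genotypic parameters,
#' or 1 for direct trait prediction). Hidden activations are ReLU. Targets
#' are scaled to `[0, 1]` (genotypic parameters by their calibration
#' bounds, a trait by its training range); training minimizes a relative
#' root-mean-square loss on the scaled targets with the Adam optimizer.
#'
#' @param kernels,strides,channels Integer vectors (one per conv layer).
#' @param dense_units Width of the fully connected layer.
#' @param lr Adam learning rate.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param val_fraction Fraction of the training set held out for early
#'   stopping (0 disables early stopping).
#' @param patience Early-stopping patience in epochs.
#' @param rel_floor Floor added to the scaled target in the relative-error
#'   denominator, guarding the loss against near-zero scaled targets.
#' @param target_bounds Optional list with `lower` and `upper` vectors
#'   defining a fixed target scaling (e.g. the parameter bounds); when
#'   `NULL` the training data set the range.
#' @param seed Integer seed (initialization, batching, validation split).
#' @param verbose Print the loss once per `verbose` epochs (0 = silent).
#' @return Settings list.
#' @export
cnn_settings <- function(kernels = c(11, 11, 9, 13, 9),
                         strides = c(1, 3, 5, 5, 5),
                         channels = c(8, 16, 16, 32, 32),
                         dense_units = 32, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, adam_eps = 1e-8, batch_size = 16,
                         epochs = 200, val_fraction = 0.1, patience = 20,
                         rel_floor = 0.1, target_bounds = NULL, seed = 1,
                         verbose = 0) {
  stopifnot(length(kernels) == length(strides),
            length(kernels) == length(channels))
  list(kernels = kernels, strides = strides, channels = channels,
       dense_units = dense_units, lr = lr, beta1 = beta1, beta2 = beta2,
       adam_eps = adam_eps, batch_size = batch_size, epochs = epochs,
       val_fraction = val_fraction, patience = patience,
       rel_floor = rel_floor, target_bounds = target_bounds, seed = seed,
       verbose = verbose)
}

#' Feature lengths along the convolution stack
#'
#' Under 'same' padding each layer outputs `ceiling(L / stride)` positions.
#'
#' @param p Input length (number of markers).
#' @param strides Integer stride per layer.
#' @return Integer vector: length after each layer.
#' @export
conv_out_lengths <- function(p, strides = c(1, 3, 5, 5, 5)) {
  out <- integer(length(strides))
  L <- p
  for (i in seq_along(strides)) {
    L <- ceiling(L / strides[i])
    out[i] <- L
  }
  out
}

# ---- layout: layer activations are (L * B) x C matrices, row l + L*(b-1);
# a conv output in this layout feeds the next layer without any reshaping.
# The weight matrix has k row-blocks of C_in (tap u block, channel within),
# matching the k row-gathers that build the im2col matrix.

conv_pad_plan <- function(L_in, k, stride) {
  L_out <- ceiling(L_in / stride)
  pad_total <- max(0L, (L_out - 1L) * stride + k - L_in)
  pad_l <- pad_total %/% 2L
  idx <- outer(seq_len(k), (seq_len(L_out) - 1L) * stride, "+")  # k x L_out
  list(L_in = L_in, L_out = L_out, L_pad = L_in + pad_total, pad_l = pad_l,
       k = k, idx = idx)
}

# row indices of real (non-padding) positions, and per-tap gather rows
conv_row_maps <- function(plan, B) {
  real <- as.vector(outer(plan$pad_l + seq_len(plan$L_in),
                          (seq_len(B) - 1L) * plan$L_pad, "+"))
  taps <- lapply(seq_len(plan$k), function(u)
    as.vector(outer(plan$idx[u, ], (seq_len(B) - 1L) * plan$L_pad, "+")))
  list(real = real, taps = taps)
}

conv_forward <- function(A, W, b, plan, B) {
  C_in <- ncol(A)
  maps <- conv_row_maps(plan, B)
  Ap <- matrix(0, plan$L_pad * B, C_in)
  Ap[maps$real, ] <- A
  Xcol <- .im2col_gather(Ap, maps$taps)
  Z <- Xcol %*% W + rep(b, each = plan$L_out * B)
  list(Z = Z, Xcol = Xcol, maps = maps)
}

conv_backward <- function(dZ, cache, W, plan, C_in, B) {
  dW <- crossprod(cache$Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- dZ %*% t(W)
  dAp <- .col2im_scatter(dXcol, cache$maps$taps, plan$L_pad * B, C_in)
  list(dA = dAp[cache$maps$real, , drop = FALSE], dW = dW, db = db)
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

cnn_init <- function(p, m, s) {
  n_conv <- length(s$kernels)
  params <- list()
  L <- p; C <- 1L
  plans <- vector("list", n_conv)
  for (i in seq_len(n_conv)) {
    plans[[i]] <- conv_pad_plan(L, s$kernels[i], s$strides[i])
    fan_in <- s$kernels[i] * C
    params[[paste0("Wc", i)]] <-
      matrix(stats::rnorm(fan_in * s$channels[i], 0, sqrt(2 / fan_in)),
             fan_in, s$channels[i])
    params[[paste0("bc", i)]] <- rep(0, s$channels[i])
    L <- plans[[i]]$L_out; C <- s$channels[i]
  }
  flat <- L * C
  params$W1 <- matrix(stats::rnorm(flat * s$dense_units, 0, sqrt(2 / flat)),
                      flat, s$dense_units)
  params$b1 <- rep(0, s$dense_units)
  params$W2 <- matrix(stats::rnorm(s$dense_units * m, 0,
                                   sqrt(1 / s$dense_units)),
                      s$dense_units, m)
  params$b2 <- rep(0, m)
  list(params = params, plans = plans, flat = flat, final_L = L, final_C = C)
}

cnn_forward <- function(X, net, s, keep_cache = FALSE) {
  B <- nrow(X)
  A <- matrix(as.vector(t(X)), ncol = 1L)  # (L * B) x 1, L fastest
  caches <- list()
  for (i in seq_along(net$plans)) {
    C_in <- ncol(A)
    cv <- conv_forward(A, net$params[[paste0("Wc", i)]],
                       net$params[[paste0("bc", i)]], net$plans[[i]], B)
    A <- relu(cv$Z)
    if (keep_cache) caches[[i]] <- list(Xcol = cv$Xcol, Z = cv$Z,
                                        maps = cv$maps, C_in = C_in)
  }
  # flatten (L * B) x C -> B x (L * C); the final map is small
  Fl <- matrix(aperm(array(A, c(net$final_L, B, net$final_C)), c(2, 1, 3)),
               B, net$flat)
  Z1 <- Fl %*% net$params$W1 + rep(net$params$b1, each = B)
  H <- relu(Z1)
  Z2 <- H %*% net$params$W2 + rep(net$params$b2, each = B)
  Yhat <- sigmoid(Z2)
  if (!keep_cache) return(list(Yhat = Yhat))
  list(Yhat = Yhat, caches = caches, Fl = Fl, Z1 = Z1, H = H, B = B)
}

cnn_loss <- function(Ys, Yhat, rel_floor) {
  sqrt(mean(((Ys - Yhat) / (Ys + rel_floor))^2))
}

cnn_backward <- function(X, Ys, fw, net, s) {
  B <- fw$B
  r <- (Ys - fw$Yhat) / (Ys + s$rel_floor)
  loss <- sqrt(mean(r^2))
  N <- length(Ys)
  dYhat <- -r / ((Ys + s$rel_floor) * N * max(loss, 1e-8))
  dZ2 <- dYhat * fw$Yhat * (1 - fw$Yhat)
  grads <- list()
  grads$W2 <- crossprod(fw$H, dZ2)
  grads$b2 <- colSums(dZ2)
  dH <- dZ2 %*% t(net$params$W2)
  dZ1 <- dH * (fw$Z1 > 0)
  grads$W1 <- crossprod(fw$Fl, dZ1)
  grads$b1 <- colSums(dZ1)
  dFl <- dZ1 %*% t(net$params$W1)
  dA <- matrix(aperm(array(dFl, c(B, net$final_L, net$final_C)), c(2, 1, 3)),
               net$final_L * B, net$final_C)
  for (i in rev(seq_along(net$plans))) {
    ca <- fw$caches[[i]]
    dZ <- dA * (ca$Z > 0)
    bk <- conv_backward(dZ, ca, net$params[[paste0("Wc", i)]],
                        net$plans[[i]], ca$C_in, B)
    grads[[paste0("Wc", i)]] <- bk$dW
    grads[[paste0("bc", i)]] <- bk$db
    dA <- bk$dA
  }
  list(grads = grads, loss = loss)
}

cnn_fit_impl <- function(X, Y, s) {
  Y <- as.matrix(Y)
  m <- ncol(Y)
  if (!m %in% c(1L, 8L))
    warning("CNN head of size ", m,
            " (typical uses are 8 parameters or 1 trait)")
  scaler <- if (!is.null(s$target_bounds))
    target_scaler(s$target_bounds$lower, s$target_bounds$upper)
  else scaler_from_data(Y)
  Ys_all <- scaler$forward(Y)
  set.seed(s$seed)
  net <- cnn_init(ncol(X), m, s)

  n <- nrow(X)
  n_val <- if (s$val_fraction > 0) max(1L, floor(s$val_fraction * n)) else 0L
  idx <- sample.int(n)
  val_i <- if (n_val > 0 && n - n_val >= 2) idx[seq_len(n_val)] else integer(0)
  tr_i <- setdiff(idx, val_i)

  adam_m <- lapply(net$params, function(p) p * 0)
  adam_v <- lapply(net$params, function(p) p * 0)
  step <- 0L
  best_val <- Inf; best_params <- net$params; wait <- 0L
  history <- numeric(0)

  for (ep in seq_len(s$epochs)) {
    ord <- sample(tr_i)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, length(ord), by = s$batch_size)) {
      bi <- ord[start:min(start + s$batch_size - 1L, length(ord))]
      fw <- cnn_forward(X[bi, , drop = FALSE], net, s, keep_cache = TRUE)
      bk <- cnn_backward(X[bi, , drop = FALSE],
                         Ys_all[bi, , drop = FALSE], fw, net, s)
      if (!is.finite(bk$loss))
        stop("non-finite CNN training loss at epoch ", ep)
      step <- step + 1L
      for (nmp in names(net$params)) {
        g <- bk$grads[[nmp]]
        adam_m[[nmp]] <- s$beta1 * adam_m[[nmp]] + (1 - s$beta1) * g
        adam_v[[nmp]] <- s$beta2 * adam_v[[nmp]] + (1 - s$beta2) * g^2
        mhat <- adam_m[[nmp]] / (1 - s$beta1^step)
        vhat <- adam_v[[nmp]] / (1 - s$beta2^step)
        net$params[[nmp]] <- net$params[[nmp]] -
          s$lr * mhat / (sqrt(vhat) + s$adam_eps)
      }
      ep_loss <- ep_loss + bk$loss; nb <- nb + 1L
    }
    history <- c(history, ep_loss / nb)
    if (s$verbose > 0 && ep %% s$verbose == 0)
      message("epoch ", ep, " loss ", signif(ep_loss / nb, 4))
    if (length(val_i)) {
      fv <- cnn_forward(X[val_i, , drop = FALSE], net, s)
      vl <- cnn_loss(Ys_all[val_i, , drop = FALSE], fv$Yhat, s$rel_floor)
      if (vl < best_val - 1e-6) {
        best_val <- vl; best_params <- net$params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= s$patience) break
      }
    }
  }
  if (length(val_i)) net$params <- best_params
  list(net = net, scaler = scaler, settings = s, history = history,
       final_loss = utils::tail(history, 1))
}

cnn_predict_impl <- function(state, X) {
  s <- state$settings
  n <- nrow(X)
  out <- NULL
  # bounded batches keep the im2col buffers small
  for (start in seq(1, n, by = 256)) {
    bi <- start:min(start + 255, n)
    fw <- cnn_forward(X[bi, , drop = FALSE], state$net, s)
    out <- rbind(out, fw$Yhat)
  }
  state$scaler$inverse(out)
}
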