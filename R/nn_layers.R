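# Sequential neural-network engine used by the point classifiers.
#
# Activations travel either as a matrix (batch x features) or a 3D array
# (batch x time x channels).  Reshape nodes are inserted at compile time
# when a sequence layer receives flat input (width k -> k x 1 sequence)
# or a dense layer receives a sequence (flattened).  All gradients are
# exact analytic backpropagation; a finite-difference check in the test
# suite guards every layer type.

#' Layer descriptors for sequential model specifications
#'
#' Constructors for the processing layers accepted by [model_spec()].
#' An input layer is prepended and a softmax output layer appended
#' automatically by [model_spec()].
#'
#' @param units Number of units (dense, LSTM).
#' @param activation `"relu"` or `"linear"` (dense).
#' @param filters,kernel_size 1D convolution size parameters.
#' @param pool_size Max-pooling window along the sequence axis.
#' @param rate Dropout rate in `[0, 1)`.
#' @param return_sequences If `TRUE` an LSTM emits its full hidden
#'   sequence, otherwise only the final hidden state.
#' @return A layer descriptor list.
#' @name layers
NULL

#' @rdname layers
#' @export
layer_dense <- function(units, activation = "relu") {
  stopifnot(units >= 1, activation %in% c("relu", "linear"))
  list(kind = "dense", units = as.integer(units), activation = activation)
}

#' @rdname layers
#' @export
layer_conv1d <- function(filters, kernel_size = 5L) {
  stopifnot(filters >= 1, kernel_size >= 1)
  list(kind = "conv-1d", filters = as.integer(filters),
       kernel_size = as.integer(kernel_size))
}

#' @rdname layers
#' @export
layer_maxpool <- function(pool_size = 2L) {
  stopifnot(pool_size >= 1)
  list(kind = "max-pool", pool_size = as.integer(pool_size))
}

#' @rdname layers
#' @export
layer_dropout <- function(rate = 0.25) {
  stopifnot(rate >= 0, rate < 1)
  list(kind = "dropout", rate = rate)
}

#' @rdname layers
#' @export
layer_lstm <- function(units, return_sequences = FALSE) {
  stopifnot(units >= 1)
  list(kind = "lstm", units = as.integer(units),
       return_sequences = isTRUE(return_sequences))
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(prod(dims), -lim, lim), dims[1], dims[2])
}

sigm <- function(x) 1 / (1 + exp(-x))

# Compile a model_spec into a list of executable nodes with initialized
# parameters.  Uses the current RNG state (caller seeds).
compile_network <- function(spec) {
  shape <- spec$input_k        # length-1: flat width; length-2: (T, C)
  nodes <- list()
  add <- function(node) nodes[[length(nodes) + 1L]] <<- node

  for (ly in spec$layers) {
    kind <- ly$kind
    if (kind == "input") next
    if (kind %in% c("conv-1d", "max-pool", "lstm") && length(shape) == 1L) {
      add(list(kind = "to-seq"))
      shape <- c(shape, 1L)
    }
    if (kind %in% c("dense", "output-softmax") && length(shape) == 2L) {
      add(list(kind = "flatten", in_shape = shape))
      shape <- prod(shape)
    }
    if (kind == "dense" || kind == "output-softmax") {
      units <- if (kind == "dense") ly$units else spec$n_classes
      act <- if (kind == "dense") ly$activation else "linear"
      add(list(kind = "dense", activation = act,
               params = list(W = glorot(shape, units, c(shape, units)),
                             b = rep(0, units))))
      shape <- units
    } else if (kind == "conv-1d") {
      K <- ly$kernel_size; C <- shape[2]; nf <- ly$filters
      if (shape[1] < K)
        abort_param("conv-1d kernel %d longer than sequence %d", K, shape[1])
      add(list(kind = "conv-1d", K = K, C = C, F = nf,
               params = list(W = glorot(K * C, nf, c(K * C, nf)),
                             b = rep(0, nf))))
      shape <- c(shape[1] - K + 1L, nf)
    } else if (kind == "max-pool") {
      s <- ly$pool_size
      add(list(kind = "max-pool", s = s, t_in = shape[1]))
      shape <- c(shape[1] %/% s, shape[2])
    } else if (kind == "dropout") {
      add(list(kind = "dropout", rate = ly$rate))
    } else if (kind == "lstm") {
      C <- shape[2]; H <- ly$units
      b <- rep(0, 4 * H)
      b[(H + 1):(2 * H)] <- 1   # forget-gate bias
      add(list(kind = "lstm", H = H, C = C, seq = ly$return_sequences,
               params = list(Wx = glorot(C, 4 * H, c(C, 4 * H)),
                             Wh = glorot(H, 4 * H, c(H, 4 * H)),
                             b = b)))
      shape <- if (ly$return_sequences) c(shape[1], H) else H
    } else {
      abort_param("unknown layer kind '%s'", kind)
    }
  }
  if (length(shape) != 1L || shape != spec$n_classes)
    stop("internal: network does not end in n_classes logits")
  nodes
}

net_forward <- function(nodes, x, training = FALSE) {
  caches <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    res <- switch(nd$kind,
      "to-seq" = list(y = array(x, c(nrow(x), ncol(x), 1L)), cache = NULL),
      "flatten" = {
        d <- dim(x)
        list(y = matrix(x, d[1], d[2] * d[3]), cache = d)
      },
      "dense" = fwd_dense(nd, x),
      "conv-1d" = fwd_conv(nd, x),
      "max-pool" = fwd_pool(nd, x),
      "dropout" = fwd_dropout(nd, x, training),
      "lstm" = fwd_lstm(nd, x))
    x <- res$y
    caches[[i]] <- res$cache
  }
  list(out = x, caches = caches)
}

net_backward <- function(nodes, caches, dout) {
  grads <- vector("list", length(nodes))
  dy <- dout
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    res <- switch(nd$kind,
      "to-seq" = list(dx = matrix(dy, dim(dy)[1], dim(dy)[2]), grads = NULL),
      "flatten" = list(dx = array(dy, caches[[i]]), grads = NULL),
      "dense" = bwd_dense(nd, caches[[i]], dy),
      "conv-1d" = bwd_conv(nd, caches[[i]], dy),
      "max-pool" = bwd_pool(nd, caches[[i]], dy),
      "dropout" = bwd_dropout(nd, caches[[i]], dy),
      "lstm" = bwd_lstm(nd, caches[[i]], dy))
    dy <- res$dx
    grads[i] <- list(res$grads)  # keep NULL placeholders for param-free nodes
  }
  grads
}

fwd_dense <- function(nd, x) {
  pre <- sweep(x %*% nd$params$W, 2, nd$params$b, `+`)
  y <- if (nd$activation == "relu") pmax(pre, 0) else pre
  list(y = y, cache = list(x = x, pre = pre))
}

bwd_dense <- function(nd, cache, dy) {
  if (nd$activation == "relu") dy <- dy * (cache$pre > 0)
  list(dx = dy %*% t(nd$params$W),
       grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

unfold_seq <- function(x, K, Tout) {
  d <- dim(x); B <- d[1]; C <- d[3]
  cols <- vector("list", K * C)
  for (c in seq_len(C))
    for (j in seq_len(K))
      cols[[(c - 1L) * K + j]] <- as.vector(x[, j:(j + Tout - 1L), c])
  matrix(unlist(cols, use.names = FALSE), B * Tout, K * C)
}

fwd_conv <- function(nd, x) {
  d <- dim(x); B <- d[1]; Tin <- d[2]
  Tout <- Tin - nd$K + 1L
  xu <- unfold_seq(x, nd$K, Tout)
  pre <- sweep(xu %*% nd$params$W, 2, nd$params$b, `+`)
  y <- array(pmax(pre, 0), c(B, Tout, nd$F))
  list(y = y, cache = list(xu = xu, pre = pre, B = B, Tin = Tin, Tout = Tout))
}

bwd_conv <- function(nd, cache, dy) {
  B <- cache$B; Tout <- cache$Tout
  dym <- matrix(dy, B * Tout, nd$F) * (cache$pre > 0)
  dW <- crossprod(cache$xu, dym)
  db <- colSums(dym)
  dxu <- dym %*% t(nd$params$W)
  dx <- array(0, c(B, cache$Tin, nd$C))
  for (c in seq_len(nd$C))
    for (j in seq_len(nd$K)) {
      sl <- matrix(dxu[, (c - 1L) * nd$K + j], B, Tout)
      dx[, j:(j + Tout - 1L), c] <- dx[, j:(j + Tout - 1L), c] + sl
    }
  list(dx = dx, grads = list(W = dW, b = db))
}

fwd_pool <- function(nd, x) {
  d <- dim(x); B <- d[1]; C <- d[3]; s <- nd$s
  Tout <- d[2] %/% s
  best <- x[, seq(1L, by = s, length.out = Tout), , drop = FALSE]
  winner <- array(1L, dim(best))
  if (s > 1) for (i in 2:s) {
    cand <- x[, seq(i, by = s, length.out = Tout), , drop = FALSE]
    upd <- cand > best      # ties keep the earlier position
    best[upd] <- cand[upd]
    winner[upd] <- i
  }
  list(y = best, cache = list(winner = winner, t_in = d[2], B = B, C = C,
                              Tout = Tout))
}

bwd_pool <- function(nd, cache, dy) {
  s <- nd$s
  dx <- array(0, c(cache$B, cache$t_in, cache$C))
  for (i in seq_len(s)) {
    m <- dy * (cache$winner == i)
    dx[, seq(i, by = s, length.out = cache$Tout), ] <- m
  }
  list(dx = dx, grads = NULL)
}

fwd_dropout <- function(nd, x, training) {
  if (!training || nd$rate == 0)
    return(list(y = x, cache = NULL))
  mask <- (runif(length(x)) >= nd$rate) / (1 - nd$rate)
  if (is.array(x) || is.matrix(x)) dim(mask) <- dim(x)
  list(y = x * mask, cache = mask)
}

bwd_dropout <- function(nd, cache, dy) {
  if (is.null(cache)) return(list(dx = dy, grads = NULL))
  list(dx = dy * cache, grads = NULL)
}

fwd_lstm <- function(nd, x) {
  d <- dim(x); B <- d[1]; Tn <- d[2]; H <- nd$H
  Wx <- nd$params$Wx; Wh <- nd$params$Wh; b <- nd$params$b
  I <- G <- Fg <- O <- Cs <- Tc <- Hs <- array(0, c(B, Tn, H))
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H)
  i4 <- (3 * H + 1):(4 * H)
  for (t in seq_len(Tn)) {
    xt <- x[, t, , drop = FALSE]; dim(xt) <- c(B, nd$C)
    z <- sweep(xt %*% Wx + h %*% Wh, 2, b, `+`)
    it <- sigm(z[, i1, drop = FALSE]); ft <- sigm(z[, i2, drop = FALSE])
    gt <- tanh(z[, i3, drop = FALSE]); ot <- sigm(z[, i4, drop = FALSE])
    cc <- ft * cc + it * gt
    tc <- tanh(cc)
    h <- ot * tc
    I[, t, ] <- it; Fg[, t, ] <- ft; G[, t, ] <- gt; O[, t, ] <- ot
    Cs[, t, ] <- cc; Tc[, t, ] <- tc; Hs[, t, ] <- h
  }
  y <- if (nd$seq) Hs else h
  list(y = y, cache = list(x = x, I = I, Fg = Fg, G = G, O = O,
                           Cs = Cs, Tc = Tc, Hs = Hs, B = B, Tn = Tn))
}

bwd_lstm <- function(nd, cache, dy) {
  B <- cache$B; Tn <- cache$Tn; H <- nd$H
  Wx <- nd$params$Wx; Wh <- nd$params$Wh
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- rep(0, 4 * H)
  dx <- array(0, dim(cache$x))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  slab <- function(a, t, ncols) {
    s <- a[, t, , drop = FALSE]; dim(s) <- c(B, ncols); s
  }
  for (t in rev(seq_len(Tn))) {
    dh <- dh_next + if (nd$seq) slab(dy, t, H) else
      (if (t == Tn) dy else matrix(0, B, H))
    it <- slab(cache$I, t, H); ft <- slab(cache$Fg, t, H)
    gt <- slab(cache$G, t, H); ot <- slab(cache$O, t, H)
    tc <- slab(cache$Tc, t, H)
    c_prev <- if (t > 1) slab(cache$Cs, t - 1, H) else matrix(0, B, H)
    dc <- dc_next + dh * ot * (1 - tc^2)
    dzo <- dh * tc * ot * (1 - ot)
    dzi <- dc * gt * it * (1 - it)
    dzf <- dc * c_prev * ft * (1 - ft)
    dzg <- dc * it * (1 - gt^2)
    dz <- cbind(dzi, dzf, dzg, dzo)
    xt <- slab(cache$x, t, nd$C)
    h_prev <- if (t > 1) slab(cache$Hs, t - 1, H) else matrix(0, B, H)
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
    dc_next <- dc * ft
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy loss and logit gradient for 0-based integer labels
softmax_xent <- function(logits, y) {
  p <- softmax(logits)
  n <- nrow(p)
  ix <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[ix], 1e-12)))
  dz <- p
  dz[ix] <- dz[ix] - 1
  list(loss = loss, dlogits = dz / n, p = p)
}
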