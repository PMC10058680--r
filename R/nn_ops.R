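# Minimal CNN primitives on dense arrays, layout [H, W, N, C] (batch third so
# that subwindow copies reshape straight into (H*W*N, C) matrices for BLAS).
# Each op returns its output plus the cache its backward pass needs; gradients
# are exact and verified against finite differences in the test suite.

# ---- 3x3 "same" convolution ------------------------------------------------
# Weights: matrix [9*Cin, Cout], rows grouped by kernel offset (dr,dc) in
# row-major order over dr = -1..1, dc = -1..1; bias: length Cout.

conv_offsets <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))

pad_hw <- function(x, p) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

shifted_input <- function(xp, k, H, Wd, Cin) {
  dr <- conv_offsets[k, 1]; dc <- conv_offsets[k, 2]
  xs <- xp[(1 + 1 + dr):(H + 1 + dr), (1 + 1 + dc):(Wd + 1 + dc), , ,
           drop = FALSE]
  dim(xs) <- c(length(xs) / Cin, Cin)
  xs
}

conv3_forward <- function(x, W, b) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- ncol(W)
  xp <- pad_hw(x, 1L)
  y <- matrix(rep(b, each = H * Wd * N), H * Wd * N, Cout)
  for (k in 1:9)
    y <- y + shifted_input(xp, k, H, Wd, Cin) %*%
      W[((k - 1) * Cin + 1):(k * Cin), , drop = FALSE]
  dim(y) <- c(H, Wd, N, Cout)
  # only the padded input is cached; shifted views are rebuilt on backward
  list(out = y, cache = list(xp = xp, W = W, dims = d))
}

conv3_backward <- function(cache, dout) {
  d <- cache$dims
  H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  W <- cache$W
  Cout <- ncol(W)
  dy <- dout; dim(dy) <- c(H * Wd * N, Cout)
  dW <- matrix(0, nrow(W), Cout)
  dxp <- array(0, c(H + 2, Wd + 2, N, Cin))
  for (k in 1:9) {
    rows <- ((k - 1) * Cin + 1):(k * Cin)
    dW[rows, ] <- crossprod(shifted_input(cache$xp, k, H, Wd, Cin), dy)
    dxs <- dy %*% t(W[rows, , drop = FALSE])
    dim(dxs) <- c(H, Wd, N, Cin)
    dr <- conv_offsets[k, 1]; dc <- conv_offsets[k, 2]
    rs <- (1 + 1 + dr):(H + 1 + dr); cs <- (1 + 1 + dc):(Wd + 1 + dc)
    dxp[rs, cs, , ] <- dxp[rs, cs, , , drop = FALSE] + dxs
  }
  list(dx = dxp[2:(H + 1), 2:(Wd + 1), , , drop = FALSE],
       dW = dW, db = colSums(dy))
}

# ---- 1x1 convolution (final classifier) ------------------------------------

conv1_forward <- function(x, W, b) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  y <- sweep(xm %*% W, 2, b, "+")
  dim(y) <- c(d[1:3], ncol(W))
  list(out = y, cache = list(xm = xm, W = W, dims = d))
}

conv1_backward <- function(cache, dout) {
  d <- cache$dims
  dy <- dout; dim(dy) <- c(prod(d[1:3]), ncol(cache$W))
  dx <- dy %*% t(cache$W)
  dim(dx) <- d
  list(dx = dx, dW = crossprod(cache$xm, dy), db = colSums(dy))
}

# ---- ReLU -------------------------------------------------------------------

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(cache, dout) dout * cache

# ---- 2x2 max pooling, stride 2 ----------------------------------------------

pool_forward <- function(x) {
  d <- dim(x)
  r1 <- seq(1L, d[1], 2L); r2 <- r1 + 1L
  c1 <- seq(1L, d[2], 2L); c2 <- c1 + 1L
  a <- list(x[r1, c1, , , drop = FALSE], x[r2, c1, , , drop = FALSE],
            x[r1, c2, , , drop = FALSE], x[r2, c2, , , drop = FALSE])
  y <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  taken <- array(FALSE, dim(y))
  masks <- vector("list", 4L)
  for (k in 1:4) {
    m <- (a[[k]] == y) & !taken   # ties routed to the first candidate
    masks[[k]] <- m
    taken <- taken | m
  }
  list(out = y, cache = list(masks = masks, dims = d))
}

pool_backward <- function(cache, dout) {
  d <- cache$dims
  dx <- array(0, d)
  r1 <- seq(1L, d[1], 2L); r2 <- r1 + 1L
  c1 <- seq(1L, d[2], 2L); c2 <- c1 + 1L
  sel <- list(list(r1, c1), list(r2, c1), list(r1, c2), list(r2, c2))
  for (k in 1:4)
    dx[sel[[k]][[1]], sel[[k]][[2]], , ] <- dout * cache$masks[[k]]
  dx
}

# ---- 2x2 transposed convolution, stride 2 -----------------------------------
# Weights: matrix [4*Cin, Cout], rows grouped by output sub-position (a,b),
# a = row offset 0..1 (fastest), b = col offset 0..1.

upconv_forward <- function(x, W, b) {
  d <- dim(x)
  Cin <- d[4]; Cout <- ncol(W)
  xm <- x; dim(xm) <- c(prod(d[1:3]), Cin)
  y <- array(0, c(2 * d[1], 2 * d[2], d[3], Cout))
  for (k in 1:4) {
    a <- (k - 1) %% 2; bb <- (k - 1) %/% 2
    yk <- sweep(xm %*% W[((k - 1) * Cin + 1):(k * Cin), , drop = FALSE],
                2, b, "+")
    dim(yk) <- c(d[1], d[2], d[3], Cout)
    y[seq(1 + a, 2 * d[1], 2), seq(1 + bb, 2 * d[2], 2), , ] <- yk
  }
  list(out = y, cache = list(xm = xm, W = W, dims = d))
}

upconv_backward <- function(cache, dout) {
  d <- cache$dims
  Cin <- d[4]; Cout <- ncol(cache$W)
  dW <- matrix(0, nrow(cache$W), Cout)
  dx <- matrix(0, prod(d[1:3]), Cin)
  db <- numeric(Cout)
  for (k in 1:4) {
    a <- (k - 1) %% 2; bb <- (k - 1) %/% 2
    dyk <- dout[seq(1 + a, 2 * d[1], 2), seq(1 + bb, 2 * d[2], 2), , ,
                drop = FALSE]
    dim(dyk) <- c(prod(d[1:3]), Cout)
    rows <- ((k - 1) * Cin + 1):(k * Cin)
    dW[rows, ] <- crossprod(cache$xm, dyk)
    dx <- dx + dyk %*% t(cache$W[rows, , drop = FALSE])
    db <- db + colSums(dyk)
  }
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# ---- dropout ----------------------------------------------------------------

dropout_forward <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  keep <- array(runif(length(x)) >= p, dim(x))
  list(out = x * keep / (1 - p), cache = list(keep = keep, p = p))
}

dropout_backward <- function(cache, dout) {
  if (is.null(cache)) return(dout)
  dout * cache$keep / (1 - cache$p)
}

# ---- channel concatenation (skip connections) -------------------------------

concat_forward <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(c(a, b), c(da[1:3], da[4] + db[4]))
  list(out = y, cache = c(da[4], db[4]))
}

concat_backward <- function(cache, dout) {
  ca <- cache[1]
  list(da = dout[, , , seq_len(ca), drop = FALSE],
       db = dout[, , , ca + seq_len(cache[2]), drop = FALSE])
}

# ---- softmax cross-entropy --------------------------------------------------
# logits [H, W, N, K]; targets integer class codes 0..K-1, [H, W, N].

softmax_probs <- function(logits) {
  d <- dim(logits)
  lm <- logits; dim(lm) <- c(prod(d[1:3]), d[4])
  lm <- lm - apply(lm, 1, max)
  p <- exp(lm)
  p <- p / rowSums(p)
  dim(p) <- d
  p
}

softmax_ce <- function(logits, targets) {
  d <- dim(logits)
  n <- prod(d[1:3])
  p <- softmax_probs(logits)
  pm <- p; dim(pm) <- c(n, d[4])
  idx <- cbind(seq_len(n), as.integer(targets) + 1L)
  loss <- -mean(log(pmax(pm[idx], 1e-12)))
  grad <- pm
  grad[idx] <- grad[idx] - 1
  grad <- grad / n
  dim(grad) <- d
  list(loss = loss, grad = grad)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
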