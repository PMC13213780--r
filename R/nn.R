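# Internal neural-network engine for the 1-D convolutional spectral
# regressor and the chemical-spectral fusion variants.  Everything is plain
# matrix code: forward pass, exact backpropagation (including batch
# normalization), and Adam updates, fully deterministic given a seed.
#
# Spectral encoder (all tags with a convolutional branch):
#   conv1  1 -> 16 channels, kernel 3, zero 'same' padding, ReLU
#   maxpool width 2, stride 2 (odd final position dropped)
#   conv2 16 -> 32 channels, kernel 3, 'same' padding, ReLU
#   global average pool -> 32-d feature vector (band-count independent)
# spectral head: dense 32 -> 16 ReLU -> 16 -> 1            (2177 params)
# mcsf: chem dense 2 -> 16 ReLU -> 16 -> 8, concat 40 ->
#   dense 40 -> 48 -> batchnorm -> ReLU -> dense 48 -> 1   (3929 params)
# chemical-only: chem branch -> dense 8 -> 1 (ablation control)
#
# Activations with position structure are stored as (n * positions) x
# channels matrices, position-major; shifts and pooling are row-index
# operations precomputed once per input shape.

nn_shapes <- function(tag) {
  enc <- list(W1 = c(3, 16), b1 = 16, W2 = c(48, 32), b2 = 32)
  switch(tag,
    spectral = c(enc, list(W3 = c(32, 16), b3 = 16, W4 = c(16, 1), b4 = 1)),
    mcsf = ,
    mcsf_fr = c(enc, list(
      Wc1 = c(2, 16), bc1 = 16, Wc2 = c(16, 8), bc2 = 8,
      Wf = c(40, 48), bf = 48, gamma = 48, beta = 48,
      Wo = c(48, 1), bo = 1)),
    chemical = list(Wc1 = c(2, 16), bc1 = 16, Wc2 = c(16, 8), bc2 = 8,
                    Wo8 = c(8, 1), bo = 1),
    abort(paste("unknown model tag:", tag))
  )
}

nn_init <- function(tag, seed = 0) {
  shapes <- nn_shapes(tag)
  set.seed(seed)
  w <- lapply(names(shapes), function(nm) {
    sh <- shapes[[nm]]
    if (nm == "gamma") return(rep(1, sh))
    if (length(sh) == 1) return(rep(0, sh))
    fan_in <- sh[1]
    matrix(rnorm(prod(sh), 0, sqrt(2 / fan_in)), sh[1], sh[2])
  })
  names(w) <- names(shapes)
  buffers <- if (tag %in% c("mcsf", "mcsf_fr")) {
    list(running_mean = rep(0, 48), running_var = rep(1, 48))
  } else {
    list()
  }
  list(tag = tag, w = w, buffers = buffers)
}

frelu <- function(x) x * (x > 0)

add_bias <- function(M, b) M + rep(b, each = nrow(M))

# shift columns of an n x p matrix: position j of the result takes column
# j + o of the input, zero outside.
shift_cols <- function(X, o) {
  n <- nrow(X); p <- ncol(X)
  Y <- matrix(0, n, p)
  if (o == 0) return(X)
  if (o > 0) Y[, seq_len(p - o)] <- X[, (1 + o):p, drop = FALSE]
  else Y[, (1 - o):p] <- X[, seq_len(p + o), drop = FALSE]
  Y
}

# unfold for kernel-3 'same' convolution over 1 channel: (n*p) x 3
conv1_unfold <- function(X) {
  cbind(as.vector(shift_cols(X, -1)), as.vector(X),
        as.vector(shift_cols(X, 1)))
}

# Row-index vectors for pooling and pooled-layer shifts at batch size n and
# p input bands.  Pooled matrices have n*q rows (position-major); index
# n*q + 1 addresses an appended zero row.
conv_indices <- function(n, p) {
  q <- p %/% 2L
  pos_rows <- function(pos) as.vector(outer(seq_len(n), (pos - 1L) * n, "+"))
  shift_rows <- function(o) {
    src <- seq_len(q) + o
    off <- ifelse(src >= 1 & src <= q, (src - 1L) * n, NA_integer_)
    idx <- outer(seq_len(n), off, "+")
    idx[is.na(idx)] <- n * q + 1L
    as.vector(idx)
  }
  list(q = q,
       iodd = pos_rows(seq(1L, 2L * q - 1L, 2L)),
       ieven = pos_rows(seq(2L, 2L * q, 2L)),
       im1 = shift_rows(-1L), ip1 = shift_rows(1L),
       gap_group = rep(seq_len(n), times = q),
       gap_expand = rep(seq_len(n), times = q))
}

nn_forward <- function(net, X, C = NULL, training = FALSE,
                       bn_momentum = 0.1, bn_eps = 1e-5) {
  w <- net$w
  tag <- net$tag
  cache <- list(tag = tag, training = training)
  n <- if (!is.null(X)) nrow(X) else nrow(C)

  if (tag != "chemical") {
    p <- ncol(X)
    ix <- attr(X, "conv_idx") %||% conv_indices(n, p)
    q <- ix$q
    U1 <- attr(X, "unfold") %||% conv1_unfold(X)
    A1pre <- add_bias(U1 %*% w$W1, w$b1)       # (n*p) x 16
    A1 <- frelu(A1pre)
    odd <- A1[ix$iodd, , drop = FALSE]
    even <- A1[ix$ieven, , drop = FALSE]
    mask <- odd >= even
    P <- even + (odd - even) * mask            # max pool, (n*q) x 16
    Pz <- rbind(P, 0)
    U2 <- cbind(Pz[ix$im1, , drop = FALSE], P, Pz[ix$ip1, , drop = FALSE])
    A2pre <- add_bias(U2 %*% w$W2, w$b2)       # (n*q) x 32
    A2 <- frelu(A2pre)
    Fm <- rowsum(A2, group = ix$gap_group) / q # n x 32
    cache <- c(cache, list(U1 = U1, A1pre = A1pre, mask = mask,
                           U2 = U2, A2pre = A2pre, A2 = A2, Fm = Fm,
                           ix = ix, n = n, p = p, q = q))
  }

  if (tag == "spectral") {
    Hpre <- add_bias(Fm %*% w$W3, w$b3)
    H <- frelu(Hpre)
    yhat <- drop(H %*% w$W4) + w$b4
    cache <- c(cache, list(Hpre = Hpre, H = H))
  } else if (tag %in% c("mcsf", "mcsf_fr", "chemical")) {
    C1pre <- add_bias(C %*% w$Wc1, w$bc1)
    C1 <- frelu(C1pre)
    C2 <- add_bias(C1 %*% w$Wc2, w$bc2)
    cache <- c(cache, list(C = C, C1pre = C1pre, C1 = C1, C2 = C2))
    if (tag == "chemical") {
      yhat <- drop(C2 %*% w$Wo8) + w$bo
    } else {
      Fcat <- cbind(Fm, C2)
      Zf <- add_bias(Fcat %*% w$Wf, w$bf)
      if (training) {
        mu <- colMeans(Zf)
        v <- colMeans(Zf^2) - mu^2
        net$buffers$running_mean <-
          (1 - bn_momentum) * net$buffers$running_mean + bn_momentum * mu
        net$buffers$running_var <-
          (1 - bn_momentum) * net$buffers$running_var + bn_momentum * v
      } else {
        mu <- net$buffers$running_mean
        v <- net$buffers$running_var
      }
      ivar <- 1 / sqrt(v + bn_eps)
      xhat <- add_bias(Zf, -mu) * rep(ivar, each = n)
      BNout <- add_bias(xhat * rep(w$gamma, each = n), w$beta)
      Rr <- frelu(BNout)
      yhat <- drop(Rr %*% w$Wo) + w$bo
      cache <- c(cache, list(Fcat = Fcat, Zf = Zf, xhat = xhat, ivar = ivar,
                             BNout = BNout, Rr = Rr))
    }
  }
  list(yhat = yhat, cache = cache, buffers = net$buffers)
}

# Backward pass: dY is dL/dyhat (length n).  Returns gradients named like
# the weights.
nn_backward <- function(net, cache, dY) {
  w <- net$w
  tag <- net$tag
  g <- list()
  dY <- matrix(dY, ncol = 1)
  n <- nrow(dY)

  dF <- NULL
  if (tag == "spectral") {
    g$W4 <- crossprod(cache$H, dY)
    g$b4 <- sum(dY)
    dH <- dY %*% t(w$W4)
    dHpre <- dH * (cache$Hpre > 0)
    g$W3 <- crossprod(cache$Fm, dHpre)
    g$b3 <- colSums(dHpre)
    dF <- dHpre %*% t(w$W3)
  } else if (tag == "chemical") {
    g$Wo8 <- crossprod(cache$C2, dY)
    g$bo <- sum(dY)
    dC2 <- dY %*% t(w$Wo8)
  } else {
    g$Wo <- crossprod(cache$Rr, dY)
    g$bo <- sum(dY)
    dRr <- dY %*% t(w$Wo)
    dBN <- dRr * (cache$BNout > 0)
    g$gamma <- colSums(dBN * cache$xhat)
    g$beta <- colSums(dBN)
    dxhat <- dBN * rep(w$gamma, each = n)
    if (cache$training) {
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * cache$xhat)
      dZf <- add_bias(n * dxhat, -s1) - cache$xhat * rep(s2, each = n)
      dZf <- dZf * rep(cache$ivar / n, each = n)
    } else {
      dZf <- dxhat * rep(cache$ivar, each = n)
    }
    g$Wf <- crossprod(cache$Fcat, dZf)
    g$bf <- colSums(dZf)
    dFcat <- dZf %*% t(w$Wf)
    dF <- dFcat[, 1:32, drop = FALSE]
    dC2 <- dFcat[, 33:40, drop = FALSE]
  }

  if (tag %in% c("mcsf", "mcsf_fr", "chemical")) {
    g$Wc2 <- crossprod(cache$C1, dC2)
    g$bc2 <- colSums(dC2)
    dC1 <- dC2 %*% t(w$Wc2)
    dC1pre <- dC1 * (cache$C1pre > 0)
    g$Wc1 <- crossprod(cache$C, dC1pre)
    g$bc1 <- colSums(dC1pre)
  }

  if (tag != "chemical") {
    ix <- cache$ix
    q <- cache$q; p <- cache$p
    dA2 <- dF[ix$gap_expand, , drop = FALSE] / q
    dA2pre <- dA2 * (cache$A2pre > 0)
    g$W2 <- crossprod(cache$U2, dA2pre)
    g$b2 <- colSums(dA2pre)
    dU2 <- dA2pre %*% t(w$W2)
    B1 <- dU2[, 1:16, drop = FALSE]
    B2 <- dU2[, 17:32, drop = FALSE]
    B3 <- dU2[, 33:48, drop = FALSE]
    # output position k read source k-1 (B1) and k+1 (B3): scatter back
    dP <- B2 + rbind(B1, 0)[ix$ip1, , drop = FALSE] +
      rbind(B3, 0)[ix$im1, , drop = FALSE]
    da1 <- matrix(0, n * p, 16)
    da1[ix$iodd, ] <- dP * cache$mask
    da1[ix$ieven, ] <- dP * (!cache$mask)
    dA1pre <- da1 * (cache$A1pre > 0)
    g$W1 <- crossprod(cache$U1, dA1pre)
    g$b1 <- colSums(dA1pre)
  }
  g
}

adam_init <- function(w) {
  list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0),
       t = 0)
}

adam_step <- function(w, g, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    w[[nm]] <- w[[nm]] - lr * (st$m[[nm]] / c1) /
      (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(w = w, state = st)
}
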