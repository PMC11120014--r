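# Minimal deterministic neural-network layers with explicit forward /
# backward passes. Each layer is an environment with
#   params : named list of arrays
#   grads  : named list, same shapes (accumulated)
#   decay  : named logical, whether AdamW weight decay applies
#   fwd(x, training), bwd(dy)
# Activations for the CNN path are 5D arrays (X, Y, Z, C, N); vectors are
# matrices (features x N). All randomness comes from the caller's RNG.

newLayer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list(); e$grads <- list(); e$decay <- logical(0)
  e
}

zeroGrads <- function(layers) {
  for (e in layers)
    for (nm in names(e$params))
      e$grads[[nm]] <- e$params[[nm]] * 0
  invisible(NULL)
}

layerConv3d <- function(cin, cout, k, stride, pad) {
  e <- newLayer("conv3d")
  fan_in <- k^3 * cin
  e$params$W <- array(rnorm(k^3 * cin * cout, sd = sqrt(2 / fan_in)),
                      c(k, k, k, cin, cout))
  e$params$b <- numeric(cout)
  e$decay <- c(W = TRUE, b = FALSE)
  e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  e$fwd <- function(x, training = FALSE) {
    e$x <- if (training || e$retain) x else NULL
    y <- conv3d_fwd_cpp(x, e$params$W, e$params$b, e$stride, e$pad)
    y
  }
  e$retain <- FALSE
  e$bwd <- function(dy) {
    r <- conv3d_bwd_cpp(e$x, e$params$W, dy, e$stride, e$pad)
    e$grads$W <- e$grads$W + r$dw
    e$grads$b <- e$grads$b + r$db
    r$dx
  }
  e
}

layerReLU <- function() {
  e <- newLayer("relu")
  e$fwd <- function(x, training = FALSE) {
    e$mask <- x > 0
    x * e$mask
  }
  e$bwd <- function(dy) dy * e$mask
  e
}

layerBatchNorm3d <- function(C, momentum = 0.1, eps = 1e-5) {
  e <- newLayer("bn3d")
  e$params$gamma <- rep(1, C)
  e$params$beta <- rep(0, C)
  e$decay <- c(gamma = FALSE, beta = FALSE)
  e$rm <- rep(0, C); e$rv <- rep(1, C)
  e$eps <- eps; e$momentum <- momentum; e$C <- C
  e$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    xp <- aperm(x, c(1, 2, 3, 5, 4))          # (X,Y,Z,N,C)
    M <- matrix(xp, ncol = e$C)
    if (training) {
      mu <- colMeans(M)
      v <- colMeans(M^2) - mu^2
      e$rm <- (1 - e$momentum) * e$rm + e$momentum * mu
      e$rv <- (1 - e$momentum) * e$rv + e$momentum * v
    } else {
      mu <- e$rm; v <- e$rv
    }
    sig <- sqrt(v + e$eps)
    Mh <- sweep(sweep(M, 2, mu), 2, sig, "/")
    Y <- sweep(sweep(Mh, 2, e$params$gamma, "*"), 2, e$params$beta, "+")
    e$cache <- list(Mh = Mh, sig = sig, d = d, training = training)
    aperm(array(Y, dim(xp)), c(1, 2, 3, 5, 4))
  }
  e$bwd <- function(dy) {
    cc <- e$cache
    dp <- aperm(dy, c(1, 2, 3, 5, 4))
    Dm <- matrix(dp, ncol = e$C)
    e$grads$gamma <- e$grads$gamma + colSums(Dm * cc$Mh)
    e$grads$beta <- e$grads$beta + colSums(Dm)
    dxh <- sweep(Dm, 2, e$params$gamma, "*")
    if (cc$training) {
      dxm <- sweep(dxh, 2, colMeans(dxh)) -
        sweep(cc$Mh, 2, colMeans(dxh * cc$Mh), "*")
    } else {
      dxm <- dxh
    }
    dxm <- sweep(dxm, 2, cc$sig, "/")
    dxp <- array(dxm, c(cc$d[1], cc$d[2], cc$d[3], cc$d[5], cc$d[4]))
    aperm(dxp, c(1, 2, 3, 5, 4))
  }
  e
}

layerGlobalAvgPool3d <- function() {
  e <- newLayer("gap3d")
  e$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    e$d <- d
    S <- prod(d[1:3])
    M <- matrix(x, nrow = S)
    matrix(colMeans(M), nrow = d[4], ncol = d[5])   # (C, N)
  }
  e$bwd <- function(dy) {
    S <- prod(e$d[1:3])
    array(rep(as.numeric(dy), each = S) / S, e$d)
  }
  e
}

layerDense <- function(nin, nout, init = c("he", "vit")) {
  init <- match.arg(init)
  e <- newLayer("dense")
  sdv <- if (init == "he") sqrt(2 / nin) else 0.02
  e$params$W <- matrix(rnorm(nout * nin, sd = sdv), nout, nin)
  e$params$b <- numeric(nout)
  e$decay <- c(W = TRUE, b = FALSE)
  e$fwd <- function(x, training = FALSE) {
    e$x <- x
    e$params$W %*% x + e$params$b
  }
  e$bwd <- function(dy) {
    e$grads$W <- e$grads$W + dy %*% t(e$x)
    e$grads$b <- e$grads$b + rowSums(dy)
    crossprod(e$params$W, dy)
  }
  e
}

layerLayerNorm <- function(D, eps = 1e-6) {
  e <- newLayer("ln")
  e$params$g <- rep(1, D)
  e$params$b <- rep(0, D)
  e$decay <- c(g = FALSE, b = FALSE)
  e$eps <- eps
  e$fwd <- function(x, training = FALSE) {   # x: (D, cols)
    mu <- colMeans(x)
    sig <- sqrt(colMeans(x^2) - mu^2 + e$eps)
    Xh <- sweep(sweep(x, 2, mu), 2, sig, "/")
    e$cache <- list(Xh = Xh, sig = sig)
    Xh * e$params$g + e$params$b
  }
  e$bwd <- function(dy) {
    cc <- e$cache
    e$grads$g <- e$grads$g + rowSums(dy * cc$Xh)
    e$grads$b <- e$grads$b + rowSums(dy)
    dxh <- dy * e$params$g
    dx <- sweep(dxh, 2, colMeans(dxh)) -
      sweep(cc$Xh, 2, colMeans(dxh * cc$Xh), "*")
    sweep(dx, 2, cc$sig, "/")
  }
  e
}

gelu <- function(x) x * pnorm(x)
geluGrad <- function(x) pnorm(x) + x * dnorm(x)

layerMLP <- function(D, hidden) {
  e <- newLayer("mlp")
  e$fc1 <- layerDense(D, hidden, init = "vit")
  e$fc2 <- layerDense(hidden, D, init = "vit")
  e$sub <- list(e$fc1, e$fc2)
  e$fwd <- function(x, training = FALSE) {
    h <- e$fc1$fwd(x, training)
    e$h <- h
    e$fc2$fwd(gelu(h), training)
  }
  e$bwd <- function(dy) {
    dg <- e$fc2$bwd(dy)
    e$fc1$bwd(dg * geluGrad(e$h))
  }
  e
}

softmaxRows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# multi-head self-attention over token sequences
# activations: array (D, T, N); attention retained per layer
layerMHSA <- function(D, H) {
  e <- newLayer("mhsa")
  dh <- D %/% H
  for (nm in c("Wq", "Wk", "Wv", "Wo"))
    e$params[[nm]] <- matrix(rnorm(D * D, sd = 0.02), D, D)
  for (nm in c("bq", "bk", "bv", "bo")) e$params[[nm]] <- numeric(D)
  e$decay <- c(Wq = TRUE, Wk = TRUE, Wv = TRUE, Wo = TRUE,
               bq = FALSE, bk = FALSE, bv = FALSE, bo = FALSE)
  e$H <- H; e$dh <- dh; e$D <- D
  e$fwd <- function(x, training = FALSE) {   # x: (D, T, N)
    d <- dim(x); T <- d[2]; N <- d[3]
    M <- matrix(x, nrow = e$D)
    Q <- e$params$Wq %*% M + e$params$bq
    K <- e$params$Wk %*% M + e$params$bk
    V <- e$params$Wv %*% M + e$params$bv
    Qa <- array(Q, c(dh, e$H, T, N)); Ka <- array(K, c(dh, e$H, T, N))
    Va <- array(V, c(dh, e$H, T, N))
    A <- array(0, c(T, T, e$H, N))
    Oa <- array(0, c(dh, e$H, T, N))
    sc <- 1 / sqrt(dh)
    for (n in seq_len(N)) for (h in seq_len(e$H)) {
      Qh <- matrix(Qa[, h, , n], dh, T)
      Kh <- matrix(Ka[, h, , n], dh, T)
      Vh <- matrix(Va[, h, , n], dh, T)
      Ah <- softmaxRows(crossprod(Qh, Kh) * sc)
      A[, , h, n] <- Ah
      Oa[, h, , n] <- Vh %*% t(Ah)
    }
    O <- matrix(Oa, nrow = e$D)
    e$cache <- list(M = M, Qa = Qa, Ka = Ka, Va = Va, A = A, O = O,
                    T = T, N = N)
    e$attention <- A
    array(e$params$Wo %*% O + e$params$bo, d)
  }
  e$bwd <- function(dy) {
    cc <- e$cache; T <- cc$T; N <- cc$N
    dM_out <- matrix(dy, nrow = e$D)
    e$grads$Wo <- e$grads$Wo + dM_out %*% t(cc$O)
    e$grads$bo <- e$grads$bo + rowSums(dM_out)
    dO <- crossprod(e$params$Wo, dM_out)
    dOa <- array(dO, c(dh, e$H, T, N))
    dQa <- array(0, c(dh, e$H, T, N)); dKa <- dQa; dVa <- dQa
    sc <- 1 / sqrt(dh)
    for (n in seq_len(N)) for (h in seq_len(e$H)) {
      Qh <- matrix(cc$Qa[, h, , n], dh, T)
      Kh <- matrix(cc$Ka[, h, , n], dh, T)
      Vh <- matrix(cc$Va[, h, , n], dh, T)
      Ah <- matrix(cc$A[, , h, n], T, T)
      dOh <- matrix(dOa[, h, , n], dh, T)
      dVa[, h, , n] <- dOh %*% Ah
      dA <- crossprod(dOh, Vh)
      dS <- Ah * (dA - rowSums(dA * Ah))
      dQa[, h, , n] <- sc * (Kh %*% t(dS))
      dKa[, h, , n] <- sc * (Qh %*% dS)
    }
    dQ <- matrix(dQa, nrow = e$D); dK <- matrix(dKa, nrow = e$D)
    dV <- matrix(dVa, nrow = e$D)
    e$grads$Wq <- e$grads$Wq + dQ %*% t(cc$M)
    e$grads$Wk <- e$grads$Wk + dK %*% t(cc$M)
    e$grads$Wv <- e$grads$Wv + dV %*% t(cc$M)
    e$grads$bq <- e$grads$bq + rowSums(dQ)
    e$grads$bk <- e$grads$bk + rowSums(dK)
    e$grads$bv <- e$grads$bv + rowSums(dV)
    dM <- crossprod(e$params$Wq, dQ) + crossprod(e$params$Wk, dK) +
      crossprod(e$params$Wv, dV)
    array(dM, c(e$D, T, N))
  }
  e
}

# AdamW optimizer over a list of layer environments
adamW <- function(layers, lr, weightDecay = 0.01, beta1 = 0.9,
                  beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L
  opt$m <- list(); opt$v <- list()
  for (i in seq_along(layers)) {
    opt$m[[i]] <- lapply(layers[[i]]$params, function(p) p * 0)
    opt$v[[i]] <- lapply(layers[[i]]$params, function(p) p * 0)
  }
  opt$step <- function() {
    opt$t <- opt$t + 1L
    bc1 <- 1 - beta1^opt$t
    bc2 <- 1 - beta2^opt$t
    for (i in seq_along(layers)) {
      e <- layers[[i]]
      for (nm in names(e$params)) {
        g <- e$grads[[nm]]
        opt$m[[i]][[nm]] <- beta1 * opt$m[[i]][[nm]] + (1 - beta1) * g
        opt$v[[i]][[nm]] <- beta2 * opt$v[[i]][[nm]] + (1 - beta2) * g^2
        upd <- (opt$m[[i]][[nm]] / bc1) /
          (sqrt(opt$v[[i]][[nm]] / bc2) + eps)
        wd <- if (isTRUE(e$decay[[nm]])) weightDecay else 0
        e$params[[nm]] <- e$params[[nm]] - lr * (upd + wd * e$params[[nm]])
      }
    }
  }
  opt
}

# flatten all parameter-holding environments of a model into one list
paramLayers <- function(model) model$paramEnvs
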