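# Low-level differentiable ops. Batches are arrays (H, W, C, N) for images
# and matrices (features, N) for vectors. Every forward returns list(out,
# cache); every backward takes (dout, cache) and returns gradients. These are
# internal: the public surface is in nn-model.R.

# "same"-style convolution plan: output H is ceil(H / stride); padding may be
# asymmetric (extra on the bottom/right). The plan precomputes the gather
# index turning the padded image into an im2col patch matrix.
conv_plan <- function(H, W, C, k, stride) {
  Ho <- ceiling(H / stride); Wo <- ceiling(W / stride)
  tot_h <- max((Ho - 1L) * stride + k - H, 0L)
  tot_w <- max((Wo - 1L) * stride + k - W, 0L)
  pt <- tot_h %/% 2L; pl <- tot_w %/% 2L
  Hp <- H + tot_h; Wp <- W + tot_w
  off <- as.vector(outer(0:(k - 1L), Hp * (0:(k - 1L)), `+`))
  off <- as.vector(outer(off, Hp * Wp * (0:(C - 1L)), `+`))
  base <- as.vector(outer(stride * (0:(Ho - 1L)), Hp * stride * (0:(Wo - 1L)), `+`))
  idx <- as.vector(outer(off, base, `+`)) + 1L
  list(H = H, W = W, C = C, k = k, stride = stride, Ho = Ho, Wo = Wo,
       Hp = Hp, Wp = Wp, pt = pt, pl = pl, P = Ho * Wo,
       kkC = k * k * C, idx = idx)
}

conv_forward <- function(x, Wm, b, plan) {
  d <- dim(x); N <- d[4]
  xp <- array(0, c(plan$Hp, plan$Wp, plan$C, N))
  xp[plan$pt + seq_len(plan$H), plan$pl + seq_len(plan$W), , ] <- x
  dim(xp) <- c(plan$Hp * plan$Wp * plan$C, N)
  Pm <- xp[plan$idx, , drop = FALSE]
  dim(Pm) <- c(plan$kkC, plan$P * N)
  out <- Wm %*% Pm + b
  dim(out) <- c(nrow(Wm), plan$P, N)
  out <- aperm(out, c(2, 1, 3))
  dim(out) <- c(plan$Ho, plan$Wo, nrow(Wm), N)
  list(out = out, cache = list(Pm = Pm, Wm = Wm, N = N, plan = plan))
}

conv_backward <- function(dout, cache) {
  plan <- cache$plan; N <- cache$N
  K <- dim(dout)[3]
  dm <- dout
  dim(dm) <- c(plan$P, K, N)
  dm <- aperm(dm, c(2, 1, 3))
  dim(dm) <- c(K, plan$P * N)
  dW <- dm %*% t(cache$Pm)
  db <- rowSums(dm)
  dPm <- crossprod(cache$Wm, dm)
  dim(dPm) <- c(plan$kkC * plan$P, N)
  dxp <- matrix(0, plan$Hp * plan$Wp * plan$C, N)
  rs <- rowsum(dPm, plan$idx)
  dxp[as.integer(rownames(rs)), ] <- rs
  dim(dxp) <- c(plan$Hp, plan$Wp, plan$C, N)
  dx <- dxp[plan$pt + seq_len(plan$H), plan$pl + seq_len(plan$W), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# 2x2 max pooling with stride 2; odd trailing edges padded with -Inf
# (ceil-mode). Windows never overlap, so the backward scatter is collision
# free.
pool_plan <- function(H, W) {
  Ho <- ceiling(H / 2); Wo <- ceiling(W / 2)
  Hp <- 2L * Ho; Wp <- 2L * Wo
  off <- c(0L, 1L, Hp, Hp + 1L)
  base <- as.vector(outer(2L * (0:(Ho - 1L)), Hp * 2L * (0:(Wo - 1L)), `+`))
  idx4 <- outer(off, base, `+`) + 1L   # 4 x P
  list(H = H, W = W, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp, P = Ho * Wo,
       idx4 = idx4)
}

pool_forward <- function(x, plan) {
  d <- dim(x); C <- d[3]; N <- d[4]; M <- C * N
  xp <- array(-Inf, c(plan$Hp, plan$Wp, M))
  xp[seq_len(plan$H), seq_len(plan$W), ] <- x
  dim(xp) <- c(plan$Hp * plan$Wp, M)
  G <- xp[as.vector(plan$idx4), , drop = FALSE]   # (4*P) x M
  dim(G) <- c(4L, plan$P, M)
  Gm <- matrix(aperm(G, c(2, 3, 1)), plan$P * M, 4L)
  sel <- max.col(Gm, ties.method = "first")
  mx <- Gm[cbind(seq_len(plan$P * M), sel)]
  out <- array(mx, c(plan$Ho, plan$Wo, C, N))
  list(out = out, cache = list(sel = sel, plan = plan, C = C, N = N))
}

pool_backward <- function(dout, cache) {
  plan <- cache$plan; M <- cache$C * cache$N
  p <- rep(seq_len(plan$P), times = M)
  mm <- rep(seq_len(M), each = plan$P)
  spat <- plan$idx4[cbind(cache$sel, p)]
  gidx <- spat + (plan$Hp * plan$Wp) * (mm - 1)
  dxp <- numeric(plan$Hp * plan$Wp * M)
  dxp[gidx] <- as.vector(dout)
  dim(dxp) <- c(plan$Hp, plan$Wp, M)
  dx <- dxp[seq_len(plan$H), seq_len(plan$W), , drop = FALSE]
  dim(dx) <- c(plan$H, plan$W, cache$C, cache$N)
  dx
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}
relu_backward <- function(dout, mask) dout * mask

dense_forward <- function(x, W, b) {
  list(out = W %*% x + b, cache = list(x = x, W = W))
}
dense_backward <- function(dout, cache) {
  list(dx = crossprod(cache$W, dout),
       dW = tcrossprod(dout, cache$x),
       db = rowSums(dout))
}

# nearest-neighbour 2x upsampling followed by a crop to (Ht, Wt); used by
# the decoder's resize-convolution blocks
upsample_forward <- function(x, Ht, Wt) {
  d <- dim(x)
  up <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
          drop = FALSE]
  list(out = up[seq_len(Ht), seq_len(Wt), , , drop = FALSE],
       cache = list(din = d, Ht = Ht, Wt = Wt))
}

upsample_backward <- function(dout, cache) {
  d <- cache$din
  dup <- array(0, c(2L * d[1], 2L * d[2], d[3], d[4]))
  dup[seq_len(cache$Ht), seq_len(cache$Wt), , ] <- dout
  odd_r <- seq(1L, 2L * d[1], by = 2L); odd_c <- seq(1L, 2L * d[2], by = 2L)
  (dup[odd_r, odd_c, , , drop = FALSE] + dup[odd_r + 1L, odd_c, , , drop = FALSE] +
     dup[odd_r, odd_c + 1L, , , drop = FALSE] +
     dup[odd_r + 1L, odd_c + 1L, , , drop = FALSE])
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
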