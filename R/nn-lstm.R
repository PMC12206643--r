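# LSTM / BiLSTM internals. The recursion follows the standard gate form:
#   f_t = sigma(Wf [h_{t-1}, x_t] + bf)      (forget)
#   i_t = sigma(Wi [h_{t-1}, x_t] + bi)      (input)
#   g_t = tanh(Wc [h_{t-1}, x_t] + bc)       (candidate cell)
#   c_t = f_t * c_{t-1} + i_t * g_t
#   o_t = sigma(Wo [h_{t-1}, x_t] + bo)      (output)
#   h_t = o_t * tanh(c_t)
# Gates are stacked rows [i; f; g; o] in one 4H x D input map `Wx`, one
# 4H x H recurrent map `Wh` and bias `b`. The encoder emits the final
# hidden state of each direction.

lstm_forward <- function(xs, p, H) {
  T <- length(xs); N <- ncol(xs[[1]])
  h <- matrix(0, H, N); cc <- matrix(0, H, N)
  caches <- vector("list", T)
  ri <- seq_len(H); rf <- H + ri; rg <- 2L * H + ri; ro <- 3L * H + ri
  for (t in seq_len(T)) {
    z <- p$Wx %*% xs[[t]] + p$Wh %*% h + p$b
    i <- sigmoid(z[ri, , drop = FALSE])
    f <- sigmoid(z[rf, , drop = FALSE])
    g <- tanh(z[rg, , drop = FALSE])
    o <- sigmoid(z[ro, , drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    caches[[t]] <- list(i = i, f = f, g = g, o = o, cprev = cc, hprev = h,
                        x = xs[[t]], tc = tc)
    cc <- c_new
    h <- o * tc
  }
  list(h = h, caches = caches)
}

lstm_backward <- function(dh_last, caches, p, H) {
  T <- length(caches); N <- ncol(dh_last)
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  db <- numeric(length(p$b))
  dxs <- vector("list", T)
  dh <- dh_last
  dc <- matrix(0, H, N)
  for (t in rev(seq_len(T))) {
    ch <- caches[[t]]
    do_ <- dh * ch$tc
    dc <- dc + dh * ch$o * (1 - ch$tc^2)
    di <- dc * ch$g
    dg <- dc * ch$i
    df <- dc * ch$cprev
    dc_prev <- dc * ch$f
    dz <- rbind(di * ch$i * (1 - ch$i),
                df * ch$f * (1 - ch$f),
                dg * (1 - ch$g^2),
                do_ * ch$o * (1 - ch$o))
    dWx <- dWx + tcrossprod(dz, ch$x)
    dWh <- dWh + tcrossprod(dz, ch$hprev)
    db <- db + rowSums(dz)
    dxs[[t]] <- crossprod(p$Wx, dz)
    dh <- crossprod(p$Wh, dz)
    dc <- dc_prev
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

# Bidirectional encoding of a sequence of feature vectors. `merge_mode` is
# one of "concat" (dim 2H), "sum" or "average" (dim H).
bilstm_forward <- function(xs, params, H, merge_mode) {
  fw <- lstm_forward(xs, params$fwd, H)
  bw <- lstm_forward(rev(xs), params$bwd, H)
  out <- switch(merge_mode,
                concat = rbind(fw$h, bw$h),
                sum = fw$h + bw$h,
                average = (fw$h + bw$h) / 2,
                stop_invalid("unknown merge_mode `%s`", merge_mode))
  list(out = out, cache = list(fw = fw$caches, bw = bw$caches,
                               merge_mode = merge_mode, H = H))
}

bilstm_backward <- function(dout, cache, params) {
  H <- cache$H
  d <- switch(cache$merge_mode,
              concat = list(f = dout[seq_len(H), , drop = FALSE],
                            b = dout[H + seq_len(H), , drop = FALSE]),
              sum = list(f = dout, b = dout),
              average = list(f = dout / 2, b = dout / 2))
  gf <- lstm_backward(d$f, cache$fw, params$fwd, H)
  gb <- lstm_backward(d$b, cache$bw, params$bwd, H)
  dxs_b <- rev(gb$dxs)
  dxs <- Map(`+`, gf$dxs, dxs_b)
  list(dxs = dxs,
       grads = list(fwd = list(Wx = gf$dWx, Wh = gf$dWh, b = gf$db),
                    bwd = list(Wx = gb$dWx, Wh = gb$dWh, b = gb$db)))
}
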