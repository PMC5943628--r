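# Scalar reference implementations, coded independently of the batched
# trainer, used as oracles for the network building blocks.
oracle_lstm_step <- function(p, x, h, c) {
  k <- length(p$b1)
  sg <- function(z) 1 / (1 + exp(-z))
  i <- g <- f <- o <- c_t <- h_t <- numeric(k)
  for (r in seq_len(k)) {
    zi <- p$b1[r]; zg <- p$b2[r]; zf <- p$b3[r]; zo <- p$b4[r]
    for (cix in seq_len(k)) {
      zi <- zi + p$W1[r, cix] * x[cix] + p$W2[r, cix] * h[cix]
      zg <- zg + p$W3[r, cix] * x[cix] + p$W4[r, cix] * h[cix]
      zf <- zf + p$W5[r, cix] * x[cix] + p$W6[r, cix] * h[cix]
      zo <- zo + p$W7[r, cix] * x[cix] + p$W8[r, cix] * h[cix]
    }
    i[r] <- sg(zi); g[r] <- tanh(zg); f[r] <- sg(zf); o[r] <- sg(zo)
    c_t[r] <- f[r] * c[r] + i[r] * g[r]
    h_t[r] <- o[r] * tanh(c_t[r])
  }
  list(h = h_t, c = c_t, i = i, f = f, o = o)
}

oracle_attend <- function(p, S, h_last) {
  m <- length(p$w); L <- ncol(S)
  sc <- numeric(L)
  for (t in seq_len(L)) {
    Mt <- numeric(m)
    for (r in seq_len(m)) {
      v <- 0
      for (cix in seq_len(m)) {
        v <- v + p$W1[r, cix] * S[cix, t] + p$W2[r, cix] * h_last[cix]
      }
      Mt[r] <- tanh(v)
    }
    sc[t] <- sum(p$w * Mt)
  }
  a <- exp(sc) / sum(exp(sc))
  z <- as.numeric(S %*% a)
  hp <- numeric(m)
  for (r in seq_len(m)) {
    v <- 0
    for (cix in seq_len(m)) {
      v <- v + p$W3[r, cix] * z[cix] + p$W4[r, cix] * h_last[cix]
    }
    hp[r] <- tanh(v)
  }
  list(a = a, z = z, h_prime = hp)
}

oracle_compose <- function(p, hl, hr, feats = NULL) {
  v <- c(hl, hr, feats)
  r <- numeric(nrow(p$W))
  for (i in seq_len(nrow(p$W))) r[i] <- tanh(sum(p$W[i, ] * v) + p$b[i])
  logits <- numeric(length(p$bs))
  for (i in seq_along(logits)) logits[i] <- sum(p$Ws[i, ] * r) + p$bs[i]
  exp(logits) / sum(exp(logits))
}

rand_lstm_params <- function(k) {
  ps <- lapply(1:8, function(i) matrix(rnorm(k * k, sd = 0.5), k, k))
  names(ps) <- paste0("W", 1:8)
  c(ps, list(b1 = rnorm(k), b2 = rnorm(k), b3 = rnorm(k), b4 = rnorm(k)))
}

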