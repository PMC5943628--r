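# Batched forward/backward passes, ADAM optimization and the training loop
# of the neural relation extractors. Parameters use a packed LSTM layout
# (gate order: input, candidate, forget, output); lstm_block_to_eq() exposes
# the equation-level view, and the test suite checks that both agree.

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward one LSTM direction over a list of k x B inputs.
lstm_forward_seq <- function(block, X) {
  L <- length(X)
  k <- length(block$b) / 4
  B <- ncol(X[[1]])
  h <- matrix(0, k, B)
  c <- matrix(0, k, B)
  H <- vector("list", L)
  cache <- vector("list", L)
  idx_i <- 1:k; idx_g <- (k + 1):(2 * k)
  idx_f <- (2 * k + 1):(3 * k); idx_o <- (3 * k + 1):(4 * k)
  for (t in seq_len(L)) {
    pre <- block$Wx %*% X[[t]] + block$Wh %*% h + block$b
    i <- sigmoid(pre[idx_i, , drop = FALSE])
    g <- tanh(pre[idx_g, , drop = FALSE])
    f <- sigmoid(pre[idx_f, , drop = FALSE])
    o <- sigmoid(pre[idx_o, , drop = FALSE])
    c_new <- f * c + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(x = X[[t]], h_prev = h, c_prev = c, i = i, g = g,
                       f = f, o = o, c = c_new, tc = tc)
    h <- h_new
    c <- c_new
    H[[t]] <- h_new
  }
  list(H = H, cache = cache)
}

# Backward through one LSTM direction. dH: list of k x B gradients on the
# outputs (downstream use only; recurrent gradients are handled internally).
lstm_backward_seq <- function(block, cache, dH) {
  L <- length(cache)
  k <- length(block$b) / 4
  B <- ncol(dH[[1]])
  gWx <- matrix(0, 4 * k, k)
  gWh <- matrix(0, 4 * k, k)
  gb <- numeric(4 * k)
  dX <- vector("list", L)
  dh_rec <- matrix(0, k, B)
  dc_rec <- matrix(0, k, B)
  idx_i <- 1:k; idx_g <- (k + 1):(2 * k)
  idx_f <- (2 * k + 1):(3 * k); idx_o <- (3 * k + 1):(4 * k)
  for (t in rev(seq_len(L))) {
    cc <- cache[[t]]
    dh <- dH[[t]] + dh_rec
    do <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_rec
    df <- dc * cc$c_prev
    di <- dc * cc$g
    dg <- dc * cc$i
    dpre <- rbind(di * cc$i * (1 - cc$i),
                  dg * (1 - cc$g^2),
                  df * cc$f * (1 - cc$f),
                  do * cc$o * (1 - cc$o))
    gWx <- gWx + dpre %*% t(cc$x)
    gWh <- gWh + dpre %*% t(cc$h_prev)
    gb <- gb + rowSums(dpre)
    dX[[t]] <- crossprod(block$Wx, dpre)
    dh_rec <- crossprod(block$Wh, dpre)
    dc_rec <- dc * cc$f
  }
  list(dX = dX, grads = list(Wx = gWx, Wh = gWh, b = gb))
}

# Forward one entity encoder (projection + LSTM(s) + dropout + attention).
encoder_forward <- function(params, cfg, enc, att, ids, train) {
  L <- nrow(ids)
  B <- ncol(ids)
  k <- cfg$hidden
  E <- vector("list", L)   # embedding columns
  X <- vector("list", L)   # projected (and dropped-out) LSTM inputs
  mask_in <- vector("list", L)
  for (t in seq_len(L)) {
    Et <- t(params$emb[ids[t, ], , drop = FALSE])
    xt <- params$W_in %*% Et + params$b_in
    if (train && cfg$dropout_in > 0) {
      mask_in[[t]] <- matrix(stats::rbinom(k * B, 1, 1 - cfg$dropout_in), k, B) /
        (1 - cfg$dropout_in)
      xt <- xt * mask_in[[t]]
    }
    E[[t]] <- Et
    X[[t]] <- xt
  }
  fwd <- lstm_forward_seq(enc$fwd, X)
  if (cfg$bidirectional) {
    bwd <- lstm_forward_seq(enc$bwd, rev(X))
    U <- lapply(seq_len(L), function(t) rbind(fwd$H[[t]], bwd$H[[L - t + 1]]))
  } else {
    bwd <- NULL
    U <- fwd$H
  }
  att_cache <- NULL
  if (cfg$attention) {
    hL <- U[[L]]
    WS <- lapply(U, function(u) att$W1 %*% u)
    q <- att$W2 %*% hL
    M <- lapply(seq_len(L), function(t) tanh(WS[[t]] + q))
    Sc <- do.call(rbind, lapply(M, function(mt) as.numeric(crossprod(att$w, mt))))
    Sc <- matrix(Sc, nrow = L)
    Scs <- sweep(Sc, 2, apply(Sc, 2, max))
    A <- exp(Scs)
    A <- sweep(A, 2, colSums(A), `/`)
    z <- Reduce(`+`, lapply(seq_len(L), function(t) {
      U[[t]] * rep(A[t, ], each = nrow(U[[t]]))
    }))
    hpre <- att$W3 %*% z + att$W4 %*% hL
    hprime <- tanh(hpre)
    att_cache <- list(M = M, A = A, z = z, hL = hL, hprime = hprime)
    out <- hprime
  } else {
    out <- U[[L]]
  }
  # output dropout on the representation handed to the classifier
  mask_out <- NULL
  if (train && cfg$dropout_out > 0) {
    mo <- nrow(out)
    mask_out <- matrix(stats::rbinom(mo * B, 1, 1 - cfg$dropout_out), mo, B) /
      (1 - cfg$dropout_out)
    out <- out * mask_out
  }
  list(out = out, U = U, E = E, ids = ids, mask_in = mask_in,
       mask_out = mask_out, fwd = fwd, bwd = bwd, att = att_cache)
}

# Backward one entity encoder. dout: gradient on the encoder output.
# Returns parameter gradients plus embedding-row accumulations.
encoder_backward <- function(params, cfg, enc, att, fc, dout) {
  L <- length(fc$U)
  B <- ncol(dout)
  k <- cfg$hidden
  m <- nrow(fc$U[[1]])
  dU <- lapply(seq_len(L), function(t) matrix(0, m, B))
  grads <- list()
  if (!is.null(fc$mask_out)) dout <- dout * fc$mask_out
  if (cfg$attention) {
    ac <- fc$att
    dpre <- dout * (1 - ac$hprime^2)
    gW3 <- dpre %*% t(ac$z)
    gW4 <- dpre %*% t(ac$hL)
    dz <- crossprod(att$W3, dpre)
    dhL <- crossprod(att$W4, dpre)
    dA <- matrix(0, L, B)
    for (t in seq_len(L)) {
      dA[t, ] <- colSums(dz * fc$U[[t]])
      dU[[t]] <- dU[[t]] + dz * rep(ac$A[t, ], each = m)
    }
    dSc <- ac$A * sweep(dA, 2, colSums(ac$A * dA))
    gW1 <- matrix(0, m, m)
    gW2 <- matrix(0, m, m)
    gw <- numeric(m)
    for (t in seq_len(L)) {
      dM <- outer(att$w, dSc[t, ]) # m x B
      gw <- gw + as.numeric(ac$M[[t]] %*% dSc[t, ])
      dP <- dM * (1 - ac$M[[t]]^2)
      gW1 <- gW1 + dP %*% t(fc$U[[t]])
      dU[[t]] <- dU[[t]] + crossprod(att$W1, dP)
      gW2 <- gW2 + dP %*% t(ac$hL)
      dhL <- dhL + crossprod(att$W2, dP)
    }
    dU[[L]] <- dU[[L]] + dhL
    grads$att <- list(W1 = gW1, W2 = gW2, W3 = gW3, W4 = gW4, w = gw)
  } else {
    dU[[L]] <- dU[[L]] + dout
  }
  if (cfg$bidirectional) {
    dHf <- lapply(dU, function(d) d[1:k, , drop = FALSE])
    dHb <- lapply(seq_len(L), function(t) {
      dU[[L - t + 1]][(k + 1):(2 * k), , drop = FALSE]
    })
    bf <- lstm_backward_seq(enc$fwd, fc$fwd$cache, dHf)
    bb <- lstm_backward_seq(enc$bwd, fc$bwd$cache, dHb)
    dX <- lapply(seq_len(L), function(t) bf$dX[[t]] + bb$dX[[L - t + 1]])
    grads$fwd <- bf$grads
    grads$bwd <- bb$grads
  } else {
    bf <- lstm_backward_seq(enc$fwd, fc$fwd$cache, dU)
    dX <- bf$dX
    grads$fwd <- bf$grads
  }
  gW_in <- matrix(0, k, cfg$emb_dim)
  gb_in <- numeric(k)
  demb <- matrix(0, nrow(params$emb), cfg$emb_dim)
  for (t in seq_len(L)) {
    dx <- dX[[t]]
    if (!is.null(fc$mask_in[[t]])) dx <- dx * fc$mask_in[[t]]
    gW_in <- gW_in + dx %*% t(fc$E[[t]])
    gb_in <- gb_in + rowSums(dx)
    dE <- crossprod(params$W_in, dx) # emb_dim x B
    rs <- rowsum(t(dE), fc$ids[t, ])
    demb[as.integer(rownames(rs)), ] <- demb[as.integer(rownames(rs)), ] + rs
  }
  list(grads = grads, gW_in = gW_in, gb_in = gb_in, demb = demb)
}

# Full forward pass over a batch. Returns probabilities, loss and caches.
neural_forward <- function(params, cfg, batch, train = FALSE) {
  fc_l <- encoder_forward(params, cfg, params$enc_l, params$att_l,
                          batch$ids_l, train)
  fc_r <- encoder_forward(params, cfg, params$enc_r, params$att_r,
                          batch$ids_r, train)
  feats <- NULL
  if (cfg$augmented) {
    feats <- rbind(t(params$feat$dist[batch$dist_b, , drop = FALSE]),
                   t(params$feat$ment[batch$ment_b, , drop = FALSE]),
                   t(params$feat$type[batch$ltype, , drop = FALSE]),
                   t(params$feat$type[batch$rtype, , drop = FALSE]))
  }
  v <- rbind(fc_l$out, fc_r$out, feats)
  q <- params$mlp$W %*% v + params$mlp$b
  r <- tanh(q)
  logits <- params$mlp$Ws %*% r + params$mlp$bs
  ls <- sweep(logits, 2, apply(logits, 2, max))
  P <- exp(ls)
  P <- sweep(P, 2, colSums(P), `/`)
  loss <- NA_real_
  if (!is.null(batch$y)) {
    B <- ncol(P)
    py <- P[cbind(batch$y, seq_len(B))]
    loss <- -mean(log(pmax(py, 1e-12)))
  }
  list(P = P, loss = loss, v = v, r = r, fc_l = fc_l, fc_r = fc_r)
}

# l2 regularization of the weight matrices (projections, recurrences,
# attention and MLP; biases, embeddings and feature lookup tables are
# excluded), applied as decoupled weight decay: each update shrinks a weight
# by lr * 2 * l2 * w, the gradient of the l2 penalty scaled by the learning
# rate but kept outside the adaptive-moment normalization, which would
# otherwise let the penalty dominate the small data gradients.
apply_weight_decay <- function(params, cfg, lr) {
  decay <- function(w) w * (1 - 2 * cfg$l2 * lr)
  params$W_in <- decay(params$W_in)
  params$mlp$W <- decay(params$mlp$W)
  params$mlp$Ws <- decay(params$mlp$Ws)
  for (e in c("enc_l", "enc_r")) {
    for (d in names(params[[e]])) {
      params[[e]][[d]]$Wx <- decay(params[[e]][[d]]$Wx)
      params[[e]][[d]]$Wh <- decay(params[[e]][[d]]$Wh)
    }
  }
  if (cfg$attention) {
    for (a in c("att_l", "att_r")) {
      for (nm in c("W1", "W2", "W3", "W4", "w")) {
        params[[a]][[nm]] <- decay(params[[a]][[nm]])
      }
    }
  }
  params
}

# Full backward pass; returns gradients with the same structure as params.
neural_backward <- function(params, cfg, batch, fw) {
  B <- ncol(fw$P)
  k <- cfg$hidden
  m <- k * (1 + cfg$bidirectional)
  dl <- fw$P
  dl[cbind(batch$y, seq_len(B))] <- dl[cbind(batch$y, seq_len(B))] - 1
  dl <- dl / B
  gWs <- dl %*% t(fw$r)
  gbs <- rowSums(dl)
  dr <- crossprod(params$mlp$Ws, dl)
  dq <- dr * (1 - fw$r^2)
  gW_mlp <- dq %*% t(fw$v)
  gb_mlp <- rowSums(dq)
  dv <- crossprod(params$mlp$W, dq)
  d_l <- dv[1:m, , drop = FALSE]
  d_r <- dv[(m + 1):(2 * m), , drop = FALSE]
  grads <- list(
    emb = matrix(0, nrow(params$emb), cfg$emb_dim),
    W_in = matrix(0, k, cfg$emb_dim),
    b_in = numeric(k),
    mlp = list(W = gW_mlp, b = gb_mlp, Ws = gWs, bs = gbs)
  )
  if (cfg$augmented) {
    f <- cfg$feat_dim
    dfeat <- dv[(2 * m + 1):nrow(dv), , drop = FALSE]
    gdist <- rowsum(t(dfeat[1:f, , drop = FALSE]), batch$dist_b)
    gment <- rowsum(t(dfeat[(f + 1):(2 * f), , drop = FALSE]), batch$ment_b)
    gtyL <- rowsum(t(dfeat[(2 * f + 1):(3 * f), , drop = FALSE]), batch$ltype)
    gtyR <- rowsum(t(dfeat[(3 * f + 1):(4 * f), , drop = FALSE]), batch$rtype)
    gd <- matrix(0, 9, f); gm <- matrix(0, 9, f)
    gt <- matrix(0, length(ENTITY_TYPES), f)
    gd[as.integer(rownames(gdist)), ] <- gdist
    gm[as.integer(rownames(gment)), ] <- gment
    gt[as.integer(rownames(gtyL)), ] <- gt[as.integer(rownames(gtyL)), ] + gtyL
    gt[as.integer(rownames(gtyR)), ] <- gt[as.integer(rownames(gtyR)), ] + gtyR
    grads$feat <- list(dist = gd, ment = gm, type = gt)
  }
  bl <- encoder_backward(params, cfg, params$enc_l, params$att_l, fw$fc_l, d_l)
  br <- encoder_backward(params, cfg, params$enc_r, params$att_r, fw$fc_r, d_r)
  grads$enc_l <- bl$grads[intersect(c("fwd", "bwd"), names(bl$grads))]
  grads$enc_r <- br$grads[intersect(c("fwd", "bwd"), names(br$grads))]
  if (cfg$attention) {
    grads$att_l <- bl$grads$att
    grads$att_r <- br$grads$att
  }
  grads$W_in <- bl$gW_in + br$gW_in
  grads$b_in <- bl$gb_in + br$gb_in
  grads$emb <- bl$demb + br$demb
  grads$emb[1, ] <- 0 # <pad> stays fixed
  # align gradient structure with the parameter structure
  grads[names(unclass(params))]
}

# Recursive ADAM update over matching parameter/gradient structures.
adam_init <- function(params) {
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else list(m = x * 0, v = x * 0)
  }
  lapply(unclass(params), walk)
}

adam_update <- function(params, grads, state, lr, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        skip = character(0)) {
  upd <- function(p, g, s, path) {
    if (is.list(p) && !identical(names(p), c("m", "v"))) {
      for (nm in names(p)) {
        if (nm %in% skip && path == "") next
        r <- upd(p[[nm]], g[[nm]], s[[nm]], paste0(path, nm))
        p[[nm]] <- r$p
        s[[nm]] <- r$s
      }
      return(list(p = p, s = s))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^step)
    vhat <- s$v / (1 - beta2^step)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  cl <- class(params)
  r <- upd(unclass(params), grads, state, "")
  class(r$p) <- cl
  r
}

#' Train a neural relation extractor
#'
#' Minimizes cross-entropy plus the l2 penalty with ADAM over minibatches.
#' Input and output dropout are applied during training only. After every
#' epoch the model is evaluated on the development set; the returned model is
#' the epoch with the highest development macro-F1. Training aborts with a
#' diagnostic if the loss diverges to NaN.
#'
#' @param config A [neural_config()].
#' @param train_dataset,dev_dataset Labeled `relex_dataset`s.
#' @param docs Named document list covering both datasets.
#' @param train_docs Documents used to build the vocabulary (defaults to the
#'   documents referenced by the training dataset).
#' @param embeddings Optional pretrained `relex_embeddings`; when supplied,
#'   embeddings are frozen unless `config$train_embeddings` is `TRUE`.
#' @return An object of class `relex_neural` with the best-epoch parameters,
#'   the config, vocabulary, class set and the per-epoch trace (train loss,
#'   dev macro-F1).
#' @export
train_neural <- function(config, train_dataset, dev_dataset, docs,
                         train_docs = NULL, embeddings = NULL) {
  if (nrow(train_dataset) == 0 || nrow(dev_dataset) == 0) {
    stop_relex("empty training or development set", "relex_fit_error")
  }
  if (is.null(train_docs)) {
    train_docs <- docs[unique(train_dataset$doc_id)]
  }
  vocab <- build_vocab(train_docs)
  classes <- sort(unique(train_dataset$label))
  enc_train <- encode_examples(train_dataset, docs, vocab, config$window)
  enc_dev <- encode_examples(dev_dataset, docs, vocab, config$window)
  y_train <- match(train_dataset$label, classes)
  train_emb <- config$train_embeddings %||% is.null(embeddings)

  with_seed(config$seed, {
    params <- init_neural_params(config, length(vocab), length(classes),
                                 pretrained = embeddings, vocab = vocab)
    rownames(params$mlp$W) <- classes
    # start the softmax bias at the log class priors so the imbalanced None
    # class is modeled by the bias from step one and gradient energy goes to
    # discrimination rather than to entrenching the majority class
    prior <- table(factor(train_dataset$label, levels = classes)) /
      nrow(train_dataset)
    params$mlp$bs <- as.numeric(log(pmax(prior, 1e-6)))
    state <- adam_init(params)
    skip <- if (train_emb) character(0) else "emb"
    n <- nrow(train_dataset)
    trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        dev_macro_f1 = numeric(0))
    best <- list(f1 = -Inf, params = params, epoch = 0L)
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        batch <- slice_batch(enc_train, idx, y_train)
        fw <- neural_forward(params, config, batch, train = TRUE)
        if (!is.finite(fw$loss)) {
          stop_relex(sprintf("training diverged (non-finite loss) at epoch %d",
                             epoch), "relex_divergence_error")
        }
        gr <- neural_backward(params, config, batch, fw)
        step <- step + 1L
        r <- adam_update(params, gr, state, config$lr, step, skip = skip)
        params <- r$p
        state <- r$s
        if (config$l2 > 0) params <- apply_weight_decay(params, config, config$lr)
        params$emb[1, ] <- 0
        losses <- c(losses, fw$loss)
      }
      pred_dev <- predict_encoded(params, config, enc_dev, classes)
      dev_f1 <- score(dev_dataset$label, pred_dev)$macro_f1
      trace <- rbind(trace, data.frame(epoch = epoch,
                                       train_loss = mean(losses),
                                       dev_macro_f1 = dev_f1))
      if (dev_f1 > best$f1) {
        best <- list(f1 = dev_f1, params = params, epoch = epoch)
      }
    }
    structure(
      list(params = best$params, config = config, vocab = vocab,
           classes = classes, best_epoch = best$epoch, trace = trace),
      class = "relex_neural"
    )
  })
}

slice_batch <- function(enc, idx, y = NULL) {
  list(ids_l = enc$ids_l[, idx, drop = FALSE],
       ids_r = enc$ids_r[, idx, drop = FALSE],
       dist_b = enc$dist_b[idx], ment_b = enc$ment_b[idx],
       ltype = enc$ltype[idx], rtype = enc$rtype[idx], y = y[idx])
}

predict_encoded <- function(params, config, enc, classes, chunk = 256) {
  n <- ncol(enc$ids_l)
  out <- character(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    batch <- slice_batch(enc, idx)
    fw <- neural_forward(params, config, batch, train = FALSE)
    out[idx] <- classes[apply(fw$P, 2, which.max)]
  }
  out
}

#' Predict relation labels with a trained neural model
#'
#' Dropout is disabled at inference, so repeated prediction is
#' deterministic; the label with the highest class probability is returned.
#'
#' @param model A `relex_neural`.
#' @param dataset A `relex_dataset` of examples to classify.
#' @param docs Named document list covering the dataset.
#' @return Character vector of predicted labels.
#' @export
predict_neural <- function(model, dataset, docs) {
  enc <- encode_examples(dataset, docs, model$vocab, model$config$window)
  predict_encoded(model$params, model$config, enc, model$classes)
}

#' Relative agreement between analytic and numerical gradients
#'
#' Flattens the model parameters, perturbs a random subset of coordinates,
#' and compares central finite differences of the batch loss with the
#' analytic backpropagation gradient. Used to validate the hand-derived
#' backward pass.
#'
#' @param config A `relex_neural_config` (dropout is disabled for the
#'   check, which requires a deterministic loss).
#' @param batch An encoded batch with labels `y`.
#' @param params Model parameters.
#' @param n_coords Number of randomly chosen coordinates to check.
#' @param h Finite-difference step.
#' @param seed Seed for coordinate selection.
#' @return Maximum relative error over the checked coordinates.
#' @export
gradient_check <- function(config, batch, params, n_coords = 60, h = 1e-4,
                           seed = 1) {
  cfg <- config
  cfg$dropout_in <- 0
  cfg$dropout_out <- 0
  flat <- unlist(unclass(params))
  fw <- neural_forward(params, cfg, batch, train = TRUE)
  gr <- neural_backward(params, cfg, batch, fw)
  gflat <- unlist(gr)
  stopifnot(length(gflat) == length(flat))
  template <- unclass(params)
  loss_at <- function(v) {
    p <- utils::relist(v, template)
    class(p) <- "relex_neural_params"
    neural_forward(p, cfg, batch, train = TRUE)$loss
  }
  # restrict to coordinates with non-negligible gradient: central
  # differences on a double-precision loss cannot resolve smaller ones
  active <- which(abs(gflat) > 1e-5)
  coords <- with_seed(seed, sample(active, min(n_coords, length(active))))
  max_rel <- 0
  for (ci in coords) {
    vp <- flat; vp[ci] <- vp[ci] + h
    vm <- flat; vm[ci] <- vm[ci] - h
    num <- (loss_at(vp) - loss_at(vm)) / (2 * h)
    rel <- abs(num - gflat[ci]) / max(abs(num), abs(gflat[ci]), 1e-8)
    max_rel <- max(max_rel, rel)
  }
  max_rel
}
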