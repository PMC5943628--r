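#' One LSTM cell update
#'
#' Computes the gated recurrent update for a single time step:
#' input gate `i = sigmoid(W1 x + W2 h + b1)`, candidate
#' `i' = tanh(W3 x + W4 h + b2)`, forget gate `f = sigmoid(W5 x + W6 h +
#' b3)`, output gate `o = sigmoid(W7 x + W8 h + b4)`, cell state
#' `c_t = f * c + i * i'` and output `h_t = o * tanh(c_t)` (all products
#' element-wise). Gate activations lie strictly in (0, 1).
#'
#' @param params List with matrices `W1`..`W8` (`k x k`) and biases
#'   `b1`..`b4` (length `k`); see [lstm_block_to_eq()].
#' @param x Input vector (length `k`).
#' @param h_prev,c_prev Previous output and cell state (length `k`).
#' @return List with `h`, `c`, and the gate activations `i`, `g`, `f`, `o`.
#' @export
lstm_step <- function(params, x, h_prev, c_prev) {
  k <- length(params$b1)
  if (length(x) != ncol(params$W1) || length(h_prev) != k || length(c_prev) != k) {
    stop_relex("lstm_step: input shapes do not match the hidden size",
               "relex_shape_error")
  }
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(as.numeric(params$W1 %*% x + params$W2 %*% h_prev) + params$b1)
  g <- tanh(as.numeric(params$W3 %*% x + params$W4 %*% h_prev) + params$b2)
  f <- sig(as.numeric(params$W5 %*% x + params$W6 %*% h_prev) + params$b3)
  o <- sig(as.numeric(params$W7 %*% x + params$W8 %*% h_prev) + params$b4)
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, i = i, g = g, f = f, o = o)
}

#' Global attention over encoder outputs
#'
#' Given the window outputs `S` (one column per position) and the final
#' output `h_last`, computes `M = tanh(W1 S + (W2 h_last) 1^T)`, attention
#' weights `a = softmax(w^T M)`, the attention representation `z = S a^T`,
#' and the final entity representation `h' = tanh(W3 z + W4 h_last)`. The
#' attention weights are positive and sum to one.
#'
#' @param params List with `W1`..`W4` (`m x m`) and vector `w` (length `m`).
#' @param S Matrix of output vectors (`m x L`).
#' @param h_last Final output vector (length `m`).
#' @return List with `a` (length `L`), `z` and `h_prime` (length `m`).
#' @export
attend <- function(params, S, h_last) {
  m <- length(params$w)
  if (nrow(S) != m || length(h_last) != m) {
    stop_relex("attend: shapes do not match", "relex_shape_error")
  }
  M <- tanh(params$W1 %*% S + as.numeric(params$W2 %*% h_last))
  sc <- as.numeric(crossprod(params$w, M))
  a <- exp(sc - max(sc))
  a <- a / sum(a)
  z <- as.numeric(S %*% a)
  h_prime <- tanh(as.numeric(params$W3 %*% z + params$W4 %*% h_last))
  list(a = a, z = z, h_prime = h_prime)
}

#' Compose two entity representations and classify
#'
#' The relation representation is a perceptron over the concatenated entity
#' representations (and, in the augmented variant, the embedded distance and
#' mention-type features): `r = tanh(W [h_l; h_r; feats] + b)` with `W` of
#' shape `|Y| x D`, followed by the softmax layer
#' `p = softmax(Ws r + bs)` that normalizes the probability distribution
#' over relation types.
#'
#' @param params List with `W` (`|Y| x D`), `b` (length `|Y|`), and the
#'   softmax-layer weights `Ws` (`|Y| x |Y|`) and `bs`.
#' @param h_l,h_r Entity representations.
#' @param feats Optional additional feature vector appended to the
#'   concatenation.
#' @return Named numeric vector of class probabilities (sums to 1).
#' @export
compose_and_classify <- function(params, h_l, h_r, feats = NULL) {
  v <- c(h_l, h_r, feats)
  if (length(v) != ncol(params$W)) {
    stop_relex("compose_and_classify: input width does not match W",
               "relex_shape_error")
  }
  r <- tanh(as.numeric(params$W %*% v) + params$b)
  logits <- as.numeric(params$Ws %*% r) + params$bs
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  if (!is.null(rownames(params$W))) names(p) <- rownames(params$W)
  p
}
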