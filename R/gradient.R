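# Backpropagation through time for the time-aware LSTM + classifier head.
# Gradients are exact for the batched mean (optionally class-weighted)
# cross-entropy; validated against central finite differences in the tests.

zero_grads <- function(par) lapply(par, function(a) array(0, dim = dim(a) %||% length(a)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Returns list(ce = mean cross-entropy, grad = tlstm_params-shaped gradients).
ce_loss_and_grad <- function(par, records, class_weights = NULL,
                             adjust = "add") {
  bt <- batch_tensors(records)
  fw <- tlstm_forward_batch(bt, par, adjust, keep_cache = TRUE)
  K <- ncol(fw$probs)
  y1 <- bt$y + 1L
  if (any(y1 < 1L | y1 > K)) stop("label outside {0..K-1}")
  w <- if (is.null(class_weights)) rep(1, bt$B) else class_weights[y1]
  wsum <- sum(w)
  p_true <- pmax(fw$probs[cbind(seq_len(bt$B), y1)], 1e-12)
  ce <- sum(w * -log(p_true)) / wsum

  onehot <- matrix(0, bt$B, K)
  onehot[cbind(seq_len(bt$B), y1)] <- 1
  dlogits <- (fw$probs - onehot) * (w / wsum)

  g <- zero_grads(par)
  g$W2 <- t(dlogits) %*% fw$Z1
  g$b2 <- colSums(dlogits)
  dZ1 <- dlogits %*% par$W2
  dA1 <- dZ1 * (1 - fw$Z1^2)
  g$W1 <- t(dA1) %*% fw$Hfinal
  g$b1 <- colSums(dA1)
  dHfinal <- dA1 %*% par$W1

  H <- nrow(par$Wf)
  dH <- matrix(0, bt$B, H)
  dC <- matrix(0, bt$B, H)
  for (t in rev(seq_len(bt$Mmax))) {
    st <- fw$caches[[t]]
    inject <- bt$len == t
    if (any(inject)) dH[inject, ] <- dH[inject, , drop = FALSE] +
        dHfinal[inject, , drop = FALSE]
    do_ <- dH * st$tC
    dCt <- dC + dH * st$o * (1 - st$tC^2)
    df <- dCt * st$Cstar
    dCstar <- dCt * st$f
    di <- dCt * st$ct
    dct <- dCt * st$i
    dzf <- df * st$f * (1 - st$f)
    dzi <- di * st$i * (1 - st$i)
    dzo <- do_ * st$o * (1 - st$o)
    dzc <- dct * (1 - st$ct^2)
    dCS <- dCstar * (st$sgn * st$g - 1)
    dAd <- dCS * (1 - st$CS^2)

    g$Wd <- g$Wd + t(dAd) %*% st$Cprev
    g$bd <- g$bd + colSums(dAd)
    g$Wf <- g$Wf + t(dzf) %*% st$X; g$Uf <- g$Uf + t(dzf) %*% st$Hprev
    g$bf <- g$bf + colSums(dzf)
    g$Wi <- g$Wi + t(dzi) %*% st$X; g$Ui <- g$Ui + t(dzi) %*% st$Hprev
    g$bi <- g$bi + colSums(dzi)
    g$Wc <- g$Wc + t(dzc) %*% st$X; g$Uc <- g$Uc + t(dzc) %*% st$Hprev
    g$bc <- g$bc + colSums(dzc)
    g$Wo <- g$Wo + t(dzo) %*% st$X; g$Uo <- g$Uo + t(dzo) %*% st$Hprev
    g$bo <- g$bo + colSums(dzo)

    dH <- dzf %*% par$Uf + dzi %*% par$Ui + dzc %*% par$Uc + dzo %*% par$Uo
    dC <- dCstar + dAd %*% par$Wd
  }
  list(ce = ce, grad = g, probs = fw$probs)
}

flatten_grads <- function(g) unlist(lapply(g, as.numeric), use.names = FALSE)

# Gradient of log p(observed label) for one record (used by the Fisher
# importance estimate): the negative of the single-record cross-entropy
# gradient.
logprob_grad <- function(par, record, adjust = "add") {
  -flatten_grads(ce_loss_and_grad(par, list(record), adjust = adjust)$grad)
}
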