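# Independent oracles used across the suite. Each reimplements the quantity
# under test from first principles, without calling the package's internal
# code path.

# Plain LSTM cell (no time decomposition), elementwise on vectors.
plain_lstm_cell_oracle <- function(x, h_prev, C_prev, par) {
  sig <- function(z) 1 / (1 + exp(-z))
  f <- sig(par$Wf %*% x + par$Uf %*% h_prev + par$bf)
  i <- sig(par$Wi %*% x + par$Ui %*% h_prev + par$bi)
  o <- sig(par$Wo %*% x + par$Uo %*% h_prev + par$bo)
  ct <- tanh(par$Wc %*% x + par$Uc %*% h_prev + par$bc)
  C <- as.numeric(f) * C_prev + as.numeric(i) * as.numeric(ct)
  list(h = as.numeric(o) * tanh(C), C = C)
}

# Exhaustive pairwise Mann-Whitney AUC.
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Central finite differences of the mean cross-entropy.
finite_diff_grad <- function(par, records, eps = 1e-5) {
  flat <- flatten_params(par)
  g <- numeric(length(flat))
  for (j in seq_along(flat)) {
    up <- flat; up[j] <- up[j] + eps
    dn <- flat; dn[j] <- dn[j] - eps
    g[j] <- (ccts:::ce_loss_and_grad(relist_params(up, par), records)$ce -
               ccts:::ce_loss_and_grad(relist_params(dn, par), records)$ce) /
      (2 * eps)
  }
  g
}

# Offline least-squares segmentation: brute force over all placements of k
# changepoints minimizing within-segment squared error.
ls_changepoint_oracle <- function(x, k) {
  n <- length(x)
  sse <- function(seg) if (length(seg) < 2) 0 else sum((seg - mean(seg))^2)
  cost_of <- function(bounds) {
    cuts <- c(0, bounds, n)
    sum(vapply(seq_len(length(cuts) - 1), function(i)
      sse(x[(cuts[i] + 1):cuts[i + 1]]), numeric(1)))
  }
  best <- NULL; best_cost <- Inf
  combos <- utils::combn(seq_len(n - 1), k)
  for (c_i in seq_len(ncol(combos))) {
    b <- combos[, c_i]
    cost <- cost_of(b)
    if (cost < best_cost) { best_cost <- cost; best <- b }
  }
  best  # positions: segment i ends at best[i]; new regime starts at best[i]+1
}

# Plain sequential minibatch SGD trainer mirroring the package's batching
# protocol (seeded shuffle per epoch, consecutive chunks, gradient-norm
# clipping), written against the gradient function only.
reference_sgd_trainer <- function(model, stream, epochs, batch_size, lr,
                                  seed, clip = 5) {
  flat <- flatten_params(model)
  par <- model
  losses <- numeric(0)
  set.seed(seed)
  for (task in stream$tasks) {
    n <- length(task$dataset$records)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      for (s in seq(1, n, by = batch_size)) {
        idx <- perm[s:min(s + batch_size - 1, n)]
        lg <- ccts:::ce_loss_and_grad(par, task$dataset$records[idx])
        g <- ccts:::flatten_grads(lg$grad)
        gn <- sqrt(sum(g^2))
        if (gn > clip) g <- g * (clip / gn)
        flat <- flat - lr * g
        par <- relist_params(flat, par)
        losses <- c(losses, lg$ce)
      }
    }
    # the packaged trainer estimates the Fisher at each task end; that step
    # is RNG-free and must not perturb the trajectory, so the reference
    # deliberately omits it
  }
  list(params = par, flat = flat, losses = losses)
}
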