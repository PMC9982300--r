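#' Elapsed-time discount weight
#'
#' The short-term memory component of the time-aware LSTM is discounted by
#' `g(Delta) = 1 / ln(e + Delta)` (natural log), a strictly decreasing map
#' from the time gap onto `(0, 1]` with `g(0) = 1`.
#'
#' @param delta Non-negative time gap(s), in the units of the time axis.
#' @return Discount weight(s) in `(0, 1]`.
#' @export
elapsed_weight <- function(delta) {
  if (any(delta < 0)) stop("delta must be non-negative")
  1 / log(exp(1) + delta)
}

#' Initialize time-aware LSTM parameters
#'
#' Builds the named parameter groups of the two-block architecture: a memory
#' decomposition map (`Wd`, `bd`), four gates (forget/input/candidate/output,
#' each with input weight `W` `(H x D)`, recurrent weight `U` `(H x H)` and
#' bias `b`), and a classifier head (one tanh hidden layer of width
#' `head_width`, then an affine map to `n_classes` logits). Weights are drawn
#' uniformly in `±1/sqrt(H)`; every trainable scalar is addressable by a
#' hierarchical name (see [param_name_table()]).
#'
#' @param input_dim Number of input variables `D`.
#' @param hidden_dim Hidden size `H`.
#' @param n_classes Number of classes.
#' @param head_width Width of the classifier hidden layer (default `H`).
#' @param seed Integer seed for the initialization draw.
#' @return An object of class `tlstm_params` (named list of arrays).
#' @export
tlstm_params <- function(input_dim, hidden_dim, n_classes = 2L,
                         head_width = hidden_dim, seed = 1L) {
  H <- hidden_dim; D <- input_dim; K <- n_classes; Hh <- head_width
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  s <- 1 / sqrt(H)
  rmat <- function(r, c) matrix(stats::runif(r * c, -s, s), r, c)
  par <- list(
    Wd = rmat(H, H), bd = numeric(H),
    Wf = rmat(H, D), Uf = rmat(H, H), bf = numeric(H),
    Wi = rmat(H, D), Ui = rmat(H, H), bi = numeric(H),
    Wc = rmat(H, D), Uc = rmat(H, H), bc = numeric(H),
    Wo = rmat(H, D), Uo = rmat(H, H), bo = numeric(H),
    W1 = rmat(Hh, H), b1 = numeric(Hh),
    W2 = rmat(K, Hh), b2 = numeric(K))
  structure(par, class = "tlstm_params",
            dims = list(D = D, H = H, K = K, Hh = Hh))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.tlstm_params <- function(x, ...) {
  d <- attr(x, "dims")
  cat(sprintf("<tlstm_params> D=%d H=%d head=%d classes=%d (%d scalars)\n",
              d$D, d$H, d$Hh, d$K, length(flatten_params(x))))
  invisible(x)
}

#' Flatten parameters to a named numeric vector
#'
#' The flattening order is fixed, so the name table is a bijection onto all
#' trainable scalars; optimizer math and the importance ledger operate on this
#' flat view.
#'
#' @param par A `tlstm_params` object (or any named list of arrays).
#' @return Named numeric vector.
#' @export
flatten_params <- function(par) {
  v <- unlist(lapply(par, as.numeric), use.names = FALSE)
  names(v) <- param_name_table(par)$name
  v
}

#' Restore a flat vector to the parameter list shape
#'
#' @param flat Numeric vector as produced by [flatten_params()].
#' @param template A `tlstm_params` object providing shapes and attributes.
#' @return A `tlstm_params` object.
#' @export
relist_params <- function(flat, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    x <- flat[pos + seq_len(n)]
    dim(x) <- dim(template[[nm]])
    names(x) <- NULL
    out[[nm]] <- x
    pos <- pos + n
  }
  out
}

#' Hierarchical name table of all trainable scalars
#'
#' @param par A `tlstm_params` object.
#' @return Data frame with columns `name` (e.g. `"Wf[3,2]"`), `block`
#'   (`decomposition`/`gates`/`head`), `group` (array name) and the flat
#'   index. One row per scalar; names are unique.
#' @export
param_name_table <- function(par) {
  block_of <- c(Wd = "decomposition", bd = "decomposition",
                Wf = "gates", Uf = "gates", bf = "gates",
                Wi = "gates", Ui = "gates", bi = "gates",
                Wc = "gates", Uc = "gates", bc = "gates",
                Wo = "gates", Uo = "gates", bo = "gates",
                W1 = "head", b1 = "head", W2 = "head", b2 = "head")
  rows <- lapply(names(par), function(nm) {
    a <- par[[nm]]
    if (is.matrix(a)) {
      idx <- expand.grid(r = seq_len(nrow(a)), c = seq_len(ncol(a)))
      nms <- sprintf("%s[%d,%d]", nm, idx$r, idx$c)
    } else nms <- sprintf("%s[%d]", nm, seq_along(a))
    data.frame(name = nms, block = unname(block_of[nm]), group = nm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$index <- seq_len(nrow(out))
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' One step of the time-aware LSTM cell
#'
#' Decomposes the previous memory into short- and long-term parts, discounts
#' the short-term part by [elapsed_weight()] of the time gap, recombines, and
#' applies the standard gated update:
#' `CS = tanh(Wd C + bd)`, `CS_hat = CS * g(Delta)`, `CT = C - CS`,
#' `C* = CT + CS_hat` (set `adjust = "subtract"` for the variant
#' `C* = CT - CS_hat`), gates by sigmoid, candidate by tanh,
#' `C' = f*C* + i*Ctilde`, `h' = o*tanh(C')`.
#'
#' @param x Input vector (length `D`) or `B x D` matrix.
#' @param prev List with elements `h` and `C` (vectors of length `H`, or
#'   `B x H` matrices for a batch).
#' @param delta Non-negative time gap (scalar or length-`B` vector).
#' @param par A `tlstm_params` object.
#' @param adjust `"add"` (default) or `"subtract"` memory recombination.
#' @return List with the new `h` and `C` (same shapes as `prev`).
#' @export
tlstm_cell <- function(x, prev, delta, par, adjust = c("add", "subtract")) {
  adjust <- match.arg(adjust)
  vec_in <- is.null(dim(x))
  if (vec_in) {
    x <- matrix(x, 1L)
    prev <- list(h = matrix(prev$h, 1L), C = matrix(prev$C, 1L))
  }
  if (ncol(x) != ncol(par$Wf)) stop("input dimension mismatch")
  if (ncol(prev$h) != nrow(par$Wf)) stop("hidden dimension mismatch")
  st <- tlstm_step(x, prev$h, prev$C, elapsed_weight(delta), par, adjust)
  out <- list(h = st$h, C = st$C)
  if (vec_in) out <- list(h = drop(out$h), C = drop(out$C))
  out
}

# Core batched step; returns the full cache used by backprop.
tlstm_step <- function(X, Hprev, Cprev, g, par, adjust = "add") {
  CS <- tanh(sweep(Cprev %*% t(par$Wd), 2L, par$bd, `+`))
  sgn <- if (adjust == "add") 1 else -1
  Cstar <- Cprev + CS * (sgn * g - 1)
  zf <- sweep(X %*% t(par$Wf) + Hprev %*% t(par$Uf), 2L, par$bf, `+`)
  zi <- sweep(X %*% t(par$Wi) + Hprev %*% t(par$Ui), 2L, par$bi, `+`)
  zc <- sweep(X %*% t(par$Wc) + Hprev %*% t(par$Uc), 2L, par$bc, `+`)
  zo <- sweep(X %*% t(par$Wo) + Hprev %*% t(par$Uo), 2L, par$bo, `+`)
  f <- sigmoid(zf); i <- sigmoid(zi); o <- sigmoid(zo); ct <- tanh(zc)
  C <- f * Cstar + i * ct
  tC <- tanh(C)
  h <- o * tC
  list(h = h, C = C, tC = tC, f = f, i = i, o = o, ct = ct,
       CS = CS, Cstar = Cstar, X = X, Hprev = Hprev, Cprev = Cprev, g = g,
       sgn = sgn)
}

head_forward <- function(Hfinal, par) {
  A1 <- sweep(Hfinal %*% t(par$W1), 2L, par$b1, `+`)
  Z1 <- tanh(A1)
  logits <- sweep(Z1 %*% t(par$W2), 2L, par$b2, `+`)
  list(probs = softmax_rows(logits), Z1 = Z1, Hfinal = Hfinal)
}

# Pad a list of records into dense arrays for batched evaluation.
batch_tensors <- function(records) {
  B <- length(records)
  len <- vapply(records, function(r) length(r$times), integer(1))
  Mmax <- max(len)
  D <- ncol(records[[1L]]$values)
  X <- array(0, c(B, Mmax, D))
  delta <- matrix(0, B, Mmax)
  for (b in seq_len(B)) {
    r <- records[[b]]
    X[b, seq_len(len[b]), ] <- r$values
    delta[b, seq_len(len[b])] <- compute_deltas(r)
  }
  y <- vapply(records, function(r) r$label, integer(1))
  list(X = X, delta = delta, len = len, y = y, B = B, Mmax = Mmax, D = D)
}

# Batched forward pass over padded tensors; optionally keeps per-step caches.
tlstm_forward_batch <- function(bt, par, adjust = "add", keep_cache = FALSE) {
  H <- nrow(par$Wf)
  Hs <- matrix(0, bt$B, H); Cs <- matrix(0, bt$B, H)
  Hfinal <- matrix(0, bt$B, H)
  caches <- if (keep_cache) vector("list", bt$Mmax) else NULL
  for (t in seq_len(bt$Mmax)) {
    Xt <- bt$X[, t, , drop = FALSE]
    dim(Xt) <- c(bt$B, bt$D)
    st <- tlstm_step(Xt, Hs, Cs, elapsed_weight(bt$delta[, t]), par, adjust)
    Hs <- st$h; Cs <- st$C
    if (keep_cache) caches[[t]] <- st
    done <- bt$len == t
    if (any(done)) Hfinal[done, ] <- Hs[done, , drop = FALSE]
  }
  hf <- head_forward(Hfinal, par)
  list(probs = hf$probs, Hfinal = Hfinal, Z1 = hf$Z1, caches = caches)
}

#' Class probabilities for records
#'
#' Runs the time-aware LSTM over each record (per-step time gaps from
#' [compute_deltas()]), feeds the final hidden state to the classifier head,
#' and returns softmax probabilities. Rows sum to one.
#'
#' @param par A `tlstm_params` object.
#' @param dataset A [ccts_dataset()] or a single [irregular_series()].
#' @param adjust Memory recombination convention, see [tlstm_cell()].
#' @return `N x K` matrix of class probabilities.
#' @export
predict_proba <- function(par, dataset, adjust = "add") {
  if (inherits(dataset, "irregular_series"))
    dataset <- ccts_dataset(list(dataset))
  if (length(dataset$records) == 0L) stop("empty dataset")
  if (any(vapply(dataset$records, function(r) length(r$times), integer(1)) < 1L))
    stop("empty series")
  bt <- batch_tensors(dataset$records)
  tlstm_forward_batch(bt, par, adjust)$probs
}
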