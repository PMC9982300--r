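# Importance-based interpretation: block-wise aggregation of the Fisher
# ledger, changepoint staging of the importance trajectory, biomarker
# ranking and per-stage data profiles.

#' Extract the per-task importance ledger from a training history
#'
#' @param history An `ru_history` (or `ru_fit`) from [train_ru()].
#' @param use `"contribution"` (default) for the per-task Fisher
#'   contribution, or `"mean"` for the running-mean Fisher after each task.
#'   The contribution view reacts to distribution change undiluted by earlier
#'   tasks and is what the staging pipeline consumes.
#' @return An object of class `importance_ledger`: per-task flat importance
#'   snapshots plus the parameter template for block-wise aggregation.
#' @export
importance_ledger <- function(history, use = c("contribution", "mean")) {
  use <- match.arg(use)
  if (inherits(history, "ru_fit")) history <- history$history
  snaps <- lapply(history$importance, function(s)
    if (use == "contribution") s$contribution else s$F)
  if (any(vapply(snaps, function(s) any(s < 0), logical(1))))
    stop("importance snapshots must be non-negative")
  structure(list(snapshots = snaps, template = history$template, use = use),
            class = "importance_ledger")
}

#' @export
print.importance_ledger <- function(x, ...) {
  cat(sprintf("<importance_ledger> %d task snapshots (%s view), %d scalars\n",
              length(x$snapshots), x$use, length(x$snapshots[[1L]])))
  invisible(x)
}

#' @export
length.importance_ledger <- function(x) length(x$snapshots)

ledger_snapshot <- function(ledger, task_index) {
  if (task_index < 1L || task_index > length(ledger$snapshots))
    stop("task index out of range")
  relist_params(ledger$snapshots[[task_index]], ledger$template)
}

#' Aggregate importance per input feature
#'
#' The overall importance of input feature `d` is the summed importance of
#' every first-layer weight touching it: column `d` of all four gate input
#' weight matrices. With `normalize = TRUE` the result sums to one, making
#' snapshots comparable across tasks.
#'
#' @param ledger An [importance_ledger()].
#' @param task_index Task snapshot to aggregate.
#' @param normalize Normalize to unit sum (default `TRUE`).
#' @return Numeric vector of length `D`.
#' @export
feature_importance <- function(ledger, task_index, normalize = TRUE) {
  Fp <- ledger_snapshot(ledger, task_index)
  a <- colSums(Fp$Wf) + colSums(Fp$Wi) + colSums(Fp$Wc) + colSums(Fp$Wo)
  if (normalize && sum(a) > 0) a <- a / sum(a)
  a
}

#' Aggregate importance per gate group
#'
#' Sums importance over all parameters (`W`, `U`, `b`) of each of the four
#' gates of the recurrent cell.
#'
#' @inheritParams feature_importance
#' @return Named numeric vector `c(forget, input, candidate, output)`.
#' @export
gate_importance <- function(ledger, task_index, normalize = FALSE) {
  Fp <- ledger_snapshot(ledger, task_index)
  a <- c(forget = sum(Fp$Wf) + sum(Fp$Uf) + sum(Fp$bf),
         input = sum(Fp$Wi) + sum(Fp$Ui) + sum(Fp$bi),
         candidate = sum(Fp$Wc) + sum(Fp$Uc) + sum(Fp$bc),
         output = sum(Fp$Wo) + sum(Fp$Uo) + sum(Fp$bo))
  if (normalize && sum(a) > 0) a <- a / sum(a)
  a
}

#' Aggregate importance per neuron of a head layer
#'
#' A neuron's importance is the summed importance of its outgoing weights.
#' Layer 1 is the recurrent hidden state (outgoing weights: first head
#' matrix), layer 2 the head hidden layer (outgoing weights: logit matrix).
#' The output layer has no outgoing weights.
#'
#' @inheritParams feature_importance
#' @param layer Layer index (1 or 2).
#' @return Numeric vector, one entry per neuron of the layer.
#' @export
neuron_importance <- function(ledger, task_index, layer = 1L,
                              normalize = FALSE) {
  Fp <- ledger_snapshot(ledger, task_index)
  a <- switch(as.character(layer),
              "1" = colSums(Fp$W1),
              "2" = colSums(Fp$W2),
              stop("layer ", layer, " has no outgoing weights"))
  if (normalize && sum(a) > 0) a <- a / sum(a)
  a
}

# --- Bayesian online changepoint detection ---------------------------------

#' Bayesian online changepoint detection with a Normal-Gamma model
#'
#' Standard run-length filtering: at each observation the posterior over
#' "time since the last changepoint" is propagated under a constant hazard
#' `1/hazard` and a Normal observation model with Normal-Gamma conjugate
#' prior (Student-t predictive). Each column of the returned run-length
#' posterior sums to one.
#'
#' @param x Numeric series.
#' @param hazard Expected run length between changepoints (constant hazard
#'   `1/hazard`). Default 10.
#' @param mu0,kappa0,alpha0,beta0 Normal-Gamma prior. Defaults: `mu0` = mean
#'   of the first `min(3, n)` points, `kappa0 = 1`, `alpha0 = 1`, `beta0` =
#'   series variance estimate (floored away from zero).
#' @return List with `run_length_posterior` (an `(n+1) x n` matrix, run
#'   lengths 0..n in rows), `mode` (per-step posterior mode run length) and
#'   `changepoints` (series indices where a reset was flagged: the posterior
#'   mode dropped and more than half the mass fell below the previous mode).
#' @export
bocd <- function(x, hazard = 10, mu0 = NULL, kappa0 = 1, alpha0 = 1,
                 beta0 = NULL) {
  n <- length(x)
  if (n < 2L) stop("changepoint detection needs a series of length >= 2")
  if (is.null(mu0)) mu0 <- mean(x[seq_len(min(3L, n))])
  if (is.null(beta0)) beta0 <- max(stats::var(x), 1e-12)
  H <- 1 / hazard
  Rl <- matrix(0, n + 1L, n)
  # sufficient statistics per live run length (index 1 = run length 0)
  mu <- mu0; kappa <- kappa0; alpha <- alpha0; beta <- beta0
  prev <- 1  # P(r_0 = 0) = 1
  mode_trace <- integer(n)
  changepoints <- integer(0)
  prev_mode <- 0L
  for (t in seq_len(n)) {
    # Student-t predictive for each run length hypothesis
    df <- 2 * alpha
    scale <- sqrt(beta * (kappa + 1) / (alpha * kappa))
    pred <- stats::dt((x[t] - mu) / scale, df = df) / scale
    growth <- prev * pred * (1 - H)
    cp <- sum(prev * pred * H)
    post <- c(cp, growth)
    s <- sum(post)
    if (s <= 0 || !is.finite(s)) post <- c(1, rep(0, length(growth)))
    else post <- post / s
    Rl[seq_along(post), t] <- post
    # posterior parameter update: run length 0 restarts from the prior
    mu_new <- c(mu0, (kappa * mu + x[t]) / (kappa + 1))
    kappa_new <- c(kappa0, kappa + 1)
    alpha_new <- c(alpha0, alpha + 0.5)
    beta_new <- c(beta0, beta + kappa * (x[t] - mu)^2 / (2 * (kappa + 1)))
    mu <- mu_new; kappa <- kappa_new; alpha <- alpha_new; beta <- beta_new
    prev <- post
    mode_t <- which.max(post) - 1L
    mode_trace[t] <- mode_t
    if (t > 1L && mode_t < prev_mode &&
        sum(post[seq_len(prev_mode)]) > 0.5)
      changepoints <- c(changepoints, t)
    prev_mode <- mode_t
  }
  list(run_length_posterior = Rl, mode = mode_trace,
       changepoints = changepoints)
}

#' Detect learning stages from an importance trajectory
#'
#' Segments the per-task importance snapshots into stages with Bayesian
#' online changepoint detection. Two readings of the trajectory are
#' offered:
#' \describe{
#'   \item{`"per_series"` (default for matrix input)}{runs [bocd()] on the
#'     first differences of each mass-normalized importance coordinate.
#'     Within a stage a coordinate's importance accumulates at a roughly
#'     constant rate, so stages are level regimes of the increments, which
#'     is exactly the piecewise-constant signal the Normal observation
#'     model is built for. Each coordinate is scanned forward and
#'     time-reversed (online detection lags at a regime onset; the reversed
#'     pass recovers boundaries near the start), resets are pooled as votes
#'     per task, boundaries require `min_votes` votes, boundaries inside
#'     the establishment window (first `burn_in` tasks, from which the
#'     observation prior itself is estimated) are suppressed, and flags
#'     within two tasks of each other are merged onto the stronger one.}
#'   \item{`"pooled"`}{scalarizes consecutive snapshots to the L2 norm of
#'     their normalized difference and runs a single [bocd()] pass on that
#'     series; regime changes appear as isolated spikes, which is a weaker
#'     signal but a single interpretable summary.}
#' }
#' A constant trajectory yields a single stage. Scalar input (one value per
#' task transition) is segmented directly.
#'
#' @param importance_trajectory Numeric matrix (rows = tasks, columns =
#'   importance coordinates, e.g. per-task [feature_importance()] rows), an
#'   [importance_ledger()], or an already-scalar numeric series.
#' @param hazard Expected run length passed to [bocd()].
#' @param prior Optional named list overriding `mu0`, `kappa0`, `alpha0`,
#'   `beta0`.
#' @param method `"per_series"` or `"pooled"` (matrix input only).
#' @param min_votes Coordinate resets required to call a boundary under
#'   `"per_series"`.
#' @param burn_in Establishment window: boundaries in tasks `1..burn_in`
#'   are not callable under `"per_series"`.
#' @return An object of class `stage_assignment`: `changepoints` (task
#'   indices at which a new stage starts), `stage_of_task` (contiguous ids
#'   from 1), the scalar `series` (pooled summary, always reported), and
#'   `votes` (per-task reset votes, `per_series` only).
#' @export
detect_stages <- function(importance_trajectory, hazard = 10, prior = list(),
                          method = c("per_series", "pooled"),
                          min_votes = 3L, burn_in = 4L) {
  method <- match.arg(method)
  if (inherits(importance_trajectory, "importance_ledger"))
    importance_trajectory <- do.call(rbind, importance_trajectory$snapshots)
  scalar_in <- !is.matrix(importance_trajectory)
  if (scalar_in) {
    series <- as.numeric(importance_trajectory)
    Tn <- length(series) + 1L
    if (Tn < 2L) stop("trajectory must cover at least two tasks")
    norm <- NULL
  } else {
    Tn <- nrow(importance_trajectory)
    if (Tn < 2L) stop("trajectory must cover at least two tasks")
    norm <- importance_trajectory /
      pmax(rowSums(importance_trajectory), 1e-300)
    series <- vapply(2:Tn, function(t)
      sqrt(sum((norm[t, ] - norm[t - 1L, ])^2)), numeric(1))
  }
  degenerate <- function() structure(
    list(changepoints = integer(0), stage_of_task = rep(1L, Tn),
         series = series, votes = NULL, bocd = NULL),
    class = "stage_assignment")

  if (scalar_in || method == "pooled") {
    if (length(series) < 2L || stats::sd(series) < 1e-12) return(degenerate())
    args <- c(list(x = series, hazard = hazard), prior)
    fit <- do.call(bocd, args)
    # series index j covers the transition task (j) -> (j+1): a reset at j
    # means a new stage starts at task j+1
    boundaries <- fit$changepoints + 1L
    votes <- NULL
  } else {
    if (all(apply(norm, 2L, stats::sd) < 1e-12)) return(degenerate())
    votes <- integer(Tn)
    nd <- Tn - 1L
    for (j in seq_len(ncol(norm))) {
      d <- diff(norm[, j])
      if (length(d) < 3L) next
      b0 <- stats::var(diff(d)) / 2
      if (!is.finite(b0) || b0 < 1e-12) next
      args <- utils::modifyList(list(hazard = hazard, beta0 = b0), prior)
      # forward pass: a reset at increment k opens a new stage at task k+1
      cpf <- do.call(bocd, c(list(x = d), args))$changepoints
      votes[cpf + 1L] <- votes[cpf + 1L] + 1L
      # reversed pass: catches boundaries the online scan reaches before
      # the first regime is established
      cpb <- do.call(bocd, c(list(x = rev(d)), args))$changepoints
      bdb <- nd - cpb + 2L
      bdb <- bdb[bdb >= 2L & bdb <= Tn]
      votes[bdb] <- votes[bdb] + 1L
    }
    boundaries <- which(votes >= min_votes)
    boundaries <- boundaries[boundaries > burn_in]
    # merge flags within two tasks onto the stronger one
    if (length(boundaries) > 1L) {
      keep <- rep(TRUE, length(boundaries))
      for (i in 2:length(boundaries))
        if (boundaries[i] - boundaries[i - 1L] <= 2L && keep[i - 1L]) {
          if (votes[boundaries[i]] > votes[boundaries[i - 1L]])
            keep[i - 1L] <- FALSE else keep[i] <- FALSE
        }
      boundaries <- boundaries[keep]
    }
    fit <- NULL
  }
  boundaries <- boundaries[boundaries >= 2L & boundaries <= Tn]
  stage_of_task <- cumsum(seq_len(Tn) %in% boundaries) + 1L
  structure(list(changepoints = boundaries, stage_of_task = stage_of_task,
                 series = series, votes = votes, bocd = fit),
            class = "stage_assignment")
}

#' @export
print.stage_assignment <- function(x, ...) {
  cat(sprintf("<stage_assignment> %d stages over %d tasks; boundaries: %s\n",
              max(x$stage_of_task), length(x$stage_of_task),
              if (length(x$changepoints)) paste(x$changepoints, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Per-stage biomarker ranking
#'
#' Features are scored by their stage-averaged normalized overall importance
#' and ranked per stage, ties broken by feature index.
#'
#' @param feature_imp Matrix of per-task feature importance (rows = tasks,
#'   columns = features), e.g. rows of [feature_importance()].
#' @param stages A `stage_assignment` (or integer stage id per task).
#' @param top_k Number of features to report per stage (clipped to the
#'   feature count with a warning).
#' @return List, one data frame per stage with columns `feature` (index),
#'   `name` and `score`, sorted by decreasing score.
#' @export
rank_biomarkers <- function(feature_imp, stages, top_k = 5L) {
  feature_imp <- as.matrix(feature_imp)
  stage_of_task <- if (inherits(stages, "stage_assignment"))
    stages$stage_of_task else as.integer(stages)
  if (length(stage_of_task) != nrow(feature_imp))
    stop("stage assignment does not cover the task axis")
  D <- ncol(feature_imp)
  if (top_k > D) {
    warning("top_k exceeds the number of features; clipping to ", D)
    top_k <- D
  }
  nms <- colnames(feature_imp) %||% paste0("v", seq_len(D))
  lapply(sort(unique(stage_of_task)), function(s) {
    sc <- colMeans(feature_imp[stage_of_task == s, , drop = FALSE])
    ord <- order(-sc, seq_len(D))[seq_len(top_k)]
    data.frame(feature = ord, name = nms[ord], score = sc[ord],
               row.names = NULL)
  })
}

#' Per-stage, per-class feature summaries
#'
#' Maps each stage to its window on the fractional time axis (via the cut
#' fractions of the tasks it contains), then summarizes every feature's
#' observed values per stage and class: mean, standard deviation,
#' observation count, and the between-class mean difference.
#'
#' @param dataset A [ccts_dataset()].
#' @param stages A `stage_assignment` (or integer stage id per task).
#' @param cut_fractions The task stream's cut fractions (one per task).
#' @param features Optional subset of feature indices (default all).
#' @return Data frame with one row per (stage, feature): class means/sds and
#'   `class_diff` (class-1 mean minus class-0 mean; `NA` for an empty
#'   stratum).
#' @export
stage_profiles <- function(dataset, stages, cut_fractions, features = NULL) {
  stage_of_task <- if (inherits(stages, "stage_assignment"))
    stages$stage_of_task else as.integer(stages)
  if (length(stage_of_task) != length(cut_fractions))
    stop("stages must cover the task axis")
  D <- length(dataset$variables)
  if (is.null(features)) features <- seq_len(D)
  stage_ids <- sort(unique(stage_of_task))
  # stage windows on the fractional time axis, half-open (lo, hi]
  hi <- vapply(stage_ids, function(s)
    max(cut_fractions[stage_of_task == s]), numeric(1))
  lo <- c(0, hi[-length(hi)])
  rows <- list()
  for (si in seq_along(stage_ids)) {
    pooled <- list("0" = vector("list", D), "1" = vector("list", D))
    for (r in dataset$records) {
      M <- length(r$times)
      p <- seq_len(M) / M
      in_stage <- p > lo[si] & p <= hi[si]
      if (!any(in_stage)) next
      cls <- as.character(min(r$label, 1L))
      for (d in features) {
        obs <- in_stage & r$mask[, d]
        if (any(obs))
          pooled[[cls]][[d]] <- c(pooled[[cls]][[d]], r$values[obs, d])
      }
    }
    for (d in features) {
      v0 <- pooled[["0"]][[d]]; v1 <- pooled[["1"]][[d]]
      rows[[length(rows) + 1L]] <- data.frame(
        stage = stage_ids[si], feature = d,
        name = dataset$variables[d],
        mean0 = if (length(v0)) mean(v0) else NA_real_,
        sd0 = if (length(v0) > 1L) stats::sd(v0) else NA_real_,
        n0 = length(v0),
        mean1 = if (length(v1)) mean(v1) else NA_real_,
        sd1 = if (length(v1) > 1L) stats::sd(v1) else NA_real_,
        n1 = length(v1))
    }
  }
  out <- do.call(rbind, rows)
  out$class_diff <- out$mean1 - out$mean0
  out
}

#' Fraction of records staged monotonically in time
#'
#' Each record contributes a sequence of stage ids over its successive
#' prefixes; the rate is the fraction of records whose sequence never
#' decreases.
#'
#' @param stage_sequences List of integer vectors (each of length `>= 2`).
#' @return Fraction in `[0, 1]`.
#' @export
monotone_staging_rate <- function(stage_sequences) {
  if (length(stage_sequences) == 0L) return(NA_real_)
  mean(vapply(stage_sequences, function(s) all(diff(s) >= 0), logical(1)))
}

#' Per-record prefix stage sequences from a task-axis assignment
#'
#' Under the task-axis mapping, a record's prefix at task `m` belongs to the
#' stage containing task `m`, so every record shares the task-level stage
#' sequence.
#'
#' @param stages A `stage_assignment`.
#' @param n_records Number of records.
#' @return List of `n_records` integer stage sequences.
#' @export
record_stage_sequences <- function(stages, n_records) {
  rep(list(stages$stage_of_task), n_records)
}
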