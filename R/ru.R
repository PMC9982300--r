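#' Training configuration for the restricted-update strategy
#'
#' @param lambda Non-negative strength of the importance penalty (limitation
#'   mechanism). Default 0.5.
#' @param a Exponent of the step/mixing schedule `(1/(m+1))^a`, or `"auto"`
#'   for the calibrated linear relation `a = 0.933*lambda + 0.907`.
#' @param epochs_per_task Passes over each task's data. Default 20.
#' @param batch_size Minibatch size. Default 32.
#' @param D_K Radius of the L2-ball feasible set, centered at the initial
#'   parameters. `NULL` (default) resolves to `10*||theta0|| + 10` at
#'   training time.
#' @param seed Integer seed driving minibatch shuffling.
#' @param pm_enabled,lm_enabled Switches for the promotion mechanism
#'   (projection-free recursive-gradient update) and the limitation mechanism
#'   (Fisher quadratic penalty). With both `FALSE` the trainer reduces to
#'   plain sequential minibatch SGD at `learning_rate`.
#' @param learning_rate SGD step size used when `pm_enabled = FALSE`.
#' @param fisher_sample Records sampled per task for the Fisher estimate
#'   (deterministic evenly spaced subsample). Default 256.
#' @param class_weights Optional per-class weights for the cross-entropy.
#' @param adjust Memory recombination convention of the cell, see
#'   [tlstm_cell()].
#' @param metric Score used for the accuracy matrix: `"auc"` or `"accuracy"`.
#' @param schedule_scope `"global"` (default) counts schedule rounds across
#'   the whole stream, so updates contract as more distributions have been
#'   seen (the restricted-update reading); `"task"` restarts the counter at
#'   each task, giving every distribution the same optimization budget at
#'   the cost of larger early steps on later tasks.
#' @param grad_clip Global gradient-norm ceiling for the SGD path (promotion
#'   mechanism disabled); the recurrent backprop occasionally produces large
#'   gradients and the importance penalty can be stiff. `Inf` disables.
#' @param pm_memory What the promotion mechanism's gradient memory `G`
#'   stores: `"gradient"` (default) keeps the current batch's gradient
#'   re-evaluated at the previous parameters, the variance-reduced recursive
#'   estimator in its original form; `"direction"` keeps the previous update
#'   direction `g_m`, the literal re-arranged recursion.
#' @return A list of class `ru_config`.
#' @export
ru_config <- function(lambda = 0.5, a = "auto", epochs_per_task = 20L,
                      batch_size = 32L, D_K = NULL, seed = 1L,
                      pm_enabled = TRUE, lm_enabled = TRUE,
                      learning_rate = 0.05, fisher_sample = 256L,
                      class_weights = NULL, adjust = "add",
                      metric = c("auc", "accuracy"),
                      schedule_scope = c("global", "task"),
                      grad_clip = 5,
                      pm_memory = c("gradient", "direction")) {
  stopifnot(lambda >= 0, epochs_per_task >= 1)
  structure(list(lambda = lambda, a = a,
                 epochs_per_task = as.integer(epochs_per_task),
                 batch_size = as.integer(batch_size), D_K = D_K,
                 seed = as.integer(seed), pm_enabled = isTRUE(pm_enabled),
                 lm_enabled = isTRUE(lm_enabled),
                 learning_rate = learning_rate,
                 fisher_sample = as.integer(fisher_sample),
                 class_weights = class_weights, adjust = adjust,
                 metric = match.arg(metric),
                 schedule_scope = match.arg(schedule_scope),
                 grad_clip = grad_clip,
                 pm_memory = match.arg(pm_memory)),
            class = "ru_config")
}

resolve_a <- function(config) {
  if (identical(config$a, "auto")) 0.933 * config$lambda + 0.907
  else as.numeric(config$a)
}

#' Step and mixing schedule
#'
#' Both the step size `eta_m` and the estimator mixing weight `rho_m` follow
#' `(1/(m+1))^a`, `m` counted from 0.
#'
#' @param m Round counter (integer, from 0).
#' @param a Positive exponent; `a = 0.933*lambda + 0.907` under the `"auto"`
#'   calibration.
#' @return `(1/(m+1))^a`.
#' @export
ru_schedule <- function(m, a) {
  stopifnot(all(m >= 0), a > 0)
  (1 / (m + 1))^a
}

#' Initialize the Fisher-importance state
#'
#' Holds the per-parameter importance `F` (diagonal empirical Fisher, a
#' running mean over tasks), the anchor parameters from the end of the
#' previous task, and the number of tasks incorporated.
#'
#' @param anchor Flat parameter vector (see [flatten_params()]).
#' @return A list of class `importance_state` with `F` all zeros and
#'   `task_count = 0`.
#' @export
importance_state <- function(anchor) {
  structure(list(F = numeric(length(anchor)), anchor = anchor,
                 task_count = 0L),
            class = "importance_state")
}

#' Importance-regularized training loss
#'
#' Cross-entropy on the batch plus the limitation-mechanism penalty
#' `lambda * sum_i F_i (theta_i - anchor_i)^2`, which anchors parameters that
#' were important for earlier distributions.
#'
#' @param batch A [ccts_dataset()] or list of records.
#' @param params A `tlstm_params` object.
#' @param importance An [importance_state()] (its `F` may be all zeros on the
#'   first task, in which case the penalty vanishes).
#' @param lam Penalty strength `lambda >= 0`.
#' @param class_weights Optional per-class weights.
#' @param adjust Cell convention, see [tlstm_cell()].
#' @return Scalar loss.
#' @export
regularized_loss <- function(batch, params, importance, lam,
                             class_weights = NULL, adjust = "add") {
  records <- if (inherits(batch, "ccts_dataset")) batch$records else batch
  flat <- flatten_params(params)
  if (length(flat) != length(importance$anchor))
    stop("parameter shape does not match the importance anchor")
  ce <- ce_loss_and_grad(params, records, class_weights, adjust)$ce
  dev <- flat - importance$anchor
  ce + lam * sum(importance$F * dev^2)
}

fisher_sample_idx <- function(n, size) {
  if (n <= size) seq_len(n)
  else unique(as.integer(round(seq(1, n, length.out = size))))
}

#' Refresh the Fisher importance at the end of a task
#'
#' The task's contribution is the mean, over a deterministic subsample of
#' records, of the squared per-record gradient of the log-probability of the
#' observed label; `F` is the running mean of these contributions over the
#' tasks seen so far. The anchor is reset to the current parameters.
#'
#' @param importance An [importance_state()].
#' @param task_dataset The task's [ccts_dataset()].
#' @param params Current `tlstm_params`.
#' @param sample_size Maximum records used (default 256).
#' @param adjust Cell convention.
#' @return The updated `importance_state` (with the per-task contribution in
#'   `$contribution`).
#' @export
update_fisher <- function(importance, task_dataset, params,
                          sample_size = 256L, adjust = "add") {
  records <- if (inherits(task_dataset, "ccts_dataset")) task_dataset$records
             else task_dataset
  if (length(records) == 0L) stop("empty task: cannot estimate the Fisher")
  idx <- fisher_sample_idx(length(records), sample_size)
  acc <- numeric(length(importance$F))
  for (j in idx) acc <- acc + logprob_grad(params, records[[j]], adjust)^2
  contrib <- acc / length(idx)
  m <- importance$task_count
  importance$F <- (m * importance$F + contrib) / (m + 1)
  importance$anchor <- flatten_params(params)
  importance$task_count <- m + 1L
  importance$contribution <- contrib
  importance
}

#' Variance-reduced recursive gradient estimator
#'
#' `d_m = grad_now + (1 - rho) * (d_prev - g_prev)`: mixes the fresh
#' minibatch gradient with the discrepancy between the previous estimator and
#' the previous update direction. With `rho = 1` it reduces to the plain
#' stochastic gradient.
#'
#' @param grad_now Flat gradient at the current round.
#' @param pm List with `d_prev` and `g_prev` (flat vectors).
#' @param rho Mixing weight in `(0, 1]`.
#' @return Flat estimator `d_m`.
#' @export
recursive_gradient <- function(grad_now, pm, rho) {
  stopifnot(rho > 0, rho <= 1)
  if (length(pm$d_prev) != length(grad_now) ||
      length(pm$g_prev) != length(grad_now))
    stop("estimator state shape mismatch")
  grad_now + (1 - rho) * (pm$d_prev - pm$g_prev)
}

#' Linear minimization oracle over the L2-ball feasible set
#'
#' Returns the point of the ball `K = {v : ||v - center|| <= radius}`
#' minimizing the inner product with `d`, i.e.
#' `v = center - radius * d / ||d||`; for a (near-)zero `d` the center is
#' returned.
#'
#' @param d Flat direction vector.
#' @param radius Positive ball radius.
#' @param center Flat center (the initial parameters during training).
#' @return The minimizing point `v`.
#' @export
linear_minimization_oracle <- function(d, radius, center) {
  stopifnot(radius > 0)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) return(center)
  center - radius * d / nd
}

#' Projection-free promotion step
#'
#' Computes the oracle point `v_m` for the estimator `d_m`, the update
#' direction `g_m = v_m - theta`, and moves `theta' = theta + eta * g_m`
#' (a convex combination, so iterates initialized inside the feasible ball
#' stay inside it for `eta` in `[0, 1]`).
#'
#' @param params_flat Flat current parameters.
#' @param pm List with `radius` and `center` describing the feasible set.
#' @param d_m Flat recursive-gradient estimator.
#' @param eta Step size in `[0, 1]`.
#' @return List with `params` (updated flat vector) and `g` (the stored
#'   update direction, the new gradient-memory entry).
#' @export
pm_step <- function(params_flat, pm, d_m, eta) {
  v <- linear_minimization_oracle(d_m, pm$radius, pm$center)
  g <- v - params_flat
  list(params = params_flat + eta * g, g = g)
}

#' Fraction of stored task gradients at an acute angle with a new direction
#'
#' Diagnostic for the interference between the current update direction and
#' the gradients of earlier tasks: directions at an acute (or right) angle do
#' not degrade earlier-task performance to first order.
#'
#' @param g_new Flat direction.
#' @param stored_grads Matrix (one gradient per row) or list of flat vectors.
#' @return Fraction in `[0, 1]` of stored gradients with inner product
#'   `>= 0` (orthogonal counted as acute).
#' @export
acute_angle_check <- function(g_new, stored_grads) {
  if (is.list(stored_grads)) stored_grads <- do.call(rbind, stored_grads)
  if (is.null(dim(stored_grads))) stored_grads <- matrix(stored_grads, 1L)
  if (nrow(stored_grads) == 0L) return(NA_real_)
  mean(as.numeric(stored_grads %*% g_new) >= 0)
}

score_model <- function(par, dataset, metric = "auc", adjust = "add") {
  probs <- predict_proba(par, dataset, adjust)
  y <- dataset_labels(dataset)
  if (metric == "auc" && ncol(probs) == 2L) auc_roc(probs[, 2L], y)
  else mean(max.col(probs) - 1L == y)
}

#' Train with the restricted-update strategy over a prefix task stream
#'
#' Runs the sequential training loop: for each task, minibatch rounds over
#' the importance-regularized loss; each round forms the recursive gradient
#' estimator, queries the linear minimization oracle and applies the
#' projection-free promotion step (or a plain SGD step when
#' `pm_enabled = FALSE`). At each task end the Fisher importance and anchor
#' are refreshed and one row of the accuracy matrix is evaluated. With both
#' mechanisms disabled the trajectory is identical to naive sequential
#' fine-tuning at the same seed (the Fisher snapshot is still recorded for
#' the interpretation ledger but does not influence the updates).
#'
#' @param model Initial `tlstm_params`.
#' @param stream A `prefix_task_stream` (training data).
#' @param config An [ru_config()].
#' @param eval_stream Optional held-out `prefix_task_stream` used for the
#'   accuracy matrix; defaults to `stream`.
#' @return List of class `ru_fit` with elements `params` (trained
#'   `tlstm_params`) and `history` (per-round losses and schedules, gradient
#'   sign series, per-task parameter/importance snapshots, the accuracy
#'   matrix with its random-initialization reference, and the config).
#' @export
train_ru <- function(model, stream, config = ru_config(),
                     eval_stream = NULL) {
  if (length(stream$tasks) == 0L) stop("empty task stream")
  if (is.null(eval_stream)) eval_stream <- stream
  par <- model
  flat <- flatten_params(par)
  P <- length(flat)
  center <- flat
  # ball radius of the order of the initialization norm: SGD solutions stay
  # near that scale, and larger balls let early oracle points saturate the
  # nonlinearities, after which recovery is unreliable
  radius <- config$D_K %||% (sqrt(sum(flat^2)) + 1)
  a <- resolve_a(config)
  imp <- importance_state(flat)
  d_prev <- numeric(P); g_prev <- numeric(P)
  n_tasks <- length(stream$tasks)
  n_eval <- length(eval_stream$tasks)

  total_rounds <- sum(vapply(stream$tasks, function(tk) {
    nb <- ceiling(length(tk$dataset$records) / config$batch_size)
    nb * config$epochs_per_task
  }, numeric(1)))
  loss_trace <- numeric(total_rounds)
  task_trace <- integer(total_rounds)
  eta_trace <- numeric(total_rounds)
  grad_sign <- matrix(0L, total_rounds, P)
  R <- matrix(NA_real_, n_tasks, n_eval)
  importance_snapshots <- vector("list", n_tasks)
  param_snapshots <- vector("list", n_tasks)

  b_bar <- vapply(eval_stream$tasks, function(tk)
    score_model(par, tk$dataset, config$metric, config$adjust), numeric(1))

  set.seed(config$seed)
  round <- 0L
  prev_par <- NULL; prev_flat <- NULL
  # regularized objective gradient; the penalty uses mass-normalized
  # importance (mean 1) so that lambda is comparable across architectures
  # and Fisher scales
  objective_grad <- function(p, p_flat, records) {
    lg <- ce_loss_and_grad(p, records, config$class_weights, config$adjust)
    loss <- lg$ce
    grad <- flatten_grads(lg$grad)
    if (config$lm_enabled && imp$task_count > 0L && any(imp$F > 0)) {
      Fn <- imp$F / mean(imp$F)
      dev <- p_flat - imp$anchor
      loss <- loss + config$lambda * sum(Fn * dev^2)
      grad <- grad + 2 * config$lambda * Fn * dev
    }
    list(loss = loss, grad = grad)
  }
  for (m in seq_len(n_tasks)) {
    task <- stream$tasks[[m]]
    n <- length(task$dataset$records)
    task_round <- 0L
    for (ep in seq_len(config$epochs_per_task)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        round <- round + 1L
        task_round <- task_round + 1L
        idx <- perm[s:min(s + config$batch_size - 1L, n)]
        records <- task$dataset$records[idx]
        sched <- max(ru_schedule(
          if (identical(config$schedule_scope, "task")) task_round else round,
          a), 1e-12)  # floor: keeps rho/eta valid when a is extreme
        og <- objective_grad(par, flat, records)
        loss <- og$loss
        grad <- og$grad
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at round %d (task %d)", round, m))
        if (config$pm_enabled) {
          g_mem <- if (identical(config$pm_memory, "gradient")) {
            if (is.null(prev_par)) numeric(P)
            else objective_grad(prev_par, prev_flat, records)$grad
          } else g_prev
          d <- recursive_gradient(grad, list(d_prev = d_prev, g_prev = g_mem),
                                  sched)
          st <- pm_step(flat, list(radius = radius, center = center), d,
                        sched)
          prev_par <- par; prev_flat <- flat
          flat <- st$params
          d_prev <- d; g_prev <- st$g
        } else {
          gn <- sqrt(sum(grad^2))
          step <- if (is.finite(config$grad_clip) && gn > config$grad_clip)
            grad * (config$grad_clip / gn) else grad
          flat <- flat - config$learning_rate * step
        }
        par <- relist_params(flat, par)
        loss_trace[round] <- loss
        task_trace[round] <- m
        eta_trace[round] <- sched
        # sign series of the gradient that drives the update: the recursive
        # estimator under the promotion mechanism, the raw objective
        # gradient otherwise
        grad_sign[round, ] <- as.integer(sign(
          if (config$pm_enabled) d_prev else grad))
      }
    }
    imp <- update_fisher(imp, task$dataset, par, config$fisher_sample,
                         config$adjust)
    importance_snapshots[[m]] <- list(F = imp$F, contribution = imp$contribution)
    param_snapshots[[m]] <- flat
    R[m, ] <- vapply(eval_stream$tasks, function(tk)
      score_model(par, tk$dataset, config$metric, config$adjust), numeric(1))
  }
  history <- structure(
    list(loss = loss_trace, task = task_trace, eta = eta_trace,
         grad_sign = grad_sign, importance = importance_snapshots,
         param_snapshots = param_snapshots,
         accuracy_matrix = accuracy_matrix(R, b_bar),
         radius = radius, a = a, config = config,
         template = model),
    class = "ru_history")
  structure(list(params = par, history = history), class = "ru_fit")
}

#' @export
print.ru_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<ru_fit> %d tasks, %d rounds, final loss %.4f (lm=%s, pm=%s)\n",
              max(h$task), length(h$loss), h$loss[length(h$loss)],
              h$config$lm_enabled, h$config$pm_enabled))
  invisible(x)
}

#' @export
print.ru_history <- function(x, ...) {
  cat(sprintf("<ru_history> %d rounds over %d tasks; accuracy matrix %dx%d\n",
              length(x$loss), max(x$task), nrow(x$accuracy_matrix$R),
              ncol(x$accuracy_matrix$R)))
  invisible(x)
}
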