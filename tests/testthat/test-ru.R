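test_that("regularized loss is cross-entropy plus the anchored penalty", {
  par <- small_model(D = 2, H = 3)
  ds <- make_random_dataset(n = 5, M_range = c(2, 4), D = 2, seed = 2)
  flat <- flatten_params(par)
  imp <- importance_state(flat)
  ce <- ccts:::ce_loss_and_grad(par, ds$records)$ce
  # lambda = 0 and theta = anchor both reduce to plain cross-entropy
  expect_equal(regularized_loss(ds, par, imp, 0), ce)
  imp$F <- runif(length(flat))
  expect_equal(regularized_loss(ds, par, imp, 3), ce)
  # displaced anchor: direct arithmetic
  imp2 <- imp
  imp2$F <- rep(0, length(flat)); imp2$F[1] <- 2
  imp2$anchor[1] <- flat[1] - 0.5
  expect_equal(regularized_loss(ds, par, imp2, 1), ce + 2 * 0.25)
  imp_bad <- importance_state(flat[-1])
  expect_error(regularized_loss(ds, par, imp_bad, 1), "anchor")
})

test_that("Fisher update is a running mean of per-record squared gradients", {
  par <- small_model(D = 2, H = 3)
  ds <- make_random_dataset(n = 6, M_range = c(2, 3), D = 2, seed = 4)
  imp <- importance_state(flatten_params(par))
  imp1 <- update_fisher(imp, ds, par)
  # brute-force recomputation of the first contribution
  want <- Reduce(`+`, lapply(ds$records, function(r)
    ccts:::logprob_grad(par, r)^2)) / length(ds$records)
  expect_equal(imp1$F, want)
  expect_equal(imp1$contribution, want)
  expect_identical(imp1$task_count, 1L)
  expect_equal(imp1$anchor, flatten_params(par))
  # second task: running mean over the two contributions
  ds2 <- make_random_dataset(n = 4, M_range = c(2, 3), D = 2, seed = 5)
  imp2 <- update_fisher(imp1, ds2, par)
  want2 <- Reduce(`+`, lapply(ds2$records, function(r)
    ccts:::logprob_grad(par, r)^2)) / length(ds2$records)
  expect_equal(imp2$F, (want + want2) / 2)
  expect_true(all(imp2$F >= 0))
  expect_error(update_fisher(imp, list(), par), "empty task")
})

test_that("Fisher of two equal half-batches averages to the full batch", {
  par <- small_model(D = 2, H = 3)
  ds <- make_random_dataset(n = 8, M_range = c(2, 3), D = 2, seed = 6)
  full <- update_fisher(importance_state(flatten_params(par)), ds, par)
  h1 <- update_fisher(importance_state(flatten_params(par)),
                      ccts_dataset(ds$records[1:4]), par)
  h2 <- update_fisher(importance_state(flatten_params(par)),
                      ccts_dataset(ds$records[5:8]), par)
  expect_equal((h1$F + h2$F) / 2, full$F)
})

test_that("recursive estimator mixes gradient and memory as specified", {
  pm <- list(d_prev = 1, g_prev = 0.5)
  expect_equal(recursive_gradient(2, pm, 0.5), 2.25)
  expect_equal(recursive_gradient(2, pm, 1), 2)       # rho = 1: plain grad
  expect_equal(recursive_gradient(2, list(d_prev = 3, g_prev = 3), 0.3), 2)
  expect_error(recursive_gradient(1:2, list(d_prev = 1, g_prev = 1), 0.5),
               "shape")
})

test_that("linear minimization oracle returns the opposing ball point", {
  v <- linear_minimization_oracle(c(3, 4), 1, c(0, 0))
  expect_equal(v, c(-0.6, -0.8))
  expect_equal(linear_minimization_oracle(c(0, 0), 2, c(1, 1)), c(1, 1))
  # Monte-Carlo minimality: <d, v> <= <d, u> for random u in K
  set.seed(21)
  d <- rnorm(6); center <- rnorm(6); radius <- 2.5
  v <- linear_minimization_oracle(d, radius, center)
  for (i in 1:1000) {
    u <- rnorm(6); u <- center + radius * runif(1) * u / sqrt(sum(u^2))
    expect_true(sum(d * v) <= sum(d * u) + 1e-12)
  }
})

test_that("promotion step is a convex combination staying inside the ball", {
  set.seed(22)
  center <- rnorm(5); radius <- 3
  theta <- center + radius * 0.5 * (function(z) z / sqrt(sum(z^2)))(rnorm(5))
  pm <- list(radius = radius, center = center)
  st0 <- pm_step(theta, pm, rnorm(5), 0)
  expect_equal(st0$params, theta)                       # eta = 0: no move
  d <- rnorm(5)
  st1 <- pm_step(theta, pm, d, 1)
  expect_equal(st1$params, linear_minimization_oracle(d, radius, center))
  for (i in 1:200) {
    eta <- runif(1)
    st <- pm_step(theta, pm, rnorm(5), eta)
    expect_true(sqrt(sum((st$params - center)^2)) <= radius + 1e-10)
    theta <- st$params
  }
})

test_that("schedule follows (1/(m+1))^a with the calibrated auto exponent", {
  expect_equal(ru_schedule(0, 1), 1)
  expect_equal(ru_schedule(1, 1), 0.5)
  expect_equal(ccts:::resolve_a(ru_config(lambda = 0.5, a = "auto")),
               0.933 * 0.5 + 0.907)
  expect_equal(ccts:::resolve_a(ru_config(a = 2)), 2)
})

test_that("acute angle diagnostic counts non-negative inner products", {
  g <- c(1, 0)
  expect_equal(acute_angle_check(g, matrix(g, 1)), 1)
  expect_equal(acute_angle_check(g, matrix(-g, 1)), 0)
  expect_equal(acute_angle_check(g, matrix(c(0, 1), 1)), 1)  # orthogonal
  expect_equal(acute_angle_check(g, rbind(g, -g)), 0.5)
})

test_that("with both mechanisms off the trainer is a plain minibatch SGD", {
  gen <- generator_config(n_records = 24L, n_features = 3L,
                          len_range = c(4L, 7L), always_informative = 1L,
                          seed = 31L)
  ds <- generate_dataset(gen)$dataset
  stream <- build_prefix_stream(ds, c(0.5, 1))
  model <- tlstm_params(3, 4, 2, seed = 31)
  rc <- ru_config(lambda = 0, epochs_per_task = 3L, batch_size = 8L,
                  seed = 31L, pm_enabled = FALSE, lm_enabled = FALSE,
                  learning_rate = 0.05)
  fit <- train_ru(model, stream, rc)
  ref <- reference_sgd_trainer(model, stream, epochs = 3, batch_size = 8,
                               lr = 0.05, seed = 31)
  expect_identical(flatten_params(fit$params), ref$flat)
  expect_identical(fit$history$loss, ref$losses)
})

test_that("training history carries the promised structure", {
  gen <- generator_config(n_records = 16L, n_features = 3L,
                          len_range = c(3L, 5L), always_informative = 1L,
                          seed = 41L)
  ds <- generate_dataset(gen)$dataset
  stream <- build_prefix_stream(ds, c(0.5, 1))
  fit <- train_ru(tlstm_params(3, 4, 2, seed = 41), stream,
                  ru_config(epochs_per_task = 2L, batch_size = 8L,
                            seed = 41L))
  h <- fit$history
  expect_identical(length(h$loss), 8L)   # 2 tasks x 2 epochs x 2 batches
  expect_identical(dim(h$grad_sign),
                   c(8L, length(flatten_params(fit$params))))
  expect_identical(length(h$importance), 2L)
  expect_true(all(h$importance[[2]]$F >= 0))
  am <- h$accuracy_matrix
  expect_identical(dim(am$R), c(2L, 2L))
  expect_true(all(am$R >= 0 & am$R <= 1))
  expect_identical(length(am$b_bar), 2L)
  # same config and seed reproduce the run exactly
  fit2 <- train_ru(tlstm_params(3, 4, 2, seed = 41), stream,
                   ru_config(epochs_per_task = 2L, batch_size = 8L,
                             seed = 41L))
  expect_identical(flatten_params(fit2$params), flatten_params(fit$params))
})
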