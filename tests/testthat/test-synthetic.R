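test_that("generation is reproducible and respects the configuration", {
  gen <- generator_config(n_records = 30L, n_features = 4L,
                          len_range = c(5L, 9L), always_informative = 1:2,
                          seed = 61L)
  a <- generate_dataset(gen); b <- generate_dataset(gen)
  expect_equal(a$dataset, b$dataset)
  expect_identical(a$truth$labels, b$truth$labels)
  M <- vapply(a$dataset$records, function(r) length(r$times), integer(1))
  expect_true(all(M >= 5 & M <= 9))
  expect_true(all(vapply(a$dataset$records, function(r)
    all(diff(r$times) > 0), logical(1))))
  # every time row keeps at least one observed cell
  expect_true(all(vapply(a$dataset$records, function(r)
    all(rowSums(r$mask) >= 1), logical(1))))
  expect_error(generator_config(always_informative = 1L,
                                late_informative = 1L), "disjoint")
  expect_error(generator_config(stage_boundaries = c(0.5, 0.2)), "sorted")
})

test_that("label frequency matches the configured balance", {
  gen <- generator_config(n_records = 600L, n_features = 2L,
                          len_range = c(3L, 5L), class_balance = 0.3,
                          seed = 62L)
  lab <- generate_dataset(gen)$truth$labels
  p <- mean(lab)
  half_width <- qnorm(0.995) * sqrt(0.3 * 0.7 / 600)
  expect_lt(abs(p - 0.3), half_width)
})

test_that("per-stage class-conditional means recover configured shifts", {
  gen <- generator_config(n_records = 500L, n_features = 3L,
                          len_range = c(10L, 14L), stage_boundaries = 0.5,
                          stage_shifts = rbind(c(1.5, 0, 0), c(-1.5, 2, 0)),
                          missing_rate = 0, seed = 63L)
  out <- generate_dataset(gen)
  pool <- function(stage, feature, label) {
    unlist(lapply(out$dataset$records, function(r) {
      if (r$label != label) return(NULL)
      M <- length(r$times)
      s <- ccts:::stage_of_position(seq_len(M) / M, gen$stage_boundaries)
      r$values[s == stage, feature]
    }))
  }
  for (case in list(c(1, 1, 1.5), c(2, 1, -1.5), c(2, 2, 2), c(1, 2, 0))) {
    diff_hat <- mean(pool(case[1], case[2], 1)) - mean(pool(case[1], case[2], 0))
    n_eff <- min(length(pool(case[1], case[2], 1)),
                 length(pool(case[1], case[2], 0)))
    se <- sqrt(2 / n_eff) * 2.5   # AR(1) inflates the iid standard error
    expect_lt(abs(diff_hat - case[3]), 3 * se)
  }
})

test_that("null configuration is chance-level for the reference rule", {
  aucs <- vapply(1:20, function(i) {
    gen <- generator_config(n_records = 120L, n_features = 4L,
                            len_range = c(4L, 8L), effect_size = 0,
                            seed = 700L + i)
    out <- generate_dataset(gen)
    sc <- bayes_discriminant(out$dataset, out$truth)
    # all scores identical: the tie convention pins AUC at 1/2
    auc_roc(sc + seq_along(sc) * 0, out$truth$labels)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("reference-rule AUC increases with the effect size", {
  mean_auc <- function(effect) {
    mean(vapply(1:20, function(i) {
      gen <- generator_config(n_records = 80L, n_features = 4L,
                              len_range = c(4L, 8L), effect_size = effect,
                              always_informative = 1:2, seed = 800L + i)
      out <- generate_dataset(gen)
      auc_roc(bayes_discriminant(out$dataset, out$truth),
              out$truth$labels)
    }, numeric(1)))
  }
  grid <- vapply(c(0.3, 0.8, 1.5), mean_auc, numeric(1))
  expect_true(all(diff(grid) > 0))
})

test_that("default signal supports a strong linear classifier at final time", {
  skip_if_not_installed("glmnet")
  gen <- generator_config(n_records = 400L, n_features = 10L,
                          len_range = c(8L, 14L), effect_size = 1.5,
                          always_informative = 1:3, seed = 65L)
  out <- generate_dataset(gen)
  X <- t(vapply(out$dataset$records, function(r)
    r$values[nrow(r$values), ], numeric(10)))
  y <- out$truth$labels
  set.seed(65)
  fit <- glmnet::cv.glmnet(X, y, family = "binomial", nfolds = 5)
  pred <- as.numeric(predict(fit, X, s = "lambda.min"))
  expect_gt(auc_roc(pred, y), 0.8)
})

test_that("standard streams expose the documented fixtures", {
  st <- standard_streams(seed = 3L)
  expect_setequal(names(st), c("forgetting-2d", "staging-4", "null"))
  expect_identical(st[["forgetting-2d"]]$n_stages, 2L)
  sh <- stage_shift_matrix(st[["forgetting-2d"]])
  expect_true(all(sh[1, 1:3] > 0) && all(sh[2, 1:3] < 0))
  expect_identical(st[["staging-4"]]$n_stages, 4L)
  expect_equal(sum(abs(stage_shift_matrix(st[["null"]]))), 0)
  expect_length(attr(st[["staging-4"]], "cut_fractions"), 17L)
})

test_that("ground-truth sidecar and CSVs are written together", {
  gen <- generator_config(n_records = 10L, n_features = 2L,
                          len_range = c(3L, 4L), seed = 66L)
  out <- generate_dataset(gen)
  dir <- withr::local_tempdir()
  paths <- write_generated(out, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$labels, out$truth$labels)
})
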