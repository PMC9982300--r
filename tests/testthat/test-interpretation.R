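# Builds a tiny ledger by hand: a history-like object whose importance
# snapshots are chosen, so aggregation can be checked by counting.
make_ledger <- function(snaps, template) {
  h <- structure(list(importance = lapply(snaps, function(s)
    list(F = s, contribution = s)), template = template),
    class = "ru_history")
  importance_ledger(h)
}

test_that("feature importance sums first-layer gate columns and conserves mass", {
  par <- tlstm_params(3, 4, 2, seed = 1)
  ones <- flatten_params(par); ones[] <- 1
  led <- make_ledger(list(ones), par)
  a <- feature_importance(led, 1, normalize = FALSE)
  expect_equal(a, rep(4 * 4, 3))          # 4 gates x H rows per column
  # conservation: total equals summed importance of all gate input weights
  Fp <- relist_params(ones, par)
  expect_equal(sum(a), sum(Fp$Wf) + sum(Fp$Wi) + sum(Fp$Wc) + sum(Fp$Wo))
  expect_equal(sum(feature_importance(led, 1)), 1)
  zeros <- ones; zeros[] <- 0
  led0 <- make_ledger(list(zeros), par)
  expect_equal(feature_importance(led0, 1, normalize = FALSE), rep(0, 3))
  # scale invariance of the normalized view
  set.seed(2); rnd <- ones; rnd[] <- runif(length(rnd))
  l1 <- make_ledger(list(rnd), par); l2 <- make_ledger(list(7.3 * rnd), par)
  expect_equal(feature_importance(l1, 1), feature_importance(l2, 1))
})

test_that("gate importance totals each gate's parameter group", {
  par <- tlstm_params(3, 4, 2, seed = 1)
  ones <- flatten_params(par); ones[] <- 1
  led <- make_ledger(list(ones), par)
  g <- gate_importance(led, 1)
  per_gate <- 4 * 3 + 4 * 4 + 4      # W (HxD) + U (HxH) + b (H)
  expect_equal(unname(g), rep(per_gate, 4))
  expect_named(g, c("forget", "input", "candidate", "output"))
  # permuting hidden units leaves totals unchanged
  set.seed(3); rnd <- ones; rnd[] <- runif(length(rnd))
  Fp <- relist_params(rnd, par)
  perm <- sample(4)
  Fq <- Fp
  for (nm in c("Wf", "Wi", "Wc", "Wo"))
    Fq[[nm]] <- Fp[[nm]][perm, , drop = FALSE]
  for (nm in c("Uf", "Ui", "Uc", "Uo"))
    Fq[[nm]] <- Fp[[nm]][perm, perm, drop = FALSE]
  for (nm in c("bf", "bi", "bc", "bo")) Fq[[nm]] <- Fp[[nm]][perm]
  lp <- make_ledger(list(rnd), par)
  lq <- make_ledger(list(flatten_params(Fq)), par)
  expect_equal(gate_importance(lp, 1), gate_importance(lq, 1))
})

test_that("neuron importance row-sums outgoing weights, last layer errors", {
  par <- tlstm_params(3, 4, 2, head_width = 5, seed = 1)
  ones <- flatten_params(par); ones[] <- 1
  led <- make_ledger(list(ones), par)
  expect_equal(neuron_importance(led, 1, layer = 1), rep(5, 4))  # -> W1
  expect_equal(neuron_importance(led, 1, layer = 2), rep(2, 5))  # -> W2
  expect_error(neuron_importance(led, 1, layer = 3), "outgoing")
  # brute-force per-scalar summation
  set.seed(4); rnd <- ones; rnd[] <- runif(length(rnd))
  lr <- make_ledger(list(rnd), par)
  Fp <- relist_params(rnd, par)
  expect_equal(neuron_importance(lr, 1, layer = 1), colSums(Fp$W1))
})

test_that("run-length posterior columns are normalized probabilities", {
  set.seed(31)
  x <- c(rnorm(30), rnorm(30, 4))
  f <- bocd(x, hazard = 20)
  expect_equal(colSums(f$run_length_posterior), rep(1, 60),
               tolerance = 1e-9)
  expect_true(all(f$run_length_posterior >= 0))
})

test_that("a strong mean shift is located near the least-squares optimum", {
  set.seed(32)
  x <- c(rnorm(50), rnorm(50, 5))   # +5 sd shift after index 50
  st <- detect_stages(x, hazard = 25)
  expect_identical(length(st$changepoints), 1L)
  oracle <- ls_changepoint_oracle(x, 1) + 1L  # oracle: new regime start
  expect_lte(abs(st$changepoints - oracle), 3)
  expect_lte(abs(st$changepoints - 51), 3)
})

test_that("two injected shifts give three stages near the oracle cuts", {
  set.seed(33)
  x <- c(rnorm(40), rnorm(40, 5), rnorm(40, -3))
  st <- detect_stages(x, hazard = 30)
  expect_identical(max(st$stage_of_task), 3L)
  oracle <- ls_changepoint_oracle(x, 2) + 1L
  expect_true(all(abs(st$changepoints - oracle) <= 3))
})

test_that("constant importance trajectories yield a single stage", {
  st <- detect_stages(matrix(1, 8, 5))
  expect_identical(max(st$stage_of_task), 1L)
  expect_identical(st$changepoints, integer(0))
  st2 <- detect_stages(rep(0.3, 9))
  expect_identical(max(st2$stage_of_task), 1L)
})

test_that("per-series staging recovers a planted regime rotation", {
  set.seed(34)
  Tn <- 18; D <- 8
  traj <- matrix(abs(rnorm(Tn * D, 0.05, 0.01)), Tn, D)
  ramp <- function(tasks, f) traj[tasks, f] <<-
    traj[tasks, f] + 0.08 * seq_along(tasks)
  ramp(1:8, 1:2); ramp(9:13, 3:4); ramp(14:18, 5:6)
  st <- detect_stages(traj, hazard = 8)
  expect_identical(max(st$stage_of_task), 3L)
  expect_true(all(abs(st$changepoints - c(9, 14)) <= 1))
})

test_that("biomarker ranking is stage-averaged with index tie-breaks", {
  feat <- rbind(c(0.6, 0.2, 0.2), c(0.5, 0.3, 0.2),
                c(0.1, 0.1, 0.8), c(0.2, 0.1, 0.7))
  stages <- c(1L, 1L, 2L, 2L)
  out <- rank_biomarkers(feat, stages, top_k = 2)
  expect_identical(out[[1]]$feature, c(1L, 2L))
  expect_identical(out[[2]]$feature, c(3L, 1L))
  uni <- rank_biomarkers(matrix(1 / 3, 2, 3), c(1L, 1L), top_k = 3)
  expect_identical(uni[[1]]$feature, 1:3)          # tie rule: index order
  expect_warning(rank_biomarkers(feat, stages, top_k = 9), "clipping")
})

test_that("stage profiles recover class differences and pool correctly", {
  gen <- generator_config(n_records = 500L, n_features = 2L,
                          len_range = c(10L, 14L), stage_boundaries = 0.75,
                          stage_shifts = rbind(c(0, 0), c(7, 0)),
                          noise_sd = 1, missing_rate = 0, seed = 51L)
  ds <- generate_dataset(gen)$dataset
  # single stage reproduces whole-dataset class means
  prof1 <- stage_profiles(ds, rep(1L, 2), c(0.5, 1))
  all1 <- unlist(lapply(ds$records, function(r)
    if (r$label == 1) r$values[, 1] else NULL))
  expect_equal(prof1$mean1[1], mean(all1), tolerance = 1e-9)
  # stage windows: +7 sd shift on feature 1 only in the late stage
  stages <- c(1L, 1L, 1L, 2L)
  prof <- stage_profiles(ds, stages, c(0.25, 0.5, 0.75, 1))
  late1 <- prof[prof$stage == 2 & prof$feature == 1, ]
  early1 <- prof[prof$stage == 1 & prof$feature == 1, ]
  expect_lt(abs(late1$class_diff - 7), 1)
  expect_lt(abs(early1$class_diff), 1)
  # identical classes: zero differences
  ds0 <- generate_dataset(generator_config(
    n_records = 200L, n_features = 2L, len_range = c(6L, 8L),
    effect_size = 0, missing_rate = 0, seed = 52L))$dataset
  prof0 <- stage_profiles(ds0, c(1L, 1L), c(0.5, 1))
  expect_true(all(abs(prof0$class_diff) < 0.5))
})

test_that("importance heatmaps render to file", {
  f <- withr::local_tempfile(fileext = ".png")
  plot_importance_heatmap(matrix(runif(24), 6, 4), file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("monotone staging rate counts non-decreasing sequences", {
  expect_equal(monotone_staging_rate(list(c(1, 1, 2), c(1, 2, 3))), 1)
  expect_equal(monotone_staging_rate(list(c(2, 1))), 0)
  expect_equal(monotone_staging_rate(list(c(1, 2), c(2, 1))), 0.5)
  st <- structure(list(stage_of_task = c(1L, 1L, 2L)),
                  class = "stage_assignment")
  seqs <- record_stage_sequences(st, 3)
  expect_identical(length(seqs), 3L)
  expect_equal(monotone_staging_rate(seqs), 1)
})
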