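# Canned study designs: the forgetting/recovery benchmark on the two-stage
# reversal stream and the staging benchmark on the four-stage stream. Tests,
# the vignette and the README all run these rather than re-assembling the
# pipeline by hand.

#' Forgetting/recovery benchmark on the two-stage reversal stream
#'
#' For each seed, generates a training and a held-out evaluation split of the
#' `"forgetting-2d"` stream, builds the two-task prefix stream (cut fractions
#' 0.5 and 1), and trains four variants from the same initialization: naive
#' sequential fine-tuning, limitation mechanism only, promotion mechanism
#' only, and the full restricted-update strategy. Reports per-seed backward
#' transfer and gradient fluctuation.
#'
#' The benchmark runs the penalty at `lambda = 0.25` (half the training
#' default): stiff enough that the anchored variants do not forget, while
#' leaving the promotion mechanism's projection-free update some room to
#' move, so the two mechanisms remain distinguishable in the transfer
#' scores.
#'
#' @param seeds Integer vector of seeds (one run set per seed).
#' @param n_records Training records per seed (evaluation split is the same
#'   size at an offset seed).
#' @param epochs_per_task Passes per task.
#' @param hidden_dim Hidden size of the recurrent cell.
#' @param lambda Penalty strength for the variants with the limitation
#'   mechanism.
#' @param variants Character subset of
#'   `c("naive", "lm", "pm", "ru")`.
#' @return Data frame with one row per (seed, variant): `bwt`,
#'   `grad_fluctuation`, and the diagonal/final-row scores of the accuracy
#'   matrix.
#' @export
forgetting_benchmark <- function(seeds = 1:5, n_records = 400L,
                                 epochs_per_task = 10L, hidden_dim = 16L,
                                 lambda = 0.25,
                                 variants = c("naive", "lm", "pm", "ru")) {
  flags <- list(naive = c(FALSE, FALSE), lm = c(TRUE, FALSE),
                pm = c(FALSE, TRUE), ru = c(TRUE, TRUE))
  rows <- list()
  for (seed in seeds) {
    cfg <- standard_streams(seed = seed)[["forgetting-2d"]]
    cfg$n_records <- as.integer(n_records)
    fractions <- attr(cfg, "cut_fractions")
    train <- generate_dataset(cfg)
    cfg_test <- cfg
    cfg_test$seed <- cfg$seed + 10000L
    test <- generate_dataset(cfg_test)
    stream <- build_prefix_stream(train$dataset, fractions)
    estream <- build_prefix_stream(test$dataset, fractions)
    D <- cfg$n_features
    for (v in variants) {
      rc <- ru_config(lambda = lambda, epochs_per_task = epochs_per_task,
                      seed = seed, lm_enabled = flags[[v]][1L],
                      pm_enabled = flags[[v]][2L])
      model <- tlstm_params(D, hidden_dim, 2L, seed = seed)
      fit <- train_ru(model, stream, rc, estream)
      am <- fit$history$accuracy_matrix
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, variant = v, bwt = bwt(am), fwt = fwt(am),
        grad_fluctuation = gradient_fluctuation(fit$history$grad_sign),
        r11 = am$R[1L, 1L], r21 = am$R[2L, 1L], r22 = am$R[2L, 2L])
    }
  }
  do.call(rbind, rows)
}

#' Staging benchmark on the four-stage stream
#'
#' For each seed, trains the full restricted-update strategy over a
#' twelve-task prefix stream of the `"staging-4"` fixture, extracts the
#' per-task Fisher contribution ledger, detects stages on the importance
#' trajectory, and summarizes feature importance at the first and last task.
#'
#' The changepoint hazard defaults to twice the fixture's per-stage task
#' count (about four tasks per stage): long enough that the reset prior does
#' not fire on its own, short enough to stay sensitive.
#'
#' @param seeds Integer vector of seeds.
#' @param n_records Training records per seed.
#' @param epochs_per_task Passes per task.
#' @param hidden_dim Hidden size.
#' @param hazard Expected run length for [detect_stages()].
#' @return List with one element per seed: the `stage_assignment`, the
#'   per-task normalized feature-importance matrix, the fitted model and the
#'   generator truth.
#' @export
staging_benchmark <- function(seeds = 1:5, n_records = 320L,
                              epochs_per_task = 6L, hidden_dim = 16L,
                              hazard = 8) {
  out <- list()
  for (seed in seeds) {
    cfg <- standard_streams(seed = seed)[["staging-4"]]
    cfg$n_records <- as.integer(n_records)
    fractions <- attr(cfg, "cut_fractions")
    train <- generate_dataset(cfg)
    stream <- build_prefix_stream(train$dataset, fractions)
    rc <- ru_config(epochs_per_task = epochs_per_task, seed = seed)
    model <- tlstm_params(cfg$n_features, hidden_dim, 2L, seed = seed)
    fit <- train_ru(model, stream, rc)
    led <- importance_ledger(fit$history)
    feat <- do.call(rbind, lapply(seq_along(led$snapshots), function(m)
      feature_importance(led, m)))
    stages <- detect_stages(feat, hazard = hazard)
    out[[as.character(seed)]] <- list(
      stages = stages, feature_importance = feat, fit = fit,
      truth = train$truth, cut_fractions = fractions)
  }
  out
}

#' Task indices at which the generator's stages begin
#'
#' Maps the generator's stage boundaries (record-length fractions) onto a
#' task stream's cut fractions: a stage beginning at boundary `b` starts at
#' the first task whose cut fraction exceeds `b`.
#'
#' @param boundaries Generator stage boundaries (fractions).
#' @param cut_fractions Task cut fractions.
#' @return Integer task indices, one per boundary.
#' @export
stage_boundary_tasks <- function(boundaries, cut_fractions) {
  vapply(boundaries, function(b)
    which(cut_fractions > b + 1e-12)[1L], integer(1))
}
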