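# Synthetic multi-stage labeled time series: irregular sampling, missingness,
# piecewise-constant class-conditional mean shifts over within-record stages,
# AR(1) within-record noise. Every downstream module is testable on these
# fixtures with known ground truth.

#' Configuration for the synthetic time-series generator
#'
#' Records are irregularly sampled (exponential gaps), labeled once at their
#' final time, and drift across stages: each record's time axis is divided at
#' `stage_boundaries` (fractions of its own length), and class-1 records
#' receive per-stage mean shifts on the informative features, in units of the
#' within-stage noise standard deviation. "Always" features carry their shift
#' in every stage (congenital-marker analogue); "late" features activate only
#' from `late_onset_stage` on (acute-marker analogue). Within-record noise is
#' AR(1) so prefixes carry temporal signal.
#'
#' @param n_records Number of records.
#' @param n_features Feature count `D`.
#' @param len_range Integer `c(min, max)` observations per record.
#' @param stage_boundaries Sorted fractions in `(0, 1)` splitting each
#'   record's time axis into `length(stage_boundaries) + 1` stages.
#' @param effect_size Class-1 mean shift, in noise-sd units.
#' @param always_informative Integer feature indices shifted in every stage.
#' @param late_informative Integer feature indices shifted only from
#'   `late_onset_stage` on (disjoint from `always_informative`).
#' @param late_onset_stage First stage (1-based) at which late features
#'   activate; defaults to the first stage after the midpoint.
#' @param stage_shifts Optional explicit `n_stages x D` matrix of class-1
#'   mean shifts overriding the feature-set construction.
#' @param noise_sd Noise standard deviation (stationary sd of the AR(1)
#'   process).
#' @param ar_phi AR(1) coefficient of the within-record noise.
#' @param missing_rate Probability that a cell is unobserved (each time row
#'   keeps at least one observed cell).
#' @param mean_gap Mean of the exponential inter-observation gaps (time
#'   units).
#' @param class_balance Probability of class 1.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_records = 400L, n_features = 10L,
                             len_range = c(12L, 20L),
                             stage_boundaries = 0.5, effect_size = 1.5,
                             always_informative = integer(0),
                             late_informative = integer(0),
                             late_onset_stage = NULL, stage_shifts = NULL,
                             noise_sd = 1, ar_phi = 0.5, missing_rate = 0.1,
                             mean_gap = 1, class_balance = 0.5, seed = 1L) {
  n_stages <- length(stage_boundaries) + 1L
  if (length(stage_boundaries) &&
      (is.unsorted(stage_boundaries, strictly = TRUE) ||
       any(stage_boundaries <= 0 | stage_boundaries >= 1)))
    stop("stage boundaries must be sorted fractions in (0, 1)")
  if (length(intersect(always_informative, late_informative)))
    stop("always- and late-informative feature sets must be disjoint")
  if (any(c(always_informative, late_informative) > n_features))
    stop("informative feature index exceeds n_features")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (class_balance < 0 || class_balance > 1)
    stop("class_balance must lie in [0, 1]")
  if (is.null(late_onset_stage)) late_onset_stage <- floor(n_stages / 2) + 1L
  if (!is.null(stage_shifts)) {
    stage_shifts <- as.matrix(stage_shifts)
    if (!identical(dim(stage_shifts), c(n_stages, as.integer(n_features))))
      stop("stage_shifts must be n_stages x n_features")
  }
  structure(list(n_records = as.integer(n_records),
                 n_features = as.integer(n_features),
                 len_range = as.integer(len_range),
                 stage_boundaries = as.numeric(stage_boundaries),
                 n_stages = n_stages, effect_size = effect_size,
                 always_informative = as.integer(always_informative),
                 late_informative = as.integer(late_informative),
                 late_onset_stage = as.integer(late_onset_stage),
                 stage_shifts = stage_shifts, noise_sd = noise_sd,
                 ar_phi = ar_phi, missing_rate = missing_rate,
                 mean_gap = mean_gap, class_balance = class_balance,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Per-stage class-1 mean-shift matrix of a configuration
#'
#' @param config A [generator_config()].
#' @return `n_stages x D` matrix, in noise-sd units.
#' @export
stage_shift_matrix <- function(config) {
  if (!is.null(config$stage_shifts)) return(config$stage_shifts)
  S <- matrix(0, config$n_stages, config$n_features)
  S[, config$always_informative] <- config$effect_size
  if (length(config$late_informative)) {
    late <- seq(config$late_onset_stage, config$n_stages)
    S[late, config$late_informative] <- config$effect_size
  }
  S
}

stage_of_position <- function(p, boundaries) {
  findInterval(p, boundaries, left.open = TRUE) + 1L
}

#' Generate a synthetic labeled dataset with known stage structure
#'
#' See [generator_config()] for the generative model. Unobserved cells are
#' imputed with the package's standard rule (forward fill, then per-variable
#' dataset mean), so the in-memory dataset is identical to what
#' [load_long_csv()] would reconstruct from [write_long_csv()] output.
#'
#' @param config A [generator_config()].
#' @return List with `dataset` (a [ccts_dataset()]) and `truth` (stage
#'   boundaries, the shift matrix, informative feature sets, labels, and the
#'   configuration).
#' @export
generate_dataset <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  D <- config$n_features
  shifts <- stage_shift_matrix(config)
  records <- vector("list", config$n_records)
  labels <- integer(config$n_records)
  lens <- seq(config$len_range[1L], config$len_range[2L])
  for (i in seq_len(config$n_records)) {
    M <- lens[sample.int(length(lens), 1L)]  # safe for a length-1 range
    gaps <- stats::rexp(M - 1L, rate = 1 / config$mean_gap)
    times <- cumsum(c(0, gaps))
    label <- stats::rbinom(1L, 1L, config$class_balance)
    stage <- stage_of_position(seq_len(M) / M, config$stage_boundaries)
    noise <- matrix(stats::rnorm(M * D), M, D) * config$noise_sd
    if (M > 1L) {
      innov_sd <- sqrt(1 - config$ar_phi^2)
      noise[1L, ] <- noise[1L, ]
      for (m in 2:M)
        noise[m, ] <- config$ar_phi * noise[m - 1L, ] +
          innov_sd * noise[m, ]
    }
    values <- noise
    if (label == 1L)
      values <- values + shifts[stage, , drop = FALSE] * config$noise_sd
    mask <- matrix(stats::runif(M * D) >= config$missing_rate, M, D)
    for (m in which(rowSums(mask) == 0L))
      mask[m, sample.int(D, 1L)] <- TRUE
    records[[i]] <- structure(
      list(record_id = sprintf("r%04d", i), times = times, values = values,
           mask = mask, label = label),
      class = "irregular_series")
    labels[i] <- label
  }
  dataset <- impute_missing(
    ccts_dataset(records, paste0("v", seq_len(D))))
  truth <- list(stage_boundaries = config$stage_boundaries,
                stage_shifts = shifts,
                always_informative = config$always_informative,
                late_informative = config$late_informative,
                labels = labels, config = config)
  list(dataset = dataset, truth = truth)
}

#' Likelihood-ratio reference score for generated records
#'
#' Matched-filter discriminant under an independence approximation of the
#' generative model: the sum over observed cells of
#' `shift[stage(m), d] * x[m, d] / noise_sd^2`. With all effect sizes zero
#' every record scores 0. Used as the analytic reference rule in tests, never
#' by the trainer.
#'
#' @param dataset A [ccts_dataset()] from [generate_dataset()].
#' @param truth The matching ground-truth record.
#' @return Numeric score per record.
#' @export
bayes_discriminant <- function(dataset, truth) {
  shifts <- truth$stage_shifts
  sd2 <- truth$config$noise_sd^2
  vapply(dataset$records, function(r) {
    M <- length(r$times)
    stage <- stage_of_position(seq_len(M) / M, truth$stage_boundaries)
    W <- shifts[stage, , drop = FALSE] * truth$config$noise_sd
    sum((W * r$values)[r$mask]) / sd2
  }, numeric(1))
}

#' Named standard fixture configurations
#'
#' Fixed generator configurations used throughout the test suite:
#' \describe{
#'   \item{`forgetting-2d`}{Two maximally distinct stages: the early
#'     features' class shift reverses sign in the second stage while a
#'     disjoint late set activates, so naive sequential training on the
#'     full-length task degrades first-task performance.}
#'   \item{`staging-4`}{Four stages with rotating informative pairs plus one
#'     always-informative feature; the stage structure is recoverable from
#'     the importance trajectory.}
#'   \item{`null`}{No informative features; chance-level separability.}
#' }
#' Each entry carries the cut fractions its experiments use as attribute
#' `cut_fractions`.
#'
#' @param seed Base seed stored in each configuration.
#' @return Named list of [generator_config()] objects.
#' @export
standard_streams <- function(seed = 1L) {
  shifts2 <- matrix(0, 2, 10)
  shifts2[1, 1:3] <- 1.5
  shifts2[2, 1:3] <- -1.5
  forgetting <- generator_config(
    n_records = 400L, n_features = 10L, len_range = c(12L, 20L),
    stage_boundaries = 0.5, stage_shifts = shifts2,
    always_informative = 1:3, seed = seed)
  attr(forgetting, "cut_fractions") <- c(0.5, 1)

  shifts4 <- matrix(0, 4, 10)
  for (s in 1:4) shifts4[s, c(2 * s - 1, 2 * s)] <- 2
  shifts4[, 9] <- 1
  staging <- generator_config(
    n_records = 320L, n_features = 10L, len_range = c(16L, 24L),
    stage_boundaries = c(0.45, 0.65, 0.85), stage_shifts = shifts4,
    always_informative = 9L, late_informative = 7:8,
    late_onset_stage = 4L, seed = seed)
  # tasks start at a fifth of each record (very short prefixes carry too few
  # observations for a stable importance estimate) and step by 5%
  attr(staging, "cut_fractions") <- seq(0.2, 1, by = 0.05)

  null_cfg <- generator_config(
    n_records = 400L, n_features = 10L, len_range = c(12L, 20L),
    stage_boundaries = 0.5, effect_size = 0, seed = seed)
  attr(null_cfg, "cut_fractions") <- c(0.5, 1)

  list("forgetting-2d" = forgetting, "staging-4" = staging,
       "null" = null_cfg)
}

#' Write a generated dataset plus its ground truth
#'
#' Writes the long-format CSV pair ([write_long_csv()]) and a JSON sidecar
#' with the ground-truth record.
#'
#' @param generated The list returned by [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three paths.
#' @export
write_generated <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data_path <- file.path(dir, "data.csv")
  label_path <- file.path(dir, "labels.csv")
  truth_path <- file.path(dir, "truth.json")
  write_long_csv(generated$dataset, data_path, label_path)
  tr <- generated$truth
  jsonlite::write_json(
    list(stage_boundaries = tr$stage_boundaries,
         stage_shifts = tr$stage_shifts,
         always_informative = tr$always_informative,
         late_informative = tr$late_informative,
         labels = tr$labels,
         noise_sd = tr$config$noise_sd, seed = tr$config$seed),
    truth_path, auto_unbox = FALSE, digits = NA, matrix = "rowmajor")
  invisible(c(data_path, label_path, truth_path))
}
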