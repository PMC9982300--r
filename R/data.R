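#' Construct a single labeled irregular time series
#'
#' A record holds `M` observation times, an `M x D` value matrix, an
#' observation mask of the same shape, and one class label fixed at the final
#' time. Times must be strictly increasing; the mask marks which cells were
#' actually observed (unobserved cells carry imputed values).
#'
#' @param record_id Character scalar identifying the record.
#' @param times Numeric vector of strictly increasing observation times.
#' @param values Numeric `M x D` matrix of (possibly imputed) values.
#' @param mask Logical `M x D` matrix, `TRUE` where the cell was observed.
#' @param label Integer class label in `{0, ..., K-1}` (file convention).
#' @return An object of class `irregular_series`.
#' @export
irregular_series <- function(record_id, times, values, mask = NULL,
                             label = 0L) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  mask <- as.matrix(mask)
  x <- structure(
    list(record_id = as.character(record_id), times = as.numeric(times),
         values = values, mask = mask, label = as.integer(label)),
    class = "irregular_series")
  validate_series(x)
  x
}

validate_series <- function(x) {
  M <- length(x$times)
  if (M < 1L) stop("series must have at least one observation")
  if (M >= 2L && any(diff(x$times) <= 0))
    stop("times must be strictly increasing (record ", x$record_id, ")")
  if (!identical(dim(x$values), dim(x$mask)))
    stop("values and mask shapes disagree")
  if (nrow(x$values) != M)
    stop("values must have one row per time point")
  if (length(x$label) != 1L || is.na(x$label))
    stop("label must be a single class index")
  invisible(x)
}

#' @export
print.irregular_series <- function(x, ...) {
  cat(sprintf("<irregular_series '%s'> M=%d D=%d label=%d observed=%.0f%%\n",
              x$record_id, length(x$times), ncol(x$values), x$label,
              100 * mean(x$mask)))
  invisible(x)
}

#' Bundle records into a labeled time-series dataset
#'
#' @param records List of [irregular_series()] objects.
#' @param variables Character vector naming the `D` variables (columns).
#' @return An object of class `ccts_dataset`.
#' @export
ccts_dataset <- function(records, variables = NULL) {
  if (length(records) == 0L) stop("dataset must contain at least one record")
  D <- ncol(records[[1L]]$values)
  if (is.null(variables)) variables <- paste0("v", seq_len(D))
  if (length(variables) != D) stop("variable names must match dimension D")
  for (r in records)
    if (ncol(r$values) != D) stop("all records must share dimension D")
  structure(list(records = records, variables = variables),
            class = "ccts_dataset")
}

#' @export
print.ccts_dataset <- function(x, ...) {
  M <- vapply(x$records, function(r) length(r$times), integer(1))
  lab <- vapply(x$records, function(r) r$label, integer(1))
  cat(sprintf("<ccts_dataset> %d records, D=%d, lengths %d-%d, classes: %s\n",
              length(x$records), length(x$variables), min(M), max(M),
              paste(sprintf("%d (n=%d)", sort(unique(lab)),
                            tabulate(factor(lab))), collapse = ", ")))
  invisible(x)
}

#' @export
length.ccts_dataset <- function(x) length(x$records)

dataset_labels <- function(dataset)
  vapply(dataset$records, function(r) r$label, integer(1))

#' Elapsed-time gaps of a record
#'
#' Returns the per-step time gaps `Delta_m = t_m - t_{m-1}`, with
#' `Delta_1 = 0` by convention. These feed the elapsed-time discount of the
#' time-aware LSTM memory cell.
#'
#' @param series An [irregular_series()].
#' @return Numeric vector of length `M`, first element 0.
#' @export
compute_deltas <- function(series) {
  validate_series(series)
  c(0, diff(series$times))
}

# Forward-fill each variable within the record, then fill leading gaps with
# the per-variable dataset mean over observed cells (0 if never observed).
impute_values <- function(values, mask, variable_means) {
  for (d in seq_len(ncol(values))) {
    col <- values[, d]
    obs <- mask[, d]
    if (all(obs)) next
    last <- NA_real_
    for (m in seq_along(col)) {
      if (obs[m]) last <- col[m]
      else col[m] <- last
    }
    col[is.na(col)] <- variable_means[d]
    values[, d] <- col
  }
  values
}

variable_means_of <- function(records, D) {
  sums <- numeric(D); cnts <- numeric(D)
  for (r in records) {
    obs <- r$mask
    v <- r$values
    v[!obs] <- 0
    sums <- sums + colSums(v)
    cnts <- cnts + colSums(obs)
  }
  m <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
  m
}

#' Apply the package's imputation rule to a dataset
#'
#' Unobserved cells are forward-filled within each record, and leading gaps
#' are filled with the per-variable mean over all observed cells in the
#' dataset. The mask is retained so downstream diagnostics can distinguish
#' observed from imputed cells.
#'
#' @param dataset A [ccts_dataset()].
#' @return The dataset with imputed values.
#' @export
impute_missing <- function(dataset) {
  D <- length(dataset$variables)
  vm <- variable_means_of(dataset$records, D)
  dataset$records <- lapply(dataset$records, function(r) {
    vals <- r$values
    vals[!r$mask] <- NA_real_
    r$values <- impute_values(vals, r$mask, vm)
    r
  })
  dataset
}

#' Read a long-format time-series table and its label table
#'
#' The data file has columns `record_id,time,variable,value` (one row per
#' observed cell); the label file has columns `record_id,label`. Rows are
#' sorted by time within record; cells absent from the file are masked and
#' imputed (forward fill within record, then per-variable dataset mean).
#'
#' @param data_path Path to the long-format observation CSV.
#' @param label_path Path to the label CSV.
#' @param variable_order Optional character vector fixing column layout;
#'   defaults to sorted unique variable names.
#' @return A [ccts_dataset()].
#' @export
load_long_csv <- function(data_path, label_path, variable_order = NULL) {
  if (!file.exists(data_path)) stop("data file not found: ", data_path)
  if (!file.exists(label_path)) stop("label file not found: ", label_path)
  dat <- utils::read.csv(data_path, stringsAsFactors = FALSE)
  lab <- utils::read.csv(label_path, stringsAsFactors = FALSE)
  if (nrow(lab) == 0L) stop("missing labels: label file is empty")
  need <- c("record_id", "time", "variable", "value")
  if (!all(need %in% names(dat)))
    stop("data file must have columns ", paste(need, collapse = ","))
  if (!all(c("record_id", "label") %in% names(lab)))
    stop("label file must have columns record_id,label")
  dup <- duplicated(dat[, c("record_id", "time", "variable")])
  if (any(dup)) {
    d <- dat[which(dup)[1L], ]
    stop(sprintf("duplicate (record, time, variable) triplet: (%s, %s, %s)",
                 d$record_id, format(d$time), d$variable))
  }
  labels <- stats::setNames(as.integer(lab$label), as.character(lab$record_id))
  ids <- unique(as.character(dat$record_id))
  missing_lab <- setdiff(ids, names(labels))
  if (length(missing_lab) > 0L)
    stop("missing labels for records: ", paste(missing_lab, collapse = ", "))
  if (is.null(variable_order)) variable_order <- sort(unique(dat$variable))
  unknown <- setdiff(unique(dat$variable), variable_order)
  if (length(unknown) > 0L)
    stop("variables not in variable_order: ", paste(unknown, collapse = ", "))
  D <- length(variable_order)
  records <- lapply(ids, function(id) {
    rows <- dat[dat$record_id == id, , drop = FALSE]
    times <- sort(unique(rows$time))
    M <- length(times)
    values <- matrix(NA_real_, M, D, dimnames = list(NULL, variable_order))
    mask <- matrix(FALSE, M, D)
    ti <- match(rows$time, times)
    di <- match(rows$variable, variable_order)
    values[cbind(ti, di)] <- rows$value
    mask[cbind(ti, di)] <- TRUE
    structure(list(record_id = id, times = times, values = values,
                   mask = mask, label = labels[[id]]),
              class = "irregular_series")
  })
  impute_missing(ccts_dataset(records, variable_order))
}

#' Write a dataset in the long-format CSV dialect
#'
#' Only observed cells (mask `TRUE`) are written, so
#' `load_long_csv(write_long_csv(x))` reproduces times, mask, label and
#' observed values exactly, and imputed cells identically (same rule applied
#' to the same observed data).
#'
#' @param dataset A [ccts_dataset()].
#' @param data_path,label_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_long_csv <- function(dataset, data_path, label_path) {
  rows <- lapply(dataset$records, function(r) {
    idx <- which(r$mask, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    data.frame(record_id = r$record_id,
               time = r$times[idx[, 1L]],
               variable = dataset$variables[idx[, 2L]],
               value = r$values[cbind(idx[, 1L], idx[, 2L])],
               stringsAsFactors = FALSE)
  })
  dat <- do.call(rbind, rows)
  lab <- data.frame(
    record_id = vapply(dataset$records, `[[`, character(1), "record_id"),
    label = dataset_labels(dataset))
  utils::write.csv(dat, data_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(lab, label_path, row.names = FALSE, quote = FALSE)
  invisible(c(data_path, label_path))
}

prefix_length <- function(M, fraction) max(1L, as.integer(floor(fraction * M + 0.5)))

truncate_series <- function(r, fraction) {
  k <- prefix_length(length(r$times), fraction)
  r$times <- r$times[seq_len(k)]
  r$values <- r$values[seq_len(k), , drop = FALSE]
  r$mask <- r$mask[seq_len(k), , drop = FALSE]
  r
}

#' Build the prefix task stream
#'
#' Each cut fraction defines one task: the dataset of all records truncated at
#' that fraction of their own length (round half up, floored at one
#' observation). Successive tasks stand for the successive data distributions
#' a model must learn without forgetting; the final fraction must be 1 so the
#' last task is the full-length dataset.
#'
#' @param dataset A [ccts_dataset()].
#' @param cut_fractions Increasing numeric vector in `(0, 1]`, ending at 1.
#' @param order_mode `"time"` (given order) or `"similarity"` (greedy
#'   nearest-centroid chaining, see [order_tasks_by_similarity()]).
#' @return An object of class `prefix_task_stream`.
#' @export
build_prefix_stream <- function(dataset, cut_fractions, order_mode = c("time", "similarity")) {
  order_mode <- match.arg(order_mode)
  if (length(cut_fractions) == 0L) stop("cut_fractions must be non-empty")
  if (any(cut_fractions <= 0 | cut_fractions > 1))
    stop("cut fractions must lie in (0, 1]")
  if (is.unsorted(cut_fractions, strictly = TRUE))
    stop("cut fractions must be strictly increasing")
  if (cut_fractions[length(cut_fractions)] != 1)
    stop("the last cut fraction must be 1.0")
  tasks <- lapply(seq_along(cut_fractions), function(m) {
    f <- cut_fractions[m]
    recs <- lapply(dataset$records, truncate_series, fraction = f)
    list(dataset = ccts_dataset(recs, dataset$variables),
         cut_fraction = f, index = m)
  })
  stream <- structure(
    list(tasks = tasks, order_mode = "time",
         permutation = seq_along(tasks)),
    class = "prefix_task_stream")
  if (order_mode == "similarity") stream <- order_tasks_by_similarity(stream)
  stream
}

#' @export
print.prefix_task_stream <- function(x, ...) {
  cat(sprintf("<prefix_task_stream> %d tasks (%s order), fractions: %s\n",
              length(x$tasks), x$order_mode,
              paste(vapply(x$tasks, `[[`, numeric(1), "cut_fraction"),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.prefix_task_stream <- function(x) length(x$tasks)

task_mean_vector <- function(task) {
  D <- length(task$dataset$variables)
  sums <- numeric(D); cnts <- numeric(D)
  for (r in task$dataset$records) {
    v <- r$values; v[!r$mask] <- 0
    sums <- sums + colSums(v)
    cnts <- cnts + colSums(r$mask)
  }
  ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
}

#' Reorder tasks by data similarity
#'
#' Deterministic greedy chaining: task 1 stays first; each subsequent slot
#' takes the remaining task whose per-task mean feature vector (over observed
#' cells) is closest in Euclidean distance to the previous slot's, ties broken
#' by original index. This is a simple stand-in for similarity-based training
#' orders; the permutation is recorded in the result.
#'
#' @param stream A `prefix_task_stream` built in time order.
#' @return The stream with tasks permuted and `order_mode = "similarity"`.
#' @export
order_tasks_by_similarity <- function(stream) {
  n <- length(stream$tasks)
  if (n <= 2L) perm <- seq_len(n)
  else {
    centroids <- lapply(stream$tasks, task_mean_vector)
    perm <- 1L
    remaining <- setdiff(seq_len(n), 1L)
    while (length(remaining) > 0L) {
      cur <- centroids[[perm[length(perm)]]]
      d <- vapply(remaining, function(j) sqrt(sum((centroids[[j]] - cur)^2)),
                  numeric(1))
      # ties broken by original index: which.min takes the first minimum and
      # `remaining` is kept sorted
      pick <- remaining[which.min(d)]
      perm <- c(perm, pick)
      remaining <- setdiff(remaining, pick)
    }
  }
  stream$tasks <- stream$tasks[perm]
  stream$order_mode <- "similarity"
  stream$permutation <- perm
  stream
}
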