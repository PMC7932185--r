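#' Baseline-correct epochs
#'
#' Subtracts, per epoch and sensor, the mean over a pre-stimulus interval
#' (default the 100 ms before picture onset, i.e. `[-100, 0)` ms).
#'
#' @param epochs An [epoch_array()].
#' @param interval Length-2 numeric, half-open interval `[from, to)` in ms.
#' @return The corrected `epoch_array`; the baseline-interval mean is 0 per
#'   epoch and sensor afterwards.
#' @export
baseline_correct <- function(epochs, interval = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_array"))
  sel <- epochs$times >= interval[1L] & epochs$times < interval[2L]
  if (!any(sel)) stop("baseline interval contains no samples", call. = FALSE)
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1L, 2L), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over samples
  epochs
}

#' Drop epochs from trials with erroneous responses
#'
#' @param epochs An [epoch_array()].
#' @param behavior Behavior table with columns `trial` and `correct`
#'   covering every epoch's trial index.
#' @return The `epoch_array` restricted to correct trials, order preserved.
#'   Warns if nothing survives.
#' @export
reject_errors <- function(epochs, behavior) {
  stopifnot(inherits(epochs, "epoch_array"))
  m <- match(epochs$labels$trial, behavior$trial)
  if (anyNA(m)) {
    stop("behavior table is missing trial(s): ",
         paste(utils::head(epochs$labels$trial[is.na(m)]), collapse = ", "),
         call. = FALSE)
  }
  keep <- which(behavior$correct[m])
  if (length(keep) == 0L) warning("all epochs rejected", call. = FALSE)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$labels <- epochs$labels[keep, , drop = FALSE]
  rownames(epochs$labels) <- NULL
  epochs
}

#' Average random groups of same-word epochs
#'
#' Within one condition and for one word category, partitions each word's
#' epochs at random into disjoint groups of `group_size` and replaces every
#' group by its element-wise mean. With 20 correct trials per word and
#' groups of 5 this yields 4 averaged epochs per word and 20 in total — the
#' dataset the decoder trains on. Leftover epochs (count modulo
#' `group_size`) are dropped at random.
#'
#' @param epochs An [epoch_array()] (typically after [reject_errors()]).
#' @param condition Condition whose epochs to use.
#' @param category `"object"` or `"color"`: which planned word labels the
#'   averages.
#' @param group_size Epochs per average (default 5).
#' @param seed Integer seed for the random partition.
#' @return An object of class `averaged_epochs`: list with `data`
#'   (`N x sensors x samples`), `words` (length `N`), `condition`,
#'   `category`, `groups` (per average, the epoch indices — rows of the
#'   input array — that fed it), `times`, `fs`, `participant`.
#' @export
average_groups <- function(epochs, condition, category = c("object", "color"),
                           group_size = 5L, seed) {
  stopifnot(inherits(epochs, "epoch_array"))
  category <- match.arg(category)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot_scalar_number(group_size, "group_size", lower = 1)
  lab_col <- paste0("word_", category)
  word_lab <- epochs$labels[[lab_col]]
  idx_all <- which(epochs$labels$condition == condition & !is.na(word_lab))
  if (length(idx_all) == 0L) {
    stop("no epochs with a ", category, " word in condition ", condition,
         call. = FALSE)
  }
  words <- sort(unique(word_lab[idx_all]))
  counts <- table(word_lab[idx_all])
  if (any(counts < group_size)) {
    stop("fewer than group_size epochs for word(s): ",
         paste(names(counts)[counts < group_size], collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    groups <- list()
    out_words <- character(0)
    for (w in words) {
      idx <- sample(idx_all[word_lab[idx_all] == w])
      n_groups <- length(idx) %/% group_size
      for (g in seq_len(n_groups)) {
        groups[[length(groups) + 1L]] <-
          sort(idx[seq((g - 1L) * group_size + 1L, g * group_size)])
        out_words <- c(out_words, w)
      }
    }
    n_out <- length(groups)
    dm <- dim(epochs$data)
    data <- array(0, dim = c(n_out, dm[2L], dm[3L]))
    for (i in seq_len(n_out)) {
      data[i, , ] <- colMeans(
        array(epochs$data[groups[[i]], , , drop = FALSE],
              dim = c(group_size, dm[2L], dm[3L])),
        dims = 1L)
    }
    structure(list(data = data, words = out_words, condition = condition,
                   category = category, groups = groups,
                   times = epochs$times, fs = epochs$fs,
                   participant = epochs$participant),
              class = "averaged_epochs")
  })
}

#' @export
print.averaged_epochs <- function(x, ...) {
  cat(sprintf(
    "<averaged_epochs %s: %d averages (%s words x groups), condition %s, category %s>\n",
    x$participant, length(x$words), length(unique(x$words)), x$condition,
    x$category))
  invisible(x)
}

#' Valid sliding-window centers
#'
#' All window centers on a regular step grid for which a window of
#' `width_samples` samples lies fully inside the epoch. With 1000 Hz
#' sampling, 100-sample windows and epochs spanning -100 to 700 ms, the
#' 5 ms-step centers run from -50 to 650 ms (141 windows).
#'
#' @param times Sample times in ms (or an `averaged_epochs` object).
#' @param width_samples Window width in samples (default 100).
#' @param step_ms Center step in ms (default 5).
#' @return Numeric vector of centers in ms.
#' @export
window_centers <- function(times, width_samples = 100L, step_ms = 5) {
  if (inherits(times, "averaged_epochs") || inherits(times, "epoch_array")) {
    times <- times$times
  }
  dt <- times[2L] - times[1L]
  half <- width_samples / 2 * dt
  lo <- times[1L] + half
  hi <- times[length(times)] - (width_samples - 1L) * dt + half
  first <- ceiling(lo / step_ms) * step_ms
  if (first > hi) stop("no valid window centers", call. = FALSE)
  seq(first, hi, by = step_ms)
}

#' Extract and flatten one time window as a design matrix
#'
#' Takes the half-open window `[center - w/2, center + w/2)` (in samples)
#' from every averaged epoch and flattens the `sensors x width` slab
#' sensor-major (each sensor's samples contiguous) into one row, giving an
#' `N x (sensors * width_samples)` matrix with the averaged-epoch word
#' labels as row names.
#'
#' @param avg An `averaged_epochs` object.
#' @param center_ms Window center in ms.
#' @param width_samples Window width in samples (default 100).
#' @return A numeric matrix with attributes `sensors`, `width`, `center`.
#' @seealso [unflatten_window()] for the inverse of the flattening.
#' @export
slice_window <- function(avg, center_ms, width_samples = 100L) {
  stopifnot(inherits(avg, "averaged_epochs"))
  dt <- 1000 / avg$fs
  start_ms <- center_ms - width_samples / 2 * dt
  start_idx <- round((start_ms - avg$times[1L]) / dt) + 1L
  if (abs(avg$times[1L] + (start_idx - 1L) * dt - start_ms) > dt / 4) {
    stop("window start does not align with the sample grid", call. = FALSE)
  }
  stop_idx <- start_idx + width_samples - 1L
  if (start_idx < 1L || stop_idx > length(avg$times)) {
    stop("window out of bounds at center ", center_ms, " ms", call. = FALSE)
  }
  n <- dim(avg$data)[1L]
  c_sens <- dim(avg$data)[2L]
  X <- matrix(0, n, c_sens * width_samples)
  for (i in seq_len(n)) {
    X[i, ] <- as.vector(t(avg$data[i, , start_idx:stop_idx]))
  }
  rownames(X) <- avg$words
  attr(X, "sensors") <- c_sens
  attr(X, "width") <- as.integer(width_samples)
  attr(X, "center") <- center_ms
  X
}

#' Restore a flattened window row to a sensors x samples slab
#'
#' @param row One row of a [slice_window()] matrix.
#' @param sensors,width Slab dimensions.
#' @return A `sensors x width` matrix.
#' @export
unflatten_window <- function(row, sensors, width) {
  matrix(row, nrow = sensors, ncol = width, byrow = TRUE)
}
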