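#' Construct an epoch array
#'
#' Container for one participant's epoched sensor recordings: an
#' `epochs x sensors x samples` array, the time axis in ms relative to
#' stimulus onset, and one label row per epoch.
#'
#' @param data Numeric array, `epochs x sensors x samples`, all finite.
#' @param times Numeric vector of sample times in ms (length = samples).
#' @param fs Sampling rate in Hz.
#' @param labels Data frame with one row per epoch; must contain at least
#'   `trial` and `condition` and, for decodable epochs, `word_color` /
#'   `word_object`.
#' @param participant Participant identifier.
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, times, fs, labels, participant = "p01") {
  if (length(dim(data)) != 3L) stop("`data` must be epochs x sensors x samples",
                                    call. = FALSE)
  if (!all(is.finite(data))) stop("`data` must be finite", call. = FALSE)
  if (length(times) != dim(data)[3L]) {
    stop("`times` length must equal the sample count", call. = FALSE)
  }
  if (nrow(labels) != dim(data)[1L]) {
    stop("`labels` must have one row per epoch", call. = FALSE)
  }
  structure(list(data = data, times = as.numeric(times), fs = fs,
                 labels = labels, participant = participant),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf(
    "<epoch_array %s: %d epochs x %d sensors x %d samples, %g-%g ms @ %g Hz>\n",
    x$participant, dm[1L], dm[2L], dm[3L], min(x$times), max(x$times), x$fs))
  cat("  conditions:",
      paste(sprintf("%s(%d)", names(table(x$labels$condition)),
                    table(x$labels$condition)), collapse = " "), "\n")
  invisible(x)
}

#' Default word-signal envelope
#'
#' A raised-cosine bump active 100-400 ms after picture onset for both word
#' categories, the latency range in which planned-word information is
#' typically decodable. Returned as a named list mapping category
#' (`"color"`, `"object"`) to `c(onset, offset)` in ms; per-condition
#' overrides may be supplied as nested entries named by condition.
#'
#' @param onset,offset Active interval bounds in ms.
#' @return A named list suitable for [simulate_participant()]'s `envelope`.
#' @export
default_envelope <- function(onset = 100, offset = 400) {
  list(color = c(onset, offset), object = c(onset, offset))
}

# envelope weight vector over `times` for one category in one condition
envelope_weights <- function(envelope, category, condition, times) {
  spec <- NULL
  if (!is.null(envelope[[condition]])) spec <- envelope[[condition]][[category]]
  if (is.null(spec)) spec <- envelope[[category]]
  if (is.null(spec) || length(spec) != 2L) {
    stop("envelope must give c(onset, offset) for category ", category,
         call. = FALSE)
  }
  if (spec[1L] < min(times) || spec[2L] > max(times) || spec[1L] >= spec[2L]) {
    stop("envelope interval outside epoch bounds", call. = FALSE)
  }
  g <- numeric(length(times))
  act <- times >= spec[1L] & times <= spec[2L]
  g[act] <- 0.5 * (1 - cos(2 * pi * (times[act] - spec[1L]) / (spec[2L] - spec[1L])))
  g
}

# sensors x sensors square root of a random spatial covariance with a
# decaying eigenvalue spectrum (1/k, normalized to mean 1)
spatial_mixing_sqrt <- function(n_sensors) {
  Q <- qr.Q(qr(matrix(stats::rnorm(n_sensors^2), n_sensors)))
  ev <- 1 / seq_len(n_sensors)
  ev <- ev * n_sensors / sum(ev)
  Q %*% (sqrt(ev) * t(Q))
}

# epochs x sensors x samples noise: AR(1) over time per sensor, spatially
# mixed, plus a white component; unit average power overall
simulate_noise <- function(n_epochs, n_sensors, n_samples, ar_coef, white_frac) {
  L <- spatial_mixing_sqrt(n_sensors)
  out <- array(0, dim = c(n_epochs, n_sensors, n_samples))
  innov_sd <- sqrt(1 - ar_coef^2)  # stationary unit variance
  for (e in seq_len(n_epochs)) {
    w <- matrix(stats::rnorm(n_samples * n_sensors, sd = innov_sd), n_samples)
    arn <- stats::filter(w, ar_coef, method = "recursive")
    colored <- L %*% t(matrix(as.numeric(arn), n_samples))
    white <- matrix(stats::rnorm(n_sensors * n_samples), n_sensors)
    out[e, , ] <- sqrt(1 - white_frac) * colored + sqrt(white_frac) * white
  }
  out
}

#' Mean speech-onset latencies by condition
#'
#' Defaults match the observed condition means for the four analysed
#' conditions (adjective 772 ms, noun 792 ms, list 897 ms, phrase 917 ms);
#' the unanalysed color-control condition is given a two-word-utterance
#' value of 940 ms.
#'
#' @return Named numeric vector of latencies in ms.
#' @export
default_speech_onsets <- function() {
  c(adjective = 772, noun = 792, list = 897, phrase = 917, `color-control` = 940)
}

#' Simulate one participant's MEG epochs for a trial schedule
#'
#' Each epoch is the sum, over the words planned on that trial, of a
#' sensor-space projection of the word's embedding modulated by a smooth
#' category-specific envelope, plus structured noise:
#' `sum_w (A %*% y_w) g_w(t) + noise`. The mixing matrix `A`
#' (`sensors x d`) is fixed per participant and either shared across
#' conditions or drawn per condition (`mixing_mode`), controlling whether
#' neural codes generalize across naming contexts. Noise is per-sensor AR(1)
#' over time, spatially correlated through a random covariance with a
#' decaying spectrum, plus a white component, scaled so that the
#' signal-to-noise power ratio inside the envelope-active window equals
#' `snr` (`snr = 0` yields pure noise).
#'
#' A behavior table is generated alongside: response correctness is
#' Bernoulli(`correct_rate`) and speech-onset latencies are Gaussian around
#' condition means.
#'
#' @param schedule Trial schedule from [build_trial_schedule()].
#' @param embeddings An `embedding_table` covering every word in the
#'   schedule.
#' @param snr Signal-to-noise power ratio in the active window; `>= 0`.
#' @param envelope Envelope specification, see [default_envelope()].
#' @param mixing_mode `"shared"` (one mixing matrix for all conditions) or
#'   `"condition-specific"`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param n_sensors Number of sensors (default 208).
#' @param fs Sampling rate in Hz (default 1000).
#' @param tmin,tmax Epoch bounds in ms (default -100 to 700).
#' @param ar_coef AR(1) coefficient of the temporal noise (default 0.95).
#' @param white_frac Fraction of noise power that is white (default 0.3).
#' @param correct_rate Probability of a correct response (default 0.98).
#' @param onset_means Named condition means for speech onset in ms.
#' @param onset_sd Speech-onset standard deviation in ms (default 80).
#' @param return_components If `TRUE`, also return the noise-free signal and
#'   the scaled noise arrays (for calibration checks).
#' @return A list of class `participant_sim` with `epochs` (an
#'   [epoch_array()]) and `behavior` (a data frame with columns `trial`,
#'   `condition`, `block`, `object_shape`, `object_color`,
#'   `background_color`, `correct`, `speech_onset_ms`); plus `signal` and
#'   `noise` if `return_components`.
#' @export
simulate_participant <- function(schedule, embeddings, snr = 1,
                                 envelope = default_envelope(),
                                 mixing_mode = c("shared", "condition-specific"),
                                 seed, n_sensors = 208L, fs = 1000,
                                 tmin = -100, tmax = 700,
                                 ar_coef = 0.95, white_frac = 0.3,
                                 correct_rate = 0.98,
                                 onset_means = default_speech_onsets(),
                                 onset_sd = 80,
                                 return_components = FALSE) {
  mixing_mode <- match.arg(mixing_mode)
  stopifnot(inherits(embeddings, "embedding_table"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot_scalar_number(snr, "snr", lower = 0)
  times <- seq(tmin, tmax, by = 1000 / fs)
  n_samples <- length(times)
  n_epochs <- nrow(schedule)
  d <- embeddings$d
  sched_words <- stats::na.omit(c(schedule$word1, schedule$word2))
  missing_w <- setdiff(unique(sched_words), embeddings$words)
  if (length(missing_w)) {
    stop("schedule words missing from embeddings: ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    conds <- unique(schedule$condition)
    A <- if (mixing_mode == "shared") {
      one <- matrix(stats::rnorm(n_sensors * d, sd = 1 / sqrt(d)), n_sensors)
      stats::setNames(rep(list(one), length(conds)), conds)
    } else {
      stats::setNames(lapply(conds, function(cond) {
        matrix(stats::rnorm(n_sensors * d, sd = 1 / sqrt(d)), n_sensors)
      }), conds)
    }
    # precompute per-(condition, category) envelopes and their active masks
    env <- list()
    for (cond in conds) {
      for (cat in c("color", "object")) {
        env[[paste(cond, cat)]] <- envelope_weights(envelope, cat, cond, times)
      }
    }
    active <- Reduce(`|`, lapply(env, function(g) g > 0))

    word_of <- function(trial_row, which) {
      # category of word1/word2 in each condition
      w <- trial_row[[paste0("word", which)]]
      if (is.na(w)) return(NULL)
      cat <- if (w %in% color_words) "color" else "object"
      list(word = w, category = cat)
    }
    signal <- array(0, dim = c(n_epochs, n_sensors, n_samples))
    if (snr > 0) {
      for (e in seq_len(n_epochs)) {
        tr <- schedule[e, ]
        for (which in 1:2) {
          wi <- word_of(tr, which)
          if (is.null(wi)) next
          topo <- A[[tr$condition]] %*% embeddings$vectors[wi$word, ]
          signal[e, , ] <- signal[e, , ] +
            topo %*% t(env[[paste(tr$condition, wi$category)]])
        }
      }
    }
    noise <- simulate_noise(n_epochs, n_sensors, n_samples, ar_coef, white_frac)
    if (snr > 0) {
      p_sig <- mean(signal[, , active, drop = FALSE]^2)
      p_noise <- mean(noise[, , active, drop = FALSE]^2)
      sigma <- sqrt(p_sig / (snr * p_noise))
    } else {
      sigma <- 1
    }
    noise <- sigma * noise
    data <- signal + noise

    behavior <- data.frame(
      trial = schedule$trial, condition = schedule$condition,
      block = schedule$block,
      object_shape = schedule$object_shape,
      object_color = schedule$object_color,
      background_color = schedule$background_color,
      correct = stats::runif(n_epochs) < correct_rate,
      stringsAsFactors = FALSE
    )
    mu <- onset_means[behavior$condition]
    behavior$speech_onset_ms <- pmax(1, stats::rnorm(n_epochs, mu, onset_sd))
    behavior$speech_onset_ms[!behavior$correct] <- NA_real_

    labels <- schedule[, c("trial", "condition", "block",
                           "word1", "word2", "word_color", "word_object")]
    ep <- epoch_array(data, times, fs, labels,
                      participant = sprintf("sim-seed%d", as.integer(seed)))
    out <- list(epochs = ep, behavior = behavior)
    if (return_components) {
      out$signal <- signal
      out$noise <- noise
      out$active_window <- range(times[active])
    }
    structure(out, class = "participant_sim")
  })
}

#' @export
print.participant_sim <- function(x, ...) {
  cat("<participant_sim>\n")
  print(x$epochs)
  cat(sprintf("  behavior: %d trials, %.1f%% correct\n",
              nrow(x$behavior), 100 * mean(x$behavior$correct)))
  invisible(x)
}
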