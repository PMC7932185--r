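#' Default end-to-end run configuration
#'
#' Two preset scales: `"desk"` (3 participants, 30 sensors, 25 ms window
#' step — runs in minutes on a laptop) and `"full"` (19 participants, 208
#' sensors, 5 ms step — the full study geometry, intended for batch
#' hardware). Every stochastic stage derives its seed from `seed`.
#'
#' @param scale `"desk"` or `"full"`.
#' @param seed Base integer seed.
#' @param out_dir Output directory.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(scale = c("desk", "full"), seed = 1L,
                               out_dir = "megdecode-run") {
  scale <- match.arg(scale)
  desk <- scale == "desk"
  cfg <- list(
    scale = scale,
    seed = as.integer(seed),
    out_dir = out_dir,
    participants = list(n = if (desk) 3L else 19L),
    simulation = list(
      snr = 1, mixing_mode = "shared",
      envelope = list(color = c(100, 400), object = c(100, 400)),
      n_sensors = if (desk) 30L else 208L, fs = 1000,
      ar_coef = 0.95, white_frac = 0.3, correct_rate = 0.98
    ),
    preprocessing = list(band = c(0.1, 40), order = 20L, group_size = 5L),
    decoder = list(grid = default_lambda_grid(), normalization = "train",
                   penalize_bias = FALSE),
    evaluation = list(
      width_samples = 100L, step_ms = if (desk) 25 else 5,
      categories = c("object", "color"),
      contexts = c("isolation", "list", "phrase"),
      regimes = c("isolation/phrase", "isolation/list"),
      tgm = FALSE
    ),
    stats = list(n_perm = if (desk) 500L else 10000L, alpha = 0.05,
                 threshold = 0.05, min_len = 3L,
                 windows = list(c(0, 400), c(400, 650)))
  )
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.list(cfg$stats$windows)) {
    cfg$stats$windows <- lapply(cfg$stats$windows, as.numeric)
  }
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks types, ranges, and cross-field consistency without executing
#' anything (the check behind [run_full()]'s dry-run mode).
#'
#' @param config A `run_config`.
#' @return `config`, invisibly; errors describe the offending field.
#' @export
validate_run_config <- function(config) {
  req <- function(cond, msg) if (!isTRUE(cond)) stop("config: ", msg, call. = FALSE)
  req(is.numeric(config$seed) && length(config$seed) == 1L, "seed must be one integer")
  req(is.numeric(config$participants$n) && config$participants$n >= 1,
      "participants$n must be >= 1")
  sim <- config$simulation
  req(is.numeric(sim$snr) && sim$snr >= 0, "simulation$snr must be >= 0")
  req(sim$mixing_mode %in% c("shared", "condition-specific"),
      "simulation$mixing_mode must be shared or condition-specific")
  req(sim$n_sensors >= 1, "simulation$n_sensors must be >= 1")
  pp <- config$preprocessing
  req(length(pp$band) == 2L && pp$band[1L] > 0 && pp$band[1L] < pp$band[2L] &&
        pp$band[2L] < sim$fs / 2, "preprocessing$band must be 0 < low < high < fs/2")
  req(pp$order >= 1, "preprocessing$order must be >= 1")
  req(pp$group_size >= 1, "preprocessing$group_size must be >= 1")
  dec <- config$decoder
  req(length(dec$grid) >= 1L && all(dec$grid > 0), "decoder$grid must be positive")
  req(dec$normalization %in% c("train", "global"),
      "decoder$normalization must be train or global")
  ev <- config$evaluation
  req(all(ev$categories %in% c("object", "color")), "unknown evaluation$categories")
  req(all(ev$contexts %in% c("isolation", "list", "phrase")),
      "unknown evaluation$contexts")
  for (r in ev$regimes) {
    parts <- strsplit(r, "/", fixed = TRUE)[[1L]]
    req(length(parts) == 2L && all(parts %in% c("isolation", "list", "phrase")),
        paste0("bad regime: ", r))
  }
  req(ev$width_samples >= 2, "evaluation$width_samples must be >= 2")
  st <- config$stats
  req(st$n_perm >= 1, "stats$n_perm must be >= 1")
  req(st$alpha > 0 && st$alpha < 1, "stats$alpha must be in (0,1)")
  invisible(config)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config [%s]: %d participants, %d sensors, snr %g (%s), step %g ms>\n",
    x$scale, x$participants$n, x$simulation$n_sensors, x$simulation$snr,
    x$simulation$mixing_mode, x$evaluation$step_ms))
  invisible(x)
}

# conditions a config needs simulated
conditions_needed <- function(config) {
  ev <- config$evaluation
  ctx <- unique(c(ev$contexts,
                  unlist(strsplit(ev$regimes, "/", fixed = TRUE))))
  conds <- unique(unlist(lapply(ev$categories, function(cat) {
    vapply(ctx, condition_for, "", category = cat)
  })))
  sort(conds)
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate -> band-pass -> baseline -> error rejection ->
#' group averaging -> per-window decoding for every participant, category,
#' and context, then group-level pointwise ANOVA with cluster-permutation
#' correction across the within-condition curves. Writes long-format
#' accuracy CSVs, a cluster-statistics JSON, figure files, and a manifest
#' listing every output with an MD5 content hash. Identical configurations
#' produce identical outputs.
#'
#' @param config A `run_config`.
#' @param dry_run If `TRUE`, validate the configuration and return the run
#'   plan without executing.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `curves` (long-format data frame),
#'   `panel` (participants x category x context x time accuracy array),
#'   `clusters` (a `cluster_result`), `manifest` (data frame of outputs),
#'   and `tgms` when enabled.
#' @export
run_full <- function(config = default_run_config(), dry_run = FALSE,
                     quiet = FALSE) {
  validate_run_config(config)
  conds <- conditions_needed(config)
  plan <- list(conditions = conds,
               participants = config$participants$n,
               windows_per_curve = NA_integer_)
  if (dry_run) return(invisible(plan))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  vocab <- c(object_shapes, color_words)
  emb <- make_embeddings(vocab, d = 50L, seed = child_seed(config$seed, 1L))
  ev <- config$evaluation
  curves <- list()
  tgms <- list()
  for (pi in seq_len(config$participants$n)) {
    pseed <- child_seed(config$seed, 100L + pi)
    say("participant %d/%d: simulate (%s)", pi, config$participants$n,
        paste(conds, collapse = ", "))
    sched <- build_trial_schedule(conds, seed = pseed)
    sim <- simulate_participant(
      sched, emb, snr = config$simulation$snr,
      envelope = config$simulation$envelope,
      mixing_mode = config$simulation$mixing_mode,
      seed = child_seed(pseed, 1L),
      n_sensors = config$simulation$n_sensors,
      fs = config$simulation$fs,
      ar_coef = config$simulation$ar_coef,
      white_frac = config$simulation$white_frac,
      correct_rate = config$simulation$correct_rate)
    say("participant %d: preprocess", pi)
    epo <- bandpass(sim$epochs, config$preprocessing$band[1L],
                    config$preprocessing$band[2L], config$preprocessing$order)
    epo <- baseline_correct(epo)
    epo <- reject_errors(epo, sim$behavior)
    averaged <- list()
    for (cat in ev$categories) {
      for (ctx in unique(c(ev$contexts,
                           unlist(strsplit(ev$regimes, "/", fixed = TRUE))))) {
        cond <- condition_for(cat, ctx)
        key <- paste(cat, ctx)
        if (!is.null(averaged[[key]])) next
        averaged[[key]] <- average_groups(
          epo, cond, cat, config$preprocessing$group_size,
          seed = child_seed(pseed, 2L + match(cat, c("object", "color"))))
      }
    }
    centers <- window_centers(epo$times, ev$width_samples, ev$step_ms)
    for (cat in ev$categories) {
      for (ctx in ev$contexts) {
        say("participant %d: decode %s %s/%s", pi, cat, ctx, ctx)
        cur <- accuracy_timecourse(
          averaged[[paste(cat, ctx)]], emb, centers = centers,
          width_samples = ev$width_samples, grid = config$decoder$grid,
          normalization = config$decoder$normalization,
          penalize_bias = config$decoder$penalize_bias,
          regime = paste0(ctx, "/", ctx))
        curves[[length(curves) + 1L]] <- data.frame(
          participant = pi, regime = cur$regime, category = cat,
          train_ms = cur$centers, test_ms = cur$centers,
          accuracy = cur$accuracy)
      }
      if (isTRUE(ev$tgm)) {
        for (r in ev$regimes) {
          parts <- strsplit(r, "/", fixed = TRUE)[[1L]]
          say("participant %d: TGM %s %s", pi, cat, r)
          tg <- tgm(averaged[[paste(cat, parts[1L])]], emb,
                    test = averaged[[paste(cat, parts[2L])]],
                    train_centers = centers, test_centers = centers,
                    width_samples = ev$width_samples,
                    grid = config$decoder$grid,
                    normalization = config$decoder$normalization,
                    penalize_bias = config$decoder$penalize_bias)
          tgms[[sprintf("p%02d %s %s", pi, cat, r)]] <- tg
          curves[[length(curves) + 1L]] <- data.frame(
            participant = pi, regime = r, category = cat,
            train_ms = rep(centers, times = length(centers)),
            test_ms = rep(centers, each = length(centers)),
            accuracy = as.vector(tg$M))
        }
      }
    }
  }
  curves <- do.call(rbind, curves)

  # group panel from the within-condition curves -> cluster ANOVA
  within <- curves[curves$train_ms == curves$test_ms &
                     sub("/.*", "", curves$regime) ==
                       sub(".*/", "", curves$regime), ]
  panel <- array(
    NA_real_,
    dim = c(config$participants$n, length(ev$categories),
            length(ev$contexts), length(unique(within$train_ms))),
    dimnames = list(NULL, ev$categories, ev$contexts,
                    sort(unique(within$train_ms))))
  for (r in seq_len(nrow(within))) {
    row <- within[r, ]
    panel[row$participant, row$category, sub("/.*", "", row$regime),
          as.character(row$train_ms)] <- row$accuracy
  }
  clusters <- NULL
  if (length(ev$contexts) == 3L && length(ev$categories) == 2L &&
        config$participants$n >= 2L) {
    say("group stats: 2x3 cluster permutation (%d perms)", config$stats$n_perm)
    clusters <- cluster_permutation(
      panel, design = "2x3", times = as.numeric(dimnames(panel)[[4L]]),
      threshold = config$stats$threshold, min_len = config$stats$min_len,
      n_perm = config$stats$n_perm, windows = config$stats$windows,
      seed = child_seed(config$seed, 7L))
  }

  # outputs + manifest
  files <- character(0)
  files <- c(files, write_csv(curves, file.path(config$out_dir, "accuracy.csv")))
  if (!is.null(clusters)) {
    jsonlite::write_json(as.data.frame(clusters),
                         file.path(config$out_dir, "clusters.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, file.path(config$out_dir, "clusters.json"))
  }
  fig <- file.path(config$out_dir, "curves.png")
  grDevices::png(fig, width = 900, height = 600)
  op <- graphics::par(mfrow = c(length(ev$categories), length(ev$contexts)),
                      mar = c(4, 4, 2, 1))
  tmean <- sort(unique(within$train_ms))
  for (cat in ev$categories) {
    for (ctx in ev$contexts) {
      m <- apply(panel[, cat, ctx, , drop = FALSE], 4L, mean)
      graphics::plot(tmean, m, type = "l", lwd = 2, ylim = c(0.3, 1),
                     xlab = "window center (ms)", ylab = "2-vs-2 accuracy",
                     main = sprintf("%s, %s/%s", cat, ctx, ctx))
      graphics::abline(h = 0.5, lty = 2, col = "grey40")
    }
  }
  graphics::par(op)
  grDevices::dev.off()
  files <- c(files, fig)
  if (length(tgms)) {
    figt <- file.path(config$out_dir, "tgms.png")
    grDevices::png(figt, width = 300 * min(length(tgms), 4L),
                   height = 300 * ceiling(length(tgms) / 4))
    op <- graphics::par(mfrow = c(ceiling(length(tgms) / 4),
                                  min(length(tgms), 4L)), mar = c(4, 4, 2, 1))
    for (nm in names(tgms)) plot(tgms[[nm]], main = nm)
    graphics::par(op)
    grDevices::dev.off()
    files <- c(files, figt)
  }
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  files <- c(files, cfg_path)
  manifest <- data.frame(
    file = basename(files),
    md5 = as.vector(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("megdecode")),
         seed = config$seed, scale = config$scale, files = manifest),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in %.1f s", proc.time()[["elapsed"]] - t0)
  invisible(list(curves = curves, panel = panel, clusters = clusters,
                 manifest = manifest, tgms = if (length(tgms)) tgms))
}
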