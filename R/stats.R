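#' Permutation null distribution of 2-vs-2 accuracy
#'
#' Re-runs the full window evaluation on datasets whose epoch-to-word
#' mapping has been randomly shuffled, simulating the absence of any
#' relation between recordings and planned words. By default the word
#' labels of the averaged epochs are shuffled (`level = "averaged"`);
#' `level = "raw"` instead shuffles the word assignment of the raw epochs
#' and re-averages per permutation, which is statistically equivalent under
#' the null but costlier.
#'
#' @param avg An `averaged_epochs` object.
#' @param embeddings An `embedding_table`.
#' @param center Window center in ms.
#' @param n_perm Number of shuffles (default 100).
#' @param seed Integer seed.
#' @param level `"averaged"` (default) or `"raw"`.
#' @param raw For `level = "raw"`: the [epoch_array()] to re-average.
#' @param group_size For `level = "raw"`: epochs per average.
#' @inheritParams window_accuracy
#' @return An object of class `null_distribution`: list with
#'   `null_accuracies` (length `n_perm`), `bw` (Silverman kernel bandwidth),
#'   `center`, `seed`.
#' @export
permutation_null <- function(avg, embeddings, center, n_perm = 100L, seed,
                             level = c("averaged", "raw"), raw = NULL,
                             group_size = 5L, width_samples = 100L,
                             grid = default_lambda_grid(),
                             normalization = "train", penalize_bias = FALSE,
                             distance = "cosine", tie_tol = 1e-12) {
  level <- match.arg(level)
  if (n_perm < 2L) stop("`n_perm` must be at least 2", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (level == "raw" && is.null(raw)) {
    stop("`raw` epochs are required for level = \"raw\"", call. = FALSE)
  }
  acc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      if (level == "averaged") {
        shuffled <- avg
        shuffled$words <- sample(avg$words)
        window_accuracy(shuffled, embeddings, center, width_samples, grid,
                        normalization, penalize_bias, distance, tie_tol)
      } else {
        shuf <- raw
        lab_col <- paste0("word_", avg$category)
        sel <- which(shuf$labels$condition == avg$condition &
                       !is.na(shuf$labels[[lab_col]]))
        shuf$labels[[lab_col]][sel] <- sample(shuf$labels[[lab_col]][sel])
        reavg <- average_groups(shuf, avg$condition, avg$category, group_size,
                                seed = child_seed(seed, i))
        window_accuracy(reavg, embeddings, center, width_samples, grid,
                        normalization, penalize_bias, distance, tie_tol)
      }
    }, numeric(1L))
  })
  bw <- stats::bw.nrd0(acc)
  structure(list(null_accuracies = acc, bw = bw, center = center,
                 n_perm = as.integer(n_perm), seed = seed, level = level),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution: %d shuffles @ %g ms, mean %.4f, sd %.4f, bw %.4f>\n",
    x$n_perm, x$center, mean(x$null_accuracies), stats::sd(x$null_accuracies),
    x$bw))
  invisible(x)
}

#' @export
plot.null_distribution <- function(x, ...) {
  graphics::hist(x$null_accuracies, freq = FALSE, breaks = "FD",
                 xlab = "2-vs-2 accuracy", main = "permutation null", ...)
  dens <- stats::density(x$null_accuracies, bw = x$bw)
  graphics::lines(dens, col = "red3", lwd = 2)
  invisible(x)
}

#' Upper-tail p-value from a kernel-density null
#'
#' Fits a Gaussian kernel density (Silverman's bandwidth) to the null
#' accuracies and returns the mass at and above the observed accuracy —
#' computed exactly as the mean Gaussian upper tail over kernels.
#'
#' @param observed Observed accuracy.
#' @param null A `null_distribution`.
#' @return A p-value in (0, 1).
#' @export
kde_pvalue <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  x <- null$null_accuracies
  if (null$bw <= 0 || stats::sd(x) == 0) {
    stop("degenerate null distribution (all accuracies identical)", call. = FALSE)
  }
  mean(stats::pnorm(observed, mean = x, sd = null$bw, lower.tail = FALSE))
}

#' Benjamini-Yekutieli FDR mask
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence
#' (the Benjamini-Hochberg threshold divided by the harmonic sum
#' `c(m) = sum(1/i)`), applied over one family of p-values (one time
#' course, or one TGM's cells).
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return Logical mask, `TRUE` where rejected.
#' @export
fdr_by <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BY") <= alpha
}

# Balanced two-way fixed-effects ANOVA, vectorized over time.
# arr: participants x A x B x time. Returns list(F, p): 3 x T matrices with
# rows factor_a, factor_b, interaction.
balanced_two_way_F <- function(arr) {
  dm <- dim(arr)
  n <- dm[1L]; a <- dm[2L]; b <- dm[3L]; tt <- dm[4L]
  if (n < 2L) stop("need at least 2 participants per cell", call. = FALSE)
  cell <- colMeans(arr, dims = 1L)                        # a x b x T
  am <- colMeans(aperm(cell, c(2L, 1L, 3L)), dims = 1L)   # a x T
  bm <- colMeans(cell, dims = 1L)                         # b x T
  gm <- colMeans(matrix(cell, a * b, tt))                 # T
  ssa <- n * b * colSums((am - rep(gm, each = a))^2)
  ssb <- n * a * colSums((bm - rep(gm, each = b))^2)
  inter <- cell -
    aperm(array(am, c(a, tt, b)), c(1L, 3L, 2L)) -
    aperm(array(bm, c(b, tt, a)), c(3L, 1L, 2L)) +
    aperm(array(gm, c(tt, a, b)), c(2L, 3L, 1L))
  ssab <- n * colSums(matrix(inter^2, a * b, tt))
  resid <- arr - aperm(array(cell, c(a, b, tt, n)), c(4L, 1L, 2L, 3L))
  sse <- colSums(matrix(resid^2, n * a * b, tt))
  dfa <- a - 1L; dfb <- b - 1L; dfab <- dfa * dfb; dfe <- a * b * (n - 1L)
  mse <- sse / dfe
  Fm <- rbind(factor_a = (ssa / dfa) / mse,
              factor_b = (ssb / dfb) / mse,
              interaction = (ssab / dfab) / mse)
  pm <- rbind(factor_a = stats::pf(Fm[1L, ], dfa, dfe, lower.tail = FALSE),
              factor_b = stats::pf(Fm[2L, ], dfb, dfe, lower.tail = FALSE),
              interaction = stats::pf(Fm[3L, ], dfab, dfe, lower.tail = FALSE))
  list(F = Fm, p = pm, df = c(dfa = dfa, dfb = dfb, dfab = dfab, dfe = dfe))
}

# validate/subset a participants x category x context [x time] panel
as_panel_array <- function(panel, design, contexts = NULL) {
  if (length(dim(panel)) == 3L) {
    dn <- dimnames(panel)
    dim(panel) <- c(dim(panel), 1L)
    if (!is.null(dn)) dimnames(panel) <- c(dn, list(NULL))
  }
  if (length(dim(panel)) != 4L) {
    stop("panel must be participants x category x context [x time]", call. = FALSE)
  }
  if (design == "2x2") {
    if (dim(panel)[3L] > 2L) {
      if (is.null(contexts)) {
        stop("a 2x2 design needs `contexts` naming the two contexts", call. = FALSE)
      }
      ix <- match(contexts, dimnames(panel)[[3L]])
      if (anyNA(ix)) stop("unknown context in `contexts`", call. = FALSE)
      panel <- panel[, , ix, , drop = FALSE]
    }
    if (dim(panel)[3L] != 2L) stop("2x2 design needs exactly 2 contexts", call. = FALSE)
  } else if (dim(panel)[3L] != 3L) {
    stop("2x3 design needs exactly 3 contexts", call. = FALSE)
  }
  if (dim(panel)[2L] != 2L) stop("panel must have 2 word categories", call. = FALSE)
  if (any(!is.finite(panel))) stop("panel has missing cells (unbalanced design)",
                                   call. = FALSE)
  panel
}

#' Pointwise factorial ANOVA on participant accuracies
#'
#' Two-way fixed-effects ANOVA (word category x naming context) treating
#' participants as replicates, applied to the 2-vs-2 accuracies at one time
#' point: the omnibus `2 x 3` design over isolation, list and phrase, or a
#' targeted `2 x 2` contrasting isolation with one two-word context.
#'
#' @param panel Numeric array `participants x category x context` (with
#'   dimnames), accuracies at one time point.
#' @param design `"2x3"` (default) or `"2x2"`.
#' @param contexts For `"2x2"` with a 3-context panel: the two context
#'   names to contrast.
#' @return A data frame with one row per effect (`category`, `context`,
#'   `interaction`): `F`, `df1`, `df2`, `p`.
#' @export
pointwise_anova <- function(panel, design = c("2x3", "2x2"), contexts = NULL) {
  design <- match.arg(design)
  arr <- as_panel_array(panel, design, contexts)
  res <- balanced_two_way_F(arr)
  data.frame(
    effect = c("category", "context", "interaction"),
    F = res$F[, 1L],
    df1 = c(res$df[["dfa"]], res$df[["dfb"]], res$df[["dfab"]]),
    df2 = res$df[["dfe"]],
    p = res$p[, 1L],
    row.names = NULL
  )
}

# runs of TRUE of length >= min_len; returns list of index ranges
threshold_runs <- function(flag, min_len) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  Map(c, starts[keep], ends[keep])
}

# clusters (start_idx, end_idx, mass) within one index window
find_clusters <- function(pvec, fvec, idx, threshold, min_len) {
  flag <- pvec[idx] < threshold
  runs <- threshold_runs(flag, min_len)
  lapply(runs, function(r) {
    sel <- idx[r[1L]:r[2L]]
    c(start = sel[1L], end = sel[length(sel)], mass = sum(fvec[sel]))
  })
}

#' Cluster-based permutation test over time
#'
#' Corrects the pointwise factorial ANOVA for multiple comparisons over
#' time. Clusters are runs of at least `min_len` adjacent time points with
#' pointwise `p < threshold`; each cluster's statistic is the sum of its
#' F-values. The null is formed by permuting the category/context cell
#' labels within each participant `n_perm` times and recording, per effect
#' and search window, the maximum cluster mass; the cluster p-value is
#' `(1 + #{perm max >= observed}) / (n_perm + 1)`. The largest observed
#' cluster per search window (ties: earliest onset) is reported, with the
#' remaining clusters listed for completeness.
#'
#' @param panel Numeric array `participants x category x context x time`
#'   with time dimnames or a `times` argument in ms.
#' @param design `"2x3"` or `"2x2"`.
#' @param contexts Passed to [pointwise_anova()] for `"2x2"`.
#' @param times Time axis in ms (defaults to the panel's 4th dimnames).
#' @param threshold Pointwise p threshold (default 0.05).
#' @param min_len Minimum cluster length in time points (default 3).
#' @param n_perm Number of permutations (default 10000).
#' @param windows List of `c(start, end)` search windows in ms (default
#'   0-400 and 400-650 ms, for earlier and later effects).
#' @param seed Integer seed.
#' @return An object of class `cluster_result`: a data frame with one row
#'   per observed cluster (`effect`, `window_start`, `window_end`,
#'   `cluster_start`, `cluster_end`, `mass`, `p`, `is_largest`); `p` is
#'   computed for the largest cluster per effect and window (`NA`
#'   elsewhere).
#' @export
cluster_permutation <- function(panel, design = c("2x3", "2x2"),
                                contexts = NULL, times = NULL,
                                threshold = 0.05, min_len = 3L,
                                n_perm = 10000L,
                                windows = list(c(0, 400), c(400, 650)),
                                seed) {
  design <- match.arg(design)
  if (n_perm < 1L) stop("`n_perm` must be at least 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  arr <- as_panel_array(panel, design, contexts)
  dm <- dim(arr)
  if (is.null(times)) times <- as.numeric(dimnames(panel)[[4L]])
  if (length(times) != dm[4L] || anyNA(times)) {
    stop("panel needs a time axis (4th dimnames or `times`)", call. = FALSE)
  }
  win_idx <- lapply(windows, function(w) {
    ix <- which(times >= w[1L] & times <= w[2L])
    if (length(ix) == 0L) stop("search window outside the time grid", call. = FALSE)
    ix
  })
  effects <- c("category", "context", "interaction")
  obs <- balanced_two_way_F(arr)
  observed <- list()
  for (e in seq_along(effects)) {
    for (w in seq_along(windows)) {
      cl <- find_clusters(obs$p[e, ], obs$F[e, ], win_idx[[w]],
                          threshold, min_len)
      observed[[paste(e, w)]] <- cl
    }
  }
  # permutation null of max cluster mass per effect x window
  n_cells <- dm[2L] * dm[3L]
  perm_max <- with_seed(seed, {
    out <- array(0, dim = c(length(effects), length(windows), n_perm))
    parr <- arr
    for (b in seq_len(n_perm)) {
      for (pp in seq_len(dm[1L])) {
        # permute the category x context cell labels of this participant
        perm <- sample(n_cells)
        cells <- matrix(arr[pp, , , ], nrow = n_cells)  # cells x T
        parr[pp, , , ] <- array(cells[perm, ], dim = c(dm[2L], dm[3L], dm[4L]))
      }
      pr <- balanced_two_way_F(parr)
      for (e in seq_along(effects)) {
        for (w in seq_along(windows)) {
          cl <- find_clusters(pr$p[e, ], pr$F[e, ], win_idx[[w]],
                              threshold, min_len)
          out[e, w, b] <- if (length(cl)) max(vapply(cl, `[[`, 0, "mass")) else 0
        }
      }
    }
    out
  })
  rows <- list()
  for (e in seq_along(effects)) {
    for (w in seq_along(windows)) {
      cl <- observed[[paste(e, w)]]
      if (length(cl) == 0L) next
      masses <- vapply(cl, `[[`, 0, "mass")
      largest <- which(masses == max(masses))[1L]  # tie -> earliest onset
      for (ci in seq_along(cl)) {
        pv <- if (ci == largest) {
          (1 + sum(perm_max[e, w, ] >= masses[ci])) / (n_perm + 1)
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          effect = effects[e],
          window_start = windows[[w]][1L], window_end = windows[[w]][2L],
          cluster_start = times[cl[[ci]][["start"]]],
          cluster_end = times[cl[[ci]][["end"]]],
          mass = masses[ci], p = pv, is_largest = ci == largest
        )
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame(
    effect = character(0), window_start = numeric(0), window_end = numeric(0),
    cluster_start = numeric(0), cluster_end = numeric(0),
    mass = numeric(0), p = numeric(0), is_largest = logical(0)
  )
  attr(res, "n_perm") <- as.integer(n_perm)
  attr(res, "threshold") <- threshold
  attr(res, "min_len") <- as.integer(min_len)
  class(res) <- c("cluster_result", "data.frame")
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d cluster(s), %d permutations>\n",
              nrow(x), attr(x, "n_perm")))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 4L)
  invisible(x)
}
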