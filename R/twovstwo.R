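#' Enumerate valid 2-vs-2 pairs
#'
#' All unordered pairs of averaged epochs whose word labels differ. Pairs
#' with equal labels are degenerate for the 2-vs-2 test (their two target
#' vectors coincide, so the two summed distances are equal by construction)
#' and are excluded: 5 words x 4 averages give choose(20, 2) = 190 pairs of
#' which 30 are degenerate, leaving 160 valid pairs.
#'
#' @param labels Character vector of word labels.
#' @return Integer matrix with columns `i`, `j` (`i < j`), rows in
#'   lexicographic order.
#' @export
enumerate_valid_pairs <- function(labels) {
  n <- length(labels)
  if (n == 0L) stop("`labels` must be non-empty", call. = FALSE)
  if (n < 2L) return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  idx <- utils::combn(n, 2L)
  keep <- labels[idx[1L, ]] != labels[idx[2L, ]]
  out <- t(idx[, keep, drop = FALSE])
  colnames(out) <- c("i", "j")
  out
}

# distance used by the 2-vs-2 test
tvt_distance <- function(u, v, distance) {
  switch(distance,
    cosine = cosine_distance(u, v),
    euclidean = sqrt(sum((u - v)^2)),
    stop("unknown distance: ", distance, call. = FALSE)
  )
}

#' Score one 2-vs-2 comparison
#'
#' The test passes (score 1) when each prediction is closer to its own true
#' vector than to the other's:
#' `d(pred_a, true_a) + d(pred_b, true_b) < d(pred_a, true_b) + d(pred_b, true_a)`.
#' A failing comparison scores 0; equal sums (within `tie_tol`) score 0.5.
#'
#' @param pred_a,pred_b Predicted embedding vectors.
#' @param true_a,true_b True embedding vectors.
#' @param distance `"cosine"` (default) or `"euclidean"`.
#' @param tie_tol Absolute tolerance for declaring the two sums equal.
#' @return 0, 0.5, or 1.
#' @export
two_vs_two_score <- function(pred_a, pred_b, true_a, true_b,
                             distance = c("cosine", "euclidean"),
                             tie_tol = 1e-12) {
  distance <- match.arg(distance)
  lhs <- tvt_distance(pred_a, true_a, distance) +
    tvt_distance(pred_b, true_b, distance)
  rhs <- tvt_distance(pred_a, true_b, distance) +
    tvt_distance(pred_b, true_a, distance)
  if (abs(lhs - rhs) <= tie_tol) 0.5 else if (lhs < rhs) 1 else 0
}

# Fit-and-score every valid pair for a train window matrix X (N x p raw) and
# prediction features Xtest (defaults to X: same-window evaluation).
# Returns the mean 2-vs-2 score.
pair_loop_accuracy <- function(X, Xtest, Y, pairs, grid, normalization,
                               penalize_bias, distance, tie_tol) {
  if (nrow(pairs) == 0L) stop("no valid pairs to score", call. = FALSE)
  scores <- numeric(nrow(pairs))
  glob <- if (normalization == "global") normalize_and_bias(X, Xtest) else NULL
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1L]; b <- pairs[k, 2L]
    tr <- setdiff(seq_len(nrow(X)), c(a, b))
    if (normalization == "train") {
      nb <- normalize_and_bias(X[tr, , drop = FALSE],
                               Xtest[c(a, b), , drop = FALSE])
      fit <- fit_ridge_loocv(nb$train, Y[tr, , drop = FALSE], grid,
                             penalize_bias)
      pred <- predict(fit, nb$test)
    } else {
      Xtr <- glob$train$X[tr, , drop = FALSE]
      fit <- fit_ridge_loocv(Xtr, Y[tr, , drop = FALSE], grid, penalize_bias)
      pred <- predict(fit, glob$test$X[c(a, b), , drop = FALSE])
    }
    scores[k] <- two_vs_two_score(pred[1L, ], pred[2L, ], Y[a, ], Y[b, ],
                                  distance, tie_tol = tie_tol)
  }
  mean(scores)
}

# look up the embedding target matrix for an averaged set
targets_for <- function(avg, embeddings) {
  missing_w <- setdiff(unique(avg$words), embeddings$words)
  if (length(missing_w)) {
    stop("words missing from embeddings: ", paste(missing_w, collapse = ", "),
         call. = FALSE)
  }
  embeddings$vectors[avg$words, , drop = FALSE]
}

#' 2-vs-2 decoding accuracy at one time window
#'
#' For every valid pair of averaged epochs: hold the two out, normalize and
#' fit the ridge decoder on the remaining `N - 2`, predict the two held-out
#' embedding vectors, and score the 2-vs-2 comparison. Returns the mean
#' score over pairs.
#'
#' @param avg An `averaged_epochs` object (`N >= 4`).
#' @param embeddings An `embedding_table` covering the words of `avg`.
#' @param center Window center in ms.
#' @param width_samples Window width in samples (default 100).
#' @param grid Ridge lambda grid.
#' @param normalization `"train"` (statistics from the N-2 training rows
#'   only; default) or `"global"` (statistics from all N rows).
#' @param penalize_bias Passed to [fit_ridge_loocv()].
#' @param distance,tie_tol Passed to [two_vs_two_score()].
#' @return Mean 2-vs-2 accuracy in `[0, 1]`.
#' @export
window_accuracy <- function(avg, embeddings, center, width_samples = 100L,
                            grid = default_lambda_grid(),
                            normalization = c("train", "global"),
                            penalize_bias = FALSE,
                            distance = "cosine", tie_tol = 1e-12) {
  normalization <- match.arg(normalization)
  if (length(avg$words) < 4L) stop("need at least 4 averaged epochs", call. = FALSE)
  X <- slice_window(avg, center, width_samples)
  Y <- targets_for(avg, embeddings)
  pairs <- enumerate_valid_pairs(avg$words)
  pair_loop_accuracy(X, X, Y, pairs, grid, normalization, penalize_bias,
                     distance, tie_tol)
}

#' 2-vs-2 accuracy time course
#'
#' [window_accuracy()] evaluated at every window center.
#'
#' @inheritParams window_accuracy
#' @param centers Window centers in ms (default the full grid from
#'   [window_centers()]).
#' @param step_ms Center step when `centers` is not given.
#' @param regime Label for the train/test regime, e.g. `"phrase/phrase"`.
#' @return An object of class `accuracy_curve`: list with `centers`,
#'   `accuracy`, and metadata (`participant`, `category`, `regime`).
#' @export
accuracy_timecourse <- function(avg, embeddings, centers = NULL,
                                width_samples = 100L, step_ms = 5,
                                grid = default_lambda_grid(),
                                normalization = "train",
                                penalize_bias = FALSE,
                                distance = "cosine", tie_tol = 1e-12,
                                regime = paste0(avg$condition, "/", avg$condition)) {
  if (is.null(centers)) centers <- window_centers(avg, width_samples, step_ms)
  acc <- vapply(centers, function(ct) {
    window_accuracy(avg, embeddings, ct, width_samples, grid, normalization,
                    penalize_bias, distance, tie_tol)
  }, numeric(1L))
  structure(list(centers = centers, accuracy = acc,
                 participant = avg$participant, category = avg$category,
                 regime = regime),
            class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf(
    "<accuracy_curve %s %s [%s]: %d windows, mean %.3f, max %.3f @ %g ms>\n",
    x$participant, x$category, x$regime, length(x$centers),
    mean(x$accuracy), max(x$accuracy), x$centers[which.max(x$accuracy)]))
  invisible(x)
}

#' @export
plot.accuracy_curve <- function(x, ..., chance = 0.5) {
  graphics::plot(x$centers, x$accuracy, type = "l", lwd = 2,
                 xlab = "window center (ms)", ylab = "2-vs-2 accuracy",
                 ylim = range(c(x$accuracy, 0.4, 0.6)),
                 main = sprintf("%s, %s", x$regime, x$category), ...)
  graphics::abline(h = chance, lty = 2, col = "grey40")
  invisible(x)
}

#' Temporal generalization matrix
#'
#' Accuracy of decoders trained at one time window and tested at another.
#' Within condition (`test` missing or identical context), the same two
#' averaged epochs are held out of the training window `i` and scored at the
#' testing window `j`, so the diagonal equals the same-window accuracy
#' curve. Across conditions, train and test epochs come from disjoint trial
#' sets, so the decoder is trained on *all* `N` training-context epochs at
#' window `i` and scored on every valid pair of the test context at window
#' `j`.
#'
#' @param train An `averaged_epochs` object (training context).
#' @param embeddings An `embedding_table`.
#' @param test An `averaged_epochs` object for the testing context; omit for
#'   a within-condition TGM.
#' @param train_centers,test_centers Window centers in ms (default: full
#'   grid at `step_ms`).
#' @inheritParams window_accuracy
#' @param step_ms Center step when center grids are not given.
#' @return An object of class `tgm`: list with `M`
#'   (`train_centers x test_centers` accuracy matrix), the center grids,
#'   `train_context`, `test_context`, `category`, `across`.
#' @export
tgm <- function(train, embeddings, test = NULL,
                train_centers = NULL, test_centers = NULL,
                width_samples = 100L, step_ms = 5,
                grid = default_lambda_grid(), normalization = "train",
                penalize_bias = FALSE, distance = "cosine", tie_tol = 1e-12) {
  across <- !is.null(test)
  if (!across) test <- train
  if (!setequal(unique(train$words), unique(test$words))) {
    stop("train and test contexts have mismatched vocabularies", call. = FALSE)
  }
  if (is.null(train_centers)) train_centers <- window_centers(train, width_samples, step_ms)
  if (is.null(test_centers)) test_centers <- window_centers(test, width_samples, step_ms)
  Ytr <- targets_for(train, embeddings)
  Yte <- targets_for(test, embeddings)
  test_slabs <- lapply(test_centers, function(ct) slice_window(test, ct, width_samples))
  M <- matrix(NA_real_, length(train_centers), length(test_centers),
              dimnames = list(train_centers, test_centers))
  if (!across) {
    pairs <- enumerate_valid_pairs(train$words)
    n <- length(train$words)
    for (ti in seq_along(train_centers)) {
      Xi <- slice_window(train, train_centers[ti], width_samples)
      glob <- if (normalization == "global") normalize_and_bias(Xi)
      scores <- matrix(0, nrow(pairs), length(test_centers))
      for (k in seq_len(nrow(pairs))) {
        a <- pairs[k, 1L]; b <- pairs[k, 2L]
        tr <- setdiff(seq_len(n), c(a, b))
        if (normalization == "train") {
          nb <- normalize_and_bias(Xi[tr, , drop = FALSE])
          fit <- fit_ridge_loocv(nb$train, Ytr[tr, , drop = FALSE], grid,
                                 penalize_bias)
          ctr <- nb$train$center; scl <- nb$train$scale
        } else {
          fit <- fit_ridge_loocv(glob$train$X[tr, , drop = FALSE],
                                 Ytr[tr, , drop = FALSE], grid, penalize_bias)
          ctr <- glob$train$center; scl <- glob$train$scale
        }
        for (tj in seq_along(test_centers)) {
          Xj <- test_slabs[[tj]]
          Xjn <- sweep(sweep(Xj[c(a, b), , drop = FALSE], 2L, ctr),
                       2L, scl, "/")
          pred <- predict(fit, cbind(Xjn, 1))
          scores[k, tj] <- two_vs_two_score(pred[1L, ], pred[2L, ],
                                            Ytr[a, ], Ytr[b, ],
                                            distance, tie_tol = tie_tol)
        }
      }
      M[ti, ] <- colMeans(scores)
    }
  } else {
    pairs <- enumerate_valid_pairs(test$words)
    for (ti in seq_along(train_centers)) {
      Xi <- slice_window(train, train_centers[ti], width_samples)
      nb <- normalize_and_bias(Xi)
      fit <- fit_ridge_loocv(nb$train, Ytr, grid, penalize_bias)
      for (tj in seq_along(test_centers)) {
        Xj <- test_slabs[[tj]]
        Xjn <- sweep(sweep(Xj, 2L, nb$train$center), 2L, nb$train$scale, "/")
        pred <- predict(fit, cbind(Xjn, 1))
        sc <- vapply(seq_len(nrow(pairs)), function(k) {
          a <- pairs[k, 1L]; b <- pairs[k, 2L]
          two_vs_two_score(pred[a, ], pred[b, ], Yte[a, ], Yte[b, ],
                           distance, tie_tol = tie_tol)
        }, numeric(1L))
        M[ti, tj] <- mean(sc)
      }
    }
  }
  structure(list(M = M, train_centers = train_centers,
                 test_centers = test_centers,
                 train_context = train$condition,
                 test_context = test$condition,
                 category = train$category, across = across),
            class = "tgm")
}

#' @export
print.tgm <- function(x, ...) {
  cat(sprintf(
    "<tgm %s/%s %s: %d x %d windows, mean %.3f, max %.3f>\n",
    x$train_context, x$test_context, x$category,
    nrow(x$M), ncol(x$M), mean(x$M), max(x$M)))
  invisible(x)
}

#' @export
plot.tgm <- function(x, ..., zlim = c(0, 1)) {
  graphics::image(x$train_centers, x$test_centers, x$M, zlim = zlim,
                  xlab = "training window center (ms)",
                  ylab = "testing window center (ms)",
                  main = sprintf("%s/%s, %s", x$train_context, x$test_context,
                                 x$category),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::abline(0, 1, col = "white", lty = 2)
  invisible(x)
}
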