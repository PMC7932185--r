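#' Default regularization grid
#'
#' Thirteen log-spaced values from 1e-4 to 1e8.
#'
#' @return Numeric vector.
#' @export
default_lambda_grid <- function() 10^seq(-4, 8, length.out = 13L)

#' Column-normalize a design matrix and append a bias column
#'
#' Centers and scales every column of the training matrix to mean 0 and
#' standard deviation 1 (population convention, divide by N), appends an
#' unnormalized column of ones for the bias, and applies the *training*
#' statistics to the test matrix so no test information leaks into the fit.
#' Zero-variance columns are centered but not scaled.
#'
#' @param train Numeric matrix, `N_train x p`, N_train >= 1.
#' @param test Optional numeric matrix, `N_test x p`.
#' @return A list with elements `train` and `test` (or `NULL`), each of
#'   class `design_matrix`: a list with `X` (the `N x (p+1)` normalized
#'   matrix, bias last), `center`, `scale`.
#' @export
normalize_and_bias <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 1L) stop("empty training matrix", call. = FALSE)
  if (!is.null(test)) {
    test <- as.matrix(test)
    if (ncol(test) != ncol(train)) {
      stop("train/test column counts differ", call. = FALSE)
    }
  }
  center <- colMeans(train)
  sc <- sqrt(colMeans(sweep(train, 2L, center)^2))  # population sd
  sc[sc < 1e-12] <- 1
  dm <- function(x) {
    Xn <- sweep(sweep(x, 2L, center), 2L, sc, "/")
    structure(list(X = cbind(Xn, 1), center = center, scale = sc),
              class = "design_matrix")
  }
  list(train = dm(train), test = if (!is.null(test)) dm(test))
}

# Coerce design_matrix / plain matrix (bias column last) to the X matrix.
design_X <- function(x) {
  if (inherits(x, "design_matrix")) x$X else as.matrix(x)
}

#' Ridge regression onto embeddings with per-dimension leave-one-out lambda
#'
#' Fits `d` independent L2-regularized linear regressions from a normalized
#' design matrix to each embedding dimension,
#' `w_j = (X'X + lambda_j I)^-1 X' y_j`, selecting `lambda_j` per dimension
#' as the grid value minimizing leave-one-out mean squared error (ties go to
#' the smallest lambda). A single thin SVD of the design is shared across
#' all grid values and output dimensions; LOO errors use the exact
#' hat-matrix identity `e_i / (1 - H_ii(lambda))` rather than N refits.
#'
#' By default the bias (the appended ones column) is not penalized: the
#' problem is solved on internally re-centered columns and the intercept
#' recovered in closed form. Set `penalize_bias = TRUE` to penalize the full
#' weight vector, bias included.
#'
#' @param train A `design_matrix` from [normalize_and_bias()] (or a plain
#'   matrix whose last column is the bias).
#' @param targets Numeric `N x d` matrix of embedding targets.
#' @param grid Candidate lambda values, all positive.
#' @param penalize_bias Include the bias weight in the penalty?
#' @return An object of class `ridge_decoder`: list with `W`
#'   (`(p+1) x d` weights, bias last row), `lambdas` (length `d`), `loocv`
#'   (`length(grid) x d` LOO mean squared errors), `grid`, `penalize_bias`.
#' @export
fit_ridge_loocv <- function(train, targets, grid = default_lambda_grid(),
                            penalize_bias = FALSE) {
  X <- design_X(train)
  Y <- as.matrix(targets)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 training rows", call. = FALSE)
  if (nrow(Y) != n) stop("targets must have one row per training row", call. = FALSE)
  if (length(grid) == 0L || any(grid <= 0)) {
    stop("`grid` must be non-empty with positive values", call. = FALSE)
  }
  grid <- sort(unique(as.numeric(grid)))
  p <- ncol(X) - 1L
  d_out <- ncol(Y)

  if (penalize_bias) {
    Xw <- X
    Yw <- Y
    mc <- NULL
  } else {
    # unpenalized bias: solve on column-centered data, recover intercept
    mc <- colMeans(X[, seq_len(p), drop = FALSE])
    Xw <- sweep(X[, seq_len(p), drop = FALSE], 2L, mc)
    my <- colMeans(Y)
    Yw <- sweep(Y, 2L, my)
  }
  sv <- svd(Xw)
  if (max(sv$d) < 1e-12) stop("degenerate all-zero design matrix", call. = FALSE)
  dvals <- sv$d
  d2 <- dvals^2
  C <- crossprod(sv$u, Yw)  # k x d
  loocv <- matrix(NA_real_, length(grid), d_out,
                  dimnames = list(format(grid, digits = 3L), NULL))
  for (g in seq_along(grid)) {
    f <- d2 / (d2 + grid[g])
    h <- rowSums(sweep(sv$u^2, 2L, f, "*"))
    if (!penalize_bias) h <- h + 1 / n  # intercept's hat contribution
    resid <- Yw - sv$u %*% (f * C)
    denom <- 1 - h
    if (any(denom < 1e-10)) {
      loocv[g, ] <- Inf  # interpolating fit: LOO undefined/unstable
    } else {
      loocv[g, ] <- colMeans((resid / denom)^2)
    }
  }
  best <- apply(loocv, 2L, which.min)  # first minimum = smallest lambda
  lambdas <- grid[best]

  W <- matrix(0, p + 1L, d_out)
  for (g in unique(best)) {
    j <- which(best == g)
    shrink <- dvals / (d2 + grid[g])
    wj <- sv$v %*% (shrink * C[, j, drop = FALSE])
    if (penalize_bias) {
      W[, j] <- wj
    } else {
      W[seq_len(p), j] <- wj
      W[p + 1L, j] <- my[j] - as.vector(crossprod(wj, mc))
    }
  }
  structure(list(W = W, lambdas = lambdas, loocv = loocv, grid = grid,
                 penalize_bias = penalize_bias, p = p, d = d_out, n = n),
            class = "ridge_decoder")
}

#' @export
print.ridge_decoder <- function(x, ...) {
  cat(sprintf(
    "<ridge_decoder: %d features (+bias) -> %d dimensions, N = %d>\n",
    x$p, x$d, x$n))
  cat("  lambda selected by LOOCV per dimension:\n")
  print(table(x$lambdas))
  invisible(x)
}

#' @export
coef.ridge_decoder <- function(object, ...) object$W

#' Predict embedding vectors for new windows
#'
#' `h_j(X) = X w_j` for every dimension: the matrix product of the
#' normalized test rows (bias included) with the fitted weights.
#'
#' @param object A `ridge_decoder`.
#' @param newdata A `design_matrix` (the `test` element of
#'   [normalize_and_bias()]) or a plain matrix with the bias column last.
#' @param ... Unused.
#' @return An `N_test x d` matrix of predicted embedding vectors.
#' @export
predict.ridge_decoder <- function(object, newdata, ...) {
  X <- design_X(newdata)
  if (ncol(X) != object$p + 1L) {
    stop("newdata has ", ncol(X), " columns; expected ", object$p + 1L,
         call. = FALSE)
  }
  X %*% object$W
}
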