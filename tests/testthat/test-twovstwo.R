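test_that("pair enumeration matches the design combinatorics", {
  labels <- rep(c("bag", "bell", "cane", "lamp", "plane"), each = 4L)
  pairs <- enumerate_valid_pairs(labels)
  expect_equal(nrow(pairs), 160L)
  expect_equal(ncol(utils::combn(20L, 2L)), 190L)        # total pairs
  expect_equal(190L - nrow(pairs), 30L)                  # degenerate pairs
  expect_true(all(labels[pairs[, 1L]] != labels[pairs[, 2L]]))
  expect_true(all(pairs[, 1L] < pairs[, 2L]))
  # 3 words x 2 samples: C(6,2) = 15 minus 3 same-word pairs
  expect_equal(nrow(enumerate_valid_pairs(rep(c("a", "b", "c"), 2L))), 12L)
  expect_equal(nrow(enumerate_valid_pairs(c("a", "a"))), 0L)
})

test_that("pair enumeration equals brute-force set construction", {
  set.seed(99)
  for (rep in 1:20) {
    labels <- sample(letters[1:4], sample(2:9, 1L), replace = TRUE)
    pairs <- enumerate_valid_pairs(labels)
    brute <- list()
    for (i in seq_along(labels)) for (j in seq_along(labels)) {
      if (i < j && labels[i] != labels[j]) {
        brute[[length(brute) + 1L]] <- c(i, j)
      }
    }
    expect_equal(unname(pairs),
                 if (length(brute)) do.call(rbind, brute)
                 else matrix(integer(0), 0L, 2L))
  }
})

test_that("the 2-vs-2 score awards 1, 0, or 0.5 by the distance criterion", {
  ta <- c(1, 0, 0); tb <- c(0, 1, 0)
  expect_equal(two_vs_two_score(ta, tb, ta, tb), 1)        # perfect match
  expect_equal(two_vs_two_score(tb, ta, ta, tb), 0)        # swapped
  expect_equal(two_vs_two_score(ta, ta, ta, tb), 0.5)      # equal sums
  # swapping the pair order leaves the score unchanged
  set.seed(7)
  for (rep in 1:20) {
    pa <- rnorm(5); pb <- rnorm(5); ya <- rnorm(5); yb <- rnorm(5)
    expect_equal(two_vs_two_score(pa, pb, ya, yb),
                 two_vs_two_score(pb, pa, yb, ya))
    # cosine distance is scale invariant: rescaling predictions is neutral
    expect_equal(two_vs_two_score(pa, pb, ya, yb),
                 two_vs_two_score(3.7 * pa, 3.7 * pb, ya, yb))
  }
  expect_error(two_vs_two_score(c(0, 0), tb[1:2], ta[1:2], tb[1:2]),
               "zero-norm")
})

test_that("window accuracy is perfect with injected-oracle predictions", {
  # epochs whose window content carries the words' embedding directly
  # (identity mixing): the decoder recovers it and every pair scores 1
  emb <- tiny_embeddings(d = 8L)
  words <- rep(object_shapes, each = 4L)
  times <- seq(-100, 700, by = 10)
  data <- array(0, c(20L, 8L, length(times)))
  set.seed(15)
  win <- times >= 200 & times < 300
  for (i in 1:20) {
    data[i, , win] <- emb$vectors[words[i], ] +
      matrix(rnorm(8L * sum(win), sd = 1e-3), 8L)
    data[i, , ] <- data[i, , ] + rnorm(8L * length(times), sd = 1e-4)
  }
  avg <- manual_avg(data, words, times, fs = 100, condition = "noun")
  acc <- window_accuracy(avg, emb, center = 250, width_samples = 10L)
  expect_equal(acc, 1)
})

test_that("decoding a high-SNR simulation separates active from baseline", {
  pipe <- tiny_pipeline(conditions = "noun", snr = 10, seed = 111L,
                        n_sensors = 8L, fs = 250)
  acc_active <- window_accuracy(pipe$avg$noun, pipe$emb, center = 250,
                                width_samples = 25L)
  acc_base <- window_accuracy(pipe$avg$noun, pipe$emb, center = -50,
                              width_samples = 25L)
  expect_gte(acc_active, 0.95)
  expect_gt(acc_base, 0.2)
  expect_lt(acc_base, 0.8)
})

test_that("accuracy time courses carry metadata and bounded values", {
  pipe <- tiny_pipeline(conditions = "noun", snr = 10, seed = 113L,
                        n_sensors = 6L, fs = 250)
  cur <- accuracy_timecourse(pipe$avg$noun, pipe$emb,
                             centers = c(-50, 150, 250, 450),
                             width_samples = 25L)
  expect_s3_class(cur, "accuracy_curve")
  expect_equal(cur$centers, c(-50, 150, 250, 450))
  expect_true(all(cur$accuracy >= 0 & cur$accuracy <= 1))
  expect_equal(cur$regime, "noun/noun")
})

test_that("within-condition TGM diagonal equals the same-window curve", {
  pipe <- tiny_pipeline(conditions = "noun", snr = 5, seed = 117L,
                        n_sensors = 6L, fs = 250)
  centers <- c(150, 250, 350)
  tg <- tgm(pipe$avg$noun, pipe$emb, train_centers = centers,
            test_centers = centers, width_samples = 25L)
  expect_s3_class(tg, "tgm")
  expect_false(tg$across)
  for (k in seq_along(centers)) {
    expect_identical(tg$M[k, k],
                     window_accuracy(pipe$avg$noun, pipe$emb, centers[k],
                                     width_samples = 25L))
  }
})

test_that("across-condition TGMs require matching vocabularies", {
  pipe <- tiny_pipeline(conditions = c("noun", "phrase"), snr = 5,
                        seed = 119L, n_sensors = 6L, fs = 250)
  colors <- tiny_pipeline(conditions = "adjective", category = "color",
                          snr = 5, seed = 119L, n_sensors = 6L, fs = 250)
  expect_error(tgm(pipe$avg$noun, pipe$emb, test = colors$avg$adjective,
                   train_centers = 250, test_centers = 250,
                   width_samples = 25L),
               "vocabularies")
  tg <- tgm(pipe$avg$noun, pipe$emb, test = pipe$avg$phrase,
            train_centers = c(150, 250), test_centers = c(150, 250),
            width_samples = 25L)
  expect_true(tg$across)
  expect_equal(dim(tg$M), c(2L, 2L))
  expect_true(all(tg$M >= 0 & tg$M <= 1))
})
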