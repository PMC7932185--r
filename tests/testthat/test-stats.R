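test_that("permutation nulls are centered near chance and deterministic", {
  pipe <- tiny_pipeline(conditions = "noun", snr = 2, seed = 131L,
                        n_sensors = 5L, fs = 250)
  null <- permutation_null(pipe$avg$noun, pipe$emb, center = 250,
                           n_perm = 30L, seed = 132L, width_samples = 25L)
  expect_s3_class(null, "null_distribution")
  expect_equal(length(null$null_accuracies), 30L)
  se <- sd(null$null_accuracies) / sqrt(30L)
  expect_lt(abs(mean(null$null_accuracies) - 0.5), 4 * se + 0.02)
  again <- permutation_null(pipe$avg$noun, pipe$emb, center = 250,
                            n_perm = 30L, seed = 132L, width_samples = 25L)
  expect_identical(null$null_accuracies, again$null_accuracies)
  expect_error(permutation_null(pipe$avg$noun, pipe$emb, 250, n_perm = 1L,
                                seed = 1L), "n_perm")
})

test_that("raw-level shuffling re-averages and stays near chance", {
  pipe <- tiny_pipeline(conditions = "noun", snr = 2, seed = 135L,
                        n_sensors = 5L, fs = 250)
  null <- permutation_null(pipe$avg$noun, pipe$emb, center = 250,
                           n_perm = 10L, seed = 136L, level = "raw",
                           raw = pipe$epochs, width_samples = 25L)
  expect_equal(length(null$null_accuracies), 10L)
  expect_gt(mean(null$null_accuracies), 0.3)
  expect_lt(mean(null$null_accuracies), 0.7)
})

test_that("the null spread narrows with more averaged epochs per word", {
  # signal-free datasets with 4 vs 8 averages per word
  emb <- tiny_embeddings(d = 8L)
  times <- seq(-100, 700, by = 10)
  set.seed(140)
  mk <- function(per_word) {
    n <- 3L * per_word
    manual_avg(array(rnorm(n * 3L * length(times)), c(n, 3L, length(times))),
               rep(object_shapes[1:3], each = per_word), times, fs = 100)
  }
  n_small <- permutation_null(mk(4L), emb, center = 250, n_perm = 40L,
                              seed = 141L, width_samples = 6L)
  n_large <- permutation_null(mk(8L), emb, center = 250, n_perm = 40L,
                              seed = 142L, width_samples = 6L)
  expect_lt(sd(n_large$null_accuracies), sd(n_small$null_accuracies))
})

test_that("KDE p-values match the empirical tail and decrease in accuracy", {
  set.seed(150)
  vals <- rnorm(10000L, 0.5, 0.05)
  null <- structure(list(null_accuracies = vals, bw = stats::bw.nrd0(vals),
                         center = 0, n_perm = length(vals), seed = 150L),
                    class = "null_distribution")
  for (obs in c(0.45, 0.5, 0.55, 0.6)) {
    expect_lt(abs(kde_pvalue(obs, null) - mean(vals >= obs)), 0.05)
  }
  expect_lt(abs(kde_pvalue(median(vals), null) - 0.5), 0.02)
  expect_lt(kde_pvalue(max(vals) + 0.1, null), 0.01)
  ps <- sapply(seq(0.3, 0.8, by = 0.05), kde_pvalue, null = null)
  expect_true(all(diff(ps) < 0))
  degen <- structure(list(null_accuracies = rep(0.5, 10L), bw = 0),
                     class = "null_distribution")
  expect_error(kde_pvalue(0.6, degen), "degenerate")
})

test_that("BY-FDR equals the hand-computed step-up and never beats BH", {
  expect_false(any(fdr_by(rep(1, 5))))
  expect_true(fdr_by(0.04, alpha = 0.05))
  p10 <- c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.35, 0.5)
  expect_equal(fdr_by(p10), by_stepup_oracle(p10))
  # c(10) = 2.928968...: the 10-value harmonic sum the correction divides by
  expect_equal(sum(1 / (1:10)), 2.9289682, tolerance = 1e-7)
  set.seed(160)
  for (rep in 1:50) {
    p <- runif(sample(3:30, 1L))^sample(1:3, 1L)
    expect_equal(fdr_by(p), by_stepup_oracle(p))
    bh <- p.adjust(p, "BH") <= 0.05
    expect_true(all(!fdr_by(p) | bh))  # BY rejections are a subset of BH
  }
  expect_error(fdr_by(numeric(0)), "empty")
  expect_error(fdr_by(c(0.5, 1.2)), "0, 1")
})

test_that("pointwise ANOVA reproduces aov on balanced panels", {
  set.seed(170)
  dn <- list(NULL, c("object", "color"), c("isolation", "list", "phrase"))
  for (rep in 1:10) {
    arr <- array(rnorm(6L * 2L * 3L, 0.5, 0.1), c(6L, 2L, 3L), dimnames = dn)
    res <- pointwise_anova(arr, "2x3")
    df <- expand.grid(p = 1:6, cat = dn[[2L]], ctx = dn[[3L]])
    df$y <- as.vector(arr)
    a <- summary(stats::aov(y ~ cat * ctx, df))[[1L]]
    expect_equal(res$F, a[1:3, "F value"], tolerance = 1e-8)
    expect_equal(res$p, a[1:3, "Pr(>F)"], tolerance = 1e-8)
    # targeted 2x2: isolation vs phrase only
    res22 <- pointwise_anova(arr, "2x2", contexts = c("isolation", "phrase"))
    df22 <- df[df$ctx != "list", ]
    df22$ctx <- droplevels(df22$ctx)
    a22 <- summary(stats::aov(y ~ cat * ctx, df22))[[1L]]
    expect_equal(res22$F, a22[1:3, "F value"], tolerance = 1e-8)
  }
})

test_that("flat panels give F = 0, p = 1; unbalanced panels error", {
  dn <- list(NULL, c("object", "color"), c("isolation", "list", "phrase"))
  arr <- array(rep(rnorm(6L), 6L), c(6L, 2L, 3L), dimnames = dn)
  res <- pointwise_anova(arr, "2x3")  # cells identical within participant
  expect_lt(max(abs(res$F)), 1e-10)
  expect_equal(res$p, rep(1, 3L), tolerance = 1e-10)
  arr[2L, 1L, 1L] <- NA
  expect_error(pointwise_anova(arr, "2x3"), "unbalanced|missing")
  expect_error(pointwise_anova(array(0, c(4, 2, 3)), "2x2"), "contexts")
})

test_that("cluster rules: threshold runs shorter than min_len are ignored", {
  flag <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  runs <- megdecode:::threshold_runs(flag, 3L)
  expect_equal(runs, list(c(4L, 6L)))
  expect_equal(megdecode:::threshold_runs(rep(FALSE, 5L), 3L), list())
})

test_that("cluster permutation finds an injected category effect", {
  set.seed(180)
  tt <- seq(0, 384, by = 16)
  dn <- list(NULL, c("object", "color"), c("isolation", "list", "phrase"), tt)
  pan <- array(rnorm(8L * 2L * 3L * 25L, 0.5, 0.05), c(8L, 2L, 3L, 25L),
               dimnames = dn)
  sel <- tt >= 200 & tt <= 300
  pan[, 1L, , sel] <- pan[, 1L, , sel] + 0.08
  res <- cluster_permutation(pan, "2x3", n_perm = 300L,
                             windows = list(c(0, 384)), seed = 181L)
  catcl <- res[res$effect == "category" & res$is_largest, ]
  expect_equal(nrow(catcl), 1L)
  expect_lt(catcl$p, 0.05)
  # the detected cluster covers at least half of the injected 200-300 ms
  overlap <- min(catcl$cluster_end, 300) - max(catcl$cluster_start, 200)
  expect_gte(overlap, 50)
  expect_true(all(res$mass >= 0))
  expect_true(all(res$cluster_start >= 0 & res$cluster_end <= 384))
})

test_that("cluster permutation is deterministic and validates windows", {
  set.seed(190)
  tt <- seq(0, 240, by = 16)
  dn <- list(NULL, c("object", "color"), c("isolation", "list", "phrase"), tt)
  pan <- array(rnorm(5L * 2L * 3L * 16L, 0.5, 0.05), c(5L, 2L, 3L, 16L),
               dimnames = dn)
  a <- cluster_permutation(pan, "2x3", n_perm = 50L,
                           windows = list(c(0, 240)), seed = 191L)
  b <- cluster_permutation(pan, "2x3", n_perm = 50L,
                           windows = list(c(0, 240)), seed = 191L)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(cluster_permutation(pan, "2x3", n_perm = 50L,
                                   windows = list(c(1000, 2000)), seed = 1L),
               "outside")
  expect_error(cluster_permutation(pan, "2x3", n_perm = 0L, seed = 1L),
               "n_perm")
})
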