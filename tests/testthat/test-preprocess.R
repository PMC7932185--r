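emb <- tiny_embeddings()

test_that("baseline correction zeroes the pre-stimulus mean exactly", {
  pipe <- tiny_pipeline(snr = 1, seed = 71L, n_sensors = 4L)
  ep <- pipe$sim$epochs
  out <- baseline_correct(ep)
  sel <- out$times >= -100 & out$times < 0
  base <- apply(out$data[, , sel], c(1L, 2L), mean)
  expect_lt(max(abs(base)), 1e-12)
  # constant epoch becomes all-zero
  const <- ep
  const$data[] <- 3.7
  expect_equal(max(abs(baseline_correct(const)$data)), 0)
  # a known baseline shift is subtracted everywhere on that sensor
  shifted <- ep
  shifted$data[1L, 2L, ] <- 3.5
  shifted$data[1L, 2L, !sel] <- 3.5 + sin(seq_len(sum(!sel)))
  out2 <- baseline_correct(shifted)
  expect_equal(out2$data[1L, 2L, !sel],
               shifted$data[1L, 2L, !sel] - 3.5, tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(-100, -100)), "no samples")
})

test_that("error-trial rejection drops exactly the incorrect trials in order", {
  pipe <- tiny_pipeline(snr = 0, seed = 73L, n_sensors = 3L)
  ep <- pipe$sim$epochs
  beh <- pipe$sim$behavior
  beh$correct <- TRUE
  beh$correct[c(5L, 42L)] <- FALSE
  out <- reject_errors(ep, beh)
  expect_equal(dim(out$data)[1L], nrow(ep$labels) - 2L)
  expect_identical(out$labels$trial, setdiff(ep$labels$trial, c(5L, 42L)))
  # all correct: identity
  beh$correct <- TRUE
  expect_identical(reject_errors(ep, beh)$data, ep$data)
  # all incorrect: empty with a warning
  beh$correct <- FALSE
  expect_warning(empty <- reject_errors(ep, beh), "all epochs rejected")
  expect_equal(dim(empty$data)[1L], 0L)
  # missing behavior row
  expect_error(reject_errors(ep, beh[-1L, ]), "missing trial")
})

test_that("group averaging partitions epochs into disjoint exact means", {
  pipe <- tiny_pipeline(snr = 1, seed = 79L, n_sensors = 4L)
  ep <- pipe$sim$epochs  # all 100 noun trials kept: no rejection applied
  avg <- average_groups(ep, "noun", "object", group_size = 5L, seed = 80L)
  expect_equal(length(avg$words), 20L)
  expect_true(all(table(avg$words) == 4L))
  expect_true(all(lengths(avg$groups) == 5L))
  # disjoint: no raw epoch feeds two averages
  used <- unlist(avg$groups)
  expect_equal(anyDuplicated(used), 0L)
  # every average is the exact arithmetic mean of its recorded sources
  for (i in seq_along(avg$groups)) {
    src <- avg$groups[[i]]
    expect_equal(avg$data[i, , ],
                 colMeans(array(ep$data[src, , ],
                                c(5L, dim(ep$data)[2:3])), dims = 1L),
                 tolerance = 1e-12)
    expect_true(all(ep$labels$word_object[src] == avg$words[i]))
  }
})

test_that("leftover epochs are dropped and short words rejected", {
  pipe <- tiny_pipeline(snr = 0, seed = 83L, n_sensors = 3L)
  ep <- pipe$sim$epochs
  # unbalance one word: keep 18 noun-condition "bag" epochs (-> 3 groups of
  # 5, 3 dropped) and everything else
  bag_noun <- which(ep$labels$word_object == "bag" &
                      ep$labels$condition == "noun")
  sel <- sort(c(bag_noun[1:18], setdiff(seq_len(nrow(ep$labels)), bag_noun)))
  sub <- ep
  sub$data <- ep$data[sel, , , drop = FALSE]
  sub$labels <- ep$labels[sel, ]
  avg <- average_groups(sub, "noun", "object", group_size = 5L, seed = 84L)
  expect_equal(sum(avg$words == "bag"), 3L)       # 18 %/% 5 = 3, 3 dropped
  expect_equal(length(avg$words), 19L)
  # group_size = 1 reproduces the condition's epochs up to ordering
  one <- average_groups(sub, "noun", "object", group_size = 1L, seed = 85L)
  n_noun <- sum(sub$labels$condition == "noun" &
                  !is.na(sub$labels$word_object))
  expect_equal(length(one$words), n_noun)
  reordered <- sub$data[unlist(one$groups), , , drop = FALSE]
  expect_equal(one$data, reordered, tolerance = 1e-15)
  # fewer than group_size epochs for a word
  tiny <- sub
  bag2 <- which(sub$labels$word_object == "bag" &
                  sub$labels$condition == "noun")
  sel2 <- sort(c(bag2[1:3], setdiff(seq_len(nrow(sub$labels)), bag2)))
  tiny$data <- sub$data[sel2, , , drop = FALSE]
  tiny$labels <- sub$labels[sel2, ]
  expect_error(average_groups(tiny, "noun", "object", 5L, seed = 1L),
               "fewer than group_size")
})

test_that("averaging is deterministic given the seed", {
  pipe <- tiny_pipeline(snr = 1, seed = 87L, n_sensors = 3L)
  a <- average_groups(pipe$sim$epochs, "noun", "object", 5L, seed = 88L)
  b <- average_groups(pipe$sim$epochs, "noun", "object", 5L, seed = 88L)
  expect_identical(a$data, b$data)
  expect_identical(a$groups, b$groups)
})

test_that("window slicing flattens sensor-major and inverts exactly", {
  avg <- manual_avg(array(rnorm(3 * 4 * 81), c(3, 4, 81)),
                    words = c("bag", "bell", "cane"),
                    times = seq(-100, 700, by = 10), fs = 100)
  X <- slice_window(avg, center = 250, width_samples = 10L)
  expect_equal(dim(X), c(3L, 40L))
  expect_equal(rownames(X), avg$words)
  # row = sensor-major flattening of the sensors x width slab
  idx <- which(avg$times == 200):(which(avg$times == 200) + 9L)
  expect_equal(X[2L, ], as.vector(t(avg$data[2L, , idx])))
  expect_equal(unflatten_window(X[2L, ], 4L, 10L), avg$data[2L, , idx])
  # determinism and bounds
  expect_identical(X, slice_window(avg, 250, 10L))
  expect_error(slice_window(avg, 680, 10L), "out of bounds")
})

test_that("the default window grid spans -50 to 650 ms in 141 steps", {
  centers <- window_centers(seq(-100, 700, by = 1), width_samples = 100L,
                            step_ms = 5)
  expect_equal(length(centers), 141L)
  expect_equal(centers[1L], -50)
  expect_equal(centers[141L], 650)
  # every center admits a full window; one step further does not
  avg <- manual_avg(array(0, c(1, 1, 801)), "bag",
                    seq(-100, 700, by = 1), 1000)
  for (ct in c(-50, 650)) expect_silent(slice_window(avg, ct, 100L))
  expect_error(slice_window(avg, 655, 100L), "out of bounds")
})
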