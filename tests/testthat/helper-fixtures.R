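# Small fixtures built in code; all deterministic given their seeds.

# standard 10-word vocabulary, modest dimension for speed
tiny_embeddings <- function(d = 16L, seed = 11L, similarity = 0) {
  make_embeddings(c(object_shapes, color_words), d = d, seed = seed,
                  similarity = similarity)
}

# full simulate -> preprocess -> average chain at reduced sensor count and
# sampling rate; returns the averaged sets per requested condition/category
tiny_pipeline <- function(conditions = "noun", category = "object",
                          snr = 10, seed = 21L, n_sensors = 8L, fs = 250,
                          mixing_mode = "shared", filter = FALSE,
                          emb = tiny_embeddings(), group_size = 5L) {
  # the block scheduler needs >= 2 conditions; pad with an unused one
  sched_conds <- conditions
  if (length(sched_conds) == 1L) {
    sched_conds <- c(sched_conds, setdiff(c("phrase", "list"), sched_conds)[1L])
  }
  sched <- build_trial_schedule(sched_conds, seed = seed)
  sim <- simulate_participant(sched, emb, snr = snr, seed = seed + 1L,
                              n_sensors = n_sensors, fs = fs,
                              mixing_mode = mixing_mode)
  epo <- sim$epochs
  if (filter) epo <- bandpass(epo, 0.1, 40, 20)
  epo <- baseline_correct(epo)
  epo <- reject_errors(epo, sim$behavior)
  avg <- lapply(conditions, function(cond) {
    average_groups(epo, cond, category, group_size, seed = seed + 2L)
  })
  names(avg) <- conditions
  list(sim = sim, epochs = epo, avg = avg, emb = emb)
}

# hand-built averaged_epochs object: direct control over the data array
manual_avg <- function(data, words, times, fs, condition = "noun",
                       category = "object") {
  structure(list(data = data, words = words, condition = condition,
                 category = category,
                 groups = as.list(seq_along(words)),
                 times = times, fs = fs, participant = "manual"),
            class = "averaged_epochs")
}

# brute-force leave-one-out ridge errors: explicit N refits per lambda,
# penalty on all columns except the bias (or on all, if penalize_bias)
brute_force_loocv <- function(X, Y, lambda, penalize_bias = FALSE) {
  n <- nrow(X); p1 <- ncol(X)
  J <- diag(p1)
  if (!penalize_bias) J[p1, p1] <- 0
  sapply(seq_len(ncol(Y)), function(j) {
    mean(sapply(seq_len(n), function(i) {
      Xi <- X[-i, , drop = FALSE]
      w <- solve(crossprod(Xi) + lambda * J, crossprod(Xi, Y[-i, j]))
      (Y[i, j] - sum(X[i, ] * w))^2
    }))
  })
}

# explicit Benjamini-Yekutieli step-up: find the largest k with
# p_(k) <= k * alpha / (m * c(m)), reject the k smallest p-values
by_stepup_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * alpha / (m * cm))
  mask <- rep(FALSE, m)
  if (length(k)) mask[o[seq_len(max(k))]] <- TRUE
  mask
}
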