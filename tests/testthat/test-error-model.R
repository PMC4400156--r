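test_that("neighboring quality score averages up to five bases each side", {
  q <- rep(30L, 20)
  expect_equal(compute_nqs(q, 10L), 30)
  q2 <- c(10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L, 100L, 110L)
  # index 5 (0-based) holds 60; the mean of the ten other qualities is 60
  expect_equal(compute_nqs(q2, 5L), (sum(q2) - 60) / 10)
  # read edge: index 0 of a length-20 read averages indices 1..5
  q3 <- seq(2L, 40L, by = 2L)
  expect_equal(compute_nqs(q3, 0L), mean(q3[2:6]))
  # degenerate single-base read falls back to the base's own quality
  expect_equal(compute_nqs(7L, 0L), 7)
})

test_that("training observations compare read bases against the reference", {
  reads <- data.frame(pos = 0L, seq = "ACGGT", qual = "??????", strand = "+")
  reads$qual <- intToUtf8(rep(30L + 33L, 5))
  obs <- extract_training_observations(reads, "ACGGA")
  expect_equal(nrow(obs), 5L)
  expect_equal(obs$is_error, c(0L, 0L, 0L, 0L, 1L))
  # last base is preceded by the 2-mer GG in the read
  expect_equal(obs$gg, c(0L, 0L, 0L, 0L, 1L))
  expect_true(all(obs$qs == 30L))
  # identical read: no errors
  obs2 <- extract_training_observations(
    data.frame(pos = 0L, seq = "ACGGA", qual = intToUtf8(rep(63L, 5)),
               strand = "+"), "ACGGA")
  expect_true(all(obs2$is_error == 0L))
  # reads without qualities are rejected
  expect_error(extract_training_observations(
    data.frame(pos = 0L, seq = "ACGT", qual = NA_character_), "ACGT"),
    "quality")
})

test_that("observed error fraction matches the simulated substitution rate", {
  set.seed(11)
  n <- 1000L
  L <- 120L
  ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  rate <- 0.01
  refv <- strsplit(ref, "")[[1]]
  seqs <- vapply(seq_len(n), function(i) {
    s <- refv
    err <- runif(L) < rate
    s[err] <- vapply(s[err], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    paste(s, collapse = "")
  }, character(1))
  reads <- data.frame(pos = 0L, seq = seqs,
                      qual = intToUtf8(rep(33L + 30L, L)), strand = "+")
  obs <- extract_training_observations(reads, ref)
  frac <- mean(obs$is_error)
  expect_lt(abs(frac - rate), 3 * sqrt(rate * (1 - rate) / (n * L)))
})

test_that("strand is handled in sequencing orientation", {
  # reverse read stored forward as ACCGT; in sequencing orientation it is
  # ACGGT, so its last sequenced base (forward position 1) follows GG
  reads <- data.frame(pos = 0L, seq = "ACCGT",
                      qual = intToUtf8(c(40, 35, 30, 25, 20) + 33),
                      strand = "-")
  feat <- read_base_features(reads)
  expect_equal(feat$gg, c(1L, 0L, 0L, 0L, 0L))
  # nqs is orientation-invariant (symmetric window)
  expect_equal(feat$nqs[3], mean(c(40, 35, 25, 20)))
})

test_that("fitted substitution rows are multinomial MLEs", {
  obs <- data.table::data.table(
    true_nt = 0L, nt = c(rep(1L, 50), rep(2L, 30), rep(3L, 20)),
    qs = 23L, nqs = 30, gg = 0L, is_error = 1L)
  ok <- data.table::data.table(true_nt = 0L, nt = 0L, qs = 23L, nqs = 30,
                               gg = 0L, is_error = 0L)
  fit <- fit_error_model(rbind(obs, ok[rep(1, 900)]))
  expect_equal(fit$substitution[1, 1, ], c(A = 0, C = 0.5, G = 0.3, T = 0.2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # rows always sum to one, self-substitution is zero
  for (t in 1:4) {
    expect_equal(sum(fit$substitution[t, 1, ]), 1, tolerance = 1e-12)
    expect_equal(fit$substitution[t, 1, t], 0)
  }
})

test_that("error probability follows the logistic model and its constraints", {
  naive <- naive_error_model()
  expect_equal(error_probability(naive, 0L, 0L, 20L, 30), 0.01)
  zero <- flat_error_model(0.5) # alpha = 0 at e0 = 0.5
  expect_equal(error_probability(zero, 0L, 0L, 23L, 30), 0.5)
  # with beta > 0 the probability is strictly decreasing in qs
  prof <- sim_error_profile()
  qs_grid <- c(3L, 5L, 10L, 20L, 30L, 40L)
  p <- error_probability(prof$truth, 0L, 0L, qs_grid, 30)
  expect_true(all(diff(p) < 0))
  # quality-2 strata ignore qs by construction (beta fixed at zero)
  fit <- trained_params()
  expect_true(all(fit$beta[, , 2] == 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("substitution probability is a normalised lookup", {
  params <- flat_error_model()
  expect_equal(substitution_probability(params, 0L, 0L, 1L), 1 / 3)
  expect_equal(substitution_probability(params, 0L, 0L, 0L), 0)
  alts <- setdiff(0:3, 2L)
  expect_equal(sum(substitution_probability(params, rep(2L, 3), rep(0L, 3),
                                            alts)), 1)
})

test_that("cached and uncached error probabilities agree bit for bit", {
  params <- trained_params()
  cache <- error_probability_cached(params)
  set.seed(3)
  t <- sample(0:3, 50, replace = TRUE)
  gg <- sample(0:1, 50, replace = TRUE)
  qs <- sample(c(2L, 12L, 23L, 37L), 50, replace = TRUE)
  nqs <- runif(50, 3, 40)
  direct <- error_probability(params, t, gg, qs, nqs)
  once <- cache(t, gg, qs, nqs)
  twice <- cache(t, gg, qs, nqs) # now all hits
  expect_identical(direct, once)
  expect_identical(direct, twice)
})

test_that("parameter fitting recovers generating coefficients", {
  set.seed(99)
  prof <- sim_error_profile()
  obs <- simulate_training_observations(2e5, prof$truth)
  fit <- fit_error_model(obs)
  tr <- prof$truth
  # the well-populated gg = 0 strata: every free coefficient within 3 SE
  for (tv in 1:4) {
    expect_lt(abs(fit$alpha[tv, 1, 1] - tr$alpha[tv, 1, 1]),
              3 * fit$se$alpha[tv, 1, 1])
    expect_lt(abs(fit$beta[tv, 1, 1] - tr$beta[tv, 1, 1]),
              3 * fit$se$beta[tv, 1, 1])
    expect_lt(abs(fit$gamma[tv, 1, 1] - tr$gamma[tv, 1, 1]),
              3 * fit$se$gamma[tv, 1, 1])
  }
})

test_that("degenerate strata stay finite and fall back sensibly", {
  # all-error stratum: fitted probability approaches 1 but stays finite
  obs <- data.table::data.table(
    true_nt = 0L, nt = 1L, qs = 23L, nqs = 30, gg = 0L, is_error = 1L)
  fit <- fit_error_model(obs[rep(1, 200)])
  p <- error_probability(fit, 0L, 0L, 23L, 30)
  expect_gt(p, 0.95)
  expect_lt(p, 1)
  # strata never observed inherit pooled/uniform behaviour without error
  p2 <- error_probability(fit, 3L, 1L, 2L, 10)
  expect_true(is.finite(p2) && p2 > 0 && p2 < 1)
  expect_equal(fit$substitution[4, 2, ], c(1, 1, 1, 0) / 3,
               ignore_attr = TRUE)
  expect_error(fit_error_model(obs[0]), "no training observations")
})

test_that("cross-validation ranks the full model above the naive one", {
  set.seed(5)
  prof <- sim_error_profile()
  obs <- simulate_training_observations(4e4, prof$truth)
  cv <- evaluate_error_model(obs, folds = 4)
  expect_equal(nrow(cv), 4L)
  expect_true(all(is.finite(cv$nll_full)) && all(is.finite(cv$nll_naive)))
  # feature-dependent errors: the full model wins on held-out likelihood
  expect_lt(mean(cv$nll_full), mean(cv$nll_naive))
  # errors generated exactly at 10^(-qs/10): the two models are comparable
  set.seed(6)
  qs <- sample(c(12L, 17L, 23L, 27L), 4e4, replace = TRUE)
  nqs <- pmax(qs + rnorm(4e4, 0, 3), 2)
  e <- 10^(-qs / 10)
  obs0 <- data.table::data.table(
    true_nt = sample(0:3, 4e4, replace = TRUE), qs = qs, nqs = nqs,
    gg = sample(0:1, 4e4, replace = TRUE),
    is_error = rbinom(4e4, 1, e))
  obs0[, nt := ifelse(is_error == 1L, (true_nt + 1L) %% 4L, true_nt)]
  cv0 <- evaluate_error_model(obs0, folds = 4)
  expect_lt(abs(mean(cv0$nll_full) - mean(cv0$nll_naive)),
            0.05 * mean(cv0$nll_naive))
  # plumbing: 2 folds on 10 observations gives 2 finite values
  cv2 <- evaluate_error_model(rbind(obs[1:5], obs0[1:5], fill = TRUE),
                              folds = 2)
  expect_equal(nrow(cv2), 2L)
  expect_true(all(is.finite(cv2$nll_full)))
  expect_error(evaluate_error_model(obs[1:3], folds = 4), "fewer")
})

test_that("parameter files round-trip exactly", {
  params <- trained_params()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_error_params(params, tf)
  back <- read_error_params(tf)
  expect_equal(back$alpha, params$alpha, tolerance = 1e-15)
  expect_equal(back$beta, params$beta, tolerance = 1e-15)
  expect_equal(back$gamma, params$gamma, tolerance = 1e-15)
  expect_equal(back$substitution, params$substitution, tolerance = 1e-12)
  expect_identical(back$model_kind, "full")
})
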