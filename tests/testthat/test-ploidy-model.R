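test_that("the genotype prior spreads heterozygous mass uniformly", {
  expect_equal(genotype_prior(2L, 0.005, 1L), 0.005)
  expect_equal(genotype_prior(4L, 0.005, 2L), 0.005 / 3)
  expect_equal(genotype_prior(4L, 0.005, c(0L, 4L)), rep(0.4975, 2))
  for (M in c(2L, 3L, 7L, 16L))
    expect_equal(sum(genotype_prior(M, 0.005, 0:M)), 1)
  # M = 1 renormalises the two homozygous states to 1/2 each
  expect_equal(genotype_prior(1L, 0.005, 0:1), c(0.5, 0.5))
  expect_error(genotype_prior(0L, 0.005, 0L), "M")
})

test_that("the latent allele is Bernoulli in the dosage fraction", {
  expect_equal(true_allele_prob(4L, 3L, 1L), 0.75)
  expect_equal(true_allele_prob(4L, 0L, 1L), 0)
  for (g in 0:5)
    expect_equal(true_allele_prob(5L, g, 1L) + true_allele_prob(5L, g, 2L), 1)
})

test_that("read log-likelihood matches its closed forms", {
  e0 <- 0.01
  params <- flat_error_model(e0)
  obs <- list(nt = 0L, qs = 23L, nqs = 30, gg = 0L, strand = "+")
  # matching base: log(1 - e) (substitution to self is zero)
  expect_equal(read_loglik(obs, 0L, 2L, 1L, params), log(1 - e0),
               tolerance = 1e-12)
  # base matching neither allele, uniform substitutions: log(e / 3)
  obs2 <- list(nt = 3L, qs = 23L, nqs = 30, gg = 0L, strand = "+")
  expect_equal(read_loglik(obs2, 0L, 2L, 1L, params), log(e0 / 3),
               tolerance = 1e-12)
  # e -> 0 with a mismatching base: floored, very negative, finite
  tiny <- flat_error_model(1e-12)
  v <- read_loglik(obs2, 0L, 2L, 1L, tiny)
  expect_true(is.finite(v))
  expect_lt(v, log(1e-11))
  expect_error(read_loglik(obs, 0L, NA_integer_, 2L, params), "absent")
})

test_that("position log-likelihood equals the exhaustive oracle", {
  params <- trained_params()
  set.seed(7)
  for (case in 1:12) {
    pp <- rand_pileup(sample(1:5, 1))
    M <- sample(1:4, 1)
    g <- sample(0:M, 1)
    fast <- position_loglik(pp, M, g, params)
    slow <- log(oracle_position_lik(pp, M, g, params))
    expect_equal(fast, slow, tolerance = 1e-12)
  }
  # a single read matching allele1 at g = M gives log(1 - e)
  params0 <- flat_error_model(0.02)
  pp1 <- list(observations = data.table::data.table(
    nt = 2L, qs = 23L, nqs = 30, gg = 0L, strand = "+"),
    allele1 = 2L, allele2 = 0L)
  expect_equal(position_loglik(pp1, 3L, 3L, params0), log(0.98),
               tolerance = 1e-12)
  # empty pileup contributes nothing
  expect_equal(position_loglik(list(observations = NULL), 2L, 1L, params), 0)
})

test_that("allele relabeling with g <-> M - g leaves likelihoods unchanged", {
  params <- trained_params()
  set.seed(8)
  for (case in 1:8) {
    pp <- rand_pileup(6)
    if (is.na(pp$allele2)) next
    M <- sample(2:5, 1)
    g <- sample(0:M, 1)
    swapped <- list(observations = pp$observations,
                    allele1 = pp$allele2, allele2 = pp$allele1)
    expect_equal(position_loglik(pp, M, g, params),
                 position_loglik(swapped, M, M - g, params),
                 tolerance = 1e-12)
  }
})

test_that("contig log-likelihood matches the oracle and is additive", {
  params <- trained_params()
  cfg <- model_config(p_snp = 0.01, ploidy_range = c(1L, 4L))
  set.seed(9)
  pps <- lapply(1:3, function(i) rand_pileup(sample(2:4, 1)))
  cp <- as_contig_pileup(pps)
  for (M in 1:4) {
    expect_equal(contig_loglik(cp, M, cfg, params),
                 oracle_contig_loglik(pps, M, cfg$p_snp, params),
                 tolerance = 1e-10)
  }
  # duplicating every position doubles the log-likelihood
  cp2 <- as_contig_pileup(c(pps, pps), positions = 0:5)
  expect_equal(contig_loglik(cp2, 3L, cfg, params),
               2 * contig_loglik(cp, 3L, cfg, params), tolerance = 1e-9)
  # no observations: zero for every M
  empty <- as_contig_pileup(list(list(observations = data.table::data.table(
    nt = integer(), qs = integer(), nqs = numeric(), gg = integer(),
    strand = character()), allele1 = NA_integer_, allele2 = NA_integer_)))
  expect_equal(contig_loglik(empty, 2L, cfg, params), 0)
})

test_that("ploidy selection recovers simulated truth on clean data", {
  params <- trained_params()
  cfg <- model_config(p_snp = 1 / 500, ploidy_range = c(1L, 4L))
  # M = 2, balanced SNPs, decent coverage, materialised-read path
  ds <- sim_design(2, 6000, snp_spacing = 500, coverage = 40, seed = 31)
  sim <- simulate_contig(ds)
  reads <- simulate_reads(sim$haplotypes, ds)
  cp <- build_pileups(reads_to_alignments(reads, "c1"), "c1", ds$length)
  pr <- estimate_ploidy(cp, cfg, params)
  expect_equal(pr$selected_M, 2L)
  expect_identical(pr$status, "call")
  # M = 3 has 1:2 and 2:1 sites
  ds3 <- sim_design(3, 6000, snp_spacing = 500, coverage = 40, seed = 32)
  sim3 <- simulate_contig(ds3)
  cp3 <- build_pileups(
    reads_to_alignments(simulate_reads(sim3$haplotypes, ds3), "c1"),
    "c1", ds3$length)
  expect_equal(estimate_ploidy(cp3, cfg, params)$selected_M, 3L)
  # truth beyond the candidate range clamps to the boundary with a warning
  ds5 <- sim_design(5, 6000, snp_spacing = 300, coverage = 40, seed = 33)
  sim5 <- simulate_contig(ds5)
  cp5 <- build_pileups(
    reads_to_alignments(simulate_reads(sim5$haplotypes, ds5), "c1"),
    "c1", ds5$length)
  expect_warning(pr5 <- estimate_ploidy(cp5, cfg, params), "boundary")
  expect_equal(pr5$selected_M, 4L)
  expect_identical(pr5$status, "boundary")
  # a contig with no reads yields a no-call, not an error
  empty <- build_pileups(reads_to_alignments(reads, "c1")[0], "c1", 1000L)
  pr0 <- estimate_ploidy(empty, cfg, params)
  expect_identical(pr0$status, "no-call")
  expect_true(is.na(pr0$selected_M))
})

test_that("genotype posteriors normalise and score variants sensibly", {
  params <- flat_error_model(0.002)
  cfg <- model_config(p_snp = 0.005, ploidy_range = c(1L, 4L),
                      variant_threshold = 40)
  # 30 reads split 15/15 at M = 2: heterozygous with high confidence
  obs <- data.table::data.table(
    nt = rep(c(0L, 2L), each = 15), qs = 37L, nqs = 35, gg = 0L,
    strand = "+")
  cp <- as_contig_pileup(list(list(observations = obs, allele1 = 0L,
                                   allele2 = 2L)))
  calls <- call_genotypes(cp, 2L, cfg, params)
  expect_equal(calls$g, 1L)
  expect_gt(calls$post, 0.99)
  expect_true(calls$emitted)
  # posterior over dosages sums to one
  fg <- ploidycall:::fraction_grid(2L, cfg$p_snp)
  mat <- ploidycall:::pileup_fraction_logliks(cp, params, fg$fractions)
  terms <- mat[1, fg$g_idx[[1]] + 1] + fg$g_logprior[[1]]
  post <- exp(terms - max(terms)); post <- post / sum(post)
  expect_equal(sum(post), 1, tolerance = 1e-9)
  # monomorphic pileup: dosage at a boundary, not emitted
  mono <- as_contig_pileup(list(list(
    observations = data.table::data.table(nt = rep(2L, 20), qs = 37L,
                                          nqs = 35, gg = 0L, strand = "+"),
    allele1 = 2L, allele2 = NA_integer_)))
  cm <- call_genotypes(mono, 2L, cfg, params)
  expect_true(cm$g %in% c(0L, 2L))
  expect_false(cm$emitted)
  # the score is a Phred transform of the non-variant posterior mass
  p_nonvar <- post[1] + post[3]
  expect_equal(calls$score, -10 * log10(p_nonvar), tolerance = 1e-6)
})
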