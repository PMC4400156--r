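# Shared fixtures and independent oracles. Everything is generated in code;
# expensive simulation runs used by several tests are cached per session.

# -- a fixed, analytically convenient error model ---------------------------
# constant error probability e0 for every stratum, uniform substitutions
flat_error_model <- function(e0 = 0.01) {
  # plogis(-alpha) = e0  =>  alpha = -qlogis(e0) = log((1 - e0) / e0)
  a <- array(log((1 - e0) / e0), dim = c(4, 2, 2))
  z <- array(0, dim = c(4, 2, 2))
  sub <- array(1 / 3, dim = c(4, 2, 4))
  for (t in 1:4) sub[t, , t] <- 0
  error_model_params(a, z, z, sub, model_kind = "full")
}

# an error profile with essentially no sequencing errors
noerror_profile <- function() {
  sim_error_profile(alpha0 = c(30, 30), gg_shift = 0,
                    alpha_t = c(A = 0, C = 0, G = 0, T = 0),
                    beta = 0, gamma = c(0, 0))
}

# -- random small pileups for oracle / property tests -----------------------
rand_obs <- function(n, alleles = c(0L, 2L), p_other = 0.1) {
  nt <- ifelse(stats::runif(n) < p_other, sample(0:3, n, replace = TRUE),
               sample(alleles, n, replace = TRUE))
  data.table::data.table(
    nt = as.integer(nt),
    qs = sample(c(2L, 12L, 23L, 37L), n, replace = TRUE),
    nqs = round(stats::runif(n, 5, 40), 1),
    gg = sample(0:1, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE))
}

rand_pileup <- function(n, alleles = c(0L, 2L)) {
  obs <- rand_obs(n, alleles)
  al <- select_alleles(obs$nt)
  list(observations = obs, allele1 = al$allele1, allele2 = al$allele2)
}

# -- exhaustive enumeration oracles -----------------------------------------
# Likelihood of one position for fixed (M, g), summing over every joint
# assignment of (true allele, error indicator) to every read. Deliberately
# brute force: no factorisation over reads.
oracle_position_lik <- function(pileup, M, g, params) {
  obs <- pileup$observations
  n <- nrow(obs)
  if (n == 0L) return(1)
  a2r <- if (is.na(pileup$allele2)) {
    if (pileup$allele1 == 0L) 1L else 0L
  } else pileup$allele2
  alleles <- c(pileup$allele1, a2r)
  # joint-state weight of read i in state st (st indexes (t, e) in 2 x 2)
  term <- matrix(0, nrow = n, ncol = 4L)
  for (i in seq_len(n)) {
    for (st in 1:4) {
      t <- if (st <= 2L) 1L else 2L
      e <- if (st %% 2L == 1L) 0L else 1L
      pt <- if (t == 1L) g / M else 1 - g / M
      a <- alleles[t]
      rev <- obs$strand[i] == "-"
      t_rd <- if (rev) 3L - a else a
      o_rd <- if (rev) 3L - obs$nt[i] else obs$nt[i]
      ep <- error_probability(params, t_rd, obs$gg[i], obs$qs[i], obs$nqs[i])
      po <- if (e == 0L) {
        (1 - ep) * as.numeric(obs$nt[i] == a)
      } else {
        ep * substitution_probability(params, t_rd, obs$gg[i], o_rd)
      }
      term[i, st] <- pt * po
    }
  }
  # sum over every joint assignment of states to reads
  states <- expand.grid(rep(list(1:4), n))
  total <- 0
  for (s in seq_len(nrow(states))) {
    prod <- 1
    for (i in seq_len(n)) prod <- prod * term[i, states[s, i]]
    total <- total + prod
  }
  total
}

# Contig likelihood by enumerating every dosage vector across positions
# (position likelihoods evaluated once per dosage, then combined over the
# full dosage-vector grid).
oracle_contig_loglik <- function(pileups, M, p_snp, params) {
  pl <- lapply(pileups, function(p)
    vapply(0:M, function(g) oracle_position_lik(p, M, g, params), numeric(1)))
  prior <- genotype_prior(M, p_snp, 0:M)
  gs <- expand.grid(rep(list(0:M), length(pileups)))
  total <- 0
  for (r in seq_len(nrow(gs))) {
    prod <- 1
    for (p in seq_along(pileups))
      prod <- prod * prior[gs[r, p] + 1L] * pl[[p]][gs[r, p] + 1L]
    total <- total + prod
  }
  log(total)
}

# contig_pileup built directly from a list of position pileups
as_contig_pileup <- function(pileups, positions = seq_along(pileups) - 1L,
                             length = max(positions) + 1L) {
  obs <- data.table::rbindlist(lapply(seq_along(pileups), function(i) {
    o <- data.table::copy(pileups[[i]]$observations)
    o[, pos := positions[i]]
    o[, read_id := as.character(seq_len(.N))]
    o
  }))
  al <- data.table::rbindlist(lapply(seq_along(pileups), function(i) {
    data.table::data.table(pos = positions[i],
                           a1 = pileups[[i]]$allele1,
                           a2 = pileups[[i]]$allele2,
                           n = nrow(pileups[[i]]$observations))
  }))
  structure(list(contig = "toy", length = as.integer(length),
                 obs = obs, alleles = al),
            class = "contig_pileup")
}

# -- cached expensive artefacts ---------------------------------------------
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# error model trained on a simulated monomorphic sample (shared by the
# simulation-based tests)
trained_params <- function() {
  cached("trained_params", {
    train_error_model_sim(sim_design(1, 200000, coverage = 50, seed = 424242))
  })
}

sim_model_config <- function(max_ploidy = 16L) {
  model_config(p_snp = 1 / 1000, ploidy_range = c(1L, max_ploidy),
               variant_threshold = 40)
}

# the coverage-design benchmark: 50X per copy, ploidies 1..16, 10 replicates
# of 100 kb contigs (~100 SNPs each), SNPs at mean 1 kb spacing
coverage_benchmark <- function() {
  cached("coverage_benchmark", {
    run_benchmark(ploidies = 1:16, coverages = 50, lengths = 100000L,
                  replicates = 10, params = trained_params(),
                  config = sim_model_config(16L), snp_spacing = 1000,
                  seed = 20260925)
  })
}

# the long-contig design: one 200 kb contig per (ploidy, coverage)
long_benchmark <- function() {
  cached("long_benchmark", {
    run_benchmark(ploidies = 1:16, coverages = c(15, 25, 50, 75),
                  lengths = 200000L, replicates = 1,
                  params = trained_params(), config = sim_model_config(16L),
                  snp_spacing = 1000, seed = 1123)
  })
}

# the length design: 2 kb / 20 kb / 200 kb at 50X, ploidies 1..8, one SNP
# per ~200 bp; the cheap short-contig cells get the most replicates since
# their per-cell accuracy estimates are the noisiest
length_benchmark <- function() {
  cached("length_benchmark", {
    reps <- c(`2000` = 100L, `20000` = 40L, `200000` = 20L)
    data.table::rbindlist(lapply(seq_along(reps), function(i) {
      run_benchmark(ploidies = 1:8, coverages = 50,
                    lengths = as.integer(names(reps)[i]),
                    replicates = reps[[i]], params = trained_params(),
                    config = sim_model_config(8L), snp_spacing = 200,
                    seed = 77 + i, call_genotypes = FALSE)
    }))
  })
}
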