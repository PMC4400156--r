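#' Configuration of the ploidy / dosage model
#'
#' @param p_snp prior probability that a position is heterozygous. The
#'   default of 1/200 reflects SNP densities commonly observed in higher
#'   plants; simulation benchmarks with sparser variation use 1/1000.
#' @param ploidy_range inclusive integer interval of candidate ploidies.
#' @param ploidy_prior optional numeric vector of prior weights over the
#'   candidate ploidies (normalised internally); default uniform.
#' @param variant_threshold Phred-like score above which a position is
#'   emitted as a variant.
#' @return an object of class `model_config`.
#' @export
model_config <- function(p_snp = 1 / 200, ploidy_range = c(1L, 8L),
                         ploidy_prior = NULL, variant_threshold = 40) {
  stopifnot(p_snp > 0, p_snp < 1, length(ploidy_range) == 2L,
            ploidy_range[1] >= 1L, ploidy_range[2] >= ploidy_range[1])
  ms <- seq.int(ploidy_range[1], ploidy_range[2])
  if (is.null(ploidy_prior)) ploidy_prior <- rep(1, length(ms))
  stopifnot(length(ploidy_prior) == length(ms), all(ploidy_prior > 0))
  structure(list(p_snp = p_snp, ploidy_range = as.integer(ploidy_range),
                 ploidies = ms,
                 ploidy_prior = ploidy_prior / sum(ploidy_prior),
                 variant_threshold = variant_threshold),
            class = "model_config")
}

#' Genotype (allele-dosage) prior
#'
#' The prior over the dosage g of the first allele given ploidy M: the
#' heterozygous mass `p_snp` is spread uniformly over the M-1 heterozygous
#' dosages, and the remaining mass is split evenly between the two
#' monomorphic states g = 0 and g = M. For M = 1 there are no heterozygous
#' states and the two homozygous states are renormalised to 1/2 each, so
#' that the prior always sums to one and haploid contigs are not penalised
#' by a constant per-position factor.
#'
#' @param M ploidy (>= 1).
#' @param p_snp heterozygosity prior.
#' @param g integer dosage(s) in 0..M.
#' @return numeric vector of prior probabilities.
#' @export
genotype_prior <- function(M, p_snp, g) {
  if (M < 1) stop("M must be >= 1")
  stopifnot(all(g >= 0), all(g <= M))
  if (M == 1) return(rep(0.5, length(g)))
  ifelse(g == 0L | g == M, (1 - p_snp) / 2, p_snp / (M - 1))
}

#' Probability that a read carries a given allele
#'
#' The true (unobserved) nucleotide of a read at a heterozygous position is
#' a Bernoulli draw with success probability equal to the proportion of the
#' first allele: P(T = 1) = g / M, P(T = 2) = 1 - g / M.
#'
#' @param M ploidy; `g` dosage of allele 1; `t` allele index 1 or 2.
#' @return numeric probability.
#' @export
true_allele_prob <- function(M, g, t) {
  stopifnot(all(t %in% c(1L, 2L)), all(g >= 0), all(g <= M))
  ifelse(t == 1L, g / M, 1 - g / M)
}

# When only one allele is observed at a position, the second-allele branch
# still needs a concrete nucleotide for the error-model lookups; the
# lexicographically smallest nucleotide different from allele1 is used
# (deterministic; no read can match it, so only the error branch prices it).
resolve_allele2 <- function(a1, a2) {
  ifelse(is.na(a2), ifelse(a1 == 0L, 1L, 0L), a2)
}

# P(observed base | true allele = a) for a table of observations, combining
# the no-error match branch and the error/substitution branch. `a` is a
# forward-strand nucleotide code; features are evaluated in sequencing
# orientation.
obs_probs <- function(obs, a, params) {
  rev <- obs$strand == "-"
  t_rd <- ifelse(rev, comp_int(a), a)
  o_rd <- ifelse(rev, comp_int(obs$nt), obs$nt)
  e <- error_probability(params, t_rd, obs$gg, obs$qs, obs$nqs)
  match <- as.numeric(obs$nt == a)
  (1 - e) * match + e * substitution_probability(params, t_rd, obs$gg, o_rd)
}

#' Log-likelihood of one read observation given the true allele
#'
#' log P(observed | T = allele_t), marginalised over the sequencing-error
#' indicator: the no-error branch contributes (1 - e) only when the observed
#' base matches the hypothesised allele, and the error branch contributes
#' e times the substitution probability (which is zero for the allele
#' itself). Likelihoods are floored at 1e-300 before taking logs.
#'
#' @param obs a single observation: list/row with `nt`, `qs`, `nqs`, `gg`
#'   and optionally `strand`.
#' @param allele1,allele2 candidate alleles (integer codes; `allele2` may be
#'   `NA` only when `t = 1`).
#' @param t allele index 1 or 2.
#' @param params an [error_model_params()] object.
#' @return log-probability (scalar).
#' @export
read_loglik <- function(obs, allele1, allele2, t, params) {
  a <- if (t == 1L) allele1 else allele2
  if (is.na(a)) stop("allele for t = ", t, " is absent")
  if (is.null(obs$strand)) obs$strand <- "+"
  log(max(obs_probs(obs, a, params), 1e-300))
}

#' Log-likelihood of a position pileup for one genotype
#'
#' Sum over reads of log of the Bernoulli mixture over the latent true
#' allele: sum_i log[ (g/M) P(o_i | T=allele1) + (1-g/M) P(o_i | T=allele2) ].
#' Monomorphic pileups (no second allele observed) evaluate the t = 2 branch
#' with match probability zero via a resolved placeholder allele. A pileup
#' with no reads contributes zero.
#'
#' @param pileup a list with `observations` (a `data.table` with columns
#'   `nt`, `qs`, `nqs`, `gg`, optional `strand`), `allele1` and `allele2`
#'   (integer codes; `allele2` may be `NA`).
#' @param M ploidy; `g` dosage of allele1 (0..M).
#' @param params an [error_model_params()] object.
#' @return scalar log-likelihood.
#' @export
position_loglik <- function(pileup, M, g, params) {
  stopifnot(g >= 0, g <= M)
  obs <- pileup$observations
  if (is.null(obs) || nrow(obs) == 0L) return(0)
  if (is.null(obs$strand)) obs$strand <- "+"
  a2 <- resolve_allele2(pileup$allele1, pileup$allele2)
  p1 <- obs_probs(obs, pileup$allele1, params)
  p2 <- obs_probs(obs, a2, params)
  f <- g / M
  sum(log(pmax(f * p1 + (1 - f) * p2, 1e-300)))
}

# Position x fraction log-likelihood matrix for a contig pileup, evaluated
# at an arbitrary grid of dosage fractions. This is the workhorse shared by
# ploidy estimation and genotype calling on alignment-derived pileups.
pileup_fraction_logliks <- function(cp, params, fractions) {
  obs <- cp$obs
  al <- cp$alleles
  posidx <- match(obs$pos, al$pos) - 1L
  a1 <- al$a1[posidx + 1L]
  a2r <- resolve_allele2(a1, al$a2[posidx + 1L])
  p1 <- obs_probs(obs, a1, params)
  p2 <- obs_probs(obs, a2r, params)
  cpp_obs_logliks(posidx, p1, p2, fractions, nrow(al))
}

# Distinct dosage fractions across candidate ploidies, with per-M index and
# log-prior structure (0-based indices, ready for the C++ kernels).
fraction_grid <- function(ms, p_snp) {
  fr <- sort(unique(unlist(lapply(ms, function(m) (0:m) / m))))
  g_idx <- lapply(ms, function(m) match((0:m) / m, fr) - 1L)
  g_logprior <- lapply(ms, function(m) log(genotype_prior(m, p_snp, 0:m)))
  list(fractions = fr, g_idx = g_idx, g_logprior = g_logprior)
}

#' Total log-likelihood of a contig for a candidate ploidy
#'
#' Sum over positions of the log of the prior-weighted sum over dosages of
#' the position likelihood, computed in log space with log-sum-exp.
#' Positions with no coverage contribute zero.
#'
#' @param cp a `contig_pileup` from [build_pileups()].
#' @param M candidate ploidy.
#' @param config a [model_config()].
#' @param params an [error_model_params()] object.
#' @return scalar log-likelihood.
#' @export
contig_loglik <- function(cp, M, config, params) {
  if (nrow(cp$obs) == 0L) return(0)
  fg <- fraction_grid(M, config$p_snp)
  mat <- pileup_fraction_logliks(cp, params, fg$fractions)
  lp <- fg$g_logprior[[1L]]
  terms <- sweep(mat[, fg$g_idx[[1L]] + 1L, drop = FALSE], 2L, lp, `+`)
  mx <- apply(terms, 1L, max)
  sum(mx + log(rowSums(exp(terms - mx))))
}

#' Estimate the ploidy of a contig
#'
#' Evaluates [contig_loglik()] for every candidate ploidy in the
#' configuration's range and selects the maximum of log-likelihood plus
#' log ploidy-prior, breaking ties toward the smaller ploidy (parsimony).
#' A contig with no aligned reads yields a no-call result rather than an
#' error. When the maximum sits on the upper boundary of the range the
#' result is flagged, since the true ploidy may lie beyond the range.
#'
#' @inheritParams contig_loglik
#' @return a `ploidy_result`: list with `contig`, `loglik` (named vector
#'   over candidate ploidies), `selected_M`, `n_positions_used`,
#'   `mean_coverage` and `status` (`"call"`, `"boundary"` or `"no-call"`).
#' @export
estimate_ploidy <- function(cp, config, params) {
  ms <- config$ploidies
  if (nrow(cp$obs) == 0L) {
    return(structure(list(contig = cp$contig,
                          loglik = stats::setNames(rep(NA_real_, length(ms)), ms),
                          selected_M = NA_integer_, n_positions_used = 0L,
                          mean_coverage = 0, status = "no-call"),
                     class = "ploidy_result"))
  }
  fg <- fraction_grid(ms, config$p_snp)
  mat <- pileup_fraction_logliks(cp, params, fg$fractions)
  ll <- vapply(seq_along(ms), function(i) {
    terms <- sweep(mat[, fg$g_idx[[i]] + 1L, drop = FALSE], 2L,
                   fg$g_logprior[[i]], `+`)
    mx <- apply(terms, 1L, max)
    sum(mx + log(rowSums(exp(terms - mx))))
  }, numeric(1))
  post <- ll + log(config$ploidy_prior)
  sel <- ms[which.max(post)] # which.max takes the first (smallest M) on ties
  status <- if (sel == max(ms) && length(ms) > 1L) "boundary" else "call"
  if (status == "boundary")
    warning("selected ploidy sits on the upper range boundary (",
            sel, "); the true ploidy may be larger")
  structure(list(contig = cp$contig, loglik = stats::setNames(ll, ms),
                 selected_M = sel,
                 n_positions_used = nrow(cp$alleles),
                 mean_coverage = nrow(cp$obs) / cp$length, status = status),
            class = "ploidy_result")
}

#' @export
print.ploidy_result <- function(x, ...) {
  cat("Contig ", x$contig, ": ploidy ",
      ifelse(is.na(x$selected_M), "no-call", x$selected_M),
      " (", x$status, "), ", x$n_positions_used, " covered positions, ",
      "mean coverage ", round(x$mean_coverage, 1), "\n", sep = "")
  invisible(x)
}

#' Call per-position genotypes at a fixed ploidy
#'
#' Computes the posterior over the dosage g at every covered position by
#' Bayes' rule with the genotype prior, reports the maximum-a-posteriori
#' dosage and a Phred-like variant score, -10 log10 P(g = 0 or g = M | data).
#' Positions are emitted as variants when the score exceeds the configured
#' threshold; monomorphic posteriors concentrate on g in {0, M} and are not
#' emitted.
#'
#' @param cp a `contig_pileup`.
#' @param selected_M the ploidy assumed constant along the contig.
#' @param config a [model_config()].
#' @param params an [error_model_params()] object.
#' @return a `data.table` with one row per covered position: `pos`
#'   (0-based), `a1`, `a2` (`NA` at monomorphic pileups), `g`, `post`
#'   (posterior of the MAP dosage), `score`, `n_p`, `emitted`.
#' @export
call_genotypes <- function(cp, selected_M, config, params) {
  al <- cp$alleles
  if (nrow(al) == 0L)
    return(data.table::data.table(pos = integer(), a1 = integer(),
                                  a2 = integer(), g = integer(),
                                  post = numeric(), score = numeric(),
                                  n_p = integer(), emitted = logical()))
  M <- as.integer(selected_M)
  fg <- fraction_grid(M, config$p_snp)
  mat <- pileup_fraction_logliks(cp, params, fg$fractions)
  terms <- sweep(mat, 2L, fg$g_logprior[[1L]], `+`)
  mx <- apply(terms, 1L, max)
  w <- exp(terms - mx)
  tot <- rowSums(w)
  post <- w / tot
  g <- max.col(post, ties.method = "first") - 1L
  lse_all <- mx + log(tot)
  mnv <- pmax(terms[, 1L], terms[, M + 1L])
  lse_nonvar <- mnv + log(exp(terms[, 1L] - mnv) + exp(terms[, M + 1L] - mnv))
  score <- -10 / log(10) * (lse_nonvar - lse_all)
  data.table::data.table(
    pos = al$pos, a1 = al$a1, a2 = al$a2, g = g,
    post = post[cbind(seq_len(nrow(post)), g + 1L)],
    score = pmax(score, 0), n_p = al$n,
    emitted = score > config$variant_threshold)
}
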