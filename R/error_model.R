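#' Sequencing-error model parameters
#'
#' Container for the per-base sequencing-error model. The probability that an
#' aligned base is a sequencing error is modelled, separately for every
#' stratum defined by the true nucleotide `t`, the GG-context flag `gg`
#' (whether the base is preceded in the read by two G's) and the quality-2
#' indicator `q` (`qs == 2`), as
#'
#'   P(E = 1 | t, gg, qs, nqs) = 1 / (1 + exp(alpha + beta * log(qs) +
#'                                            gamma * log(nqs)))
#'
#' where `qs` is the Phred quality of the base and `nqs` the neighboring
#' quality score (mean Phred quality of up to five flanking bases on each
#' side). `beta` is fixed at zero in quality-2 strata, where the nominal
#' quality carries no information. Conditional on an error, the observed
#' nucleotide follows a multinomial substitution distribution over the three
#' alternatives, indexed by (true nucleotide, gg).
#'
#' @param alpha,beta,gamma numeric arrays of dim `c(4, 2, 2)` indexed by
#'   (true nucleotide A/C/G/T, gg 0/1, q 0/1). `beta[, , 2]` must be zero.
#' @param substitution numeric array of dim `c(4, 2, 4)` giving
#'   P(observed | true, gg, error); the diagonal (observed == true) must be
#'   zero and each row must sum to one.
#' @param model_kind `"full"` or `"naive"`. The naive model ignores all
#'   features except `qs` and sets P(E = 1) = 10^(-qs / 10), with a uniform
#'   substitution distribution.
#' @param nqs_bin width used to discretise `nqs` when computing (and caching)
#'   error probabilities. Defaults to 0.1; likelihoods are insensitive to
#'   finer binning.
#' @param se optional list of arrays `alpha`, `beta`, `gamma` with standard
#'   errors of the estimates (filled in by [fit_error_model()]).
#' @return an object of class `error_model_params`.
#' @export
error_model_params <- function(alpha, beta, gamma, substitution,
                               model_kind = "full", nqs_bin = 0.1,
                               se = NULL) {
  dn <- list(NUCLEOTIDES, c("gg0", "gg1"), c("q0", "q1"))
  shape <- function(a) {
    a <- array(as.numeric(a), dim = c(4, 2, 2), dimnames = dn)
    a
  }
  alpha <- shape(alpha); beta <- shape(beta); gamma <- shape(gamma)
  if (any(beta[, , 2] != 0))
    stop("beta must be zero in quality-2 strata (q = 1)")
  substitution <- array(as.numeric(substitution), dim = c(4, 2, 4),
                        dimnames = list(NUCLEOTIDES, c("gg0", "gg1"),
                                        NUCLEOTIDES))
  for (t in 1:4) {
    if (any(abs(substitution[t, , t]) > 0))
      stop("substitution probability of the true nucleotide itself must be 0")
    rs <- rowSums(substitution[t, , , drop = TRUE])
    if (any(abs(rs - 1) > 1e-12))
      stop("substitution rows must sum to 1")
  }
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         substitution = substitution, model_kind = match.arg(model_kind,
                                                             c("full", "naive")),
         nqs_bin = nqs_bin, se = se),
    class = "error_model_params")
}

#' The naive quality-score-only error model
#'
#' P(E = 1 | qs) = 10^(-qs/10), uniform substitutions. Used as the baseline
#' in cross-validation comparisons and available for ploidy estimation.
#'
#' @return an `error_model_params` object with `model_kind = "naive"`.
#' @export
naive_error_model <- function() {
  sub <- array(1 / 3, dim = c(4, 2, 4))
  for (t in 1:4) sub[t, , t] <- 0
  z <- array(0, dim = c(4, 2, 2))
  error_model_params(z, z, z, sub, model_kind = "naive")
}

#' @export
print.error_model_params <- function(x, ...) {
  cat("Sequencing-error model (", x$model_kind, ")\n", sep = "")
  if (x$model_kind == "full") {
    cat("  logistic coefficients per (true nt, gg, q2) stratum; nqs bin ",
        x$nqs_bin, "\n", sep = "")
    cat("  alpha range: [", round(min(x$alpha), 3), ", ",
        round(max(x$alpha), 3), "]\n", sep = "")
  }
  invisible(x)
}

#' Neighboring quality score
#'
#' Mean Phred quality of up to ten bases adjacent to a given position (five
#' on each side, excluding the base itself). Near the read ends the average
#' runs over however many of those neighbors exist; for a read of length one
#' it falls back to the base's own quality.
#'
#' @param quality_string integer vector of Phred qualities for one read.
#' @param index 0-based position(s) within the read; defaults to all.
#' @return numeric vector of neighboring quality scores.
#' @export
compute_nqs <- function(quality_string, index = seq_along(quality_string) - 1L) {
  n <- length(quality_string)
  stopifnot(all(index >= 0L), all(index < n))
  if (n == 1L) return(as.numeric(quality_string[index + 1L]))
  cs <- cumsum(c(0, quality_string))
  i <- index + 1L # 1-based
  lo <- pmax(i - 5L, 1L)
  hi <- pmin(i + 5L, n)
  tot <- cs[hi + 1L] - cs[lo] - quality_string[i]
  cnt <- hi - lo # window size minus the base itself
  tot / cnt
}

# GG flag for every base of a read, given the observed sequence in
# sequencing orientation (integer codes). The first two bases get 0.
gg_flags <- function(seq_int) {
  n <- length(seq_int)
  if (n < 3L) return(rep(0L, n))
  g <- as.integer(seq_int == 2L)
  c(0L, 0L, as.integer(g[seq_len(n - 2L)] & g[2:(n - 1L)]))
}

#' Per-base features of aligned reads
#'
#' Computes, for every aligned (non-clipped, non-deleted) base of each read,
#' the observed nucleotide together with its error-model features: Phred
#' quality, neighboring quality score and GG-context flag. Features are
#' always computed in the read's sequencing orientation; observed and true
#' nucleotides are reported on the forward (reference) strand.
#'
#' @param reads a `data.frame` with one row per read and columns
#'   `pos` (0-based leftmost reference position), `seq` (read bases as
#'   aligned to the forward strand), `qual` (Phred+33 string), `strand`
#'   (`"+"`/`"-"`), and optionally `cigar` (defaults to fully aligned) and
#'   `read_id`.
#' @return a [data.table::data.table] with columns `read_id`, `refpos`
#'   (0-based), `nt` (forward-strand observed nucleotide), `qs`, `nqs`, `gg`
#'   (0/1), `strand`. Bases that are `N` are dropped and counted in the
#'   `dropped` attribute.
#' @export
read_base_features <- function(reads) {
  reads <- as.data.frame(reads)
  if (is.null(reads$cigar)) reads$cigar <- NA_character_
  if (is.null(reads$read_id)) reads$read_id <- as.character(seq_len(nrow(reads)))
  if (is.null(reads$strand)) reads$strand <- "+"
  if (is.null(reads$qual) || anyNA(reads$qual))
    stop("reads without quality strings cannot be used")
  out <- vector("list", nrow(reads))
  dropped <- 0L
  for (r in seq_len(nrow(reads))) {
    s <- seq2int(reads$seq[r])
    q <- qual2int(reads$qual[r])
    if (length(s) != length(q))
      stop("sequence and quality of read ", reads$read_id[r],
           " differ in length")
    rev <- identical(reads$strand[r], "-")
    # sequencing-orientation view of the read
    s_rd <- if (rev) comp_int(rev(s)) else s
    q_rd <- if (rev) rev(q) else q
    nqs_rd <- compute_nqs(q_rd)
    gg_rd <- gg_flags(s_rd)
    n <- length(s)
    # map read-orientation features back onto forward-strand coordinates
    ord <- if (rev) n:1 else 1:n
    nqs <- nqs_rd[order(ord)]
    gg <- gg_rd[order(ord)]
    # reference positions consumed per query base
    refpos <- cigar_query_refpos(reads$cigar[r], reads$pos[r], n)
    keep <- !is.na(refpos) & !is.na(s)
    dropped <- dropped + sum(!is.na(refpos) & is.na(s))
    out[[r]] <- data.table::data.table(
      read_id = reads$read_id[r], refpos = refpos[keep], nt = s[keep],
      qs = q[keep], nqs = nqs[keep], gg = gg[keep],
      strand = reads$strand[r])
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "dropped", dropped)
  res
}

# 0-based reference position for each query base, NA for soft-clipped or
# inserted bases. `cigar` NA means fully aligned.
cigar_query_refpos <- function(cigar, pos, qlen) {
  if (is.na(cigar)) return(pos + seq_len(qlen) - 1L)
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  refpos <- rep(NA_integer_, qlen)
  qi <- 0L; ri <- pos
  for (k in seq_along(ops)) {
    op <- ops[k]; ln <- lens[k]
    if (op %in% c("M", "=", "X")) {
      refpos[qi + seq_len(ln)] <- ri + seq_len(ln) - 1L
      qi <- qi + ln; ri <- ri + ln
    } else if (op %in% c("I", "S")) {
      qi <- qi + ln
    } else if (op %in% c("D", "N")) {
      ri <- ri + ln
    } # H, P consume nothing
  }
  refpos
}

#' Extract error-model training observations
#'
#' Compares each aligned base of a (monomorphic-sample) read set against a
#' trusted reference sequence, assuming the reference is error-free, so that
#' observed/reference mismatches can be attributed to sequencing error. One
#' observation is produced per aligned, non-clipped base, carrying the
#' error-model features computed from the read's own sequence and qualities.
#'
#' @param reads as in [read_base_features()].
#' @param reference reference sequence for the aligned contig, either a
#'   string or an integer-coded vector.
#' @return a `data.table` with columns `true_nt`, `nt` (both forward-strand
#'   integer codes 0..3), `qs`, `nqs`, `gg`, `strand` and `is_error`.
#'   Bases whose reference is ambiguous are dropped.
#' @export
extract_training_observations <- function(reads, reference) {
  if (is.character(reference)) reference <- seq2int(reference)
  feat <- read_base_features(reads)
  if (nrow(feat) && max(feat$refpos) >= length(reference))
    stop("reference does not cover all aligned positions")
  feat[, true_nt := reference[refpos + 1L]]
  feat <- feat[!is.na(true_nt)]
  feat[, is_error := as.integer(nt != true_nt)]
  feat[]
}

# Stratum-wise design matrix columns for the logistic fit. In sequencing
# orientation the stratum true nucleotide is complemented for minus-strand
# observations by the caller; here t/gg/q are already resolved.
.fit_one_stratum <- function(cells, q2, lambda, max_iter, tol) {
  # cells: data.table(lqs, lnqs, n, k)
  X <- if (q2) cbind(1, cells$lnqs) else cbind(1, cells$lqs, cells$lnqs)
  p <- ncol(X)
  pen <- c(1e-8, rep(lambda, p - 1L))
  b <- rep(0, p)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% b), -30), 30)
    mu <- stats::plogis(eta)
    ll <- sum(cells$k * eta - cells$n * log1p(exp(eta))) - 0.5 * sum(pen * b^2)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    W <- cells$n * mu * (1 - mu)
    H <- crossprod(X, X * W) + diag(pen, p)
    g <- crossprod(X, cells$k - cells$n * mu) - pen * b
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    b <- pmin(pmax(b + drop(step), -30), 30)
  }
  eta <- pmin(pmax(drop(X %*% b), -30), 30)
  mu <- stats::plogis(eta)
  W <- cells$n * mu * (1 - mu)
  H <- crossprod(X, X * W) + diag(pen, p)
  se <- sqrt(diag(tryCatch(solve(H), error = function(e) diag(NA_real_, p))))
  list(coef = b, se = se)
}

#' Fit the sequencing-error model
#'
#' Maximum-likelihood logistic fit of the error indicator on `log(qs)` and
#' `log(nqs)`, separately for every (true nucleotide, gg, quality-2) stratum,
#' with the `log(qs)` coefficient fixed at zero in quality-2 strata. A light
#' L2 penalty (`lambda`, applied to the slope coefficients) keeps the fit
#' finite in degenerate strata, e.g. when a small training set contains no
#' errors for some stratum; coefficients are additionally capped at +/-30.
#' Substitution rows are the maximum-likelihood multinomial frequencies of
#' the observed nucleotide among errors per (true nucleotide, gg); strata
#' with no observed errors fall back to the uniform distribution. Strata
#' with no observations at all inherit the coefficients of the fit pooled
#' over true nucleotides for the same (gg, q).
#'
#' Note: the fit conditions on the *sequencing-orientation* true nucleotide,
#' so minus-strand observations are complemented before stratification.
#'
#' @param observations a `data.table` from
#'   [extract_training_observations()] (columns `true_nt`, `nt`, `qs`,
#'   `nqs`, `gg`, `is_error`, optional `strand`, optional `weight`).
#' @param lambda ridge penalty on slope coefficients (default `1e-3`).
#' @param max_iter,tol IRLS iteration cap and log-likelihood convergence
#'   tolerance.
#' @param nqs_bin `nqs` discretisation used for fitting and later caching.
#' @return an [error_model_params()] object with standard errors in `$se`.
#' @export
fit_error_model <- function(observations, lambda = 1e-3, max_iter = 100,
                            tol = 1e-8, nqs_bin = 0.1) {
  obs <- data.table::as.data.table(observations)
  if (nrow(obs) == 0L) stop("no training observations")
  if (is.null(obs$weight)) obs[, weight := 1]
  if (!is.null(obs$strand)) {
    rev <- obs$strand == "-"
    obs[, `:=`(t_rd = ifelse(rev, comp_int(true_nt), true_nt),
               o_rd = ifelse(rev, comp_int(nt), nt))]
  } else {
    obs[, `:=`(t_rd = true_nt, o_rd = nt)]
  }
  obs[, `:=`(q2 = as.integer(qs == 2L),
             nqsb = pmax(floor(nqs / nqs_bin + 0.5) * nqs_bin, nqs_bin))]
  cells <- obs[, .(n = sum(weight), k = sum(weight * is_error)),
               by = .(t_rd, gg, q2, qs, nqsb)]
  cells[, `:=`(lqs = log(qs), lnqs = log(nqsb))]

  dn <- list(NUCLEOTIDES, c("gg0", "gg1"), c("q0", "q1"))
  alpha <- beta <- gamma <- array(NA_real_, dim = c(4, 2, 2), dimnames = dn)
  se_a <- se_b <- se_g <- array(NA_real_, dim = c(4, 2, 2), dimnames = dn)
  pooled <- vector("list", 4L)
  for (ggv in 0:1) for (qv in 0:1) {
    cp <- cells[gg == ggv & q2 == qv]
    pool_fit <- if (nrow(cp)) {
      cpa <- cp[, .(n = sum(n), k = sum(k)), by = .(qs, nqsb, lqs, lnqs)]
      .fit_one_stratum(cpa, qv == 1L, lambda, max_iter, tol)
    } else NULL
    for (tv in 0:3) {
      ct <- cp[t_rd == tv]
      fit <- if (nrow(ct)) {
        .fit_one_stratum(ct, qv == 1L, lambda, max_iter, tol)
      } else pool_fit
      if (is.null(fit)) next
      # stored in the convention P(E=1) = plogis(-(a + b log qs + g log nqs))
      co <- -fit$coef
      if (qv == 1L) {
        alpha[tv + 1L, ggv + 1L, 2L] <- co[1L]
        beta[tv + 1L, ggv + 1L, 2L] <- 0
        gamma[tv + 1L, ggv + 1L, 2L] <- co[2L]
        se_a[tv + 1L, ggv + 1L, 2L] <- fit$se[1L]
        se_g[tv + 1L, ggv + 1L, 2L] <- fit$se[2L]
      } else {
        alpha[tv + 1L, ggv + 1L, 1L] <- co[1L]
        beta[tv + 1L, ggv + 1L, 1L] <- co[2L]
        gamma[tv + 1L, ggv + 1L, 1L] <- co[3L]
        se_a[tv + 1L, ggv + 1L, 1L] <- fit$se[1L]
        se_b[tv + 1L, ggv + 1L, 1L] <- fit$se[2L]
        se_g[tv + 1L, ggv + 1L, 1L] <- fit$se[3L]
      }
    }
  }
  alpha[is.na(alpha)] <- 30; beta[is.na(beta)] <- 0; gamma[is.na(gamma)] <- 0

  sub <- array(1 / 3, dim = c(4, 2, 4))
  for (t in 1:4) sub[t, , t] <- 0
  errs <- obs[is_error == 1L,
              .(n = sum(weight)), by = .(t_rd, gg, o_rd)]
  for (tv in 0:3) for (ggv in 0:1) {
    e <- errs[t_rd == tv & gg == ggv]
    if (nrow(e)) {
      row <- rep(0, 4)
      row[e$o_rd + 1L] <- e$n
      row[tv + 1L] <- 0
      if (sum(row) > 0) sub[tv + 1L, ggv + 1L, ] <- row / sum(row)
    }
  }
  error_model_params(alpha, beta, gamma, sub, model_kind = "full",
                     nqs_bin = nqs_bin,
                     se = list(alpha = se_a, beta = se_b, gamma = se_g))
}

#' Per-base error probability
#'
#' Evaluates the fitted error model for vectors of features. `nqs` is
#' discretised to the model's `nqs_bin` so that repeated queries with
#' equivalent features are exactly reproducible (and cacheable). For the
#' naive model the probability is `10^(-qs/10)` regardless of the other
#' features.
#'
#' @param params an [error_model_params()] object.
#' @param true_nt integer codes 0..3 of the hypothesised true nucleotide in
#'   sequencing orientation.
#' @param gg,qs,nqs feature vectors (recycled).
#' @return numeric vector of error probabilities in (0, 1).
#' @export
error_probability <- function(params, true_nt, gg, qs, nqs) {
  if (params$model_kind == "naive") {
    p <- 10^(-qs / 10)
    return(pmin(pmax(p, 1e-12), 1 - 1e-12))
  }
  stopifnot(all(qs >= 2), all(nqs > 0))
  # round half away from zero, matching the C++ kernels exactly
  nqsb <- pmax(floor(nqs / params$nqs_bin + 0.5) * params$nqs_bin,
               params$nqs_bin)
  q <- as.integer(qs == 2L)
  idx <- cbind(true_nt + 1L, gg + 1L, q + 1L)
  eta <- params$alpha[idx] + params$beta[idx] * log(qs) +
    params$gamma[idx] * log(nqsb)
  pmin(pmax(stats::plogis(-eta), 1e-12), 1 - 1e-12)
}

#' Memoised error-probability evaluator
#'
#' Returns a function with the same interface as [error_probability()] that
#' caches results per (true nt, gg, qs, binned nqs) key. Cached and uncached
#' values agree bit-for-bit because both evaluate the model on the binned
#' `nqs` value.
#'
#' @param params an [error_model_params()] object.
#' @return a function `(true_nt, gg, qs, nqs) -> probability` with an
#'   environment-backed cache.
#' @export
error_probability_cached <- function(params) {
  cache <- new.env(parent = emptyenv())
  function(true_nt, gg, qs, nqs) {
    nqsb <- pmax(floor(nqs / params$nqs_bin + 0.5) * params$nqs_bin,
                 params$nqs_bin)
    key <- paste(true_nt, gg, qs, format(nqsb, digits = 12), sep = "|")
    out <- numeric(length(key))
    for (i in seq_along(key)) {
      hit <- cache[[key[i]]]
      if (is.null(hit)) {
        hit <- error_probability(params, true_nt[i], gg[i], qs[i], nqsb[i])
        assign(key[i], hit, envir = cache)
      }
      out[i] <- hit
    }
    out
  }
}

#' Substitution probability under the error branch
#'
#' P(observed | true, gg, error); zero when the observed equals the true
#' nucleotide. Nucleotides are in sequencing orientation.
#'
#' @param params an [error_model_params()] object.
#' @param true_nt,gg,observed_nt integer feature vectors (codes 0..3).
#' @return numeric vector of probabilities.
#' @export
substitution_probability <- function(params, true_nt, gg, observed_nt) {
  params$substitution[cbind(true_nt + 1L, gg + 1L, observed_nt + 1L)]
}

#' Cross-validated comparison of the full and naive error models
#'
#' K-fold cross-validation of the full logistic model against the naive
#' quality-only model. The fit metric is the mean held-out negative
#' log-likelihood of the error indicator (lower is better).
#'
#' @param observations training observations as for [fit_error_model()].
#' @param folds number of folds (>= 2).
#' @param lambda passed to [fit_error_model()].
#' @return a `data.frame` with one row per fold and columns `fold`,
#'   `nll_full`, `nll_naive`.
#' @export
evaluate_error_model <- function(observations, folds = 4, lambda = 1e-3) {
  obs <- data.table::as.data.table(observations)
  if (folds < 2) stop("folds must be >= 2")
  if (nrow(obs) < folds) stop("fewer observations than folds")
  fold <- sample(rep_len(seq_len(folds), nrow(obs)))
  naive <- naive_error_model()
  res <- lapply(seq_len(folds), function(f) {
    train <- obs[fold != f]
    test <- obs[fold == f]
    fit <- fit_error_model(train, lambda = lambda)
    t_rd <- test$true_nt
    if (!is.null(test$strand)) {
      rev <- test$strand == "-"
      t_rd <- ifelse(rev, comp_int(test$true_nt), test$true_nt)
    }
    pf <- error_probability(fit, t_rd, test$gg, test$qs, test$nqs)
    pn <- error_probability(naive, t_rd, test$gg, test$qs, test$nqs)
    nll <- function(p) -mean(ifelse(test$is_error == 1L, log(p), log1p(-p)))
    data.frame(fold = f, nll_full = nll(pf), nll_naive = nll(pn))
  })
  do.call(rbind, res)
}

#' Write / read error-model parameters as TSV
#'
#' Plain-text persistence for fitted models. The file has two sections:
#' `coef` rows with columns (section, true_nt, gg, q, alpha, beta, gamma)
#' and `sub` rows with columns (section, true_nt, gg, obs_nt, prob), in that
#' column order, preceded by `#` header lines recording the model kind and
#' nqs bin.
#'
#' @param params an [error_model_params()] object.
#' @param path file path.
#' @return `read_error_params` returns an `error_model_params` object.
#' @export
write_error_params <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ploidycall error model"),
               paste0("# model_kind\t", params$model_kind),
               paste0("# nqs_bin\t", format(params$nqs_bin, digits = 12)),
               "section\ttrue_nt\tgg\tq\tobs_nt\talpha\tbeta\tgamma\tprob"),
             con)
  for (tv in 1:4) for (ggv in 1:2) for (qv in 1:2) {
    writeLines(paste("coef", NUCLEOTIDES[tv], ggv - 1L, qv - 1L, ".",
                     format(params$alpha[tv, ggv, qv], digits = 17),
                     format(params$beta[tv, ggv, qv], digits = 17),
                     format(params$gamma[tv, ggv, qv], digits = 17), ".",
                     sep = "\t"), con)
  }
  for (tv in 1:4) for (ggv in 1:2) for (ov in 1:4) {
    writeLines(paste("sub", NUCLEOTIDES[tv], ggv - 1L, ".", NUCLEOTIDES[ov],
                     ".", ".", ".",
                     format(params$substitution[tv, ggv, ov], digits = 17),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_error_params
#' @export
read_error_params <- function(path) {
  hdr <- readLines(path, n = 3L)
  kind <- sub("^# model_kind\t", "", hdr[2L])
  nqs_bin <- as.numeric(sub("^# nqs_bin\t", "", hdr[3L]))
  tab <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           na.strings = ".", stringsAsFactors = FALSE)
  alpha <- beta <- gamma <- array(0, dim = c(4, 2, 2))
  sub <- array(0, dim = c(4, 2, 4))
  co <- tab[tab$section == "coef", ]
  idx <- cbind(match(co$true_nt, NUCLEOTIDES), co$gg + 1L, co$q + 1L)
  alpha[idx] <- co$alpha; beta[idx] <- co$beta; gamma[idx] <- co$gamma
  su <- tab[tab$section == "sub", ]
  sub[cbind(match(su$true_nt, NUCLEOTIDES), su$gg + 1L,
            match(su$obs_nt, NUCLEOTIDES))] <- su$prob
  # renormalise against round-off in the text representation
  for (t in 1:4) for (g in 1:2) {
    s <- sum(sub[t, g, ]); if (s > 0) sub[t, g, ] <- sub[t, g, ] / s
  }
  error_model_params(alpha, beta, gamma, sub, model_kind = kind,
                     nqs_bin = nqs_bin)
}

#' Simulate training observations from known coefficients
#'
#' Draws feature vectors (quality from a discrete level distribution, `nqs`
#' as the mean of ten independent quality draws, `gg` Bernoulli, true
#' nucleotide uniform) and error indicators from the logistic model with the
#' supplied parameters. Used for parameter-recovery and model-comparison
#' tests; the error indicator is sampled from the *same* family the fitter
#' assumes.
#'
#' @param n number of observations.
#' @param params an [error_model_params()] object supplying the generating
#'   coefficients and substitution rows (either model kind).
#' @param q_levels,q_weights discrete quality levels and their sampling
#'   weights.
#' @param p_gg marginal probability of the GG context flag.
#' @return a `data.table` in the format accepted by [fit_error_model()].
#' @export
simulate_training_observations <- function(n, params,
                                           q_levels = c(2L, 12L, 23L, 32L, 37L),
                                           q_weights = c(.05, .05, .12, .25, .53),
                                           p_gg = 0.06) {
  qs <- sample(q_levels, n, replace = TRUE, prob = q_weights)
  nqs <- colMeans(matrix(sample(q_levels, 10L * n, replace = TRUE,
                                prob = q_weights), nrow = 10L))
  gg <- stats::rbinom(n, 1L, p_gg)
  true_nt <- sample(0:3, n, replace = TRUE)
  e <- error_probability(params, true_nt, gg, qs, nqs)
  is_error <- stats::rbinom(n, 1L, e)
  nt <- true_nt
  if (any(is_error == 1L)) {
    idx <- which(is_error == 1L)
    for (i in idx) {
      p <- params$substitution[true_nt[i] + 1L, gg[i] + 1L, ]
      nt[i] <- sample(0:3, 1L, prob = p)
    }
  }
  data.table::data.table(true_nt = true_nt, nt = nt, qs = qs, nqs = nqs,
                         gg = gg, is_error = is_error)
}
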