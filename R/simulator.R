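#' Parametric Illumina-like error/quality profile for the read simulator
#'
#' The simulator draws base qualities from a small set of discrete levels
#' (mirroring the binned quality scores emitted by recent Illumina
#' base callers), with per-cycle level weights interpolated linearly
#' between a start-of-read and end-of-read mixture so that mean quality
#' decays along the read. Sequencing errors are then drawn from a logistic
#' model on log quality and log neighboring quality with a GG-context
#' effect and a separate quality-2 stratum in which the nominal quality is
#' ignored -- quality-2 bases are given a true error rate far below the
#' 63% their Phred value would imply, emulating the well-known
#' miscalibration of the lowest quality bin. Substitutions conditional on
#' an error are transition-biased.
#'
#' @param q_levels integer quality levels.
#' @param w_start,w_end level weights at the first and last cycle.
#' @param alpha_t small per-nucleotide offsets to the logistic intercept.
#' @param beta,gamma slopes on log(qs) (non-quality-2 strata only) and
#'   log(nqs); `gamma` has one value per quality-2 stratum (q = 0, q = 1).
#' @param alpha0 intercepts for the (q = 0, q = 1) strata at gg = 0.
#' @param gg_shift intercept shift applied when the base is preceded by GG
#'   (negative values increase the error odds).
#' @return an object of class `sim_error_profile` containing the level
#'   model and the generating [error_model_params()] (`$truth`).
#' @export
sim_error_profile <- function(q_levels = c(2L, 12L, 23L, 32L, 37L),
                              w_start = c(0.02, 0.02, 0.06, 0.20, 0.70),
                              w_end = c(0.08, 0.06, 0.16, 0.30, 0.40),
                              alpha_t = c(A = 0, C = 0.1, G = -0.15, T = 0.05),
                              beta = 3.0, gamma = c(0.5, 0.8),
                              alpha0 = c(-5.996, -0.524), gg_shift = -0.4) {
  stopifnot(length(q_levels) == length(w_start),
            length(w_start) == length(w_end),
            all(w_start > 0), all(w_end > 0), length(gamma) == 2L,
            length(alpha0) == 2L)
  a <- array(0, dim = c(4, 2, 2))
  b <- array(0, dim = c(4, 2, 2))
  g <- array(0, dim = c(4, 2, 2))
  for (tv in 1:4) for (ggv in 1:2) for (qv in 1:2) {
    a[tv, ggv, qv] <- alpha0[qv] + alpha_t[tv] + (ggv - 1L) * gg_shift
    b[tv, ggv, qv] <- if (qv == 1L) beta else 0
    g[tv, ggv, qv] <- gamma[qv]
  }
  # transition-biased substitution rows P(observed | true, gg, error)
  sub <- array(0, dim = c(4, 2, 4))
  rows <- rbind(c(0, 0.22, 0.50, 0.28),   # A -> (C, G, T)
                c(0.24, 0, 0.26, 0.50),   # C
                c(0.50, 0.26, 0, 0.24),   # G
                c(0.28, 0.50, 0.22, 0))   # T
  for (ggv in 1:2) sub[, ggv, ] <- rows
  truth <- error_model_params(a, b, g, sub, model_kind = "full")
  structure(list(q_levels = as.integer(q_levels), w_start = w_start,
                 w_end = w_end, truth = truth, beta = beta, gamma = gamma),
            class = "sim_error_profile")
}

#' Simulation design
#'
#' Bundles all knobs of one simulated sequencing experiment: the ploidy and
#' length of the contig, the mean SNP spacing (heterozygous sites are
#' placed by a Poisson process), the per-haploid-copy coverage, read and
#' fragment geometry, the error profile, and the seed making the run fully
#' reproducible.
#'
#' @param ploidy number of haploid copies M (>= 1).
#' @param length contig length in bp.
#' @param snp_spacing mean distance between heterozygous sites in bp.
#' @param coverage per-haploid-copy coverage (X); total coverage is
#'   `ploidy * coverage`.
#' @param read_length read length in bp (paired reads).
#' @param frag_mean,frag_sd fragment length distribution (bp).
#' @param profile a [sim_error_profile()].
#' @param seed integer seed.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(ploidy, length, snp_spacing = 1000, coverage = 50,
                       read_length = 100L, frag_mean = 300, frag_sd = 30,
                       profile = sim_error_profile(), seed = 1L) {
  stopifnot(ploidy >= 1, length > 0, snp_spacing > 0, coverage > 0,
            read_length >= 2L, frag_mean >= read_length, frag_sd >= 0)
  structure(list(ploidy = as.integer(ploidy), length = as.integer(length),
                 snp_spacing = snp_spacing, coverage = coverage,
                 read_length = as.integer(read_length),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 profile = profile, seed = as.integer(seed)),
            class = "sim_design")
}

# Per-cycle cumulative quality-level weights (Q x read_length matrix).
quality_cycle_cum <- function(profile, read_length) {
  Q <- length(profile$q_levels)
  w <- vapply(seq_len(read_length), function(j) {
    frac <- if (read_length == 1L) 0 else (j - 1) / (read_length - 1)
    wj <- profile$w_start + frac * (profile$w_end - profile$w_start)
    cumsum(wj / sum(wj))
  }, numeric(Q))
  matrix(w, nrow = Q)
}

# Flattened generative arrays for the C++ kernel.
gen_model_arrays <- function(profile) {
  tr <- profile$truth
  subcum <- array(0, dim = c(4, 2, 4))
  for (tv in 1:4) for (ggv in 1:2)
    subcum[tv, ggv, ] <- cumsum(tr$substitution[tv, ggv, ])
  list(alpha = as.numeric(tr$alpha), beta = profile$beta,
       gamma = profile$gamma, subcum = as.numeric(subcum))
}

# Analysis-side lookup tables for the C++ kernel: error probabilities per
# (true nt, gg, quality level, binned nqs) and substitution probabilities.
analysis_tables <- function(params, q_levels, nqs_bin, nqs_max = 45) {
  Q <- length(q_levels)
  B <- as.integer(ceiling(nqs_max / nqs_bin)) + 2L
  grid <- expand.grid(t = 0:3, gg = 0:1, q = seq_len(Q) - 1L,
                      nb = seq_len(B) - 1L)
  nqs <- pmax(grid$nb, 1L) * nqs_bin
  e <- error_probability(params, grid$t, grid$gg, q_levels[grid$q + 1L], nqs)
  psub <- numeric(4 * 2 * 4)
  for (tv in 0:3) for (ggv in 0:1) for (ov in 0:3)
    psub[1L + tv + 4L * (ggv + 2L * ov)] <-
      params$substitution[tv + 1L, ggv + 1L, ov + 1L]
  list(etab = e, psub = psub, B = B)
}

#' Simulate a polyploid contig with heterozygous sites
#'
#' Draws an i.i.d. uniform consensus sequence, places heterozygous sites by
#' a Poisson process with the design's mean spacing, samples each SNP's
#' dosage uniformly from 1..(M-1), and assigns the alternative allele to a
#' random subset of haplotype copies so that exactly `dosage` copies carry
#' the consensus (first) allele. A haploid design has no heterozygous
#' sites.
#'
#' @param design a [sim_design()]. The design seed is applied unless
#'   `reseed = FALSE` (used internally when the caller manages the RNG).
#' @param reseed set the RNG to `design$seed` first (default `TRUE`).
#' @return a list with `haplotypes` (M x L integer matrix of codes 0..3)
#'   and `truth` (`data.table` with `pos` (0-based), `allele1`, `allele2`,
#'   `dosage`), plus the design.
#' @export
simulate_contig <- function(design, reseed = TRUE) {
  if (reseed) set.seed(design$seed)
  M <- design$ploidy
  L <- design$length
  consensus <- sample.int(4L, L, replace = TRUE) - 1L
  haps <- matrix(rep(consensus, each = M), nrow = M)
  truth <- data.table::data.table(pos = integer(), allele1 = integer(),
                                  allele2 = integer(), dosage = integer())
  if (M >= 2L) {
    n_snp <- stats::rpois(1L, L / design$snp_spacing)
    n_snp <- min(n_snp, L)
    if (n_snp > 0L) {
      pos <- sort(sample.int(L, n_snp)) - 1L
      a1 <- consensus[pos + 1L]
      alt <- vapply(a1, function(a) sample(setdiff(0:3, a), 1L), integer(1))
      dosage <- sample.int(M - 1L, n_snp, replace = TRUE)
      for (i in seq_len(n_snp)) {
        carriers <- sample.int(M, M - dosage[i]) # copies with allele2
        haps[carriers, pos[i] + 1L] <- alt[i]
      }
      truth <- data.table::data.table(pos = pos, allele1 = a1,
                                      allele2 = alt, dosage = dosage)
    }
  }
  list(haplotypes = haps, truth = truth, design = design)
}

n_fragments <- function(design) {
  max(0L, as.integer(round(design$length * design$ploidy * design$coverage /
                             (2 * design$read_length))))
}

#' Simulate paired reads from a haplotype set
#'
#' Fragments are placed uniformly along the contig and assigned to a
#' haplotype copy uniformly at random (the random-sampling assumption of
#' the ploidy model); each fragment yields a forward first mate and a
#' reverse-complemented second mate of the design's read length, with
#' qualities and substitution errors drawn from the design's error
#' profile. Reads are returned in coordinate order of their fragments.
#'
#' @param haplotypes M x L integer matrix (from [simulate_contig()]).
#' @param design a [sim_design()].
#' @param reseed set the RNG to `design$seed + 1` first (default `TRUE`;
#'   the offset keeps read placement independent of contig simulation).
#' @return a `data.table` with one row per read: `read_id`, `frag`, `mate`
#'   (1/2), `start` (0-based leftmost forward-strand position), `strand`
#'   (`"+"`/`"-"`), `hap`, `seq` and `qual` in sequencing orientation.
#' @export
simulate_reads <- function(haplotypes, design, reseed = TRUE) {
  if (reseed) set.seed(design$seed + 1L)
  prof <- design$profile
  gen <- gen_model_arrays(prof)
  qcum <- quality_cycle_cum(prof, design$read_length)
  # analysis tables are unused in read-emission mode; pass minimal ones
  dummy <- analysis_tables(naive_error_model(), prof$q_levels, 0.5)
  res <- cpp_sim_run(haplotypes, n_fragments(design), design$read_length,
                     design$frag_mean, design$frag_sd, prof$q_levels, qcum,
                     gen$alpha, gen$beta, gen$gamma, gen$subcum,
                     dummy$etab, dummy$psub, 0.5, dummy$B,
                     numeric(0), list(), list(), 4L, 0L, 0)
  mate <- rep_len(1:2, length(res$start))
  data.table::data.table(
    read_id = paste0("frag", res$frag + 1L, "/", mate),
    frag = res$frag + 1L, mate = mate, start = res$start,
    strand = c("+", "-")[res$strand + 1L], hap = res$hap + 1L,
    seq = res$seq, qual = res$qual)
}

#' Convert simulated reads to alignment records
#'
#' Rewrites the sequencing-orientation reads of [simulate_reads()] as
#' forward-strand alignment records with perfect (truth) placements, the
#' format consumed by [build_pileups()] and [filter_alignments()] -- an
#' alignment-free stand-in for running an external aligner on simulator
#' output.
#'
#' @param reads a `data.table` from [simulate_reads()].
#' @param contig contig name used in the records.
#' @return a `data.table` of alignment records (forward-strand `seq` and
#'   `qual`, `flag`, `mapq` 60, full-match `cigar`, template length).
#' @export
reads_to_alignments <- function(reads, contig = "contig1") {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           vapply(s, function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = ""),
                  character(1), USE.NAMES = FALSE))
  }
  rev <- reads$strand == "-"
  seqf <- reads$seq
  qualf <- reads$qual
  if (any(rev)) {
    seqf[rev] <- revcomp(reads$seq[rev])
    qualf[rev] <- vapply(reads$qual[rev],
                         function(x) paste(rev(strsplit(x, "")[[1L]]),
                                           collapse = ""),
                         character(1), USE.NAMES = FALSE)
  }
  rl <- nchar(reads$seq)
  dt <- data.table::data.table(
    read_id = reads$read_id, flag = ifelse(rev, 16L, 0L) +
      ifelse(reads$mate == 1L, 64L, 128L) + 1L + 2L + 32L,
    contig = contig, pos = reads$start, mapq = 60L,
    cigar = paste0(rl, "M"), strand = reads$strand, isize = 0L,
    seq = seqf, qual = qualf)
  # template length per fragment (leftmost mate positive)
  frag <- reads$frag
  span <- stats::ave(reads$start + rl, frag, FUN = max) -
    stats::ave(reads$start, frag, FUN = min)
  dt[, isize := ifelse(reads$mate == 1L, span, -span)]
  data.table::setkey(dt, pos)
  dt[]
}

#' Write simulated reads as FASTQ
#'
#' @param reads a `data.table` from [simulate_reads()].
#' @param prefix output path prefix; `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return the two file paths, invisibly.
#' @export
write_sim_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, "_", 1:2, ".fastq")
  for (m in 1:2) {
    rm_ <- reads[reads$mate == m]
    lines <- as.vector(rbind(paste0("@", rm_$read_id), rm_$seq, "+", rm_$qual))
    writeLines(lines, paths[m])
  }
  invisible(paths)
}

#' Write simulated reads as SAM with truth placements
#'
#' Emits an unsorted SAM file whose alignments are the simulator's true
#' placements, suitable for conversion with [Rsamtools::asBam()] to drive
#' the BAM-based estimation path in tests.
#'
#' @param reads a `data.table` from [simulate_reads()].
#' @param contig contig name; `length` its length for the header.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(reads, contig, length, path) {
  aln <- reads_to_alignments(reads, contig)
  aln <- aln[order(aln$pos)]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", contig, "\tLN:", length))
  body <- paste(sub("/[12]$", "", aln$read_id), aln$flag, contig,
                aln$pos + 1L, aln$mapq, aln$cigar, "=", 1L, aln$isize,
                aln$seq, aln$qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Downsample read pairs
#'
#' Keeps each fragment (read pair) independently with the given
#' probability; both mates are kept or dropped together.
#'
#' @param reads a `data.table` from [simulate_reads()].
#' @param fraction keep probability in (0, 1].
#' @param seed integer seed.
#' @return the downsampled `data.table`.
#' @export
downsample <- function(reads, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(reads)
  set.seed(seed)
  frags <- unique(reads$frag)
  keep <- frags[stats::runif(length(frags)) < fraction]
  reads[reads$frag %in% keep]
}

# ---------------------------------------------------------------------------
# fused simulation + analysis (the scale path)
# ---------------------------------------------------------------------------

#' Simulate a contig and analyse it without materialising reads
#'
#' Runs the full pipeline -- haplotype simulation, paired-read generation,
#' pileup construction, ploidy estimation and (optionally) genotype
#' calling -- in a single streaming pass, without storing reads or
#' per-base observations. The read stream is identical to
#' [simulate_reads()] with the same design (both consume the same RNG
#' stream), so results agree with the materialised path.
#'
#' @param design a [sim_design()].
#' @param params the [error_model_params()] used for analysis (typically
#'   fitted by [fit_error_model()] on training simulations; the generating
#'   profile is never given to the analysis).
#' @param config a [model_config()].
#' @param call_genotypes also produce per-position genotype calls at the
#'   selected ploidy (default `TRUE`).
#' @param nqs_bin discretisation of the neighboring quality score used for
#'   likelihood caching in the streaming kernel (default 0.5).
#' @param quant resolution of the streaming kernel's likelihood cache, in
#'   quantisation steps per natural-log unit of probability (default 64,
#'   i.e. error probabilities are represented to within ~1.6%); 0 disables
#'   quantisation and keeps one exact cached row per feature combination.
#' @return a list with `ploidy` (a `ploidy_result`), `calls` (a
#'   `data.table` as returned by [call_genotypes()], or `NULL`), `truth`
#'   (the simulated SNP table) and `design`.
#' @export
analyze_simulation <- function(design, params, config,
                               call_genotypes = TRUE, nqs_bin = 0.5,
                               quant = 64) {
  sim <- simulate_contig(design) # seeds the RNG
  prof <- design$profile
  gen <- gen_model_arrays(prof)
  qcum <- quality_cycle_cum(prof, design$read_length)
  at <- analysis_tables(params, prof$q_levels, nqs_bin)
  ms <- config$ploidies
  fg <- fraction_grid(ms, config$p_snp)
  set.seed(design$seed + 1L)
  est <- cpp_sim_run(sim$haplotypes, n_fragments(design), design$read_length,
                     design$frag_mean, design$frag_sd, prof$q_levels, qcum,
                     gen$alpha, gen$beta, gen$gamma, gen$subcum,
                     at$etab, at$psub, nqs_bin, at$B,
                     fg$fractions, fg$g_idx, fg$g_logprior,
                     if (call_genotypes) 5L else 1L, 0L, quant)
  ll <- stats::setNames(est$loglik, ms)
  if (est$n_pos_used == 0L) {
    pr <- structure(list(contig = "sim", loglik = ll * NA,
                         selected_M = NA_integer_, n_positions_used = 0L,
                         mean_coverage = 0, status = "no-call"),
                    class = "ploidy_result")
    return(list(ploidy = pr, calls = NULL, truth = sim$truth,
                design = design))
  }
  post <- ll + log(config$ploidy_prior)
  sel <- ms[which.max(post)]
  status <- if (sel == max(ms) && length(ms) > 1L) "boundary" else "call"
  pr <- structure(list(contig = "sim", loglik = ll, selected_M = sel,
                       n_positions_used = est$n_pos_used,
                       mean_coverage = est$total_bases / design$length,
                       status = status),
                  class = "ploidy_result")
  calls <- NULL
  if (call_genotypes) {
    isel <- match(sel, ms)
    covered <- which(est$n_p > 0L)
    terms <- sweep(est$mat[covered, fg$g_idx[[isel]] + 1L, drop = FALSE],
                   2L, fg$g_logprior[[isel]], `+`)
    mx <- apply(terms, 1L, max)
    w <- exp(terms - mx)
    tot <- rowSums(w)
    g <- max.col(w, ties.method = "first") - 1L
    lse_all <- mx + log(tot)
    Mi <- sel + 1L
    mnv <- pmax(terms[, 1L], terms[, Mi])
    lse_nonvar <- mnv + log(exp(terms[, 1L] - mnv) + exp(terms[, Mi] - mnv))
    calls <- data.table::data.table(
      pos = covered - 1L, a1 = est$a1[covered],
      a2 = ifelse(est$a2[covered] < 0L, NA_integer_, est$a2[covered]),
      g = g, post = (w / tot)[cbind(seq_along(covered), g + 1L)],
      score = pmax(-10 / log(10) * (lse_nonvar - lse_all), 0),
      n_p = est$n_p[covered])
    calls[, emitted := score > config$variant_threshold]
  }
  list(ploidy = pr, calls = calls, truth = sim$truth, design = design)
}

#' Fit the error model on simulated monomorphic training data
#'
#' Simulates a haploid (monomorphic) contig with the given profile, streams
#' reads over it and tallies error/total counts per feature stratum exactly
#' as [extract_training_observations()] would, then fits the logistic error
#' model on the grouped counts. This is the training half of the pipeline
#' run at simulation scale.
#'
#' @param design a haploid [sim_design()] (ploidy is forced to 1).
#' @param nqs_bin feature discretisation for the grouped fit.
#' @param lambda ridge penalty passed to the stratum fits.
#' @return an [error_model_params()] object.
#' @export
train_error_model_sim <- function(design, nqs_bin = 0.1, lambda = 1e-3) {
  design$ploidy <- 1L
  sim <- simulate_contig(design)
  prof <- design$profile
  gen <- gen_model_arrays(prof)
  qcum <- quality_cycle_cum(prof, design$read_length)
  at <- analysis_tables(naive_error_model(), prof$q_levels, nqs_bin)
  set.seed(design$seed + 1L)
  res <- cpp_sim_run(sim$haplotypes, n_fragments(design), design$read_length,
                     design$frag_mean, design$frag_sd, prof$q_levels, qcum,
                     gen$alpha, gen$beta, gen$gamma, gen$subcum,
                     at$etab, at$psub, nqs_bin, at$B,
                     numeric(0), list(), list(), 3L, 0L, 0)
  fit_error_model_counts(res$err_n, res$tot_n, res$sub_n,
                         prof$q_levels, nqs_bin, at$B, lambda = lambda)
}

# Fit from grouped (t, gg, qlevel, nqs-bin) error/total counts as produced
# by the streaming kernel.
fit_error_model_counts <- function(err_n, tot_n, sub_n, q_levels, nqs_bin, B,
                                   lambda = 1e-3) {
  Q <- length(q_levels)
  idx <- which(tot_n > 0)
  idx0 <- idx - 1L
  t_rd <- idx0 %% 4L
  gg <- (idx0 %/% 4L) %% 2L
  q <- (idx0 %/% 8L) %% Q
  nb <- idx0 %/% (8L * Q)
  obs <- data.table::data.table(
    true_nt = t_rd, nt = t_rd, # placeholder; substitution handled separately
    qs = q_levels[q + 1L], nqs = pmax(nb, 1L) * nqs_bin, gg = gg)
  # expand into error / non-error grouped rows with weights
  err <- err_n[idx]
  tot <- tot_n[idx]
  rows <- rbind(
    obs[, .(true_nt, nt = true_nt, qs, nqs, gg, is_error = 0L,
            weight = tot - err)],
    obs[, .(true_nt, nt = (true_nt + 1L) %% 4L, qs, nqs, gg, is_error = 1L,
            weight = err)])
  rows <- rows[weight > 0]
  fit <- fit_error_model(rows, lambda = lambda, nqs_bin = nqs_bin)
  # overwrite the substitution rows with the true tallies
  sub <- array(1 / 3, dim = c(4, 2, 4))
  for (t in 1:4) sub[t, , t] <- 0
  for (tv in 0:3) for (ggv in 0:1) {
    row <- sub_n[1L + tv + 4L * (ggv + 2L * (0:3))]
    row[tv + 1L] <- 0
    if (sum(row) > 0) sub[tv + 1L, ggv + 1L, ] <- row / sum(row)
  }
  error_model_params(fit$alpha, fit$beta, fit$gamma, sub,
                     model_kind = "full", nqs_bin = nqs_bin, se = fit$se)
}

#' Score a simulated run against its truth table
#'
#' Computes the benchmark metrics: whether the ploidy call is correct,
#' the exact-dosage accuracy among significantly called true SNPs (only
#' defined when the ploidy was called correctly, and reconciled for allele
#' anchoring: a call anchored on the truth's second allele matches when its
#' dosage equals M - g), the SNP false negative rate, and the false
#' positive rate over covered true-monomorphic positions.
#'
#' @param ploidy a `ploidy_result`.
#' @param calls a `data.table` of genotype calls (with `emitted`).
#' @param truth the simulator's SNP truth table.
#' @param true_M the simulated ploidy.
#' @return a list with `ploidy_correct`, `n_true_snps`, `n_called`, `fnr`,
#'   `fpr`, `dosage_accuracy` (`NA` when the ploidy call is wrong or no
#'   true SNP was called).
#' @export
score_run <- function(ploidy, calls, truth, true_M) {
  ploidy_correct <- !is.na(ploidy$selected_M) && ploidy$selected_M == true_M
  n_true <- nrow(truth)
  if (is.null(calls)) {
    return(list(ploidy_correct = ploidy_correct, n_true_snps = n_true,
                n_called = 0L, fnr = if (n_true) 1 else NA_real_,
                fpr = 0, dosage_accuracy = NA_real_))
  }
  em <- calls[which(calls$emitted)]
  hit <- em[which(em$pos %in% truth$pos)]
  fn <- n_true - nrow(hit)
  covered_mono <- nrow(calls) - sum(calls$pos %in% truth$pos)
  fp <- nrow(em) - nrow(hit)
  acc <- NA_real_
  if (ploidy_correct && nrow(hit) > 0L) {
    m <- merge(hit, truth, by = "pos")
    M <- ploidy$selected_M
    ok <- (m$a1 == m$allele1 & m$g == m$dosage) |
      (m$a1 == m$allele2 & m$g == M - m$dosage)
    acc <- mean(ok)
  }
  list(ploidy_correct = ploidy_correct, n_true_snps = n_true,
       n_called = nrow(hit), fnr = if (n_true) fn / n_true else NA_real_,
       fpr = if (covered_mono > 0) fp / covered_mono else NA_real_,
       dosage_accuracy = acc)
}
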