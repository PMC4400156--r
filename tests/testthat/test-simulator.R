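test_that("simulated contigs carry Poisson-spaced SNPs with uniform dosages", {
  ds <- sim_design(4, 200000, snp_spacing = 1000, coverage = 10, seed = 51)
  sim <- simulate_contig(ds)
  n <- nrow(sim$truth)
  expect_lt(abs(n - 200), 3 * sqrt(200))
  expect_true(all(sim$truth$dosage %in% 1:3))
  expect_true(all(sim$truth$pos >= 0 & sim$truth$pos < ds$length))
  # exactly dosage haplotypes carry allele1 at every SNP
  for (i in sample(n, 20)) {
    col <- sim$haplotypes[, sim$truth$pos[i] + 1L]
    expect_equal(sum(col == sim$truth$allele1[i]), sim$truth$dosage[i])
    expect_equal(sum(col == sim$truth$allele2[i]),
                 ds$ploidy - sim$truth$dosage[i])
  }
  # haploid contigs have no heterozygous sites
  expect_equal(nrow(simulate_contig(sim_design(1, 50000, seed = 5))$truth), 0L)
  # determinism
  expect_identical(simulate_contig(ds), simulate_contig(ds))
})

test_that("read simulation respects coverage, haplotype balance and errors", {
  ds <- sim_design(4, 20000, snp_spacing = 1000, coverage = 12, seed = 52)
  sim <- simulate_contig(ds)
  reads <- simulate_reads(sim$haplotypes, ds)
  total <- sum(nchar(reads$seq))
  expect_lt(abs(total - 20000 * 4 * 12) / (20000 * 4 * 12), 0.05)
  # uniform haplotype sampling
  share <- table(reads$hap) / nrow(reads)
  p <- 1 / 4
  expect_true(all(abs(share - p) <
                    3 * sqrt(p * (1 - p) / (nrow(reads) / 2))))
  # determinism of the full read stream
  expect_identical(reads, simulate_reads(sim$haplotypes, ds))
  # an error-free profile reproduces the haplotypes exactly
  ds0 <- sim_design(2, 3000, snp_spacing = 1000, coverage = 5,
                    profile = noerror_profile(), seed = 53)
  sim0 <- simulate_contig(ds0)
  r0 <- simulate_reads(sim0$haplotypes, ds0)
  aln0 <- reads_to_alignments(r0, "c1")
  for (i in seq_len(min(nrow(aln0), 50))) {
    hap <- sim0$haplotypes[r0$hap[match(aln0$read_id[i], r0$read_id)], ]
    seg <- hap[(aln0$pos[i] + 1):(aln0$pos[i] + nchar(aln0$seq[i]))]
    expect_identical(ploidycall:::seq2int(aln0$seq[i]), seg)
  }
})

test_that("downsampling keeps pairs together at the requested rate", {
  ds <- sim_design(2, 50000, snp_spacing = 1000, coverage = 20, seed = 54)
  sim <- simulate_contig(ds)
  reads <- simulate_reads(sim$haplotypes, ds)
  expect_identical(downsample(reads, 1), reads)
  half <- downsample(reads, 0.5, seed = 99)
  n_pairs <- length(unique(reads$frag))
  kept <- length(unique(half$frag))
  expect_lt(abs(kept - 0.5 * n_pairs), 3 * sqrt(0.25 * n_pairs))
  # mates stay together
  expect_true(all(table(half$frag) == 2L))
  expect_identical(half, downsample(reads, 0.5, seed = 99))
})

test_that("FASTQ and SAM writers are deterministic and well-formed", {
  ds <- sim_design(2, 2000, snp_spacing = 500, coverage = 4, seed = 55)
  sim <- simulate_contig(ds)
  reads <- simulate_reads(sim$haplotypes, ds)
  td <- withr::local_tempdir()
  p1 <- write_sim_fastq(reads, file.path(td, "a"))
  fq <- readLines(paste0(file.path(td, "a"), "_1.fastq"))
  expect_equal(length(fq), 4 * sum(reads$mate == 1))
  expect_true(all(startsWith(fq[seq(1, length(fq), by = 4)], "@")))
  expect_equal(nchar(fq[seq(2, length(fq), by = 4)]),
               nchar(fq[seq(4, length(fq), by = 4)]))
  write_sim_fastq(reads, file.path(td, "b"))
  expect_identical(readLines(paste0(file.path(td, "a"), "_1.fastq")),
                   readLines(paste0(file.path(td, "b"), "_1.fastq")))
  sam <- write_sim_sam(reads, "ctg", ds$length, file.path(td, "x.sam"))
  lines <- readLines(sam)
  expect_true(startsWith(lines[1], "@HD"))
  expect_equal(length(lines) - 2L, nrow(reads))
})

test_that("run scoring counts dosage hits, misses and false calls", {
  truth <- data.table::data.table(pos = c(10L, 20L, 30L, 40L, 50L),
                                  allele1 = 0L, allele2 = 2L,
                                  dosage = c(1L, 1L, 2L, 2L, 3L))
  pr <- structure(list(selected_M = 4L, status = "call"),
                  class = "ploidy_result")
  mk_calls <- function(pos, g, score, a1 = 0L, a2 = 2L) {
    data.table::data.table(pos = pos, a1 = a1, a2 = a2, g = g,
                           post = 0.99, score = score, n_p = 50L,
                           emitted = score > 40)
  }
  # perfect caller over covered positions 0..99
  covered <- data.table::data.table(
    pos = setdiff(0:99, truth$pos), a1 = 0L, a2 = NA_integer_, g = 4L,
    post = 1, score = 0, n_p = 50L, emitted = FALSE)
  perfect <- rbind(mk_calls(truth$pos, truth$dosage, 90), covered)
  sc <- score_run(pr, perfect, truth, 4L)
  expect_true(sc$ploidy_correct)
  expect_equal(sc$dosage_accuracy, 1)
  expect_equal(sc$fnr, 0)
  expect_equal(sc$fpr, 0)
  # four SNPs called with one dosage error, one SNP missed:
  # accuracy 3/4 of the called SNPs, FNR 1/5
  partial <- rbind(mk_calls(c(10L, 20L, 30L, 40L), c(1L, 1L, 1L, 2L), 90),
                   mk_calls(50L, 3L, 10), # below threshold -> missed
                   covered)
  sc2 <- score_run(pr, partial, truth, 4L)
  expect_equal(sc2$dosage_accuracy, 0.75)
  expect_equal(sc2$fnr, 1 / 5)
  # swapped anchoring still counts as correct dosage
  swapped <- rbind(mk_calls(truth$pos, 4L - truth$dosage, 90, a1 = 2L,
                            a2 = 0L), covered)
  expect_equal(score_run(pr, swapped, truth, 4L)$dosage_accuracy, 1)
  # a caller emitting nothing has FNR 1
  sc3 <- score_run(pr, covered, truth, 4L)
  expect_equal(sc3$fnr, 1)
  # false positives counted over covered monomorphic positions
  fp <- rbind(mk_calls(c(truth$pos, 60L, 70L), c(truth$dosage, 1L, 1L), 90),
              covered[!pos %in% c(60L, 70L)])
  expect_equal(score_run(pr, fp, truth, 4L)$fpr, 2 / 95)
})

test_that("error-free high-coverage simulations recover every ploidy", {
  prof <- noerror_profile()
  params <- trained_params()
  cfg <- sim_model_config(8L)
  ok <- TRUE
  for (seed in 1:20) {
    M <- (seed - 1L) %% 8L + 1L
    ds <- sim_design(M, 20000, snp_spacing = 600, coverage = 50,
                     profile = prof, seed = 3000 + seed)
    res <- suppressWarnings(
      analyze_simulation(ds, params, cfg, call_genotypes = FALSE))
    ok <- ok && (res$ploidy$selected_M == M)
  }
  expect_true(ok)
})
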