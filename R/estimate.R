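#' Estimate ploidy and call variants for every contig of a BAM file
#'
#' The end-to-end driver for real alignments: reads each contig's records
#' from a coordinate-sorted indexed BAM, applies the alignment filters,
#' builds pileups, estimates the contig ploidy and calls genotypes at the
#' selected ploidy. Contigs are analysed independently of each other, in
#' BAM header order; results do not depend on the processing order. A TSV
#' report (one row per contig, including no-calls) and a VCF of significant
#' variants are written when `out_prefix` is given.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param params an [error_model_params()] object (or path to a TSV written
#'   by [write_error_params()]).
#' @param config a [model_config()].
#' @param out_prefix optional output prefix; writes `<prefix>.ploidy.tsv`
#'   and `<prefix>.vcf`.
#' @param reference optional FASTA of the assembly; when given, VCF REF
#'   alleles are anchored to the assembly base at each site.
#' @param min_mapq,fragment_range,keep_duplicates passed to
#'   [filter_alignments()].
#' @return a list with `ploidy` (a `data.table`, one row per contig) and
#'   `variants` (a `data.table` of emitted variant calls).
#' @export
run_estimate <- function(bam, params, config = model_config(),
                         out_prefix = NULL, reference = NULL,
                         min_mapq = 40L, fragment_range = NULL,
                         keep_duplicates = FALSE) {
  if (is.character(params)) params <- read_error_params(params)
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  targets <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (length(targets) == 0L) stop("BAM header declares no contigs")
  refseq <- NULL
  if (!is.null(reference)) {
    refseq <- Biostrings::readDNAStringSet(reference)
    names(refseq) <- sub("\\s.*$", "", names(refseq))
  }
  ms <- config$ploidies
  rows <- vector("list", length(targets))
  vars <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    ctg <- names(targets)[i]
    len <- targets[[i]]
    aln <- read_alignments(bam, ctg)
    aln <- filter_alignments(aln, min_mapq = min_mapq,
                             fragment_range = fragment_range,
                             keep_duplicates = keep_duplicates)
    cp <- build_pileups(aln, ctg, len)
    pr <- suppressWarnings(estimate_ploidy(cp, config, params))
    ll <- as.list(pr$loglik)
    names(ll) <- paste0("loglik_M", ms)
    rows[[i]] <- data.table::as.data.table(
      c(list(contig = ctg, length = len,
             mean_coverage = round(pr$mean_coverage, 3),
             selected_ploidy = pr$selected_M, status = pr$status), ll))
    if (pr$status != "no-call") {
      calls <- call_genotypes(cp, pr$selected_M, config, params)
      emitted <- calls[calls$emitted & !is.na(calls$a2)]
      if (nrow(emitted)) {
        emitted[, `:=`(contig = ctg, M = pr$selected_M)]
        vars[[i]] <- emitted
      }
    }
  }
  ploidy_tab <- data.table::rbindlist(rows)
  variants <- data.table::rbindlist(vars)
  if (!is.null(out_prefix)) {
    data.table::fwrite(ploidy_tab, paste0(out_prefix, ".ploidy.tsv"),
                       sep = "\t", na = "NA")
    write_variants_vcf(variants, targets, paste0(out_prefix, ".vcf"),
                       refseq = refseq)
  }
  list(ploidy = ploidy_tab, variants = variants)
}

#' Write dosage calls as VCF 4.2
#'
#' Biallelic records with 1-based positions. By default REF is the
#' majority allele of the pileup (allele1) and ALT the minor allele; when
#' the assembly sequence is supplied and matches the minor allele, the
#' record is swapped so REF agrees with the assembly. The genotype field
#' carries the dosage as an unphased genotype with `g` REF copies out of
#' `M`; INFO fields `PM` (contig ploidy), `DG` (dosage of REF) and `VS`
#' (Phred-like variant score) carry the model outputs.
#'
#' @param variants a `data.table` of emitted calls with columns `contig`,
#'   `pos` (0-based), `a1`, `a2`, `g`, `score`, `M`.
#' @param targets named integer vector of contig lengths (header order).
#' @param path output path.
#' @param refseq optional `DNAStringSet` of the assembly.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, targets, path, refseq = NULL) {
  if (is.null(variants) || nrow(variants) == 0L) {
    writeLines(c("##fileformat=VCFv4.2",
                 paste0("##contig=<ID=", names(targets), ",length=",
                        unlist(targets), ">"),
                 paste0("##INFO=<ID=PM,Number=1,Type=Integer,",
                        "Description=\"Estimated contig ploidy\">"),
                 paste0("##INFO=<ID=DG,Number=1,Type=Integer,",
                        "Description=\"Dosage of the REF allele\">"),
                 paste0("##INFO=<ID=VS,Number=1,Type=Float,",
                        "Description=\"Phred-like variant score\">"),
                 paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                        "Description=\"Genotype\">"),
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "sample1", sep = "\t")), path)
    return(invisible(path))
  }
  v <- data.table::copy(variants)
  v[, `:=`(ref_nt = a1, alt_nt = a2, ref_dosage = g)]
  if (!is.null(refseq)) {
    for (ctg in unique(v$contig)) {
      if (!ctg %in% names(refseq)) next
      sel <- which(v$contig == ctg)
      base <- nt2int(strsplit(as.character(
        Biostrings::subseq(refseq[[ctg]], 1L, max(v$pos[sel]) + 1L)),
        "")[[1L]])[v$pos[sel] + 1L]
      swap <- !is.na(base) & base == v$a2[sel]
      v$ref_nt[sel][swap] <- v$a2[sel][swap]
      v$alt_nt[sel][swap] <- v$a1[sel][swap]
      v$ref_dosage[sel][swap] <- v$M[sel][swap] - v$g[sel][swap]
    }
  }
  gt <- mapply(function(g, M) paste(c(rep("0", g), rep("1", M - g)),
                                    collapse = "/"),
               v$ref_dosage, v$M)
  gr <- GenomicRanges::GRanges(v$contig,
                               IRanges::IRanges(v$pos + 1L, width = 1L))
  GenomeInfoDb::seqlengths(gr) <- targets[GenomeInfoDb::seqlevels(gr)]
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(int2nt(v$ref_nt)),
    ALT = Biostrings::DNAStringSetList(as.list(int2nt(v$alt_nt))),
    QUAL = round(v$score, 2), FILTER = "PASS")
  info <- S4Vectors::DataFrame(PM = v$M, DG = v$ref_dosage,
                               VS = round(v$score, 2))
  geno <- S4Vectors::SimpleList(
    GT = matrix(gt, ncol = 1L, dimnames = list(NULL, "sample1")))
  hdr <- VariantAnnotation::VCFHeader(samples = "sample1")
  VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "1", "1"), Type = c("Integer", "Integer", "Float"),
    Description = c("Estimated contig ploidy", "Dosage of the REF allele",
                    "Phred-like variant score"),
    row.names = c("PM", "DG", "VS"))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = "1", Type = "String", Description = "Genotype",
    row.names = "GT")
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed,
                                info = info, geno = geno,
                                colData = S4Vectors::DataFrame(
                                  Samples = 1L, row.names = "sample1"),
                                collapsed = TRUE)
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Simulation benchmark over a design grid
#'
#' Simulates and analyses contigs over a grid of ploidies, coverages,
#' lengths and replicates, scoring each run against its truth table. Each
#' cell uses an independent seed derived from `seed`, so the whole table
#' is reproducible and cells are independent of evaluation order.
#'
#' @param ploidies integer vector of simulated (true) ploidies.
#' @param coverages per-copy coverages (X).
#' @param lengths contig lengths (bp).
#' @param replicates replicates per grid cell.
#' @param params analysis [error_model_params()].
#' @param config a [model_config()]; its `ploidy_range` is the candidate
#'   range used for every run.
#' @param snp_spacing mean SNP spacing passed to the designs.
#' @param seed base seed.
#' @param call_genotypes score dosage/FNR/FPR as well (slower).
#' @param nqs_bin streaming-kernel nqs discretisation.
#' @param quant streaming-kernel likelihood cache resolution (see
#'   [analyze_simulation()]).
#' @return a `data.table` with one row per run: grid coordinates,
#'   `selected_M`, `correct`, `n_true_snps`, `fnr`, `fpr`,
#'   `dosage_accuracy`.
#' @export
run_benchmark <- function(ploidies, coverages, lengths, replicates,
                          params, config, snp_spacing = 1000, seed = 1L,
                          call_genotypes = TRUE, nqs_bin = 0.5, quant = 64) {
  grid <- expand.grid(rep = seq_len(replicates), ploidy = ploidies,
                      coverage = coverages, length = lengths)
  if (nrow(grid) == 0L) {
    return(data.table::data.table(
      ploidy = integer(), coverage = numeric(), length = integer(),
      rep = integer(), selected_M = integer(), correct = logical(),
      n_true_snps = integer(), fnr = numeric(), fpr = numeric(),
      dosage_accuracy = numeric()))
  }
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gi <- grid[i, ]
    ds <- sim_design(gi$ploidy, gi$length, snp_spacing = snp_spacing,
                     coverage = gi$coverage,
                     seed = (seed %% 1000003L) * 97L + i * 1009L)
    res <- suppressWarnings(
      analyze_simulation(ds, params, config,
                         call_genotypes = call_genotypes,
                         nqs_bin = nqs_bin, quant = quant))
    sc <- score_run(res$ploidy, res$calls, res$truth, gi$ploidy)
    out[[i]] <- data.table::data.table(
      ploidy = gi$ploidy, coverage = gi$coverage, length = gi$length,
      rep = gi$rep, selected_M = res$ploidy$selected_M,
      correct = sc$ploidy_correct, n_true_snps = sc$n_true_snps,
      fnr = sc$fnr, fpr = sc$fpr, dosage_accuracy = sc$dosage_accuracy)
  }
  data.table::rbindlist(out)
}

#' Summarise a benchmark table per grid cell
#'
#' @param runs the output of [run_benchmark()].
#' @return a `data.table` with, per (ploidy, coverage, length):
#'   `pct_correct`, `mean_dosage_accuracy` (over runs with a correct
#'   ploidy call), `mean_fnr`, `mean_fpr`, `n`.
#' @export
summarize_benchmark <- function(runs) {
  runs[, .(pct_correct = 100 * mean(correct),
           mean_dosage_accuracy = mean(dosage_accuracy, na.rm = TRUE),
           mean_fnr = mean(fnr, na.rm = TRUE),
           mean_fpr = mean(fpr, na.rm = TRUE), n = .N),
       by = .(ploidy, coverage, length)]
}
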