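#' Read alignment records from a BAM file
#'
#' Thin wrapper around [Rsamtools::scanBam()] returning one row per primary
#' alignment record with the fields the filtering and pileup steps need.
#' Positions are converted to the package-internal 0-based convention.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param contig optional contig name to restrict to (requires the index).
#' @return a `data.table` with columns `read_id`, `flag`, `contig`, `pos`
#'   (0-based leftmost), `mapq`, `cigar`, `strand`, `isize`, `seq`, `qual`.
#' @export
read_alignments <- function(bam, contig = NULL) {
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
            "isize", "seq", "qual")
  param <- if (is.null(contig)) {
    Rsamtools::ScanBamParam(what = what)
  } else {
    hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
    if (!contig %in% names(hdr)) stop("contig ", contig, " not in BAM header")
    Rsamtools::ScanBamParam(
      what = what,
      which = GenomicRanges::GRanges(contig, IRanges::IRanges(1L, hdr[[contig]])))
  }
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  data.table::data.table(
    read_id = res$qname, flag = res$flag,
    contig = as.character(res$rname), pos = res$pos - 1L,
    mapq = res$mapq, cigar = res$cigar, strand = as.character(res$strand),
    isize = res$isize,
    seq = as.character(res$seq), qual = as.character(res$qual))
}

#' Filter alignment records
#'
#' Applies the alignment hygiene rules used before ploidy estimation:
#' only primary, mapped, non-duplicate records with Phred mapping quality
#' strictly greater than `min_mapq` (a proxy for unique alignment) and,
#' when mate information is present, an absolute template length within
#' `fragment_range` are retained. When `fragment_range` is `NULL` it is
#' estimated as mean +/- 4 SD of the absolute template length over the
#' first 100,000 properly paired records. Filtering is idempotent.
#'
#' @param aln a `data.table` of alignment records (see [read_alignments()]).
#' @param min_mapq retain records with `mapq > min_mapq` (default 40).
#' @param fragment_range numeric length-2 vector `(min, max)` in bp, or
#'   `NULL` to estimate from the data.
#' @param keep_duplicates retain PCR-duplicate-flagged records (default
#'   `FALSE`).
#' @return the filtered `data.table`, with the fragment range used stored in
#'   the `fragment_range` attribute.
#' @export
filter_alignments <- function(aln, min_mapq = 40L, fragment_range = NULL,
                              keep_duplicates = FALSE) {
  aln <- data.table::as.data.table(aln)
  if (nrow(aln) == 0L) return(aln)
  if (is.unsorted(aln$pos) &&
      (is.null(aln$contig) || any(aln[, is.unsorted(pos), by = contig]$V1)))
    stop("alignments are not coordinate-sorted; sort the input first")
  flag <- aln$flag %||% rep(0L, nrow(aln))
  keep <- bitwAnd(flag, 4L) == 0L &        # mapped
    bitwAnd(flag, 256L) == 0L &            # primary
    bitwAnd(flag, 2048L) == 0L             # not supplementary
  if (!keep_duplicates) keep <- keep & bitwAnd(flag, 1024L) == 0L
  keep <- keep & !is.na(aln$mapq) & aln$mapq > min_mapq
  has_mate <- !is.na(aln$isize) & aln$isize != 0L
  if (is.null(fragment_range)) {
    proper <- which(has_mate & bitwAnd(flag, 2L) != 0L)
    if (length(proper) == 0L) proper <- which(has_mate)
    proper <- utils::head(proper, 100000L)
    if (length(proper) >= 2L) {
      af <- abs(aln$isize[proper])
      fragment_range <- c(max(0, mean(af) - 4 * stats::sd(af)),
                          mean(af) + 4 * stats::sd(af))
    } else {
      fragment_range <- c(0, Inf)
    }
  }
  keep <- keep & (!has_mate | (abs(aln$isize) >= fragment_range[1] &
                                 abs(aln$isize) <= fragment_range[2]))
  out <- aln[keep]
  data.table::setattr(out, "fragment_range", fragment_range)
  out
}

#' Choose the candidate biallelic pair at a position
#'
#' allele1 is the most frequent observed nucleotide and allele2 the second
#' most frequent one, provided it was observed at least once; ties are
#' broken by the fixed nucleotide order A < C < G < T. With no observations
#' both are absent.
#'
#' @param nts integer vector of observed nucleotide codes (0..3) at one
#'   position.
#' @return list with integer `allele1` and `allele2` (either may be `NA`).
#' @export
select_alleles <- function(nts) {
  if (length(nts) == 0L) return(list(allele1 = NA_integer_, allele2 = NA_integer_))
  cnt <- tabulate(nts + 1L, nbins = 4L)
  a1 <- which.max(cnt) - 1L # which.max takes the first maximum: A < C < G < T
  cnt2 <- cnt
  cnt2[a1 + 1L] <- -1L
  a2 <- which.max(cnt2) - 1L
  if (cnt2[a2 + 1L] <= 0L) a2 <- NA_integer_
  list(allele1 = a1, allele2 = a2)
}

#' Build per-position pileups for one contig
#'
#' Expands filtered alignments into one observation per aligned,
#' non-clipped, non-deleted base, carrying the error-model features
#' computed from the read's own sequence and qualities, and chooses the
#' candidate biallelic pair at every covered position.
#'
#' @param aln filtered alignment records for a single contig (columns as in
#'   [read_alignments()]; `cigar` may be `NA` for fully aligned reads).
#' @param contig contig name.
#' @param length contig length in bases.
#' @return a `contig_pileup`: list with `contig`, `length`, `obs` (a
#'   `data.table` of read observations with columns `read_id`, `pos`, `nt`,
#'   `qs`, `nqs`, `gg`, `strand`) and `alleles` (per covered position:
#'   `pos`, `a1`, `a2`, `n`).
#' @export
build_pileups <- function(aln, contig, length) {
  aln <- data.table::as.data.table(aln)
  if (!is.null(aln$contig)) aln <- aln[aln$contig == contig]
  if (nrow(aln)) {
    feat <- read_base_features(aln)
    data.table::setnames(feat, "refpos", "pos")
    feat <- feat[pos >= 0L & pos < length]
    data.table::setkey(feat, pos)
  } else {
    feat <- data.table::data.table(read_id = character(), pos = integer(),
                                   nt = integer(), qs = integer(),
                                   nqs = numeric(), gg = integer(),
                                   strand = character())
  }
  alleles <- if (nrow(feat)) {
    feat[, {
      al <- select_alleles(nt)
      list(a1 = al$allele1, a2 = al$allele2, n = .N)
    }, by = pos]
  } else {
    data.table::data.table(pos = integer(), a1 = integer(), a2 = integer(),
                           n = integer())
  }
  structure(list(contig = contig, length = as.integer(length),
                 obs = feat, alleles = alleles),
            class = "contig_pileup")
}

#' @export
print.contig_pileup <- function(x, ...) {
  cat("contig_pileup: ", x$contig, " (", x$length, " bp), ",
      nrow(x$alleles), " covered positions, ", nrow(x$obs),
      " base observations\n", sep = "")
  invisible(x)
}

#' Extract the pileup of a single position
#'
#' @param cp a `contig_pileup`.
#' @param pos 0-based position.
#' @return a list with `observations` (possibly empty), `allele1`,
#'   `allele2`, suitable for [position_loglik()].
#' @export
position_pileup <- function(cp, pos) {
  iobs <- which(cp$obs$pos == pos)
  ial <- which(cp$alleles$pos == pos)
  obs <- cp$obs[iobs]
  al <- cp$alleles[ial]
  list(contig = cp$contig, pos = pos, observations = obs,
       allele1 = if (nrow(al)) al$a1 else NA_integer_,
       allele2 = if (nrow(al)) al$a2 else NA_integer_)
}
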