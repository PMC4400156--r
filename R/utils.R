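#' @useDynLib ploidycall, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Map nucleotide characters to internal integer codes
#'
#' Internally all sequence is stored as integers 0..3 for A, C, G, T
#' (the order also used to break ties when choosing candidate alleles).
#'
#' @param x character vector of single-letter nucleotides.
#' @return integer vector with values in 0..3, `NA` for other letters.
#' @export
nt2int <- function(x) {
  match(toupper(x), NUCLEOTIDES) - 1L
}

#' @rdname nt2int
#' @export
int2nt <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & x >= 0L & x <= 3L
  out[ok] <- NUCLEOTIDES[x[ok] + 1L]
  out
}

#' Complement of integer-coded nucleotides (A<->T, C<->G)
#' @keywords internal
comp_int <- function(x) 3L - x

# Split a sequence string into integer codes; NA for ambiguity codes.
seq2int <- function(s) nt2int(strsplit(s, "", fixed = TRUE)[[1L]])

# Phred string (offset 33) -> integer qualities
qual2int <- function(q) utf8ToInt(q) - 33L

int2qual <- function(q) intToUtf8(q + 33L)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
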