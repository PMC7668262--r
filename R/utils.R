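#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over the DNA alphabet; any base outside
#' `{A,C,G,T}` becomes `N`.
#'
#' @param seqs Character vector of upper-case DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AACG")
#' @export
revcomp <- function(seqs) {
  stopifnot(is.character(seqs))
  cpp_revcomp(seqs)
}

#' Fold sequence input to the internal DNA alphabet
#'
#' Upper-cases and maps `U` to `T`, so RNA and DNA input share one internal
#' alphabet. Characters outside `{A,C,G,T,N}` are rejected.
#'
#' @param seqs Character vector.
#' @param what Label used in error messages.
#' @return Character vector over `{A,C,G,T,N}`.
#' @export
fold_to_dna <- function(seqs, what = "sequence") {
  out <- chartr("u", "U", toupper(seqs))
  out <- chartr("U", "T", out)
  bad <- stringi::stri_detect_regex(out, "[^ACGTN]")
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N,U}: element %d",
                  what, which(bad)[1]))
  }
  out
}

#' Convert internal intervals to 1-based display strings
#'
#' Internal coordinates are 0-based half-open; reports print 1-based
#' inclusive intervals in UCSC browser style (`chr:start-end`).
#'
#' @param chrom,start,end Vectors describing 0-based half-open intervals.
#' @return Character vector like `"chr2:5532107-5532415"`.
#' @seealso [display_to_interval()]
#' @export
interval_to_display <- function(chrom, start, end) {
  stopifnot(all(start < end), all(start >= 0))
  sprintf("%s:%d-%d", chrom, as.integer(start) + 1L, as.integer(end))
}

#' Parse 1-based display strings back to internal intervals
#'
#' Inverse of [interval_to_display()].
#'
#' @param x Character vector like `"chr1:101-200"`.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
display_to_interval <- function(x) {
  m <- stringi::stri_match_first_regex(x, "^(.+):([0-9]+)-([0-9]+)$")
  if (anyNA(m[, 1])) abort("malformed interval display string")
  tibble(chrom = m[, 2],
         start = as.integer(m[, 3]) - 1L,
         end = as.integer(m[, 4]))
}

# deterministic 32-bit sub-seed derivation for per-component RNG substreams
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1000003 * k) %% 2147483647)
}

check_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "seq", "mult") %in% names(reads)))
  if (nrow(reads) > 0 && any(reads$mult < 1)) abort("read multiplicity must be >= 1")
  invisible(reads)
}
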