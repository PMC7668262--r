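#' Known library-preparation adaptor and exogenous-siRNA constants
#'
#' `adaptor_truseq_small_rna()` returns the 33-nt 3' adaptor used for the
#' total small-RNA libraries, `adaptor_ago2_ip()` the 28-nt adaptor of the
#' AGO2-immunoprecipitation library, `dicing_adaptors()` the 5'/3' adaptor
#' pair of the in vitro dicing-product libraries, and
#' `exogenous_sirna_blacklist()` the four 21-mers of the transfected
#' control/knockdown siRNAs whose reads are removed before annotation.
#'
#' @return Character vector(s) of adaptor/blacklist sequences.
#' @name adaptors
NULL

#' @rdname adaptors
#' @export
adaptor_truseq_small_rna <- function() "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC"

#' @rdname adaptors
#' @export
adaptor_ago2_ip <- function() "TCTCGTATCGTATGCCGTCTTCTGCTTG"

#' @rdname adaptors
#' @export
dicing_adaptors <- function() {
  c(adaptor5 = "TGGAATTCTCGGGCACCAAGGT", adaptor3 = "ACGCTGGAATTCGCGGTTAAA")
}

#' @rdname adaptors
#' @export
exogenous_sirna_blacklist <- function() {
  c("CGTACGCGGAATACTTCGAAG", "TCGAAGTATTCCGCGTACGAT",
    "CCGCCATCATTATGAAAAAAG", "TTTTTCATAATGATGGCGGAT")
}

#' Remove a 3' adaptor by exact prefix match
#'
#' For each read, finds the leftmost cut point `p >= 1` such that the read
#' suffix from `p` exactly equals a prefix of the adaptor of length at
#' least `min_overlap` (the suffix always runs to the read end, so a read
#' ending in a truncated adaptor is trimmed too). The insert `[0, p)` is
#' returned; a read with no such cut point keeps `insert = NA`. A read
#' equal to the adaptor itself yields no insert (empty inserts are
#' disallowed). Matching is exact: zero mismatches.
#'
#' @param reads Read tibble (`read_id`, `seq`, `mult`).
#' @param adaptor 3' adaptor sequence.
#' @param min_overlap Minimum read/adaptor overlap (default 6).
#' @return The read tibble with an added character column `insert`
#'   (`NA` where no adaptor was found).
#' @export
trim_adaptor <- function(reads, adaptor, min_overlap = 6L) {
  check_reads(reads)
  adaptor <- fold_to_dna(adaptor, "adaptor")
  stopifnot(min_overlap >= 1, nchar(adaptor) >= min_overlap)
  seq <- reads$seq
  L <- nchar(seq)
  la <- nchar(adaptor)
  n <- length(seq)
  insert <- rep(NA_character_, n)
  done <- logical(n)
  if (n > 0 && max(L) > 1) {
    for (p in seq_len(max(L) - 1L)) {
      k <- L - p
      cand <- !done & p < L & k >= min_overlap & k <= la
      if (!any(cand)) next
      hit <- cand
      hit[cand] <- substring(seq[cand], p + 1L, L[cand]) ==
        substring(adaptor, 1L, k[cand])
      insert[hit] <- substring(seq[hit], 1L, p)
      done <- done | hit
    }
  }
  mutate(reads, insert = insert)
}

#' Remove reads matching transfected exogenous siRNAs
#'
#' A read is removed iff its sequence contains any blacklist sequence as a
#' substring, or is itself contained within a blacklist sequence (which
#' catches partially trimmed siRNA reads). Order is preserved.
#'
#' @param reads Read tibble.
#' @param blacklist Character vector of siRNA sequences (may be empty, in
#'   which case all reads are kept).
#' @return List with `reads` (kept tibble) and `removed`
#'   (multiplicity-weighted removed count).
#' @export
remove_exogenous <- function(reads, blacklist = character(0)) {
  check_reads(reads)
  if (length(blacklist) == 0 || nrow(reads) == 0) {
    return(list(reads = reads, removed = 0))
  }
  blacklist <- fold_to_dna(blacklist, "blacklist")
  drop <- rep(FALSE, nrow(reads))
  for (b in blacklist) {
    drop <- drop | stringi::stri_detect_fixed(reads$seq, b) |
      stringi::stri_detect_fixed(b, reads$seq)
  }
  list(reads = reads[!drop, , drop = FALSE],
       removed = sum(reads$mult[drop]))
}

#' Keep reads within an inclusive length window
#'
#' @param reads Read tibble.
#' @param lo,hi Inclusive bounds (defaults 19 and 35 nt).
#' @return List with `reads` (kept tibble, order preserved) and `report`,
#'   a one-row tibble of multiplicity-weighted counts `n_input`, `n_fail`,
#'   `n_pass`.
#' @export
length_filter <- function(reads, lo = 19L, hi = 35L) {
  check_reads(reads)
  stopifnot(lo <= hi)
  len <- nchar(reads$seq)
  keep <- len >= lo & len <= hi
  list(reads = reads[keep, , drop = FALSE],
       report = tibble(n_input = sum(reads$mult),
                       n_fail = sum(reads$mult[!keep]),
                       n_pass = sum(reads$mult[keep])))
}

#' Preprocess a raw small-RNA library
#'
#' Applies the read-processing stages in order: 3' adaptor removal
#' ([trim_adaptor()]), exogenous-siRNA removal ([remove_exogenous()]) and
#' the 19-35 nt length gate ([length_filter()]). Reads with no detectable
#' adaptor are discarded by default (their 3' end is unknown); set
#' `keep_untrimmed = TRUE` to retain them untrimmed.
#'
#' @param reads Raw read tibble (`read_id`, `seq`, `mult`).
#' @param adaptor 3' adaptor sequence.
#' @param blacklist Exogenous siRNA sequences to remove (default none).
#' @param min_overlap Minimum adaptor overlap for trimming.
#' @param min_len,max_len Inclusive insert-length window.
#' @param keep_untrimmed Keep reads with no detectable adaptor?
#' @return List with `reads` (tibble of passing inserts) and `report`, a
#'   one-row tibble of multiplicity-weighted counts (`n_input`,
#'   `n_no_adaptor`, `n_exogenous_removed`, `n_length_fail`, `n_pass`)
#'   that always partition the input exactly.
#' @export
preprocess_reads <- function(reads, adaptor,
                             blacklist = character(0),
                             min_overlap = 6L,
                             min_len = 19L, max_len = 35L,
                             keep_untrimmed = FALSE) {
  check_reads(reads)
  n_input <- sum(reads$mult)
  trimmed <- trim_adaptor(reads, adaptor, min_overlap)
  no_ad <- is.na(trimmed$insert)
  if (keep_untrimmed) {
    trimmed$insert[no_ad] <- trimmed$seq[no_ad]
    n_no_adaptor <- 0
  } else {
    n_no_adaptor <- sum(trimmed$mult[no_ad])
    trimmed <- trimmed[!no_ad, , drop = FALSE]
  }
  inserts <- tibble(read_id = trimmed$read_id, seq = trimmed$insert,
                    mult = trimmed$mult)
  ex <- remove_exogenous(inserts, blacklist)
  lf <- length_filter(ex$reads, min_len, max_len)
  report <- tibble(n_input = n_input,
                   n_no_adaptor = n_no_adaptor,
                   n_exogenous_removed = ex$removed,
                   n_length_fail = lf$report$n_fail,
                   n_pass = lf$report$n_pass)
  stopifnot(report$n_input == report$n_no_adaptor +
              report$n_exogenous_removed + report$n_length_fail +
              report$n_pass)
  list(reads = lf$reads, report = report)
}
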