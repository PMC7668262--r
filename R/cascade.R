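#' Ungapped both-strand alignment with bounded mismatches
#'
#' Enumerates every end-to-end placement of `query` on the forward strand
#' of each reference, and of its reverse complement (reported as `-`
#' strand hits), with Hamming mismatch count at most `max_mm`. `N` bases
#' never match, not even `N` against `N`. Hits are sorted by
#' `(mismatches, start, strand with + before -, reference input order)`.
#' A query longer than a reference simply yields no hits there.
#'
#' @param query Nucleotide string (folded to DNA alphabet).
#' @param refs A `reference_set`, or a tibble with `id`, `seq`.
#' @param max_mm Maximum Hamming mismatches (default 2, emulating the
#'   two-mismatch short-read alignment the cascade uses).
#' @return Tibble of hits: `ref_id`, `start`, `end` (0-based half-open),
#'   `strand`, `mismatches`.
#' @export
align_ungapped <- function(query, refs, max_mm = 2L) {
  stopifnot(is.character(query), length(query) == 1, max_mm >= 0)
  query <- fold_to_dna(query, "query")
  seqs <- if (inherits(refs, "reference_set")) refs$sequences else as_tibble(refs)
  hits <- cpp_align_all(query, seqs$seq, as.integer(max_mm))
  tibble(ref_id = seqs$id[hits$ref_idx],
         start = hits$start,
         end = hits$start + nchar(query),
         strand = hits$strand,
         mismatches = hits$mismatches)
}

#' Assign reads to the first matching reference category
#'
#' The heart of the hierarchical annotation: each read is aligned against
#' the ordered reference sets and assigned to the first category with at
#' least one hit; the reported hit is the best one under the
#' deterministic tie-break of [align_ungapped()]. Reads matching no set
#' are `unaligned`. Repeat-set hits carry the repeat subfamily.
#'
#' @param reads Read tibble (`read_id`, `seq`, `mult`).
#' @param refs Ordered list of `reference_set` objects (default order:
#'   rRNA, tRNA, miRNA, repeat, snoRNA, transcript, genome; any subset in
#'   any order is accepted and used as given).
#' @param max_mm Maximum mismatches, applied uniformly to all steps.
#' @return Assignment tibble: `read_id`, `seq`, `mult`, `length`,
#'   `category`, `ref_id`, `subfamily`, `start`, `end`, `strand`,
#'   `mismatches` (hit columns `NA` for unaligned reads).
#' @export
assign_reads <- function(reads, refs, max_mm = 2L) {
  check_reads(reads)
  stopifnot(is.list(refs), length(refs) > 0,
            all(vapply(refs, inherits, logical(1), "reference_set")))
  categories <- vapply(refs, function(r) r$category, character(1))
  if (anyDuplicated(categories)) abort("duplicate category in reference list")
  if (nrow(reads) == 0) {
    return(tibble(read_id = character(0), seq = character(0),
                  mult = integer(0), length = integer(0),
                  category = character(0), ref_id = character(0),
                  subfamily = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  mismatches = integer(0)))
  }
  # align each distinct sequence once; expand back to reads afterwards
  uniq <- unique(reads$seq)
  res <- cpp_cascade(uniq, lapply(refs, function(r) r$sequences$seq),
                     as.integer(max_mm))
  cat_of <- c("unaligned", categories)[res$category + 1L]
  ref_of <- rep(NA_character_, length(uniq))
  sub_of <- rep(NA_character_, length(uniq))
  aligned <- res$category > 0L
  if (any(aligned)) {
    ids <- vapply(refs, function(r) list(r$sequences$id), list(1))
    ref_of[aligned] <- mapply(function(s, r) ids[[s]][r],
                              res$category[aligned], res$ref_idx[aligned])
    is_rep <- aligned & cat_of == "repeat"
    if (any(is_rep)) {
      rep_set <- refs[[which(categories == "repeat")]]
      sf <- stats::setNames(rep_set$sequences$id, rep_set$sequences$id)
      if (!is.null(rep_set$subfamily_of)) {
        sf[names(rep_set$subfamily_of)] <- rep_set$subfamily_of
      }
      sub_of[is_rep] <- unname(sf[ref_of[is_rep]])
    }
  }
  idx <- match(reads$seq, uniq)
  tibble(read_id = reads$read_id, seq = reads$seq, mult = reads$mult,
         length = nchar(reads$seq),
         category = cat_of[idx],
         ref_id = ref_of[idx],
         subfamily = sub_of[idx],
         start = res$start[idx],
         end = res$start[idx] + ifelse(aligned[idx], nchar(reads$seq), NA),
         strand = res$strand[idx],
         mismatches = res$mismatches[idx])
}

#' Run the full annotation cascade over a preprocessed library
#'
#' Produces the library partition over the seven reference categories
#' plus `unaligned`, with multiplicity-weighted counts that always sum to
#' the input total, and the per-read assignments.
#'
#' @inheritParams assign_reads
#' @return An `annotation_summary` object: a list with `assignments`
#'   (tibble from [assign_reads()]), `counts` (per-category
#'   multiplicity-weighted read counts over all categories plus
#'   `unaligned`), `total_input`, and `category_order`.
#' @export
run_cascade <- function(reads, refs, max_mm = 2L) {
  assignments <- assign_reads(reads, refs, max_mm)
  categories <- vapply(refs, function(r) r$category, character(1))
  bins <- c(categories, "unaligned")
  counts <- assignments |>
    group_by(category = factor(.data$category, levels = bins)) |>
    summarise(reads = sum(.data$mult), .groups = "drop") |>
    tidyr::complete(category = factor(bins, levels = bins),
                    fill = list(reads = 0)) |>
    mutate(category = as.character(.data$category), reads = as.numeric(.data$reads))
  total_input <- sum(assignments$mult)
  stopifnot(sum(counts$reads) == total_input)
  structure(list(assignments = assignments, counts = counts,
                 total_input = total_input, category_order = categories),
            class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf("<annotation_summary> %s reads over %d categories\n",
              format(x$total_input, big.mark = ","),
              length(x$category_order)))
  df <- x$counts
  df$fraction <- if (x$total_input > 0) df$reads / x$total_input else 0
  print(as_tibble(df))
  invisible(x)
}

#' Tidy an annotation summary into per-category counts
#'
#' @param x An `annotation_summary`.
#' @param ... Unused.
#' @return Tibble with `category`, `reads` (multiplicity-weighted) and
#'   `fraction` of the library total.
#' @export
tidy.annotation_summary <- function(x, ...) {
  mutate(x$counts,
         fraction = if (x$total_input > 0) .data$reads / x$total_input else 0)
}

#' One-row overview of an annotation summary
#'
#' @param x An `annotation_summary`.
#' @param ... Unused.
#' @return One-row tibble: `total_input`, `aligned`, `aligned_fraction`,
#'   `alu_reads` (repeat-category reads on Alu subfamilies).
#' @export
glance.annotation_summary <- function(x, ...) {
  unal <- x$counts$reads[x$counts$category == "unaligned"]
  alu <- alu_read_count(x)
  tibble(total_input = x$total_input,
         aligned = x$total_input - unal,
         aligned_fraction = if (x$total_input > 0)
           (x$total_input - unal) / x$total_input else NA_real_,
         alu_reads = alu)
}

# multiplicity-weighted count of repeat-category reads on Alu subfamilies,
# optionally restricted to a length window
alu_read_count <- function(summary, lo = NULL, hi = NULL) {
  a <- summary$assignments
  keep <- a$category == "repeat" & !is.na(a$subfamily) &
    stringi::stri_startswith_fixed(a$subfamily, "Alu")
  if (!is.null(lo)) keep <- keep & a$length >= lo & a$length <= hi
  sum(a$mult[keep])
}

category_count <- function(summary, category) {
  sum(summary$counts$reads[summary$counts$category == category])
}
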