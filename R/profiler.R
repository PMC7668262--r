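#' Select Alu-derived endo-siRNAs from an annotation summary
#'
#' An Alu endo-siRNA is a read assigned to the repeat category, on a
#' subfamily whose name begins with `Alu`, with insert length inside the
#' siRNA window (19-24 nt by default). Strand is taken from the alignment
#' hit: `+` reads match the consensus (sense), `-` reads its reverse
#' complement (antisense).
#'
#' @param summary An `annotation_summary` from [run_cascade()].
#' @param lo,hi Inclusive siRNA length window (defaults 19 and 24).
#' @return Assignment tibble restricted to Alu siRNAs.
#' @export
select_alu_sirnas <- function(summary, lo = 19L, hi = 24L) {
  stopifnot(inherits(summary, "annotation_summary"))
  a <- summary$assignments
  a[a$category == "repeat" & !is.na(a$subfamily) &
      stringi::stri_startswith_fixed(a$subfamily, "Alu") &
      a$length >= lo & a$length <= hi, , drop = FALSE]
}

#' Strand-resolved length distribution of Alu reads in CPM
#'
#' Counts Alu-mapped reads (repeat category, `Alu*` subfamily) per insert
#' length and strand over the full preprocessed window and scales to
#' counts per million: `cpm = count / library_total * 1e6`.
#'
#' @param summary An `annotation_summary`.
#' @param denominator_mode What the library-size denominator counts:
#'   `"preprocessed"` (all reads entering the cascade; default),
#'   `"aligned"` (reads assigned to any category), or `"total_raw"`
#'   (a caller-supplied raw read count via `total_raw`).
#' @param total_raw Raw library size, required for
#'   `denominator_mode = "total_raw"`.
#' @param lo,hi Length window of the distribution (defaults 19 and 35).
#' @return A `length_distribution` tibble: `length`, `strand`, `count`,
#'   `cpm` on the complete length x strand grid, with the denominator in
#'   attribute `library_total`.
#' @export
length_distribution <- function(summary,
                                denominator_mode = c("preprocessed",
                                                     "aligned", "total_raw"),
                                total_raw = NULL, lo = 19L, hi = 35L) {
  stopifnot(inherits(summary, "annotation_summary"))
  denominator_mode <- match.arg(denominator_mode)
  denom <- switch(denominator_mode,
    preprocessed = summary$total_input,
    aligned = summary$total_input -
      category_count(summary, "unaligned"),
    total_raw = {
      if (is.null(total_raw)) abort("total_raw must be supplied")
      total_raw
    })
  if (!isTRUE(denom > 0)) abort("library-size denominator is zero")
  alu <- select_alu_sirnas(summary, lo = lo, hi = hi)
  grid <- tidyr::expand_grid(length = lo:hi, strand = c("+", "-"))
  dist <- alu |>
    group_by(.data$length, .data$strand) |>
    summarise(count = sum(.data$mult), .groups = "drop")
  out <- grid |>
    left_join(dist, by = c("length", "strand")) |>
    mutate(count = tidyr::replace_na(.data$count, 0),
           cpm = .data$count / denom * 1e6)
  structure(out, library_total = denom,
            class = c("length_distribution", class(out)))
}

#' Positional 5'-start profile of Alu siRNAs on one consensus
#'
#' Histograms the 5'-start position (leftmost reference base of the hit,
#' for both strands, so sense and antisense share one axis) of Alu
#' siRNAs over a repeat consensus. Start-position profiles resolve the
#' DICER cleavage register along the consensus.
#'
#' @param alu_hits Assignment tibble (e.g. from [select_alu_sirnas()]).
#' @param consensus Tibble row or list with `id` and `seq` of the
#'   consensus the hits are profiled on.
#' @return A `consensus_profile` tibble: `consensus_id`, `pos` (0-based,
#'   full consensus grid), `strand`, `count` (multiplicity-weighted).
#' @export
consensus_profile <- function(alu_hits, consensus) {
  stopifnot(all(c("ref_id", "start", "end", "strand", "mult") %in%
                  names(alu_hits)))
  len <- nchar(consensus$seq)
  hits <- alu_hits[!is.na(alu_hits$ref_id) &
                     alu_hits$ref_id == consensus$id, , drop = FALSE]
  if (nrow(hits) > 0 && any(hits$start < 0 | hits$end > len)) {
    abort("hit interval outside consensus length")
  }
  grid <- tidyr::expand_grid(pos = 0:(len - 1L), strand = c("+", "-"))
  prof <- hits |>
    group_by(pos = .data$start, .data$strand) |>
    summarise(count = sum(.data$mult), .groups = "drop")
  out <- grid |>
    left_join(prof, by = c("pos", "strand")) |>
    mutate(count = tidyr::replace_na(.data$count, 0),
           consensus_id = consensus$id) |>
    select("consensus_id", "pos", "strand", "count")
  structure(out, class = c("consensus_profile", class(out)))
}

#' Exclusion-normalized Alu siRNA count
#'
#' The Alu siRNA read count divided by the library total excluding miRNA
#' and Alu siRNA reads, times one million:
#' `alu / (total - miRNA - alu) * 1e6`. Excluding the two numerator-side
#' classes from the denominator makes the statistic robust to the large,
#' condition-dependent miRNA fraction. The per-length variant restricts
#' the numerator to one insert length while keeping the same global
#' denominator.
#'
#' @param summary An `annotation_summary`.
#' @param lo,hi Inclusive siRNA window defining "Alu siRNA" (19-24 nt).
#' @param per_length If `TRUE`, return a tibble with one normalized value
#'   per length in `lo:hi` (same global denominator); otherwise a single
#'   number.
#' @return A numeric scalar, or a tibble `length`, `normalized`.
#' @export
normalized_alu_count <- function(summary, lo = 19L, hi = 24L,
                                 per_length = FALSE) {
  stopifnot(inherits(summary, "annotation_summary"))
  alu <- alu_read_count(summary, lo, hi)
  mirna <- category_count(summary, "miRNA")
  denom <- summary$total_input - mirna - alu
  if (!isTRUE(denom > 0)) {
    abort("non-positive denominator: total - miRNA - Alu siRNA must be > 0")
  }
  if (!per_length) return(alu / denom * 1e6)
  sel <- select_alu_sirnas(summary, lo, hi)
  per_len <- sel |>
    group_by(.data$length) |>
    summarise(count = sum(.data$mult), .groups = "drop")
  tibble(length = lo:hi) |>
    left_join(per_len, by = "length") |>
    mutate(count = tidyr::replace_na(.data$count, 0),
           normalized = .data$count / denom * 1e6) |>
    select("length", "normalized")
}

#' Per-length differential of exclusion-normalized Alu siRNA counts
#'
#' Computes, per insert length, the normalized Alu siRNA read number of
#' the treated (e.g. knockdown) library minus that of the control
#' library, each per [normalized_alu_count()] with its own library-level
#' denominator. A negative delta means fewer normalized Alu siRNA reads
#' after treatment (the expected direction when the dsRNA-processing
#' machinery is depleted).
#'
#' @param treated,control `annotation_summary` objects.
#' @param lo,hi Inclusive siRNA length window (19-24 nt).
#' @return A `differential_profile` tibble: `length`, `norm_treated`,
#'   `norm_control`, `delta`, with the normalization components
#'   (`alu_count`, `denominator` per library) in attribute `components`.
#' @export
differential_profile <- function(treated, control, lo = 19L, hi = 24L) {
  nt <- normalized_alu_count(treated, lo, hi, per_length = TRUE)
  nc <- normalized_alu_count(control, lo, hi, per_length = TRUE)
  out <- tibble(length = nt$length,
                norm_treated = nt$normalized,
                norm_control = nc$normalized,
                delta = nt$normalized - nc$normalized)
  comp <- tibble(
    library = c("treated", "control"),
    alu_count = c(alu_read_count(treated, lo, hi),
                  alu_read_count(control, lo, hi)),
    mirna_count = c(category_count(treated, "miRNA"),
                    category_count(control, "miRNA")),
    total = c(treated$total_input, control$total_input))
  comp$denominator <- comp$total - comp$mirna_count - comp$alu_count
  structure(out, components = comp,
            class = c("differential_profile", class(out)))
}

#' @export
tidy.differential_profile <- function(x, ...) as_tibble(unclass_keep(x))

#' @export
glance.differential_profile <- function(x, ...) {
  comp <- attr(x, "components")
  tibble(norm_treated_total = sum(x$norm_treated),
         norm_control_total = sum(x$norm_control),
         delta_total = sum(x$delta),
         denominator_treated = comp$denominator[comp$library == "treated"],
         denominator_control = comp$denominator[comp$library == "control"])
}

unclass_keep <- function(x) {
  class(x) <- setdiff(class(x), c("length_distribution", "consensus_profile",
                                  "differential_profile", "strand_coverage"))
  x
}

#' Map in vitro dicing products onto a hairpin and accumulate coverage
#'
#' Implements the dicing-product analysis mode: the 5' adaptor is removed
#' as an exact prefix, the 3' adaptor by [trim_adaptor()], and the
#' resulting inserts are mapped with zero mismatches to both strands of
#' the hairpin sequence; per-strand per-position coverage is accumulated
#' over each hit interval. Reads that fail trimming or do not map are
#' counted, not errors.
#'
#' @param raw_reads Raw read tibble.
#' @param hairpin A [hairpin_locus()].
#' @param adaptor5,adaptor3 The 5' and 3' cloning adaptors (defaults:
#'   [dicing_adaptors()]).
#' @param min_overlap Minimum 3'-adaptor overlap for trimming.
#' @return A `strand_coverage` tibble (`pos`, `strand`, `coverage` over
#'   the full hairpin grid) with attributes `hairpin` (name), `intervals`
#'   (arm/loop intervals) and `report` (one-row tibble: `n_input`,
#'   `n_untrimmed`, `n_unmapped`, `n_mapped`, multiplicity-weighted).
#' @export
map_dicing_products <- function(raw_reads, hairpin,
                                adaptor5 = dicing_adaptors()[["adaptor5"]],
                                adaptor3 = dicing_adaptors()[["adaptor3"]],
                                min_overlap = 6L) {
  check_reads(raw_reads)
  stopifnot(inherits(hairpin, "hairpin_locus"))
  adaptor5 <- fold_to_dna(adaptor5, "adaptor5")
  n_input <- sum(raw_reads$mult)
  seq <- raw_reads$seq
  has5 <- stringi::stri_startswith_fixed(seq, adaptor5)
  seq[has5] <- substring(seq[has5], nchar(adaptor5) + 1L)
  stripped <- tibble(read_id = raw_reads$read_id, seq = seq,
                     mult = raw_reads$mult)
  stripped <- stripped[nchar(stripped$seq) > 0, , drop = FALSE]
  trimmed <- trim_adaptor(stripped, adaptor3, min_overlap)
  ok <- !is.na(trimmed$insert)
  n_untrimmed <- n_input - sum(trimmed$mult[ok])
  inserts <- tibble(read_id = trimmed$read_id[ok], seq = trimmed$insert[ok],
                    mult = trimmed$mult[ok])
  hp_set <- reference_set("repeat",
                          tibble(id = hairpin$name, seq = hairpin$full_seq))
  asg <- assign_reads(inserts, list(hp_set), max_mm = 0L)
  mapped <- asg[asg$category != "unaligned", , drop = FALSE]
  n_mapped <- sum(mapped$mult)
  n_unmapped <- sum(inserts$mult) - n_mapped
  len <- nchar(hairpin$full_seq)
  cov <- matrix(0, nrow = len, ncol = 2,
                dimnames = list(NULL, c("+", "-")))
  if (nrow(mapped) > 0) {
    for (i in seq_len(nrow(mapped))) {
      idx <- (mapped$start[i] + 1L):mapped$end[i]
      cov[idx, mapped$strand[i]] <- cov[idx, mapped$strand[i]] + mapped$mult[i]
    }
  }
  out <- tibble(pos = rep(0:(len - 1L), 2),
                strand = rep(c("+", "-"), each = len),
                coverage = c(cov[, "+"], cov[, "-"]))
  structure(out,
            hairpin = hairpin$name,
            intervals = list(left_arm = hairpin$left_arm,
                             loop = hairpin$loop,
                             right_arm = hairpin$right_arm),
            report = tibble(n_input = n_input, n_untrimmed = n_untrimmed,
                            n_unmapped = n_unmapped, n_mapped = n_mapped),
            class = c("strand_coverage", class(out)))
}
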