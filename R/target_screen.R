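#' Count sense/antisense Alu elements in each gene's 3'UTR
#'
#' For every gene, counts Alu-family repeat annotations whose genomic
#' interval overlaps the 3'UTR interval by at least `min_overlap_frac` of
#' the repeat length (default 1, i.e. fully contained). Orientation is
#' relative to the mRNA: a repeat on the same genomic strand as the gene
#' is sense, on the opposite strand antisense.
#'
#' @param genes Gene model tibble (see [read_gene_models()]).
#' @param repeats Repeat annotation tibble (see
#'   [read_repeat_annotations()]).
#' @param min_overlap_frac Minimum overlap as a fraction of repeat length.
#' @return Tibble with `gene_id`, `n_sense`, `n_antisense`, `expression`.
#' @export
classify_utr_alus <- function(genes, repeats, min_overlap_frac = 1) {
  stopifnot(all(c("gene_id", "chrom", "strand", "utr3_start", "utr3_end",
                  "expression") %in% names(genes)))
  alus <- repeats[repeats$family == "Alu", , drop = FALSE]
  base <- tibble(gene_id = genes$gene_id, n_sense = 0L, n_antisense = 0L,
                 expression = genes$expression)
  if (nrow(alus) == 0 || nrow(genes) == 0) return(base)
  joined <- inner_join(
    select(genes, "gene_id", "chrom", gene_strand = "strand",
           "utr3_start", "utr3_end"),
    select(alus, "chrom", "start", "end", rep_strand = "strand"),
    by = "chrom", relationship = "many-to-many")
  if (nrow(joined) == 0) return(base)
  joined <- joined |>
    mutate(overlap = pmax(0L, pmin(.data$end, .data$utr3_end) -
                            pmax(.data$start, .data$utr3_start)),
           rep_len = .data$end - .data$start) |>
    filter(.data$overlap >= min_overlap_frac * .data$rep_len,
           .data$overlap > 0)
  counts <- joined |>
    group_by(.data$gene_id) |>
    summarise(n_sense = sum(.data$rep_strand == .data$gene_strand),
              n_antisense = sum(.data$rep_strand != .data$gene_strand),
              .groups = "drop")
  base |>
    select(-"n_sense", -"n_antisense") |>
    left_join(counts, by = "gene_id") |>
    mutate(n_sense = as.integer(tidyr::replace_na(.data$n_sense, 0L)),
           n_antisense = as.integer(tidyr::replace_na(.data$n_antisense, 0L))) |>
    select("gene_id", "n_sense", "n_antisense", "expression")
}

#' Screen for expressed genes with a single-copy 3'UTR Alu
#'
#' Keeps genes with exactly one Alu in the requested orientation and none
#' in the other (a gene with one sense plus one antisense copy forms a
#' potential inverted repeat and is excluded from both screens), whose
#' expression strictly exceeds the threshold.
#'
#' @param statuses Output of [classify_utr_alus()].
#' @param orientation `"antisense"` (targets of sense Alu siRNAs) or
#'   `"sense"`.
#' @param expr_threshold Expression cut on the log10 scale (default 4.5);
#'   strict inequality, so a gene exactly at the threshold is excluded.
#' @return Candidate tibble (same columns as `statuses`), sorted by
#'   `gene_id`.
#' @export
screen_single_alu_genes <- function(statuses,
                                    orientation = c("antisense", "sense"),
                                    expr_threshold = 4.5) {
  orientation <- match.arg(orientation)
  keep <- if (orientation == "antisense") {
    statuses$n_antisense == 1L & statuses$n_sense == 0L
  } else {
    statuses$n_sense == 1L & statuses$n_antisense == 0L
  }
  statuses[keep & statuses$expression > expr_threshold, , drop = FALSE] |>
    arrange(.data$gene_id)
}

#' Extract the seed of an siRNA (positions 2-8 from the 5' end)
#'
#' The standard 7-nt seed window; silencing is nucleated by a perfect
#' reverse-complement match of this seed in the target 3'UTR.
#'
#' @param sirna_seq siRNA sequence, 5' to 3', 19-24 nt (RNA accepted).
#' @return The 7-nt seed as a DNA string.
#' @export
sirna_seed <- function(sirna_seq) {
  seq <- fold_to_dna(sirna_seq, "siRNA")
  if (nchar(seq) < 19 || nchar(seq) > 24) {
    abort("siRNA length must be within [19, 24]")
  }
  substr(seq, 2, 8)
}

#' Predict seed-complementary siRNA target sites in a 3'UTR
#'
#' Scans the mRNA-sense 3'UTR for occurrences of the reverse complement
#' of the siRNA seed (positions 2-8). Exact occurrences are
#' `perfect_seed` sites; with `allow_seed_mm = 1`, positions at Hamming
#' distance exactly 1 are reported as `seed_with_mismatch`. Overlapping
#' sites are all reported, sorted by start. No supplementary pairing,
#' G:U wobbles or context scoring is applied.
#'
#' @param sirna_seq siRNA sequence (19-24 nt, 5' to 3').
#' @param utr3_seq 3'UTR sequence in mRNA-sense orientation (a UTR
#'   shorter than 7 nt yields no sites).
#' @param allow_seed_mm 0 (perfect only) or 1.
#' @param sirna_name Name recorded in `matched_sirna`.
#' @param gene_id Optional gene id recorded with each site.
#' @return Tibble of target sites: `gene_id`, `start`, `end` (0-based
#'   half-open on the UTR), `match_class`, `matched_sirna`, `site_seq`.
#' @export
predict_target_sites <- function(sirna_seq, utr3_seq, allow_seed_mm = 0L,
                                 sirna_name = "siRNA",
                                 gene_id = NA_character_) {
  stopifnot(allow_seed_mm %in% c(0L, 1L))
  seed <- sirna_seed(sirna_seq)
  utr <- fold_to_dna(utr3_seq, "utr3_seq")
  empty <- tibble(gene_id = character(0), start = integer(0),
                  end = integer(0), match_class = character(0),
                  matched_sirna = character(0), site_seq = character(0))
  if (nchar(utr) < 7) return(empty)
  motif <- revcomp(seed)
  hits <- cpp_align_all(motif, utr, as.integer(allow_seed_mm))
  hits <- hits[hits$strand == "+", , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  tibble(gene_id = gene_id,
         start = hits$start,
         end = hits$start + 7L,
         match_class = ifelse(hits$mismatches == 0L, "perfect_seed",
                              "seed_with_mismatch"),
         matched_sirna = sirna_name,
         site_seq = substring(utr, hits$start + 1L, hits$start + 7L)) |>
    arrange(.data$start)
}
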