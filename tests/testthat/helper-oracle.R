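# Independent brute-force reference implementations used as oracles.
# Deliberately plain R, sharing no code with the package internals.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# all end-to-end placements of `query` on both strands of `ref` with
# Hamming mismatches <= max_mm; N (either side) never matches
oracle_align <- function(query, ref, max_mm) {
  empty <- data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0))
  lq <- nchar(query); lr <- nchar(ref)
  if (lq == 0 || lq > lr) return(empty)
  rchars <- strsplit(ref, "", fixed = TRUE)[[1]]
  n_off <- lr - lq + 1
  W <- vapply(seq_len(lq), function(i) rchars[i:(i + n_off - 1)],
              character(n_off))
  W <- matrix(W, nrow = n_off)
  mm_of <- function(q) {
    qm <- matrix(strsplit(q, "", fixed = TRUE)[[1]], n_off, lq, byrow = TRUE)
    ok <- (W == qm) & (W %in% c("A", "C", "G", "T"))
    lq - rowSums(ok)
  }
  mm_p <- mm_of(query)
  mm_m <- mm_of(oracle_revcomp(query))
  out <- rbind(
    data.frame(start = which(mm_p <= max_mm) - 1L,
               strand = rep("+", sum(mm_p <= max_mm)),
               mismatches = mm_p[mm_p <= max_mm]),
    data.frame(start = which(mm_m <= max_mm) - 1L,
               strand = rep("-", sum(mm_m <= max_mm)),
               mismatches = mm_m[mm_m <= max_mm]))
  out[order(out$mismatches, out$start, out$strand == "-"), , drop = FALSE]
}

# brute-force per-gene 3'UTR Alu orientation counts
oracle_classify <- function(genes, repeats, min_overlap_frac = 1) {
  res <- data.frame(gene_id = genes$gene_id, n_sense = 0L, n_antisense = 0L)
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(repeats))) {
      if (repeats$family[j] != "Alu") next
      if (repeats$chrom[j] != genes$chrom[i]) next
      ov <- min(repeats$end[j], genes$utr3_end[i]) -
        max(repeats$start[j], genes$utr3_start[i])
      if (ov <= 0) next
      if (ov < min_overlap_frac * (repeats$end[j] - repeats$start[j])) next
      if (repeats$strand[j] == genes$strand[i]) {
        res$n_sense[i] <- res$n_sense[i] + 1L
      } else {
        res$n_antisense[i] <- res$n_antisense[i] + 1L
      }
    }
  }
  res
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

make_reads <- function(seqs, mult = 1L, prefix = "t") {
  tibble::tibble(read_id = sprintf("%s%04d", prefix, seq_along(seqs)),
                 seq = seqs,
                 mult = as.integer(rep(mult, length.out = length(seqs))))
}

# tiny two-category reference universe used by several unit tests
tiny_refs <- function() {
  alu <- paste0(
    "GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTTGGGAGGCCGAGGCGGGCGGA",
    "TCACGAGGTCAGGAGATCGAGACCATCCTGGCTAACACGGTGAAACCCCGTCTCTACTAA")
  trna <- "GGGGGTATAGCTCAGTTGGTAGAGCGCTGCCTTTGCACGGCAGATGTCAGGGGTTCGAGTCCCCTTACCTCCA"
  list(
    repeat_set = alusirna::reference_set(
      "repeat", tibble::tibble(id = "AluY_syn", seq = alu),
      subfamily_of = c(AluY_syn = "AluY_syn")),
    trna_set = alusirna::reference_set(
      "tRNA", tibble::tibble(id = "tRNA_1", seq = trna)),
    alu_seq = alu, trna_seq = trna)
}
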