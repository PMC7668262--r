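make_gene <- function(id, strand, s = 1000L, e = 2500L, expr = 5) {
  tibble::tibble(gene_id = id, chrom = "chr3", strand = strand,
                 utr3_start = s, utr3_end = e, expression = expr,
                 utr3_seq = NA_character_)
}
make_alu <- function(s, e, strand, sub = "AluJb", chrom = "chr3") {
  tibble::tibble(chrom = chrom, start = s, end = e, strand = strand,
                 subfamily = sub, family = "Alu")
}

test_that("3'UTR Alu orientation is counted relative to the mRNA", {
  # plus-strand gene with one minus-strand Alu inside its 3'UTR:
  # the single-antisense configuration
  st <- classify_utr_alus(make_gene("CDCP1like", "+"),
                          make_alu(1200L, 1500L, "-"))
  expect_equal(st$n_sense, 0L)
  expect_equal(st$n_antisense, 1L)

  # minus-strand gene with a minus-strand Alu: sense to the mRNA
  st <- classify_utr_alus(make_gene("G2", "-"), make_alu(1200L, 1500L, "-"))
  expect_equal(st$n_sense, 1L)
  expect_equal(st$n_antisense, 0L)

  # repeat outside the UTR, or on another chromosome: not counted
  st <- classify_utr_alus(make_gene("G3", "+"),
                          dplyr::bind_rows(make_alu(4000L, 4300L, "-"),
                                           make_alu(1200L, 1500L, "-",
                                                    chrom = "chr7")))
  expect_equal(st$n_sense + st$n_antisense, 0L)

  # non-Alu families are ignored
  l1 <- make_alu(1200L, 1500L, "-")
  l1$family <- "L1"
  expect_equal(classify_utr_alus(make_gene("G4", "+"), l1)$n_antisense, 0L)
})

test_that("partial overlaps respect min_overlap_frac", {
  g <- make_gene("G1", "+")
  half_in <- make_alu(850L, 1150L, "-")  # 150 of 300 bp inside the UTR
  expect_equal(classify_utr_alus(g, half_in)$n_antisense, 0L)
  expect_equal(classify_utr_alus(g, half_in,
                                 min_overlap_frac = 0.5)$n_antisense, 1L)
  expect_equal(classify_utr_alus(g, half_in,
                                 min_overlap_frac = 0)$n_antisense, 1L)
})

test_that("classification matches a brute-force overlap count on random sets", {
  set.seed(19)
  for (rep in 1:5) {
    genes <- tibble::tibble(
      gene_id = sprintf("G%02d", 1:12), chrom = sample(c("c1", "c2"), 12, TRUE),
      strand = sample(c("+", "-"), 12, TRUE),
      utr3_start = sample.int(5000, 12),
      expression = runif(12, 4, 5.5))
    genes$utr3_end <- genes$utr3_start + sample(300:1200, 12, TRUE)
    genes$utr3_seq <- NA_character_
    reps <- tibble::tibble(
      chrom = sample(c("c1", "c2"), 30, TRUE),
      start = sample.int(6000, 30),
      strand = sample(c("+", "-"), 30, TRUE),
      subfamily = sample(c("AluY", "AluSz", "L1M"), 30, TRUE))
    reps$end <- reps$start + sample(250:320, 30, TRUE)
    reps$family <- ifelse(startsWith(reps$subfamily, "Alu"),
                          "Alu", reps$subfamily)
    for (frac in c(1, 0.5)) {
      got <- classify_utr_alus(genes, reps, min_overlap_frac = frac)
      want <- oracle_classify(genes, reps, min_overlap_frac = frac)
      expect_equal(got$n_sense, want$n_sense)
      expect_equal(got$n_antisense, want$n_antisense)
    }
    # orientation anti-symmetry: flipping both strands changes nothing
    flip <- function(s) ifelse(s == "+", "-", "+")
    g2 <- dplyr::mutate(genes, strand = flip(strand))
    r2 <- dplyr::mutate(reps, strand = flip(strand))
    expect_equal(classify_utr_alus(g2, r2)[c("n_sense", "n_antisense")],
                 classify_utr_alus(genes, reps)[c("n_sense", "n_antisense")])
  }
})

test_that("the single-Alu screen applies exactly-one and strict expression rules", {
  st <- tibble::tibble(
    gene_id = c("gAS", "gS", "gBoth", "gNone", "gLow", "gEdge", "gTwo"),
    n_sense = c(0L, 1L, 1L, 0L, 0L, 0L, 0L),
    n_antisense = c(1L, 0L, 1L, 0L, 1L, 1L, 2L),
    expression = c(4.7, 5.0, 5.2, 5.0, 4.2, 4.5, 5.1))
  as_hits <- screen_single_alu_genes(st, "antisense")
  expect_equal(as_hits$gene_id, "gAS")  # gEdge at exactly 4.5 is excluded
  s_hits <- screen_single_alu_genes(st, "sense")
  expect_equal(s_hits$gene_id, "gS")
  # inverted-pair and two-copy genes are excluded from both screens
  expect_false(any(c("gBoth", "gTwo") %in%
                     c(as_hits$gene_id, s_hits$gene_id)))
  # results come back sorted by gene_id
  st2 <- dplyr::bind_rows(st, dplyr::mutate(st[1, ], gene_id = "aFirst"))
  expect_equal(screen_single_alu_genes(st2, "antisense")$gene_id,
               c("aFirst", "gAS"))
})

test_that("seed sites are reverse-complement matches of positions 2-8", {
  sirna <- "UAUGGCCAAGUCAGCUAAGCU"   # seed AUGGCCA -> site motif TGGCCAT
  expect_equal(sirna_seed(sirna), "ATGGCCA")
  utr <- paste0(strrep("A", 30), "TGGCCAT", strrep("C", 30))
  sites <- predict_target_sites(sirna, utr, sirna_name = "S2")
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 30L)
  expect_equal(sites$end, 37L)
  expect_equal(sites$match_class, "perfect_seed")
  expect_equal(sites$site_seq, "TGGCCAT")
  expect_equal(sites$matched_sirna, "S2")

  # two embedded sites: the two-site configuration is fully recovered
  utr2 <- paste0(strrep("A", 10), "TGGCCAT", strrep("G", 20), "TGGCCAT")
  sites2 <- predict_target_sites(sirna, utr2)
  expect_equal(sites2$start, c(10L, 37L))

  # a UTR without the 7-mer yields nothing; short UTRs yield nothing
  expect_equal(nrow(predict_target_sites(sirna, strrep("AC", 50))), 0L)
  expect_equal(nrow(predict_target_sites(sirna, "ACGT")), 0L)
  expect_error(sirna_seed("ACGT"), "length")
})

test_that("one-mismatch seed sites are reported as a separate class", {
  sirna <- "TATGGCCAAGTCAGCTAAGCT"
  utr <- paste0("TGGACAT", strrep("A", 10), "TGGCCAT")  # 1 mm, then perfect
  s0 <- predict_target_sites(sirna, utr, allow_seed_mm = 0)
  expect_equal(nrow(s0), 1L)
  s1 <- predict_target_sites(sirna, utr, allow_seed_mm = 1)
  expect_equal(s1$match_class[s1$start == 0],  "seed_with_mismatch")
  expect_equal(s1$match_class[s1$start == 17], "perfect_seed")
  expect_true(!is.unsorted(s1$start))
})

test_that("overlapping seed sites are all reported", {
  sirna <- "TAAAAAACGTACGTACGTACG"  # seed AAAAAAC -> motif GTTTTTT
  utr <- paste0("CC", "GTTTTTTTT", "CC")
  sites <- predict_target_sites(sirna, utr)
  # GTTTTTTTT contains GTTTTTT only at offset 2 (G required first)
  expect_equal(sites$start, 2L)
  utr2 <- "GGTTTTTTGTTTTTTGG"
  expect_equal(nrow(predict_target_sites(sirna, utr2)), 2L)
})
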