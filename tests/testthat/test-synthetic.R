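test_that("generation is deterministic for a fixed seed", {
  r1 <- make_synthetic_references(seed = 5)
  r2 <- make_synthetic_references(seed = 5)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$consensi, r2$consensi)
  expect_identical(r1$repeats, r2$repeats)
  expect_identical(r1$genes, r2$genes)

  cfg <- sim_config(seed = 5, n_reads = 2000)
  l1 <- simulate_library(cfg, r1)
  l2 <- simulate_library(cfg, r2)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$truth, l2$truth)

  fa1 <- withr::local_tempfile(); fa2 <- withr::local_tempfile()
  write_fasta(r1$consensi, fa1); write_fasta(r2$consensi, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
})

test_that("embedded Alu copies match the genome and, unmutated, the consensus", {
  refs <- make_synthetic_references(seed = 6, mutation_rate = 0)
  gseq <- refs$genome$seq
  for (i in seq_len(nrow(refs$repeats))) {
    r <- refs$repeats[i, ]
    emb <- substr(gseq, r$start + 1, r$end)
    cons <- refs$consensi$seq[refs$consensi$id == r$subfamily]
    expect_identical(if (r$strand == "+") emb else revcomp(emb), cons)
  }
  # mRNA-sense UTR sequences agree with the genome
  for (i in seq_len(nrow(refs$genes))) {
    g <- refs$genes[i, ]
    emb <- substr(gseq, g$utr3_start + 1, g$utr3_end)
    expect_identical(if (g$strand == "+") emb else revcomp(emb), g$utr3_seq)
  }
})

test_that("the constructed gene configurations are recovered by the screen", {
  refs <- make_synthetic_references(seed = 8, low_expr_genes = 2)
  st <- classify_utr_alus(refs$genes, refs$repeats)
  truth <- refs$gene_truth
  got_as <- screen_single_alu_genes(st, "antisense")$gene_id
  got_s <- screen_single_alu_genes(st, "sense")$gene_id
  expect_setequal(got_as, truth$gene_id[truth$candidate_antisense])
  expect_setequal(got_s, truth$gene_id[truth$candidate_sense])
  # inverted-pair genes count one of each orientation
  inv <- st[st$gene_id %in% truth$gene_id[truth$config == "inverted"], ]
  expect_true(all(inv$n_sense == 1L & inv$n_antisense == 1L))
})

test_that("dicer fragments stay within arms and round-trip at 0 mismatches", {
  refs <- make_synthetic_references(seed = 9)
  hp <- refs$hairpins[[1]]
  fr <- simulate_dicer_products(hp, 400, seed = 9)
  expect_true(all(fr$length %in% 21:24))
  in_arm <- (fr$start >= hp$left_arm[1] &
               fr$start + fr$length <= hp$left_arm[2]) |
    (fr$start >= hp$right_arm[1] & fr$start + fr$length <= hp$right_arm[2])
  expect_true(all(in_arm))
  for (i in sample.int(400, 25)) {
    h <- align_ungapped(fr$seq[i],
                        tibble::tibble(id = "hp", seq = hp$full_seq), 0)
    expect_gt(nrow(h), 0)
    expect_true(any(h$start == fr$start[i] & h$mismatches == 0))
  }
  expect_equal(nrow(simulate_dicer_products(hp, 0)), 0L)
  short <- hairpin_locus("s", strrep("ACGT", 10), c(0L, 10L), c(10L, 30L),
                         c(30L, 40L))
  expect_error(simulate_dicer_products(short, 5), "arm")
})

test_that("one-sided strand ratios give one-sided hairpin coverage", {
  refs <- make_synthetic_references(seed = 10)
  hp <- refs$hairpins[[1]]
  fr <- simulate_dicer_products(hp, 200, seed = 10, strand_prob = 1)
  ads <- dicing_adaptors()
  raw <- make_reads(paste0(ads["adaptor5"], fr$seq, ads["adaptor3"]))
  cov <- map_dicing_products(raw, hp)
  expect_equal(sum(cov$coverage[cov$strand == "-"]), 0)
  expect_gt(sum(cov$coverage[cov$strand == "+"]), 0)
})

test_that("realized class counts concentrate around the class mix", {
  cfg <- sim_config(seed = 12, n_reads = 20000)
  refs <- make_synthetic_references(seed = 12)
  lib <- simulate_library(cfg, refs)
  n <- cfg$n_reads
  for (cl in names(cfg$class_mix)) {
    p <- cfg$class_mix[[cl]]
    se <- sqrt(n * p * (1 - p))
    expect_lte(abs(sum(lib$class_counts[cl]) - n * p), 4 * se + 1)
  }
})

test_that("cascade assignment recovers simulated ground truth", {
  refs <- make_synthetic_references(seed = 13, mutation_rate = 0)
  cfg <- sim_config(seed = 13, n_reads = 8000, mutation_rate = 0)
  lib <- simulate_library(cfg, refs)
  pp <- preprocess_reads(lib$reads, cfg$adaptor)
  expect_equal(pp$report$n_pass, cfg$n_reads)  # error-free library passes whole
  summ <- run_cascade(pp$reads, refs$ref_sets)
  m <- dplyr::inner_join(summ$assignments, lib$truth, by = "read_id")
  expected_cat <- c(miRNA = "miRNA", rRNA_frag = "rRNA", tRNA_frag = "tRNA",
                    alu_sirna_sense = "repeat",
                    alu_sirna_antisense = "repeat")
  core <- m[m$class != "random_background", ]
  expect_equal(mean(core$category == expected_cat[core$class]), 1)
  # strand of Alu hits matches the simulated strand
  alu <- m[m$class %in% c("alu_sirna_sense", "alu_sirna_antisense"), ]
  expect_true(all(alu$strand.x == alu$strand.y))
  # background lands in genome or unaligned
  bg <- m[m$class == "random_background", ]
  expect_gte(mean(bg$category %in% c("genome", "unaligned")), 0.99)

  # with mutated copies and <= 2 mismatches, recovery stays >= 99%
  refs2 <- make_synthetic_references(seed = 14, mutation_rate = 0.02)
  cfg2 <- sim_config(seed = 14, n_reads = 8000, mutation_rate = 0.02)
  lib2 <- simulate_library(cfg2, refs2)
  pp2 <- preprocess_reads(lib2$reads, cfg2$adaptor)
  summ2 <- run_cascade(pp2$reads, refs2$ref_sets)
  m2 <- dplyr::inner_join(summ2$assignments, lib2$truth, by = "read_id")
  core2 <- m2[m2$class != "random_background", ]
  expect_gte(mean(core2$category == expected_cat[core2$class]), 0.99)
})

test_that("alu_scale rescales only the Alu classes", {
  refs <- make_synthetic_references(seed = 15)
  cfg0 <- sim_config(seed = 15, n_reads = 30000,
                     class_mix = c(miRNA = 0.4, rRNA_frag = 0.2,
                                   tRNA_frag = 0.1, alu_sirna_sense = 0.05,
                                   alu_sirna_antisense = 0.05,
                                   random_background = 0.2))
  cfg5 <- sim_config(seed = 15, n_reads = 30000, alu_scale = 0.5,
                     class_mix = cfg0$class_mix)
  n_alu <- function(lib) sum(lib$class_counts[c("alu_sirna_sense",
                                                "alu_sirna_antisense")])
  a0 <- n_alu(simulate_library(cfg0, refs))
  a5 <- n_alu(simulate_library(cfg5, refs))
  # expected ratio ~ 0.5 / (1 - 0.05) after renormalization
  expect_lt(abs(a5 / a0 - 0.5 / 0.95), 0.07)
})
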