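# build a small annotated library over one Alu consensus and one tRNA
profiler_fixture <- function() {
  tr <- tiny_refs()
  alu <- tr$alu_seq
  reads <- tibble::tibble(
    read_id = c("s22", "as21", "long30", "trna21", "bg"),
    seq = c(substr(alu, 51, 72),              # 22-nt sense Alu siRNA
            revcomp(substr(alu, 11, 31)),     # 21-nt antisense Alu siRNA
            substr(alu, 1, 30),               # 30-nt Alu read (not an siRNA)
            substr(tr$trna_seq, 5, 25),       # tRNA fragment
            strrep("N", 21)),                 # unaligned
    mult = c(300L, 100L, 50L, 200L, 350L))
  list(summary = run_cascade(reads, list(tr$trna_set, tr$repeat_set)),
       consensus = list(id = "AluY_syn", seq = alu), tr = tr)
}

test_that("Alu siRNA selection applies category, subfamily and length gates", {
  fx <- profiler_fixture()
  sel <- select_alu_sirnas(fx$summary)
  expect_setequal(sel$read_id, c("s22", "as21"))
  expect_equal(sel$strand[sel$read_id == "s22"], "+")
  expect_equal(sel$strand[sel$read_id == "as21"], "-")
  # the 19-24 window is inclusive and configurable
  expect_true("long30" %in% select_alu_sirnas(fx$summary, hi = 30)$read_id)
})

test_that("length distribution obeys the CPM formula and scale invariance", {
  fx <- profiler_fixture()
  ld <- length_distribution(fx$summary)   # library total = 1000 reads
  expect_s3_class(ld, "length_distribution")
  expect_equal(attr(ld, "library_total"), 1000L)
  expect_equal(ld$cpm[ld$length == 22 & ld$strand == "+"], 300 / 1000 * 1e6)
  expect_equal(ld$cpm[ld$length == 21 & ld$strand == "-"], 100 / 1000 * 1e6)
  # the distribution spans the full 19-35 nt window, incl. the 30-mer
  expect_equal(sum(ld$count), 450)
  expect_equal(ld$count[ld$length == 30 & ld$strand == "+"], 50)

  # doubling every multiplicity leaves all CPM unchanged
  tr <- fx$tr
  reads2 <- fx$summary$assignments |>
    dplyr::mutate(mult = mult * 2L) |>
    dplyr::select(read_id, seq, mult)
  ld2 <- length_distribution(run_cascade(reads2,
                                         list(tr$trna_set, tr$repeat_set)))
  expect_equal(ld2$cpm, ld$cpm)

  expect_error(length_distribution(
    run_cascade(make_reads(character(0)), list(tr$repeat_set))), "zero")
  # aligned-denominator mode excludes unaligned reads
  ld3 <- length_distribution(fx$summary, denominator_mode = "aligned")
  expect_equal(attr(ld3, "library_total"), 650L)
})

test_that("consensus profiles histogram 5' starts per strand", {
  fx <- profiler_fixture()
  sel <- select_alu_sirnas(fx$summary)
  prof <- consensus_profile(sel, fx$consensus)
  expect_equal(prof$count[prof$pos == 50 & prof$strand == "+"], 300)
  expect_equal(prof$count[prof$pos == 10 & prof$strand == "-"], 100)
  # per-strand profile mass equals the profiled reads on that strand
  expect_equal(sum(prof$count[prof$strand == "+"]),
               sum(sel$mult[sel$strand == "+"]))
  expect_equal(sum(prof$count[prof$strand == "-"]),
               sum(sel$mult[sel$strand == "-"]))

  empty <- consensus_profile(sel[0, ], fx$consensus)
  expect_true(all(empty$count == 0))
  expect_equal(nrow(empty), 2L * nchar(fx$consensus$seq))

  bad <- sel
  bad$start <- nchar(fx$consensus$seq) - 1L
  bad$end <- bad$start + 22L
  expect_error(consensus_profile(bad, fx$consensus), "outside")
})

test_that("the exclusion-normalized count follows alu/(total - miRNA - alu) * 1e6", {
  # alu = 100, total = 1,000,100, miRNA = 900,000 -> denominator 100,000
  tr <- tiny_refs()
  mirna_set <- alusirna::reference_set(
    "miRNA", tibble::tibble(id = "mir1", seq = random_seq(22)))
  reads <- tibble::tibble(
    read_id = c("m", "a", "u"),
    seq = c(mirna_set$sequences$seq, substr(tr$alu_seq, 31, 51),
            strrep("N", 21)),
    mult = c(900000L, 100L, 100000L))
  summ <- run_cascade(reads, list(mirna_set, tr$repeat_set))
  expect_equal(normalized_alu_count(summ), 1000.0)

  per_len <- normalized_alu_count(summ, per_length = TRUE)
  expect_equal(per_len$normalized[per_len$length == 21], 1000.0)
  expect_equal(sum(per_len$normalized), 1000.0)  # same global denominator

  # zero Alu reads give zero; ratio is invariant to a global scale factor
  summ0 <- run_cascade(reads[c(1, 3), ], list(mirna_set, tr$repeat_set))
  expect_equal(normalized_alu_count(summ0), 0)
  reads3 <- dplyr::mutate(reads, mult = mult * 3L)
  summ3 <- run_cascade(reads3, list(mirna_set, tr$repeat_set))
  expect_equal(normalized_alu_count(summ3), normalized_alu_count(summ))

  # non-positive denominator is an error
  only <- run_cascade(reads[2, ], list(mirna_set, tr$repeat_set))
  expect_error(normalized_alu_count(only), "denominator")
})

test_that("differential profile is zero on identity and signed correctly", {
  fx <- profiler_fixture()
  d0 <- differential_profile(fx$summary, fx$summary)
  expect_true(all(d0$delta == 0))

  # control without Alu reads, treated with some: delta > 0
  tr <- fx$tr
  ctrl_reads <- tibble::tibble(read_id = c("t", "u"),
                               seq = c(substr(tr$trna_seq, 1, 21),
                                       strrep("N", 21)),
                               mult = c(200L, 800L))
  ctrl <- run_cascade(ctrl_reads, list(tr$trna_set, tr$repeat_set))
  d <- differential_profile(fx$summary, ctrl)
  expect_true(all(d$delta[d$norm_treated > 0] > 0))
  expect_true(all(d$delta[c(22, 21) - 18] != 0))
  comp <- attr(d, "components")
  expect_equal(comp$denominator,
               comp$total - comp$mirna_count - comp$alu_count)
  expect_equal(glance(d)$delta_total, sum(d$delta))
})

test_that("dicing products map at zero mismatches with per-strand coverage", {
  set.seed(17)
  hp <- make_synthetic_hairpin("hp", random_seq(120), random_seq(118),
                               loop_len = 60)
  ads <- dicing_adaptors()
  frag_fwd <- substr(hp$full_seq, 11, 32)             # + strand stem 22-mer
  frag_rev <- revcomp(substr(hp$full_seq, 41, 62))    # - strand stem 22-mer
  frag_mm <- frag_fwd
  substr(frag_mm, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                   substr(frag_mm, 5, 5))[1]
  raw <- make_reads(paste0(ads["adaptor5"],
                           c(frag_fwd, frag_rev, frag_mm),
                           ads["adaptor3"]))
  cov <- map_dicing_products(raw, hp)
  expect_equal(sum(cov$coverage[cov$strand == "+" & cov$pos %in% 10:31]), 22)
  expect_equal(sum(cov$coverage[cov$strand == "+"]), 22)
  expect_equal(sum(cov$coverage[cov$strand == "-" & cov$pos %in% 40:61]), 22)
  rep <- attr(cov, "report")
  expect_equal(rep$n_mapped, 2L)      # the 1-mismatch read stays unmapped
  expect_equal(rep$n_unmapped, 1L)
  expect_equal(rep$n_input, rep$n_untrimmed + rep$n_unmapped + rep$n_mapped)

  # a read lacking the 3' adaptor is counted as untrimmed
  cov2 <- map_dicing_products(make_reads(frag_fwd), hp)
  expect_equal(attr(cov2, "report")$n_untrimmed, 1L)
})
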