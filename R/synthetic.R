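sim_classes <- function() {
  c("miRNA", "rRNA_frag", "tRNA_frag", "alu_sirna_sense",
    "alu_sirna_antisense", "random_background")
}

random_dna <- function(n, len) {
  stringi::stri_rand_strings(n, len, "[ACGT]")
}

# per-base substitution at the given rate (to one of the other 3 bases)
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

all_kmers <- function(seqs, k) {
  unlist(lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  }))
}

# draw a random sequence sharing no k-mer (either strand) with `forbidden`
rejection_dna <- function(len, forbidden, k = 19L, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(1, len)
    if (len < k || !any(all_kmers(s, k) %in% forbidden)) return(s)
  }
  abort("could not sample a sequence avoiding shared k-mers")
}

#' Default simulated insert-length distribution
#'
#' Weights over 19-35 nt with a major mode at 21-24 nt and a small
#' secondary bump at 30-32 nt, mimicking the length profile of a total
#' small-RNA library dominated by miRNA-sized species.
#'
#' @return Named numeric vector over `"19"`..`"35"` summing to 1.
#' @export
default_read_len_dist <- function() {
  w <- c(`19` = 3, `20` = 5, `21` = 14, `22` = 16, `23` = 13, `24` = 10,
         `25` = 6, `26` = 4, `27` = 3, `28` = 2, `29` = 2, `30` = 3,
         `31` = 3, `32` = 3, `33` = 1.5, `34` = 1, `35` = 0.5)
  w / sum(w)
}

#' Simulation configuration for a synthetic small-RNA library
#'
#' The defaults emulate a total small-RNA library from a somatic cell
#' line: miRNAs dominate, rRNA/tRNA fragments make up most of the rest,
#' and Alu endo-siRNAs (sense plus antisense) amount to 0.3% of the
#' miRNA reads. `alu_scale` multiplies both Alu class probabilities and
#' renormalizes, emulating depletion of the dsRNA-processing machinery
#' (e.g. `alu_scale = 0.5` halves Alu siRNA output).
#'
#' @param seed Integer RNG seed; a fixed seed gives byte-identical
#'   libraries.
#' @param n_reads Number of reads to simulate.
#' @param class_mix Named proportions over the six read classes
#'   (`miRNA`, `rRNA_frag`, `tRNA_frag`, `alu_sirna_sense`,
#'   `alu_sirna_antisense`, `random_background`); must sum to 1.
#' @param alu_scale Multiplier on the two Alu class probabilities.
#' @param read_len_dist Named weights over insert lengths 19-35
#'   (default [default_read_len_dist()]).
#' @param adaptor 3' adaptor appended to every insert.
#' @param mutation_rate Per-base substitution rate applied to the Alu
#'   copies (hairpin arms) reads derive from.
#' @param machine_len Fixed sequencer read length; insert plus adaptor
#'   is truncated to this many bases.
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       n_reads = 1e5L,
                       class_mix = c(miRNA = 0.60, rRNA_frag = 0.18,
                                     tRNA_frag = 0.10,
                                     alu_sirna_sense = 0.0009,
                                     alu_sirna_antisense = 0.0009,
                                     random_background = 0.1182),
                       alu_scale = 1,
                       read_len_dist = default_read_len_dist(),
                       adaptor = adaptor_truseq_small_rna(),
                       mutation_rate = 0.01,
                       machine_len = 50L) {
  stopifnot(setequal(names(class_mix), sim_classes()),
            all(class_mix >= 0),
            abs(sum(class_mix) - 1) < 1e-9,
            alu_scale >= 0,
            all(names(read_len_dist) %in% as.character(19:35)),
            all(read_len_dist >= 0), sum(read_len_dist) > 0)
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 class_mix = class_mix[sim_classes()],
                 alu_scale = alu_scale,
                 read_len_dist = read_len_dist / sum(read_len_dist),
                 adaptor = fold_to_dna(adaptor, "adaptor"),
                 mutation_rate = mutation_rate,
                 machine_len = as.integer(machine_len)),
            class = "sim_config")
}

#' Build a synthetic inverted-repeat hairpin from Alu-like consensi
#'
#' Left arm: a (mutated) copy of `left_consensus`; right arm: the
#' reverse complement of a (mutated) copy of `right_consensus`; a random
#' connecting loop in between. The default loop length matches the long
#' intronic inverted-Alu configuration (533 nt); arms are ~300 nt like a
#' full-length Alu.
#'
#' @param name Hairpin name.
#' @param left_consensus,right_consensus Consensus sequences the arms
#'   derive from (right defaults to left).
#' @param loop_len Loop length in nt.
#' @param mutation_rate Per-base substitution rate applied to each arm.
#' @param seed Optional RNG seed.
#' @return A [hairpin_locus()].
#' @export
make_synthetic_hairpin <- function(name, left_consensus,
                                   right_consensus = left_consensus,
                                   loop_len = 533L, mutation_rate = 0,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  left <- mutate_seq(fold_to_dna(left_consensus), mutation_rate)
  right <- revcomp(mutate_seq(fold_to_dna(right_consensus), mutation_rate))
  loop <- random_dna(1, loop_len)
  ll <- nchar(left); lo <- nchar(loop); lr <- nchar(right)
  hairpin_locus(name, paste0(left, loop, right),
                left_arm = c(0L, ll), loop = c(ll, ll + lo),
                right_arm = c(ll + lo, ll + lo + lr))
}

#' Generate synthetic references, annotations, genes and hairpins
#'
#' Builds a self-consistent desk-scale universe with known ground truth:
#' Alu-like ~300 nt consensus sequences; a genome with embedded, mutated,
#' annotated Alu copies; gene models whose 3'UTRs carry 0, 1 sense, 1
#' antisense, or an inverted pair of Alu copies; disjoint rRNA / tRNA /
#' miRNA / snoRNA / transcript sets (rejection-sampled to share no
#' 19-mer with the Alu consensi on either strand); and inverted-repeat
#' hairpins whose arms derive from the consensi. With
#' `cross_contaminate = TRUE` a 21-mer from the first rRNA sequence is
#' planted into the first Alu consensus, so reads of that 21-mer test
#' the cascade's category precedence.
#'
#' @param seed Integer RNG seed.
#' @param n_subfamilies Number of Alu-like subfamily consensi.
#' @param alu_len Consensus length (nt).
#' @param genes_none,genes_sense,genes_antisense,genes_inverted Gene
#'   counts per 3'UTR Alu configuration.
#' @param mutation_rate Per-base substitution rate applied to every
#'   embedded Alu copy and hairpin arm.
#' @param n_mirna,n_trna,n_snorna Sizes of the corresponding sets.
#' @param loop_len Hairpin loop length (nt).
#' @param low_expr_genes How many single-Alu genes get expression drawn
#'   below the 4.5 screening threshold (default 0: all candidates pass).
#' @param cross_contaminate Plant a shared rRNA/Alu 21-mer?
#' @return A list: `ref_sets` (ordered `reference_set` list for
#'   [run_cascade()]), `consensi`, `repeats`, `genes`, `gene_truth`
#'   (gene_id, config, candidate flags), `genome`, `hairpins`, and
#'   `planted_kmer` (or `NA`).
#' @export
make_synthetic_references <- function(seed = 1L,
                                      n_subfamilies = 3L,
                                      alu_len = 300L,
                                      genes_none = 1L,
                                      genes_sense = 3L,
                                      genes_antisense = 4L,
                                      genes_inverted = 2L,
                                      mutation_rate = 0.01,
                                      n_mirna = 50L,
                                      n_trna = 10L,
                                      n_snorna = 8L,
                                      loop_len = 533L,
                                      low_expr_genes = 0L,
                                      cross_contaminate = FALSE) {
  set.seed(sub_seed(seed, 11L))
  stopifnot(alu_len >= 50, n_subfamilies >= 1)

  sub_names <- paste0("Alu", c("Ya", "Szb", "Jc", "Yd", "Se")[
    seq_len(min(n_subfamilies, 5L))], "_syn")
  if (n_subfamilies > 5) {
    sub_names <- c(sub_names, sprintf("AluX%d_syn", seq_len(n_subfamilies - 5L)))
  }
  consensi <- tibble(id = sub_names, seq = random_dna(n_subfamilies, alu_len))

  # other reference categories must not share Alu 19-mers (either strand)
  rrna_seqs <- c(random_dna(1, 1000L), random_dna(1, 1500L))
  if (cross_contaminate) {
    kmer <- substr(rrna_seqs[1], 101, 121)
    substr(consensi$seq[1], 51, 71) <- kmer
  } else {
    kmer <- NA_character_
  }
  forbidden <- all_kmers(c(consensi$seq, revcomp(consensi$seq)), 19L)
  rrna_seqs <- vapply(rrna_seqs, function(s) {
    if (any(all_kmers(s, 19L) %in% forbidden) && !cross_contaminate)
      rejection_dna(nchar(s), forbidden) else s
  }, character(1), USE.NAMES = FALSE)
  trna_seqs <- vapply(sample(72:90, n_trna, replace = TRUE),
                      rejection_dna, character(1), forbidden = forbidden)
  mirna_seqs <- vapply(sample(21:22, n_mirna, replace = TRUE),
                       rejection_dna, character(1), forbidden = forbidden)
  snorna_seqs <- vapply(sample(80:150, n_snorna, replace = TRUE),
                        rejection_dna, character(1), forbidden = forbidden)

  # gene loci with 3'UTR Alu configurations, embedded in one genome
  configs <- c(rep("none", genes_none), rep("sense", genes_sense),
               rep("antisense", genes_antisense),
               rep("inverted", genes_inverted))
  n_genes <- length(configs)
  configs <- sample(configs)   # shuffle order along the genome
  gene_ids <- sprintf("GSYN%03d", seq_len(n_genes))
  strands <- rep(c("+", "-"), length.out = n_genes)

  single_idx <- which(configs %in% c("sense", "antisense"))
  expr <- round(stats::runif(n_genes, 4.6, 5.4), 2)
  if (low_expr_genes > 0) {
    low <- utils::head(single_idx, low_expr_genes)
    expr[low] <- round(stats::runif(length(low), 3.8, 4.4), 2)
  }

  genome_parts <- character(0)
  offset <- 0L
  add_part <- function(s) {
    genome_parts[[length(genome_parts) + 1L]] <<- s
    offset <<- offset + nchar(s)
  }
  genes <- list(); repeats <- list(); transcripts <- character(n_genes)
  cds_len <- 200L
  for (i in seq_len(n_genes)) {
    add_part(random_dna(1, 150L))  # intergenic spacer
    cfg <- configs[i]
    copies <- list()  # list of (offset in mRNA-sense UTR, orientation, subfam, seq)
    if (cfg == "none") {
      utr <- random_dna(1, 400L)
    } else if (cfg %in% c("sense", "antisense")) {
      sub_i <- sample(n_subfamilies, 1)
      cp <- mutate_seq(consensi$seq[sub_i], mutation_rate)
      pad <- random_dna(2, c(150L, 250L))
      emb <- if (cfg == "sense") cp else revcomp(cp)
      utr <- paste0(pad[1], emb, pad[2])
      copies[[1]] <- list(off = 150L, orient = cfg, sub = consensi$id[sub_i],
                          len = alu_len)
    } else {  # inverted pair: one sense + one antisense copy
      sub_i <- sample(n_subfamilies, 2, replace = TRUE)
      cp1 <- mutate_seq(consensi$seq[sub_i[1]], mutation_rate)
      cp2 <- mutate_seq(consensi$seq[sub_i[2]], mutation_rate)
      pad <- random_dna(3, c(100L, 120L, 150L))
      utr <- paste0(pad[1], cp1, pad[2], revcomp(cp2), pad[3])
      copies[[1]] <- list(off = 100L, orient = "sense",
                          sub = consensi$id[sub_i[1]], len = alu_len)
      copies[[2]] <- list(off = 100L + alu_len + 120L, orient = "antisense",
                          sub = consensi$id[sub_i[2]], len = alu_len)
    }
    utr_len <- nchar(utr)
    cds <- random_dna(1, cds_len)
    if (strands[i] == "+") {
      gene_start <- offset
      add_part(paste0(cds, utr))
      utr_g <- c(gene_start + cds_len, gene_start + cds_len + utr_len)
    } else {
      gene_start <- offset
      add_part(revcomp(paste0(cds, utr)))
      utr_g <- c(gene_start, gene_start + utr_len)
    }
    transcripts[i] <- paste0(cds, utr)
    genes[[i]] <- tibble(gene_id = gene_ids[i], chrom = "chrS",
                         strand = strands[i],
                         utr3_start = utr_g[1], utr3_end = utr_g[2],
                         expression = expr[i], utr3_seq = utr)
    for (cp in copies) {
      if (strands[i] == "+") {
        g_start <- utr_g[1] + cp$off
        g_strand <- if (cp$orient == "sense") "+" else "-"
      } else {
        g_start <- utr_g[1] + (utr_len - cp$off - cp$len)
        g_strand <- if (cp$orient == "sense") "-" else "+"
      }
      repeats[[length(repeats) + 1L]] <-
        tibble(chrom = "chrS", start = g_start, end = g_start + cp$len,
               strand = g_strand, subfamily = cp$sub, family = "Alu")
    }
  }
  # two intergenic Alu copies outside any UTR
  for (j in 1:2) {
    add_part(random_dna(1, 100L))
    sub_i <- sample(n_subfamilies, 1)
    cp <- mutate_seq(consensi$seq[sub_i], mutation_rate)
    st <- sample(c("+", "-"), 1)
    g_start <- offset
    add_part(if (st == "+") cp else revcomp(cp))
    repeats[[length(repeats) + 1L]] <-
      tibble(chrom = "chrS", start = g_start, end = g_start + alu_len,
             strand = st, subfamily = consensi$id[sub_i], family = "Alu")
  }
  add_part(random_dna(1, 150L))
  genome <- tibble(id = "chrS", seq = paste(genome_parts, collapse = ""))

  # arms pair distinct subfamilies (as in the long intronic inverted-Alu
  # case) so +/- placements on a hairpin are unambiguous when
  # n_subfamilies > 1
  hairpins <- lapply(seq_len(n_subfamilies), function(s) {
    make_synthetic_hairpin(paste0("hp_", consensi$id[s]), consensi$seq[s],
                           consensi$seq[(s %% n_subfamilies) + 1L],
                           loop_len = loop_len,
                           mutation_rate = mutation_rate)
  })
  names(hairpins) <- consensi$id

  genes <- bind_rows(genes)
  gene_truth <- tibble(gene_id = gene_ids, config = configs,
                       expression = expr,
                       candidate_antisense = configs == "antisense" & expr > 4.5,
                       candidate_sense = configs == "sense" & expr > 4.5)
  ref_sets <- list(
    reference_set("rRNA", tibble(id = paste0("rRNA_", 1:2), seq = rrna_seqs)),
    reference_set("tRNA", tibble(id = sprintf("tRNA_%02d", seq_len(n_trna)),
                                 seq = trna_seqs)),
    reference_set("miRNA", tibble(id = sprintf("miR_syn_%03d", seq_len(n_mirna)),
                                  seq = mirna_seqs)),
    reference_set("repeat", consensi,
                  subfamily_of = stats::setNames(consensi$id, consensi$id)),
    reference_set("snoRNA", tibble(id = sprintf("snoRNA_%02d", seq_len(n_snorna)),
                                   seq = snorna_seqs)),
    reference_set("transcript", tibble(id = paste0(gene_ids, "_mRNA"),
                                       seq = transcripts)),
    reference_set("genome", genome))
  list(ref_sets = ref_sets, consensi = consensi,
       repeats = bind_rows(repeats), genes = genes,
       gene_truth = gene_truth, genome = genome, hairpins = hairpins,
       planted_kmer = kmer)
}

#' Simulate independent DICER cleavage products from a hairpin stem
#'
#' Fragments of 21-24 nt (by default) with 5' starts uniform within the
#' arms, each fragment fully inside its arm so the loop is never
#' covered. Fragments are sampled independently (no processive phasing):
#' a `+` fragment is an arm substring, a `-` fragment the reverse
#' complement of one. Every fragment maps back to the hairpin with zero
#' mismatches.
#'
#' @param hairpin A [hairpin_locus()]; both arms must be at least as
#'   long as the longest fragment.
#' @param n Number of fragments.
#' @param seed Optional RNG seed.
#' @param lengths Fragment lengths sampled uniformly (default 21:24).
#' @param strand_prob Probability of the `+` strand (default 0.5).
#' @param arms Sample from `"both"` arms (default), `"left"` only, or
#'   `"right"` only.
#' @return Tibble: `seq`, `strand`, `start` (0-based on the hairpin),
#'   `length`, `arm`.
#' @export
simulate_dicer_products <- function(hairpin, n, seed = NULL,
                                    lengths = 21:24, strand_prob = 0.5,
                                    arms = c("both", "left", "right")) {
  stopifnot(inherits(hairpin, "hairpin_locus"), n >= 0)
  arms <- match.arg(arms)
  if (!is.null(seed)) set.seed(seed)
  arm_iv <- list(left = hairpin$left_arm, right = hairpin$right_arm)
  use <- switch(arms, both = c("left", "right"), left = "left",
                right = "right")
  min_arm <- min(vapply(arm_iv[use], diff, integer(1)))
  if (min_arm < max(lengths)) abort("hairpin arm shorter than fragment length")
  if (n == 0) {
    return(tibble(seq = character(0), strand = character(0),
                  start = integer(0), length = integer(0),
                  arm = character(0)))
  }
  arm <- use[sample.int(length(use), n, replace = TRUE)]
  len <- lengths[sample.int(length(lengths), n, replace = TRUE)]
  lo <- vapply(arm_iv[arm], `[`, integer(1), 1L)
  hi <- vapply(arm_iv[arm], `[`, integer(1), 2L)
  start <- lo + floor(stats::runif(n) * (hi - lo - len + 1L))
  strand <- ifelse(stats::runif(n) < strand_prob, "+", "-")
  sub <- substring(hairpin$full_seq, start + 1L, start + len)
  seq <- ifelse(strand == "+", sub, revcomp(sub))
  tibble(seq = seq, strand = strand, start = as.integer(start),
         length = as.integer(len), arm = arm)
}

#' Simulate a raw small-RNA library with per-read ground truth
#'
#' Draws each read's class from the (alu-scaled, renormalized) class
#' mix, then its insert: miRNA reads are exact mature sequences;
#' rRNA/tRNA fragments are random substrings (19-35 nt); Alu siRNA reads
#' are DICER-style fragments of hairpin arms derived from the repeat
#' consensi (sense = consensus-strand substrings, antisense = their
#' reverse complements); background reads are i.i.d. uniform. The full
#' 3' adaptor is appended and the read truncated to the machine length.
#' Per-class RNG substreams are derived from the seed, so changing one
#' class's parameters does not perturb the other classes' draws.
#'
#' @param config A [sim_config()].
#' @param refs Output of [make_synthetic_references()] (uses `ref_sets`
#'   and `consensi`).
#' @param hairpins Optional named list of [hairpin_locus()] objects, one
#'   per consensus, to draw Alu fragments from; by default fresh
#'   sense-arm hairpins are built from the consensi at the config's
#'   mutation rate.
#' @return List: `reads` (raw read tibble with adaptor appended),
#'   `truth` (tibble `read_id`, `class`, `source`, `strand`, `length`),
#'   and `class_counts`.
#' @export
simulate_library <- function(config, refs, hairpins = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mix <- config$class_mix
  mix[c("alu_sirna_sense", "alu_sirna_antisense")] <-
    mix[c("alu_sirna_sense", "alu_sirna_antisense")] * config$alu_scale
  mix <- mix / sum(mix)
  n <- config$n_reads
  set.seed(sub_seed(config$seed, 0L))
  cls <- sample(sim_classes(), n, replace = TRUE, prob = mix)

  lens <- as.integer(names(config$read_len_dist))
  get_set <- function(category) {
    i <- which(vapply(refs$ref_sets, function(r) r$category, character(1)) ==
                 category)
    refs$ref_sets[[i]]$sequences
  }
  if (is.null(hairpins)) {
    set.seed(sub_seed(config$seed, 9L))
    hairpins <- lapply(seq_len(nrow(refs$consensi)), function(s) {
      make_synthetic_hairpin(paste0("lib_hp_", refs$consensi$id[s]),
                             refs$consensi$seq[s], loop_len = 150L,
                             mutation_rate = config$mutation_rate)
    })
    names(hairpins) <- refs$consensi$id
  }

  insert <- character(n)
  source <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)

  draw_frag <- function(idx, seqs_tbl) {
    set_n <- length(idx)
    ref_i <- sample.int(nrow(seqs_tbl), set_n, replace = TRUE)
    ref_len <- nchar(seqs_tbl$seq[ref_i])
    len <- pmin(sample(lens, set_n, replace = TRUE,
                       prob = config$read_len_dist), ref_len)
    start <- floor(stats::runif(set_n) * (ref_len - len + 1))
    list(seq = substring(seqs_tbl$seq[ref_i], start + 1, start + len),
         source = seqs_tbl$id[ref_i])
  }
  draw_alu <- function(idx, want_strand) {
    set_n <- length(idx)
    hp_i <- sample.int(length(hairpins), set_n, replace = TRUE)
    out_seq <- character(set_n); out_src <- character(set_n)
    for (h in unique(hp_i)) {
      sel <- which(hp_i == h)
      fr <- simulate_dicer_products(hairpins[[h]], length(sel),
                                    strand_prob = if (want_strand == "+") 1 else 0,
                                    arms = "left")
      out_seq[sel] <- fr$seq
      out_src[sel] <- names(hairpins)[h]
    }
    list(seq = out_seq, source = out_src)
  }

  for (k in seq_along(sim_classes())) {
    class_k <- sim_classes()[k]
    idx <- which(cls == class_k)
    if (length(idx) == 0) next
    set.seed(sub_seed(config$seed, k))
    if (class_k == "miRNA") {
      tbl <- get_set("miRNA")
      i <- sample.int(nrow(tbl), length(idx), replace = TRUE)
      insert[idx] <- tbl$seq[i]; source[idx] <- tbl$id[i]
      strand[idx] <- "+"
    } else if (class_k == "rRNA_frag") {
      d <- draw_frag(idx, get_set("rRNA"))
      insert[idx] <- d$seq; source[idx] <- d$source; strand[idx] <- "+"
    } else if (class_k == "tRNA_frag") {
      d <- draw_frag(idx, get_set("tRNA"))
      insert[idx] <- d$seq; source[idx] <- d$source; strand[idx] <- "+"
    } else if (class_k == "alu_sirna_sense") {
      d <- draw_alu(idx, "+")
      insert[idx] <- d$seq; source[idx] <- d$source; strand[idx] <- "+"
    } else if (class_k == "alu_sirna_antisense") {
      d <- draw_alu(idx, "-")
      insert[idx] <- d$seq; source[idx] <- d$source; strand[idx] <- "-"
    } else {
      len <- sample(lens, length(idx), replace = TRUE,
                    prob = config$read_len_dist)
      insert[idx] <- random_dna(length(idx), len)
    }
  }
  raw <- substr(paste0(insert, config$adaptor), 1L, config$machine_len)
  reads <- tibble(read_id = sprintf("r%07d", seq_len(n)), seq = raw,
                  mult = 1L)
  truth <- tibble(read_id = reads$read_id, class = cls, source = source,
                  strand = strand, length = nchar(insert))
  list(reads = reads, truth = truth,
       class_counts = table(factor(cls, levels = sim_classes())))
}
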