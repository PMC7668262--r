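#' Read a FASTA file into a sequence tibble
#'
#' Records are returned in file order, upper-cased, with `U` folded to `T`
#' so RNA references (rRNA, miRNA) and DNA references share one alphabet.
#' Identifiers are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- stringi::stri_extract_first_regex(names(ss), "^\\S+")
  seqs <- as.character(ss)
  if (any(is.na(ids)) || any(ids == "")) abort("FASTA record with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate FASTA id: %s", dup[1]))
  }
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) {
    abort(sprintf("empty FASTA record: %s", ids[empty[1]]))
  }
  tibble(id = unname(ids), seq = fold_to_dna(unname(seqs), "FASTA sequence"))
}

#' Write a sequence tibble as FASTA
#'
#' @param x Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::BStringSet(stats::setNames(x$seq, x$id))
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' FASTQ qualities are ignored. Each read gets multiplicity 1; use
#' [collapse_reads()] to collapse identical sequences.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param format `"auto"` (by extension/first byte), `"fasta"` or `"fastq"`.
#' @return A read tibble with columns `read_id`, `seq`, `mult`.
#' @export
read_small_rna <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) {
      format <- "fastq"
    } else if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
      format <- "fasta"
    } else {
      first <- substr(readLines(path, n = 1L), 1, 1)
      format <- if (identical(first, "@")) "fastq" else "fasta"
    }
  }
  if (format == "fasta") {
    x <- read_fasta(path)
    return(tibble(read_id = x$id, seq = x$seq, mult = 1L))
  }
  ss <- Biostrings::readBStringSet(path, format = "fastq")
  ids <- stringi::stri_extract_first_regex(names(ss), "^\\S+")
  tibble(read_id = unname(ids),
         seq = fold_to_dna(unname(as.character(ss)), "FASTQ sequence"),
         mult = 1L)
}

#' Write reads as FASTQ with constant placeholder qualities
#'
#' @param reads Read tibble (`read_id`, `seq`, `mult`); each row is written
#'   once regardless of multiplicity.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_reads(reads)
  qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Collapse identical read sequences, summing multiplicities
#'
#' Downstream counts are multiplicity-weighted, so collapsed and
#' uncollapsed libraries give identical results.
#'
#' @param reads Read tibble.
#' @return Read tibble with one row per distinct sequence (first id kept).
#' @export
collapse_reads <- function(reads) {
  check_reads(reads)
  reads |>
    group_by(.data$seq) |>
    summarise(read_id = .data$read_id[1], mult = sum(.data$mult),
              .groups = "drop") |>
    select("read_id", "seq", "mult") |>
    arrange(match(.data$read_id, reads$read_id))
}

#' The ordered annotation categories of the cascade
#'
#' Reads are assigned to the first category whose reference set they align
#' to: rRNA, tRNA, miRNA, repeat consensus, snoRNA, transcript, genome.
#'
#' @return Character vector of the seven category names, in cascade order.
#' @export
cascade_categories <- function() {
  c("rRNA", "tRNA", "miRNA", "repeat", "snoRNA", "transcript", "genome")
}

#' Build a reference set for one cascade category
#'
#' @param category One of [cascade_categories()].
#' @param sequences Tibble with `id`, `seq` (as from [read_fasta()]).
#' @param subfamily_of Optional named character vector mapping reference ids
#'   to repeat subfamily names (repeat category only); ids absent from the
#'   map default to their own id.
#' @return A `reference_set` object.
#' @export
reference_set <- function(category, sequences, subfamily_of = NULL) {
  if (!category %in% cascade_categories()) {
    abort(sprintf("unknown category: %s", category))
  }
  stopifnot(is.data.frame(sequences), all(c("id", "seq") %in% names(sequences)))
  if (anyDuplicated(sequences$id)) abort("duplicate reference id")
  if (!is.null(subfamily_of)) {
    if (category != "repeat") abort("subfamily_of only applies to the repeat set")
    if (!all(names(subfamily_of) %in% sequences$id)) {
      abort("subfamily_of names must be reference ids")
    }
  }
  structure(list(category = category,
                 sequences = as_tibble(sequences[c("id", "seq")]),
                 subfamily_of = subfamily_of),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %s: %d sequence(s), total %d nt\n",
              x$category, nrow(x$sequences), sum(nchar(x$sequences$seq))))
  invisible(x)
}

#' Read repeat annotations (rmsk-style TSV or BED6)
#'
#' Both dialects are 0-based half-open. The rmsk dialect consumes only the
#' columns `genoName`, `genoStart`, `genoEnd`, `strand`, `repName` and,
#' when present, `repFamily`; all others are ignored. In BED6 the `name`
#' column carries the subfamily. When no family column is available the
#' family is derived from the subfamily prefix (`AluJb` -> `Alu`).
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed6"` or `"rmsk_tsv"`.
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `subfamily`,
#'   `family`.
#' @export
read_repeat_annotations <- function(path, dialect = c("bed6", "rmsk_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "bed6") {
    df <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                              "name", "score", "strand"),
                          col_types = "ciicic", progress = FALSE)
    out <- tibble(chrom = df$chrom, start = df$start, end = df$end,
                  strand = df$strand, subfamily = df$name,
                  family = derive_family(df$name))
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    need <- c("genoName", "genoStart", "genoEnd", "strand", "repName")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0) {
      abort(sprintf("rmsk table missing column(s): %s",
                    paste(miss, collapse = ", ")))
    }
    start <- suppressWarnings(as.integer(df$genoStart))
    end <- suppressWarnings(as.integer(df$genoEnd))
    if (anyNA(start) || anyNA(end)) abort("malformed rmsk coordinates")
    fam <- if ("repFamily" %in% names(df)) df$repFamily else
      derive_family(df$repName)
    out <- tibble(chrom = df$genoName, start = start, end = end,
                  strand = df$strand, subfamily = df$repName, family = fam)
  }
  validate_repeat_annotations(out)
}

derive_family <- function(subfamily) {
  ifelse(stringi::stri_startswith_fixed(subfamily, "Alu"), "Alu", subfamily)
}

validate_repeat_annotations <- function(x) {
  if (nrow(x) == 0) return(x)
  bad <- which(!(x$start < x$end) | x$start < 0)
  if (length(bad) > 0) {
    abort(sprintf("repeat annotation row %d: start must be < end and >= 0",
                  bad[1]))
  }
  if (!all(x$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  x
}

#' Write repeat annotations as BED6
#'
#' @param x Repeat annotation tibble (see [read_repeat_annotations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_annotations <- function(x, path) {
  readr::write_tsv(tibble(chrom = x$chrom, start = x$start, end = x$end,
                          name = x$subfamily, score = 0L, strand = x$strand),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models with single-interval 3'UTRs
#'
#' Flat TSV with header `gene_id`, `chrom`, `strand`, `utr3_start`,
#' `utr3_end`, `expression` and optional `utr3_seq` (mRNA-sense
#' orientation). Coordinates are 0-based half-open; `expression` is on a
#' log10 scale. Multi-exon 3'UTRs are out of scope by design.
#'
#' @param path Path to the TSV file.
#' @return Gene model tibble.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("gene_id", "chrom", "strand", "utr3_start", "utr3_end",
            "expression")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("gene model table missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  utr3_start <- suppressWarnings(as.integer(df$utr3_start))
  utr3_end <- suppressWarnings(as.integer(df$utr3_end))
  expression <- suppressWarnings(as.numeric(df$expression))
  if (anyNA(utr3_start) || anyNA(utr3_end) || anyNA(expression)) {
    abort("malformed numeric field in gene model table")
  }
  out <- tibble(gene_id = df$gene_id, chrom = df$chrom, strand = df$strand,
                utr3_start = utr3_start, utr3_end = utr3_end,
                expression = expression,
                utr3_seq = if ("utr3_seq" %in% names(df))
                  fold_to_dna(df$utr3_seq, "utr3_seq") else NA_character_)
  validate_gene_models(out)
}

validate_gene_models <- function(x) {
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup) > 0) abort(sprintf("duplicate gene_id: %s", dup[1]))
  if (!all(x$strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
  bad <- which(!(x$utr3_start < x$utr3_end))
  if (length(bad) > 0) {
    abort(sprintf("gene %s: utr3_start must be < utr3_end", x$gene_id[bad[1]]))
  }
  with_seq <- which(!is.na(x$utr3_seq))
  lens_ok <- nchar(x$utr3_seq[with_seq]) ==
    (x$utr3_end - x$utr3_start)[with_seq]
  if (!all(lens_ok)) {
    abort(sprintf("gene %s: utr3_seq length does not match interval",
                  x$gene_id[with_seq[which(!lens_ok)[1]]]))
  }
  x
}

#' Write gene models as TSV
#'
#' @param x Gene model tibble (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Define a hairpin locus (inverted-repeat stem plus connecting loop)
#'
#' The three intervals are 0-based half-open on `full_seq`, contiguous,
#' in order left arm, loop, right arm, and must cover the sequence. In an
#' inverted-Alu hairpin the left arm is a sense Alu copy and the right arm
#' the reverse complement of another.
#'
#' @param name Locus name.
#' @param full_seq The full hairpin sequence (folded to DNA alphabet).
#' @param left_arm,loop,right_arm Length-2 integer vectors `c(start, end)`.
#' @return A `hairpin_locus` object.
#' @export
hairpin_locus <- function(name, full_seq, left_arm, loop, right_arm) {
  full_seq <- fold_to_dna(full_seq, "hairpin sequence")
  iv <- rbind(left_arm, loop, right_arm)
  if (!(iv[1, 1] == 0 && iv[1, 2] == iv[2, 1] && iv[2, 2] == iv[3, 1] &&
        iv[3, 2] == nchar(full_seq) && all(iv[, 1] < iv[, 2]))) {
    abort("left_arm, loop, right_arm must be contiguous, ordered and cover full_seq")
  }
  structure(list(name = name, full_seq = full_seq,
                 left_arm = as.integer(left_arm), loop = as.integer(loop),
                 right_arm = as.integer(right_arm)),
            class = "hairpin_locus")
}

#' @export
print.hairpin_locus <- function(x, ...) {
  cat(sprintf("<hairpin_locus> %s: arms %d/%d nt, loop %d nt\n", x$name,
              diff(x$left_arm), diff(x$right_arm), diff(x$loop)))
  invisible(x)
}

#' Write a named list of result tables as deterministic TSVs
#'
#' Each data-frame element is written as `<name>.tsv` under `out_dir`.
#' Output is byte-identical across runs on identical inputs; an empty
#' table yields a headers-only file.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_tables <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)),
            all(names(results) != ""))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (!is.data.frame(x)) abort(sprintf("result '%s' is not a data frame", nm))
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(x), p, progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
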