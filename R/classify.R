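#' Build a species-tagged k-mer index
#'
#' Indexes every canonical (strand-collapsed) k-mer of every transcript of
#' both species, mapping it to its (species, transcript, offset)
#' occurrences. The default `k = 15` guarantees, by pigeonhole, that a
#' 50-nt read with at most 2 substitutions relative to its source
#' transcript always retains at least one exact seed, so seeding cannot
#' miss the source.
#'
#' @param ref a `dual_reference`.
#' @param k k-mer size; `11 <= k <= 31` and `k` must not exceed the read
#'   length you intend to classify.
#' @return a `kmer_index` object.
#' @export
kmer_index <- function(ref, k = 15) {
  if (k < 11 || k > 31) abort("k must lie in [11, 31].")
  tr <- ref$transcripts
  if (anyDuplicated(tr$transcript_id)) abort("duplicate transcript ids.")
  genes <- unique(tr$gene_id)
  ptr <- .xs_index_build(tr$sequence, tr$transcript_id,
                         as.integer(tr$species == "B"), genes,
                         match(tr$gene_id, genes) - 1L, as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), transcripts = tr),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d transcripts, %.0f indexed positions\n",
              x$k, nrow(x$transcripts), .xs_index_size(x$ptr)))
  invisible(x)
}

#' Number of indexed k-mer positions
#' @param index a `kmer_index`.
#' @return total indexed positions (`sum(length - k + 1)` over transcripts).
#' @export
kmer_index_size <- function(index) .xs_index_size(index$ptr)

#' Look up one k-mer in the index
#'
#' Strand-collapsed: the query and its reverse complement hit the same
#' entries. An absent k-mer returns an empty tibble.
#'
#' @param index a `kmer_index`.
#' @param kmer a string of length `k`.
#' @return tibble: `species`, `transcript_id`, `position` (0-based),
#'   `canonical_is_forward`.
#' @export
kmer_lookup <- function(index, kmer) {
  as_tibble(.xs_index_lookup(index$ptr, kmer))
}

#' Per-species mappability of reads
#'
#' A read is mappable to a species when some transcript of that species
#' admits a gapless alignment, within `band` diagonals of a k-mer seed,
#' with identity `>= min_identity` over a window of at least
#' `min_read_coverage` of the read length. The classifier is
#' strand-agnostic.
#'
#' @param reads character vector of read sequences, or a tibble with a
#'   `sequence` column.
#' @param index a [kmer_index()].
#' @param min_identity minimum fractional identity over the aligned window.
#' @param min_read_coverage minimum aligned fraction of the read.
#' @param band half-width of the verification band around the seed diagonal.
#' @return tibble: `mappable_a`, `mappable_b`, `identity_a`, `identity_b`
#'   (best qualifying window identity, `NA` when not mappable),
#'   `best_transcript`.
#' @export
read_mappability <- function(reads, index, min_identity = 0.95,
                             min_read_coverage = 0.90, band = 3) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  check_criterion(min_identity, min_read_coverage)
  res <- .xs_classify(index$ptr, seqs, NULL, min_identity,
                      min_read_coverage, as.integer(band))
  as_tibble(res)[c("mappable_a", "mappable_b", "identity_a", "identity_b",
                   "best_transcript")]
}

check_criterion <- function(min_identity, min_read_coverage) {
  if (min_identity <= 0 || min_identity > 1 ||
      min_read_coverage <= 0 || min_read_coverage > 1) {
    abort("min_identity and min_read_coverage must lie in (0, 1].")
  }
}

#' Classify reads by species of origin
#'
#' Implements the dual-genome uniqueness rule used for tumor-on-host
#' RNA-seq: a read (or read pair) mappable only to species A is
#' `species_a`, only to B is `species_b`, to both is `ambiguous` (and is
#' excluded from quantification downstream), and to neither is `unmapped`.
#' For pairs, mappability to a species is the OR over mates, so a pair with
#' one mate mapping A-only and the other unmapped is `species_a`, while
#' discordant mates (one A-only, one B-only) are `ambiguous`.
#'
#' @param reads a tibble with `read_id` and `sequence` (and `sequence2` for
#'   pairs), a character vector of sequences, or a FASTQ path.
#' @param index a [kmer_index()].
#' @inheritParams read_mappability
#' @return tibble: `read_id`, `class` (factor `species_a`, `species_b`,
#'   `ambiguous`, `unmapped`), `mappable_a`, `mappable_b`,
#'   `best_transcript` and `best_gene` in the assigned species (lowest
#'   transcript id on within-species ties; `best_gene` is `NA` when two or
#'   more genes tie for best score, flagged in `gene_tie`), and `identity`.
#' @examples
#' ref <- simulate_reference_pair(30, 5, seed = 1)
#' idx <- kmer_index(ref)
#' sim <- simulate_reads(ref, "tumor_on_cam", n_reads = 200, seed = 2)
#' cls <- classify_reads(sim$reads, idx)
#' summarize_classification(cls)
#' @export
classify_reads <- function(reads, index, min_identity = 0.95,
                           min_read_coverage = 0.90, band = 3) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read_%07d", seq_along(reads)),
                    sequence = reads)
  }
  check_criterion(min_identity, min_read_coverage)
  mate2 <- if ("sequence2" %in% names(reads)) {
    if (any(nchar(reads$sequence2) != nchar(reads$sequence))) {
      abort("mate-length mismatch.")
    }
    reads$sequence2
  } else NULL
  res <- as_tibble(.xs_classify(index$ptr, reads$sequence, mate2,
                                min_identity, min_read_coverage,
                                as.integer(band)))
  tibble(
    read_id = reads$read_id,
    class = factor(READ_CLASSES[res$class_code], levels = READ_CLASSES),
    mappable_a = res$mappable_a,
    mappable_b = res$mappable_b,
    best_transcript = res$best_transcript,
    best_gene = res$best_gene,
    gene_tie = res$gene_tie,
    identity = res$identity
  )
}

#' Per-sample classification summary
#'
#' Counts and percentages per read class; the percentages sum to 100 up to
#' rounding and reproduce the stacked partition reported for dual-genome
#' mapping experiments.
#'
#' @param classified output of [classify_reads()], optionally with a
#'   `sample` column for multi-sample input.
#' @return tibble: (`sample`,) `class`, `n`, `percent` -- one row per class,
#'   zero classes included.
#' @export
summarize_classification <- function(classified) {
  if (nrow(classified) < 1) abort("need at least one read.")
  grp <- if ("sample" %in% names(classified)) c("sample", "class") else "class"
  classified |>
    mutate(class = factor(.data$class, levels = READ_CLASSES)) |>
    count(across(all_of(grp)), .drop = FALSE, name = "n") |>
    group_by(across(all_of(setdiff(grp, "class")))) |>
    mutate(percent = 100 * .data$n / sum(.data$n)) |>
    ungroup()
}

#' Write per-read and summary classification TSVs
#'
#' @param classified output of [classify_reads()].
#' @param stem output path stem; writes `<stem>_reads.tsv` and
#'   `<stem>_summary.tsv`.
#' @return invisibly, the paths written.
#' @export
write_classification <- function(classified, stem) {
  p1 <- paste0(stem, "_reads.tsv")
  readr::write_tsv(
    select(classified, "read_id", "class", "best_transcript", "identity"), p1)
  p2 <- paste0(stem, "_summary.tsv")
  readr::write_tsv(summarize_classification(classified), p2)
  invisible(c(p1, p2))
}
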