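#' Simulate a dual-species transcriptome reference
#'
#' Builds a pair of transcript sets emulating a tumor species ("A", e.g.
#' human) and a host species ("B", e.g. chick) that have diverged from a
#' common ancestor. Each homologous gene pair shares a transcript in which
#' species B differs from species A by i.i.d. substitutions at rate
#' `divergence` per site, except inside an optional conserved block that is
#' copied verbatim (emulating deeply conserved coding stretches that defeat
#' species assignment). Each species additionally carries genes with no
#' homolog in the other species.
#'
#' Transcript lengths are drawn log-normally (median `median_length`,
#' log-scale SD `sdlog_length`) and floored at `min_length`. With the
#' defaults (one 150-nt conserved block in 15% of homolog pairs, 50-nt
#' reads), the expected fraction of reads falling entirely inside a
#' conserved block -- and therefore unassignable to a single species -- is
#' about 1%, matching what dual-genome mapping of tumor-on-host samples
#' typically reports. See [expected_ambiguous_fraction()].
#'
#' @param n_homolog_pairs number of homologous gene pairs shared by the two
#'   species.
#' @param n_unique_per_species number of species-specific genes per species.
#' @param divergence substitution rate per site between homologs, in
#'   `[0, 0.75]`. Substitutions replace a base by one of the three other
#'   bases uniformly, so the expected sequence identity between homologs
#'   outside conserved blocks is exactly `1 - divergence`.
#' @param median_length,sdlog_length,min_length transcript length
#'   distribution: log-normal with the given median and log-scale SD,
#'   floored at `min_length` nt.
#' @param block_length,block_fraction conserved-block rule: a single block
#'   of `block_length` nt is placed (uniformly) in a fraction
#'   `block_fraction` of homolog pairs and copied unchanged into species B.
#' @param seed optional integer seed; the generator is deterministic under a
#'   fixed seed.
#' @return A `dual_reference` object: a list with elements
#'   `transcripts` (tibble: `species`, `gene_id`, `transcript_id`, `length`,
#'   `sequence`), `homology` (tibble: `gene_a`, `gene_b`, `transcript_a`,
#'   `transcript_b`, `divergence`, `block_start`, `block_length`; block
#'   coordinates are 0-based half-open in transcript space, `NA` when the
#'   pair has no conserved block), and `unique_a` / `unique_b` (character
#'   vectors of species-specific gene ids).
#' @examples
#' ref <- simulate_reference_pair(n_homolog_pairs = 20,
#'                                n_unique_per_species = 3, seed = 1)
#' glance(ref)
#' @export
simulate_reference_pair <- function(n_homolog_pairs = 1000,
                                    n_unique_per_species = 150,
                                    divergence = 0.20,
                                    median_length = 1500,
                                    sdlog_length = 0.25,
                                    min_length = 300,
                                    block_length = 150,
                                    block_fraction = 0.15,
                                    seed = NULL) {
  if (divergence < 0 || divergence > 0.75) {
    abort("`divergence` must lie in [0, 0.75].")
  }
  if (block_length > min_length) {
    abort("`block_length` must not exceed the minimum transcript length.")
  }
  if (!is.null(seed)) set.seed(seed)

  n_a <- n_homolog_pairs + n_unique_per_species
  n_b <- n_homolog_pairs + n_unique_per_species

  draw_lengths <- function(n) {
    pmax(min_length, round(rlnorm(n, meanlog = log(median_length),
                                  sdlog = sdlog_length)))
  }
  random_seq <- function(len) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }

  len_a <- draw_lengths(n_a)
  seq_a <- vapply(len_a, random_seq, character(1))

  gene_a <- sprintf("GA%04d", seq_len(n_a))
  tx_a <- sprintf("TA%04d", seq_len(n_a))
  homolog_idx <- seq_len(n_homolog_pairs)

  # conserved blocks for a subset of homolog pairs
  has_block <- runif(n_homolog_pairs) < block_fraction
  block_start <- rep(NA_integer_, n_homolog_pairs)
  ns <- len_a[homolog_idx] - block_length
  block_start[has_block] <- vapply(which(has_block), function(i) {
    as.integer(sample.int(ns[i] + 1L, 1L) - 1L)  # 0-based start
  }, integer(1))

  # species B homolog transcripts: substitute outside the conserved block
  diverge_one <- function(s, bs) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(chars)) < divergence
    if (!is.na(bs)) hit[(bs + 1):(bs + block_length)] <- FALSE
    idx <- which(hit)
    if (length(idx)) {
      code <- match(chars[idx], DNA_BASES)
      shift <- sample.int(3L, length(idx), replace = TRUE)
      chars[idx] <- DNA_BASES[((code - 1L + shift) %% 4L) + 1L]
    }
    paste(chars, collapse = "")
  }
  seq_b_hom <- vapply(homolog_idx, function(i) {
    diverge_one(seq_a[i], block_start[i])
  }, character(1))

  # species-B unique genes: fresh random sequence
  len_b_unique <- draw_lengths(n_unique_per_species)
  seq_b_unique <- vapply(len_b_unique, random_seq, character(1))

  gene_b <- sprintf("GB%04d", seq_len(n_b))
  tx_b <- sprintf("TB%04d", seq_len(n_b))
  seq_b <- c(seq_b_hom, seq_b_unique)
  len_b <- c(len_a[homolog_idx], len_b_unique)

  transcripts <- bind_rows(
    tibble(species = "A", gene_id = gene_a, transcript_id = tx_a,
           length = as.integer(len_a), sequence = seq_a),
    tibble(species = "B", gene_id = gene_b, transcript_id = tx_b,
           length = as.integer(len_b), sequence = seq_b)
  )

  homology <- tibble(
    gene_a = gene_a[homolog_idx],
    gene_b = gene_b[homolog_idx],
    transcript_a = tx_a[homolog_idx],
    transcript_b = tx_b[homolog_idx],
    divergence = divergence,
    block_start = block_start,
    block_length = ifelse(is.na(block_start), NA_integer_,
                          as.integer(block_length))
  )

  out <- structure(
    list(
      transcripts = transcripts,
      homology = homology,
      unique_a = gene_a[n_homolog_pairs + seq_len(n_unique_per_species)],
      unique_b = gene_b[n_homolog_pairs + seq_len(n_unique_per_species)],
      params = list(divergence = divergence, block_length = block_length,
                    block_fraction = block_fraction,
                    median_length = median_length,
                    sdlog_length = sdlog_length, min_length = min_length)
    ),
    class = "dual_reference"
  )
  validate_dual_reference(out)
  out
}

validate_dual_reference <- function(ref) {
  tr <- ref$transcripts
  stopifnot(!anyDuplicated(tr$transcript_id), !anyDuplicated(tr$gene_id))
  hm <- ref$homology
  all_a <- tr$gene_id[tr$species == "A"]
  all_b <- tr$gene_id[tr$species == "B"]
  # every gene in exactly one of {homology, unique_a, unique_b}
  if (!setequal(all_a, c(hm$gene_a, ref$unique_a)) ||
      !setequal(all_b, c(hm$gene_b, ref$unique_b)) ||
      length(intersect(hm$gene_a, ref$unique_a)) ||
      length(intersect(hm$gene_b, ref$unique_b))) {
    abort("dual_reference invariant violated: gene partition is not exact.")
  }
  invisible(ref)
}

#' @export
print.dual_reference <- function(x, ...) {
  cat("<dual_reference>\n")
  cat(sprintf("  homolog pairs: %d (%d with a conserved block)\n",
              nrow(x$homology), sum(!is.na(x$homology$block_start))))
  cat(sprintf("  unique genes: %d (A) + %d (B)\n",
              length(x$unique_a), length(x$unique_b)))
  cat(sprintf("  divergence: %.2f substitutions/site\n", x$params$divergence))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.dual_reference <- function(x, ...) {
  tibble(
    n_homolog_pairs = nrow(x$homology),
    n_conserved_blocks = sum(!is.na(x$homology$block_start)),
    n_unique_a = length(x$unique_a),
    n_unique_b = length(x$unique_b),
    divergence = x$params$divergence,
    median_length = median(x$transcripts$length)
  )
}

#' Transcript subsets of one species
#'
#' @param ref a [simulate_reference_pair()] result.
#' @param species `"A"` or `"B"`.
#' @return tibble of transcripts for that species.
#' @export
species_transcripts <- function(ref, species = c("A", "B")) {
  species <- match.arg(species)
  filter(ref$transcripts, .data$species == !!species)
}

#' Closed-form expected ambiguous-read fraction
#'
#' A read is unassignable to a single species when it lies entirely (up to
#' the clipping allowance of the mappability criterion) inside a conserved
#' block shared verbatim by a homolog pair. Under uniform start positions
#' and transcript sampling proportional to `expression x effective length`,
#' the expected ambiguous fraction among reads of one species is the
#' expression-weighted mean of `(block_length - read_length + 1) /
#' (transcript_length - read_length + 1)` over that species' transcripts
#' (zero where there is no block).
#'
#' @param ref a `dual_reference`.
#' @param read_length read length in nt.
#' @param expression optional named per-gene relative expression for species
#'   A and B (list with elements `A`, `B`); uniform when `NULL`.
#' @param origin_fractions length-3 numeric `(species_a, species_b,
#'   contaminant)`; the returned value is the expectation over all reads of
#'   a sample with this composition.
#' @return expected fraction of all reads classified ambiguous.
#' @export
expected_ambiguous_fraction <- function(ref, read_length = 50,
                                        expression = NULL,
                                        origin_fractions = c(0.64, 0.235, 0.125)) {
  per_species <- function(sp, gene_block) {
    tr <- species_transcripts(ref, sp)
    w <- if (is.null(expression)) rep(1, nrow(tr)) else
      expression[[sp]][tr$gene_id]
    eff <- pmax(0, tr$length - read_length + 1)
    bl <- gene_block[tr$gene_id]
    bl[is.na(bl)] <- 0
    amb <- pmax(0, bl - read_length + 1)
    sum(w * amb) / sum(w * eff)
  }
  hm <- ref$homology
  block_a <- setNames(hm$block_length, hm$gene_a)
  block_b <- setNames(hm$block_length, hm$gene_b)
  fa <- per_species("A", block_a)
  fb <- per_species("B", block_b)
  origin_fractions[1] * fa + origin_fractions[2] * fb
}

#' Write a dual reference to disk
#'
#' Emits one FASTA per species, a homology-map TSV, and a GTF-like
#' annotation (1-based inclusive coordinates, `gene_id`/`transcript_id`
#' attributes) in `dir`.
#'
#' @param ref a `dual_reference`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sp in c("A", "B")) {
    tr <- species_transcripts(ref, sp)
    dss <- Biostrings::DNAStringSet(setNames(tr$sequence, tr$transcript_id))
    p <- file.path(dir, sprintf("species_%s.fasta", tolower(sp)))
    Biostrings::writeXStringSet(dss, p)
    paths <- c(paths, p)
  }
  hp <- file.path(dir, "homology_map.tsv")
  readr::write_tsv(ref$homology, hp)
  gp <- file.path(dir, "annotation.gtf")
  tr <- ref$transcripts
  gtf <- sprintf(
    '%s\txenosplit\ttranscript\t1\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s";',
    tr$transcript_id, tr$length, tr$gene_id, tr$transcript_id)
  writeLines(gtf, gp)
  invisible(c(paths, hp, gp))
}
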