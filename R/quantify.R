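#' Species-split gene-level counting of classified reads
#'
#' Converts species-classified reads into two gene-level count matrices,
#' one per species compartment. Only uniquely assigned reads are counted:
#' `ambiguous` and `unmapped` reads never contribute, and a read whose best
#' alignment score is tied between two or more distinct genes is discarded
#' (union-counting behavior), reported separately from the species-level
#' ambiguity so the read-partition semantics stay clean. Genes with zero
#' counts everywhere are retained.
#'
#' @param classified a named list of [classify_reads()] tibbles (one per
#'   sample), or a single tibble with a `sample` column.
#' @param ref the `dual_reference` the index was built from (fixes the gene
#'   universe of each matrix).
#' @param metadata optional tibble with a `sample` column plus `condition`
#'   (and any other columns) carried into the matrices; defaults to
#'   condition `"unknown"`.
#' @return list with `species_a` and `species_b` (`count_matrix` objects)
#'   and `accounting` (tibble per sample: `n_reads`, `counted_a`,
#'   `counted_b`, `gene_tie_discarded`, `ambiguous`, `unmapped`). For every
#'   sample `counted_a + counted_b + gene_tie_discarded + ambiguous +
#'   unmapped == n_reads` exactly.
#' @export
count_reads <- function(classified, ref, metadata = NULL) {
  if (is.data.frame(classified)) {
    if (!"sample" %in% names(classified)) classified$sample <- "sample_1"
    classified <- split(classified, classified$sample)
  }
  if (is.null(names(classified)) || anyDuplicated(names(classified))) {
    abort("samples must be uniquely named.")
  }
  samples <- names(classified)
  genes_a <- species_transcripts(ref, "A")$gene_id
  genes_b <- species_transcripts(ref, "B")$gene_id

  count_one <- function(cls, genes, class_label) {
    keep <- cls$class == class_label & !cls$gene_tie & !is.na(cls$best_gene)
    tab <- table(factor(cls$best_gene[keep], levels = genes))
    as.integer(tab)
  }
  mat_a <- vapply(classified, count_one, integer(length(genes_a)),
                  genes = genes_a, class_label = "species_a")
  mat_b <- vapply(classified, count_one, integer(length(genes_b)),
                  genes = genes_b, class_label = "species_b")
  mat_a <- matrix(mat_a, nrow = length(genes_a),
                  dimnames = list(genes_a, samples))
  mat_b <- matrix(mat_b, nrow = length(genes_b),
                  dimnames = list(genes_b, samples))

  accounting <- purrr::imap(classified, function(cls, nm) {
    counted_a <- sum(mat_a[, nm])
    counted_b <- sum(mat_b[, nm])
    tie <- sum(cls$class %in% c("species_a", "species_b") &
                 (cls$gene_tie | is.na(cls$best_gene)))
    tibble(sample = nm, n_reads = nrow(cls),
           counted_a = counted_a, counted_b = counted_b,
           gene_tie_discarded = tie,
           ambiguous = sum(cls$class == "ambiguous"),
           unmapped = sum(cls$class == "unmapped"))
  }) |> bind_rows()

  meta <- tibble(sample = samples)
  if (!is.null(metadata)) {
    meta <- left_join(meta, metadata, by = "sample")
  }
  if (!"condition" %in% names(meta)) meta$condition <- "unknown"
  list(
    species_a = new_count_matrix(mat_a, mutate(meta, species = "A")),
    species_b = new_count_matrix(mat_b, mutate(meta, species = "B")),
    accounting = accounting
  )
}

#' Write count matrices and accounting to TSV
#'
#' One matrix per species (genes as rows, samples as columns) plus the
#' per-sample accounting table.
#'
#' @param counted result of [count_reads()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_counts <- function(counted, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sp in c("species_a", "species_b")) {
    p <- file.path(dir, sprintf("counts_%s.tsv", sp))
    readr::write_tsv(as_tibble(counted[[sp]]$counts, rownames = "gene"), p)
    paths <- c(paths, p)
  }
  pa <- file.path(dir, "accounting.tsv")
  readr::write_tsv(counted$accounting, pa)
  invisible(c(paths, pa))
}
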