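# Independent brute-force oracles, kept deliberately naive.

# Smith-Waterman mappability oracle via Biostrings local alignment,
# applying the same identity/coverage criterion as the classifier.
sw_mappable_one <- function(read, subjects, min_id = 0.95, min_cov = 0.90) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  test_orient <- function(rd) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = rep(rd, length(subjects)),
      subject = Biostrings::DNAStringSet(subjects),
      type = "local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2)
    nm <- Biostrings::nmatch(aln)
    alen <- nm + Biostrings::nmismatch(aln)   # gapless columns
    cov <- Biostrings::width(Biostrings::pattern(aln)) / nchar(rd)
    any(alen > 0 & nm / alen >= min_id & cov >= min_cov)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  test_orient(read) || test_orient(rc)
}

sw_classify_one <- function(read, ref, min_id = 0.95, min_cov = 0.90) {
  seq_a <- ref$transcripts$sequence[ref$transcripts$species == "A"]
  seq_b <- ref$transcripts$sequence[ref$transcripts$species == "B"]
  a <- length(seq_a) > 0 && sw_mappable_one(read, seq_a, min_id, min_cov)
  b <- length(seq_b) > 0 && sw_mappable_one(read, seq_b, min_id, min_cov)
  if (a && b) "ambiguous" else if (a) "species_a" else if (b) "species_b"
  else "unmapped"
}

# best-gene assignment oracle: full local SW score per transcript
sw_best_gene <- function(read, ref, species) {
  tr <- ref$transcripts[ref$transcripts$species == species, ]
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  sc <- Biostrings::pairwiseAlignment(
    pattern = rep(read, nrow(tr)),
    subject = Biostrings::DNAStringSet(tr$sequence),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
  best <- max(sc)
  genes <- unique(tr$gene_id[sc == best])
  if (length(genes) > 1) NA_character_ else genes
}

# textbook double-loop BH
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) {
      best <- min(best, m * p[ord[j]] / j)
    }
    adj[ord[i]] <- min(best, 1)
  }
  adj
}

# O(n^3) complete-linkage agglomeration; returns merge heights and the
# sequence of merged label sets (each sorted)
linkage_oracle <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(rownames(x))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, best_h)
    merges <- c(merges, list(merged))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Pearson chi-square from the E-matrix definition
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - e)^2 / e),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}
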