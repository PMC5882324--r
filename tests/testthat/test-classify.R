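test_that("k-mer index counts positions and supports lookups", {
  tx <- random_dna(60, seed = 1)
  ref <- manual_ref(tx)
  idx <- kmer_index(ref, k = 15)
  expect_equal(kmer_index_size(idx), 60 - 15 + 1)  # L - k + 1
  hit <- kmer_lookup(idx, substr(tx, 10, 24))
  expect_gte(nrow(hit), 1)
  expect_true(any(hit$transcript_id == "TA0001" & hit$position == 9))
  # reverse complement of the query hits the same entries
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(tx, 10, 24))))
  expect_identical(kmer_lookup(idx, rc), hit)
  # absent k-mer -> empty
  expect_equal(nrow(kmer_lookup(idx, strrep("A", 15))), 0)
})

test_that("conserved-block k-mers occur in both species", {
  ref <- simulate_reference_pair(10, 0, block_fraction = 1, seed = 2)
  idx <- kmer_index(ref)
  hm <- ref$homology[1, ]
  seqs <- setNames(ref$transcripts$sequence, ref$transcripts$transcript_id)
  km <- substr(seqs[[hm$transcript_a]], hm$block_start + 1, hm$block_start + 15)
  hit <- kmer_lookup(idx, km)
  expect_setequal(unique(hit$species), c("A", "B"))
})

test_that("duplicate transcript ids are rejected", {
  ref <- manual_ref(c(random_dna(300, seed = 3), random_dna(300)))
  ref$transcripts$transcript_id <- c("TX", "TX")
  expect_error(kmer_index(ref), "duplicate")
})

test_that("exact substrings are mappable; random reads are not", {
  ref <- ref_small(seed = 4)
  idx <- kmer_index(ref)
  tx <- species_transcripts(ref, "A")$sequence[1]
  mp <- read_mappability(substr(tx, 41, 90), idx)
  expect_true(mp$mappable_a)
  expect_equal(mp$identity_a, 1)
  # chance mappability of i.i.d. random 50-mers is < 1e-3 per read
  set.seed(5)
  rnd <- vapply(seq_len(2000), function(i) random_dna(50), character(1))
  mp <- read_mappability(rnd, idx)
  expect_lte(sum(mp$mappable_a | mp$mappable_b), 2)
})

test_that("cross-species reads at divergence 0.2 are unmappable, matching the SW oracle", {
  ref <- simulate_reference_pair(20, 0, median_length = 400,
                                 block_fraction = 0, seed = 6)
  idx <- kmer_index(ref)
  seqs <- species_transcripts(ref, "A")$sequence
  set.seed(7)
  reads <- vapply(seq_len(20), function(i) {
    s <- seqs[[sample.int(length(seqs), 1)]]
    p <- sample.int(nchar(s) - 49, 1)
    substr(s, p, p + 49)
  }, character(1))
  mp <- read_mappability(reads, idx)
  expect_true(all(mp$mappable_a))
  expect_false(any(mp$mappable_b))
  seq_b <- species_transcripts(ref, "B")$sequence
  oracle_b <- vapply(reads, sw_mappable_one, logical(1), subjects = seq_b)
  expect_false(any(oracle_b))
})

test_that("classification implements the dual-genome uniqueness rule", {
  ref <- simulate_reference_pair(10, 2, block_fraction = 1, seed = 8)
  idx <- kmer_index(ref)
  seqs <- setNames(ref$transcripts$sequence, ref$transcripts$transcript_id)
  hm <- ref$homology[1, ]
  # an error-free read wholly inside a conserved block is ambiguous
  block_read <- substr(seqs[[hm$transcript_a]], hm$block_start + 1,
                       hm$block_start + 50)
  # reads outside the block classify to their species
  a_read <- substr(seqs[[hm$transcript_a]],
                   hm$block_start + 160, hm$block_start + 209)
  b_read <- substr(seqs[[hm$transcript_b]],
                   hm$block_start + 160, hm$block_start + 209)
  cont <- random_dna(50, seed = 9)
  cls <- classify_reads(c(block_read, a_read, b_read, cont), idx)
  expect_identical(as.character(cls$class),
                   c("ambiguous", "species_a", "species_b", "unmapped"))
})

test_that("pair classification is the OR over mates per species", {
  ref <- ref_small(seed = 10)
  idx <- kmer_index(ref)
  seqs <- setNames(ref$transcripts$sequence, ref$transcripts$transcript_id)
  hm <- ref$homology
  blocked <- hm[!is.na(hm$block_start), ][1, ]
  a_tx <- species_transcripts(ref, "A")$sequence[10]
  b_tx <- species_transcripts(ref, "B")$sequence[10]
  a_read <- substr(a_tx, 1, 50)
  b_read <- substr(b_tx, 1, 50)
  cont <- random_dna(50, seed = 11)
  pairs <- tibble::tibble(
    read_id = c("p1", "p2", "p3"),
    sequence = c(a_read, a_read, cont),
    sequence2 = c(cont, b_read, random_dna(50)))
  cls <- classify_reads(pairs, idx)
  # mate1 A-only + mate2 unmapped -> species_a
  # discordant mates (A-only + B-only) -> ambiguous
  # both unmapped -> unmapped
  expect_identical(as.character(cls$class),
                   c("species_a", "ambiguous", "unmapped"))
  # oracle agreement for the pair rule
  oracle <- vapply(seq_len(3), function(i) {
    a <- sw_classify_one(pairs$sequence[i], ref) %in%
      c("species_a", "ambiguous") ||
      sw_classify_one(pairs$sequence2[i], ref) %in%
      c("species_a", "ambiguous")
    b <- sw_classify_one(pairs$sequence[i], ref) %in%
      c("species_b", "ambiguous") ||
      sw_classify_one(pairs$sequence2[i], ref) %in%
      c("species_b", "ambiguous")
    if (a && b) "ambiguous" else if (a) "species_a"
    else if (b) "species_b" else "unmapped"
  }, character(1))
  expect_identical(as.character(cls$class), oracle)
  # mate length mismatch is rejected
  bad <- tibble::tibble(read_id = "x", sequence = a_read,
                        sequence2 = substr(a_read, 1, 30))
  expect_error(classify_reads(bad, idx), "mate-length")
})

test_that("classifier agrees exactly with the SW oracle on simulated reads with <= 2 errors", {
  ref <- simulate_reference_pair(15, 3, median_length = 350,
                                 sdlog_length = 0.1, seed = 12)
  idx <- kmer_index(ref)
  sim <- simulate_reads(ref, "tumor_on_cam", n_reads = 140, seed = 13)
  keep <- sim$truth$n_errors <= 2
  reads <- sim$reads$sequence[keep]
  cls <- classify_reads(reads, idx)
  oracle <- vapply(reads, sw_classify_one, character(1), ref = ref)
  expect_identical(as.character(cls$class), unname(oracle))
})

test_that("relaxing min_identity moves reads only toward mapped classes", {
  ref <- ref_small(seed = 14)
  idx <- kmer_index(ref)
  sim <- simulate_reads(ref, "tumor_on_cam", n_reads = 400, seed = 15)
  strict <- classify_reads(sim$reads, idx, min_identity = 0.95)
  relaxed <- classify_reads(sim$reads, idx, min_identity = 0.80)
  expect_true(all(relaxed$mappable_a[strict$mappable_a]))
  expect_true(all(relaxed$mappable_b[strict$mappable_b]))
})

test_that("classification is independent of read input order", {
  ref <- ref_small(seed = 16)
  idx <- kmer_index(ref)
  sim <- simulate_reads(ref, "tumor_on_cam", n_reads = 300, seed = 17)
  cls <- classify_reads(sim$reads, idx)
  perm <- sample(nrow(sim$reads))
  cls_p <- classify_reads(sim$reads[perm, ], idx)
  expect_identical(cls_p$class, cls$class[perm])
  expect_identical(cls_p$best_gene, cls$best_gene[perm])
})

test_that("true species is recovered for >= 99% of clean informative reads", {
  ref <- simulate_reference_pair(200, 30, seed = 18)
  idx <- kmer_index(ref)
  sim <- simulate_reads(ref, "tumor_on_cam", n_reads = 20000, seed = 19)
  cls <- classify_reads(sim$reads, idx)
  hm <- ref$homology
  block_of <- setNames(hm$block_start, hm$transcript_a)
  block_of_b <- setNames(hm$block_start, hm$transcript_b)
  bs <- dplyr::coalesce(block_of[sim$truth$transcript_id],
                        block_of_b[sim$truth$transcript_id])
  overlaps_block <- !is.na(bs) & sim$truth$position < bs + 150 &
    sim$truth$position + 50 > bs
  eligible <- sim$truth$true_origin != "contaminant" &
    sim$truth$n_errors <= 2 & !overlaps_block
  expect_gte(mean(as.character(cls$class[eligible]) ==
                    sim$truth$true_origin[eligible]), 0.99)
})

test_that("summaries report exact per-class counts and percentages", {
  cls <- tibble::tibble(
    read_id = sprintf("r%03d", 1:100),
    class = factor(rep(c("species_a", "species_b", "ambiguous", "unmapped"),
                       c(63, 23, 1, 13)),
                   levels = c("species_a", "species_b", "ambiguous",
                              "unmapped")))
  s <- summarize_classification(cls)
  expect_equal(s$percent, c(63, 23, 1, 13))
  expect_equal(sum(s$percent), 100)
  # all-A input still reports the four classes
  s2 <- summarize_classification(cls[cls$class == "species_a", ])
  expect_equal(s2$percent, c(100, 0, 0, 0))
  expect_error(summarize_classification(cls[0, ]), "at least one")
})
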