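#' Simulate sequencing reads from a dual-species reference
#'
#' Draws each read's species of origin from the preset's
#' `(frac_a, frac_b, frac_contaminant)` composition, picks a source
#' transcript within the species proportionally to
#' `expression x (length - read_length + 1)` (effective length), a start
#' position uniformly over valid starts, and applies i.i.d. substitution
#' errors at `error_rate` per base (to one of the three other bases).
#' Contaminant reads are i.i.d. uniform-random sequence with no source and
#' emulate the unalignable fraction of real libraries. In paired mode the
#' two 50-nt mates are the sense-strand prefix and reverse-complement
#' suffix of a fixed-length fragment (`fragment_length`). Deterministic
#' under `seed`.
#'
#' @param ref a `dual_reference`.
#' @param preset a row name from [sample_presets], or a one-row tibble with
#'   the same columns.
#' @param n_reads number of reads (or read pairs).
#' @param expression_a,expression_b named per-gene relative expression for
#'   each species; defaults to an independent log-normal draw (median 1,
#'   log-SD 1.2) under the run seed.
#' @param fragment_length insert size for paired-end mode.
#' @param seed optional integer seed.
#' @return list with `reads` (tibble: `read_id`, `sequence`, and `sequence2`
#'   for paired presets) and `truth` (tibble: `read_id`, `true_origin` in
#'   `species_a`/`species_b`/`contaminant`, `gene_id`, `transcript_id`,
#'   `position` 0-based, `n_errors`; contaminants carry `NA` source fields).
#'   Row counts and ids of the two tibbles match bijectively.
#' @examples
#' ref <- simulate_reference_pair(50, 5, seed = 1)
#' sim <- simulate_reads(ref, "tumor_on_cam", n_reads = 500, seed = 1)
#' table(sim$truth$true_origin)
#' @export
simulate_reads <- function(ref, preset = "tumor_on_cam", n_reads = 200000,
                           expression_a = NULL, expression_b = NULL,
                           fragment_length = 180, seed = NULL) {
  if (is.character(preset)) {
    preset <- filter(sample_presets, .data$preset == !!preset)
    if (nrow(preset) != 1) abort("unknown preset name.")
  }
  fr <- c(preset$frac_a, preset$frac_b, preset$frac_contaminant)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-8) {
    abort("origin fractions must lie in [0,1] and sum to 1.")
  }
  rl <- preset$read_length
  if (rl > min(ref$transcripts$length)) {
    abort("read length exceeds the shortest transcript.")
  }
  paired <- identical(preset$end_mode, "paired")
  if (paired && fragment_length > min(ref$transcripts$length)) {
    abort("fragment length exceeds the shortest transcript.")
  }
  if (!is.null(seed)) set.seed(seed)

  default_expr <- function(sp) {
    tr <- species_transcripts(ref, sp)
    setNames(rlnorm(nrow(tr), 0, 1.2), tr$gene_id)
  }
  expression_a <- expression_a %ifnull% default_expr("A")
  expression_b <- expression_b %ifnull% default_expr("B")
  if (!length(expression_a) || !length(expression_b)) {
    abort("expression must be defined for all genes of both species.")
  }

  n_origin <- as.vector(stats::rmultinom(1, n_reads, fr))
  span <- if (paired) fragment_length else rl

  sim_species <- function(sp, n, expr) {
    if (n == 0) {
      return(list(reads = character(0), reads2 = character(0),
                  truth = tibble(read_id = character(0),
                                 true_origin = character(0),
                                 gene_id = character(0),
                                 transcript_id = character(0),
                                 position = integer(0),
                                 n_errors = integer(0))))
    }
    tr <- species_transcripts(ref, sp)
    expr_tx <- expr[tr$gene_id]
    if (anyNA(expr_tx)) abort("expression missing for some genes.")
    eff <- pmax(0L, tr$length - as.integer(span) + 1L)
    w <- expr_tx * eff
    tx_i <- sample.int(nrow(tr), n, replace = TRUE, prob = w)
    start <- floor(runif(n) * eff[tx_i])  # 0-based uniform over valid starts
    reads <- .xs_extract_reads(tr$sequence, tx_i - 1L, as.integer(start), rl)
    err1 <- inject_errors(reads, preset$error_rate)
    out <- list(reads = err1$reads, reads2 = character(0))
    n_err <- err1$n
    if (paired) {
      s2 <- as.integer(start) + fragment_length - rl
      m2 <- .xs_extract_reads(tr$sequence, tx_i - 1L, s2, rl)
      m2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(m2)))
      err2 <- inject_errors(m2, preset$error_rate)
      out$reads2 <- err2$reads
      n_err <- n_err + err2$n
    }
    out$truth <- tibble(read_id = NA_character_,
                        true_origin = if (sp == "A") "species_a" else "species_b",
                        gene_id = tr$gene_id[tx_i],
                        transcript_id = tr$transcript_id[tx_i],
                        position = as.integer(start),
                        n_errors = as.integer(n_err))
    out
  }

  random_reads <- function(n) {
    if (n == 0) return(character(0))
    chars <- sample(DNA_BASES, n * rl, replace = TRUE)
    big <- paste(chars, collapse = "")
    substring(big, seq(1, n * rl, by = rl), seq(rl, n * rl, by = rl))
  }

  a <- sim_species("A", n_origin[1], expression_a)
  b <- sim_species("B", n_origin[2], expression_b)
  nc <- n_origin[3]
  cont <- list(reads = random_reads(nc),
               reads2 = if (paired) random_reads(nc) else character(0),
               truth = tibble(read_id = rep(NA_character_, nc),
                              true_origin = rep("contaminant", nc),
                              gene_id = NA_character_,
                              transcript_id = NA_character_,
                              position = NA_integer_,
                              n_errors = 0L))

  reads <- c(a$reads, b$reads, cont$reads)
  truth <- bind_rows(a$truth, b$truth, cont$truth)
  ids <- sprintf("read_%07d", seq_along(reads))
  truth$read_id <- ids
  reads_tbl <- tibble(read_id = ids, sequence = reads)
  if (paired) reads_tbl$sequence2 <- c(a$reads2, b$reads2, cont$reads2)
  list(reads = reads_tbl, truth = truth)
}

# i.i.d. substitution errors at `rate` per base; returns mutated reads and
# the per-read error count.
inject_errors <- function(reads, rate) {
  n <- length(reads)
  if (n == 0 || rate <= 0) return(list(reads = reads, n = integer(n)))
  rl <- nchar(reads[1])
  n_err <- rbinom(n, rl, rate)
  idx <- rep.int(seq_len(n), n_err)
  if (!length(idx)) return(list(reads = reads, n = n_err))
  pos <- unlist(lapply(n_err[n_err > 0], function(k) sample.int(rl, k) - 1L),
                use.names = FALSE)
  cur <- substring(reads[idx], pos + 1, pos + 1)
  code <- match(cur, DNA_BASES)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  newb <- DNA_BASES[((code - 1L + shift) %% 4L) + 1L]
  list(reads = .xs_apply_substitutions(reads, idx, pos, newb), n = n_err)
}

#' Write simulated reads as FASTQ
#'
#' Phred+33 with a constant quality character. Paired reads go to
#' `<stem>_1.fastq` / `<stem>_2.fastq`; single-end to `<stem>.fastq`.
#'
#' @param sim result of [simulate_reads()] (or its `reads` tibble).
#' @param stem output path stem (no extension).
#' @param quality constant quality character.
#' @return invisibly, the path(s) written.
#' @export
write_reads_fastq <- function(sim, stem, quality = "I") {
  reads <- if (is.data.frame(sim)) sim else sim$reads
  qual <- strrep(quality, nchar(reads$sequence[1] %||% ""))
  emit <- function(ids, seqs, path) {
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
    path
  }
  if ("sequence2" %in% names(reads)) {
    p1 <- emit(reads$read_id, reads$sequence, paste0(stem, "_1.fastq"))
    p2 <- emit(reads$read_id, reads$sequence2, paste0(stem, "_2.fastq"))
    invisible(c(p1, p2))
  } else {
    invisible(emit(reads$read_id, reads$sequence, paste0(stem, ".fastq")))
  }
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path (optionally a second mate file as `path2`).
#' @param path2 optional mate-2 FASTQ.
#' @return tibble with `read_id`, `sequence` (and `sequence2`).
#' @export
read_fastq <- function(path, path2 = NULL) {
  rd <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- tibble(read_id = names(rd), sequence = unname(as.character(rd)))
  if (!is.null(path2)) {
    rd2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
    if (length(rd2) != nrow(out)) abort("mate files differ in record count.")
    out$sequence2 <- unname(as.character(rd2))
  }
  out
}
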