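#' Marquee fixture genes
#'
#' Five simulator genes with programmed condition effects mimicking the
#' hallmark regulations seen when hepatoblastoma cells adapt to growth on
#' the chick chorioallantoic membrane: a humanin-family mitochondrial
#' peptide gene induced 100-fold *in vivo*, an HMGCS2-like ketogenesis gene
#' rising 27-fold from tumor day 1 to day 7, a VEGFA-like angiogenic factor
#' up 3.6-fold at day 4 and 2.8-fold at day 7 versus culture, an RPL41-like
#' ribosomal gene 13.3-fold down on the membrane, and a LIN28A-like stem
#' cell marker with a slight (1.5-fold) decline over tumor days.
#'
#' Columns `cell_line`, `T1`, `T4`, `T7` are relative expression multipliers
#' applied to `baseline`; `baseline` sets the gene's relative abundance in
#' the cell-line condition (in the units of the expression program's
#' log-normal baseline, median 1).
#'
#' @format tibble with one row per fixture gene.
#' @export
marquee_genes <- tibble::tibble(
  gene_key  = c("humanin_like", "hmgcs2_like", "vegfa_like",
                "rpl41_like", "lin28a_like"),
  baseline  = c(8, 2, 4, 30, 6),
  cell_line = c(1, 1, 1, 1, 1),
  T1        = c(100, 1,          1,   1 / 13.3, 1),
  T4        = c(100, sqrt(27),   3.6, 1 / 13.3, 1 / sqrt(1.5)),
  T7        = c(100, 27,         2.8, 1 / 13.3, 1 / 1.5)
)

#' Programmed fold changes of the marquee fixture genes
#'
#' The per-contrast truth implied by [marquee_genes]; `fold_change` is the
#' linear-scale ratio (second condition over first is encoded in the
#' contrast name as `<treatment>_vs_<reference>`).
#'
#' @format tibble: `gene_key`, `contrast`, `fold_change`.
#' @export
marquee_contrasts <- tibble::tibble(
  gene_key = c("humanin_like", "humanin_like", "humanin_like",
               "hmgcs2_like", "vegfa_like", "vegfa_like",
               "rpl41_like", "lin28a_like"),
  contrast = c("T1_vs_cell_line", "T4_vs_cell_line", "T7_vs_cell_line",
               "T7_vs_T1", "T4_vs_cell_line", "T7_vs_cell_line",
               "T1_vs_cell_line", "T7_vs_T1"),
  fold_change = c(100, 100, 100, 27, 3.6, 2.8, 1 / 13.3, 1 / 1.5)
)

#' Sample composition presets
#'
#' Per-sample-type mixing of tumor-species reads, host-species reads and an
#' unalignable contaminant fraction (which stands in for the reads real
#' experiments fail to map: adapter, rRNA, low quality). The mixed
#' `tumor_on_cam` preset reproduces the partition reported for tumors grown
#' on the membrane (63% tumor / 23% host / ~1% ambiguous / 13% unmapped);
#' `huh6_invitro` and `cam_pure` reproduce the pure cell-line and pure
#' membrane samples.
#'
#' @format tibble: `preset`, `frac_a`, `frac_b`, `frac_contaminant`,
#'   `end_mode`, `read_length`, `error_rate`, `condition`.
#' @export
sample_presets <- tibble::tibble(
  preset = c("huh6_invitro", "cam_pure", "tumor_on_cam"),
  frac_a = c(0.875, 0, 0.64),
  frac_b = c(0, 0.85, 0.235),
  frac_contaminant = c(0.125, 0.15, 0.125),
  end_mode = c("paired", "single", "single"),
  read_length = 50L,
  error_rate = 0.01,
  condition = c("cell_line", "E14", "T4")
)

#' Simulate a condition-dependent expression program
#'
#' Draws per-gene baseline expression from a log-normal (median 1, log-SD
#' `base_sdlog`) and overlays condition effects. For the tumor compartment
#' (`species = "A"`, conditions cell line then tumor days T1/T4/T7) a
#' fraction `frac_de` of genes respond to implantation with log2 effects
#' drawn `N(0, effect_sd)` applied to all membrane days, and a smaller
#' fraction drift gradually across days; the five [marquee_genes] override
#' their designated genes. For the host compartment (`species = "B"`,
#' embryonic days E11/E14/E17 plus tumor-bearing days T1/T4/T7) genes drift
#' with development and a fraction respond to tumor presence.
#'
#' @param ref a `dual_reference`.
#' @param species `"A"` (tumor) or `"B"` (host).
#' @param frac_de fraction of genes with a condition effect.
#' @param effect_sd SD of log2 effect sizes.
#' @param base_sdlog log-scale SD of baseline expression.
#' @param dispersion negative-binomial dispersion assigned to every gene
#'   (variance `mu + dispersion * mu^2`).
#' @param marquee include the marquee fixture genes (species A only).
#' @param seed optional integer seed.
#' @return an `expression_program`: list with `means` (genes x conditions
#'   matrix of relative expression), `contrasts` (tibble of programmed
#'   `gene_id`, `contrast`, `fold_change`; unchanged genes have fold change
#'   1 by construction), `dispersion` (named per-gene), `species`, and
#'   `marquee` (gene_key -> gene_id map, species A only).
#' @export
simulate_expression_program <- function(ref, species = c("A", "B"),
                                        frac_de = 0.25, effect_sd = 1,
                                        base_sdlog = 1.2,
                                        dispersion = 0.05,
                                        marquee = identical(match.arg(species), "A"),
                                        seed = NULL) {
  species <- match.arg(species)
  if (!is.null(seed)) set.seed(seed)
  tr <- species_transcripts(ref, species)
  genes <- tr$gene_id
  n <- length(genes)
  base <- rlnorm(n, meanlog = 0, sdlog = base_sdlog)

  conditions <- if (species == "A") c("cell_line", "T1", "T4", "T7") else
    c("E11", "E14", "E17", "T1", "T4", "T7")
  means <- matrix(base, nrow = n, ncol = length(conditions),
                  dimnames = list(genes, conditions))
  contrasts <- tibble(gene_id = character(), contrast = character(),
                      fold_change = numeric())
  marquee_map <- NULL

  if (species == "A") {
    # implantation response: jump from cell_line to all membrane days
    de <- runif(n) < frac_de
    jump <- ifelse(de, rnorm(n, 0, effect_sd), 0)
    for (cc in c("T1", "T4", "T7")) means[, cc] <- base * 2^jump
    # gradual drift across tumor days for a smaller subset
    drift_gene <- runif(n) < frac_de / 2.5
    slope <- ifelse(drift_gene, rnorm(n, 0, effect_sd / 2), 0)
    means[, "T4"] <- means[, "T4"] * 2^slope
    means[, "T7"] <- means[, "T7"] * 2^(2 * slope)
    if (marquee) {
      idx <- seq_len(nrow(marquee_genes))  # first genes host the fixtures
      marquee_map <- tibble(gene_key = marquee_genes$gene_key,
                            gene_id = genes[idx])
      for (j in seq_along(idx)) {
        b <- marquee_genes$baseline[j]
        means[idx[j], ] <- b * unlist(
          marquee_genes[j, c("cell_line", "T1", "T4", "T7")])
      }
      contrasts <- bind_rows(contrasts,
        left_join(marquee_contrasts, marquee_map, by = "gene_key") |>
          select("gene_id", "contrast", "fold_change"))
    }
  } else {
    # developmental drift (day index 1..3 for E11/E14/E17 and matched T days)
    drift_gene <- runif(n) < frac_de
    slope <- ifelse(drift_gene, rnorm(n, 0, effect_sd / 2), 0)
    day_of <- c(E11 = 0, E14 = 1, E17 = 2, T1 = 0, T4 = 1, T7 = 2)
    for (cc in conditions) means[, cc] <- base * 2^(slope * day_of[[cc]])
    # tumor-presence response on the T side
    tum_gene <- runif(n) < frac_de / 2
    tum <- ifelse(tum_gene, rnorm(n, 0, effect_sd), 0)
    for (cc in c("T1", "T4", "T7")) means[, cc] <- means[, cc] * 2^tum
  }

  structure(
    list(means = means, contrasts = contrasts,
         dispersion = setNames(rep(dispersion, n), genes),
         species = species, marquee = marquee_map),
    class = "expression_program")
}

#' @export
print.expression_program <- function(x, ...) {
  cat(sprintf("<expression_program> species %s: %d genes x %d conditions\n",
              x$species, nrow(x$means), ncol(x$means)))
  cat("  conditions:", paste(colnames(x$means), collapse = ", "), "\n")
  if (!is.null(x$marquee)) {
    cat("  marquee genes:",
        paste(sprintf("%s=%s", x$marquee$gene_key, x$marquee$gene_id),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Condition snapshot of an expression program
#'
#' @param program an `expression_program`.
#' @param condition one of the program's condition labels.
#' @return named numeric vector of relative per-gene expression.
#' @export
program_expression <- function(program, condition) {
  if (!condition %in% colnames(program$means)) {
    abort(sprintf("condition '%s' not in program (%s)", condition,
                  paste(colnames(program$means), collapse = ", ")))
  }
  program$means[, condition]
}

# ---- truth-level count simulation --------------------------------------

new_count_matrix <- function(counts, samples) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            identical(colnames(counts), samples$sample))
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers.")
  }
  if (anyDuplicated(samples$sample)) abort("duplicate sample names.")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$samples, n = 6)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.count_matrix <- function(x, ...) {
  as_tibble(x$counts, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample",
                        values_to = "count") |>
    left_join(x$samples, by = "sample")
}

#' @exportS3Method generics::glance
glance.count_matrix <- function(x, ...) {
  tibble(n_genes = nrow(x$counts), n_samples = ncol(x$counts),
         total_counts = sum(x$counts),
         n_conditions = length(unique(x$samples$condition)))
}

#' Simulate gene-level counts from an expression program
#'
#' Truth-level negative-binomial count simulation: for each sample the
#' expected count of gene *i* is `library_size` times the gene's relative
#' expression in the sample's condition (normalized within condition), and
#' counts are drawn NB with the program's per-gene dispersion (`alpha = 0`
#' degenerates to Poisson). Deterministic under `seed`.
#'
#' @param program an `expression_program`.
#' @param n_reps biological replicates per condition (>= 2).
#' @param library_size expected reads per sample; scalar or per-sample.
#' @param conditions subset of program conditions (default: all).
#' @param seed optional integer seed.
#' @return a `count_matrix` (genes x samples, with sample metadata).
#' @export
simulate_counts <- function(program, n_reps = 3, library_size = 5e5,
                            conditions = NULL, seed = NULL) {
  if (n_reps < 2) abort("need >= 2 replicates per condition.")
  if (!is.null(seed)) set.seed(seed)
  conditions <- conditions %ifnull% colnames(program$means)
  missing <- setdiff(conditions, colnames(program$means))
  if (length(missing)) abort(sprintf("unknown condition(s): %s",
                                     paste(missing, collapse = ", ")))
  means <- program$means[, conditions, drop = FALSE]
  if (any(means < 0)) abort("expression means must be >= 0.")
  alpha <- program$dispersion[rownames(means)]
  if (any(alpha < 0)) abort("dispersions must be >= 0.")

  samples <- tidyr::expand_grid(condition = conditions,
                                replicate = seq_len(n_reps)) |>
    mutate(sample = sprintf("%s_r%d", .data$condition, .data$replicate),
           species = program$species) |>
    select("sample", "condition", "replicate", "species")
  lib <- rep_len(library_size, nrow(samples))

  counts <- matrix(0L, nrow = nrow(means), ncol = nrow(samples),
                   dimnames = list(rownames(means), samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- lib[j] * means[, samples$condition[j]] / sum(means[, samples$condition[j]])
    pois <- alpha == 0
    k <- integer(length(mu))
    if (any(pois)) k[pois] <- rpois(sum(pois), mu[pois])
    if (any(!pois)) k[!pois] <- rnbinom(sum(!pois), mu = mu[!pois],
                                        size = 1 / alpha[!pois])
    counts[, j] <- k
  }
  new_count_matrix(counts, samples)
}
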