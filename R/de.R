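#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors by the median-of-ratios convention:
#' for each gene with nonzero counts in every sample, take the ratio of the
#' sample's count to the gene's geometric mean across samples; the sample's
#' size factor is the median of those ratios. Invariant to gene order, and
#' robust to library-composition shifts as long as most genes are
#' unchanged.
#'
#' @param counts a `count_matrix` or an integer matrix (genes x samples).
#' @return named numeric vector of positive per-sample factors.
#' @examples
#' m <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  k <- counts_matrix_of(counts)
  pos <- rowSums(k > 0) == ncol(k)
  if (!any(pos)) {
    abort(paste("no gene has nonzero counts in every sample; the",
                "pseudo-reference fallback is off by design -- filter or",
                "merge samples first."))
  }
  logk <- log(k[pos, , drop = FALSE])
  ref <- rowMeans(logk)
  sf <- apply(logk, 2, function(col) exp(median(col - ref)))
  setNames(sf, colnames(k))
}

counts_matrix_of <- function(counts) {
  if (inherits(counts, "count_matrix")) counts$counts else {
    stopifnot(is.matrix(counts))
    counts
  }
}

conditions_of <- function(counts, condition = NULL) {
  if (inherits(counts, "count_matrix")) counts$samples$condition else {
    if (is.null(condition)) abort("supply `condition` for a bare matrix.")
    condition
  }
}

#' Estimate negative-binomial dispersions with trend shrinkage
#'
#' Per-gene dispersion by method of moments on normalized counts pooled
#' within conditions, `alpha_hat = max(0, (s2 - mu) / mu^2)`; a mean
#' dispersion trend `alpha_tr(mu) = a0 + a1 / mu` fit by least squares over
#' genes with positive `alpha_hat`; and shrinkage toward the trend by
#' weighted geometric interpolation in log space, with the prior carrying
#' weight equivalent to 4 observations against the gene's `n` samples.
#' Genes whose moment estimate is exactly zero take the trend value;
#' all-zero genes take the trend evaluated at `mu = 1`.
#'
#' @param counts a `count_matrix`, or integer matrix with `condition`.
#' @param sf size factors (computed when `NULL`).
#' @param condition per-sample condition labels (taken from the
#'   `count_matrix` metadata when available).
#' @return a `dispersion_model`: per-gene tibble (`gene`, `base_mean`,
#'   `alpha_mom`, `alpha_trend`, `alpha`) plus trend coefficients `a0`,
#'   `a1`.
#' @export
estimate_dispersions <- function(counts, sf = NULL, condition = NULL) {
  k <- counts_matrix_of(counts)
  condition <- conditions_of(counts, condition)
  sf <- sf %ifnull% size_factors(k)
  q <- sweep(k, 2, sf, "/")
  cond <- factor(condition)
  reps <- table(cond)
  if (!any(reps >= 2)) abort("need >= 2 replicates in some condition.")
  use <- cond %in% names(reps)[reps >= 2]

  mu <- rowMeans(q)
  # pooled within-condition variance over conditions with replication
  qq <- q[, use, drop = FALSE]
  cc <- droplevels(cond[use])
  centered <- qq
  for (lv in levels(cc)) {
    j <- cc == lv
    centered[, j] <- qq[, j, drop = FALSE] - rowMeans(qq[, j, drop = FALSE])
  }
  df <- ncol(qq) - nlevels(cc)
  s2 <- rowSums(centered^2) / df
  alpha_mom <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), NA_real_)

  fit_on <- !is.na(alpha_mom) & alpha_mom > 0 & mu > 0
  if (sum(fit_on) >= 2) {
    co <- stats::lm.fit(cbind(1, 1 / mu[fit_on]), alpha_mom[fit_on])$coefficients
  } else {
    co <- c(1e-8, 0)
  }
  a0 <- max(co[1], 1e-8)   # trend must stay positive at any mu > 0
  a1 <- max(co[2], 0)
  trend <- function(m) a0 + a1 / pmax(m, 1e-8)

  alpha_trend <- ifelse(mu > 0, trend(mu), trend(1))
  n_obs <- ncol(k)
  w <- n_obs / (n_obs + 4)
  alpha <- ifelse(!is.na(alpha_mom) & alpha_mom > 0,
                  exp(w * log(alpha_mom) + (1 - w) * log(alpha_trend)),
                  alpha_trend)

  structure(
    list(genes = tibble(gene = rownames(k), base_mean = unname(mu),
                        alpha_mom = unname(alpha_mom),
                        alpha_trend = unname(alpha_trend),
                        alpha = unname(alpha)),
         a0 = a0, a1 = a1, n_obs = n_obs),
    class = "dispersion_model")
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat(sprintf("<dispersion_model> %d genes; trend a0=%.4g, a1=%.4g\n",
              nrow(x$genes), x$a0, x$a1))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dispersion_model <- function(x, ...) x$genes

#' @exportS3Method generics::glance
glance.dispersion_model <- function(x, ...) {
  tibble(a0 = x$a0, a1 = x$a1, n_genes = nrow(x$genes),
         median_alpha = median(x$genes$alpha))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement (the textbook
#' `min over j >= i of m * p_(j) / j`, capped at 1).
#'
#' @param p numeric p-values in `[0, 1]`; `NaN` is rejected.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) abort("NaN p-values are not allowed.")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Two-group negative-binomial Wald test
#'
#' For each gene, group means are means of size-factor-normalized counts;
#' `log2FC = log2((mu2 + eps) / (mu1 + eps))` with `eps = 0` when both
#' group means are positive and a Haldane-style `eps = 0.5` otherwise;
#' `Var(ln FC) = sum over groups of (1/n_g)(1/mu_g + alpha)` from the NB
#' Fisher information, with `alpha` evaluated on the fitted mean-dispersion
#' trend at the gene's base mean (a named per-gene vector can be supplied
#' to override); the Wald statistic `z = ln FC / SE` gets a
#' two-sided normal p-value; BH adjustment runs across all genes of the
#' matrix; and a gene is `significant` when `padj < alpha_level` and
#' `|log2FC| > lfc_cutoff` (the conventional filter: adjusted p < 0.05 and
#' |log2 fold change| > 1). Genes at zero in both groups get `p = 1`,
#' `log2FC = 0`.
#'
#' @param counts a `count_matrix` or integer matrix.
#' @param contrast length-2 character `c(treatment, reference)`: the fold
#'   change is treatment over reference.
#' @param condition per-sample labels for a bare matrix.
#' @param sf size factors (computed when `NULL`).
#' @param dispersions a `dispersion_model` or named per-gene alpha vector
#'   (estimated on the full matrix when `NULL`).
#' @param alpha_level,lfc_cutoff significance filter thresholds.
#' @return a `de_result` tibble: `gene`, `base_mean`, `log2_fc`, `lfc_se`,
#'   `stat`, `p_value`, `p_adj`, `significant`, with the contrast stored as
#'   an attribute. `p_adj >= p_value` always holds.
#' @export
wald_de <- function(counts, contrast, condition = NULL, sf = NULL,
                    dispersions = NULL, alpha_level = 0.05, lfc_cutoff = 1) {
  k <- counts_matrix_of(counts)
  condition <- conditions_of(counts, condition)
  if (length(contrast) != 2) abort("contrast must be c(treatment, reference).")
  missing <- setdiff(contrast, unique(condition))
  if (length(missing)) {
    abort(sprintf("condition(s) not present: %s",
                  paste(missing, collapse = ", ")),
          class = "xenosplit_missing_condition")
  }
  j2 <- condition == contrast[1]   # treatment / numerator
  j1 <- condition == contrast[2]   # reference / denominator
  if (sum(j1) < 2 || sum(j2) < 2) abort("both conditions need >= 2 replicates.")

  sf <- sf %ifnull% size_factors(k)
  q <- sweep(k, 2, sf, "/")
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(k[, j1 | j2, drop = FALSE],
                                        sf = sf[j1 | j2],
                                        condition = condition[j1 | j2])
  }
  mu1 <- rowMeans(q[, j1, drop = FALSE])
  mu2 <- rowMeans(q[, j2, drop = FALSE])
  n1 <- sum(j1); n2 <- sum(j2)
  base_mean <- rowMeans(q[, j1 | j2, drop = FALSE])

  alpha <- if (inherits(dispersions, "dispersion_model")) {
    # the Wald SE uses the fitted mean-dispersion trend rather than the
    # per-gene shrunken values: with 3 replicates the per-gene moment
    # estimates are noisy enough to inflate the type-I error of the
    # plug-in Wald statistic, while the trend keeps it calibrated
    dispersions$a0 + dispersions$a1 / pmax(base_mean, 1e-8)
  } else {
    dispersions[rownames(k)]
  }

  eps <- ifelse(mu1 > 0 & mu2 > 0, 0, 0.5)
  both_zero <- mu1 == 0 & mu2 == 0
  lfc_ln <- log((mu2 + eps) / (mu1 + eps))
  var_ln <- (1 / n1) * (1 / (mu1 + eps) + alpha) +
            (1 / n2) * (1 / (mu2 + eps) + alpha)
  se_ln <- sqrt(var_ln)
  z <- lfc_ln / se_ln
  p <- 2 * pnorm(-abs(z))
  lfc_ln[both_zero] <- 0
  z[both_zero] <- 0
  p[both_zero] <- 1

  padj <- bh_adjust(p)
  res <- tibble(
    gene = rownames(k),
    base_mean = unname(base_mean),
    log2_fc = unname(lfc_ln) / log(2),
    lfc_se = unname(se_ln) / log(2),
    stat = unname(z),
    p_value = unname(p),
    p_adj = unname(padj),
    significant = unname(padj < alpha_level & abs(lfc_ln / log(2)) > lfc_cutoff)
  )
  structure(res, class = c("de_result", class(res)),
            contrast = contrast, alpha_level = alpha_level,
            lfc_cutoff = lfc_cutoff)
}

#' @exportS3Method generics::tidy
tidy.de_result <- function(x, ...) as_tibble(unclass(x))

#' @exportS3Method generics::glance
glance.de_result <- function(x, ...) {
  tibble(contrast = paste(attr(x, "contrast"), collapse = "_vs_"),
         n_genes = nrow(x),
         n_significant = sum(x$significant),
         n_up = sum(x$significant & x$log2_fc > 0),
         n_down = sum(x$significant & x$log2_fc < 0))
}

#' Default staged contrasts for a condition set
#'
#' Tumor side (when `cell_line` is present): each tumor day versus the
#' cell line, plus T4 vs T1, T7 vs T4, T7 vs T1. Host side (when E-days
#' are present): each tumor-bearing day versus the matched embryonic day,
#' successive E-days, and successive tumor-bearing days.
#'
#' @param conditions character vector of condition labels.
#' @return list of `c(treatment, reference)` pairs, named
#'   `<treatment>_vs_<reference>`.
#' @export
default_contrasts <- function(conditions) {
  pairs <- list()
  add <- function(t, r) {
    if (all(c(t, r) %in% conditions)) pairs[[paste0(t, "_vs_", r)]] <<- c(t, r)
  }
  add("T1", "cell_line"); add("T4", "cell_line"); add("T7", "cell_line")
  add("T4", "T1"); add("T7", "T4"); add("T7", "T1")
  add("T1", "E11"); add("T4", "E14"); add("T7", "E17")
  add("E14", "E11"); add("E17", "E14"); add("E17", "E11")
  pairs
}

#' Run a set of two-group contrasts on one count matrix
#'
#' @param counts a `count_matrix`.
#' @param contrasts list of `c(treatment, reference)` pairs or
#'   `"T7_vs_T1"`-style strings; defaults to [default_contrasts()] on the
#'   matrix's conditions. A contrast naming a condition absent from the
#'   matrix raises a named error.
#' @param ... passed to [wald_de()].
#' @return list with `results` (named list of `de_result`) and `summary`
#'   (tibble: `contrast`, `n_significant`, `n_up`, `n_down`).
#' @export
run_contrasts <- function(counts, contrasts = NULL, ...) {
  conds <- unique(conditions_of(counts))
  contrasts <- contrasts %ifnull% default_contrasts(conds)
  contrasts <- lapply(contrasts, function(ct) {
    if (is.character(ct) && length(ct) == 1) {
      strsplit(ct, "_vs_", fixed = TRUE)[[1]]
    } else ct
  })
  if (is.null(names(contrasts)) || any(names(contrasts) == "")) {
    names(contrasts) <- vapply(contrasts, paste, character(1),
                               collapse = "_vs_")
  }
  sf <- size_factors(counts)
  results <- purrr::map(contrasts, function(ct) {
    wald_de(counts, contrast = ct, sf = sf, ...)
  })
  summary <- purrr::map(results, glance) |> bind_rows()
  list(results = results, summary = summary)
}

#' Write a DE table in the conventional column order
#'
#' Columns: `gene`, `baseMean`, `log2FC`, `lfcSE`, `stat`, `pvalue`,
#' `padj`, `significant`.
#'
#' @param de a `de_result`.
#' @param path output TSV path.
#' @export
write_de_tsv <- function(de, path) {
  out <- tibble(gene = de$gene, baseMean = de$base_mean,
                log2FC = de$log2_fc, lfcSE = de$lfc_se, stat = de$stat,
                pvalue = de$p_value, padj = de$p_adj,
                significant = de$significant)
  readr::write_tsv(out, path)
  invisible(path)
}
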