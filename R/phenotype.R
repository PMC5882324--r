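#' Simulate blinded observer phenotype scores
#'
#' Emulates the semi-quantitative scoring of treated vs control tumors:
#' each tumor has a latent binary phenotype per criterion (`white_areas`,
#' `normal_appearance`) drawn from group-specific probabilities; each of
#' three blinded observers reports the latent value, flipped with
#' probability `observer_error` and missing with probability
#' `missing_rate` (a missing vote is the only way the two-of-three
#' consensus can fail with binary scores).
#'
#' @param n_control,n_treated tumors per arm (defaults mirror a 35/36
#'   cohort).
#' @param p_white named probabilities of white (necrotic) areas per group.
#' @param p_normal named probabilities of normal appearance per group.
#' @param n_observers number of observers.
#' @param observer_error per-vote flip probability.
#' @param missing_rate per-vote missing probability.
#' @param seed optional integer seed.
#' @return tibble: `tumor_id`, `group`, `observer_id`, `criterion`,
#'   `score` (0/1/`NA`).
#' @export
simulate_phenotype_scores <- function(n_control = 35, n_treated = 36,
                                      p_white = c(control = 0.15, treated = 0.60),
                                      p_normal = c(control = 0.75, treated = 0.25),
                                      n_observers = 3,
                                      observer_error = 0.10,
                                      missing_rate = 0.03,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tumors <- tibble(
    tumor_id = sprintf("tumor_%02d", seq_len(n_control + n_treated)),
    group = rep(c("control", "treated"), c(n_control, n_treated)))
  probs <- list(white_areas = p_white, normal_appearance = p_normal)
  purrr::map(names(probs), function(cr) {
    latent <- rbinom(nrow(tumors), 1, probs[[cr]][tumors$group])
    purrr::map(seq_len(n_observers), function(ob) {
      flip <- rbinom(nrow(tumors), 1, observer_error)
      score <- ifelse(flip == 1, 1 - latent, latent)
      score[rbinom(nrow(tumors), 1, missing_rate) == 1] <- NA_integer_
      mutate(tumors, observer_id = sprintf("obs_%d", ob), criterion = cr,
             score = as.integer(score))
    }) |> bind_rows()
  }) |> bind_rows() |>
    arrange(.data$tumor_id, .data$criterion, .data$observer_id)
}

#' Observer consensus per tumor and criterion
#'
#' A tumor's consensus for a criterion is the value shared by at least two
#' non-missing observers (the two-of-three rule); tumors where no value
#' reaches two votes are `excluded` from further processing. With more
#' than three observers a generalized majority of `ceiling((n+1)/2)` votes
#' is required, with a warning. Invariant to observer order; with three
#' non-missing binary votes exclusion is impossible.
#'
#' @param scores tibble as from [simulate_phenotype_scores()] (columns
#'   `tumor_id`, `group`, `observer_id`, `criterion`, `score`).
#' @return tibble: `tumor_id`, `group`, `criterion`, `consensus` (factor
#'   `"0"`, `"1"`, `"excluded"`).
#' @export
consensus_scores <- function(scores) {
  n_obs <- length(unique(scores$observer_id))
  needed <- if (n_obs <= 3) 2L else {
    warn(sprintf("%d observers: using generalized majority >= %d.",
                 n_obs, ceiling((n_obs + 1) / 2)))
    as.integer(ceiling((n_obs + 1) / 2))
  }
  scores |>
    group_by(.data$tumor_id, .data$group, .data$criterion) |>
    summarise(consensus = {
      v <- .data$score[!is.na(.data$score)]
      n1 <- sum(v == 1); n0 <- sum(v == 0)
      if (n1 >= needed) "1" else if (n0 >= needed) "0" else "excluded"
    }, .groups = "drop") |>
    mutate(consensus = factor(.data$consensus,
                              levels = c("0", "1", "excluded")))
}

#' Treatment-group contingency table of consensus phenotypes
#'
#' Excluded tumors are dropped; margins equal the processed-tumor counts.
#'
#' @param consensus output of [consensus_scores()].
#' @param criterion which criterion to tabulate.
#' @return integer matrix, groups x phenotype (`0`, `1`).
#' @export
contingency_table <- function(consensus, criterion = "white_areas") {
  d <- filter(consensus, .data$criterion == !!criterion,
              .data$consensus != "excluded")
  tab <- table(group = d$group, phenotype = droplevels(d$consensus))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Pearson chi-square test of a contingency table
#'
#' `sum((O - E)^2 / E)` with expected counts from the margins,
#' `df = (r - 1)(c - 1)`, upper-tail chi-square p-value; no continuity
#' correction by default. All margins must be positive.
#'
#' @param tab integer matrix of counts.
#' @param correct apply Yates continuity correction (2x2 only).
#' @return tibble: `statistic`, `df`, `p_value`.
#' @export
phenotype_chisq <- function(tab, correct = FALSE) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero row or column margin.")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value))
}

#' Randomized blinded presentation order
#'
#' Seeded permutation of tumor photo ids for blinded scoring.
#'
#' @param tumor_ids character vector of ids.
#' @param seed optional integer seed.
#' @return tibble: `position`, `tumor_id`.
#' @export
blind_order <- function(tumor_ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble(position = seq_along(tumor_ids),
         tumor_id = sample(tumor_ids))
}
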