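test_that("size factors follow the median-of-ratios convention", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- m; m2[, 2] <- 2L * m2[, 1]
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # 5x3 fixture against direct arithmetic
  set.seed(1)
  k <- matrix(rpois(15, 50) + 1L, nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  gm <- apply(k, 1, function(r) exp(mean(log(r))))
  manual <- apply(k, 2, function(col) median(col / gm))
  expect_equal(unname(size_factors(k)), unname(manual))
  # invariance to gene order
  expect_equal(size_factors(k[5:1, ]), size_factors(k))
  # all-zero-gene-free requirement
  k0 <- k; k0[, 1] <- 0L
  expect_error(size_factors(k0), "pseudo-reference")
})

test_that("Poisson data yield near-zero shrunken dispersions at high counts", {
  set.seed(2)
  ng <- 2000
  mu <- exp(runif(ng, log(100), log(5000)))
  k <- sapply(1:6, function(j) rpois(ng, mu))
  dimnames(k) <- list(sprintf("g%04d", 1:ng), paste0("s", 1:6))
  storage.mode(k) <- "integer"
  dm <- estimate_dispersions(k, condition = rep(c("a", "b"), each = 3))
  expect_lt(median(dm$genes$alpha), 0.01)
})

test_that("the dispersion trend recovers a constant true alpha", {
  set.seed(3)
  ng <- 2000
  mu <- exp(runif(ng, log(50), log(5000)))
  k <- sapply(1:6, function(j) rnbinom(ng, mu = mu, size = 1 / 0.05))
  dimnames(k) <- list(sprintf("g%04d", 1:ng), paste0("s", 1:6))
  storage.mode(k) <- "integer"
  dm <- estimate_dispersions(k, condition = rep(c("a", "b"), each = 3))
  expect_lt(abs(dm$a0 - 0.05), 0.02)
})

test_that("identical genes get identical dispersions; all-zero genes take the trend at mu = 1", {
  set.seed(4)
  row <- rnbinom(6, mu = 300, size = 20)
  k <- matrix(rep(row, each = 100), nrow = 100, byrow = FALSE)
  k <- rbind(k, matrix(50L + rpois(600, 10), nrow = 100))
  k[1:2, ] <- 0L  # hide two all-zero genes among the duplicates
  k[3:100, ] <- matrix(rep(row, each = 98), nrow = 98)
  dimnames(k) <- list(sprintf("g%03d", 1:200), paste0("s", 1:6))
  storage.mode(k) <- "integer"
  dm <- estimate_dispersions(k, condition = rep(c("a", "b"), each = 3))
  a <- dm$genes$alpha
  expect_equal(length(unique(a[3:100])), 1)
  expect_equal(unname(a[1]), dm$a0 + dm$a1, tolerance = 1e-9)  # trend at mu = 1
  # shrunken values sit between raw and trend in log space
  g <- dm$genes[!is.na(dm$genes$alpha_mom) & dm$genes$alpha_mom > 0, ]
  expect_true(all(
    log(g$alpha) >= pmin(log(g$alpha_mom), log(g$alpha_trend)) - 1e-9 &
    log(g$alpha) <= pmax(log(g$alpha_mom), log(g$alpha_trend)) + 1e-9))
})

test_that("BH adjustment matches the double-loop definition and base properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  set.seed(5)
  p <- runif(1000)^2
  expect_equal(bh_adjust(p), bh_oracle(p))
  # monotone nondecreasing in p
  ord <- order(p)
  expect_true(all(diff(bh_adjust(p)[ord]) >= -1e-12))
  expect_error(bh_adjust(c(0.1, NaN)), "NaN")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("identical groups give null results on a deterministic fixture", {
  k <- matrix(rep(c(1000L, 500L, 2000L, 100L, 800L), 6), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  de <- wald_de(k, c("b", "a"), condition = rep(c("a", "b"), each = 3),
                dispersions = setNames(rep(0.05, 5), paste0("g", 1:5)))
  expect_true(all(abs(de$log2_fc) < 0.05))
  expect_true(all(de$p_value > 0.5))
  expect_true(all(de$p_adj >= de$p_value))
})

test_that("zero-in-both-groups genes get p = 1 and log2FC = 0", {
  set.seed(6)
  k <- matrix(rpois(60, 100), nrow = 10)
  k[1, ] <- 0L
  dimnames(k) <- list(paste0("g", 1:10), paste0("s", 1:6))
  storage.mode(k) <- "integer"
  de <- wald_de(k, c("b", "a"), condition = rep(c("a", "b"), each = 3))
  expect_equal(unname(de$p_value[1]), 1)
  expect_equal(unname(de$log2_fc[1]), 0)
})

test_that("swapping the contrast direction negates every log2FC exactly", {
  set.seed(7)
  k <- matrix(rnbinom(120, mu = 300, size = 20), nrow = 20)
  dimnames(k) <- list(sprintf("g%02d", 1:20), paste0("s", 1:6))
  storage.mode(k) <- "integer"
  cond <- rep(c("a", "b"), each = 3)
  d1 <- wald_de(k, c("b", "a"), condition = cond)
  d2 <- wald_de(k, c("a", "b"), condition = cond)
  expect_equal(d2$log2_fc, -d1$log2_fc)
  expect_equal(d2$p_value, d1$p_value)
})

test_that("programmed 4-fold genes at high counts are recovered on average", {
  set.seed(8)
  ng <- 1000
  mu <- rep(500, ng)
  fc <- rep(1, ng)
  fc[1:100] <- 4   # programmed genes among a null majority
  k <- cbind(sapply(1:3, function(j) rnbinom(ng, mu = mu, size = 1 / 0.05)),
             sapply(1:3, function(j) rnbinom(ng, mu = fc * mu,
                                             size = 1 / 0.05)))
  dimnames(k) <- list(sprintf("g%04d", 1:ng), paste0("s", 1:6))
  storage.mode(k) <- "integer"
  de <- wald_de(k, c("b", "a"), condition = rep(c("a", "b"), each = 3))
  expect_lt(abs(mean(de$log2_fc[1:100]) - 2), 0.15)
})

test_that("integer rescaling of one sample changes only its size factor", {
  # counting-noise (1/mu) terms are negligible at these depths, isolating
  # the scale-invariance of the normalization and test statistics
  set.seed(9)
  k <- matrix(rnbinom(600, mu = 1e6, size = 20) + 1L, nrow = 100)
  dimnames(k) <- list(sprintf("g%03d", 1:100), paste0("s", 1:6))
  storage.mode(k) <- "integer"
  cond <- rep(c("a", "b"), each = 3)
  alpha <- setNames(rep(0.05, 100), rownames(k))
  k2 <- k; k2[, 1] <- 3L * k2[, 1]
  sf1 <- size_factors(k); sf2 <- size_factors(k2)
  # the scaled sample's factor grows 3x relative to every other sample
  expect_equal(unname(sf2[1] / sf1[1]) / unname(sf2[2] / sf1[2]), 3,
               tolerance = 1e-10)
  d1 <- wald_de(k, c("b", "a"), condition = cond, dispersions = alpha)
  d2 <- wald_de(k2, c("b", "a"), condition = cond, dispersions = alpha)
  expect_equal(d2$log2_fc, d1$log2_fc, tolerance = 1e-6)
  expect_equal(d2$p_value, d1$p_value, tolerance = 1e-6)
})

test_that("run_contrasts covers the staged design and errors on absent conditions", {
  ref <- ref_small(seed = 10)
  prog <- simulate_expression_program(ref, "A", seed = 11)
  cm <- simulate_counts(prog, n_reps = 3, library_size = 1e5, seed = 12)
  rc <- run_contrasts(cm)
  expect_setequal(names(rc$results),
                  c("T1_vs_cell_line", "T4_vs_cell_line", "T7_vs_cell_line",
                    "T4_vs_T1", "T7_vs_T4", "T7_vs_T1"))
  expect_identical(rc$summary$contrast, names(rc$results))
  expect_error(run_contrasts(cm, contrasts = list(c("T9", "T1"))),
               class = "xenosplit_missing_condition")
  # host side picks up the E-day contrasts
  progb <- simulate_expression_program(ref, "B", seed = 13)
  cmb <- simulate_counts(progb, n_reps = 3, library_size = 1e5, seed = 14)
  rcb <- run_contrasts(cmb)
  expect_true(all(c("T1_vs_E11", "T4_vs_E14", "T7_vs_E17",
                    "E14_vs_E11", "E17_vs_E14") %in% names(rcb$results)))
})

test_that("a condition contrasted with itself calls nothing significant", {
  ref <- ref_small(seed = 15)
  prog <- simulate_expression_program(ref, "A", seed = 16)
  cm <- simulate_counts(prog, n_reps = 6, library_size = 1e5, seed = 17,
                        conditions = "T4")
  k <- cm$counts
  de <- wald_de(k, c("half2", "half1"),
                condition = rep(c("half1", "half2"), each = 3))
  expect_lte(sum(de$significant), 1)
})

test_that("DE table writer uses the conventional column order", {
  ref <- ref_small(seed = 18)
  prog <- simulate_expression_program(ref, "A", seed = 19)
  cm <- simulate_counts(prog, seed = 20)
  de <- wald_de(cm, c("T7", "cell_line"))
  path <- file.path(withr::local_tempdir(), "de.tsv")
  write_de_tsv(de, path)
  expect_identical(names(readr::read_tsv(path, show_col_types = FALSE)),
                   c("gene", "baseMean", "log2FC", "lfcSE", "stat",
                     "pvalue", "padj", "significant"))
})
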