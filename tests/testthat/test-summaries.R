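test_that("VST closed form behaves at zero and at the large-count asymptote", {
  a0 <- 0.05; a1 <- 2
  k <- matrix(c(0L, 1000L), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
  v <- vst_transform(k, sf = c(s1 = 1), dispersion = c(a0, a1))
  expect_equal(v["g1", 1], log2((1 + a1) / (4 * a0)))
  # vst(2q) - vst(q) -> 1 for q >= 1e4 / a0
  q <- ceiling(1e4 / a0)
  k2 <- matrix(as.integer(c(q, 2 * q)), nrow = 2,
               dimnames = list(c("g1", "g2"), "s1"))
  v2 <- vst_transform(k2, sf = c(s1 = 1), dispersion = c(a0, a1))
  expect_lt(abs((v2["g2", 1] - v2["g1", 1]) - 1), 0.01)
  # strictly increasing in q
  ks <- matrix(as.integer(seq(0, 5000, by = 250)), ncol = 1,
               dimnames = list(sprintf("g%02d", 1:21), "s1"))
  vs <- vst_transform(ks, sf = c(s1 = 1), dispersion = c(a0, a1))
  expect_true(all(diff(vs[, 1]) > 0))
})

test_that("VST flattens the variance-mean relationship of NB counts", {
  set.seed(1)
  means <- rep(c(10, 100, 1000, 10000), each = 100)
  k <- sapply(1:50, function(j) rnbinom(400, mu = means, size = 1 / 0.05))
  dimnames(k) <- list(sprintf("g%03d", 1:400), sprintf("s%02d", 1:50))
  storage.mode(k) <- "integer"
  sf <- setNames(rep(1, 50), colnames(k))
  v <- vst_transform(k, sf = sf, dispersion = c(0.05, 0))
  sd_bin <- function(m) tapply(apply(m, 1, sd), means, median)
  raw_ratio <- max(sd_bin(k)) / min(sd_bin(k))
  vst_ratio <- max(sd_bin(v)) / min(sd_bin(v))
  expect_gt(raw_ratio, 10)
  expect_lt(vst_ratio, 2.5)
})

test_that("a0 = 0 falls back to log2(q + 1) with a message", {
  k <- matrix(c(0L, 3L), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
  expect_message(v <- vst_transform(k, sf = c(s1 = 1), dispersion = c(0, 0)),
                 "log2")
  expect_equal(v[, 1], log2(c(g1 = 0, g2 = 3) + 1))
})

test_that("top_expressed selects by mean, deterministically and order-invariantly", {
  set.seed(2)
  m <- matrix(rnorm(120), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:6)))
  m[3:12, ] <- m[3:12, ] + 100
  expect_setequal(top_expressed(m, 10), sprintf("g%02d", 3:12))
  expect_identical(top_expressed(m[, c(4, 1, 6, 2, 3, 5)], 10),
                   top_expressed(m, 10))
  expect_warning(all_genes <- top_expressed(m, 50), "taking all")
  expect_length(all_genes, 20)
  # tie-break by gene id
  mt <- matrix(1, nrow = 3, ncol = 2,
               dimnames = list(c("gB", "gA", "gC"), c("s1", "s2")))
  expect_identical(top_expressed(mt, 2), c("gA", "gB"))
})

test_that("PCA matches the eigendecomposition oracle and handles degenerate input", {
  set.seed(3)
  m <- matrix(rnorm(24), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  pc <- pca_samples(m, n_pc = 3)
  # oracle: eigendecomposition of the covariance of gene-centered samples
  x <- t(m - rowMeans(m))
  ev <- eigen(crossprod(x))
  scores_oracle <- x %*% ev$vectors[, 1:3]
  for (j in 1:3) {
    got <- pc$scores[[paste0("PC", j)]]
    expect_equal(abs(cor(got, scores_oracle[, j])), 1, tolerance = 1e-9)
    expect_equal(sd(got), sd(scores_oracle[, j]), tolerance = 1e-9)
  }
  expect_equal(unname(pc$var_explained[1]), ev$values[1] / sum(ev$values),
               tolerance = 1e-9)
  # rank-1 fixture: PC1 explains everything
  r1 <- outer(rnorm(6), c(1, 2, 3, 4))
  rownames(r1) <- paste0("g", 1:6); colnames(r1) <- paste0("s", 1:4)
  expect_gt(pca_samples(r1)$var_explained[1], 0.999)
  # duplicated samples coincide
  md <- cbind(m, s4b = m[, 4])
  sc <- pca_samples(md)$scores
  expect_equal(unlist(sc[4, -1]), unlist(sc[5, -1]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # constant matrix: all scores zero
  cm <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_true(all(pca_samples(cm)$scores$PC1 == 0))
})

test_that("complete-linkage clustering matches the brute-force linkage oracle", {
  set.seed(4)
  m <- matrix(rnorm(35), nrow = 7,
              dimnames = list(paste0("g", 1:7), paste0("s", 1:5)))
  got <- hclust_order(m, "samples")
  oracle <- linkage_oracle(t(m))
  expect_equal(sort(got$hclust$height), sort(oracle$heights))
  # same sequence of merged label sets
  hc <- got$hclust
  sets <- list()
  members <- function(i) {
    if (i < 0) hc$labels[-i] else sets[[i]]
  }
  for (step in seq_len(nrow(hc$merge))) {
    sets[[step]] <- sort(c(members(hc$merge[step, 1]),
                           members(hc$merge[step, 2])))
  }
  expect_identical(sets, oracle$merges)
})

test_that("identical items merge at height zero; translation leaves the tree unchanged", {
  m <- matrix(rnorm(20), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  m[, 2] <- m[, 1]
  hc <- hclust_order(m, "samples")$hclust
  expect_equal(min(hc$height), 0)
  expect_true(all(diff(hc$height) >= -1e-12))  # nondecreasing merges
  shifted <- hclust_order(m + 7, "samples")$hclust
  expect_equal(shifted$height, hc$height)
  expect_identical(shifted$merge, hc$merge)
})
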