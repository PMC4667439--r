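test_that("median-of-ratios size factors match hand computation and DESeq2", {
  m <- matrix(c(2, 6, 4, 12), nrow = 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(medianRatioSizeFactors(m),
               c(a = 1 / sqrt(2), b = sqrt(2)))
  ## identical samples give unit factors
  m2 <- matrix(rep(c(3, 8, 20), 4), nrow = 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(medianRatioSizeFactors(m2)), rep(1, 4))
  ## agreement with the established implementation
  set.seed(1)
  m3 <- matrix(rnbinom(300 * 8, mu = 80, size = 5) + 1L, 300, 8,
               dimnames = list(paste0("g", 1:300), paste0("s", 1:8)))
  expect_equal(unname(medianRatioSizeFactors(m3)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m3)),
               tolerance = 1e-12)
  ## error path: no gene covered in every sample
  m4 <- matrix(c(0, 5, 5, 0), 2)
  rownames(m4) <- c("g1", "g2"); colnames(m4) <- c("s1", "s2")
  expect_error(medianRatioSizeFactors(m4), "no gene")
})

test_that("size factors are scale-equivariant on random matrices", {
  ## the size-factor vector is defined up to a global constant (the
  ## geometric-mean reference moves with the rescaled sample), so the
  ## meaningful statement is on factor ratios: scaling one sample by c
  ## scales its factor by c relative to every other sample's
  set.seed(42)
  for (i in 1:10) {
    m <- matrix(rnbinom(20 * 4, mu = 50, size = 3) + 1L, 20, 4,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
    f0 <- medianRatioSizeFactors(m)
    m2 <- m
    m2[, 2] <- m2[, 2] * 2
    f2 <- medianRatioSizeFactors(m2)
    expect_equal(unname((f2[2] / f2[-2]) / (f0[2] / f0[-2])),
                 rep(2, 3), tolerance = 1e-12)
    ## unchanged samples keep their relative factors
    expect_equal(unname(f2[3] / f2[4]), unname(f0[3] / f0[4]),
                 tolerance = 1e-12)
  }
})

test_that("count normalization floors at 1 and is idempotent", {
  m <- matrix(c(0L, 10L, 4L, 20L, 2L, 14L, 6L, 18L, 8L, 16L), nrow = 1)
  m <- rbind(m, m * 3L)
  dimnames(m) <- list(c("g1", "g2"), paste0("s", 1:10))
  ce <- CXExperiment(m, rep(cxPopulations(), each = 2), scale = "counts")
  em <- normalizeCounts(ce, factors = rep(1, 10))
  expect_equal(SummarizedExperiment::assay(em)["g1", 1], 1)  # floored 0
  expect_true(all(SummarizedExperiment::assay(em) >= 1))
  em2 <- normalizeCounts(ce, factors = rep(2, 10))
  expect_equal(SummarizedExperiment::assay(em2)["g1", 2], 5)  # 10 / 2
  ## size factors of an already-normalized, unfloored matrix are all 1
  set.seed(7)
  big <- matrix(rnbinom(200 * 6, mu = 200, size = 10) + 50L, 200, 6,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  ceb <- CXExperiment(big, rep(cxPopulations()[1:3], each = 2),
                      scale = "counts")
  emb <- normalizeCounts(ceb)
  ## re-estimation finds nothing left to correct: the factor vector is
  ## constant (its absolute level is the arbitrary geometric-mean scale)
  refac <- medianRatioSizeFactors(SummarizedExperiment::assay(emb))
  expect_lt(max(refac) / min(refac) - 1, 1e-12)
  f0 <- medianRatioSizeFactors(ceb)
  expect_equal(unname(refac), rep(exp(mean(log(f0))), 6),
               tolerance = 1e-12)
})

test_that("present filters apply strict/inclusive group-mean thresholds", {
  gv <- rbind(c(12, 5, 1, 1, 1),
              c(10, 10, 10, 10, 10),
              c(1, 1, 1, 1, 1),
              c(300, 2, 2, 2, 2))
  rownames(gv) <- paste0("g", 1:4)
  em <- makeEM(gv, reps = 2)
  kept <- rownames(filterPresentRNA(em, min_mean = 10))
  expect_identical(kept, c("g1", "g4"))  # strict >10; all-10 drops

  ga <- rbind(c(7.0, 6.0, 6.0, 6.0, 6.0),
              c(6.5, 6.5, 6.5, 6.5, 6.5),
              c(6.7886, 5, 5, 5, 5))
  rownames(ga) <- paste0("p", 1:3)
  ema <- makeEM(ga, reps = 2, scale = "log2")
  kepta <- rownames(filterPresentMicroarray(ema, background = 6.7886))
  expect_identical(kepta, c("p1", "p3"))  # inclusive >=; all-below drops
})

test_that("the variable filter keeps group-structured genes and drops flat ones", {
  ## identical group means with within-group spread: F = 0, dropped
  pops <- cxPopulations()
  vals <- rbind(rep(c(1, 2, 3), 5),        # same triple in every group
                rep(c(1, 2, 3), 5) + 10)
  colnames(vals) <- paste0(rep(pops, each = 3), "_R", 1:3)
  rownames(vals) <- c("flat1", "flat2")
  em <- CXExperiment(vals, rep(pops, each = 3), scale = "log2")
  expect_identical(nrow(filterVariable(em)), 0L)
  ## constant gene: dropped with warning, no division by zero
  vals2 <- rbind(vals, const = rep(5, 15))
  em2 <- CXExperiment(vals2, rep(pops, each = 3), scale = "log2")
  expect_warning(out <- filterVariable(em2), "constant")
  expect_false("const" %in% rownames(out))
  ## planted signature genes survive the filter almost always
  sim <- generateRNA(n_genes = 400, n_sig = 40, n_modules = 0,
                     reps_per_group = 5, seed = 55)
  emv <- normalizeCounts(sim$counts)
  kept <- rownames(filterVariable(emv))
  expect_gte(mean(signatureGenes(sim$truth) %in% kept), 0.95)
})

test_that("z-transform standardizes rows and drops constants", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(z <- zTransform(m), "zero-variance")
  expect_identical(rownames(z), "a")
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  set.seed(3)
  m2 <- matrix(rnorm(50 * 6), 50, 6,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  z2 <- zTransform(m2)
  expect_true(all(abs(rowMeans(z2)) < 1e-12))
  expect_equal(unname(apply(z2, 1, sd)), rep(1, 50))
})

test_that("sample PCA is an exact SVD decomposition", {
  set.seed(11)
  base <- rnorm(8)
  m <- rbind(g1 = base, g2 = 2 * base + 3)   # perfectly correlated pair
  p <- samplePCA(zTransform(m))
  expect_equal(p$explained[1] / sum(p$explained), 1, tolerance = 1e-12)
  m2 <- matrix(rnorm(30 * 6), 30, 6,
               dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
  z <- zTransform(m2)
  p2 <- samplePCA(z)
  ## orthonormal loadings, exact reconstruction
  expect_equal(crossprod(p2$loadings), diag(ncol(p2$loadings)),
               tolerance = 1e-9, ignore_attr = TRUE)
  recon <- p2$scores %*% t(p2$loadings)
  centered <- t(z) - matrix(colMeans(t(z)), nrow(t(z)), ncol(t(z)),
                            byrow = TRUE)
  expect_equal(recon, centered, tolerance = 1e-9, ignore_attr = TRUE)
  ## explained variances sum to total variance
  expect_equal(sum(p2$explained), sum(apply(t(z), 2, var)),
               tolerance = 1e-9)
})

test_that("quantile normalization equalizes sample distributions", {
  set.seed(5)
  m <- matrix(rnorm(200 * 4, mean = rep(c(0, 2, 4, 6), each = 200)), 200, 4)
  qn <- quantileNormalize(m)
  for (j in 2:4)
    expect_equal(sort(qn[, 1]), sort(qn[, j]), tolerance = 1e-12)
})

test_that("protein filtering honours flags and the valid-value rule", {
  pops <- cxPopulations()
  ## 5 groups x 3 replicates
  cols <- paste0(rep(pops, each = 3), "_R", 1:3)
  vals <- matrix(NA_real_, 4, 15, dimnames = list(paste0("P", 1:4), cols))
  vals["P1", 4:6] <- 1e6            # 3 valid in one group, 0 elsewhere
  vals["P2", ] <- 2e6               # complete but contaminant
  vals["P3", c(1, 2, 4, 5, 7, 8, 10, 11, 13, 14)] <- 3e6  # 2 per group
  vals["P4", ] <- 4e6               # complete and clean
  pt <- ProteinExperiment(vals, accession = paste0("P", 1:4),
                          population = rep(pops, each = 3),
                          contaminant = c(FALSE, TRUE, FALSE, FALSE))
  filt <- filterProteins(pt, min_valid = 3)
  expect_identical(rownames(filt), c("P1", "P4"))   # P2 flagged, P3 sparse
  expect_identical(scaleType(filt), "log2")
  expect_equal(SummarizedExperiment::assay(filt)["P4", 1], log2(4e6))
})

test_that("downshifted-normal imputation matches its distributional contract", {
  set.seed(1)
  n_obs <- 2000
  n_miss <- 10000
  obs <- rnorm(n_obs, 25, 2)
  vals <- matrix(c(obs, rep(NA_real_, n_miss)), ncol = 1)
  rownames(vals) <- paste0("P", seq_len(nrow(vals)))
  colnames(vals) <- "NAIVE_R1"
  pt <- ProteinExperiment(vals, accession = rownames(vals),
                          population = "NAIVE", scale = "log2")
  imp <- imputeMissing(pt, shift = 1.8, width = 0.3, seed = 9)
  drawn <- SummarizedExperiment::assay(imp)[is.na(vals[, 1]), 1]
  mu <- mean(obs); sig <- sd(obs)
  target_mean <- mu - 1.8 * sig
  target_sd <- 0.3 * sig
  se_mean <- target_sd / sqrt(n_miss)
  se_sd <- target_sd / sqrt(2 * (n_miss - 1))
  expect_lt(abs(mean(drawn) - target_mean), 3 * se_mean)
  expect_lt(abs(sd(drawn) - target_sd), 3 * se_sd)
  ## determinism and identity without missing values
  imp2 <- imputeMissing(pt, shift = 1.8, width = 0.3, seed = 9)
  expect_identical(SummarizedExperiment::assay(imp),
                   SummarizedExperiment::assay(imp2))
  full <- ProteinExperiment(matrix(obs, ncol = 1,
                                   dimnames = list(paste0("Q", 1:n_obs),
                                                   "NAIVE_R1")),
                            accession = paste0("Q", 1:n_obs),
                            population = "NAIVE", scale = "log2")
  expect_identical(SummarizedExperiment::assay(imputeMissing(full, seed = 1)),
                   SummarizedExperiment::assay(full))
})
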