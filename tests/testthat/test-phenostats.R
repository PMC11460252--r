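mkPlate <- function(cond, cells, rep, counts) {
  row <- data.frame(condition_id = cond, cells_plated = cells,
                    replicate = rep, stringsAsFactors = FALSE)
  full <- stats::setNames(rep(0L, 6), morphologyClasses())
  full[names(counts)] <- counts
  cbind(row, as.data.frame(as.list(full)))
}

test_that("percent CFUs per plated cell and plate averaging", {
  p1 <- mkPlate("a", 300L, 1L, c(CFU_GM = 30L))
  r1 <- cfuPercent(p1)
  expect_equal(r1$pct_cfu, 10)
  plates <- rbind(p1, mkPlate("a", 100L, 2L, c(BFU_E = 10L)))
  r2 <- cfuPercent(plates)
  expect_equal(r2$pct_cfu, 10)
  expect_equal(r2$n_plates, 2L)
})

test_that("plating efficiency is recovered within Poisson bounds", {
  m <- defaultEffectModel()
  m$noiseSd <- 0; m$slope <- 0; m$intercept <- 24; m$nDonors <- 1L
  ph <- simulatePhenotypes(c(x = 50), m, seed = 61)
  r <- cfuPercent(ph$cfu)
  # 6 plates at rates 72/24/6 colonies; 3-sigma on the mean percentage
  lambda <- 0.24 * m$platedCells
  sigmaPct <- sqrt(sum((100 / m$platedCells)^2 * lambda * m$nReplicates)) /
    (length(m$platedCells) * m$nReplicates)
  expect_lte(abs(r$pct_cfu - 24), 3 * sigmaPct)
})

test_that("lineage proportions split erythroid/myeloid and exclude CFU-GEMM", {
  p <- mkPlate("a", 300L, 1L, c(BFU_E = 20L, CFU_GM = 20L, CFU_GEMM = 5L))
  r <- lineageProportions(p)
  expect_equal(r$erythroid_pct, 50)
  expect_equal(r$myeloid_pct, 50)
  expect_equal(r$gemm_count, 5L)
  p2 <- mkPlate("b", 300L, 1L, c(CFU_E = 10L))
  r2 <- lineageProportions(p2)
  expect_equal(r2$erythroid_pct, 100)
  expect_equal(r2$myeloid_pct, 0)
  expect_error(lineageProportions(mkPlate("c", 300L, 1L, c(CFU_GEMM = 3L))),
               "zero classified")
  # binomial recovery of a 60/40 split
  set.seed(62)
  n <- 200
  ery <- rbinom(1, n, 0.6)
  p3 <- mkPlate("d", 300L, 1L, c(BFU_E = ery, CFU_GM = n - ery))
  r3 <- lineageProportions(p3)
  expect_lte(abs(r3$erythroid_pct - 60), 3 * sqrt(0.6 * 0.4 / n) * 100)
})

test_that("purity-clonogenicity regression matches the normal-equations oracle", {
  # exact line (perfect-fit warning from summary.lm is expected here)
  r <- suppressWarnings(purityCfuRegression(c(0, 1, 2, 5), c(1, 3, 5, 11)))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  # symmetric case: slope 0, r2 0
  r0 <- purityCfuRegression(c(0, 1, 2), c(0, 1, 0))
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  expect_equal(r0$r_squared, 0, tolerance = 1e-12)
  # noisy case against closed-form least squares
  set.seed(63)
  x <- runif(20, 0, 100)
  y <- 5 + 0.2 * x + rnorm(20, 0, 2)
  r2 <- purityCfuRegression(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(r2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r2$slope, beta[2], tolerance = 1e-10)
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (20 - 2)
  se <- sqrt(sigma2 * solve(t(X) %*% X)[2, 2])
  tstat <- beta[2] / se
  expect_equal(r2$p_value, 2 * pt(-abs(tstat), df = 18), tolerance = 1e-10)
  expect_equal(r2$r_squared, cor(x, y)^2, tolerance = 1e-10)
  expect_error(purityCfuRegression(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(purityCfuRegression(c(1, 2), c(1, 2)), "3 points")
})

test_that("delta-delta-Ct arithmetic and scale consistency", {
  expect_equal(ddctFoldChange(24, 18, 26, 18), 4)
  expect_equal(ddctFoldChange(c(24, 24.2), c(18, 17.8), c(24, 24.2),
                              c(18, 17.8)), 1)
  expect_error(ddctFoldChange(24, numeric(), 26, 18), "present")
  # adding a constant to every Ct of condition AND mock leaves fold intact
  f1 <- ddctFoldChange(25, 18, 27, 19)
  f2 <- ddctFoldChange(25 + 3, 18 + 3, 27 + 3, 19 + 3)
  expect_equal(f1, f2)
  # adding c to the target only multiplies fold by 2^-c
  f3 <- ddctFoldChange(25 + 2, 18, 27, 19)
  expect_equal(f3, f1 * 2^-2)
})

test_that("fold-change matrix recovers planted expression effects", {
  m <- defaultEffectModel()
  m$ctSd <- 0.1
  truthFold <- 0.5
  m$geneSensitivity[] <- 0
  m$geneSensitivity["FAS"] <- log2(truthFold) / 50 # purity 50 -> fold 0.5
  ph <- simulatePhenotypes(c(x = 50), m, seed = 64)
  fc <- foldChangeMatrix(ph$ct)
  expect_lte(abs(fc["FAS", "x"] - truthFold) / truthFold, 0.10)
  expect_lte(max(abs(log2(fc[setdiff(rownames(fc), "FAS"), "x"]))), 0.3)
  # missing beta-actin errors
  ct2 <- ph$ct[ph$ct$gene != "ACTB", ]
  expect_error(foldChangeMatrix(ct2), "ACTB")
})

test_that("heatmap table is log2 with errors naming missing cells", {
  folds <- matrix(c(1, 4, 2, 0.5), 2, 2,
                  dimnames = list(c("FAS", "BAX"), c("a", "b")))
  h <- expressionHeatmapTable(folds)
  expect_equal(h["FAS", "a"], 0)
  expect_equal(h["BAX", "a"], 2)
  expect_equal(h["BAX", "b"], -1)
  foldsNA <- folds; foldsNA["FAS", "b"] <- NA
  expect_error(expressionHeatmapTable(foldsNA), "FAS x b")
  # TSV round trip
  path <- tempfile(fileext = ".tsv")
  writeMatrixTsv(h, path)
  expect_equal(readMatrixTsv(path), h)
})

test_that("Welch comparison assigns stars and matches a permutation oracle", {
  idGroups <- groupCompare(c(5, 5, 5), c(5, 5, 5))
  expect_equal(idGroups$p_value, 1)
  expect_equal(idGroups$stars, "")
  sep <- groupCompare(c(0, 0, 0), c(10, 10, 10.0001))
  expect_lt(sep$p_value, 0.0001)
  expect_equal(sep$stars, "****")
  # star thresholds
  expect_equal(groupCompare(c(1, 2, 3), c(1, 2, 3))$stars, "")
  # exhaustive permutation oracle on a 6+6 planted shift
  set.seed(65)
  a <- rnorm(6, 0, 1)
  b <- rnorm(6, 1.4, 1)
  welchP <- groupCompare(a, b)$p_value
  pooled <- c(a, b)
  combs <- utils::combn(12, 6)
  obs <- abs(mean(a) - mean(b))
  stat <- apply(combs, 2, function(idx) {
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  permP <- mean(stat >= obs - 1e-12)
  expect_lte(abs(welchP - permP), 0.02)
})

test_that("regression slope CI covers the generating slope in >= 90% of runs", {
  m <- defaultEffectModel()
  m$nDonors <- 1L
  purity <- stats::setNames(seq(10, 95, length.out = 8),
                            paste0("prep", 1:8))
  covered <- 0L
  nRuns <- 100L
  for (s in seq_len(nRuns)) {
    ph <- simulatePhenotypes(purity, m, seed = 1000 + s)
    r <- cfuPercent(ph$cfu)
    fit <- purityCfuRegression(purity[r$condition_id], r$pct_cfu)
    if (fit$ci[1] <= m$slope && m$slope <= fit$ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})

test_that("viability summaries are descriptive means and sds", {
  m <- defaultEffectModel()
  ph <- simulatePhenotypes(c(dirty = 30, clean = 95), m, seed = 66)
  vs <- viabilitySummary(ph$viability)
  expect_setequal(unique(vs$condition_id), c("dirty", "clean"))
  expect_true(all(vs$n == m$nDonors))
  d1 <- vs[vs$day == 1, ]
  expect_gt(d1$mean[d1$condition_id == "clean"],
            d1$mean[d1$condition_id == "dirty"])
})
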