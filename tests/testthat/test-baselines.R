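test_that("LOD imputation completes the matrix at the LOD before MOD", {
  ce <- toy_cqe(lod = 35)
  imp <- imputeLOD(ce)
  expect_false(anyNA(imp))
  ## hand oracle: censored cell participates in both passes at 35
  m <- cqValues(ce)
  m[isCensored(ce)] <- 35
  a <- m - rowMeans(m)
  expected <- sweep(a, 2, colMeans(a))
  expect_equal(unname(imp), unname(expected), ignore_attr = TRUE)
  ## no censoring: identical to plain MOD
  sim <- simulateCqExperiment(nTargets = 4, groupSizes = c(A = 3, B = 3),
                              nDE = 0, seed = 2)
  expect_equal(unname(imputeLOD(sim)),
               unname(modNormalize(sim)$normalized), ignore_attr = TRUE)
})

test_that("MNV+1 fills with the per-target max normalized value plus one", {
  x <- rbind(t1 = c(-1.2, 0.3, NA), t2 = c(0.5, NA, NA), t3 = c(1, 2, 3))
  out <- imputeMNV1(x)
  expect_equal(unname(out["t1", 3]), 1.3)
  expect_equal(unname(out["t2", 2:3]), c(1.5, 1.5))   # ties
  expect_equal(out["t3", ], x["t3", ])                # identity without UV
  ## imputed values sit exactly 1 above every expressed value of the target
  for (t in rownames(x)) {
    expr <- x[t, !is.na(x[t, ])]
    expect_true(all(out[t, is.na(x[t, ])] == max(expr) + 1))
  }
  expect_error(imputeMNV1(rbind(c(NA, NA))), "fully censored")
})

test_that("KNN imputation averages the nearest expressed neighbours", {
  ## duplicate rows at distance zero: k = 1 copies the duplicate
  x <- rbind(t1 = c(1, 2, 3, 4), t2 = c(1, 2, 3, NA),
             t3 = c(10, 9, 8, 7), t4 = c(0, 0, 0, 0), t5 = c(5, 5, 5, 5))
  out <- imputeKNN(x, k = 1)
  expect_equal(unname(out["t2", 4]), 4)
  ## 5-target hand-computable case, k = 2: distances from t2 over
  ## pairwise-complete samples pick t1 (0) and t4/t5 by scaled distance
  d_t1 <- sqrt(sum((x["t2", 1:3] - x["t1", 1:3])^2) * 4 / 3)
  d_t4 <- sqrt(sum((x["t2", 1:3] - x["t4", 1:3])^2) * 4 / 3)
  d_t5 <- sqrt(sum((x["t2", 1:3] - x["t5", 1:3])^2) * 4 / 3)
  d_t3 <- sqrt(sum((x["t2", 1:3] - x["t3", 1:3])^2) * 4 / 3)
  ord <- order(c(d_t1, d_t3, d_t4, d_t5))
  nn <- c("t1", "t3", "t4", "t5")[ord][1:2]
  out2 <- imputeKNN(x, k = 2)
  expect_equal(unname(out2["t2", 4]), mean(x[nn, 4]))
  ## identity with no unexpressed cells
  expect_equal(unname(imputeKNN(x[-2, ], k = 2)), unname(x[-2, ]),
               ignore_attr = TRUE)
  expect_error(imputeKNN(x, k = 5), "k \\+ 1")
  ## fewer than k expressed neighbours at the sample: falls back, warns
  y <- rbind(t1 = c(1, NA), t2 = c(1.1, NA), t3 = c(0.9, 2), t4 = c(1, NA))
  expect_warning(imputeKNN(y, k = 3), "fewer than k")
})

test_that("sequential t and Wilcoxon behave as documented", {
  x <- rbind(t1 = rep(1, 8), t2 = c(rnorm(4, 0, 0.1), rnorm(4, 2, 0.1)))
  grp <- rep(c("A", "B"), each = 4)
  res <- suppressWarnings(sequentialTest(x, grp))
  ## identical values: delta 0, p 1 (with a warning)
  expect_equal(res$delta_hat[1], 0)
  expect_equal(res$p_value[1], 1)
  expect_warning(sequentialTest(x[1, , drop = FALSE], grp), "zero variance")
  ## clearly separated groups: tiny p, delta = group-mean difference
  expect_lt(res$p_value[2], 1e-6)
  expect_equal(res$delta_hat[2], mean(x[2, 1:4]) - mean(x[2, 5:8]))
  ## pooled t equals the closed form
  a <- x[2, 1:4]; b <- x[2, 5:8]
  sp <- sqrt(((3) * var(a) + (3) * var(b)) / 6)
  tstat <- (mean(a) - mean(b)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(res$stat[2], tstat, tolerance = 1e-10)
})

test_that("wilcoxon on tied values matches the tie-corrected z oracle", {
  set.seed(3)
  for (r in 1:8) {
    a <- c(round(rnorm(6, 0, 1), 1), 2.5, 2.5)   # forced ties (MNV+1 style)
    b <- c(round(rnorm(6, 1, 1), 1), 2.5)
    x <- matrix(c(a, b), 1, dimnames = list("t", NULL))
    res <- sequentialTest(x, rep(c("A", "B"), c(8, 7)), test = "wilcoxon")
    expect_equal(res$p_value, wilcox_z_oracle(a, b), tolerance = 1e-10)
  }
})

test_that("with zero censoring all three imputation pipelines coincide", {
  sim <- simulateCqExperiment(nTargets = 12, groupSizes = c(A = 6, B = 6),
                              nDE = 4, seed = 14)
  res <- lapply(c("LOD", "MNV1", "KNN"), function(m)
    baselineDE(sim, method = m))
  expect_equal(res[[1]]$p_value, res[[2]]$p_value, tolerance = 1e-12)
  expect_equal(res[[1]]$p_value, res[[3]]$p_value, tolerance = 1e-12)
  expect_equal(res[[1]]$delta_hat, res[[3]]$delta_hat, tolerance = 1e-12)
})

test_that("baselineDE applies the removal rule and records it", {
  sim <- simulateCqExperiment(nTargets = 6, groupSizes = c(A = 6, B = 6),
                              nDE = 0, seed = 4)
  cq <- cqValues(sim)
  cq[1, 1:11] <- 45
  ce <- CqExperiment(cq, group = groupLabels(sim), lod = 40)
  res <- baselineDE(ce, method = "MNV1", removalThreshold = 0.8)
  expect_false(rownames(ce)[1] %in% res$target_id)
  expect_equal(attr(res, "removed")$target_id, rownames(ce)[1])
})
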