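test_that("the generator is reproducible and honours its configuration", {
  a <- simulateCqExperiment(nTargets = 10, groupSizes = c(A = 5, B = 5),
                            nDE = 4, seed = 123)
  b <- simulateCqExperiment(nTargets = 10, groupSizes = c(A = 5, B = 5),
                            nDE = 4, seed = 123)
  expect_equal(cqValues(a), cqValues(b))
  truth <- S4Vectors::metadata(a)$truth
  expect_equal(sum(truth$delta != 0), 4L)
  expect_equal(sum(truth$delta), 0)            # up/down balanced
  expect_equal(sum(isCensored(a)), 0L)
  ## sigma -> 0 limit: group means equal per target when delta = 0
  tiny <- simulateCqExperiment(nTargets = 3, groupSizes = c(A = 6, B = 6),
                               nDE = 0, sigma = 1e-4, betaSD = 0, seed = 1)
  cq <- cqValues(tiny); grp <- groupLabels(tiny)
  expect_lt(max(abs(rowMeans(cq[, grp == "A"]) -
                    rowMeans(cq[, grp == "B"]))), 1e-3)
})

test_that("injected effects match their empirical group-mean difference", {
  sim <- simulateCqExperiment(nTargets = 3, groupSizes = c(A = 5000,
                                                           B = 5000),
                              nDE = 2, delta = 2, sigma = 1, betaSD = 0,
                              seed = 42)
  truth <- S4Vectors::metadata(sim)$truth
  cq <- cqValues(sim); grp <- groupLabels(sim)
  emp <- rowMeans(cq[, grp == "A"]) - rowMeans(cq[, grp == "B"])
  expect_equal(unname(emp), unname(truth$delta), tolerance = 0.1)
})

test_that("nullifyGroups equalizes normalized group means to 1e-10", {
  sim <- simulateCqExperiment(nTargets = 9, groupSizes = c(A = 7, B = 5),
                              nDE = 4, seed = 31)
  nl <- nullifyGroups(sim)
  nm <- modNormalize(nl)$normalized
  grp <- groupLabels(nl)
  d <- rowMeans(nm[, grp == "A"]) - rowMeans(nm[, grp == "B"])
  expect_lt(max(abs(d)), 1e-10)
  expect_equal(S4Vectors::metadata(nl)$truth$delta,
               setNames(numeric(9), rownames(nl)))
  ## already-null data needs no shift
  nl2 <- nullifyGroups(nl)
  expect_equal(cqValues(nl2), cqValues(nl), tolerance = 1e-9)
  ## censored data are rejected
  expect_error(nullifyGroups(censorAtFraction(sim, 0.2)), "fully observed")
})

test_that("the sweep censors from the top with sound bookkeeping", {
  sim <- simulateCqExperiment(nTargets = 6, groupSizes = c(A = 6, B = 6),
                              nDE = 2, sigma = 0.8, seed = 17)
  sw <- suppressWarnings(
    censoringSweep(sim, methods = c("LOD", "MNV1"), stride = 5,
                   maxCensoredFraction = 0.4))
  steps <- unique(sw[, c("step", "lod", "n_censored")])
  steps <- steps[order(steps$step), ]
  ## LOD strictly decreasing, censored count non-decreasing
  expect_true(all(diff(steps$lod[-1]) < 0))
  expect_true(all(diff(steps$n_censored) >= 0))
  ## censored count at step s equals the count of values >= that lod
  cq <- cqValues(sim)
  for (r in 2:nrow(steps))
    expect_equal(steps$n_censored[r], sum(cq >= steps$lod[r]))
  ## step 0 is the fully observed state
  expect_equal(steps$n_censored[1], 0L)
  ## removal events are logged with estimates absent
  rem <- sw[sw$removed, ]
  if (nrow(rem)) expect_true(all(is.na(rem$delta_hat)))
})

test_that("at step 0 all methods agree and the summary scores them", {
  sim <- simulateCqExperiment(nTargets = 8, groupSizes = c(A = 8, B = 8),
                              nDE = 4, delta = 2, sigma = 0.7, seed = 19)
  sw <- suppressWarnings(
    censoringSweep(sim, stride = 1000, maxCensoredFraction = 0.05, k = 5))
  s0 <- sw[sw$step == 0, ]
  wide <- split(s0$delta_hat, s0$method)
  ## no-censoring equivalence across all four methods
  expect_equal(wide$UCNR, wide$LOD, tolerance = 1e-6)
  expect_equal(wide$LOD, wide$MNV1, tolerance = 1e-12)
  expect_equal(wide$LOD, wide$KNN, tolerance = 1e-12)
  sm <- sweepSummary(sw)
  s0m <- sm[sm$step == 0, ]
  expect_true(all(abs(s0m$bias) < 0.5))
  expect_true(all(s0m$rmse < 1))
  expect_equal(sort(unique(sm$method)), c("KNN", "LOD", "MNV1", "UCNR"))
})

test_that("robustness proportion follows its definition", {
  trace <- data.frame(step = rep(c(0, 1, 2, 3), 2),
                      lod = rep(c(Inf, 33, 32, 31), 2),
                      n_censored = rep(c(0, 1, 2, 3), 2),
                      method = rep(c("UCNR", "LOD"), each = 4),
                      target_id = "t1",
                      delta_hat = 2,
                      p_value = c(0.001, 0.01, 0.2, 0.3,
                                  0.001, 0.04, 0.04, 0.04),
                      censored_fraction = rep(c(0, 0.1, 0.2, 0.3), 2),
                      removed = FALSE)
  class(trace) <- c("ucnr_sweep", "data.frame")
  ## fails first at step 2 -> the fraction at that step
  expect_equal(robustnessProportion(trace, "t1", "UCNR"), 0.2)
  ## never fails: the fraction at the last step it was present
  expect_equal(robustnessProportion(trace, "t1", "LOD"), 0.3)
  ## a truly-null target is rejected when truth is attached
  attr(trace, "truth") <- list(delta = c(t1 = 2, t2 = 0))
  expect_error(robustnessProportion(trace, "t2", "UCNR"),
               "not differentially expressed")
})
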