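test_that("with no censoring the fit reproduces the least-squares solution", {
  sim <- simulateCqExperiment(nTargets = 10, groupSizes = c(A = 10, B = 10),
                              nDE = 4, seed = 21)
  fit <- fitUCNR(sim)
  expect_true(fit@converged)
  dc <- deltaContrasts(fit)
  ## closed-form oracle: group-mean differences of MOD-normalized values
  nm <- modNormalize(sim)$normalized
  grp <- groupLabels(sim)
  md <- rowMeans(nm[, grp == "A"]) - rowMeans(nm[, grp == "B"])
  expect_equal(dc$delta_hat, unname(md[dc$target_id]), tolerance = 1e-6)
})

test_that("single-target fit matches a grid/profile search of the likelihood", {
  set.seed(31)
  y <- c(rnorm(8, 30, 1), rnorm(8, 32, 1))
  m <- matrix(y, 1, 16, dimnames = list("t1", paste0("s", 1:16)))
  ce <- CqExperiment(m, group = rep(c("A", "B"), each = 8), lod = 31.5)
  expect_gt(sum(isCensored(ce)), 2)
  fit <- suppressWarnings(fitUCNR(ce))
  expect_true(fit@converged)
  co <- ucnrCoef(fit)
  delta_fit <- deltaContrasts(fit)$delta_hat

  ## brute-force oracle: iterative grid refinement over (m1, m2, sigma)
  yv <- cqValues(ce)[1, ]; cen <- isCensored(ce)[1, ]
  g1 <- groupLabels(ce) == "A"
  ll <- function(m1, m2, s) {
    mu <- ifelse(g1, m1, m2)
    sum(dnorm(yv[!cen], mu[!cen], s, log = TRUE)) +
      sum(pnorm((31.5 - mu[cen]) / s, lower.tail = FALSE, log.p = TRUE))
  }
  ctr <- c(mean(yv[g1]), mean(yv[!g1]), 1)
  width <- c(2, 2, 0.9)
  for (pass in 1:8) {
    grid <- expand.grid(m1 = seq(ctr[1] - width[1], ctr[1] + width[1],
                                 length.out = 11),
                        m2 = seq(ctr[2] - width[2], ctr[2] + width[2],
                                 length.out = 11),
                        s = seq(max(0.1, ctr[3] - width[3]),
                                ctr[3] + width[3], length.out = 11))
    vals <- mapply(ll, grid$m1, grid$m2, grid$s)
    ctr <- unlist(grid[which.max(vals), ])
    width <- width / 4
  }
  expect_equal(delta_fit, unname(ctr[1] - ctr[2]), tolerance = 1e-3)
  expect_equal(unname(co$sigma), unname(ctr[3]), tolerance = 1e-3)
})

test_that("final log-likelihood improves on the LOD-imputed starting point", {
  sim <- simulateCqExperiment(nTargets = 8, groupSizes = c(A = 8, B = 8),
                              nDE = 2, seed = 12)
  cen <- censorAtFraction(sim, 0.3)
  fit <- suppressWarnings(fitUCNR(cen))
  ## rebuild the deterministic initializer used by the optimizer
  d <- fit@design
  XtX <- Matrix::crossprod(d$X)
  eta0 <- as.vector(Matrix::solve(XtX, Matrix::crossprod(d$X, d$obs$y)))
  res <- d$obs$y - as.vector(d$X %*% eta0)
  rs <- vapply(seq_len(d$I), function(t) {
    r <- res[d$obs$i == t]
    if (length(r) >= 2) sd(r) else 0.05
  }, numeric(1))
  ll0 <- -ucnr_negll(c(eta0, log(pmax(rs, 0.05))), d)
  expect_gte(ucnrLogLik(fit), ll0)
})

test_that("estimates and standard errors are invariant to the coding", {
  sim <- simulateCqExperiment(nTargets = 8, groupSizes = c(A = 8, B = 8),
                              nDE = 2, seed = 5)
  cen <- censorAtFraction(sim, 0.25)
  ctl <- list(gtol = 1e-9)
  f1 <- suppressWarnings(fitUCNR(cen, control = ctl))
  ## permuting targets and samples changes which coefficients are
  ## constrained (a different full-rank coding of the same model)
  set.seed(99)
  perm <- cen[sample(nrow(cen)), sample(ncol(cen))]
  f2 <- suppressWarnings(fitUCNR(perm, control = ctl))
  d1 <- deltaContrasts(f1); d2 <- deltaContrasts(f2)
  m <- match(d1$target_id, d2$target_id)
  expect_equal(d1$delta_hat, d2$delta_hat[m], tolerance = 1e-8)
  expect_equal(d1$se, d2$se[m], tolerance = 1e-6)
})

test_that("parameter recovery sharpens with sample size", {
  set.seed(404)
  sizes <- c(10, 50, 250)
  reps <- c(24, 10, 6)
  bias <- mapply(function(npg, nrep) {
    errs <- replicate(nrep, {
      ## a tight baseline range keeps 30% censoring spread over all
      ## targets, so none is removed and the centered estimand stays the
      ## injected truth
      sim <- simulateCqExperiment(nTargets = 6,
                                  groupSizes = c(A = npg, B = npg),
                                  nDE = 2, delta = 2, sigma = 1,
                                  targetRange = c(26, 28))
      cen <- censorAtFraction(sim, 0.3)
      fit <- suppressWarnings(fitUCNR(cen, hessian = FALSE))
      dc <- deltaContrasts(fit)
      tr <- S4Vectors::metadata(sim)$truth
      mean(dc$delta_hat - tr$delta[dc$target_id])
    })
    abs(mean(errs))
  }, sizes, reps)
  expect_lt(bias[[3]], 0.05)
  expect_lt(bias[[3]], bias[[1]])
})

test_that("removal rule and degenerate-group handling are reported", {
  m <- matrix(28, nrow = 4, ncol = 10,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:10)))
  m[, 6:10] <- 29
  m <- m + matrix(rnorm(40, 0, 0.5), 4)
  m[1, ] <- c(rep(26, 5), rep(40, 5))    # group B fully censored
  m[2, 1:9] <- 40                        # 90% censored: removed
  ce <- CqExperiment(m, group = rep(c("A", "B"), each = 5), lod = 35)
  fit <- suppressWarnings(fitUCNR(ce))
  expect_equal(fit@removed$target_id, "t2")
  expect_false("t2" %in% deltaContrasts(fit)$target_id)
  expect_true(any(grepl("t1.*group B fully censored", fit@notes)))
  ## the pinned group mean sits at the plausibility boundary above the LOD
  expect_gt(ucnrFitted(fit)["t1", "s6"], 35)
  ## at threshold 1 only fully censored targets are removed
  m2 <- m
  m2[2, ] <- 40
  ce2 <- CqExperiment(m2, group = rep(c("A", "B"), each = 5), lod = 35)
  fit2 <- suppressWarnings(fitUCNR(ce2, modelSpec(removalThreshold = 1)))
  expect_equal(fit2@removed$target_id, "t2")
})

test_that("the covariance matrix is symmetric positive semi-definite", {
  sim <- simulateCqExperiment(nTargets = 6, groupSizes = c(A = 8, B = 8),
                              nDE = 2, seed = 8)
  cen <- censorAtFraction(sim, 0.2)
  fit <- suppressWarnings(fitUCNR(cen))
  V <- fit@vcov
  expect_equal(V, t(V), tolerance = 1e-10)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8 * max(abs(ev))))
  expect_true(is.finite(ucnrLogLik(fit)))
})

test_that("the flat parameter export matches the fit", {
  sim <- simulateCqExperiment(nTargets = 5, groupSizes = c(A = 6, B = 6),
                              nDE = 2, seed = 13)
  fit <- suppressWarnings(fitUCNR(censorAtFraction(sim, 0.15)))
  tab <- ucnrParameters(fit)
  expect_equal(tab$estimate, unname(fit@theta))
  expect_equal(tab$se, unname(sqrt(pmax(diag(fit@vcov), 0))))
  expect_true(all(c("name", "estimate", "se") %in% names(tab)))
})
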