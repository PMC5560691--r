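test_that("undetermined tokens and above-LOD values become censored at the LOD", {
  df <- data.frame(sample_id = rep(c("s1", "s2"), each = 3),
                   target_id = rep(c("t1", "t2", "t3"), 2),
                   cq = c("24.1", "Undetermined", "31.2",
                          "25.0", "30.4", "41.2"),
                   group = rep(c("A", "B"), each = 3))
  path <- write_long_csv(df)
  ce <- readCqTable(path, format = "long", lod = 40)
  expect_s4_class(ce, "CqExperiment")
  expect_equal(dim(ce), c(3L, 2L))
  ## sentinel maps to a censored observation stored at the LOD
  expect_true(isCensored(ce)["t2", "s1"])
  expect_equal(cqValues(ce)["t2", "s1"], 40)
  ## 41.2 >= lod is censored at 40 as well
  expect_true(isCensored(ce)["t3", "s2"])
  expect_equal(cqValues(ce)["t3", "s2"], 40)
  expect_equal(sum(isCensored(ce)), 2L)
})

test_that("wide format parses, with transpose support", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("target_id,s1,s2",
               "t1,24.5,26.0",
               "t2,Undetermined,33.1"), path)
  samp <- data.frame(sample_id = c("s1", "s2"), group = c("A", "B"))
  ce <- readCqTable(path, format = "wide", lod = 35, samples = samp)
  expect_equal(rownames(ce), c("t1", "t2"))
  expect_true(isCensored(ce)["t2", "s1"])

  patht <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,t1,t2",
               "s1,24.5,Undetermined",
               "s2,26.0,33.1"), patht)
  cet <- readCqTable(patht, format = "wide", lod = 35, samples = samp,
                     transpose = TRUE)
  expect_equal(cqValues(cet), cqValues(ce))
})

test_that("parse and validation errors are informative", {
  df <- data.frame(sample_id = c("s1", "s1"), target_id = c("t1", "t1"),
                   cq = c("24", "25"), group = c("A", "A"))
  expect_error(readCqTable(write_long_csv(df), "long", lod = 40),
               "duplicate.*s1.*t1")
  df2 <- data.frame(sample_id = c("s1", "s2"), target_id = c("t1", "t1"),
                    cq = c("24", "oops"), group = c("A", "B"))
  expect_error(readCqTable(write_long_csv(df2), "long", lod = 40),
               "non-numeric.*oops")
  df3 <- data.frame(sample_id = c("s1", "s2"), target_id = c("t1", "t1"),
                    cq = c("24", "25"))
  samp <- data.frame(sample_id = "s1", group = "A")
  expect_error(readCqTable(write_long_csv(df3), "long", lod = 40,
                           samples = samp),
               "unknown group label.*s2")
  expect_error(readCqTable(write_long_csv(df3), "long", lod = 40),
               "group")
})

test_that("missing tokens give missing wells, not censored ones", {
  df <- data.frame(sample_id = c("s1", "s2"), target_id = c("t1", "t1"),
                   cq = c("24", "missing"), group = c("A", "B"))
  ce <- readCqTable(write_long_csv(df), "long", lod = 40)
  expect_true(is.na(cqValues(ce)["t1", "s2"]))
  expect_true(is.na(isCensored(ce)["t1", "s2"]))
})

test_that("long-form export round-trips a dataset exactly", {
  sim <- simulateCqExperiment(nTargets = 5, groupSizes = c(A = 4, B = 3),
                              nDE = 2, nReference = 1, seed = 10)
  cen <- censorAtFraction(sim, 0.2)
  path <- tempfile(fileext = ".tsv")
  writeCqTable(cen, path)
  back <- readCqTable(path, "long", lod = lodValue(cen))
  expect_equal(cqValues(back), cqValues(cen))
  expect_equal(isCensored(back), isCensored(cen))
  expect_equal(as.character(groupLabels(back)),
               as.character(groupLabels(cen)))
  expect_equal(isReference(back), isReference(cen))
  ## idempotence: a second write/read cycle is identical
  path2 <- tempfile(fileext = ".tsv")
  writeCqTable(back, path2)
  expect_equal(readLines(path), readLines(path2))
})

test_that("results tables round-trip at full numeric precision", {
  res <- data.frame(target_id = c("t1", "t2"),
                    delta_hat = c(1.23456789012, -0.5),
                    se = c(0.1111111111, 0.2),
                    wald_stat = c(11.1, -2.5),
                    p_value = c(3.58e-5, 0.01234),
                    p_adj = c(7.16e-5, 0.01234),
                    fc = 2^c(1.23456789012, -0.5),
                    fc_ci_low = c(1.21, NA),
                    fc_ci_high = c(1.86, NA),
                    n_censored_per_group = c("2/5", "0/0"))
  path <- tempfile(fileext = ".tsv")
  writeResults(res, path)
  lines <- readLines(path)
  expect_length(lines, 3L)     # header + one line per target, input order
  back <- readResults(path)
  expect_equal(back$target_id, res$target_id)
  for (col in c("delta_hat", "se", "wald_stat", "p_value", "p_adj", "fc"))
    expect_equal(back[[col]], res[[col]], tolerance = 1e-9)
  expect_error(writeResults(res[0, ], tempfile()), "non-empty")
})

test_that("censored count is monotone in the LOD", {
  sim <- simulateCqExperiment(nTargets = 8, groupSizes = c(A = 6, B = 6),
                              nDE = 2, seed = 3)
  lods <- quantile(cqValues(sim), c(0.9, 0.7, 0.5, 0.3))
  counts <- integer(0)
  dat <- sim
  for (L in lods) {
    dat <- censorAtLod(dat, L)
    counts <- c(counts, sum(isCensored(dat)))
  }
  expect_true(all(diff(counts) >= 0))
  ## lowering the lod never uncensors: recensoring at the lowest directly
  direct <- censorAtLod(sim, lods[4])
  expect_equal(isCensored(direct), isCensored(dat))
})
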