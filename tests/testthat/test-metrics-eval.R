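test_that("trial averaging reproduces the reference column", {
  df <- sunflowerTrials()
  av <- averageTrials(df)
  expect_equal(av$mean_measured_deg,
               c(103, 90, 91.5, 75.5, 96.5, 74, 76, 95, 83, 100.5))
  expect_equal(averageTrials(data.frame(trial1_deg = 5, trial2_deg = 5))
               $mean_measured_deg, 5)
  expect_error(averageTrials(data.frame(trial1_deg = 1)), "MISSING_TRIAL")
  expect_error(averageTrials(data.frame(trial1_deg = 1, trial2_deg = NA)),
               "MISSING_TRIAL")
})

test_that("metrics match hand-derived values on the toy example", {
  rec <- data.frame(mean_measured_deg = c(1, 2, 3),
                    predicted_deg = c(1, 2, 4))
  r <- computeMetrics(rec)
  expect_equal(r@maeDeg, 1 / 3)
  expect_equal(r@rmseDeg, 1 / sqrt(3))
  expect_equal(r@r2, 0.5)                 # SSres 1, SStot 2
  # perfect fit
  perf <- computeMetrics(data.frame(mean_measured_deg = c(70, 90, 110),
                                    predicted_deg = c(70, 90, 110)))
  expect_equal(perf@rmseDeg, 0); expect_equal(perf@maeDeg, 0)
  expect_equal(perf@r2, 1)
  # symmetric errors (-1, 0, 1): skewness 0, sample sd 1
  sym <- computeMetrics(data.frame(mean_measured_deg = c(10, 20, 30),
                                   predicted_deg = c(9, 20, 31)))
  expect_equal(sym@errorSkewness, 0)
  expect_equal(sym@errorSd, 1)
  # constant actuals: r2 flagged undefined, the rest intact
  const <- computeMetrics(data.frame(mean_measured_deg = c(90, 90),
                                     predicted_deg = c(91, 89)))
  expect_true(is.na(const@r2))
  expect_equal(const@rmseDeg, 1)
  expect_error(computeMetrics(data.frame(mean_measured_deg = 1,
                                         predicted_deg = 1)),
               "TOO_FEW_RECORDS")
})

test_that("metrics agree with brute-force summation and rmse >= mae always", {
  set.seed(111)
  for (i in 1:25) {
    n <- sample(3:60, 1)
    y <- runif(n, 60, 130)
    yh <- y + rnorm(n, 0, 4)
    r <- computeMetrics(data.frame(mean_measured_deg = y,
                                   predicted_deg = yh))
    expect_equal(r@rmseDeg, sqrt(sum((y - yh)^2) / n), tolerance = 1e-12)
    expect_equal(r@maeDeg, sum(abs(y - yh)) / n, tolerance = 1e-12)
    expect_equal(r@r2, 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    expect_gte(r@rmseDeg, r@maeDeg)
    # r2 invariant to a common constant shift
    r2b <- computeMetrics(data.frame(mean_measured_deg = y + 37,
                                     predicted_deg = yh + 37))@r2
    expect_equal(r2b, r@r2, tolerance = 1e-9)
  }
})

test_that("interval decomposition partitions records and recombines SSres", {
  set.seed(121)
  y <- runif(40, 65, 115)
  rec <- data.frame(mean_measured_deg = y,
                    predicted_deg = y + rnorm(40, 0, 3))
  iv <- list(c(70, 80), c(100, 110))
  sub <- intervalBreakdown(rec, iv)
  expect_named(sub, c("[70, 80]", "[100, 110]", "other"))
  # membership equals brute-force filtering
  for (j in 1:2) {
    member <- y >= iv[[j]][1] & y <= iv[[j]][2]
    expect_equal(sub[[j]]@n, sum(member))
    expect_equal(sub[[j]]@rmseDeg,
                 sqrt(mean((rec$predicted_deg[member] - y[member])^2)))
  }
  # pooled SSres over the partition equals the global SSres
  ssres <- vapply(sub, function(r) r@n * r@rmseDeg^2, numeric(1))
  glob <- computeMetrics(rec)
  expect_equal(sum(ssres), glob@n * glob@rmseDeg^2, tolerance = 1e-9)
  # all records in one interval: sub-report equals the global report
  one <- intervalBreakdown(rec, list(c(0, 200)))
  expect_equal(one[["[0, 200]"]]@rmseDeg, glob@rmseDeg)
  expect_equal(one[["[0, 200]"]]@r2, glob@r2)
  # empty interval flagged with n = 0
  emp <- intervalBreakdown(rec, list(c(300, 310)))
  expect_equal(emp[["[300, 310]"]]@n, 0L)
  expect_error(intervalBreakdown(rec, list(c(70, 90), c(80, 100))),
               "OVERLAPPING")
})

test_that("angle CSVs parse, validate and round-trip", {
  ref <- system.file("extdata", "sunflower_trials.csv", package = "DiskTilt")
  rec <- readAngleCsv(ref)
  expect_equal(nrow(rec), 10L)
  expect_equal(rec$mean_measured_deg, averageTrials(sunflowerTrials())$mean_measured_deg)
  expect_equal(rec$predicted_deg, sunflowerTrials()$predicted_deg)
  # write-then-read round trip preserves values exactly
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec[, c("plant_id", "trial1_deg", "trial2_deg", "predicted_deg")],
            f, row.names = FALSE)
  rec2 <- readAngleCsv(f)
  expect_equal(rec2, rec)
  # malformed inputs
  writeLines("plant,one,two", f)
  expect_error(readAngleCsv(f), "MALFORMED_HEADER")
  writeLines("plant_id,trial1_deg,trial2_deg", f)
  expect_error(readAngleCsv(f), "EMPTY_DATA")
  writeLines(c("plant_id,trial1_deg,trial2_deg", "1,abc,90"), f)
  expect_error(readAngleCsv(f), "NON_NUMERIC")
})

test_that("metric reports serialize to JSON and CSV", {
  rec <- averageTrials(sunflowerTrials())
  rep <- computeMetrics(rec)
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  writeMetricsReport(rep, fj, fc)
  back <- jsonlite::fromJSON(fj)
  expect_equal(back$rmse_deg, rep@rmseDeg)
  expect_equal(back$mae_deg, rep@maeDeg)
  expect_equal(back$r2, rep@r2)
  expect_equal(read.csv(fc)$n, 10L)
})
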