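makePairs <- function(model, rater, ...) {
  data.frame(model_category = model, rater_category = rater, ...,
             stringsAsFactors = FALSE)
}

test_that("agreement counts exact category matches", {
  p <- makePairs(rep("0-90", 10), rep("0-90", 10))
  expect_equal(categoricalAgreement(p)@fraction, 1.0)

  p2 <- makePairs(c("0", "0-90", "90-180", "180-270"),
                  c("0", "0-90", "90-180", "270-360"))
  a <- categoricalAgreement(p2)
  expect_equal(a@nAgree, 3L)
  expect_equal(a@nTotal, 4L)
  expect_equal(a@fraction, 0.75)
  expect_error(categoricalAgreement(p2[0, ]), "empty")
})

test_that("agreement stratifies and is invariant to record order", {
  p <- makePairs(c(rep("0-90", 6), rep("90-180", 4)),
                 c(rep("0-90", 5), "0", rep("90-180", 3), "0"),
                 vessel_class = c(rep("arterial", 6), rep("venous", 4)))
  a <- categoricalAgreement(p, stratifyBy = "vessel_class")
  expect_equal(sort(a@strata$nTotal), c(4L, 6L))
  expect_equal(a@strata$nAgree[a@strata$stratum == "arterial"], 5L)
  expect_equal(a@strata$nAgree[a@strata$stratum == "venous"], 3L)

  set.seed(1)
  perm <- sample(nrow(p))
  expect_equal(categoricalAgreement(p[perm, ])@fraction, a@fraction)
  expect_error(categoricalAgreement(p, stratifyBy = "nope"), "stratifier")
})

test_that("model categories are validated against the degree binning", {
  p <- makePairs("0-90", "0-90", model_degrees = 95)  # 95 bins to 90-180
  expect_error(categoricalAgreement(p), "inconsistent")
  p2 <- makePairs("90-180", "0-90", model_degrees = 95)
  expect_equal(categoricalAgreement(p2)@fraction, 0)
})

test_that("per-group summaries match independent order-statistics on a
           12-record fixture", {
  deg <- c(0, 0, 0, 0,              # group "0"
           10, 20, 30,              # group "0-90"
           100, 120, 150, 160, 170) # group "90-180"
  p <- data.frame(rater_category = c(rep("0", 4), rep("0-90", 3),
                                     rep("90-180", 5)),
                  model_degrees = deg, stringsAsFactors = FALSE)
  expect_message(s <- summarizeByRaterGroup(p), "absent")
  expect_equal(s$rater_category, c("0", "0-90", "90-180"))
  expect_equal(s$n, c(4L, 3L, 5L))
  expect_equal(s$median[1], 0)
  expect_equal(s$q1[1], 0)
  expect_equal(s$q3[1], 0)
  expect_equal(s$median[2], 20)
  g3 <- deg[8:12]
  expect_equal(s$median[3], oracleQuantile(g3, 0.5))
  expect_equal(s$q1[3], oracleQuantile(g3, 0.25))
  expect_equal(s$q3[3], oracleQuantile(g3, 0.75))
  expect_setequal(attr(s, "missing_groups"), c("180-270", "270-360"))
})

test_that("one-way ANOVA matches the definitional sums of squares", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  got <- oneWayAnova(g)
  want <- oracleAnova(g)
  expect_equal(got@F, want$F, tolerance = 1e-12)
  expect_equal(got@p, want$p, tolerance = 1e-12)
  expect_equal(got@dfBetween, 1L)
  expect_equal(got@dfWithin, 4L)

  # equal group means: F = 0
  expect_equal(oneWayAnova(list(c(1, 3), c(2, 2)))@F, 0)

  set.seed(7)
  g2 <- list(rnorm(8), rnorm(5, mean = 1), rnorm(12, mean = 2))
  got2 <- oneWayAnova(g2)
  want2 <- oracleAnova(g2)
  expect_equal(got2@F, want2$F, tolerance = 1e-12)
  expect_equal(got2@p, want2$p, tolerance = 1e-12)
})

test_that("ANOVA invariances and degenerate inputs", {
  set.seed(3)
  g <- list(rnorm(6), rnorm(4, 1), rnorm(5, 2))
  f1 <- oneWayAnova(g)@F
  expect_equal(oneWayAnova(rev(g))@F, f1, tolerance = 1e-10)
  expect_equal(oneWayAnova(lapply(g, function(x) x + 100))@F, f1,
               tolerance = 1e-6)

  expect_error(oneWayAnova(list(c(1, 2))), "two groups")
  expect_error(oneWayAnova(list(1, 2)), "two or more values")
  deg <- oneWayAnova(list(c(1, 1), c(2, 2)))
  expect_equal(deg@F, Inf)
  expect_equal(deg@p, 0)
  same <- oneWayAnova(list(c(5, 5), c(5, 5)))
  expect_equal(same@F, 0)
  expect_equal(same@p, 1)
})

test_that("rater CSVs are validated on read", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(case_id = c("a", "a"), vessel = c("SMA", "PV"),
                       rater_category = c("0-90", "0")), f,
            row.names = FALSE)
  df <- readRaterCategories(f)
  expect_equal(nrow(df), 2L)

  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(case_id = "a", vessel = "SMA",
                       rater_category = "45-90"), f2, row.names = FALSE)
  expect_error(readRaterCategories(f2), "categories")
  f3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(case_id = "a", vessel = "aorta",
                       rater_category = "0"), f3, row.names = FALSE)
  expect_error(readRaterCategories(f3), "vessels")
})

test_that("pairWithTruth aligns measured reports with phantom truth", {
  ph <- makeMultiVesselPhantom(c(CeTr = 0, HA = 0, SMA = 90, SMV = 0,
                                 PV = 0))
  rep <- quantifyVolume(ph$volume)
  pairs <- pairWithTruth(list(rep), list(ph$truth))
  expect_equal(nrow(pairs), 5L)
  expect_setequal(pairs$vessel, vesselNames())
  expect_equal(pairs$model_category, binDegree(pairs$model_degrees))
  a <- categoricalAgreement(pairs)
  expect_gte(a@fraction, 0.8)
})
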