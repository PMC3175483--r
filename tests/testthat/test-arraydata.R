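test_that("delimited tables round-trip through read/write with values preserved", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tp1\tp2\tp3", "s1\t1\t2\t3", "s2\t4\t5\t6"), f)
  x <- readIntensityTable(f, format = "tsv",
                          labelMap = c(s1 = "a", s2 = "b"))
  expect_s4_class(x, "PeptideArrayExperiment")
  expect_equal(dim(rfu(x)), c(3L, 2L))
  expect_equal(unname(rfu(x)["p2", "s2"]), 5)
  expect_equal(groupLabels(x), c("a", "b"))

  # round trip at higher precision values
  set.seed(1)
  vals <- matrix(runif(12, 100, 60000), 3, 4,
                 dimnames = list(paste0("s", 1:3), paste0("p", 1:4)))
  x2 <- PeptideArrayExperiment(vals, groups = c("a", "a", "b"))
  f2 <- tempfile(fileext = ".tsv")
  writeIntensityTable(x2, f2)
  x3 <- readIntensityTable(f2, format = "tsv")
  expect_equal(rfu(x3), rfu(x2), tolerance = 1e-6)
})

test_that("GPR dialect is parsed, empty spots flagged by name token", {
  d <- tempdir()
  f1 <- writeDemoGPR(file.path(d, "sampleA.gpr"),
                     ids = c("V1", "V2", "V3", "V4"),
                     names = c("pep1", "empty", "pep3", "pep4"),
                     values = c(210, 180, 3000, 950))
  f2 <- writeDemoGPR(file.path(d, "sampleB.gpr"),
                     ids = c("V1", "V2", "V3", "V4"),
                     names = c("pep1", "empty", "pep3", "pep4"),
                     values = c(250, 190, 2500, 1100))
  x <- readIntensityTable(c(f1, f2), format = "gpr",
                          labelMap = c(sampleA = "normal",
                                       sampleB = "single_tumor"))
  expect_equal(colnames(x), c("sampleA", "sampleB"))
  expect_equal(unname(emptySpots(x)), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(unname(rfu(x)["V3", "sampleB"]), 2500)
  # missing signal column is a format error
  f3 <- file.path(d, "bad.gpr")
  writeLines(gsub("F635 Median", "Other", readLines(f1)), f3)
  expect_error(readIntensityTable(f3, format = "gpr"), "signal column")
})

test_that("malformed tables raise validation errors naming the problem", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tp1\tp1\tp2", "s1\t1\t2\t3", "s2\t4\t5\t6"), f)
  expect_error(readIntensityTable(f, format = "tsv"), "duplicate peptide")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tp1\tp2\tp3", "s1\t1\t-2\t3", "s2\t4\t5\t6"), f2)
  expect_error(readIntensityTable(f2, format = "tsv"), "negative intensity")
  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tp1\tp2\tp3", "s1\t1\tzz\t3", "s2\t4\t5\t6"), f3)
  expect_error(readIntensityTable(f3, format = "tsv"), "non-numeric")
  expect_error(PeptideArrayExperiment(matrix(1:6, 2, 3,
                                             dimnames = list(c("s", "s"),
                                                             NULL))),
               "unique")
})

test_that("median normalization equalizes sample medians on the log10 scale", {
  m <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("p1", "p2", "p3")))
  x <- medianNormalizeLog10(PeptideArrayExperiment(m, c("a", "b")))
  v <- normalizedValues(x)
  # pure scale difference: identical rows after normalization
  expect_equal(v[, "s1"], v[, "s2"])
  expect_equal(length(unique(round(apply(10^v, 2, median), 9))), 1L)
  # constants recover each raw array median
  expect_equal(unname(apply(10^v, 2, median) / normConstants(x)),
               unname(apply(rfu(x), 2, median)))
  # a sample whose values span decades: median element maps to log10(median)
  m2 <- matrix(c(10, 100, 1000, 10, 100, 1000), nrow = 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("p1", "p2", "p3")))
  x2 <- medianNormalizeLog10(PeptideArrayExperiment(m2, c("a", "b")))
  expect_equal(unname(normalizedValues(x2)["p2", "s1"]), log10(100))
  # zeros are an error when the offset guard is disabled
  m3 <- m2; m3[1, 1] <- 0
  expect_error(medianNormalizeLog10(PeptideArrayExperiment(m3, c("a", "b")),
                                    zeroOffset = 0), "zero")
  expect_silent(medianNormalizeLog10(PeptideArrayExperiment(m3, c("a", "b"))))
})

test_that("normalization is idempotent", {
  set.seed(7)
  vals <- matrix(10^rnorm(50 * 6, 2.5, 0.4), 6, 50,
                 dimnames = list(paste0("s", 1:6), paste0("p", 1:50)))
  # introduce per-sample scale bias
  vals <- sweep(vals, 1, c(0.5, 1, 2, 1.5, 0.8, 1.2), `*`)
  x1 <- medianNormalizeLog10(PeptideArrayExperiment(vals, rep("a", 6)))
  back <- t(10^normalizedValues(x1))   # samples x peptides, RFU scale
  x2 <- medianNormalizeLog10(PeptideArrayExperiment(back, rep("a", 6)))
  expect_lt(max(abs(normalizedValues(x2) - normalizedValues(x1))), 1e-9)
})

test_that("group descriptives match hand computation and algebraic identities", {
  m <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("p", 1:4)))
  d <- describeGroups(PeptideArrayExperiment(m, c("g1", "g2")))
  g1 <- d[d$group == "g1", ]
  expect_equal(g1$mean, 2.5)
  expect_equal(g1$minimum, 1)
  expect_equal(g1$maximum, 4)
  expect_equal(g1$range, 3)
  # identities on randomized fixtures
  set.seed(11)
  for (i in 1:5) {
    vals <- matrix(runif(8 * 20, 0, 65500), 8, 20,
                   dimnames = list(paste0("s", 1:8), paste0("p", 1:20)))
    groups <- sample(c("a", "b", "c"), 8, replace = TRUE)
    if (length(unique(groups)) < 2) groups[1:2] <- c("a", "b")
    d <- describeGroups(PeptideArrayExperiment(vals, groups))
    expect_equal(d$variance, d$std_deviation^2, tolerance = 1e-9)
    expect_equal(d$range, d$maximum - d$minimum)
    expect_true(all(d$minimum <= d$mean & d$mean <= d$maximum))
  }
})
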