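test_that("the 25-run cyclic design reproduces the printed calibration block", {
  d <- brereton_design(low = 10, high = 30, analytes = c("LCZ", "MLK"))
  conc <- as.matrix(d$concentrations[c("LCZ", "MLK")])
  dimnames(conc) <- list(NULL, c("LCZ", "MLK"))
  expect_equal(conc, table1_calibration())
  expect_equal(unname(conc[1, ]), c(20, 20))      # center-point first run
  # balance: each of the five levels occurs exactly five times per analyte
  for (a in c("LCZ", "MLK")) {
    expect_equal(as.vector(table(conc[, a])), rep(5L, 5))
  }
  # coded columns: zero-sum, orthogonal, cyclic-shift related
  coded <- as.matrix(d$coded)
  expect_equal(colSums(coded), c(LCZ = 0, MLK = 0))
  expect_equal(sum(coded[, 1] * coded[, 2]), 0)
  expect_equal(coded[, 2], c(coded[-1, 1], coded[1, 1]),
               ignore_attr = TRUE)
})

test_that("design codes map linearly onto arbitrary ranges", {
  d <- brereton_design(low = c(2, 50), high = c(10, 150),
                       analytes = c("x", "y"))
  expect_equal(d$concentrations$x[1], 6)    # center of 2-10
  expect_equal(d$concentrations$y[1], 100)  # center of 50-150
  expect_equal(sort(unique(d$concentrations$x)), seq(2, 10, by = 2))
  expect_error(brereton_design(low = 10, high = 10), "degenerate")
  expect_error(brereton_design(n_levels = 3), "unsupported")
  expect_error(brereton_design(analytes = c("a", "b", "c")), "two analytes")
})

test_that("LHS places exactly one sample per stratum per analyte", {
  for (seed in c(1, 17, 902)) {
    d <- lhs_design(n_strata = 13, seed = seed)
    expect_equal(nrow(d$concentrations), 13L)
    for (a in d$analytes) {
      expect_equal(sort(d$strata[[a]]), 1:13)
      w <- (30 - 10) / 13
      stratum <- ceiling((d$concentrations[[a]] - 10) / w)
      expect_equal(sort(stratum), 1:13)
    }
  }
  # determinism under a fixed seed
  expect_equal(lhs_design(seed = 5), lhs_design(seed = 5))
  expect_error(lhs_design(n_strata = 1, seed = 1), "n_strata")
  expect_error(lhs_design(seed = 1, low = 10, high = 10), "positive")
})

test_that("LHS samples are uniform within strata over many draws", {
  # chi-square sanity check on the pooled within-stratum position
  draws <- unlist(lapply(1:100, function(s) {
    d <- lhs_design(n_strata = 5, seed = 7000 + s)
    (d$concentrations$analyte1 - 10) / 4
  }))
  pos <- draws - floor(draws)
  counts <- table(cut(pos, seq(0, 1, by = 0.1)))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("rounding that collapses samples is warned and recorded", {
  found <- FALSE
  for (s in 1:50) {
    d <- suppressWarnings(lhs_design(n_strata = 13, seed = s, round_to = 0))
    if (length(d$warnings) > 0) { found <- TRUE; break }
  }
  expect_true(found)  # integer rounding of 13 strata over 10-30 must collide
  expect_s3_class(d, "mixture_design")
  expect_named(d$concentrations_raw, d$analytes)
})

test_that("coverage diagnostics report orthogonality and occupancy", {
  cal <- brereton_design()
  diag <- coverage_diagnostics(cal)
  expect_equal(diag$coded_correlation, 0)
  expect_gt(diag$min_pair_distance, 0)
  val <- lhs_design(seed = 3)
  dv <- coverage_diagnostics(val)
  expect_equal(dv$stratum_occupancy$analyte1, rep(1L, 13))
  expect_equal(dv$stratum_occupancy$analyte2, rep(1L, 13))
  # degenerate single-sample design is flagged, not an error
  single <- val
  single$concentrations <- single$concentrations[1, ]
  single$strata <- single$strata[1, , drop = FALSE]
  ds <- coverage_diagnostics(single)
  expect_true(is.na(ds$min_pair_distance))
  expect_match(ds$flags, "single-sample", all = FALSE)
})

test_that("designs export to the concentrations CSV dialect", {
  d <- brereton_design(analytes = c("LCZ", "MLK"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(d, path)
  back <- read_concentrations(path)
  expect_equal(back$LCZ, d$concentrations$LCZ)
  expect_true(file.exists(sub("\\.csv$", "_coded.csv", path)))
})
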