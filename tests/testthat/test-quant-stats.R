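# Label-free statistics: transform, normalize, filter, impute, test

test_that("log2 transform maps zero to missing and powers of two exactly", {
  m <- matrix(c(4, 0, 8, 2, 1, 0), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  pg <- tinyProteinGroups(m, group = c("g1", "g2"))
  lm <- log2Transform(pg)
  expect_equal(logValues(lm)[, "a"], c(P1 = 2, P2 = NA, P3 = 3))
  expect_equal(logValues(lm)["P1", "b"], 1)
  expect_true(is.na(logValues(lm)["P3", "b"]))
  # all-zero row survives transform as all-missing
  m2 <- rbind(m, c(0, 0))
  pg2 <- tinyProteinGroups(m2, group = c("g1", "g2"))
  expect_true(all(is.na(logValues(log2Transform(pg2))[4, ])))
})

test_that("median normalization zeroes column medians and is idempotent", {
  v <- matrix(c(1, 2, 3, 5, NA, 7), 3, 2, dimnames = list(NULL, c("a", "b")))
  lm <- logIntensityMatrix(v, c("g1", "g2"))
  n1 <- medianNormalize(lm)
  expect_equal(logValues(n1)[, "a"], c(P1 = -1, P2 = 0, P3 = 1))
  expect_equal(logValues(n1)[, "b"], c(P1 = -1, P2 = NA, P3 = 1))
  expect_equal(apply(logValues(n1), 2, median, na.rm = TRUE),
               c(a = 0, b = 0))
  expect_equal(logValues(medianNormalize(n1)), logValues(n1))
  # an empty column is an error
  v[, 2] <- NA
  expect_error(medianNormalize(logIntensityMatrix(v, c("g1", "g2"))),
               "no present values")
})

test_that("valid-value filter keeps rows with >= minValid in some group", {
  v <- rbind(c(1, 2, 3, NA, NA, NA),   # 3 in A, 0 in B -> kept
             c(1, 2, NA, 3, 4, NA),    # 2 and 2 -> removed
             c(NA, NA, NA, 1, 2, 3))   # 0 and 3 -> kept
  colnames(v) <- paste0("s", 1:6)
  lm <- logIntensityMatrix(v, rep(c("A", "B"), each = 3))
  out <- filterMinValid(lm, 3L)
  expect_identical(rownames(logValues(out)), c("P1", "P3"))
  # minValid = 1 keeps any row with a value
  expect_identical(nrow(logValues(filterMinValid(lm, 1L))), 3L)
  # warning when a group is smaller than minValid
  expect_warning(filterMinValid(logIntensityMatrix(v[, 1:4],
                                                   c("A", "A", "A", "B")), 3L),
                 "exceeds")
})

test_that("downshift imputation follows the stated Gaussian law", {
  # a column whose present values have mean 20 and sd 1 exactly
  pres <- as.numeric(scale(stats::rnorm(100, 20, 1))) + 20
  v <- matrix(c(pres, rep(NA_real_, 10000)), ncol = 1,
              dimnames = list(NULL, "s1"))
  lm <- logIntensityMatrix(v, "g")
  out <- imputeGaussianDownshift(lm, width = 0.3, downshift = 1.8, seed = 99)
  imp <- logValues(out)[-(1:100), 1]
  expect_equal(mean(imp), 20 - 1.8, tolerance = 0.05 / 1.8)
  expect_equal(sd(imp), 0.3, tolerance = 0.03 / 0.3)
  # determinism and identity without missing values
  out2 <- imputeGaussianDownshift(lm, seed = 99)
  expect_identical(logValues(out), logValues(out2))
  full <- logIntensityMatrix(matrix(pres, ncol = 1,
                                    dimnames = list(NULL, "s1")), "g")
  expect_identical(logValues(imputeGaussianDownshift(full, seed = 1)),
                   logValues(full))
  # degenerate column rejected
  bad <- logIntensityMatrix(matrix(c(5, 5, 5, NA), ncol = 1,
                                   dimnames = list(NULL, "s1")), "g")
  expect_error(imputeGaussianDownshift(bad, seed = 1), "degenerate")
})

test_that("imputed values depend only on column statistics and seed", {
  set.seed(1)
  v <- matrix(rnorm(40, 20), 10, 4,
              dimnames = list(paste0("P", 1:10), paste0("s", 1:4)))
  v[c(2, 17, 35)] <- NA
  lm <- logIntensityMatrix(v, rep(c("A", "B"), each = 2))
  a <- logValues(imputeGaussianDownshift(lm, seed = 7))
  perm <- sample(nrow(v))
  lmP <- logIntensityMatrix(v[perm, ], rep(c("A", "B"), each = 2))
  b <- logValues(imputeGaussianDownshift(lmP, seed = 7))
  # permuting the rows permutes the imputed cells identically
  expect_equal(b[rownames(v), ], a)
})

test_that("pooled t-test matches the closed form and stats::t.test", {
  v <- rbind(c(0, 1, 2, 3), c(1, 2, 1, 2), c(5, 5, 5, 5))
  colnames(v) <- paste0("s", 1:4)
  lm <- logIntensityMatrix(v, c("T", "T", "C", "C"))
  res <- twoSampleTTest(lm, c("T", "C"))
  # hand-computed pooled t for {0,1} vs {2,3}: diff -2, sp^2 = 0.5, t = -2.828
  expect_equal(res$difference[1], -2)
  expect_equal(res$t[1], -2 / sqrt(0.5 * (0.5 + 0.5)), tolerance = 1e-12)
  tt <- stats::t.test(v[1, 1:2], v[1, 3:4], var.equal = TRUE)
  expect_equal(res$t[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-12)
  # identical groups: t = 0, p = 1 (zero-variance convention)
  expect_equal(res$t[3], 0)
  expect_equal(res$p[3], 1)
  expect_equal(res$difference[2], 0)
})

test_that("permutation FDR equals the exhaustive-enumeration oracle (3v3)", {
  for (seed in 1:3) {
    set.seed(seed)
    v <- matrix(rnorm(20 * 6, 20), 20, 6,
                dimnames = list(paste0("P", 1:20), paste0("s", 1:6)))
    v[1:2, 1:3] <- v[1:2, 1:3] + 4   # two shifted proteins
    lm <- logIntensityMatrix(v, rep(c("T", "C"), each = 3))
    res <- permutationFDR(lm, c("T", "C"), nPermutations = 250L, seed = 1)
    qOracle <- oraclePermutationFDR(v, rep(c("T", "C"), each = 3),
                                    c("T", "C"))
    expect_equal(res$q, unname(qOracle), tolerance = 1e-10)
  }
})

test_that("permutation FDR oracle agreement holds on 4v4 designs too", {
  set.seed(5)
  v <- matrix(rnorm(15 * 8, 20), 15, 8,
              dimnames = list(paste0("P", 1:15), paste0("s", 1:8)))
  v[1, 1:4] <- v[1, 1:4] + 5
  lm <- logIntensityMatrix(v, rep(c("T", "C"), each = 4))
  res <- permutationFDR(lm, c("T", "C"), nPermutations = 250L, seed = 1)
  qOracle <- oraclePermutationFDR(v, rep(c("T", "C"), each = 4), c("T", "C"))
  expect_equal(res$q, unname(qOracle), tolerance = 1e-10)
  # the planted protein ranks first
  expect_identical(which.min(res$q), 1L)
  expect_error(permutationFDR(
    logIntensityMatrix(matrix(rnorm(8), 2, 4,
                              dimnames = list(NULL, paste0("s", 1:4))),
                       c("T", "T", "C", "C")), c("T", "C")),
    NA)  # 4 samples, 5 distinct permutations: allowed
})

test_that("a single strongly shifted protein gets the smallest q", {
  set.seed(11)
  v <- matrix(rnorm(100 * 8, 20, 0.5), 100, 8,
              dimnames = list(paste0("P", 1:100), paste0("s", 1:8)))
  v[42, 1:4] <- v[42, 1:4] + 10
  lm <- logIntensityMatrix(v, rep(c("T", "C"), each = 4))
  res <- permutationFDR(lm, c("T", "C"), seed = 2)
  expect_identical(res$protein[which.min(res$q)], "P42")
  expect_true(all(res$q >= 0 & res$q <= 1))
})

test_that("enrichment pipeline logs monotone row counts and catches empties", {
  ds <- noiseFreeDataset(seed = 17)
  # add noise-free data but flag two rows to exercise the filter
  pg <- proteinGroups(ds)
  SummarizedExperiment::rowData(pg)$reverse[1:2] <- TRUE
  res <- enrichmentAnalysis(pg, sampleDesign(ds),
                            contrast = c("bait", "control"), seed = 3)
  expect_true(all(diff(res$stageLog$rows) <= 0))
  expect_identical(res$stageLog$rows[1] - res$stageLog$rows[2], 2L)
  # empty after filtering is an explicit error
  zero <- tinyProteinGroups(
    matrix(0, 3, 4, dimnames = list(NULL, paste0("s", 1:4))),
    group = rep(c("bait", "control"), each = 2))
  expect_error(enrichmentAnalysis(zero, contrast = c("bait", "control")),
               "no present values|no proteins left")
})

test_that("set overlap reproduces the published DEG percentages", {
  # weaker mutant: 1227 DEGs, 938 shared with the stronger mutant; the
  # stronger mutant's 3151 DEGs also share 12 with the rescue control, so
  # 3151 - 938 - 12 = 2201 are unique to it
  degB <- paste0("g", seq_len(1227))
  degW <- c(paste0("v", seq_len(12)), paste0("w", seq_len(17)))
  degA <- c(paste0("g", seq_len(938)), paste0("v", seq_len(12)),
            paste0("u", seq_len(2201)))
  ov <- setOverlap(degB, degA)
  expect_identical(ov$nIntersection, 938L)
  expect_identical(ov$pctAInBRounded, 76)   # 938 of 1227
  ov2 <- setOverlap(degA, union(degB, degW))
  expect_identical(ov2$pctAUniqueRounded, 70)  # 2201 of 3151 unique
  expect_identical(ov2$nA - ov2$nIntersection, 2201L)
  # identity and empty-set behaviour
  same <- setOverlap(degB, degB)
  expect_identical(same$pctAInBRounded, 100)
  empty <- setOverlap(character(0), degB)
  expect_true(is.na(empty$pctAInB))
  expect_identical(empty$emptySide, "A")
})
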