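# Complex proportions, mass balance, subunit ratios, differential binding

sixCatalog <- function() {
  ComplexCatalog(lapply(seq_len(6), function(i)
    list(name = paste0("CX", i), members = paste0("D", i),
         directBinders = paste0("D", i))))
}

test_that("direct-binder iBAQ sums partition into the published percentages", {
  mu <- setNames(c(49, 28, 15, 4, 3, 1), paste0("D", 1:6))
  ab <- complexProportions(ibaqTableFromMeans(mu), sixCatalog())
  expect_equal(unname(baitProportions(ab)),
               c(0.49, 0.28, 0.15, 0.04, 0.03, 0.01))
  expect_equal(abundanceTable(ab)$percent, c(49, 28, 15, 4, 3, 1))
  top3 <- sum(sort(abundanceTable(ab)$percent, decreasing = TRUE)[1:3])
  expect_identical(top3, 92)
  # single complex holds everything
  one <- complexProportions(ibaqTableFromMeans(c(D1 = 7)),
                            ComplexCatalog(list(list(name = "CX1",
                                                     members = "D1",
                                                     directBinders = "D1"))))
  expect_equal(unname(baitProportions(one)), 1)
})

test_that("proportions are scale-invariant and ignore non-catalog proteins", {
  mu <- setNames(c(49, 28, 15, 4, 3, 1), paste0("D", 1:6))
  base <- baitProportions(complexProportions(ibaqTableFromMeans(mu),
                                             sixCatalog()))
  scaled <- baitProportions(complexProportions(ibaqTableFromMeans(mu * 1e7),
                                               sixCatalog()))
  expect_equal(scaled, base, tolerance = 1e-12)
  extra <- baitProportions(complexProportions(
    ibaqTableFromMeans(c(mu, OTHER = 1e9)), sixCatalog()))
  expect_equal(extra, base, tolerance = 1e-12)
  # undetected direct binders contribute zero and are reported
  mu0 <- mu; mu0[["D6"]] <- 0
  ab0 <- complexProportions(ibaqTableFromMeans(mu0), sixCatalog())
  expect_equal(unname(baitProportions(ab0))[6], 0)
  expect_identical(abundanceTable(ab0)$undetectedDirectBinders[6], "D6")
  expect_error(complexProportions(ibaqTableFromMeans(
    setNames(rep(0, 6), paste0("D", 1:6))), sixCatalog()),
    "no direct binders")
})

test_that("interchangeable direct binders within a complex are summed", {
  cat <- ComplexCatalog(list(
    list(name = "MiDAC", members = c("MIDEAS", "TRERF1", "DNTTIP1"),
         directBinders = c("MIDEAS", "TRERF1")),
    list(name = "SIN3", members = "SIN3A", directBinders = "SIN3A")))
  mu <- c(MIDEAS = 30, TRERF1 = 10, DNTTIP1 = 5, SIN3A = 60)
  ab <- complexProportions(ibaqTableFromMeans(mu), cat)
  expect_equal(unname(baitProportions(ab)), c(0.4, 0.6))
})

test_that("bait mass balance divides binder sums by bait iBAQ", {
  # binder iBAQs summing to 91 against a bait iBAQ of 100
  mu <- c(setNames(0.91 * c(49, 28, 15, 4, 3, 1), paste0("D", 1:6)),
          BAIT = 100)
  ib <- ibaqTableFromMeans(mu)
  expect_equal(baitMassBalance(ib, "BAIT", sixCatalog()), 0.91)
  mu0 <- mu; mu0[paste0("D", 1:6)] <- 0
  expect_equal(baitMassBalance(ibaqTableFromMeans(mu0), "BAIT", sixCatalog()),
               0)
  expect_error(baitMassBalance(ibaqTableFromMeans(mu), "NOPE", sixCatalog()),
               "not detected")
  # over-assignment flagged
  muHot <- mu; muHot[["D1"]] <- 200
  expect_warning(baitMassBalance(ibaqTableFromMeans(muHot), "BAIT",
                                 sixCatalog()), "over-assigned")
})

test_that("noise-free simulation closes the mass-balance loop at 0.91", {
  ds <- noiseFreeDataset(occupancy = 0.91, seed = 23)
  truth <- groundTruth(ds)
  ib <- computeIbaq(proteinGroups(ds), fastaSequences(ds),
                    design = sampleDesign(ds), treatmentGroup = "bait")
  mb <- baitMassBalance(ib, baitId(truth), asComplexCatalog(truth))
  expect_equal(mb, 0.91, tolerance = 1e-9)
  # mass balance times bait copies equals total bound copies
  cn <- copyNumbers(truth)
  bound <- sum(unlist(lapply(truth@complexes, function(cx)
    cn[cx$directBinders])))
  expect_equal(mb * cn[[baitId(truth)]], bound, tolerance = 1e-9)
})

test_that("subunit ratios report iBAQ quotients in R:1 style", {
  mu <- c(MBD3 = 5e7, MBD2 = 5e6, CHD4 = 2e7, CHD3 = 2e7, GHOST = 0)
  ib <- ibaqTableFromMeans(mu)
  r <- subunitRatio(ib, "MBD3", "MBD2")
  expect_equal(r$ratio, 10)
  expect_identical(r$formatted, "10.0:1")
  expect_equal(subunitRatio(ib, "CHD4", "CHD3")$ratio, 1)
  expect_true(subunitRatio(ib, "MBD3", "GHOST")$undefined)
  expect_error(subunitRatio(ib, "MBD3", "MISSING"), "not in the iBAQ")
})

test_that("noise-free copy ratios survive iBAQ normalization exactly", {
  ds <- noiseFreeDataset(proportions = c(0.7, 0.3), nBackground = 0,
                         seed = 31)
  truth <- groundTruth(ds)
  ib <- computeIbaq(proteinGroups(ds), fastaSequences(ds),
                    design = sampleDesign(ds), treatmentGroup = "bait")
  cn <- copyNumbers(truth)
  members <- unlist(lapply(truth@complexes, `[[`, "members"))
  a <- members[1]; b <- members[2]
  expect_equal(subunitRatio(ib, a, b)$ratio, cn[[a]] / cn[[b]],
               tolerance = 1e-9)
})

test_that("differential binding matrix recovers a planted ablation pattern", {
  cat <- ComplexCatalog(list(
    list(name = "NuRD", members = paste0("N", 1:4),
         directBinders = "N1"),
    list(name = "MiDAC", members = paste0("M", 1:3), directBinders = "M1"),
    list(name = "SIN3", members = paste0("S", 1:4), directBinders = "S1")))
  comps <- c(paste0("N", 1:4), paste0("M", 1:3), paste0("S", 1:4))
  set.seed(77)
  wt <- matrix(rnorm(length(comps) * 8, 25, 0.2), length(comps), 8,
               dimnames = list(comps, paste0("s", 1:8)))
  mut <- wt
  ablated <- c(paste0("N", 1:4), paste0("M", 1:3))
  mut[ablated, 1:4] <- mut[ablated, 1:4] - 6   # mutant loses NuRD + MiDAC
  lm <- logIntensityMatrix(mut, rep(c("mutant", "wt"), each = 4))
  res <- permutationFDR(lm, c("mutant", "wt"), seed = 1)
  bm <- differentialBindingMatrix(list(Y48E = res), cat)
  ld <- bindingLogDiff(bm)[, "Y48E"]
  expect_true(all(ld[paste("NuRD", paste0("N", 1:4), sep = ":")] < 0))
  expect_true(all(ld[paste("MiDAC", paste0("M", 1:3), sep = ":")] < 0))
  summ <- bindingSummary(bm)
  expect_identical(summ$decreased[summ$complex == "NuRD"], 4L)
  expect_identical(summ$decreased[summ$complex == "MiDAC"], 3L)
  expect_identical(summ$decreased[summ$complex == "SIN3"], 0L)
  expect_identical(summ$increased[summ$complex == "SIN3"], 0L)
})

test_that("identical mutant and reference data give zero differences", {
  cat <- ComplexCatalog(list(list(name = "C", members = c("A", "B"),
                                  directBinders = "A")))
  set.seed(3)
  v <- matrix(rnorm(2 * 8, 20), 2, 8,
              dimnames = list(c("A", "B"), paste0("s", 1:8)))
  v[, 1:4] <- v[, 5:8]
  lm <- logIntensityMatrix(v, rep(c("m", "w"), each = 4))
  res <- permutationFDR(lm, c("m", "w"), seed = 1)
  bm <- differentialBindingMatrix(list(mut = res), cat)
  expect_equal(unname(bindingLogDiff(bm)[, 1]), c(0, 0))
  # absent component flagged missing, not zero
  cat2 <- ComplexCatalog(list(list(name = "C", members = c("A", "B", "ZZ"),
                                   directBinders = "A")))
  bm2 <- differentialBindingMatrix(list(mut = res), cat2)
  expect_true(is.na(bindingLogDiff(bm2)["C:ZZ", 1]))
  expect_identical(bm2@direction["C:ZZ", 1], "missing")
  # no overlap at all is an error
  none <- res; none$protein <- paste0("X", seq_len(nrow(none)))
  expect_error(differentialBindingMatrix(list(mut = none), cat),
               "shares no proteins")
})
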