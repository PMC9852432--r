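## fitness fixture with an additive per-E-count effect plus a site-4 boost,
## built from the noise-free simulator
makeFitness <- function(perSite = rep(0.002, 8), nRep = 3) {
  spec <- fixAESpec
  pool <- poolGenotypes(spec)
  stMat <- do.call(rbind, strsplit(pool, ""))
  s <- setNames(as.vector((stMat == "E") %*% perSite), pool)
  s["WWWWWWWW"] <- 0
  cn <- simulatePool(competitionModel(pool, s = s), nRep, noise = FALSE)
  list(fit = estimateSC(cn, "WWWWWWWW", pseudocount = 0), s = s)
}

test_that("per-count groups have binomial sizes and pool replicate values", {
  res <- makeFitness()
  lib <- enumerateLibrary(fixAESpec)
  byK <- groupByCount(res$fit, "E", genotypes = lib)
  expect_identical(byK$k, 0:8)
  expect_equal(byK$n_genotypes, choose(8, 0:8))
  expect_identical(byK$n_values, as.integer(choose(8, 0:8) * 3))
  expect_identical(sum(byK$n_values), 256L * 3L)
})

test_that("additive fitness makes group medians linear in the E count", {
  res <- makeFitness()
  byK <- groupByCount(res$fit, "E", genotypes = enumerateLibrary(fixAESpec))
  expect_equal(byK$median, 0.002 * (0:8), tolerance = 1e-9)
  ## constant SC collapses every median to that constant
  resC <- makeFitness(perSite = rep(0, 8))
  byKC <- groupByCount(resC$fit, "E",
                       genotypes = enumerateLibrary(fixAESpec))
  expect_true(all(abs(byKC$median) < 1e-10))
})

test_that("per-site groups split the library in half and localize effects", {
  ## only site 4 (T460) carries an effect
  res <- makeFitness(perSite = c(0, 0, 0, 0.01, 0, 0, 0, 0))
  lib <- enumerateLibrary(fixAESpec)
  byS <- groupBySite(res$fit, fixScheme, genotypes = lib)
  expect_true(all(byS$n_genotypes == 128))
  expect_true(all(byS$n_values == 128 * 3))
  gap <- vapply(unique(byS$site), function(st) {
    abs(byS$median[byS$site == st & byS$state == "E"] -
        byS$median[byS$site == st & byS$state == "A"])
  }, 0)
  expect_identical(names(which.max(gap)), "T460")
  expect_equal(unname(gap["T460"]), 0.01, tolerance = 1e-9)
  expect_true(all(gap[names(gap) != "T460"] < 1e-10))
})

test_that("medians and quartiles match the sort-based oracle", {
  res <- makeFitness(perSite = seq(-0.004, 0.01, length.out = 8))
  lib <- enumerateLibrary(fixAESpec)
  byK <- groupByCount(res$fit, "E", genotypes = lib)
  k <- countState(lib, "E")
  for (i in seq_len(nrow(byK))) {
    vals <- as.vector(sc(res$fit)[match(lib[k == byK$k[i]],
                                        res$fit@genotype), ])
    expect_equal(byK$median[i], sortMedian(vals))
    expect_equal(byK$q25[i], sortQuantile(vals, 0.25))
    expect_equal(byK$q75[i], sortQuantile(vals, 0.75))
  }
})

test_that("Tukey whiskers and outliers follow the 1.5 IQR rule", {
  v <- c(1, 2, 3, 4, 100)  # 100 is an outlier
  st <- PhosphoScan:::tukeyStats(v)
  expect_equal(st$median, 3)
  expect_identical(st$outliers, 100)
  expect_equal(st$whisker_hi, 4)
  expect_equal(st$whisker_lo, 1)
})

test_that("the empirical CDF is monotone, right-continuous and ends at 1", {
  res <- makeFitness()
  cdf <- cumulativeSC(res$fit, genotypes = enumerateLibrary(fixAESpec))
  expect_true(all(diff(cdf$fraction) > 0))
  expect_equal(tail(cdf$fraction, 1), 1)
  ## single value: one step from 0 to 1
  one <- toyCounts(rbind(r = c(10, 10), g = c(10, 10)), c(0, 12), c(1, 1))
  fitOne <- estimateSC(one, "r", 0)
  cdf1 <- cumulativeSC(fitOne, genotypes = "g")
  expect_identical(nrow(cdf1), 1L)
  expect_equal(cdf1$fraction, 1)
  ## direct count check at an interior point
  vals <- c(-1, 0, 1)
  expect_equal(mean(vals <= 0), 2 / 3)
})

test_that("replicate correlations behave at the extremes", {
  res <- makeFitness(nRep = 3)
  r <- replicateCorrelation(res$fit)
  expect_equal(dim(r), c(3, 3))
  expect_true(all(abs(r - 1) < 1e-9))  # noise-free replicates are identical

  ## anti-correlated toy: build a two-replicate table by hand
  fit <- res$fit
  fit@sc <- cbind(`1` = c(0, 1, -1), `2` = c(0, -1, 1))
  fit@genotype <- c("WWWWWWWW", "x", "y")
  fit@scMean <- rowMeans(fit@sc)
  fit@scSD <- apply(fit@sc, 1, sd)
  fit@nReplicates <- rep(2L, 3)
  expect_equal(replicateCorrelation(fit)[1, 2], -1)

  fit@sc <- cbind(`1` = c(0, 0, 0), `2` = c(0, -1, 1))
  expect_error(replicateCorrelation(fit), "zero-variance")
})
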