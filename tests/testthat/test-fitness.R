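test_that("log2 fractions follow the pseudocount definition", {
  cn <- toyCounts(matrix(c(5, 5, 5, 5), 4, 1,
                         dimnames = list(letters[1:4], NULL)), 0, 1)
  lf <- log2Fractions(cn, pseudocount = 0)
  expect_true(all(lf == -2))

  cn2 <- toyCounts(matrix(c(0, 10), 2, 1,
                          dimnames = list(c("a", "b"), NULL)), 0, 1)
  lf2 <- log2Fractions(cn2, pseudocount = 0.5)
  expect_equal(as.vector(2^lf2), c(0.5 / 11, 10.5 / 11))

  ## scale invariance: doubling all counts at a timepoint changes nothing
  m <- matrix(c(3, 7, 6, 14), 2, 2, dimnames = list(c("a", "b"), NULL))
  lfA <- log2Fractions(toyCounts(m, c(0, 12), c(1, 1)), 0)
  expect_equal(lfA[, 1, 1], lfA[, 2, 1])
  expect_error(log2Fractions(toyCounts(matrix(0, 2, 1,
    dimnames = list(c("a", "b"), NULL)), 0, 1)), "all-zero")
})

test_that("SC is the OLS slope of log2 fraction minus the reference slope", {
  ## mutant/reference ratio gaining exactly +1 per 12 h: SC = 1/12
  tps <- seq(0, 72, by = 12)
  ref <- rep(1000, 7)
  mut <- 1000 * 2^(tps / 12)
  cn <- toyCounts(rbind(ref = ref, mut = mut), tps, rep(1, 7))
  fit <- estimateSC(cn, "ref", pseudocount = 0)
  expect_equal(unname(scMean(fit)["mut"]), 1 / 12, tolerance = 1e-12)
  expect_equal(unname(scMean(fit)["ref"]), 0)
  ## cross-check the internal OLS against lm() on the same log fractions
  lf <- log2Fractions(cn, 0)
  lmSlope <- unname(coef(lm(lf["mut", , 1] ~ tps))[2] -
                    coef(lm(lf["ref", , 1] ~ tps))[2])
  expect_equal(unname(scMean(fit)["mut"]), lmSlope, tolerance = 1e-10)
})

test_that("proportional counts give SC = 0 and reference SC is exactly 0", {
  tps <- seq(0, 72, by = 12)
  base <- c(100, 180, 320, 410, 520, 610, 700)
  m <- rbind(ref = base, mut = 3 * base)
  cn <- toyCounts(cbind(m, m), rep(tps, 2), rep(1:2, each = 7))
  fit <- estimateSC(cn, "ref", pseudocount = 0)
  expect_equal(unname(scMean(fit)["mut"]), 0, tolerance = 1e-12)
  expect_true(all(sc(fit)["ref", ] == 0))
})

test_that("selection coefficients are invariant to sequencing depth", {
  set.seed(23)
  tps <- seq(0, 72, by = 12)
  m <- matrix(rpois(4 * 7, 500), 4, 7,
              dimnames = list(c("r", "a", "b", "c"), NULL))
  fit1 <- estimateSC(toyCounts(m, tps, rep(1, 7)), "r", 0)
  scale <- matrix(rep(c(2, 5, 1, 10, 3, 7, 4), each = 4), 4, 7)
  fit2 <- estimateSC(toyCounts(m * scale, tps, rep(1, 7)), "r", 0)
  expect_equal(scMean(fit1), scMean(fit2), tolerance = 1e-10)
})

test_that("noise-free simulation is recovered exactly through the pipeline", {
  pool <- poolGenotypes(fixAESpec)
  set.seed(2)
  s <- setNames(runif(length(pool), -0.02, 0.02), pool)
  s["WWWWWWWW"] <- 0
  cn <- simulatePool(competitionModel(pool, s = s), 2, noise = FALSE)
  fit <- estimateSC(cn, "WWWWWWWW", pseudocount = 0)
  expect_lt(max(abs(scMean(fit) - s[names(scMean(fit))])), 1e-10)
})

test_that("enrichment matrix is zero at t0 and on the reference row", {
  pool <- c("WWWWWWWW", "EEEEEEEE", "AAAAAAAA")
  s <- c(WWWWWWWW = 0, EEEEEEEE = 0.01, AAAAAAAA = -0.02)
  cn <- simulatePool(competitionModel(pool, s = s), 1, noise = FALSE)
  enr <- enrichmentMatrix(cn, "WWWWWWWW", pseudocount = 0)
  expect_true(all(enr$mean[, "0"] == 0))
  expect_true(all(abs(enr$mean["WWWWWWWW", ]) < 1e-12))
  expect_equal(unname(enr$mean["EEEEEEEE", "72"]), 0.72, tolerance = 1e-10)
  ## SC equals the OLS slope of the enrichment row versus time
  fit <- estimateSC(cn, "WWWWWWWW", pseudocount = 0)
  tps <- as.numeric(colnames(enr$mean))
  slope <- unname(coef(lm(enr$mean["AAAAAAAA", ] ~ tps))[2])
  expect_equal(unname(scMean(fit)["AAAAAAAA"]), slope, tolerance = 1e-10)
})

test_that("pairwise SC handles the definition and its edge cases", {
  tps <- seq(0, 72, by = 12)
  flat <- data.frame(timepoint_h = tps, pct_mut = 50, pct_ref = 50)
  expect_equal(pairwiseSC(flat), 0)
  ratio <- 2^(0.02 * tps)
  p <- 100 * ratio / (1 + ratio)
  curve <- data.frame(timepoint_h = tps, pct_mut = p, pct_ref = 100 - p)
  expect_equal(pairwiseSC(curve), 0.02, tolerance = 1e-12)
  bad <- data.frame(timepoint_h = tps, pct_mut = c(100, p[-1]),
                    pct_ref = c(0, 100 - p[-1]))
  expect_error(pairwiseSC(bad), "truncate")
})

test_that("a missing reference genotype is an error", {
  cn <- toyCounts(matrix(1:4, 2, 2, dimnames = list(c("a", "b"), NULL)),
                  c(0, 12), c(1, 1))
  expect_error(estimateSC(cn, "zz"), "missing")
})
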