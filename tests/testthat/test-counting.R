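test_that("matcher builds unambiguously on the full allele set", {
  m <- buildMatcher(fixAlleles, 150L)
  expect_length(m$key, 257)
  expect_false(anyDuplicated(m$key) > 0)
  ## single allele is trivially unambiguous
  expect_silent(buildMatcher(fixAlleles[1], 150L))
})

test_that("alleles differing only outside both windows are an ambiguity error", {
  a <- strrep("A", 200)
  b <- a
  substr(b, 100, 100) <- "G"   # windows with readLength 80: 1-80 and 121-200
  al <- Biostrings::DNAStringSet(c(g1 = a, g2 = b))
  expect_error(buildMatcher(al, 80L), "ambiguity")
  expect_silent(buildMatcher(al, 110L))  # windows now cover position 100
})

test_that("exact-match counting assigns correct pairs and tallies discards", {
  g <- "AAAEEAAA"
  w <- mateWindows(as.character(fixAlleles[[g]]))
  dir <- withr::local_tempdir()
  r1 <- c(rep(w$r1, 10), w$r1, substr(strrep("A", 150), 1, 150))
  r2 <- c(rep(w$r2, 10), paste0("T", substr(w$r2, 2, 150)), w$r2)
  writeFastq(file.path(dir, "r1.fq"), r1)
  writeFastq(file.path(dir, "r2.fq"), r2)
  m <- buildMatcher(fixAlleles, 150L)
  res <- countReads(file.path(dir, "r1.fq"), file.path(dir, "r2.fq"), m)
  expect_identical(unname(res$counts[g]), 10L)
  expect_identical(sum(res$counts), 10L)
  expect_identical(unname(res$discards["mate2_mismatch"]), 1L)
  expect_identical(unname(res$discards["mate1_mismatch"]), 1L)
  expect_identical(sum(res$counts) + sum(res$discards), res$total)
})

test_that("malformed records are discarded with a reason, not assigned", {
  g <- names(fixAlleles)[1]
  w <- mateWindows(as.character(fixAlleles[[g]]))
  dir <- withr::local_tempdir()
  nr1 <- w$r1; substr(nr1, 5, 5) <- "N"
  writeFastq(file.path(dir, "r1.fq"), c(w$r1, nr1, substr(w$r1, 1, 100)))
  writeFastq(file.path(dir, "r2.fq"), c(w$r2, w$r2, w$r2))
  m <- buildMatcher(fixAlleles, 150L)
  res <- countReads(file.path(dir, "r1.fq"), file.path(dir, "r2.fq"), m)
  expect_identical(sum(res$counts), 1L)
  expect_identical(unname(res$discards["bad_characters"]), 1L)
  expect_identical(unname(res$discards["bad_length"]), 1L)
})

test_that("mate files of unequal record count are an input error", {
  dir <- withr::local_tempdir()
  w <- mateWindows(as.character(fixAlleles[[1]]))
  writeFastq(file.path(dir, "r1.fq"), c(w$r1, w$r1))
  writeFastq(file.path(dir, "r2.fq"), w$r2)
  m <- buildMatcher(fixAlleles, 150L)
  expect_error(countReads(file.path(dir, "r1.fq"), file.path(dir, "r2.fq"),
                          m), "unequal")
})

test_that("counting is invariant to read order", {
  set.seed(31)
  g <- sample(names(fixAlleles), 40, replace = TRUE)
  dir <- withr::local_tempdir()
  wins <- lapply(as.character(fixAlleles[g]), mateWindows)
  writeFastq(file.path(dir, "a1.fq"), vapply(wins, `[[`, "", "r1"))
  writeFastq(file.path(dir, "a2.fq"), vapply(wins, `[[`, "", "r2"))
  ord <- sample(length(g))
  writeFastq(file.path(dir, "b1.fq"), vapply(wins, `[[`, "", "r1")[ord])
  writeFastq(file.path(dir, "b2.fq"), vapply(wins, `[[`, "", "r2")[ord])
  m <- buildMatcher(fixAlleles, 150L)
  resA <- countReads(file.path(dir, "a1.fq"), file.path(dir, "a2.fq"), m)
  resB <- countReads(file.path(dir, "b1.fq"), file.path(dir, "b2.fq"), m)
  expect_identical(resA$counts, resB$counts)
})

test_that("FASTQ round trip at zero error rate reproduces simulator counts", {
  spec <- fixAESpec
  pool <- poolGenotypes(spec)
  m <- competitionModel(pool, s = 0, depth = 4000, nCycles = 1L)
  cn <- simulatePool(m, 1, noise = TRUE, seed = 17)
  man <- emitFastq(cn, fixAlleles, withr::local_tempdir(), seed = 2)
  counted <- countScreen(man, buildMatcher(fixAlleles, 150L))
  expect_equal(assay(counted, "counts")[rownames(cn), ],
               assay(cn, "counts"))
  d <- discardSummary(counted)
  expect_true(all(d$assigned == d$total))
})

test_that("count tables round-trip through the TSV interchange format", {
  m <- competitionModel(letters[1:3], s = c(0, 0.01, -0.01), depth = 1e3)
  cn <- simulatePool(m, 2, noise = TRUE, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(cn, path)
  back <- readCountTable(path)
  expect_equal(assay(back, "counts")[rownames(cn), colnames(cn)],
               assay(cn, "counts"))
  expect_equal(timepoints(back), timepoints(cn))
  ## column-rename adapter maps foreign schemas in
  df <- read.delim(path)
  names(df) <- c("allele", "rep", "hours", "n")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- readCountTable(path2, columns = c(genotype = "allele",
                                             replicate = "rep",
                                             timepoint_h = "hours",
                                             count = "n"))
  expect_equal(assay(back2, "counts"), assay(back, "counts"))
})
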