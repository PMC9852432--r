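test_that("six-tile plan over the 270-bp region keeps sites out of overlaps", {
  plan <- tileRegion(fixRegion, fixScheme, 6, c(21, 27))
  tab <- tilePlanTable(plan)
  expect_equal(nrow(tab), 6)
  ov <- width(plan@overlaps)
  expect_length(ov, 5)
  expect_true(all(ov >= 21 & ov <= 27))
  expect_identical(tab$start[1], 1L)
  expect_identical(tab$end[6], 270L)
  ## every site interior to exactly one tile, never inside an overlap
  expect_identical(sort(unlist(plan@siteIndex)), 1:8)
  ovBases <- unlist(Map(seq, start(plan@overlaps), end(plan@overlaps)))
  for (k in 1:8) {
    cod <- PhosphoScan:::siteCodonRange(fixScheme, k)
    expect_length(intersect(cod[1]:cod[2], ovBases), 0)
  }
})

test_that("degenerate single-tile plan is the whole region", {
  plan <- tileRegion(fixRegion, fixScheme, 1)
  expect_equal(length(plan@tiles), 1L)
  expect_identical(c(start(plan@tiles), end(plan@tiles)), c(1L, 270L))
  expect_length(plan@overlaps, 0)
})

test_that("two-tile toy solution matches an exhaustive cut-point scan", {
  ## 60-bp toy region, one site per tile, overlap exactly 20
  sch <- phosphositeScheme(c("s1", "s2"), c(3L, 16L), c("T", "S"),
                           c(1L, 20L))
  region <- paste(rep("GAT", 20), collapse = "")
  substr(region, 7, 12) <- "ACCCCT"   # site 1 codons (residues 3-4)
  substr(region, 46, 51) <- "TCCCCT"  # site 2 codons (residues 16-17)
  plan <- tileRegion(region, sch, 2, c(20, 20))
  ## oracle: enumerate all placements of a 20-bp interior window avoiding
  ## both site codon spans; leftmost wins
  feasible <- Filter(function(p) {
    w <- p:(p + 19)
    p >= 2 && max(w) <= 59 &&
      !any(w %in% 7:12) && !any(w %in% 46:51)
  }, 2:40)
  ## solver must also keep each site interior to one tile; check agreement
  ## with the first oracle placement that satisfies that too
  ok <- Filter(function(p) {
    tiles <- list(c(1, p + 19), c(p, 60))
    inT <- function(sp, t) sp[1] > t[1] && sp[2] < t[2]
    sum(vapply(tiles, inT, TRUE, sp = c(7, 12))) == 1 &&
      sum(vapply(tiles, inT, TRUE, sp = c(46, 51))) == 1
  }, feasible)
  expect_identical(start(plan@overlaps), as.integer(ok[[1]]))
  expect_identical(width(plan@overlaps), 20L)
})

test_that("infeasible tilings fail with a design error", {
  sch <- phosphositeScheme("s1", 1L, "T", c(1L, 3L))  # site at region edge
  region <- "ACCCCTGATGAT"                            # 12 bp, 4 codons
  expect_error(tileRegion(region, sch, 2, c(4, 4)), "design error")
})

test_that("assembly products reproduce the combinatorial library", {
  plan <- addTileVariants(tileRegion(fixRegion, fixScheme, 6), fixAESpec)
  tab <- tilePlanTable(plan)
  expect_equal(tab$n_variants, 2^tab$n_sites)
  expect_equal(prod(tab$n_variants), 256)
  ## overlap flanks identical across all variants of each tile
  for (i in seq_len(5)) {
    ovLen <- end(plan@tiles)[i] - start(plan@tiles)[i + 1] + 1
    lefts <- as.character(plan@variants[[i]])
    expect_length(unique(substr(lefts, nchar(lefts) - ovLen + 1,
                                nchar(lefts))), 1)
    rights <- as.character(plan@variants[[i + 1]])
    expect_length(unique(substr(rights, 1, ovLen)), 1)
  }
  pr <- enumerateAssemblyProducts(plan)
  expect_length(pr$products, 256)
  expect_equal(pr$nImpossible, 0)
  expect_true(all(Biostrings::width(pr$products) == 270))
  expect_setequal(names(pr$products), enumerateLibrary(fixAESpec))
  ## each product is byte-identical to the directly realized allele
  expect_setequal(unname(as.character(pr$products)),
                  unname(as.character(fixAlleles[enumerateLibrary(fixAESpec)])))
})

test_that("single-variant tiles assemble to exactly the reference region", {
  wSpec <- librarySpec(fixScheme, "W")
  plan <- addTileVariants(tileRegion(fixRegion, fixScheme, 6), wSpec)
  pr <- enumerateAssemblyProducts(plan)
  expect_length(pr$products, 1)
  expect_identical(as.character(pr$products[[1]]), as.character(fixRegion))
})

test_that("a corrupted overlap variant is excluded and counted", {
  sch <- phosphositeScheme(c("s1", "s2"), c(3L, 16L), c("T", "S"),
                           c(1L, 20L))
  region <- paste(rep("GAT", 20), collapse = "")
  substr(region, 7, 12) <- "ACCCCT"
  substr(region, 46, 51) <- "TCCCCT"
  spec <- librarySpec(sch, c("A", "E"), referenceGenotype = "WW")
  plan <- addTileVariants(tileRegion(region, sch, 2, c(20, 20)), spec)
  ## corrupt the overlap flank of one variant of tile 1
  v <- as.character(plan@variants[[1]])
  substr(v[1], nchar(v[1]), nchar(v[1])) <- "N"
  plan@variants[[1]] <- Biostrings::DNAStringSet(v)
  pr <- enumerateAssemblyProducts(plan)
  expect_equal(pr$nImpossible, 2)   # bad variant x 2 tile-2 variants
  expect_length(pr$products, 2)
})
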